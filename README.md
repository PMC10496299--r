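# swcrtbalance

Sequence balancing and imbalance indices for stepped-wedge cluster
randomized trials (SWCRTs).

In an SWCRT every cluster (clinic, hospital, school) starts on control and
crosses over to the intervention at a randomized step. Because the
crossover *order* is the randomization, a site-level characteristic that
happens to track that order — say, all rural sites crossing over late — is
confounded with time, and when the treatment effect builds up gradually
after crossover (a "learning" effect) this sequential imbalance costs real
estimation efficiency. `swcrtbalance` is for trial statisticians designing
SWCRTs: it quantifies sequential imbalance, selects balanced randomization
sequences, and measures by simulation what imbalance costs.

## The indices

For the site covariate $Z_i$ in crossover order $i = 1..I$ (mid-ranked, so
ordinal covariates with ties are the normal case), all on $[0,1]$ with 0 =
perfectly balanced:

- **Linear** $i_L = |\rho_S(Z, \text{order})|$ — absolute Spearman
  correlation with crossover order;
- **Quadratic** $i_Q$ — absolute partial Spearman correlation with $t^2$
  controlling for $t$ (U-shaped patterns);
- **Seasonal** $i_S = \sqrt{(SSE_{red} - SSE_{full})/SSE_{red}}$ — partial
  determination of a season-indicator block (season
  $= ((t-1)\bmod c) + 1$ for cycle length $c$) given the linear trend;
- **Overall** $i_o = \sum_k w_k i_k$, $\sum w_k = 1$, combining several
  (covariate, trend) components; weights set directly or from importance
  ranks via $w_r \propto (K - r + 1)^p$.

The balancing strategy scores every candidate ordering by $i_o$ and picks
uniformly at random among the minimizers, preserving genuine
randomization.

## Worked example

```r
library(swcrtbalance)

# 1. How imbalanced can a 6-site trial get? Enumerate all unique designs
#    of a three-level covariate with two sites per level.
d6 <- index_distribution(c(0, 0, 1, 1, 2, 2))
d6
#> Imbalance index distribution (linear) over 90 unique designs
#>     0  16.7    33    50    67    83   100
#> 0.000 0.120 0.239 0.359 0.478 0.717 0.956

# 2. Pick a balanced ordering of six sites with two covariates, balancing
#    linear and seasonal (yearly cycle = 4 steps) trends, equal weights.
cov <- data.frame(rurality = c(1, 1, 2, 2, 3, 3),
                  income   = c(1, 2, 1, 1, 2, 2))
sp <- imbalance_spec(
  data.frame(covariate = rep(c("rurality", "income"), each = 2),
             trend = rep(c("linear", "seasonal"), 2)),
  cycle_length = 4)
sel <- select_balanced(cov, sp, labelled = TRUE, seed = 17)
#> i_o = 0.299 | ties = 8 | range = 0.299-0.882 over the 720 orderings

# 3. What does imbalance cost under a learning effect? Compare the
#    balanced (0th percentile) and fully imbalanced (100th) design pools.
for (p in list(sequences_at_percentile(d6, 0, seed = 3),
               sequences_at_percentile(d6, 100, seed = 3))) {
  scn <- swcrt_scenario(I = 6, z_pool = p$tie_set, beta1 = 0.5, icc = 0.01,
                        effect_type = "learning", replications = 500,
                        seed = 42)
  print(run_scenario(scn))
}
#> Scenario summary (K=500 converged, 0 failed): RRMSE 0.698, rel. mean bias 0.007
#> Scenario summary (K=500 converged, 0 failed): RRMSE 1.235, rel. mean bias 0.070
```

Reading the output: the 90 unique 6-site designs have median linear
imbalance 0.359, and a sixth of them score 0.717 or worse — unrestricted
randomization courts real imbalance. The two-covariate selection finds 8
orderings tied at the minimum $i_o = 0.299$ and randomly picks one. Under
a learning effect with effect size $\beta_1 = 0.5$ and control-condition
ICC 0.01, moving from fully balanced to fully imbalanced designs inflates
the relative RMSE of the treatment-effect estimate from about 0.70 to
about 1.24 — roughly a 75% efficiency loss — while the estimate stays
essentially unbiased (relative mean bias within Monte-Carlo error of
zero at $K = 500$ replicates).

Also available: `treatment_icc(0.5, c(0,0,1,1,2,2), 0.01)` returns the
analytic treatment-condition ICC (0.174 — it grows with the effect size
because the covariate scales the treatment effect), `simulate_trial()` /
`fit_constant()` / `fit_learning()` / `fit_cluster_time()` for single
datasets and fits, `swcrt_grid()` + `run_grid()` for the full 240-scenario
factorial, and `run_benchmark_suite()` to regenerate the deterministic
reference tables. A thin command-line front end with the same operations
lives at `inst/cli/swcrt.R` (subcommands `imbalance`, `enumerate`,
`select`, `simulate`, `fit`, `evaluate`, `fixtures`, `benchmark`).

See `vignettes/stepped-wedge-balancing.Rmd` for the model, its
assumptions, and the design choices (percentile conventions, sequence
pools, convergence policy).

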