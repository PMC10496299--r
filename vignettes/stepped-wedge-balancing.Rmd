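---
title: "Balancing site-level characteristics in stepped-wedge trials: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Balancing site-level characteristics in stepped-wedge trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swcrtbalance)
```

## The problem

In a stepped-wedge cluster randomized trial (SWCRT) every cluster starts on
the control condition and crosses over to the intervention at a randomized
step, one cluster per step in the canonical layout. Because the crossover
*order* is the randomization, a cluster-level characteristic that happens to
track the crossover order — all rural sites crossing late, say — is
confounded with time. With a treatment effect that grows after crossover (a
"learning" effect), such sequential imbalance inflates the variance of the
treatment-effect estimate substantially; with an immediate constant effect
the penalty is mild. This package quantifies that imbalance, selects
balanced randomization sequences, and provides the simulation machinery to
measure what imbalance costs in estimator efficiency.

## The imbalance indices

Let $Z_i$ be the covariate of the site in crossover position $i = 1..I$, and
let $R_i$ be its mid-rank (ties averaged, so ordinal covariates are the
normal case). All indices live on $[0, 1]$: 0 is perfectly balanced, 1
perfectly imbalanced.

* **Linear**: $i_L = |\rho_S(Z, \text{order})|$, the absolute Spearman
  correlation of the covariate with crossover order, computed as the Pearson
  correlation of mid-ranks with $1..I$. Identically $\sqrt{R^2}$ of the
  rank-on-time simple regression (`linear_index()` agrees with that form to
  $10^{-12}$ in the test suite).
* **Quadratic**: $i_Q$, the absolute partial Spearman correlation of the
  ranks with $t^2$ controlling for $t$: both are residualized on
  $\{1, t\}$ by least squares and the residuals correlated. Captures U- and
  inverted-U-shaped patterns invisible to $i_L$.
* **Seasonal**: $i_S = \sqrt{(SSE_{reduced} - SSE_{full})/SSE_{reduced}}$,
  the square root of the partial coefficient of determination for a block of
  season indicators added to the controlled trends (default: linear). Season
  membership uses the actual crossover time, $s(t) = ((t-1) \bmod c) + 1$
  for cycle length $c$ (e.g. $c = 4$ steps per year), season 1 as reference.
  The indicators enter as a block of $c - 1$ dummies; the index is computed
  from the SSE difference, not from any single dummy's partial correlation.
* **Overall**: $i_o = \sum_k w_k i_k$ with $\sum_k w_k = 1$, a weighted
  average over (covariate, trend) components. Weights come from the study
  team, directly or through the rank-to-weight rule
  $w_r \propto (K - r + 1)^p$ (`weights_from_ranks()`): $p = 0$ gives equal
  weights, larger $p$ concentrates weight on the top-ranked component.

Because everything is rank-based, all indices are invariant under strictly
increasing transforms of the covariate, and $i_L$ is symmetric under
reversal of the sequence.

Three conventions are worth making explicit, because the definitions leave
them open:

* **Time axis.** The correlation indices use crossover order $1..I$; the
  result is identical under the affine shift to calendar times
  $T_i = i + 1$, and the quadratic partial index is unchanged too because
  $\{T_i^2\}$ is an affine combination of $\{i^2, i\}$. The *seasonal*
  assignment, by contrast, genuinely depends on calendar time, so it uses
  the actual crossover times (default $T_i = i + 1$: all sites on control at
  $t = 1$).
* **Degenerate covariate.** A constant covariate admits no imbalance; its
  index is defined as 0 and flagged `degenerate`.
* **Small designs and the seasonal index.** With $I$ sites, a linear
  control, and cycle $c$, the full seasonal model spends $1 + 1 + (c - 1)$
  degrees of freedom. For $I = 6$, $c = 4$ that leaves one residual degree
  of freedom, so $i_S$ is near its ceiling for most 6-site sequences —
  small designs simply cannot distinguish much seasonal structure. The
  model errors out when the full model would be saturated, and drops
  rank-deficient season dummies (e.g. an unoccupied season) with a warning.

## Choosing a sequence

`index_distribution()` enumerates every distinct ordering of the covariate
multiset (a lexicographic next-permutation walk; the count is the
multinomial coefficient — 90 orderings for levels $\{0,0,1,1,2,2\}$, 34,650
for four sites per level) and summarizes the index distribution with
**nearest-rank (ceiling) percentiles**. Nearest-rank, rather than an
interpolating quantile, because the support is discrete with heavy ties and
every reported percentile should be a value an actual sequence attains —
which is what `sequences_at_percentile()` relies on when it draws uniformly
from the **exact tie set** at a percentile. Exhaustive enumeration is capped
at 12 sites (seconds of work); beyond that `sample_sequences()` draws
uniform random orderings.

`select_balanced()` is the recommendation in executable form: score every
candidate ordering by $i_o$ and pick uniformly at random among the
minimizers. Random tie-breaking is not a convenience — it is what keeps the
allocation a randomization. When the strict minimum leaves only one or two
options, `relax = TRUE` admits the second-lowest tier as well, trading a
little balance for allocation uncertainty. `labelled = TRUE` (default)
treats sites as distinguishable (all $I!$ orderings); the unlabelled mode
collapses duplicate covariate rows and scores each distinct design once.

The bundled `caribou_demo` configuration mirrors a six-site adolescent
mental-health SWCRT with rurality (three levels, two sites each) and
community income (two levels, three sites each) balanced on linear and
seasonal (cycle 4) trends with equal weights. The pairing of the two
covariates across sites is a synthetic choice — the real site table is not
public — selected so the covariates are moderately correlated (Spearman
$\rho = 0.41$), and the reported index range for this demo therefore
characterizes this synthetic configuration, not the original trial.

## The trial simulator

`simulate_trial()` draws cross-sectional SWCRT data: $J$ fresh participants
per cluster per timepoint (no participant followed twice), $T = I + 1$
timepoints so every cluster is on control at $t = 1$, one crossover per
step at $T_i = i + 1$, total $N = I J T$. The outcome for participant $j$
in cluster $i$ at time $t$ is

$$Y_{ijt} = \beta_0 + b_{0i} + \beta_1\, m_i(t)\, Z_i\, G_{it}
  + \boldsymbol\beta_2 \boldsymbol\tau + \varepsilon_{ijt},$$

with $G_{it} = \mathbb 1[t \ge T_i]$, $b_{0i} \sim N(0, \sigma_{re}^2)$,
$\varepsilon_{ijt} \sim N(0, \sigma^2)$, and $m_i(t) = 1$ for a constant
effect or the learning ramp $m_i(t) = (t - T_i + 1)/(T - 1)$ after
crossover (zero before). The ramp rises by $1/(T-1)$ per step; only the
first cluster to cross over reaches the full effect by the final step. The
treatment term is *scaled by the covariate* $Z_i$ — that is the whole
point: between-cluster effect heterogeneity is what imbalance interacts
with. Time fixed effects $\boldsymbol\beta_2$ are generated as zero but the
estimation model always includes categorical time, mirroring field
practice. Two sensitivity variants add a cluster random slope
$b_{1i} \sim N(0, sd_{b1}^2)$ on the treatment term (default
$sd_{b1} = 0.1\beta_1$) or a cluster-by-time intercept
$b_{0it} \sim N(0, 0.10^2)$.

Parameter conventions: $\sigma = 1$ throughout, so effect sizes
$\beta_1 \in \{0.2, 0.5, 1.0\}$ are in residual-SD units; the
control-condition ICC $\in \{0.01, 0.10\}$ maps to the random-intercept SD
via $\sigma_{re} = \sigma\sqrt{icc/(1-icc)}$. Under treatment the
between-cluster variance gains the spread of $\beta_1 Z_i$, so the
treatment-condition ICC is
$(\sigma_{re}^2 + \beta_1^2 s_Z^2) / (\sigma_{re}^2 + \beta_1^2 s_Z^2 + \sigma^2)$
with $s_Z^2$ the $I-1$ sample variance of $Z$ (`treatment_icc()`) — an ICC
that grows with the effect size, unlike the conventional fixed-size
random-effect assumption.

Random draws follow a fixed order (cluster intercepts, cluster slopes,
cluster-by-time intercepts, residuals) under one seeded stream per
replicate, so every dataset is exactly reproducible from its seed.

## Estimation

The analysis model (`fit_constant()` / `fit_learning()`) deliberately does
*not* use $Z_i$ — site characteristics may be unknown or misclassified at
analysis time. It fits, by REML via `lme4`,

$$Y_{ijt} = \beta_0 + b_{0i} + (\beta_1 + b_{1i}) X_{it}
  + \boldsymbol\beta_2 \boldsymbol\tau + \varepsilon_{ijt},$$

where $X$ is the treatment indicator (constant effect) or the known
exposure ramp (learning effect), with the random intercept and random slope
independent — matching the generative independence of $b_{0i}$ and
$b_{1i}$ and helping convergence at $I = 6$. The random slope absorbs the
$Z$-driven heterogeneity and $\hat\beta_1$ estimates the sample-average
treatment effect, $\beta_1 \bar Z$. Categorical time enters with $T$
observed levels, $t = 1$ as reference. `fit_cluster_time()` adds a
cluster-by-time random intercept for data with that variance component.

Design choices worth noting:

* **Ramp as known exposure.** Under the learning effect the treatment
  regressor is the known ramp $f_i(t) G_{it}$, so $\hat\beta_1$ targets the
  full effect $\beta_1$. This is the only reading consistent with near-zero
  bias under learning-effect scenarios; a misspecified analysis that fits
  the plain indicator to learning data is available by calling
  `fit_constant()` on such data, for exploration.
* **Convergence policy.** Fits that raise errors or whose optimizer fails
  are returned with `converged = FALSE` (never an exception), counted, and
  excluded from metrics; a scenario with more than 20% failures is flagged
  unreliable. Singular/boundary fits (a variance component estimated at
  zero) are routine with $I = 6$ and small ICC; they are kept and flagged,
  not retried with alternative structures. The nlopt status
  "roundoff-limited" is accepted as converged: it is returned at a usable
  optimum, characteristically on near-degenerate (e.g. almost noise-free)
  data.
* **Speed.** The default `lmerControl(calc.derivs = FALSE)` skips the
  post-hoc derivative check, roughly halving the per-fit cost in
  simulation loops; pass your own control to restore it.
* **Noise-free recovery is approximate.** With $Z$ varying, the
  fixed-slope estimate is an information-weighted mean across clusters, and
  later-crossing clusters contribute fewer treated cells; in the exact
  noise-free limit $\hat\beta_1$ recovers $\beta_1 \bar Z$ to about 1%,
  not to machine precision. Tests assert 2%.

## Monte-Carlo evaluation

`run_scenario()` reports the relative root mean square error
$\mathrm{RRMSE} = \sqrt{K^{-1}\sum_k (\hat\beta_{1,k} - \beta_1)^2}/\beta_1$
and the relative mean bias
$|K^{-1}\sum_k (\hat\beta_{1,k} - \beta_1)|/\beta_1$ (absolute value of
the *mean* deviation, so it is always $\le$ RRMSE). `swcrt_grid()` builds
the full factorial — sites $\{6, 12\}$ × $J$ $\{10, 20\}$ × effect type ×
$\beta_1$ $\{0.2, 0.5, 1.0\}$ × ICC $\{0.01, 0.10\}$ × imbalance percentile
$\{0, 33, 67, 83, 100\}$, 240 scenarios — drawing the percentile-targeted
sequence for each (sites, percentile) pair reproducibly from the master
seed. (The middle percentile is labelled 66th in some summaries of this
design family; the nearest-rank 67th-percentile value is what those
summaries print, and is what the grid uses.)

Replication counts are presets, not different code paths: 500 for quick
checks, 2,000 for the package's own acceptance runs, 10,000 for full-scale
replication. At $K = 2000$ the Monte-Carlo standard error of an RRMSE
around 0.74 is roughly $0.74/\sqrt{2K} \approx 0.012$, which sets the
tolerances used in the test suite. The test suite evaluates eight grid
scenarios at $K = 2000$ (six-site cells plus one $J = 20$ and one 12-site
cell) and reuses the same runs for the RRMSE reproduction, bias, and
monotonicity checks — about 12 minutes of fitting on one core; the full
240-scenario grid at $K = 10{,}000$ is a `run_grid()` call away but is
multi-day desk work.

### Evaluating an imbalance *level*, not one ordering

The design choice that matters most here: a percentile-defined scenario
re-draws its covariate sequence **per replicate**, uniformly from the exact
tie set at that percentile (`z_pool`). The alternative — freezing a single
ordering — evaluates one arbitrary member of the constraint set, and it is
not what a constrained randomization strategy produces. The difference is
not cosmetic. With a frozen fully imbalanced ordering, the cluster-specific
treatment effects are deterministically aligned with crossover order, and
*every* information-weighted mixed-model estimate of the learning effect is
structurally biased: with variance components fixed at their true values,
the GLS expectation of $\hat\beta_1$ is about $0.04$ for the sorted
six-site sequence (true value $0.5$) and about $0.44$ for one balanced
ordering. Averaged over the tie set — which is closed under sequence
reversal — these orientation biases cancel, the estimator is nearly
unbiased, and the orientation spread appears where it belongs: in the
RRMSE, which rises steeply with the imbalance level under a learning
effect. "The" fully balanced design is likewise not unique (14 of the 90
six-site designs have $i_L = 0$, differing in quadratic and seasonal
structure); the pool averages over them too. Simulating one *specific*
trial design with a fixed, known sequence remains the default when
`z_sequence` is given without a pool.

## What the simulator does and does not emulate

The generator reproduces the study conditions this methodology was
evaluated under: Gaussian outcomes, cross-sectional sampling, one cluster
per step, a three-level ordinal covariate with equal site counts per level,
effect heterogeneity proportional to that covariate, and no secular trend
in generation. Passing tests therefore demonstrate correctness of the
machinery and reproduction of those conditions — not that the efficiency
numbers transfer to binary outcomes, longitudinal follow-up, multiple
clusters per step, continuous covariates with milder between-site
differences, or real secular trends. The imbalance indices themselves are
design-stage quantities and apply to any SWCRT; only the simulation
results are conditional on the generative model.

## Known limitations

* Seasonal indices on small designs are nearly saturated (see above); with
  6 sites and cycle 4 they mostly separate "a season is empty" from "it is
  not".
* The relative metrics are undefined at $\beta_1 = 0$; null-effect
  scenarios need absolute metrics, which the summaries expose via the raw
  replicate estimates.
* Because $\hat\beta_1$ estimates the sample-average effect
  $\beta_1 \bar Z$, the RRMSE and bias summaries compare it against
  $\beta_1$ and are meaningful when the covariate coding has $\bar Z = 1$ —
  true for the canonical $\{0, 1, 2\}$ coding with equal site counts. With
  another coding, rescale $Z$ (the indices are rank-based and unaffected)
  or interpret the estimand as $\beta_1 \bar Z$.
* No inferential test accompanies the indices — they are descriptive
  design diagnostics, and no standard-error calibration study is included
  (point estimation only).
* Crossover schedules are equally spaced; continuous-time or
  multiple-clusters-per-step designs are out of scope.
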