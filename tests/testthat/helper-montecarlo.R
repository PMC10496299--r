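# Shared Monte-Carlo runs for the heavyweight RRMSE / bias checks.
# Built lazily, once per test session, and reused by every block that needs
# them. Scenario seeds and the percentile-draw seeds are fixed constants.

.mc_cache <- new.env(parent = emptyenv())

mc_sequences <- function() {
  if (is.null(.mc_cache$seqs)) {
    dist6 <- index_distribution(c(0, 0, 1, 1, 2, 2))
    dist12 <- index_distribution(rep(0:2, each = 4))
    .mc_cache$seqs <- list(
      bal6 = sequences_at_percentile(dist6, 0, seed = 11)$tie_set,
      imb6 = sequences_at_percentile(dist6, 100, seed = 13)$tie_set,
      bal12 = sequences_at_percentile(dist12, 0, seed = 12)$tie_set)
  }
  .mc_cache$seqs
}

mc_scenarios <- function(K = 2000) {
  sq <- mc_sequences()
  scn <- function(pool, beta1, icc, J, effect, seed, I = length(pool[[1]])) {
    swcrt_scenario(I = I, z_pool = pool, beta1 = beta1, icc = icc, J = J,
                   effect_type = effect, replications = K, seed = seed)
  }
  list(
    const_bal    = scn(sq$bal6, 0.5, 0.01, 10, "constant", 101),
    learn_bal    = scn(sq$bal6, 0.5, 0.01, 10, "learning", 102),
    learn_imb    = scn(sq$imb6, 0.5, 0.01, 10, "learning", 103),
    const_b02    = scn(sq$bal6, 0.2, 0.01, 10, "constant", 104),
    const_b10    = scn(sq$bal6, 1.0, 0.01, 10, "constant", 105),
    learn_J20    = scn(sq$bal6, 0.5, 0.01, 20, "learning", 106),
    learn_I12    = scn(sq$bal12, 0.5, 0.01, 10, "learning", 107),
    learn_icc10  = scn(sq$bal6, 0.5, 0.10, 10, "learning", 108))
}

mc_summaries <- function() {
  if (is.null(.mc_cache$summaries)) {
    scns <- mc_scenarios()
    .mc_cache$summaries <- lapply(scns, run_scenario)
  }
  .mc_cache$summaries
}
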