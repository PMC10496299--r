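#' Relative root mean square error of treatment-effect estimates
#'
#' `RRMSE = sqrt(mean((beta1_hat_k - beta1)^2)) / beta1` — root mean square
#' error of the Monte-Carlo estimates relative to the true effect, the
#' primary efficiency metric for comparing designs.
#'
#' @param estimates Numeric vector of replicate estimates.
#' @param beta1 True (nonzero) effect size.
#' @return Non-negative scalar.
#' @examples
#' rrmse(c(0.4, 0.6), 0.5)  # 0.2
#' @export
rrmse <- function(estimates, beta1) {
  check_metric_args(estimates, beta1)
  sqrt(mean((estimates - beta1)^2)) / beta1
}

#' Relative mean bias of treatment-effect estimates
#'
#' `|mean(beta1_hat_k - beta1)| / beta1` — the absolute mean deviation of
#' the estimates from the true effect relative to the true effect, the
#' secondary (unbiasedness) metric. By Jensen's inequality it never exceeds
#' the [rrmse()] of the same estimates.
#'
#' @inheritParams rrmse
#' @return Non-negative scalar.
#' @examples
#' rel_mean_bias(c(0.4, 0.6), 0.5)  # 0: deviations cancel
#' @export
rel_mean_bias <- function(estimates, beta1) {
  check_metric_args(estimates, beta1)
  abs(mean(estimates - beta1)) / beta1
}

check_metric_args <- function(estimates, beta1) {
  if (!length(estimates)) stop("empty estimate list", call. = FALSE)
  if (beta1 == 0) {
    stop("relative metrics are undefined for beta1 = 0", call. = FALSE)
  }
  invisible(TRUE)
}

#' Monte-Carlo evaluation of one scenario
#'
#' Simulates `K` independent trials under the scenario, fits the matching
#' analysis model to each ([fit_constant()], [fit_learning()], or
#' [fit_cluster_time()]), and summarizes the replicate estimates with
#' [rrmse()] and [rel_mean_bias()]. Per-replicate seeds are drawn once from
#' the scenario's master seed, so results are reproducible and replicates
#' could be distributed across workers.
#'
#' Non-converged fits are excluded from the metrics and counted; a summary
#' with more than 20% failures is flagged unreliable.
#'
#' @param scn A [swcrt_scenario()].
#' @param K Number of replications; default `scn$replications`.
#' @param progress Print a progress line every 500 replicates to stderr?
#' @return An object of class `swcrt_scenario_summary`: the scenario,
#'   `estimates` (converged replicates), `rrmse`, `rel_mean_bias`,
#'   `n_converged`, `n_failed`, `n_singular`, `unreliable`, `runtime`
#'   (seconds).
#' @export
run_scenario <- function(scn, K = scn$replications, progress = FALSE) {
  stopifnot(inherits(scn, "swcrt_scenario"))
  t0 <- proc.time()[["elapsed"]]
  set.seed(scn$seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, K)
  fitter <- fitter_for(scn)
  est <- rep(NA_real_, K)
  singular <- logical(K)
  for (k in seq_len(K)) {
    d <- simulate_trial(scn, seed = rep_seeds[k])
    f <- fitter(d)
    if (f$converged) {
      est[k] <- f$beta1_hat
      singular[k] <- isTRUE(f$singular)
    }
    if (progress && k %% 500 == 0) {
      message("  replicate ", k, "/", K)
    }
  }
  ok <- !is.na(est)
  n_failed <- sum(!ok)
  structure(list(
    scenario = scn,
    estimates = est[ok],
    rrmse = rrmse(est[ok], scn$beta1),
    rel_mean_bias = rel_mean_bias(est[ok], scn$beta1),
    n_converged = sum(ok),
    n_failed = n_failed,
    n_singular = sum(singular[ok]),
    unreliable = n_failed > 0.2 * K,
    runtime = proc.time()[["elapsed"]] - t0
  ), class = "swcrt_scenario_summary")
}

#' @export
print.swcrt_scenario_summary <- function(x, ...) {
  cat(sprintf(
    "Scenario summary (K=%d converged, %d failed%s): RRMSE %.3f, rel. mean bias %.3f\n",
    x$n_converged, x$n_failed,
    if (x$unreliable) ", UNRELIABLE" else "", x$rrmse, x$rel_mean_bias))
  invisible(x)
}

#' Build the factorial scenario grid
#'
#' Crosses number of sites (with the canonical three-level covariate, an
#' equal number of sites per level), per-cell sample size, effect type,
#' effect size, control-condition ICC, and imbalance percentile into a list
#' of scenarios — 240 with the defaults. For each (sites, percentile) pair
#' a covariate sequence is drawn from the exact percentile tie set of the
#' enumerated linear-index distribution, reproducibly from the master seed.
#'
#' @param sites Cluster counts; each must be divisible by 3. Default
#'   `c(6, 12)`.
#' @param J Per-cell sample sizes. Default `c(10, 20)`.
#' @param effect_type Effect types. Default both.
#' @param beta1 Effect sizes. Default `c(0.2, 0.5, 1.0)`.
#' @param icc Control ICCs. Default `c(0.01, 0.10)`.
#' @param percentiles Imbalance percentiles of the enumerated distribution.
#'   Default `c(0, 33, 67, 83, 100)`.
#' @param variant Model variant applied to every scenario. Default
#'   `"base"`.
#' @param replications K per scenario. Default 500.
#' @param seed Master seed; drives sequence selection and per-scenario
#'   seeds. Default 2023.
#' Each percentile cell carries the full tie set of sequences at its index
#' value as `z_pool`, so every replicate re-randomizes the site order
#' within the imbalance level — the randomization distribution the design
#' strategy actually induces.
#'
#' @return List of [swcrt_scenario()] objects, each carrying `percentile`
#'   and `imbalance_index` fields.
#' @examples
#' length(swcrt_grid())  # 240
#' @export
swcrt_grid <- function(sites = c(6, 12), J = c(10, 20),
                       effect_type = c("constant", "learning"),
                       beta1 = c(0.2, 0.5, 1.0), icc = c(0.01, 0.10),
                       percentiles = c(0, 33, 67, 83, 100),
                       variant = "base", replications = 500, seed = 2023) {
  stopifnot(all(sites %% 3 == 0))
  set.seed(seed)
  seqs <- list()
  for (s in sites) {
    dist <- index_distribution(rep(0:2, each = s / 3))
    for (p in percentiles) {
      seqs[[paste(s, p)]] <- sequences_at_percentile(dist, p)
    }
  }
  cells <- expand.grid(icc = icc, sites = sites, J = J,
                       percentile = percentiles, effect_type = effect_type,
                       beta1 = beta1, stringsAsFactors = FALSE)
  scn_seeds <- sample.int(.Machine$integer.max - 1L, nrow(cells))
  out <- vector("list", nrow(cells))
  for (r in seq_len(nrow(cells))) {
    sel <- seqs[[paste(cells$sites[r], cells$percentile[r])]]
    scn <- swcrt_scenario(
      I = cells$sites[r], z_sequence = sel$sequence, z_pool = sel$tie_set,
      beta1 = cells$beta1[r], icc = cells$icc[r], J = cells$J[r],
      effect_type = cells$effect_type[r], variant = variant,
      replications = replications, seed = scn_seeds[r])
    scn$percentile <- cells$percentile[r]
    scn$imbalance_index <- sel$value
    out[[r]] <- scn
  }
  out
}

#' Run a scenario grid and tabulate the metrics
#'
#' Evaluates each scenario with [run_scenario()] and returns one row per
#' scenario in a long-format table shaped for CSV export.
#'
#' @param grid List of scenarios, e.g. from [swcrt_grid()].
#' @param K Optional override of each scenario's replication count.
#' @param progress Log per-scenario progress to stderr? Default `TRUE`.
#' @return data.frame with columns `icc`, `sites`, `J`, `percentile`,
#'   `imbalance_index`, `effect_type`, `beta1`, `variant`, `K`, `rrmse`,
#'   `rel_mean_bias`, `n_failed`.
#' @export
run_grid <- function(grid, K = NULL, progress = TRUE) {
  rows <- vector("list", length(grid))
  for (r in seq_along(grid)) {
    scn <- grid[[r]]
    if (progress) {
      message(sprintf("scenario %d/%d: I=%d J=%d %s beta1=%g icc=%g p=%s",
                      r, length(grid), scn$I, scn$J, scn$effect_type,
                      scn$beta1, scn$icc,
                      if (is.null(scn$percentile)) "-" else scn$percentile))
    }
    s <- run_scenario(scn, K = if (is.null(K)) scn$replications else K)
    if (progress && s$n_failed > 0) {
      message("  ", s$n_failed, " non-converged replicate(s) excluded")
    }
    rows[[r]] <- data.frame(
      icc = scn$icc, sites = scn$I, J = scn$J,
      percentile = if (is.null(scn$percentile)) NA else scn$percentile,
      imbalance_index = if (is.null(scn$imbalance_index)) NA
                        else scn$imbalance_index,
      effect_type = scn$effect_type, beta1 = scn$beta1,
      variant = scn$variant, K = s$n_converged + s$n_failed,
      rrmse = s$rrmse, rel_mean_bias = s$rel_mean_bias,
      n_failed = s$n_failed)
  }
  do.call(rbind, rows)
}
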