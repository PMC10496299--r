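#' Between-cluster SD implied by an intra-cluster correlation
#'
#' Inverts the ICC definition `icc = sigma_re^2 / (sigma_re^2 + sigma^2)`
#' to the random-intercept SD `sigma_re = sigma * sqrt(icc / (1 - icc))`.
#'
#' @param icc Control-condition intra-cluster correlation, in \[0, 1).
#' @param sigma Residual SD (default 1).
#' @return The between-cluster SD.
#' @examples
#' sigma_re_from_icc(0.01)  # 0.1005
#' sigma_re_from_icc(0.10)  # 1/3
#' @export
sigma_re_from_icc <- function(icc, sigma = 1) {
  if (icc < 0 || icc >= 1) stop("'icc' must be in [0, 1)", call. = FALSE)
  sigma * sqrt(icc / (1 - icc))
}

#' Learning-effect exposure ramp
#'
#' Fraction of the full treatment effect realized by a cluster at time t
#' under a gradual "learning" effect: 0 before crossover, then
#' `(t - T_i + 1) / (T - 1)` from crossover onward, rising by `1 / (T - 1)`
#' per step. The first cluster to cross over (T_i = 2) starts at
#' `1 / (T - 1)` and reaches exactly 1 at the final step t = T; clusters
#' crossing later never reach the full effect within the study.
#'
#' @param t Timepoint(s), 1..T (vectorized).
#' @param T_i Crossover time of the cluster.
#' @param T Total number of timepoints (>= 2).
#' @return Ramp value(s) in \[0, 1\].
#' @examples
#' learning_ramp(2, T_i = 2, T = 7)  # 1/6
#' learning_ramp(7, T_i = 2, T = 7)  # 1
#' @export
learning_ramp <- function(t, T_i, T) {
  if (T < 2) stop("'T' must be >= 2", call. = FALSE)
  ifelse(t < T_i, 0, (t - T_i + 1) / (T - 1))
}

#' Define a simulation scenario for a stepped-wedge trial
#'
#' Full generative parameterization of one cross-sectional SWCRT scenario:
#' I clusters crossing over one per step at t = 2..T (so T = I + 1 keeps
#' every cluster on control at t = 1), J new participants per cluster per
#' timepoint, a cluster-level ordinal covariate Z that scales the treatment
#' effect, and Gaussian cluster and residual variation.
#'
#' The outcome model is
#' `Y_ijt = beta0 + b_0i + beta1 * m_i(t) * Z_i * Group_it + beta2 * tau_t + e_ijt`
#' where `m_i(t)` is 1 under a constant effect or the [learning_ramp()]
#' under a learning effect. Sensitivity variants add a cluster-level random
#' slope `b_1i` on the treatment term (`variant = "random_slope"`) or a
#' cluster-by-time random intercept `b_0it` (`variant = "cluster_time"`).
#'
#' @param I Number of clusters.
#' @param z_sequence Covariate values in crossover order (length I), a
#'   numeric vector or [site_sequence()].
#' @param beta1 Full treatment effect size.
#' @param icc Control-condition ICC (maps to the random-intercept SD via
#'   [sigma_re_from_icc()]).
#' @param T Number of timepoints; default `I + 1`.
#' @param J Participants per cluster per timepoint; default 10.
#' @param beta0 Intercept; default 0.
#' @param beta2 Time fixed effects for t = 2..T (t = 1 is reference);
#'   scalar 0 or vector of length `T - 1`. Default 0 (the estimation model
#'   still includes categorical time).
#' @param sigma Residual SD; default 1.
#' @param effect_type `"constant"` or `"learning"`.
#' @param variant `"base"`, `"random_slope"`, or `"cluster_time"`.
#' @param sd_b1 SD of the cluster random slope (variant `"random_slope"`);
#'   default `0.1 * beta1`.
#' @param sd_b0it SD of the cluster-by-time random intercept (variant
#'   `"cluster_time"`); default 0.10.
#' @param z_pool Optional list of covariate sequences (each length I). When
#'   supplied, every simulated replicate re-draws its sequence uniformly
#'   from this pool — the randomization distribution of a design
#'   constrained to an imbalance level (e.g. the `tie_set` from
#'   [sequences_at_percentile()]) rather than one frozen ordering. Tie sets
#'   are closed under sequence reversal, so estimation biases of opposite
#'   orientations cancel across replicates while the orientation spread
#'   shows up in the RRMSE, which is how a constrained randomization
#'   strategy is properly evaluated.
#' @param replications Monte-Carlo replications K for [run_scenario()];
#'   default 500.
#' @param seed Integer master seed; default 2023.
#' @return An object of class `swcrt_scenario`.
#' @examples
#' swcrt_scenario(I = 6, z_sequence = c(0, 0, 1, 1, 2, 2),
#'                beta1 = 0.5, icc = 0.01)
#' @export
swcrt_scenario <- function(I, z_sequence, beta1, icc, T = I + 1, J = 10,
                           beta0 = 0, beta2 = 0, sigma = 1,
                           effect_type = c("constant", "learning"),
                           variant = c("base", "random_slope", "cluster_time"),
                           sd_b1 = 0.1 * beta1, sd_b0it = 0.10,
                           z_pool = NULL, replications = 500, seed = 2023) {
  effect_type <- match.arg(effect_type)
  variant <- match.arg(variant)
  if (!is.null(z_pool)) {
    if (!is.list(z_pool) || !length(z_pool) ||
        !all(lengths(z_pool) == I)) {
      stop("'z_pool' must be a non-empty list of length-I sequences",
           call. = FALSE)
    }
    z_pool <- lapply(z_pool, as.numeric)
  }
  if (missing(z_sequence) && !is.null(z_pool)) z_sequence <- z_pool[[1]]
  z <- as_site_sequence(z_sequence)
  if (length(z$values) != I) {
    stop("'z_sequence' must have one value per cluster", call. = FALSE)
  }
  if (T < 2) stop("'T' must be >= 2", call. = FALSE)
  if (icc < 0 || icc >= 1) stop("'icc' must be in [0, 1)", call. = FALSE)
  if (length(beta2) == 1) beta2 <- rep(beta2, T - 1)
  if (length(beta2) != T - 1) {
    stop("'beta2' must be scalar or length T - 1", call. = FALSE)
  }
  structure(list(I = I, T = T, J = J, beta0 = beta0, beta1 = beta1,
                 beta2 = beta2, icc = icc, sigma = sigma,
                 effect_type = effect_type, variant = variant,
                 sd_b1 = sd_b1, sd_b0it = sd_b0it, z_sequence = z,
                 z_pool = z_pool,
                 replications = replications, seed = as.integer(seed)),
            class = "swcrt_scenario")
}

#' @export
print.swcrt_scenario <- function(x, ...) {
  cat(sprintf(
    "SWCRT scenario: I=%d, T=%d, J=%d (N=%d), beta1=%g, ICC=%g,\n  %s effect, variant '%s', Z = {%s}, K=%d, seed=%d\n",
    x$I, x$T, x$J, x$I * x$J * x$T, x$beta1, x$icc, x$effect_type, x$variant,
    paste(x$z_sequence$values, collapse = ","), x$replications, x$seed))
  invisible(x)
}

#' Simulate one cross-sectional stepped-wedge trial
#'
#' Draws a complete long-format trial dataset under a scenario's generative
#' model. Cluster k (in crossover order) switches to the intervention at
#' `T_k = k + 1`; each (cluster, time) cell holds J fresh participants.
#' Random draws are made in a fixed order — the covariate sequence (when
#' the scenario carries a `z_pool`), then cluster intercepts, then cluster
#' random slopes (if any), then cluster-by-time intercepts (if any), then
#' residuals — so a seeded generator reproduces the dataset exactly. The
#' sequence actually used is attached as attribute `z_sequence`.
#'
#' @param scn A [swcrt_scenario()].
#' @param seed Optional integer seed (sets the RNG before drawing);
#'   default `NULL` uses the current RNG state.
#' @return A data.frame with one row per participant: `cluster`, `time`,
#'   `participant` (all 1-based), `group` (0/1 treatment indicator),
#'   `ramp` (exposure fraction, 0 wherever `group == 0`), and outcome `y`.
#' @examples
#' scn <- swcrt_scenario(I = 6, z_sequence = c(0, 1, 2, 2, 1, 0),
#'                       beta1 = 0.5, icc = 0.01)
#' d <- simulate_trial(scn, seed = 1)
#' nrow(d)  # 420 = I * J * T
#' @export
simulate_trial <- function(scn, seed = NULL) {
  stopifnot(inherits(scn, "swcrt_scenario"))
  if (!is.null(seed)) set.seed(seed)
  I <- scn$I; T <- scn$T; J <- scn$J
  Z <- if (!is.null(scn$z_pool)) {
    scn$z_pool[[sample.int(length(scn$z_pool), 1)]]
  } else {
    scn$z_sequence$values
  }
  T_i <- scn$z_sequence$crossover_times
  sre <- sigma_re_from_icc(scn$icc, scn$sigma)

  b0 <- stats::rnorm(I, 0, sre)
  b1 <- if (scn$variant == "random_slope") stats::rnorm(I, 0, scn$sd_b1) else rep(0, I)
  b0it <- if (scn$variant == "cluster_time") {
    matrix(stats::rnorm(I * T, 0, scn$sd_b0it), nrow = I)
  } else matrix(0, I, T)

  d <- expand.grid(participant = seq_len(J), time = seq_len(T),
                   cluster = seq_len(I))[, c("cluster", "time", "participant")]
  i <- d$cluster; t <- d$time
  group <- as.integer(t >= T_i[i])
  ramp <- learning_ramp(t, T_i[i], T) * group
  mult <- if (scn$effect_type == "learning") ramp else group
  time_fe <- c(0, scn$beta2)[t]
  eps <- stats::rnorm(nrow(d), 0, scn$sigma)
  d$group <- group
  d$ramp <- ramp
  d$y <- scn$beta0 + b0[i] + (scn$beta1 + b1[i]) * mult * Z[i] +
    b0it[cbind(i, t)] + time_fe + eps
  attr(d, "z_sequence") <- Z
  d
}

#' Intra-cluster correlation under the treatment condition
#'
#' Under the constant-effect model the treatment contribution
#' `beta1 * Z_i` varies between clusters, so the between-cluster variance
#' under treatment is the control-condition `sigma_re^2` plus the sample
#' variance (denominator I - 1) of `beta1 * Z_i`:
#' `icc_trt = (sigma_re^2 + beta1^2 s_Z^2) / (sigma_re^2 + beta1^2 s_Z^2 + sigma^2)`.
#' Unlike the conventional fixed-size random-effect assumption, this ICC
#' grows with the effect size.
#'
#' @param beta1 Treatment effect size.
#' @param z Cluster-level covariate values (length >= 2).
#' @param icc_control Control-condition ICC.
#' @param sigma Residual SD; default 1.
#' @return The treatment-condition ICC.
#' @examples
#' treatment_icc(0.5, c(0, 0, 1, 1, 2, 2), 0.01)  # 0.174
#' @export
treatment_icc <- function(beta1, z, icc_control, sigma = 1) {
  z <- if (inherits(z, "swcrt_site_sequence")) z$values else as.numeric(z)
  if (length(z) < 2) stop("need at least 2 clusters", call. = FALSE)
  s2_re <- sigma_re_from_icc(icc_control, sigma)^2
  between <- s2_re + beta1^2 * stats::var(z)
  between / (between + sigma^2)
}

#' Write / read a simulated trial dataset as CSV
#'
#' Plain-CSV interchange for long-format trial data with columns
#' `cluster,time,participant,group,ramp,y` (1-based indices, header
#' required).
#'
#' @param data Trial data.frame from [simulate_trial()].
#' @param path File path.
#' @return `read_trial()` returns the data.frame; `write_trial()` its path,
#'   invisibly.
#' @export
write_trial <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial
#' @export
read_trial <- function(path) {
  d <- utils::read.csv(path)
  need <- c("cluster", "time", "participant", "group", "y")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop("trial CSV missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  d
}
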