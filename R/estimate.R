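# Shared lmer wrapper: builds the formula, traps errors and optimizer
# failures, and packages the result. Singular (boundary) fits are kept and
# flagged, not discarded: with few clusters and small variance components
# they are routine and their fixed-effect estimates remain valid.
fit_lmm <- function(data, treatment_var, cluster_time = FALSE, reml = TRUE,
                    control = lme4::lmerControl(calc.derivs = FALSE)) {
  if (!treatment_var %in% names(data)) {
    stop("data has no '", treatment_var, "' column", call. = FALSE)
  }
  if (length(unique(data$cluster)) < 2) {
    stop("need at least 2 clusters", call. = FALSE)
  }
  out <- list(beta1_hat = NA_real_, fixed_effects = NULL,
              variance_components = NULL, converged = FALSE,
              singular = NA, fit_log = character(0))
  if (all(data[[treatment_var]] == 0)) {
    out$fit_log <- "treatment regressor identically zero: effect inestimable"
    return(structure(out, class = "swcrt_fit"))
  }
  data$time_f <- factor(data$time)
  rhs <- paste0(treatment_var, " + time_f + (1 | cluster) + (0 + ",
                treatment_var, " | cluster)")
  if (cluster_time) rhs <- paste0(rhs, " + (1 | cluster:time_f)")
  f <- stats::as.formula(paste("y ~", rhs))
  warns <- character(0)
  fit <- withCallingHandlers(
    tryCatch(lme4::lmer(f, data = data, REML = reml, control = control),
             error = function(e) e),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      warns <<- c(warns, sub("\n$", "", conditionMessage(m)))
      invokeRestart("muffleMessage")
    })
  out$fit_log <- warns
  if (inherits(fit, "error")) {
    out$fit_log <- c(out$fit_log, conditionMessage(fit))
    return(structure(out, class = "swcrt_fit"))
  }
  # nlopt code -4 (roundoff-limited) is returned at a usable optimum on
  # near-degenerate (e.g. noise-free) data; other nonzero codes are failures
  opt_code <- fit@optinfo$conv$opt
  conv_fail <- any(grepl("failed to converge", warns, ignore.case = TRUE)) ||
    (!is.null(opt_code) && !(opt_code %in% c(0, -4)))
  fe <- lme4::fixef(fit)
  vc <- as.data.frame(lme4::VarCorr(fit))
  vcomp <- stats::setNames(vc$vcov, paste0(vc$grp,
                                           ifelse(is.na(vc$var1), "",
                                                  paste0(".", vc$var1))))
  out$beta1_hat <- unname(fe[[treatment_var]])
  out$fixed_effects <- fe
  out$variance_components <- vcomp
  out$singular <- lme4::isSingular(fit)
  out$converged <- !conv_fail && is.finite(out$beta1_hat)
  structure(out, class = "swcrt_fit")
}

#' @export
print.swcrt_fit <- function(x, ...) {
  cat("SWCRT mixed-model fit\n")
  cat("  beta1_hat:", format(x$beta1_hat), "\n")
  cat("  converged:", x$converged,
      if (isTRUE(x$singular)) "(singular/boundary fit)" else "", "\n")
  if (length(x$fit_log)) cat("  log:", paste(x$fit_log, collapse = "; "), "\n")
  invisible(x)
}

#' Estimate the treatment effect from stepped-wedge trial data
#'
#' Fits the analysis model
#' `Y = beta0 + b_0i + (beta1 + b_1i) * X + beta2 * tau + e`
#' by REML (via \pkg{lme4}), where X is the treatment indicator `group`
#' (`fit_constant`) or the known exposure ramp `ramp` (`fit_learning`), with
#' a cluster random intercept, an independent cluster random slope on X, and
#' categorical time fixed effects (T levels, t = 1 reference). The model
#' needs no knowledge of the cluster-level covariate: the random slope
#' absorbs between-cluster effect heterogeneity and `beta1_hat` estimates
#' the sample-average treatment effect (`beta1 * mean(Z)` under the
#' generative model).
#'
#' `fit_cluster_time` adds a cluster-by-time random intercept, the matching
#' analysis model for data generated with cluster-by-time variation.
#'
#' Fits that error out or whose optimizer reports failure are returned with
#' `converged = FALSE` (never an exception) so simulation loops can count
#' and exclude them. Singular/boundary fits are flagged via `singular` but
#' kept.
#'
#' @param data Long-format trial data.frame with columns `cluster`, `time`,
#'   `group`, `y` (and `ramp` for the learning model).
#' @param reml Use REML (default) or ML.
#' @param control An [lme4::lmerControl()]; the default disables derivative
#'   re-checking for speed in large simulation loops.
#' @return An object of class `swcrt_fit`: `beta1_hat`, `fixed_effects`,
#'   `variance_components` (named variances), `converged`, `singular`,
#'   `fit_log`.
#' @examples
#' scn <- swcrt_scenario(I = 6, z_sequence = c(0, 1, 2, 2, 1, 0),
#'                       beta1 = 0.5, icc = 0.01)
#' fit_constant(simulate_trial(scn, seed = 1))$beta1_hat
#' @export
fit_constant <- function(data, reml = TRUE,
                         control = lme4::lmerControl(calc.derivs = FALSE)) {
  fit_lmm(data, "group", cluster_time = FALSE, reml = reml, control = control)
}

#' @rdname fit_constant
#' @export
fit_learning <- function(data, reml = TRUE,
                         control = lme4::lmerControl(calc.derivs = FALSE)) {
  if (!"ramp" %in% names(data)) {
    stop("learning model needs a 'ramp' column", call. = FALSE)
  }
  fit_lmm(data, "ramp", cluster_time = FALSE, reml = reml, control = control)
}

#' @rdname fit_constant
#' @param effect_type Treatment regressor for the cluster-by-time model:
#'   `"constant"` (group indicator) or `"learning"` (ramp).
#' @export
fit_cluster_time <- function(data, effect_type = c("constant", "learning"),
                             reml = TRUE,
                             control = lme4::lmerControl(calc.derivs = FALSE)) {
  effect_type <- match.arg(effect_type)
  tv <- if (effect_type == "learning") "ramp" else "group"
  fit_lmm(data, tv, cluster_time = TRUE, reml = reml, control = control)
}

# Dispatch the analysis model matching a scenario's generative model.
fitter_for <- function(scn) {
  if (scn$variant == "cluster_time") {
    function(d, ...) fit_cluster_time(d, effect_type = scn$effect_type, ...)
  } else if (scn$effect_type == "learning") {
    fit_learning
  } else {
    fit_constant
  }
}
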