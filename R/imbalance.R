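#' Site sequence for a stepped-wedge design
#'
#' Bundles the site-level covariate values, ordered by crossover position
#' (element k belongs to the site that crosses over k-th), with the
#' calendar timepoints at which each site crosses over. In the canonical
#' one-site-per-step layout with all sites on control at `t = 1`, the site
#' in position k crosses over at `t = k + 1`, which is the default.
#'
#' @param values Numeric vector of covariate levels, one per site, in
#'   crossover order. Ties are the normal case (ordinal covariates).
#' @param crossover_times Integer vector of crossover timepoints, strictly
#'   increasing, same length as `values`. Default `seq_along(values) + 1`.
#' @return An object of class `swcrt_site_sequence`.
#' @examples
#' site_sequence(c(0, 0, 1, 1, 2, 2))
#' @export
site_sequence <- function(values, crossover_times = seq_along(values) + 1) {
  values <- as.numeric(values)
  if (length(values) < 2) {
    stop("a site sequence needs at least 2 sites", call. = FALSE)
  }
  if (anyNA(values)) stop("covariate values must not contain NA", call. = FALSE)
  crossover_times <- as.numeric(crossover_times)
  if (length(crossover_times) != length(values)) {
    stop("'crossover_times' must match 'values' in length", call. = FALSE)
  }
  if (any(diff(crossover_times) <= 0)) {
    stop("'crossover_times' must be strictly increasing", call. = FALSE)
  }
  structure(list(values = values, crossover_times = crossover_times),
            class = "swcrt_site_sequence")
}

#' @export
print.swcrt_site_sequence <- function(x, ...) {
  cat("Site sequence (", length(x$values), " sites)\n", sep = "")
  cat("  values: ", paste(x$values, collapse = " "), "\n", sep = "")
  cat("  crossover times: ", paste(x$crossover_times, collapse = " "), "\n",
      sep = "")
  invisible(x)
}

as_site_sequence <- function(x) {
  if (inherits(x, "swcrt_site_sequence")) x else site_sequence(x)
}

#' Mid-ranks with ties averaged
#'
#' Ranks a numeric vector, assigning tied values the average of the ranks
#' they occupy. This is the rank transform underlying every imbalance index:
#' Spearman correlation with ties equals the Pearson correlation of
#' mid-ranks.
#'
#' @param values Non-empty numeric vector.
#' @return Numeric vector of mid-ranks; always sums to `n(n+1)/2`.
#' @examples
#' midranks(c(0, 0, 1, 1, 2, 2))
#' @export
midranks <- function(values) {
  if (length(values) == 0) stop("empty input", call. = FALSE)
  if (anyNA(values)) stop("input must not contain NA", call. = FALSE)
  rank(values, ties.method = "average")
}

index_value <- function(value, trend, degenerate = FALSE) {
  structure(list(value = value, trend = trend, degenerate = degenerate),
            class = "swcrt_index")
}

#' @export
print.swcrt_index <- function(x, ...) {
  cat(sprintf("%s imbalance index: %.3f%s\n", x$trend, x$value,
              if (x$degenerate) " (degenerate: constant covariate)" else ""))
  invisible(x)
}

#' @export
as.double.swcrt_index <- function(x, ...) x$value

is_constant <- function(x) max(x) - min(x) < .Machine$double.eps^0.5

#' Linear (sequential) imbalance index
#'
#' Absolute Spearman correlation between the site covariate and the order in
#' which sites cross over to the intervention. 0 means the covariate shows no
#' linear trend across the randomization sequence (perfectly balanced); 1
#' means sites are perfectly ordered by the covariate (perfectly imbalanced).
#' Computed as the Pearson correlation of covariate mid-ranks with the
#' crossover positions 1..I, and identical to the square root of the R^2 of
#' the rank-on-time simple regression.
#'
#' @param seq A [site_sequence()] or a numeric vector of covariate values in
#'   crossover order.
#' @return An object of class `swcrt_index` with fields `value` (in
#'   \[0, 1\]), `trend`, and `degenerate` (`TRUE`, with value 0, when the
#'   covariate is constant so no imbalance is possible).
#' @examples
#' linear_index(c(0, 0, 1, 1, 2, 2))  # sorted: maximal, 0.956
#' linear_index(c(0, 1, 2, 2, 1, 0))  # palindrome: 0
#' @export
linear_index <- function(seq) {
  seq <- as_site_sequence(seq)
  r <- midranks(seq$values)
  if (is_constant(r)) return(index_value(0, "linear", degenerate = TRUE))
  k <- seq_along(r)
  index_value(abs(stats::cor(r, k)), "linear")
}

#' Quadratic imbalance index
#'
#' Absolute partial Spearman correlation between the site covariate and
#' squared crossover time, controlling for linear time: covariate mid-ranks
#' and t^2 are each residualized on \{1, t\} by least squares and the
#' residuals correlated. Captures U- or inverted-U-shaped patterns of the
#' covariate over the crossover schedule that the linear index misses.
#'
#' @inheritParams linear_index
#' @return An object of class `swcrt_index`; value in \[0, 1\].
#' @examples
#' quadratic_index(c(0, 1, 2, 2, 1, 0))  # strong U-shape: 0.982
#' @export
quadratic_index <- function(seq) {
  seq <- as_site_sequence(seq)
  r <- midranks(seq$values)
  if (length(r) < 3) stop("quadratic index needs at least 3 sites", call. = FALSE)
  if (is_constant(r)) return(index_value(0, "quadratic", degenerate = TRUE))
  k <- seq_along(r)
  rr <- stats::lsfit(k, r)$residuals
  rq <- stats::lsfit(k, k^2)$residuals
  if (sum(rq^2) < 1e-12 * sum(k^4)) {
    stop("collinear time basis: t^2 is numerically linear in t", call. = FALSE)
  }
  if (sum(rr^2) < .Machine$double.eps^0.5) {
    # ranks are an exact linear function of time: no quadratic signal left
    return(index_value(0, "quadratic"))
  }
  index_value(min(1, abs(stats::cor(rr, rq))), "quadratic")
}

#' Seasonal (cyclic) imbalance index
#'
#' Square root of the coefficient of partial determination for a block of
#' season indicators. Covariate mid-ranks are regressed on an intercept plus
#' the controlled time trends (default: linear) — the reduced model — and
#' again with `cycle - 1` season indicator dummies added — the full model.
#' The index is `sqrt((SSE_reduced - SSE_full) / SSE_reduced)`. Season
#' membership uses the actual crossover time: `s(t) = ((t - 1) mod cycle) + 1`
#' with season 1 as reference, so with the default schedule (first crossover
#' at t = 2) and cycle 4 the six sites of a 6-site trial fall in seasons
#' 2, 3, 4, 1, 2, 3.
#'
#' @inheritParams linear_index
#' @param cycle Cycle length in timepoints (e.g. 4 steps per year); >= 2.
#' @param control Character vector of time trends to control for, any of
#'   `"linear"`, `"quadratic"`. Default `"linear"`.
#' @return An object of class `swcrt_index`; value in \[0, 1\].
#' @examples
#' seasonal_index(c(0, 0, 1, 1, 2, 2), cycle = 4)
#' @export
seasonal_index <- function(seq, cycle, control = "linear") {
  seq <- as_site_sequence(seq)
  cycle <- as.integer(cycle)
  if (is.na(cycle) || cycle < 2) stop("'cycle' must be >= 2", call. = FALSE)
  control <- match.arg(control, c("linear", "quadratic"), several.ok = TRUE)
  r <- midranks(seq$values)
  if (is_constant(r)) return(index_value(0, "seasonal", degenerate = TRUE))
  t <- seq$crossover_times
  X <- matrix(1, length(r), 1, dimnames = list(NULL, "intercept"))
  if ("linear" %in% control) X <- cbind(X, t = t)
  if ("quadratic" %in% control) X <- cbind(X, t2 = t^2)
  season <- factor(((t - 1) %% cycle) + 1, levels = 1:cycle)
  S <- stats::model.matrix(~season)[, -1, drop = FALSE]
  Xfull <- cbind(X, S)
  n <- length(r)
  qf <- qr(Xfull)
  if (qf$rank < ncol(Xfull)) {
    keep <- sort(qf$pivot[seq_len(qf$rank)])
    if (any(setdiff(seq_len(ncol(Xfull)), keep) > ncol(X))) {
      warning("rank-deficient season dummies dropped from the full model",
              call. = FALSE)
    }
    Xfull <- Xfull[, keep, drop = FALSE]
  }
  if (n <= ncol(Xfull)) {
    stop("full seasonal model is saturated: need more sites than regressors",
         call. = FALSE)
  }
  sse <- function(M) {
    fit <- stats::lm.fit(M, r)
    sum(fit$residuals^2)
  }
  sse_red <- sse(X)
  if (sse_red < .Machine$double.eps^0.5) {
    # controlled trends already fit the ranks exactly
    return(index_value(0, "seasonal"))
  }
  sse_full <- sse(Xfull)
  val <- sqrt(max(0, (sse_red - sse_full) / sse_red))
  index_value(min(1, val), "seasonal")
}

#' Imbalance specification: which trends, covariates, and weights
#'
#' Describes the overall imbalance index as a weighted average of component
#' indices, one per (covariate, trend) pair. Weights must be non-negative
#' and sum to 1; they are typically set by the study team, either directly
#' or through [weights_from_ranks()].
#'
#' @param components Data frame with columns `covariate` (name or column
#'   index) and `trend` (one of `"linear"`, `"quadratic"`, `"seasonal"`),
#'   one row per component index.
#' @param weights Numeric vector of non-negative weights, one per component,
#'   summing to 1 (tolerance 1e-9). Default: equal weights.
#' @param cycle_length Seasonal cycle length in timepoints; required (>= 2)
#'   when any component has trend `"seasonal"`.
#' @return An object of class `swcrt_imbalance_spec`.
#' @examples
#' imbalance_spec(
#'   components = data.frame(covariate = c("rurality", "rurality"),
#'                           trend = c("linear", "seasonal")),
#'   cycle_length = 4
#' )
#' @export
imbalance_spec <- function(components,
                           weights = rep(1 / nrow(components), nrow(components)),
                           cycle_length = NULL) {
  components <- as.data.frame(components)
  if (!all(c("covariate", "trend") %in% names(components))) {
    stop("'components' needs columns 'covariate' and 'trend'", call. = FALSE)
  }
  bad <- setdiff(components$trend, c("linear", "quadratic", "seasonal"))
  if (length(bad)) {
    stop("unknown trend(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  weights <- as.numeric(weights)
  if (length(weights) != nrow(components)) {
    stop("one weight per component required", call. = FALSE)
  }
  if (any(weights < 0)) stop("weights must be non-negative", call. = FALSE)
  if (abs(sum(weights) - 1) > 1e-9) {
    stop("weights must sum to 1 (tolerance 1e-9)", call. = FALSE)
  }
  if (any(components$trend == "seasonal")) {
    if (is.null(cycle_length) || as.integer(cycle_length) < 2) {
      stop("'cycle_length' >= 2 required for seasonal components", call. = FALSE)
    }
    cycle_length <- as.integer(cycle_length)
  }
  structure(list(components = components, weights = weights,
                 cycle_length = cycle_length),
            class = "swcrt_imbalance_spec")
}

#' @export
print.swcrt_imbalance_spec <- function(x, ...) {
  cat("Imbalance specification (", nrow(x$components), " components)\n", sep = "")
  df <- cbind(x$components, weight = x$weights)
  print(df, row.names = FALSE)
  if (!is.null(x$cycle_length)) {
    cat("seasonal cycle length:", x$cycle_length, "\n")
  }
  invisible(x)
}

#' Convert importance ranks to index weights
#'
#' Turns an importance ranking of the K component indices (rank 1 = most
#' important) into weights: the index ranked r receives raw weight
#' `(K - r + 1)^p`, normalized to sum to 1. The exponent p controls how
#' concentrated the weights are: p = 0 gives equal weights, larger p
#' concentrates weight on the top-ranked indices.
#'
#' @param K Number of indices.
#' @param ranks Permutation of `1:K`; `ranks[k]` is the importance rank of
#'   index k.
#' @param p Non-negative exponent. Default 1.
#' @return Numeric weight vector summing to 1.
#' @examples
#' weights_from_ranks(3, c(1, 2, 3))        # 1/2, 1/3, 1/6
#' weights_from_ranks(3, c(1, 2, 3), p = 0) # equal
#' @export
weights_from_ranks <- function(K, ranks, p = 1) {
  K <- as.integer(K)
  if (length(ranks) != K || !setequal(ranks, seq_len(K))) {
    stop("'ranks' must be a permutation of 1..K", call. = FALSE)
  }
  if (p < 0) stop("'p' must be non-negative", call. = FALSE)
  raw <- (K - ranks + 1)^p
  raw / sum(raw)
}

#' Overall (weighted) imbalance index
#'
#' Weighted average `i_o = sum(w_k * i_k)` of component imbalance indices,
#' with weights summing to 1, so the overall index stays in \[0, 1\].
#'
#' @param indices Numeric vector of component index values, or a list of
#'   `swcrt_index` objects.
#' @param weights Numeric weights, one per index, non-negative, summing to 1.
#' @return An object of class `swcrt_index` with trend `"overall"`.
#' @examples
#' overall_index(c(0.4, 0.8), c(0.5, 0.5))  # 0.6
#' @export
overall_index <- function(indices, weights = rep(1 / length(indices), length(indices))) {
  if (is.list(indices)) {
    indices <- vapply(indices, function(x) {
      if (inherits(x, "swcrt_index")) x$value else as.numeric(x)
    }, numeric(1))
  }
  weights <- as.numeric(weights)
  if (length(indices) != length(weights)) {
    stop("'indices' and 'weights' must have the same length", call. = FALSE)
  }
  if (any(weights < 0)) stop("weights must be non-negative", call. = FALSE)
  if (abs(sum(weights) - 1) > 1e-9) {
    stop("weights must sum to 1 (tolerance 1e-9)", call. = FALSE)
  }
  index_value(sum(weights * indices), "overall")
}

compute_component_index <- function(values, crossover_times, trend, cycle_length) {
  s <- site_sequence(values, crossover_times)
  switch(trend,
         linear    = linear_index(s),
         quadratic = quadratic_index(s),
         seasonal  = seasonal_index(s, cycle = cycle_length))
}

#' Component and overall imbalance indices for a covariate table
#'
#' Evaluates every (covariate, trend) component of an [imbalance_spec()] on
#' a table of site-level covariates in crossover order and combines them
#' into the overall index.
#'
#' @param covariates Data frame or matrix, one row per site in crossover
#'   order, one named column per covariate.
#' @param spec An [imbalance_spec()].
#' @param crossover_times Crossover timepoints; default `t = k + 1` for
#'   position k.
#' @return A list with `components` (data frame: covariate, trend, index,
#'   degenerate) and `overall` (numeric `i_o`).
#' @examples
#' cov <- data.frame(rurality = c(1, 1, 2, 2, 3, 3))
#' sp <- imbalance_spec(data.frame(covariate = "rurality",
#'                                 trend = c("linear", "seasonal")),
#'                      cycle_length = 4)
#' imbalance_indices(cov, sp)
#' @export
imbalance_indices <- function(covariates, spec,
                              crossover_times = seq_len(nrow(covariates)) + 1) {
  covariates <- as.data.frame(covariates)
  comp <- spec$components
  vals <- numeric(nrow(comp))
  degen <- logical(nrow(comp))
  for (k in seq_len(nrow(comp))) {
    cv <- comp$covariate[k]
    if (!(cv %in% names(covariates)) && !is.numeric(cv)) {
      stop("covariate '", cv, "' not found", call. = FALSE)
    }
    idx <- compute_component_index(covariates[[cv]], crossover_times,
                                   comp$trend[k], spec$cycle_length)
    vals[k] <- idx$value
    degen[k] <- idx$degenerate
  }
  list(components = data.frame(covariate = comp$covariate, trend = comp$trend,
                               index = vals, degenerate = degen),
       overall = overall_index(vals, spec$weights)$value)
}

#' Pairwise Spearman correlation between site-level covariates
#'
#' Multi-collinearity check for candidate balancing covariates: the Spearman
#' (mid-rank based) correlation matrix across covariate columns. Strongly
#' correlated covariates carry redundant balancing information and one of
#' them can usually be dropped.
#'
#' @param covariates Data frame or matrix, sites in rows (>= 2), covariates
#'   in columns.
#' @return Symmetric correlation matrix with unit diagonal. Degenerate
#'   (constant) columns yield 0 off-diagonal entries with a warning.
#' @examples
#' pairwise_covariate_correlation(cbind(a = c(0, 1, 2), b = c(2, 1, 0)))
#' @export
pairwise_covariate_correlation <- function(covariates) {
  X <- as.matrix(as.data.frame(covariates))
  if (nrow(X) < 2) stop("need at least 2 sites", call. = FALSE)
  R <- apply(X, 2, midranks)
  const <- apply(X, 2, is_constant)
  out <- suppressWarnings(stats::cor(R))
  if (any(const)) {
    warning("constant covariate column(s): ",
            paste(colnames(X)[const], collapse = ", "),
            "; correlations reported as 0", call. = FALSE)
    out[const, ] <- 0
    out[, const] <- 0
  }
  diag(out) <- 1
  out
}
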