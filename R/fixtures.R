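#' Read a site covariate table from CSV
#'
#' One row per site in crossover order, one named column per covariate,
#' header row required.
#'
#' @param path CSV file path.
#' @return data.frame of covariates.
#' @export
read_covariates <- function(path) {
  d <- utils::read.csv(path)
  if (!nrow(d) || !ncol(d)) stop("empty covariate table", call. = FALSE)
  d
}

#' Read an imbalance specification from YAML
#'
#' Expected keys: `components` (list of `{covariate, trend}` maps),
#' optional `cycle_length`, and either `weights` (numeric list summing to
#' 1) or `ranks` plus optional `p` (converted via [weights_from_ranks()]).
#'
#' @param path YAML file path.
#' @return An [imbalance_spec()].
#' @export
read_imbalance_spec <- function(path) {
  y <- yaml::read_yaml(path)
  comp <- do.call(rbind, lapply(y$components, function(cm) {
    data.frame(covariate = cm$covariate, trend = cm$trend)
  }))
  w <- if (!is.null(y$weights)) {
    as.numeric(y$weights)
  } else if (!is.null(y$ranks)) {
    weights_from_ranks(nrow(comp), as.integer(y$ranks),
                       p = if (is.null(y$p)) 1 else y$p)
  } else {
    rep(1 / nrow(comp), nrow(comp))
  }
  imbalance_spec(comp, weights = w, cycle_length = y$cycle_length)
}

#' Write the bundled example configurations
#'
#' Generates the small covariate CSVs and spec YAMLs used in examples and
#' tests: `six_site` (three-level covariate, two sites per level),
#' `twelve_site` (four per level), and `caribou_demo` — a synthetic
#' 6-site configuration modelled on a multi-site adolescent-depression
#' SWCRT, with rurality (levels 1/2/3, two sites each) and community income
#' (levels 1/2, three sites each) balanced on linear and seasonal (cycle 4)
#' trends with equal weights. The site-level pairing of the two covariates
#' is a synthetic choice (the real pairing is not public) that yields a
#' moderate Spearman correlation of 0.41 between them.
#'
#' @param kind One of `"six_site"`, `"twelve_site"`, `"caribou_demo"`.
#' @param dir Output directory (created if needed).
#' @return Character vector of written file paths, invisibly.
#' @export
make_fixtures <- function(kind = c("six_site", "twelve_site", "caribou_demo"),
                          dir = ".") {
  kind <- match.arg(kind)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  wr <- function(name, df) {
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    p
  }
  if (kind == "six_site") {
    paths <- wr("six_site_covariates.csv", data.frame(z = c(0, 0, 1, 1, 2, 2)))
  } else if (kind == "twelve_site") {
    paths <- wr("twelve_site_covariates.csv", data.frame(z = rep(0:2, each = 4)))
  } else {
    paths <- wr("caribou_demo_covariates.csv",
                data.frame(rurality = c(1, 1, 2, 2, 3, 3),
                           income = c(1, 2, 1, 1, 2, 2)))
    spec_path <- file.path(dir, "caribou_demo_spec.yaml")
    yaml::write_yaml(list(
      components = list(
        list(covariate = "rurality", trend = "linear"),
        list(covariate = "rurality", trend = "seasonal"),
        list(covariate = "income", trend = "linear"),
        list(covariate = "income", trend = "seasonal")),
      cycle_length = 4L,
      weights = c(0.25, 0.25, 0.25, 0.25)), spec_path)
    paths <- c(paths, spec_path)
  }
  invisible(paths)
}

#' Recompute the package's reference results
#'
#' Orchestrates the deterministic and scaled-down Monte-Carlo benchmark
#' computations in one call: the exact percentile table of the linear
#' imbalance index for the 6- and 12-site settings
#' (`index_percentiles.csv`), the analytic treatment-condition ICCs for
#' every (sites, effect size, control ICC) combination
#' (`treatment_icc.csv`), and — when `cells` are supplied — Monte-Carlo
#' RRMSE and bias for those scenario cells (`rrmse_bias_scaled.csv`). A
#' `report.csv` records each deterministic check against its reference
#' value with pass/fail at ±0.001.
#'
#' @param dir Output directory.
#' @param cells Optional list of scenarios (e.g. a subset of
#'   [swcrt_grid()]) to evaluate by Monte Carlo.
#' @param replications K for the Monte-Carlo cells; default 2000.
#' @param seed Master seed for the Monte-Carlo cells.
#' @return List with `report` (data.frame) and `ok` (all deterministic
#'   checks passed), invisibly; files are written to `dir`.
#' @export
run_benchmark_suite <- function(dir = ".", cells = NULL, replications = 2000,
                                seed = 2023) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pct <- c(0, 16.7, 33, 50, 67, 83, 100)
  ref <- list(
    "6" = c(0, 0.119, 0.239, 0.359, 0.478, 0.717, 0.956),
    "12" = c(0, 0.059, 0.148, 0.207, 0.296, 0.414, 0.946))
  tab1 <- list(); checks <- list()
  for (s in c(6, 12)) {
    d <- index_distribution(rep(0:2, each = s / 3), percentiles = pct)
    tab1[[as.character(s)]] <- data.frame(sites = s, percentile = pct,
                                          value = unname(d$quantiles))
    checks[[paste0("pct", s)]] <- data.frame(
      check = sprintf("index_percentile_%dsite_p%s", s, pct),
      value = unname(d$quantiles), reference = ref[[as.character(s)]])
  }
  utils::write.csv(do.call(rbind, tab1),
                   file.path(dir, "index_percentiles.csv"), row.names = FALSE)

  icc_ref <- expand.grid(icc = c(0.01, 0.10), sites = c(6, 12),
                         beta1 = c(0.2, 0.5, 1.0))
  icc_ref$reference <- c(0.040, 0.125, 0.038, 0.122,
                         0.174, 0.237, 0.161, 0.226,
                         0.448, 0.477, 0.424, 0.456)
  icc_ref$value <- mapply(function(b1, s, ic) {
    treatment_icc(b1, rep(0:2, each = s / 3), ic)
  }, icc_ref$beta1, icc_ref$sites, icc_ref$icc)
  utils::write.csv(icc_ref[, c("sites", "icc", "beta1", "value")],
                   file.path(dir, "treatment_icc.csv"), row.names = FALSE)
  checks$icc <- data.frame(
    check = sprintf("treatment_icc_%dsite_icc%g_b%g", icc_ref$sites,
                    icc_ref$icc, icc_ref$beta1),
    value = icc_ref$value, reference = icc_ref$reference)

  if (!is.null(cells)) {
    res <- run_grid(cells, K = replications)
    utils::write.csv(res, file.path(dir, "rrmse_bias_scaled.csv"),
                     row.names = FALSE)
  }

  report <- do.call(rbind, checks)
  report$pass <- abs(report$value - report$reference) <= 1e-3
  utils::write.csv(report, file.path(dir, "report.csv"), row.names = FALSE)
  invisible(list(report = report, ok = all(report$pass)))
}
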