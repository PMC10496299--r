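test_that("midranks average ties and always sum to n(n+1)/2", {
  expect_equal(midranks(c(0, 0, 1, 1, 2, 2)), c(1.5, 1.5, 3.5, 3.5, 5.5, 5.5))
  expect_equal(midranks(c(3, 1, 2)), c(3, 1, 2))
  expect_equal(midranks(c(5, 5, 5)), c(2, 2, 2))
  expect_error(midranks(numeric(0)), "empty")
  for (v in random_sequences(20, seed = 1)) {
    n <- length(v)
    expect_equal(sum(midranks(v)), n * (n + 1) / 2)
  }
})

test_that("linear index matches the known extremes and the palindrome zero", {
  expect_equal(round(linear_index(c(0, 0, 1, 1, 2, 2))$value, 3), 0.956)
  expect_equal(round(linear_index(rep(0:2, each = 4))$value, 3), 0.946)
  expect_equal(linear_index(c(0, 1, 2, 2, 1, 0))$value, 0)
  expect_error(linear_index(c(1)), "at least 2")
})

test_that("linear index equals sqrt(R^2) of the rank-on-time regression", {
  for (v in random_sequences(25, seed = 2)) {
    r <- midranks(v)
    if (max(r) == min(r)) next
    fit <- lm(r ~ seq_along(r))
    expect_equal(linear_index(v)$value,
                 sqrt(summary(fit)$r.squared), tolerance = 1e-12)
  }
})

test_that("quadratic index matches hand-computed and oracle values", {
  expect_equal(round(quadratic_index(c(0, 1, 2, 2, 1, 0))$value, 3), 0.982)
  expect_equal(quadratic_index(c(0, 1, 2, 2, 1, 0))$value,
               oracle_quadratic(c(0, 1, 2, 2, 1, 0)), tolerance = 1e-10)
  deg <- quadratic_index(c(3, 3, 3, 3))
  expect_equal(deg$value, 0)
  expect_true(deg$degenerate)
  expect_error(quadratic_index(c(1, 2)), "at least 3")
})

test_that("seasonal index hits the exact extremes", {
  deg <- seasonal_index(c(1, 1, 1, 1, 1, 1), cycle = 4)
  expect_equal(deg$value, 0)
  expect_true(deg$degenerate)
  # values an exact function of season (8 sites, cycle 4, seasons
  # 2,3,4,1,2,3,4,1 at times 2..9): full model fits perfectly -> index 1
  v <- c(10, 20, 30, 40, 10, 20, 30, 40)
  expect_equal(seasonal_index(v, cycle = 4)$value, 1)
  # a covariate tracking the seasons of a 12-site schedule, against oracle
  times12 <- 2:13
  season12 <- ((times12 - 1) %% 4) + 1
  v12 <- c(0, 1, 2, 0, 0, 1, 2, 1, 0, 1, 2, 2)
  expect_equal(seasonal_index(v12, cycle = 4)$value,
               oracle_seasonal(v12, times12, 4), tolerance = 1e-10)
  expect_error(suppressWarnings(seasonal_index(c(0, 1, 2, 1), cycle = 4)),
               "saturated")
})

test_that("indices are invariant under strictly increasing transforms", {
  for (v in random_sequences(15, seed = 3)) {
    w <- exp(v) + 3  # strictly increasing transform
    expect_equal(linear_index(v)$value, linear_index(w)$value,
                 tolerance = 1e-12)
    expect_equal(quadratic_index(v)$value, quadratic_index(w)$value,
                 tolerance = 1e-12)
    if (length(v) >= 8) {
      expect_equal(seasonal_index(v, cycle = 3)$value,
                   seasonal_index(w, cycle = 3)$value, tolerance = 1e-12)
    }
  }
})

test_that("linear index is symmetric under sequence reversal", {
  for (v in random_sequences(15, seed = 4)) {
    expect_equal(linear_index(v)$value, linear_index(rev(v))$value,
                 tolerance = 1e-12)
  }
})

test_that("every index stays in [0, 1]", {
  for (v in random_sequences(30, seed = 5)) {
    for (idx in list(linear_index(v), quadratic_index(v))) {
      expect_gte(idx$value, 0)
      expect_lte(idx$value, 1)
    }
    if (length(v) >= 8) {
      s <- seasonal_index(v, cycle = 3)
      expect_gte(s$value, 0)
      expect_lte(s$value, 1)
    }
  }
})

test_that("overall index is the weighted mean and validates weights", {
  expect_equal(overall_index(c(0.4, 0.8), c(0.5, 0.5))$value, 0.6)
  expect_equal(overall_index(0.3, 1)$value, 0.3)
  expect_equal(overall_index(c(0, 0, 0))$value, 0)
  expect_error(overall_index(c(0.1, 0.2), c(1)), "same length")
  expect_error(overall_index(c(0.1, 0.2), c(0.7, 0.7)), "sum to 1")
})

test_that("rank-to-weight conversion follows (K - r + 1)^p", {
  expect_equal(weights_from_ranks(3, c(1, 2, 3), p = 1), c(1/2, 1/3, 1/6))
  expect_equal(weights_from_ranks(5, c(2, 4, 1, 5, 3), p = 0), rep(1/5, 5))
  expect_equal(weights_from_ranks(2, c(1, 2), p = 2), c(0.8, 0.2))
  expect_error(weights_from_ranks(3, c(1, 1, 2)), "permutation")
})

test_that("pairwise covariate correlation is Spearman with unit diagonal", {
  M <- cbind(a = c(0, 1, 2), b = c(2, 1, 0))
  R <- pairwise_covariate_correlation(M)
  expect_equal(diag(R), c(a = 1, b = 1))
  expect_equal(R["a", "b"], -1)
  # independent covariates over many sites: correlation near zero
  set.seed(99)
  big <- cbind(x = sample(0:2, 1000, TRUE), y = rnorm(1000))
  expect_lt(abs(pairwise_covariate_correlation(big)["x", "y"]), 0.1)
  expect_warning(pairwise_covariate_correlation(cbind(u = c(1, 1), v = 1:2)),
                 "constant")
})

test_that("imbalance_spec validates trends, weights, and cycle length", {
  comp <- data.frame(covariate = "z", trend = c("linear", "seasonal"))
  expect_error(imbalance_spec(comp), "cycle_length")
  sp <- imbalance_spec(comp, cycle_length = 4)
  expect_equal(sp$weights, c(0.5, 0.5))
  expect_error(imbalance_spec(data.frame(covariate = "z", trend = "cubic")),
               "unknown trend")
  expect_error(imbalance_spec(comp, weights = c(0.6, 0.6), cycle_length = 4),
               "sum to 1")
})

test_that("imbalance_indices combines components into the overall index", {
  cov <- data.frame(z = c(0, 0, 1, 1, 2, 2))
  sp <- imbalance_spec(data.frame(covariate = "z",
                                  trend = c("linear", "quadratic")))
  out <- imbalance_indices(cov, sp)
  expect_equal(nrow(out$components), 2)
  expect_equal(out$overall,
               mean(c(linear_index(cov$z)$value, quadratic_index(cov$z)$value)))
})
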