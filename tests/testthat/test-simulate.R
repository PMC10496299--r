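test_that("ICC maps to the between-cluster SD as sqrt(icc/(1-icc))", {
  expect_equal(sigma_re_from_icc(0), 0)
  expect_equal(round(sigma_re_from_icc(0.01), 6), 0.100504)
  expect_equal(round(sigma_re_from_icc(0.10), 6), 0.333333)
  expect_error(sigma_re_from_icc(1), "\\[0, 1\\)")
})

test_that("learning ramp rises by 1/(T-1) per step from crossover", {
  expect_equal(learning_ramp(2, T_i = 2, T = 7), 1 / 6)
  expect_equal(learning_ramp(7, T_i = 2, T = 7), 1)
  expect_equal(learning_ramp(1, T_i = 3, T = 7), 0)
  expect_equal(learning_ramp(1:7, T_i = 4, T = 7),
               c(0, 0, 0, 1, 2, 3, 4) / 6)
  expect_error(learning_ramp(1, 2, T = 1), ">= 2")
})

test_that("simulated trials have the stepped-wedge layout", {
  scn <- swcrt_scenario(I = 6, z_sequence = c(0, 1, 2, 2, 1, 0),
                        beta1 = 0.5, icc = 0.01)
  d <- simulate_trial(scn, seed = 1)
  expect_equal(nrow(d), 6 * 10 * 7)
  expect_equal(names(d), c("cluster", "time", "participant", "group",
                           "ramp", "y"))
  # one crossover per step: t-1 treated clusters at time t
  treated <- tapply(d$group, list(d$cluster, d$time), max)
  expect_equal(unname(colSums(treated)), 0:6)
  expect_true(all(d$group[d$time == 1] == 0))
  expect_true(all(d$ramp[d$group == 0] == 0))
  expect_true(all(table(d$cluster, d$time) == 10L))
  # determinism under seed
  expect_identical(d, simulate_trial(scn, seed = 1))
})

test_that("noise-free limit recovers beta0 + beta1 * Z per cell", {
  scn <- swcrt_scenario(I = 6, z_sequence = c(2, 0, 1, 1, 0, 2), beta1 = 0.7,
                        icc = 0, sigma = 1e-12, beta0 = 3)
  d <- simulate_trial(scn, seed = 2)
  post <- d[d$cluster == 1 & d$time >= 2, ]
  expect_equal(post$y, rep(3 + 2 * 0.7, nrow(post)), tolerance = 1e-9)
  pre <- d[d$cluster == 6 & d$time < 7, ]
  expect_equal(pre$y, rep(3, nrow(pre)), tolerance = 1e-9)
})

test_that("learning outcomes scale with the ramp", {
  scn <- swcrt_scenario(I = 6, z_sequence = rep(1, 6), beta1 = 0.6,
                        icc = 0, sigma = 1e-12, effect_type = "learning")
  d <- simulate_trial(scn, seed = 3)
  cell <- d[d$cluster == 1 & d$time == 4, ]
  expect_equal(cell$y, rep(0.6 * 3 / 6, nrow(cell)), tolerance = 1e-9)
})

test_that("cluster-mean variance at t = 1 matches sigma_re^2 + sigma^2/J", {
  scn <- swcrt_scenario(I = 6, z_sequence = c(0, 1, 2, 2, 1, 0), beta1 = 0.5,
                        icc = 0.5, J = 10)
  set.seed(123)
  means <- replicate(2000, {
    d <- simulate_trial(scn)
    tapply(d$y[d$time == 1], d$cluster[d$time == 1], mean)
  })
  expected <- sigma_re_from_icc(0.5)^2 + 1 / 10
  expect_equal(var(as.vector(means)), expected, tolerance = 0.05)
})

test_that("sensitivity variants add their random effects", {
  base <- swcrt_scenario(I = 6, z_sequence = rep(1, 6), beta1 = 0.5,
                         icc = 0, sigma = 1e-12)
  rs <- swcrt_scenario(I = 6, z_sequence = rep(1, 6), beta1 = 0.5,
                       icc = 0, sigma = 1e-12, variant = "random_slope",
                       sd_b1 = 0.3)
  ct <- swcrt_scenario(I = 6, z_sequence = rep(1, 6), beta1 = 0.5,
                       icc = 0, sigma = 1e-12, variant = "cluster_time",
                       sd_b0it = 0.2)
  d0 <- simulate_trial(base, seed = 4)
  drs <- simulate_trial(rs, seed = 4)
  dct <- simulate_trial(ct, seed = 4)
  # random slope perturbs only treated cells
  pre <- d0$group == 0
  expect_equal(drs$y[pre], d0$y[pre], tolerance = 1e-9)
  expect_gt(sd(drs$y[!pre] - d0$y[!pre]), 0)
  # cluster-by-time noise is constant within a cell
  cell <- dct[dct$cluster == 2 & dct$time == 3, "y"]
  expect_equal(sd(cell), 0, tolerance = 1e-9)
  expect_gt(sd(tapply(dct$y - d0$y, paste(dct$cluster, dct$time), mean)), 0)
})

test_that("a sequence pool re-randomizes the site order per replicate", {
  pool <- list(c(0, 0, 1, 1, 2, 2), c(2, 2, 1, 1, 0, 0))
  scn <- swcrt_scenario(I = 6, z_pool = pool, beta1 = 5, icc = 0,
                        sigma = 1e-9)
  used <- vapply(1:30, function(s) {
    paste(attr(simulate_trial(scn, seed = s), "z_sequence"), collapse = "")
  }, "")
  expect_setequal(unique(used), c("001122", "221100"))
  # determinism: same seed, same draw and same data
  expect_identical(simulate_trial(scn, seed = 4), simulate_trial(scn, seed = 4))
  expect_error(swcrt_scenario(I = 6, z_pool = list(c(0, 1)), beta1 = 1,
                              icc = 0), "length-I")
})

test_that("treatment-condition ICC follows the closed form", {
  expect_equal(round(treatment_icc(0.5, c(0, 0, 1, 1, 2, 2), 0.01), 3), 0.174)
  expect_equal(treatment_icc(0, c(0, 0, 1, 1, 2, 2), 0.07), 0.07)
  # strictly increasing in beta1 when the covariate varies
  b <- seq(0, 2, by = 0.25)
  vals <- vapply(b, treatment_icc, numeric(1), z = c(0, 0, 1, 1, 2, 2),
                 icc_control = 0.01)
  expect_true(all(diff(vals) > 0))
})

test_that("grand mean over replicates matches the design mean", {
  scn <- swcrt_scenario(I = 6, z_sequence = c(0, 1, 2, 2, 1, 0), beta1 = 1,
                        icc = 0.01, J = 10)
  set.seed(55)
  gm <- mean(replicate(400, mean(simulate_trial(scn)$y)))
  d <- simulate_trial(scn, seed = 1)
  Z <- c(0, 1, 2, 2, 1, 0)
  expected <- mean(1 * Z[d$cluster] * d$group)
  expect_equal(gm, expected, tolerance = 0.02)
})

test_that("trial CSV round-trips", {
  scn <- swcrt_scenario(I = 6, z_sequence = rep(1, 6), beta1 = 0.5, icc = 0.01)
  d <- simulate_trial(scn, seed = 9)
  p <- tempfile(fileext = ".csv")
  write_trial(d, p)
  expect_equal(read_trial(p), d, tolerance = 1e-12, ignore_attr = TRUE)
  bad <- tempfile(fileext = ".csv")
  write.csv(data.frame(a = 1), bad, row.names = FALSE)
  expect_error(read_trial(bad), "missing column")
})
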