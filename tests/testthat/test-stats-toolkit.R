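test_that("bootstrap correlation: exact dependence, defaults, and outlier handling", {
  x <- 1:50
  b <- bootstrap_correlation(x, 2 * x, n_boot = 500, seed = 1)
  expect_equal(b$estimate, 1)
  expect_equal(c(b$conf.low, b$conf.high), c(1, 1))
  expect_equal(formals(bootstrap_correlation)$n_boot, 10000)
  # an extreme pair is screened out before resampling
  set.seed(81)
  x2 <- rnorm(60); y2 <- rnorm(60)
  x2[60] <- 30
  b2 <- bootstrap_correlation(x2, y2, n_boot = 200, seed = 2)
  expect_equal(b2$n_removed, 1)
  expect_equal(b2$n_used, 59)
  expect_error(bootstrap_correlation(rnorm(3), rnorm(3), n_boot = 10, seed = 1),
               "fewer than 4")
})

test_that("bootstrap CIs have near-nominal coverage for independent variables", {
  set.seed(82)
  hits <- replicate(120, {
    x <- rnorm(100); y <- rnorm(100)
    b <- bootstrap_correlation(x, y, n_boot = 400, seed = sample.int(1e6, 1))
    b$conf.low <= 0 && b$conf.high >= 0
  })
  expect_gt(mean(hits), 0.88)
  expect_lt(mean(hits), 1.0)
})

test_that("Steiger's z matches the published-formula oracle and its symmetries", {
  # frozen oracle: computed independently from Steiger (1980) Z1* with the
  # Dunn-Clark covariance at the pooled correlation
  s <- steiger_z(0.6, 0.3, 0.4, 100)
  expect_equal(s$z, 3.20461367526974, tolerance = 1e-8)
  expect_equal(s$p.value, 0.00135243873187133, tolerance = 1e-8)
  expect_equal(steiger_z(0.5, 0.5, 0.2, 60)$z, 0)
  expect_equal(steiger_z(0.3, 0.6, 0.4, 100)$z, -s$z, tolerance = 1e-12)
  expect_error(steiger_z(1, 0.3, 0.2, 50), "inside")
  expect_error(steiger_z(0.5, 0.3, 0.2, 3), "exceed 3")
})

test_that("partial correlation removes exactly the covariate's contribution", {
  set.seed(83)
  n <- 1000
  z <- rnorm(n)
  x <- rnorm(n); y <- 0.5 * x + rnorm(n, 0, 0.8)
  # covariate independent of both: partialling changes nothing
  expect_lt(abs(partial_correlation(x, y, z) - cor(x, y)), 0.02)
  # x and y driven only by the covariate: nothing left to correlate
  x2 <- 2 * z + rnorm(n, 0, 0.5); y2 <- -z + rnorm(n, 0, 0.5)
  expect_lt(abs(partial_correlation(x2, y2, z)), 0.05)
  expect_error(partial_correlation(x, z, z), "zero residual variance")
  expect_error(partial_correlation(1:3, 1:3, 1:3), "exceed 4")
})

test_that("within-display dependency: determinism, relabeling invariance, null behaviour", {
  ch <- simulate_cohort(n_per_group = c(middle = 6), tasks = "LTM",
                        heterogeneity = FALSE, seed = 84)
  d1 <- within_display_dependency(ch$trials, seed = 7)
  d2 <- within_display_dependency(ch$trials, seed = 7)
  expect_identical(d1$predictors$pred_random, d2$predictors$pred_random)
  expect_identical(d1$effect, d2$effect)
  # permuting display labels (a bijective relabeling) leaves the effect unchanged
  relab <- ch$trials
  relab$display_id <- 1000 - relab$display_id
  d3 <- within_display_dependency(relab, seed = 7)
  expect_equal(d3$effect, d1$effect, tolerance = 1e-12)
  # independent generation: effect inside the permutation null band
  null <- within_display_dependency(ch$trials, seed = 7, n_perms = 300)
  band <- quantile(null$null_effects, c(0.025, 0.975))
  expect_gt(d1$effect, band[1])
  expect_lt(d1$effect, band[2])
})

test_that("a shared display-level fidelity latent produces a positive dependency effect", {
  ch <- simulate_cohort(n_per_group = c(middle = 10), tasks = "LTM",
                        heterogeneity = FALSE, display_coupling = 0.8,
                        seed = 85)
  d <- within_display_dependency(ch$trials, seed = 8, n_perms = 200)
  expect_gt(d$effect, quantile(d$null_effects, 0.95))
})

test_that("displays with fewer than three tested items are skipped and counted", {
  ch <- simulate_cohort(n_per_group = c(middle = 2), tasks = "LTM",
                        heterogeneity = FALSE, seed = 86)
  first <- ch$trials$subject_id[1]
  disp <- ch$trials$display_id[ch$trials$subject_id == first][1]
  drop <- which(ch$trials$subject_id == first & ch$trials$display_id == disp)[1:2]
  partial <- ch$trials[-drop, ] # break one display of the first subject
  d <- within_display_dependency(partial, seed = 9)
  expect_equal(d$n_skipped_displays, 1)
  expect_equal(nrow(d$predictors), nrow(partial) - 1)
})
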