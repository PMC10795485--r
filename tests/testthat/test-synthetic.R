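test_that("generated displays respect the separation constraint and feasibility", {
  set.seed(61)
  d <- generate_displays(2000)
  ang <- as.matrix(d[, c("angle_1", "angle_2", "angle_3")])
  min_sep <- pmin(abs(wrap_error(ang[, 1], ang[, 2])),
                  abs(wrap_error(ang[, 1], ang[, 3])),
                  abs(wrap_error(ang[, 2], ang[, 3])))
  expect_true(all(min_sep >= 62.04))
  expect_true(all(ang >= 0 & ang < 360))
  # single object: just an angle in range
  d1 <- generate_displays(5, n_objects = 1)
  expect_true(all(d1$angle_1 >= 0 & d1$angle_1 < 360))
  # 4 objects x 100 degrees cannot fit on the circle
  expect_error(generate_displays(1, n_objects = 4, min_separation_deg = 100),
               "infeasible")
})

test_that("display positions remain marginally uniform under the constraint", {
  set.seed(62)
  d <- generate_displays(6000)
  a <- c(d$angle_1, d$angle_2, d$angle_3)
  expect_gt(suppressWarnings(ks.test(a, "punif", 0, 360)$p.value), 0.001)
})

test_that("session structure matches the task design", {
  obs <- observer_presets("young", "STM")
  stm <- generate_session(obs, "STM", seed = 1)
  expect_equal(nrow(stm), 75)
  expect_equal(sort(unique(stm$block)), 1:5)
  expect_equal(as.vector(table(stm$block)), rep(15L, 5))
  expect_equal(length(unique(stm$display_id)), 75) # one tested item per display
  ltm <- generate_session(observer_presets("old", "LTM"), "LTM", seed = 2)
  expect_equal(nrow(ltm), 75)
  expect_equal(length(unique(ltm$display_id)), 25) # 25 displays x 3 tested
  expect_true(all(table(ltm$display_id) == 3))
  expect_equal(sort(unique(ltm$block)), 1:5)
  # errors are consistent with the recorded angles
  expect_equal(ltm$signed_error_deg,
               wrap_error(ltm$target_deg, ltm$response_deg))
  empty <- generate_session(obs, "STM", blocks = 0)
  expect_equal(nrow(empty), 0)
  # deterministic given the seed
  expect_identical(generate_session(obs, "STM", seed = 9),
                   generate_session(obs, "STM", seed = 9))
})

test_that("localization responses follow the generative mixture", {
  set.seed(63)
  n <- 10000
  tgt <- runif(n, 0, 360)
  # degenerate limit: always remembered, enormous precision
  sharp <- list(p_t = 1, p_nt = 0, kappa = 1e6, coupling = 0, display_coupling = 0)
  r <- simulate_localization(sharp, tgt[1:1000])
  expect_true(all(abs(wrap_error(tgt[1:1000], r)) < 0.5))
  # pure guessing: errors uniform on the circle
  guess <- list(p_t = 0, p_nt = 0, kappa = 5, coupling = 0, display_coupling = 0)
  rg <- simulate_localization(guess, tgt)
  eg <- wrap_error(tgt, rg)
  expect_gt(suppressWarnings(ks.test(eg, "punif", -180, 180)$p.value), 0.01)
  # mean absolute error matches numeric integration of the mixture density
  obs <- observer_presets("middle", "STM") # p_t = 0.82, kappa = 13.74
  rm <- simulate_localization(obs, tgt, ident_correct = rep(1, n))
  em <- wrap_error(tgt, rm)
  evm <- integrate(function(x) abs(x) * dvonmises_deg(x, 0, obs$kappa),
                   -180, 180)$value
  expected <- obs$p_t * evm + (1 - obs$p_t) * 90
  expect_lt(abs(mean(abs(em)) - expected), 1)
})

test_that("identification accuracy matches the 2AFC forward model", {
  set.seed(64)
  chance <- list(d_prime = 0)
  expect_lt(abs(mean(simulate_identification(chance, 10000)) - 0.5), 0.02)
  young <- observer_presets("young", "STM") # d' = 1.47
  expect_lt(abs(mean(simulate_identification(young, 10000)) -
                  pc_mafc(1.47, 2)), 0.02)
  sat <- list(d_prime = 8)
  expect_gt(mean(simulate_identification(sat, 10000)), 0.999)
})

test_that("presets expose the group means and reject unknown groups", {
  y <- observer_presets("young", "STM")
  expect_equal(y$p_t, 0.89)
  expect_equal(y$kappa, 18.12)
  expect_equal(y$d_prime, 1.47)
  o <- observer_presets("old", "LTM")
  expect_equal(o$p_t, 0.70)
  expect_equal(o$kappa, 7.86)
  expect_error(observer_presets("toddler", "STM"), "unknown age group")
})

test_that("item-location coupling shifts precision on identification-incorrect trials", {
  set.seed(65)
  n <- 8000
  tgt <- runif(n, 0, 360)
  ident <- rbinom(n, 1, 0.7)
  base <- list(p_t = 0.85, p_nt = 0, kappa = 12, coupling = 0, display_coupling = 0)
  coupled <- modifyList(base, list(coupling = 0.6))
  e0 <- abs(wrap_error(tgt, simulate_localization(base, tgt, ident_correct = ident)))
  e1 <- abs(wrap_error(tgt, simulate_localization(coupled, tgt, ident_correct = ident)))
  gap0 <- mean(e0[ident == 0]) - mean(e0[ident == 1])
  gap1 <- mean(e1[ident == 0]) - mean(e1[ident == 1])
  expect_lt(abs(gap0), 3)   # no coupling: difference within simulation noise
  expect_gt(gap1, 3)        # coupling: incorrect trials are less precise
})

test_that("cohort simulation is seeded, structured, and carries its observers", {
  ch <- simulate_cohort(n_per_group = c(young = 2, old = 2), tasks = "STM",
                        seed = 101)
  expect_equal(nrow(ch$trials), 4 * 75)
  expect_equal(nrow(ch$observers), 4)
  expect_setequal(unique(ch$trials$age_group), c("young", "old"))
  ch2 <- simulate_cohort(n_per_group = c(young = 2, old = 2), tasks = "STM",
                         seed = 101)
  expect_identical(ch$trials, ch2$trials)
})
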