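test_that("MLE matches an exhaustive grid search on small instances", {
  set.seed(41)
  for (i in 1:10) {
    p_t <- runif(1, 0.3, 0.95)
    kappa <- runif(1, 2, 40)
    e <- gen_mixture_errors(20, p_t, kappa)
    fit <- fit_mixture_mle(e, min_trials = 20, seed = i)
    expect_gte(fit$loglik, grid_best_loglik(e) - 1e-3)
  }
})

test_that("MLE recovers generating parameters and is honest about uniform data", {
  set.seed(42)
  res <- t(replicate(60, {
    e <- gen_mixture_errors(75, 0.8, 12)
    f <- fit_mixture_mle(e)
    c(f$point$p_t, f$point$kappa)
  }))
  expect_lt(abs(median(res[, 1]) - 0.8), 0.05)
  expect_lt(abs(median(res[, 2]) - 12) / 12, 0.2)
  # pure guessing: p_t collapses in most replicates; when it does not, the
  # fitted von Mises sits at the lower kappa bound, i.e. is itself nearly
  # uniform, so the fitted density stays close to the guessing model
  unif <- t(replicate(100, {
    f <- fit_mixture_mle(runif(75, -180, 180))
    c(f$point$p_t, f$point$kappa)
  }))
  expect_lte(median(unif[, 1]), 0.05)
  expect_gte(mean(unif[, 1] <= 0.1), 0.7)
  escaped <- unif[unif[, 1] > 0.1, 2]
  if (length(escaped) > 0) expect_lte(median(escaped), 2)
})

test_that("MLE respects preconditions and is deterministic given a seed", {
  expect_error(fit_mixture_mle(runif(10, -180, 180)), "at least 20")
  expect_error(fit_mixture_mle(numeric(0)), "at least")
  e <- gen_mixture_errors(40, 0.75, 10)
  f1 <- fit_mixture_mle(e, seed = 99)
  f2 <- fit_mixture_mle(e, seed = 99)
  expect_identical(f1$point, f2$point)
  # all-identical errors drive kappa to its bound -> boundary flag
  f3 <- fit_mixture_mle(rep(1, 30), seed = 1)
  expect_true("boundary_estimate" %in% f3$flags)
  expect_error(fit_mixture_mle(e, model = "swap_mixture"), "nontarget_offsets")
})

test_that("swap-model MLE attributes misbinding to the nontarget components", {
  set.seed(43)
  off <- matrix(rep(c(-110, 120), each = 150), ncol = 2)
  e <- gen_mixture_errors(150, 0.55, 12, p_nt = 0.3, offsets = off)
  f <- fit_mixture_mle(e, model = "swap_mixture", nontarget_offsets = off,
                       seed = 2)
  expect_lt(abs(f$point$p_nt - 0.3), 0.15)
  expect_lt(abs(f$point$p_t - 0.55), 0.15)
})

test_that("Bayesian fit agrees with the MLE and reports sane diagnostics", {
  set.seed(44)
  e <- gen_mixture_errors(75, 0.8, 12)
  mle <- fit_mixture_mle(e, seed = 1)
  bay <- fit_mixture_bayes(e, seed = 1)
  expect_lt(abs(bay$point$p_t - mle$point$p_t), 0.05)
  expect_lt(abs(bay$point$kappa - mle$point$kappa) / mle$point$kappa, 0.10)
  expect_gt(nrow(bay$posterior), 0)
  expect_true(all(bay$diagnostics$rhat < 1.05))
  expect_true(bay$diagnostics$accept_rate > 0.05 &&
                bay$diagnostics$accept_rate < 0.9)
  expect_true(all(bay$diagnostics$n_eff > 100))
  # reproducible given the seed
  bay2 <- fit_mixture_bayes(e, seed = 1)
  expect_identical(bay$posterior, bay2$posterior)
  td <- tidy(bay)
  expect_true(all(c("conf.low", "conf.high", "rhat") %in% names(td)))
  expect_true(td$conf.low[td$term == "p_t"] <= td$estimate[td$term == "p_t"])
  expect_error(fit_mixture_bayes(numeric(0)), "at least")
})

test_that("deliberately truncated chains raise the nonconvergence flag, not an error", {
  set.seed(45)
  e <- gen_mixture_errors(75, 0.8, 12)
  short <- fit_mixture_bayes(e, n_samples = 40, n_burnin = 0, seed = 3)
  expect_s3_class(tibble::as_tibble(short$point), "tbl_df")
  expect_true("nonconvergence" %in% short$flags)
})

test_that("model selection prefers the generating model", {
  set.seed(46)
  picks <- replicate(50, {
    e <- gen_mixture_errors(75, 0.8, 12)
    s <- select_mixture_model(list(fit_mixture_mle(e),
                                   fit_mixture_mle(e, model = "uniform_only")))
    s$winner == "standard_mixture"
  })
  expect_gte(mean(picks), 0.95)
  unif_picks <- replicate(50, {
    e <- runif(75, -180, 180)
    s <- select_mixture_model(list(fit_mixture_mle(e),
                                   fit_mixture_mle(e, model = "uniform_only")))
    s$winner == "uniform_only"
  })
  expect_gte(mean(unif_picks), 0.8)
})

test_that("model selection reports both criteria and rejects mismatched data", {
  set.seed(47)
  e <- gen_mixture_errors(75, 0.8, 12)
  fits <- list(fit_mixture_mle(e), fit_mixture_bayes(e, seed = 1),
               fit_mixture_mle(e, model = "uniform_only"))
  s <- select_mixture_model(fits)
  expect_true(all(c("aic", "dic", "score", "criterion_used") %in% names(s$table)))
  # a Bayesian fit is present, so DIC decides
  expect_equal(s$table$criterion_used[1], "DIC")
  # single candidate returned unchanged
  s1 <- select_mixture_model(list(fits[[1]]))
  expect_equal(s1$winner, "standard_mixture")
  e2 <- gen_mixture_errors(75, 0.8, 12)
  expect_error(select_mixture_model(list(fit_mixture_mle(e), fit_mixture_mle(e2))),
               "identical data")
})

test_that("fit-quality flags follow their definitions", {
  set.seed(48)
  e <- gen_mixture_errors(75, 0.9, 15)
  f <- fit_mixture_mle(e, seed = 1)
  # arithmetic rule: p_t * n below the floor
  f$point$p_t <- 0.1
  expect_true("low_pT_trials" %in% flag_fit_quality(f, min_vm_trials = 10))
  f$point$p_t <- 0.9
  expect_false("low_pT_trials" %in% flag_fit_quality(f, min_vm_trials = 10))
  # synthetic rhat above threshold
  f$diagnostics <- list(rhat = c(p_t = 1.2, sd_deg = 1.0))
  expect_true("nonconvergence" %in% flag_fit_quality(f))
  f$diagnostics <- list(rhat = c(p_t = 1.01, sd_deg = 1.0))
  expect_false("nonconvergence" %in% flag_fit_quality(f))
})
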