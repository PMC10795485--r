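#' Bootstrapped Pearson correlation with outlier screening
#'
#' Removes paired observations with |z| above `z_outlier_cut` on either
#' variable, then computes the Pearson correlation and a percentile bootstrap
#' confidence interval from `n_boot` resamples (default 10,000).
#'
#' @param x,y Paired numeric vectors.
#' @param n_boot Number of bootstrap resamples.
#' @param seed Integer seed for the resampling.
#' @param z_outlier_cut Absolute z-score cut for outlier removal.
#' @param conf_level Interval level.
#' @return One-row tibble: `estimate`, `conf.low`, `conf.high`, `n_used`,
#'   `n_removed`, `n_boot`, `seed`.
#' @export
bootstrap_correlation <- function(x, y, n_boot = 10000, seed = 1,
                                  z_outlier_cut = 3, conf_level = 0.95) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  zx <- abs(x - mean(x)) / stats::sd(x)
  zy <- abs(y - mean(y)) / stats::sd(y)
  keep <- zx <= z_outlier_cut & zy <= z_outlier_cut
  n_removed <- sum(!keep)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4) stop("fewer than 4 rows after outlier removal", call. = FALSE)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  r_hat <- stats::cor(x, y)
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
  boots <- vapply(seq_len(n_boot), function(b) {
    i <- idx[, b]
    suppressWarnings(stats::cor(x[i], y[i]))
  }, numeric(1))
  boots <- boots[is.finite(boots)]
  a <- (1 - conf_level) / 2
  ci <- stats::quantile(boots, c(a, 1 - a), names = FALSE)
  tibble::tibble(estimate = r_hat, conf.low = ci[1], conf.high = ci[2],
                 n_used = n, n_removed = n_removed, n_boot = n_boot,
                 seed = seed)
}

#' Steiger's z-test for two dependent correlations sharing one variable
#'
#' Compares `r_jk` and `r_jh` — two correlations that share variable j —
#' accounting for their dependence through `r_kh`, using Fisher-z transformed
#' correlations and the Dunn-Clark covariance evaluated at the pooled
#' correlation (Steiger's Z1*). The statistic is positive when
#' `r_jk > r_jh`.
#'
#' @param r_jk,r_jh The two correlations being compared, each in (-1, 1).
#' @param r_kh Correlation between the two non-shared variables.
#' @param n Sample size, `> 3`.
#' @return One-row tibble: `z`, `p.value` (two-sided).
#' @export
steiger_z <- function(r_jk, r_jh, r_kh, n) {
  rs <- c(r_jk, r_jh, r_kh)
  if (any(!is.finite(rs)) || any(abs(rs) >= 1)) {
    stop("correlations must lie strictly inside (-1, 1)", call. = FALSE)
  }
  if (n <= 3) stop("n must exceed 3", call. = FALSE)
  z1 <- atanh(r_jk); z2 <- atanh(r_jh)
  rbar <- (r_jk + r_jh) / 2
  psi <- r_kh * (1 - 2 * rbar^2) - 0.5 * rbar^2 * (1 - 2 * rbar^2 - r_kh^2)
  s <- psi / (1 - rbar^2)^2
  z <- (z1 - z2) * sqrt((n - 3) / (2 - 2 * s))
  tibble::tibble(z = z, p.value = 2 * stats::pnorm(-abs(z)))
}

#' Partial correlation controlling for one covariate
#'
#' Pearson correlation between the residuals of `x` and `y` after linear
#' removal of the covariate from each — e.g. precision against an outcome
#' controlling for retrieval success.
#'
#' @param x,y Numeric vectors.
#' @param covariate Numeric vector to partial out of both.
#' @return Partial correlation coefficient.
#' @export
partial_correlation <- function(x, y, covariate) {
  stopifnot(length(x) == length(y), length(x) == length(covariate))
  if (length(x) <= 4) stop("n must exceed 4", call. = FALSE)
  rx <- stats::residuals(stats::lm(x ~ covariate))
  ry <- stats::residuals(stats::lm(y ~ covariate))
  if (stats::sd(rx) < 1e-12 || stats::sd(ry) < 1e-12) {
    stop("zero residual variance after removing the covariate", call. = FALSE)
  }
  stats::cor(rx, ry)
}

#' Within-display dependency of localization errors
#'
#' Builds, for each trial of an LTM-format session (all display items tested),
#' two predictors of that trial's absolute localization error: the mean
#' absolute error of the other items tested from the same display, and an
#' absolute error randomly sampled (with replacement, seeded) from all of that
#' subject's trials — a baseline that carries the subject's overall memory
#' performance but no display information. The dependency effect is the
#' difference between the subject-centered least-squares slopes of target
#' error on each predictor; the random-predictor slope is averaged over
#' `n_draws` independent resamplings to suppress Monte Carlo noise. If errors
#' are independent across items of a display the effect is near zero, while a
#' shared display-level fidelity latent makes the same-display predictor
#' stronger.
#'
#' An optional permutation null shuffles display labels within subject
#' (`n_perms > 0`), re-deriving the same-display predictor each time.
#'
#' @param trials Trial tibble; displays with fewer than 3 tested items are
#'   skipped (their count is reported).
#' @param n_draws Independent resamplings of the random predictor over which
#'   its slope is averaged; the emitted `pred_random` column is the first.
#' @param seed Seed for the sampled predictor (and permutations).
#' @param n_perms Number of display-label permutations for the null (0 = none).
#' @return List with `predictors` (trial-level tibble), `effect`
#'   (`slope_same - slope_random`), `slope_same`, `slope_random`,
#'   `n_skipped_displays`, and `null_effects` (length `n_perms`).
#' @export
within_display_dependency <- function(trials, n_draws = 50, seed = 1,
                                      n_perms = 0) {
  if (!"signed_error_deg" %in% names(trials)) {
    trials$signed_error_deg <- wrap_error(trials$target_deg, trials$response_deg)
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  d <- trials |>
    dplyr::mutate(abs_err = abs(.data$signed_error_deg)) |>
    dplyr::group_by(.data$subject_id, .data$display_id) |>
    dplyr::mutate(n_in_display = dplyr::n()) |>
    dplyr::ungroup()
  n_skipped <- d |>
    dplyr::filter(.data$n_in_display < 3) |>
    dplyr::distinct(.data$subject_id, .data$display_id) |>
    nrow()
  d <- dplyr::filter(d, .data$n_in_display >= 3)
  if (nrow(d) == 0) stop("no displays with >= 3 tested items", call. = FALSE)
  same_pred <- function(dat) {
    dat |>
      dplyr::group_by(.data$subject_id, .data$display_id) |>
      dplyr::mutate(pred_same = (sum(.data$abs_err) - .data$abs_err) /
                      (.data$n_in_display - 1)) |>
      dplyr::ungroup()
  }
  d <- same_pred(d)
  centered_slope <- function(y, x, g) {
    yc <- y - stats::ave(y, g)
    xc <- x - stats::ave(x, g)
    sum(xc * yc) / sum(xc^2)
  }
  # random baseline: errors resampled with replacement within subject
  idx_by_subj <- split(seq_len(nrow(d)), d$subject_id)
  draw_random <- function() {
    x <- numeric(nrow(d))
    for (ii in idx_by_subj) {
      x[ii] <- d$abs_err[ii][sample.int(length(ii), length(ii), replace = TRUE)]
    }
    x
  }
  rand_cols <- replicate(n_draws, draw_random(), simplify = FALSE)
  d$pred_random <- rand_cols[[1]]
  slope_same <- centered_slope(d$abs_err, d$pred_same, d$subject_id)
  slope_random <- mean(vapply(rand_cols, function(x) {
    centered_slope(d$abs_err, x, d$subject_id)
  }, numeric(1)))
  null_effects <- numeric(0)
  if (n_perms > 0) {
    null_effects <- vapply(seq_len(n_perms), function(p) {
      dp <- d |>
        dplyr::group_by(.data$subject_id) |>
        dplyr::mutate(display_id = sample(.data$display_id)) |>
        dplyr::ungroup()
      dp <- same_pred(dp)
      centered_slope(dp$abs_err, dp$pred_same, dp$subject_id) - slope_random
    }, numeric(1))
  }
  list(predictors = dplyr::select(d, dplyr::all_of(c(
         "subject_id", "display_id", "trial_index", "abs_err",
         "pred_same", "pred_random"))),
       effect = slope_same - slope_random,
       slope_same = slope_same, slope_random = slope_random,
       n_skipped_displays = n_skipped,
       null_effects = null_effects)
}
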