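#' Quality flags for a mixture fit
#'
#' Applies the exclusion heuristics used with subject-level mixture fits:
#' `"low_pT_trials"` when the expected number of von Mises trials
#' (`p_t * n_trials`) falls below `min_vm_trials` — low retrieval success
#' leaves too few target-centred trials and artificially inflates kappa;
#' `"nonconvergence"` when any split-Rhat exceeds `rhat_max`;
#' `"boundary_estimate"` when a point estimate sits at (within tolerance of)
#' a bound of its allowed range.
#'
#' @param fit A `mixture_fit`.
#' @param min_vm_trials Minimum expected von Mises trial count.
#' @param rhat_max Split-Rhat threshold.
#' @param kappa_bounds Kappa range used to detect boundary estimates.
#' @return Character vector of flags (possibly empty).
#' @export
flag_fit_quality <- function(fit, min_vm_trials = 10, rhat_max = 1.05,
                             kappa_bounds = c(0.5, 500)) {
  stopifnot(inherits(fit, "mixture_fit"))
  flags <- character(0)
  if (fit$model != "uniform_only" &&
      fit$point$p_t * fit$n_trials < min_vm_trials) {
    flags <- c(flags, "low_pT_trials")
  }
  rhat <- fit$diagnostics$rhat
  if (length(rhat) > 0 && any(is.finite(rhat) & rhat > rhat_max)) {
    flags <- c(flags, "nonconvergence")
  }
  pt <- fit$point$p_t; pnt <- fit$point$p_nt; k <- fit$point$kappa
  tol_p <- 1e-3
  at_bound <- (fit$model != "uniform_only") &&
    (pt < tol_p || pt > 1 - tol_p ||
       (fit$model == "swap_mixture" && (pnt < tol_p || pnt > 1 - tol_p)) ||
       (!is.na(k) && (k < kappa_bounds[1] * 1.01 || k > kappa_bounds[2] * 0.99)))
  if (at_bound) flags <- c(flags, "boundary_estimate")
  flags
}

#' Model selection over a set of mixture fits
#'
#' Ranks candidate mixture models fitted to the same errors. MLE fits are
#' scored by AIC and Bayesian fits by DIC; both are reported, and when any
#' Bayesian fit is present the winner is chosen by DIC, otherwise by AIC
#' (lower is better in both cases).
#'
#' @param fits List of `mixture_fit` objects fitted to identical data.
#' @return List with `winner` (the model name of the preferred fit), `fit`
#'   (the preferred `mixture_fit`) and `table` (a tibble of per-model scores,
#'   ranked best first).
#' @export
select_mixture_model <- function(fits) {
  if (inherits(fits, "mixture_fit")) fits <- list(fits)
  stopifnot(length(fits) >= 1, all(vapply(fits, inherits, logical(1), "mixture_fit")))
  e1 <- fits[[1]]$errors
  same <- vapply(fits, function(f) isTRUE(all.equal(f$errors, e1)), logical(1))
  if (!all(same)) stop("all fits must be on identical data", call. = FALSE)
  tab <- dplyr::bind_rows(lapply(fits, function(f) {
    tibble::tibble(
      model = f$model, method = f$method, loglik = f$loglik,
      aic = if (f$method == "mle") unname(f$criterion["AIC"]) else NA_real_,
      dic = if (f$method == "bayes") unname(f$criterion["DIC"]) else NA_real_
    )
  }))
  use_dic <- any(!is.na(tab$dic))
  tab$score <- if (use_dic) tab$dic else tab$aic
  tab$criterion_used <- ifelse(is.na(tab$score), NA_character_,
                               if (use_dic) "DIC" else "AIC")
  ord <- order(tab$score)
  tab <- tab[ord, ]
  fits <- fits[ord]
  list(winner = tab$model[1], fit = fits[[1]], table = tab)
}

#' Percent overlap of two posterior sample sets
#'
#' Overlap coefficient of the two kernel-density estimates on a shared grid,
#' expressed as a percentage: `100 * integral of min(f_a, f_b)`. Symmetric in
#' its arguments, bounded in \[0, 100\], and 100 for identical sample sets.
#' Used to compare group-level posterior distributions of a mixture parameter;
#' values near 0 indicate credibly nonoverlapping groups.
#'
#' @param samples_a,samples_b Numeric vectors of posterior draws.
#' @param n_grid Number of grid points for the density evaluation.
#' @return Overlap, percent.
#' @export
posterior_overlap <- function(samples_a, samples_b, n_grid = 1024) {
  if (length(samples_a) == 0 || length(samples_b) == 0) {
    stop("sample sets must be nonempty", call. = FALSE)
  }
  lo <- min(samples_a, samples_b); hi <- max(samples_a, samples_b)
  if (hi - lo < 1e-12) return(100) # degenerate: identical point masses
  pad <- 0.05 * (hi - lo)
  fa <- stats::density(samples_a, from = lo - pad, to = hi + pad, n = n_grid)
  fb <- stats::density(samples_b, from = lo - pad, to = hi + pad, n = n_grid)
  dx <- fa$x[2] - fa$x[1]
  min(100, 100 * sum(pmin(fa$y, fb$y)) * dx)
}

#' Guess cutoff from a pooled mixture fit
#'
#' The absolute error at which guessing becomes the more likely source of a
#' response: the smallest |error| where the uniform component's weighted
#' density `p_u / 360` first exceeds the target component's weighted density
#' `p_t * vM(e; 0, kappa)`. With no guess component (`p_u = 0`) there is no
#' guess region and the cutoff is 180.
#'
#' @param params A `mixture_params()` row, typically from a fit pooled across
#'   participants.
#' @return Cutoff in degrees, in (0, 180].
#' @export
derive_guess_cutoff <- function(params) {
  p_t <- params$p_t; p_u <- params$p_u; kappa <- params$kappa
  if (p_u <= 1e-12) return(180)
  if (p_t <= 1e-12) return(0)
  h <- function(e) p_t * dvonmises_deg(e, 0, kappa) - p_u / 360
  if (h(0) <= 0) return(0)     # guessing dominates even at the target
  if (h(180) > 0) return(180)  # target component dominates everywhere
  stats::uniroot(h, c(0, 180), tol = 1e-9)$root
}

#' Adjusted precision from trials inside the guess cutoff
#'
#' Recomputes dispersion using only trials whose absolute error falls below
#' the cutoff, i.e. trials plausibly drawn from the target component rather
#' than from guessing. Reports the circular SD of the retained errors and the
#' corresponding concentration.
#'
#' @param errors_deg Signed errors, degrees.
#' @param cutoff_deg Guess cutoff, degrees, in (0, 180].
#' @return One-row tibble: `n_total`, `n_used`, `cutoff_deg`, `sd_deg`, `kappa`.
#' @export
adjusted_precision <- function(errors_deg, cutoff_deg) {
  stopifnot(cutoff_deg > 0, cutoff_deg <= 180)
  keep <- abs(errors_deg) < cutoff_deg
  if (sum(keep) < 2) {
    return(tibble::tibble(n_total = length(errors_deg), n_used = sum(keep),
                          cutoff_deg = cutoff_deg, sd_deg = NA_real_,
                          kappa = NA_real_))
  }
  s <- .circ_sd_deg(errors_deg[keep])
  tibble::tibble(n_total = length(errors_deg), n_used = sum(keep),
                 cutoff_deg = cutoff_deg, sd_deg = s, kappa = sd_to_kappa(s))
}
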