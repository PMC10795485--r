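# Direct mixture sampler used as an independent generator for recovery tests:
# intentionally bypasses simulate_localization() so fits are checked against
# data produced by a second route.
gen_mixture_errors <- function(n, p_t, kappa, p_nt = 0, offsets = NULL) {
  u <- stats::runif(n)
  e <- numeric(n)
  vm <- u < p_t
  e[vm] <- rvonmises_deg(sum(vm), 0, kappa)
  sw <- !vm & u < p_t + p_nt
  if (any(sw)) {
    pick <- ifelse(stats::runif(sum(sw)) < 0.5, 1, 2)
    e[sw] <- rvonmises_deg(sum(sw), offsets[cbind(which(sw), pick)], kappa)
    e[sw] <- wrap_error(0, e[sw])
  }
  e[!vm & !sw] <- stats::runif(sum(!vm & !sw), -180, 180)
  e
}

# exhaustive grid-search oracle for the standard-mixture MLE
grid_best_loglik <- function(errors, p_step = 0.01, k_step = 0.25,
                             k_max = 60) {
  ce <- cos(errors * pi / 180)
  kgrid <- seq(0.5, k_max, by = k_step)
  pgrid <- seq(0, 1, by = p_step)
  best <- -Inf
  for (k in kgrid) {
    ft <- exp(k * (ce - 1)) / (360 * besselI(k, 0, expon.scaled = TRUE))
    for (p in pgrid) {
      ll <- sum(log(p * ft + (1 - p) / 360))
      if (ll > best) best <- ll
    }
  }
  best
}

# small synthetic neuropsychological score table
toy_scores <- function() {
  tibble::tibble(
    subject_id = paste0("s", 1:4),
    digit_span = c(10, 12, 14, 16),
    trails = c(60, 50, 40, 30),
    fluency = c(20, 18, 16, 14),
    rocft_delayed = c(20, 22, 24, 26),
    ravlt_delayed = c(10, 11, 12, 13))
}
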