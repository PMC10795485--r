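#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("<mixture_fit: %s, %s, %d trials>\n", x$model, x$method, x$n_trials))
  p <- x$point
  cat(sprintf("  p_t = %.3f  p_u = %.3f  p_nt = %.3f  kappa = %s  sd = %s deg\n",
              p$p_t, p$p_u, p$p_nt,
              ifelse(is.na(p$kappa), "NA", sprintf("%.2f", p$kappa)),
              ifelse(is.na(p$sd_deg), "NA", sprintf("%.2f", p$sd_deg))))
  cat(sprintf("  loglik = %.2f", x$loglik))
  if (!is.null(x$criterion)) {
    cat(sprintf("  %s = %.2f", names(x$criterion)[1], x$criterion[1]))
  }
  cat("\n")
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Tidy a mixture fit into one row per parameter
#'
#' Returns `term`/`estimate` pairs for the fitted mixture parameters. For
#' Bayesian fits the posterior is summarised alongside the point estimate:
#' posterior mean, 95% equal-tailed credible interval and split-Rhat.
#'
#' @param x A `mixture_fit`.
#' @param conf_level Credible-interval level for Bayesian fits.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate` and, for Bayesian fits,
#'   `mean`, `conf.low`, `conf.high`, `rhat`.
#' @method tidy mixture_fit
#' @export
tidy.mixture_fit <- function(x, conf_level = 0.95, ...) {
  terms <- c("p_t", "p_u", "p_nt", "kappa", "sd_deg")
  out <- tibble::tibble(
    term = terms,
    estimate = vapply(terms, function(t) x$point[[t]], numeric(1))
  )
  if (x$method == "bayes" && !is.null(x$posterior) && nrow(x$posterior) > 1) {
    a <- (1 - conf_level) / 2
    post <- x$posterior
    post$p_u <- 1 - post$p_t - post$p_nt
    qs <- lapply(terms, function(t) {
      v <- post[[t]]
      c(mean(v), stats::quantile(v, c(a, 1 - a), names = FALSE))
    })
    out$mean <- vapply(qs, `[`, numeric(1), 1)
    out$conf.low <- vapply(qs, `[`, numeric(1), 2)
    out$conf.high <- vapply(qs, `[`, numeric(1), 3)
    rhat <- x$diagnostics$rhat
    out$rhat <- unname(rhat[out$term])
  }
  out
}

#' One-row summary of a mixture fit
#'
#' @param x A `mixture_fit`.
#' @param ... Unused.
#' @return A tibble with the model, method, point estimates, log-likelihood,
#'   information criterion, trial count, flag summary and acceptance rate
#'   (Bayesian fits).
#' @method glance mixture_fit
#' @export
glance.mixture_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model, method = x$method,
    p_t = x$point$p_t, p_nt = x$point$p_nt, kappa = x$point$kappa,
    sd_deg = x$point$sd_deg,
    loglik = x$loglik,
    criterion = if (is.null(x$criterion)) NA_real_ else unname(x$criterion[1]),
    criterion_name = if (is.null(x$criterion)) NA_character_ else names(x$criterion)[1],
    n_trials = x$n_trials,
    n_flags = length(x$flags),
    flags = paste(x$flags, collapse = ";"),
    accept_rate = if (is.null(x$diagnostics)) NA_real_ else x$diagnostics$accept_rate
  )
}
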