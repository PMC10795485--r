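#' @importFrom rlang .data
NULL

.mixture_models <- c("uniform_only", "standard_mixture", "swap_mixture")

#' Mixture parameter set for circular localization errors
#'
#' Bundles the parameters of the von Mises-uniform mixture: retrieval success
#' `p_t` (proportion of trials drawn from a von Mises centred on the target),
#' misbinding proportion `p_nt` (von Mises components centred on nontargets; 0
#' for the standard two-component mixture), the implied guess rate
#' `p_u = 1 - p_t - p_nt`, the concentration `kappa` and its circular SD in
#' degrees.
#'
#' @param p_t Proportion of target-centred responses, in \[0, 1\].
#' @param kappa Von Mises concentration, `> 0` (may be `NA` when
#'   `p_t + p_nt == 0`, i.e. a pure-guessing model with no von Mises component).
#' @param p_nt Misbinding proportion, in \[0, 1\]; `p_t + p_nt <= 1`.
#' @return A one-row tibble with columns `p_t`, `p_u`, `p_nt`, `kappa`, `sd_deg`.
#' @export
mixture_params <- function(p_t, kappa, p_nt = 0) {
  stopifnot(length(p_t) == 1, length(kappa) == 1, length(p_nt) == 1)
  if (!is.finite(p_t) || p_t < 0 || p_t > 1) stop("p_t must be in [0,1]", call. = FALSE)
  if (!is.finite(p_nt) || p_nt < 0 || p_nt > 1) stop("p_nt must be in [0,1]", call. = FALSE)
  if (p_t + p_nt > 1 + 1e-9) stop("p_t + p_nt must not exceed 1", call. = FALSE)
  if (is.na(kappa)) {
    if (p_t + p_nt > 1e-12) stop("kappa required when p_t + p_nt > 0", call. = FALSE)
  } else if (!is.finite(kappa) || kappa <= 0) {
    stop("kappa must be > 0", call. = FALSE)
  }
  tibble::tibble(
    p_t = p_t, p_u = 1 - p_t - p_nt, p_nt = p_nt, kappa = kappa,
    sd_deg = if (is.na(kappa)) NA_real_ else kappa_to_sd(kappa)
  )
}

# precompute the trig terms the likelihood needs; offsets is an n x 2 matrix of
# signed nontarget offsets (deg) or NULL
.mixture_data <- function(errors_deg, nontarget_offsets = NULL) {
  e <- as.numeric(errors_deg)
  if (length(e) == 0) stop("at least one error is required", call. = FALSE)
  if (!all(is.finite(e))) stop("errors must be finite", call. = FALSE)
  d <- list(n = length(e), ce = cos(e * pi / 180))
  if (!is.null(nontarget_offsets)) {
    off <- as.matrix(nontarget_offsets)
    if (nrow(off) != length(e)) {
      stop("nontarget_offsets must have one row per trial", call. = FALSE)
    }
    d$co <- cos((e - off) * pi / 180) # n x n_nontargets
  }
  d
}

.loglik_core <- function(dat, p_t, p_nt, kappa) {
  p_u <- 1 - p_t - p_nt
  dens <- rep(p_u / 360, dat$n)
  if (p_t + p_nt > 0) {
    i0e <- besselI(kappa, 0, expon.scaled = TRUE)
    if (p_t > 0) dens <- dens + p_t * exp(kappa * (dat$ce - 1)) / (360 * i0e)
    if (p_nt > 0) {
      fnt <- rowMeans(exp(kappa * (dat$co - 1))) / (360 * i0e)
      dens <- dens + p_nt * fnt
    }
  }
  sum(log(dens))
}

#' Log-likelihood of a von Mises-uniform mixture
#'
#' Sum over trials of `log(p_t vM(e; 0, kappa) + p_nt mean_j vM(e; off_j, kappa)
#' + p_u / 360)`, with the von Mises density per degree. The swap (misbinding)
#' components are centred on the signed offsets of the nontargets from the
#' target and averaged with equal weight.
#'
#' @param errors_deg Signed localization errors, degrees in (-180, 180].
#' @param params A `mixture_params()` row (or any list with `p_t`, `p_nt`,
#'   `kappa`).
#' @param nontarget_offsets Optional n x 2 matrix of signed nontarget offsets
#'   (degrees); required when `params$p_nt > 0`.
#' @return Log-likelihood in nats.
#' @export
mixture_loglik <- function(errors_deg, params, nontarget_offsets = NULL) {
  p_t <- params$p_t; p_nt <- params$p_nt; kappa <- params$kappa
  if (p_nt > 0 && is.null(nontarget_offsets)) {
    stop("nontarget_offsets required for a swap mixture", call. = FALSE)
  }
  dat <- .mixture_data(errors_deg, nontarget_offsets)
  if (is.na(kappa)) kappa <- 1 # unused: weights are zero
  .loglik_core(dat, p_t, p_nt, kappa)
}

.new_mixture_fit <- function(model, method, point, loglik, n_trials,
                             posterior = NULL, diagnostics = NULL,
                             flags = character(0), errors = NULL,
                             nontarget_offsets = NULL, criterion = NULL) {
  structure(
    list(model = model, method = method, point = point, loglik = loglik,
         n_trials = n_trials, posterior = posterior, diagnostics = diagnostics,
         flags = flags, errors = errors, nontarget_offsets = nontarget_offsets,
         criterion = criterion),
    class = "mixture_fit"
  )
}

.check_fit_inputs <- function(errors_deg, model, nontarget_offsets, min_trials) {
  model <- match.arg(model, .mixture_models)
  if (length(errors_deg) < min_trials) {
    stop(sprintf("need at least %d trials, got %d", min_trials, length(errors_deg)),
         call. = FALSE)
  }
  if (model == "swap_mixture" && is.null(nontarget_offsets)) {
    stop("swap_mixture requires nontarget_offsets for every trial", call. = FALSE)
  }
  model
}

#' Maximum-likelihood fit of a circular mixture model
#'
#' Multi-start bounded optimization of the mixture log-likelihood. Mixing
#' proportions are optimized on the multinomial-logit scale and kappa on the
#' log scale within `kappa_bounds`; the best of `n_starts` random starts is
#' returned. `uniform_only` has no free parameters and is evaluated in closed
#' form (`n log(1/360)`).
#'
#' @param errors_deg Signed errors, degrees.
#' @param model One of `"standard_mixture"` (default), `"uniform_only"`,
#'   `"swap_mixture"`.
#' @param nontarget_offsets n x 2 matrix of signed nontarget offsets, degrees;
#'   required for the swap model.
#' @param n_starts Number of random multi-starts.
#' @param seed Optional integer seed; the fit is deterministic given the seed.
#' @param min_trials Refuse to fit fewer trials than this.
#' @param kappa_bounds Allowed kappa range.
#' @return A `mixture_fit` object (see [tidy.mixture_fit()], [glance.mixture_fit()]).
#' @export
fit_mixture_mle <- function(errors_deg, model = "standard_mixture",
                            nontarget_offsets = NULL, n_starts = 10,
                            seed = NULL, min_trials = 20,
                            kappa_bounds = c(0.5, 500)) {
  model <- .check_fit_inputs(errors_deg, model, nontarget_offsets, min_trials)
  n <- length(errors_deg)
  if (model == "uniform_only") {
    point <- mixture_params(0, NA_real_, 0)
    ll <- n * log(1 / 360)
    fit <- .new_mixture_fit(model, "mle", point, ll, n, errors = errors_deg,
                            criterion = c(AIC = -2 * ll))
    fit$flags <- flag_fit_quality(fit)
    return(fit)
  }
  dat <- .mixture_data(errors_deg,
                       if (model == "swap_mixture") nontarget_offsets else NULL)
  if (!is.null(seed)) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
  }
  lk <- log(kappa_bounds)
  swap <- model == "swap_mixture"
  to_par <- function(theta) {
    # theta: logits (p_t [, p_nt] vs guess) then log kappa
    if (swap) {
      z <- exp(c(theta[1], theta[2], 0))
      w <- z / sum(z)
      list(p_t = w[1], p_nt = w[2], kappa = exp(theta[3]))
    } else {
      list(p_t = stats::plogis(theta[1]), p_nt = 0, kappa = exp(theta[2]))
    }
  }
  nll <- function(theta) {
    p <- to_par(theta)
    -.loglik_core(dat, p$p_t, p$p_nt, p$kappa)
  }
  np <- if (swap) 3 else 2
  lower <- c(rep(-15, np - 1), lk[1]); upper <- c(rep(15, np - 1), lk[2])
  starts <- lapply(seq_len(n_starts), function(i) {
    if (i == 1) {
      # moment-style start: resultant length of the whole sample
      rbar <- sqrt(mean(cos(errors_deg * pi / 180))^2 +
                     mean(sin(errors_deg * pi / 180))^2)
      p0 <- min(0.95, max(0.05, rbar))
      k0 <- min(kappa_bounds[2], max(kappa_bounds[1], sd_to_kappa(
        max(2, .circ_sd_safe(errors_deg)))))
      if (swap) c(log(p0 / (1 - p0)), -2, log(k0)) else c(log(p0 / (1 - p0)), log(k0))
    } else {
      c(stats::runif(np - 1, -3, 3), stats::runif(1, lk[1], lk[2]))
    }
  })
  best <- NULL
  for (s in starts) {
    o <- tryCatch(
      stats::optim(s, nll, method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = 500)),
      error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best)) stop("optimization failed from every start", call. = FALSE)
  p <- to_par(best$par)
  point <- mixture_params(p$p_t, p$kappa, p$p_nt)
  ll <- -best$value
  fit <- .new_mixture_fit(model, "mle", point, ll, n,
                          errors = errors_deg,
                          nontarget_offsets = nontarget_offsets,
                          criterion = c(AIC = 2 * np - 2 * ll))
  fit$flags <- flag_fit_quality(fit, kappa_bounds = kappa_bounds)
  fit
}

.circ_sd_safe <- function(x) {
  s <- .circ_sd_deg(x)
  if (!is.finite(s) || s <= 0) 2 else s
}

# save/restore .Random.seed so seeded fits do not disturb the caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# fast sd (deg) -> kappa via a monotone spline, cached; used inside MCMC where
# an exact root search per iteration would dominate the run time
.sd2k_env <- new.env(parent = emptyenv())
.sd2k_fast <- function(sd_deg) {
  if (is.null(.sd2k_env$fun)) {
    kgrid <- exp(seq(log(1e-3), log(2e4), length.out = 4000))
    sdgrid <- vapply(kgrid, function(k) sqrt(-2 * log(.vm_rbar(k))) * 180 / pi,
                     numeric(1))
    ord <- order(sdgrid)
    .sd2k_env$fun <- stats::splinefun(sdgrid[ord], log(kgrid[ord]),
                                      method = "monoH.FC")
  }
  exp(.sd2k_env$fun(sd_deg))
}

#' Bayesian fit of a circular mixture model
#'
#' Random-walk Metropolis sampling of the mixture posterior under diffuse
#' priors: mixing proportions flat on the probability simplex and the von Mises
#' circular SD flat on `sd_bounds` (default \[0.5, 180\] degrees), the kappa
#' scale implied by the change of variables. Runs `n_chains` chains with
#' overdispersed starts; convergence is summarised by split-Rhat per parameter
#' and an autocorrelation-based effective sample size. The MAP estimate is the
#' highest-posterior draw refined by local optimization (under these flat
#' priors it coincides with the MLE in the (p, SD) parameterisation).
#'
#' Nonconvergence (any Rhat above `rhat_max`) sets the `"nonconvergence"` flag
#' rather than raising an error.
#'
#' @inheritParams fit_mixture_mle
#' @param n_chains Number of chains.
#' @param n_samples Post-burn-in draws per chain.
#' @param n_burnin Burn-in draws per chain, discarded.
#' @param sd_bounds Prior support for the circular SD, degrees.
#' @param rhat_max Split-Rhat threshold for the nonconvergence flag.
#' @return A `mixture_fit` with `$posterior` (one row per retained draw:
#'   `chain`, `p_t`, `p_nt`, `sd_deg`, `kappa`, `loglik`) and `$diagnostics`.
#' @export
fit_mixture_bayes <- function(errors_deg, model = "standard_mixture",
                              nontarget_offsets = NULL, n_chains = 3,
                              n_samples = 5000, n_burnin = 1000, seed = NULL,
                              min_trials = 20, sd_bounds = c(0.5, 180),
                              rhat_max = 1.05) {
  model <- .check_fit_inputs(errors_deg, model, nontarget_offsets, min_trials)
  n <- length(errors_deg)
  if (model == "uniform_only") {
    # no free parameters: the posterior is a point mass at the closed form
    point <- mixture_params(0, NA_real_, 0)
    ll <- n * log(1 / 360)
    post <- tibble::tibble(chain = 1L, p_t = 0, p_nt = 0, sd_deg = NA_real_,
                           kappa = NA_real_, loglik = ll)
    fit <- .new_mixture_fit(model, "bayes", point, ll, n, posterior = post,
                            diagnostics = list(rhat = c(), accept_rate = NA_real_,
                                               n_eff = c()),
                            errors = errors_deg, criterion = c(DIC = -2 * ll))
    fit$flags <- flag_fit_quality(fit, rhat_max = rhat_max)
    return(fit)
  }
  if (!is.null(seed)) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
  }
  swap <- model == "swap_mixture"
  dat <- .mixture_data(errors_deg,
                       if (swap) nontarget_offsets else NULL)
  lp <- function(p_t, p_nt, sd_deg) {
    # flat prior inside the support; -Inf outside
    if (p_t < 0 || p_nt < 0 || p_t + p_nt > 1 ||
        sd_deg < sd_bounds[1] || sd_deg > sd_bounds[2]) return(-Inf)
    .loglik_core(dat, p_t, p_nt, .sd2k_fast(sd_deg))
  }
  step <- c(p = 0.06, sd = 4) # RW proposal scales (probability units, degrees)
  total <- n_burnin + n_samples
  draws <- vector("list", n_chains)
  n_acc <- 0L
  for (ch in seq_len(n_chains)) {
    # overdispersed starts across the support
    p_t <- stats::runif(1, 0.1, 0.9)
    p_nt <- if (swap) stats::runif(1, 0, 1 - p_t) else 0
    sd_deg <- stats::runif(1, sd_bounds[1] + 1, sd_bounds[2] - 1)
    cur <- lp(p_t, p_nt, sd_deg)
    m <- matrix(NA_real_, n_samples, 4)
    for (it in seq_len(total)) {
      p_t2 <- p_t + stats::rnorm(1, 0, step["p"])
      p_nt2 <- if (swap) p_nt + stats::rnorm(1, 0, step["p"]) else 0
      sd2 <- sd_deg + stats::rnorm(1, 0, step["sd"])
      cand <- lp(p_t2, p_nt2, sd2)
      if (is.finite(cand) && log(stats::runif(1)) < cand - cur) {
        p_t <- p_t2; p_nt <- p_nt2; sd_deg <- sd2; cur <- cand
        if (it > n_burnin) n_acc <- n_acc + 1L
      }
      if (it > n_burnin) m[it - n_burnin, ] <- c(p_t, p_nt, sd_deg, cur)
    }
    draws[[ch]] <- m
  }
  pars <- if (swap) c("p_t", "p_nt", "sd_deg") else c("p_t", "sd_deg")
  idx <- c(p_t = 1, p_nt = 2, sd_deg = 3)
  rhat <- vapply(pars, function(p) {
    .split_rhat(lapply(draws, function(m) m[, idx[[p]]]))
  }, numeric(1))
  n_eff <- vapply(pars, function(p) {
    sum(vapply(draws, function(m) .ess(m[, idx[[p]]]), numeric(1)))
  }, numeric(1))
  post <- dplyr::bind_rows(lapply(seq_len(n_chains), function(ch) {
    m <- draws[[ch]]
    tibble::tibble(chain = ch, p_t = m[, 1], p_nt = m[, 2], sd_deg = m[, 3],
                   kappa = .sd2k_fast(m[, 3]), loglik = m[, 4])
  }))
  # MAP: best draw refined by bounded local optimization of the log-posterior
  best <- post[which.max(post$loglik), ]
  refine <- function(theta) {
    v <- lp(theta[1], if (swap) theta[2] else 0, theta[length(theta)])
    if (is.finite(v)) -v else 1e10
  }
  th0 <- if (swap) c(best$p_t, best$p_nt, best$sd_deg) else c(best$p_t, best$sd_deg)
  lo <- c(rep(1e-6, length(th0) - 1), sd_bounds[1])
  hi <- c(rep(1 - 1e-6, length(th0) - 1), sd_bounds[2])
  o <- tryCatch(stats::optim(th0, refine, method = "L-BFGS-B", lower = lo,
                             upper = hi),
                error = function(e) list(par = th0, value = refine(th0)))
  p_t_hat <- o$par[1]
  p_nt_hat <- if (swap) o$par[2] else 0
  sd_hat <- o$par[length(o$par)]
  point <- mixture_params(p_t_hat, sd_to_kappa(sd_hat), p_nt_hat)
  ll <- .loglik_core(dat, p_t_hat, p_nt_hat, point$kappa)
  # DIC from the likelihood deviance: 2 * mean(D) - D(posterior mean)
  dbar <- mean(-2 * post$loglik)
  dhat <- -2 * .loglik_core(dat, mean(post$p_t), mean(post$p_nt),
                            .sd2k_fast(mean(post$sd_deg)))
  fit <- .new_mixture_fit(model, "bayes", point, ll, n, posterior = post,
                          diagnostics = list(
                            rhat = rhat,
                            accept_rate = n_acc / (n_chains * n_samples),
                            n_eff = n_eff),
                          errors = errors_deg,
                          nontarget_offsets = nontarget_offsets,
                          criterion = c(DIC = 2 * dbar - dhat))
  fit$flags <- flag_fit_quality(fit, rhat_max = rhat_max)
  fit
}

# split-Rhat (Gelman et al.): halve each chain, then classic potential scale
# reduction across the 2m half-chains
.split_rhat <- function(chains) {
  halves <- unlist(lapply(chains, function(x) {
    h <- length(x) %/% 2
    list(x[seq_len(h)], x[seq(h + 1, 2 * h)])
  }), recursive = FALSE)
  m <- length(halves); n <- length(halves[[1]])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  w <- mean(vars)
  b <- n * stats::var(means)
  if (w < 1e-300) return(1)
  sqrt(((n - 1) / n * w + b / n) / w)
}

# effective size of one chain from the initial positive autocorrelation sums
.ess <- function(x) {
  n <- length(x)
  ac <- stats::acf(x, lag.max = min(200, n - 1), plot = FALSE)$acf[-1]
  s <- 0
  for (r in ac) {
    if (r < 0.05) break
    s <- s + r
  }
  n / (1 + 2 * s)
}
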