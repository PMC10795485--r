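#' Proportion correct in an m-alternative forced choice task
#'
#' Expected accuracy of an unbiased observer choosing among `m` alternatives
#' at sensitivity `d_prime`:
#' `pc = integral phi(x - d') Phi(x)^(m-1) dx`, evaluated by adaptive
#' quadrature. At `d_prime = 0` this is chance, `1/m`.
#'
#' @param d_prime Sensitivity (may be vectorised).
#' @param m Number of alternatives, `>= 2`.
#' @return Proportion correct in (0, 1).
#' @export
pc_mafc <- function(d_prime, m) {
  stopifnot(length(m) == 1)
  if (m < 2 || m != round(m)) stop("m must be an integer >= 2", call. = FALSE)
  vapply(d_prime, function(d) {
    if (!is.finite(d)) stop("d_prime must be finite", call. = FALSE)
    stats::integrate(function(x) stats::dnorm(x - d) * stats::pnorm(x)^(m - 1),
                     -Inf, Inf, rel.tol = 1e-10)$value
  }, numeric(1))
}

#' d-prime from m-AFC proportion correct
#'
#' Numerical inverse of [pc_mafc()] by bracketed root search on d' in
#' \[0, 10\]. Below-chance and perfect scores are outside the domain; recode
#' them first (see [recode_below_chance()]).
#'
#' @param pc Proportion correct, strictly between `1/m` and 1.
#' @param m Number of alternatives, `>= 2`.
#' @return Sensitivity d'.
#' @export
dprime_mafc <- function(pc, m) {
  stopifnot(length(m) == 1)
  vapply(pc, function(p) {
    if (!is.finite(p) || p <= 1 / m) {
      stop(sprintf("pc must exceed chance (1/%d); below-chance scores need recoding", m),
           call. = FALSE)
    }
    if (p >= 1) stop("pc = 1 is a boundary; recode before inverting", call. = FALSE)
    stats::uniroot(function(d) pc_mafc(d, m) - p, c(0, 10), tol = 1e-9)$root
  }, numeric(1))
}

#' Psychometric function for the 3-stimulus oddity task (differencing model)
#'
#' Accuracy of a differencing ("triangular") observer picking the odd one out
#' of three stimuli, two of which are identical:
#' `pc = 2 * integral_0^Inf phi(x) [Phi(-x sqrt(3) + d' sqrt(2/3)) +
#' Phi(-x sqrt(3) - d' sqrt(2/3))] dx`.
#' Chance is exactly 1/3 at `d_prime = 0`. Because the differencing strategy
#' discards information, this curve lies below the m-AFC identification curve
#' at the same d'.
#'
#' @param d_prime Sensitivity, `>= 0` (vectorised).
#' @return Proportion correct in \[1/3, 1).
#' @export
pc_oddity3 <- function(d_prime) {
  vapply(d_prime, function(d) {
    if (!is.finite(d) || d < 0) stop("d_prime must be >= 0", call. = FALSE)
    stats::integrate(function(x) {
      2 * stats::dnorm(x) *
        (stats::pnorm(-x * sqrt(3) + d * sqrt(2 / 3)) +
           stats::pnorm(-x * sqrt(3) - d * sqrt(2 / 3)))
    }, 0, Inf, rel.tol = 1e-10)$value
  }, numeric(1))
}

#' d-prime from 3-stimulus oddity accuracy
#'
#' Inverse of [pc_oddity3()] by bracketed root search on \[0, 10\]. The
#' calculation fails for below-chance performance (`pc <= 1/3`); such scores
#' must be recoded first ([recode_below_chance()]).
#'
#' @param pc Proportion correct, strictly between 1/3 and 1.
#' @return Sensitivity d'.
#' @export
dprime_oddity3 <- function(pc) {
  vapply(pc, function(p) {
    if (!is.finite(p) || p <= 1 / 3) {
      stop("pc must exceed chance (1/3); below-chance scores need recoding",
           call. = FALSE)
    }
    if (p >= 1) stop("pc = 1 is a boundary; recode before inverting", call. = FALSE)
    stats::uniroot(function(d) pc_oddity3(d) - p, c(0, 10), tol = 1e-9)$root
  }, numeric(1))
}

#' Recode boundary and below-chance accuracies before d-prime conversion
#'
#' Perfect scores are recoded to `1 - 1/(2 n)`, and zero scores to `1/(2 n)`,
#' the usual half-trial correction. Below-chance scores are handled by `rule`:
#'
#' * `"printed"` (default): recode to `1 - 1/(2 n)`, applying the published
#'   recoding rule for at-chance observers literally. Note this maps a
#'   below-chance score to a near-perfect one.
#' * `"chance"`: recode to the chance level `1/m` plus half a trial,
#'   `1/m + 1/(2 n)`, so the converted d' is just above zero — the
#'   conventional reading that a below-chance observer carries no signal.
#'
#' @param pc Proportion(s) correct in \[0, 1\].
#' @param n_trials Number of trials behind each proportion.
#' @param chance Chance level (1/3 for 3-stimulus oddity, 1/2 for 2AFC).
#' @param rule Below-chance handling, `"printed"` or `"chance"`.
#' @return A tibble with columns `pc` (recoded value) and `recoded` (logical).
#' @export
recode_below_chance <- function(pc, n_trials, chance = 1 / 3,
                                rule = c("printed", "chance")) {
  rule <- match.arg(rule)
  stopifnot(all(n_trials > 0))
  n_trials <- rep_len(n_trials, length(pc))
  out <- pc
  recoded <- rep(FALSE, length(pc))
  below <- pc <= chance
  out[below] <- if (rule == "printed") 1 - 1 / (2 * n_trials[below])
                else chance + 1 / (2 * n_trials[below])
  hi <- !below & pc >= 1
  out[hi] <- 1 - 1 / (2 * n_trials[hi])
  recoded[below | hi] <- TRUE
  tibble::tibble(pc = out, recoded = recoded)
}

#' d-prime for a table of accuracy records
#'
#' Tibble-in/tibble-out wrapper: takes one row per subject x condition with
#' counts, recodes boundary scores, and appends the proportion correct and d'
#' under the row's paradigm (`"mafc"` with `m` alternatives, or `"oddity3"`).
#'
#' @param data Data frame with columns `n_correct`, `n_trials`, `paradigm`
#'   and, for mafc rows, `m`.
#' @param rule Below-chance recoding rule, passed to [recode_below_chance()].
#' @return `data` with `pc`, `recoded` and `d_prime` columns appended.
#' @export
dprime_table <- function(data, rule = "printed") {
  stopifnot(all(c("n_correct", "n_trials", "paradigm") %in% names(data)))
  data <- tibble::as_tibble(data)
  raw <- data$n_correct / data$n_trials
  out <- purrr::pmap(list(raw, data$n_trials, data$paradigm,
                          if ("m" %in% names(data)) data$m else NA),
    function(p, n, paradigm, m) {
      chance <- if (paradigm == "oddity3") 1 / 3 else 1 / m
      rc <- recode_below_chance(p, n, chance = chance, rule = rule)
      d <- if (paradigm == "oddity3") dprime_oddity3(rc$pc)
           else dprime_mafc(rc$pc, m)
      tibble::tibble(pc = rc$pc, recoded = rc$recoded, d_prime = d)
    })
  dplyr::bind_cols(data, dplyr::bind_rows(out))
}
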