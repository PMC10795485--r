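#' Mean absolute localization error
#'
#' Model-free fidelity metric: the mean of |signed error| in degrees. Mixes
#' remembered and guessed trials, so it confounds retrieval success with
#' precision; under pure guessing its expectation is 90 degrees.
#'
#' @param errors_deg Signed errors, degrees.
#' @return Mean absolute error, degrees in \[0, 180\].
#' @export
mean_abs_error <- function(errors_deg) {
  if (length(errors_deg) == 0) stop("at least one error is required", call. = FALSE)
  mean(abs(errors_deg))
}

.trial_schema <- c("subject_id", "age_group", "task", "block", "display_id",
                   "trial_index", "target_deg", "nontarget1_deg",
                   "nontarget2_deg", "response_deg", "ident_correct")

#' Read and validate a trial-level CSV
#'
#' Expects the trial schema written by [generate_session()] / exported by the
#' pipeline: `subject_id, age_group, task, block, display_id, trial_index,
#' target_deg, nontarget1_deg, nontarget2_deg, response_deg, ident_correct`,
#' with angles in decimal degrees \[0, 360). Malformed rows are reported by
#' row number. A `signed_error_deg` column is (re)computed on read.
#'
#' @param path CSV path.
#' @return Trial tibble.
#' @export
read_trials <- function(path) {
  trials <- readr::read_csv(path, show_col_types = FALSE)
  missing <- setdiff(.trial_schema, names(trials))
  if (length(missing) > 0) {
    stop("trial CSV missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  ang_cols <- c("target_deg", "nontarget1_deg", "nontarget2_deg", "response_deg")
  bad <- which(!stats::complete.cases(trials[, ang_cols]) |
                 rowSums(sapply(trials[, ang_cols],
                                function(a) !is.finite(a) | a < 0 | a >= 360)) > 0 |
                 !(trials$ident_correct %in% c(0, 1)))
  if (length(bad) > 0) {
    stop("malformed trial rows (1-based, excluding header): ",
         paste(utils::head(bad, 20), collapse = ", "), call. = FALSE)
  }
  trials$signed_error_deg <- wrap_error(trials$target_deg, trials$response_deg)
  trials
}

#' Per-subject, per-task memory metrics
#'
#' For every subject x task cell: fits the standard mixture model to the
#' signed localization errors (MLE by default, or Bayesian MAP), computes the
#' mean absolute error, and converts 2AFC identification accuracy to d'
#' (recoding boundary scores with the half-trial rule). Fit-quality flags
#' (see [flag_fit_quality()]) propagate into an exclusion flag with a reason,
#' mirroring the practice of excluding subjects whose low retrieval success
#' inflates kappa or whose chains fail to converge; excluded subjects are
#' retained in the output, flagged rather than dropped.
#'
#' @param trials Trial tibble (schema of [read_trials()], with
#'   `signed_error_deg` present or computable).
#' @param method `"mle"` or `"bayes"`.
#' @param min_vm_trials,rhat_max Exclusion thresholds.
#' @param min_trials Minimum trials per fit.
#' @param seed Root seed; each subject x task fit gets a derived substream seed.
#' @param ... Passed to the fitting function.
#' @return Tibble with one row per subject x task: estimates, `mean_abs_error`,
#'   `d_prime`, `flags`, `excluded`, `exclusion_reason`.
#' @export
compute_subject_metrics <- function(trials, method = c("mle", "bayes"),
                                    min_vm_trials = 10, rhat_max = 1.05,
                                    min_trials = 20, seed = 1, ...) {
  method <- match.arg(method)
  if (!"signed_error_deg" %in% names(trials)) {
    trials$signed_error_deg <- wrap_error(trials$target_deg, trials$response_deg)
  }
  cells <- trials |>
    dplyr::group_by(.data$subject_id, .data$age_group, .data$task) |>
    dplyr::group_split()
  out <- purrr::imap(cells, function(cell, i) {
    errs <- cell$signed_error_deg
    fit_seed <- (seed + 7919L * i) %% .Machine$integer.max
    fit <- if (method == "mle") {
      fit_mixture_mle(errs, "standard_mixture", seed = fit_seed,
                      min_trials = min_trials, ...)
    } else {
      fit_mixture_bayes(errs, "standard_mixture", seed = fit_seed,
                        min_trials = min_trials, rhat_max = rhat_max, ...)
    }
    flags <- flag_fit_quality(fit, min_vm_trials = min_vm_trials,
                              rhat_max = rhat_max)
    pc <- recode_below_chance(mean(cell$ident_correct), nrow(cell), chance = 0.5)
    excl_flags <- intersect(flags, c("low_pT_trials", "nonconvergence"))
    tibble::tibble(
      subject_id = cell$subject_id[1], age_group = cell$age_group[1],
      task = cell$task[1], n_trials = nrow(cell),
      mean_abs_error = mean_abs_error(errs),
      p_t = fit$point$p_t, kappa = fit$point$kappa, sd_deg = fit$point$sd_deg,
      d_prime = dprime_mafc(pc$pc, 2), d_prime_recoded = pc$recoded,
      loglik = fit$loglik, flags = paste(flags, collapse = ";"),
      excluded = length(excl_flags) > 0,
      exclusion_reason = paste(excl_flags, collapse = ";"))
  })
  dplyr::bind_rows(out)
}

#' Executive and delayed-memory composite z-scores
#'
#' The executive composite averages z-scored digit span, trail-making time and
#' verbal fluency; the trails time is sign-inverted before z-scoring so that
#' higher always means better. The delayed-memory composite averages z-scored
#' delayed figure recall (ROCFT) and delayed verbal learning (RAVLT). Each
#' composite is re-standardized over the sample after averaging, so included
#' subjects have mean 0 and SD 1.
#'
#' @param scores Data frame with columns `subject_id`, `digit_span`, `trails`,
#'   `fluency`, `rocft_delayed`, `ravlt_delayed`.
#' @return Tibble: `subject_id`, `executive_composite`, `memory_composite`.
#' @export
build_composites <- function(scores) {
  need <- c("subject_id", "digit_span", "trails", "fluency",
            "rocft_delayed", "ravlt_delayed")
  missing <- setdiff(need, names(scores))
  if (length(missing) > 0) {
    stop("missing columns: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  z <- function(x, label) {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) {
      stop("zero variance in component '", label, "'", call. = FALSE)
    }
    (x - mean(x)) / s
  }
  exec_raw <- (z(scores$digit_span, "digit_span") +
                 z(-scores$trails, "trails") +
                 z(scores$fluency, "fluency")) / 3
  mem_raw <- (z(scores$rocft_delayed, "rocft_delayed") +
                z(scores$ravlt_delayed, "ravlt_delayed")) / 2
  tibble::tibble(
    subject_id = scores$subject_id,
    executive_composite = z(exec_raw, "executive composite"),
    memory_composite = z(mem_raw, "memory composite"))
}

#' Export subject metrics as a long, tidy table
#'
#' One row per subject x task x measure, deterministically ordered, suitable
#' for external mixed-model software. Excluded subjects are emitted with
#' `excluded = 1`, not dropped. Round-trips exactly through
#' `readr::read_csv()`.
#'
#' @param metrics Output of [compute_subject_metrics()].
#' @param path Optional CSV path to write to.
#' @param measures Which metric columns to emit.
#' @return The long tibble (invisibly when `path` is given).
#' @export
export_tidy <- function(metrics, path = NULL,
                        measures = c("mean_abs_error", "p_t", "kappa",
                                     "sd_deg", "d_prime")) {
  long <- metrics |>
    dplyr::select(dplyr::all_of(c("subject_id", "age_group", "task",
                                  "excluded", measures))) |>
    dplyr::mutate(excluded = as.integer(.data$excluded)) |>
    tidyr::pivot_longer(dplyr::all_of(measures), names_to = "measure",
                        values_to = "value") |>
    dplyr::arrange(.data$subject_id, .data$task, .data$measure)
  if (!is.null(path)) {
    readr::write_csv(long, path)
    return(invisible(long))
  }
  long
}
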