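#' Observer parameter presets by age group and task
#'
#' Generative observer parameters for three age groups (young, middle, old),
#' giving group-mean retrieval success `p_t`, precision `kappa`, mnemonic
#' discrimination `d_prime` for each task format (STM/LTM), and perceptual
#' discrimination d' for the low- and high-ambiguity oddity conditions,
#' together with the between-subject SDs of each. Misbinding (`p_nt`) and the
#' item-location coupling default to 0.
#'
#' @param age_group `"young"`, `"middle"` or `"old"`.
#' @param task `"STM"` or `"LTM"`.
#' @return One-row tibble of observer parameters for the group x task cell.
#' @export
observer_presets <- function(age_group, task = c("STM", "LTM")) {
  task <- match.arg(task)
  presets <- .preset_table()
  row <- presets[presets$age_group == age_group & presets$task == task, ]
  if (nrow(row) != 1) {
    stop(sprintf("unknown age group '%s'", age_group), call. = FALSE)
  }
  row
}

.preset_table <- function() {
  # group-mean (and between-subject SD) generative parameters
  g <- rep(c("young", "middle", "old"), each = 2)
  t <- rep(c("STM", "LTM"), 3)
  tibble::tibble(
    age_group = g, task = t,
    p_t       = c(0.89, 0.74, 0.82, 0.80, 0.79, 0.70),
    p_t_sd    = c(0.08, 0.22, 0.10, 0.16, 0.09, 0.19),
    kappa     = c(18.12, 13.88, 13.74, 9.64, 9.87, 7.86),
    kappa_sd  = c(7.18, 4.88, 5.46, 5.39, 4.83, 4.61),
    p_nt      = 0,
    d_prime   = c(1.47, 1.82, 1.25, 1.54, 1.12, 1.19),
    d_prime_sd = c(0.37, 0.54, 0.29, 0.51, 0.35, 0.39),
    d_prime_low  = c(5.45, 5.45, 5.40, 5.40, 5.21, 5.21),
    d_prime_high = c(3.25, 3.25, 2.51, 2.51, 2.07, 2.07),
    coupling = 0, display_coupling = 0
  )
}

#' Generate object displays on an invisible circle
#'
#' Places `n_objects` positions per display uniformly on the circle subject to
#' a minimum pairwise circular separation, by rejection sampling (the accepted
#' draws are uniform over the feasible set). The default separation of 62.04
#' degrees ensures objects do not overlap.
#'
#' @param n Number of displays.
#' @param n_objects Objects per display.
#' @param min_separation_deg Minimum pairwise circular separation, degrees.
#' @param max_attempts Rejection-sampling attempt cap per display.
#' @return Tibble with `display_id` and `angle_1` ... `angle_k` columns,
#'   angles in degrees \[0, 360).
#' @export
generate_displays <- function(n, n_objects = 3, min_separation_deg = 62.04,
                              max_attempts = 10000) {
  stopifnot(n >= 0, n_objects >= 1)
  if (n_objects * min_separation_deg >= 360) {
    stop("infeasible: n_objects * min_separation_deg must be < 360", call. = FALSE)
  }
  kept <- matrix(numeric(0), ncol = n_objects)
  attempts <- 0
  while (nrow(kept) < n) {
    batch <- max(1000, 2 * (n - nrow(kept)))
    if (attempts + batch > n * max_attempts + max_attempts) {
      stop("display rejection sampling exceeded attempt cap", call. = FALSE)
    }
    cand <- matrix(stats::runif(batch * n_objects, 0, 360), ncol = n_objects)
    ok <- rep(TRUE, batch)
    if (n_objects > 1) {
      for (i in seq_len(n_objects - 1)) {
        for (j in seq((i + 1), n_objects)) {
          ok <- ok & abs(wrap_error(cand[, i], cand[, j])) >= min_separation_deg
        }
      }
    }
    kept <- rbind(kept, cand[ok, , drop = FALSE])
    attempts <- attempts + batch
  }
  kept <- kept[seq_len(n), , drop = FALSE]
  colnames(kept) <- paste0("angle_", seq_len(n_objects))
  dplyr::bind_cols(tibble::tibble(display_id = seq_len(n)),
                   tibble::as_tibble(kept))
}

#' Simulate 2AFC mnemonic identification responses
#'
#' Bernoulli draws with success probability `pc_mafc(d_prime, 2)`.
#'
#' @param observer Observer tibble/list with a `d_prime` field.
#' @param n Number of trials.
#' @return Integer vector of 0/1 correctness flags.
#' @export
simulate_identification <- function(observer, n) {
  pc <- pc_mafc(observer$d_prime, 2)
  stats::rbinom(n, 1, pc)
}

#' Simulate localization responses from the generative mixture
#'
#' Each trial's response is, with probability `p_t`, the target plus von Mises
#' noise at the trial's concentration; with probability `p_nt`, centred on a
#' randomly chosen nontarget; otherwise uniform on the circle. The trial
#' concentration couples to identification fidelity:
#' `kappa_trial = kappa * exp(coupling * s)`, where `s` is +1 on
#' identification-correct trials and -1 otherwise. A display-shared
#' standard-normal latent `g` models whole-display encoding fidelity: it
#' scales the concentration by `exp(display_coupling * g)` and shifts the
#' retrieval-success logit by `display_coupling * g`, so poorly encoded
#' displays yield both more guessing and coarser recall for all their items.
#'
#' @param observer Observer tibble/list (`p_t`, `p_nt`, `kappa`, `coupling`,
#'   `display_coupling`; missing coupling fields are treated as 0).
#' @param target_deg Target angles, degrees.
#' @param nontarget1_deg,nontarget2_deg Nontarget angles, degrees.
#' @param ident_correct Optional 0/1 vector; required when `coupling > 0`.
#' @param display_latent Optional per-trial shared display latent `g`;
#'   required when `display_coupling > 0`.
#' @return Response angles in degrees \[0, 360).
#' @export
simulate_localization <- function(observer, target_deg, nontarget1_deg = NULL,
                                  nontarget2_deg = NULL, ident_correct = NULL,
                                  display_latent = NULL) {
  n <- length(target_deg)
  p_t <- observer$p_t; p_nt <- observer$p_nt %||% 0
  coupling <- observer$coupling %||% 0
  dcoupling <- observer$display_coupling %||% 0
  kap <- rep(observer$kappa, n)
  p_t_trial <- rep(p_t, n)
  if (coupling != 0) {
    if (is.null(ident_correct)) stop("ident_correct needed when coupling != 0", call. = FALSE)
    kap <- kap * exp(coupling * (2 * ident_correct - 1))
  }
  if (dcoupling != 0) {
    if (is.null(display_latent)) stop("display_latent needed when display_coupling != 0", call. = FALSE)
    kap <- kap * exp(dcoupling * display_latent)
    p_t_trial <- stats::plogis(stats::qlogis(pmin(pmax(p_t, 1e-6), 1 - 1e-6)) +
                                 dcoupling * display_latent)
    p_t_trial <- p_t_trial * (p_t + p_nt > 0) # keep pure guessers guessing
    if (p_nt > 0) p_t_trial <- pmin(p_t_trial, 1 - p_nt)
  }
  u <- stats::runif(n)
  comp <- ifelse(u < p_t_trial, 1L, ifelse(u < p_t_trial + p_nt, 2L, 3L))
  centre <- target_deg
  if (any(comp == 2L)) {
    pick <- stats::runif(n) < 0.5
    centre[comp == 2L] <- ifelse(pick[comp == 2L],
                                 nontarget1_deg[comp == 2L],
                                 nontarget2_deg[comp == 2L])
  }
  resp <- numeric(n)
  vm <- comp != 3L
  resp[vm] <- centre[vm] + rvonmises_deg(sum(vm), 0, kap[vm])
  resp[!vm] <- stats::runif(sum(!vm), 0, 360)
  resp %% 360
}

#' Simulate one subject's session of the precision memory task
#'
#' Builds the task structure and simulates an observer through it. The STM
#' format presents 15 three-object displays in each of 5 blocks and tests one
#' object per display (75 trials); the LTM format presents 5 displays per
#' block and tests all three objects of each display, interleaved within the
#' block's test phase (25 displays x 3 = 75 trials). Every trial records the
#' 2AFC identification outcome and the localization response. When the
#' observer's `display_coupling` is nonzero, a fidelity latent shared by the
#' items of a display couples their errors (see [simulate_localization()]).
#'
#' @param observer Observer parameters (see [observer_presets()]).
#' @param task `"STM"` or `"LTM"`.
#' @param subject_id Subject identifier carried into the records.
#' @param age_group Optional group label.
#' @param blocks Number of blocks (default 5; 0 gives an empty session).
#' @param displays_per_block Displays per block; defaults to 15 (STM) or 5 (LTM).
#' @param min_separation_deg Display separation constraint, degrees.
#' @param seed Optional integer seed; the session is deterministic given it.
#' @return Tibble of trial records: `subject_id`, `age_group`, `task`, `block`,
#'   `display_id`, `trial_index`, `target_deg`, `nontarget1_deg`,
#'   `nontarget2_deg`, `response_deg`, `signed_error_deg`, `ident_correct`.
#' @export
generate_session <- function(observer, task = c("STM", "LTM"),
                             subject_id = "s1", age_group = NA_character_,
                             blocks = 5, displays_per_block = NULL,
                             min_separation_deg = 62.04, seed = NULL) {
  task <- match.arg(task)
  if (!is.null(seed)) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
  }
  if (is.null(displays_per_block)) {
    displays_per_block <- if (task == "STM") 15 else 5
  }
  if (blocks < 0 || displays_per_block < 0) stop("invalid session config", call. = FALSE)
  empty <- tibble::tibble(
    subject_id = character(0), age_group = character(0), task = character(0),
    block = integer(0), display_id = integer(0), trial_index = integer(0),
    target_deg = numeric(0), nontarget1_deg = numeric(0),
    nontarget2_deg = numeric(0), response_deg = numeric(0),
    signed_error_deg = numeric(0), ident_correct = integer(0))
  n_displays <- blocks * displays_per_block
  if (n_displays == 0) return(empty)
  disp <- generate_displays(n_displays, 3, min_separation_deg)
  disp$block <- rep(seq_len(blocks), each = displays_per_block)
  if (task == "STM") {
    tested <- sample.int(3, n_displays, replace = TRUE)
    trials <- tibble::tibble(
      block = disp$block, display_id = disp$display_id, item = tested)
  } else {
    trials <- tidyr::expand_grid(display_id = disp$display_id, item = 1:3)
    trials <- dplyr::left_join(trials, disp[, c("display_id", "block")],
                               by = "display_id")
    # interleave the tested items within each block's test phase
    trials <- trials |>
      dplyr::group_by(.data$block) |>
      dplyr::slice_sample(prop = 1) |>
      dplyr::ungroup()
  }
  ang <- as.matrix(disp[, c("angle_1", "angle_2", "angle_3")])
  rowidx <- match(trials$display_id, disp$display_id)
  pick <- function(offset) ang[cbind(rowidx, (trials$item + offset - 1) %% 3 + 1)]
  target <- pick(0); nt1 <- pick(1); nt2 <- pick(2)
  n <- nrow(trials)
  ident <- simulate_identification(observer, n)
  g <- stats::rnorm(n_displays)[rowidx] # display-shared fidelity latent
  resp <- simulate_localization(observer, target, nt1, nt2,
                                ident_correct = ident, display_latent = g)
  tibble::tibble(
    subject_id = subject_id, age_group = age_group, task = task,
    block = as.integer(trials$block), display_id = as.integer(trials$display_id),
    trial_index = seq_len(n),
    target_deg = target, nontarget1_deg = nt1, nontarget2_deg = nt2,
    response_deg = resp,
    signed_error_deg = wrap_error(target, resp),
    ident_correct = as.integer(ident))
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a[1])) b else a

.rtnorm <- function(n, mean, sd, lo, hi) {
  if (sd <= 0) return(rep(mean, n))
  p <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(p, mean, sd)
}

#' Simulate a multi-group cohort through both task formats
#'
#' Draws per-subject observer parameters around the group presets (truncated
#' normal at the preset between-subject SDs when `heterogeneity = TRUE`) and
#' simulates a full session per subject and task. Randomness follows a
#' one-root-seed policy: the root seed spawns one substream seed per subject.
#'
#' @param n_per_group Named counts, e.g. `c(young = 30, middle = 50, old = 52)`.
#' @param tasks Task formats to simulate.
#' @param heterogeneity Draw subject-level parameters around the group means?
#' @param coupling,display_coupling Override the preset coupling strengths.
#' @param seed Root seed.
#' @return List with `trials` (all trial records) and `observers` (one row per
#'   subject x task of generating parameters).
#' @export
simulate_cohort <- function(n_per_group = c(young = 30, middle = 50, old = 52),
                            tasks = c("STM", "LTM"), heterogeneity = TRUE,
                            coupling = NULL, display_coupling = NULL,
                            seed = NULL) {
  if (!is.null(seed)) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
  }
  groups <- rep(names(n_per_group), n_per_group)
  n_sub <- length(groups)
  sub_seeds <- sample.int(.Machine$integer.max - 1, n_sub)
  ids <- sprintf("s%03d", seq_len(n_sub))
  all_trials <- vector("list", n_sub * length(tasks))
  all_obs <- vector("list", n_sub * length(tasks))
  k <- 0
  for (i in seq_len(n_sub)) {
    set.seed(sub_seeds[i])
    for (tk in tasks) {
      preset <- observer_presets(groups[i], tk)
      obs <- preset
      if (heterogeneity) {
        obs$p_t <- .rtnorm(1, preset$p_t, preset$p_t_sd, 0.02, 0.995)
        obs$kappa <- .rtnorm(1, preset$kappa, preset$kappa_sd, 1, 200)
        obs$d_prime <- .rtnorm(1, preset$d_prime, preset$d_prime_sd, 0, 8)
      }
      if (!is.null(coupling)) obs$coupling <- coupling
      if (!is.null(display_coupling)) obs$display_coupling <- display_coupling
      k <- k + 1
      all_trials[[k]] <- generate_session(obs, tk, subject_id = ids[i],
                                          age_group = groups[i])
      all_obs[[k]] <- dplyr::bind_cols(
        tibble::tibble(subject_id = ids[i]), obs)
    }
  }
  list(trials = dplyr::bind_rows(all_trials),
       observers = dplyr::bind_rows(all_obs))
}
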