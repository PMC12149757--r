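#' Configuration of the two-session advice experiment
#'
#' Describes the structure the simulator emulates: an unadvised Session 1,
#' and an advised Session 2 split into blocks whose advice accuracy follows
#' a fixed Bernoulli schedule. The default is the phase design of the
#' emulated study: nine blocks of 24 trials with advice-correctness
#' probabilities 0.9, 0.9, 0.9 (pre-error), 0.75, 0.60, 0.45 (error, with
#' block-wise decreasing accuracy) and 0.9, 0.9, 0.9 (post-error); Session 1
#' has 216 unadvised trials on the same stimuli; self-reports are queried
#' after blocks 2, 4, 6, 8 and 9 (five time points).
#'
#' @param n_participants total cohort size, split evenly at random across
#'   the two instruction conditions (default 131).
#' @param n_trials_session1 number of unadvised Session-1 trials; must equal
#'   the Session-2 total because both sessions reuse the same stimulus set.
#' @param block_trials integer vector of Session-2 block lengths.
#' @param advice_accuracy per-block probability that the scripted advice is
#'   correct (Bernoulli per trial).
#' @param phases character vector labelling each block as `"pre-error"`,
#'   `"error"` or `"post-error"`; the labels must form contiguous runs in
#'   that order (all three phases present in the default design; reduced
#'   designs may omit phases).
#' @param signal_proportion proportion of stimuli whose true category is the
#'   designated signal class (default 0.5, balanced within each block).
#' @param selfreport_blocks block indices after which the three self-report
#'   items (trust, distrust, use) are queried; exactly five time points
#'   (indices may repeat in reduced designs with few blocks).
#' @param seed optional integer seed stored with the config and used as the
#'   default for [simulate_experiment()].
#' @return an object of class `experiment_config`.
#' @examples
#' cfg <- experiment_config(n_participants = 8)
#' cfg$advice_accuracy
#' @export
experiment_config <- function(n_participants = 131,
                              n_trials_session1 = 216,
                              block_trials = rep(24L, 9L),
                              advice_accuracy = c(0.9, 0.9, 0.9,
                                                  0.75, 0.6, 0.45,
                                                  0.9, 0.9, 0.9),
                              phases = rep(c("pre-error", "error", "post-error"),
                                           times = c(3L, 3L, 3L)),
                              signal_proportion = 0.5,
                              selfreport_blocks = c(2L, 4L, 6L, 8L, 9L),
                              seed = NULL) {
  if (!is.numeric(n_participants) || length(n_participants) != 1L ||
      n_participants < 2 || n_participants != floor(n_participants))
    stop("`n_participants` must be a single integer >= 2", call. = FALSE)
  if (any(block_trials < 1) || any(block_trials != floor(block_trials)))
    stop("`block_trials` must be positive integers", call. = FALSE)
  if (length(advice_accuracy) != length(block_trials))
    stop("`advice_accuracy` must give one probability per block", call. = FALSE)
  if (any(!is.finite(advice_accuracy)) ||
      any(advice_accuracy < 0) || any(advice_accuracy > 1))
    stop("`advice_accuracy` entries must be probabilities in [0, 1]",
         call. = FALSE)
  if (!is.finite(signal_proportion) ||
      signal_proportion <= 0 || signal_proportion >= 1)
    stop("`signal_proportion` must lie strictly inside (0, 1)", call. = FALSE)
  if (sum(block_trials) != n_trials_session1)
    stop("inconsistent config: Session-2 blocks sum to ",
         sum(block_trials), " trials but `n_trials_session1` is ",
         n_trials_session1, "; both sessions reuse the same stimuli",
         call. = FALSE)
  phase_levels <- c("pre-error", "error", "post-error")
  if (length(phases) != length(block_trials) || !all(phases %in% phase_levels))
    stop("`phases` must label every block as pre-error/error/post-error",
         call. = FALSE)
  runs <- rle(phases)$values
  if (!identical(runs, phase_levels[phase_levels %in% runs]))
    stop("`phases` must form contiguous runs in the order pre-error, ",
         "error, post-error", call. = FALSE)
  if (length(selfreport_blocks) != 5L ||
      any(!selfreport_blocks %in% seq_along(block_trials)) ||
      is.unsorted(selfreport_blocks))
    stop("`selfreport_blocks` must be 5 non-decreasing block indices",
         call. = FALSE)
  structure(
    list(n_participants = as.integer(n_participants),
         n_trials_session1 = as.integer(n_trials_session1),
         block_trials = as.integer(block_trials),
         advice_accuracy = as.numeric(advice_accuracy),
         phases = phases,
         signal_proportion = signal_proportion,
         selfreport_blocks = as.integer(selfreport_blocks),
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "experiment_config")
}

#' @export
print.experiment_config <- function(x, ...) {
  cat("Two-session advice experiment config\n")
  cat("  participants:", x$n_participants, "\n")
  cat("  session 1:", x$n_trials_session1, "unadvised trials\n")
  cat("  session 2:", length(x$block_trials), "blocks (",
      paste(x$block_trials, collapse = ", "), ") trials\n")
  cat("  advice accuracy:", paste(format(x$advice_accuracy), collapse = ", "),
      "\n")
  cat("  phases:", paste(x$phases, collapse = ", "), "\n")
  cat("  self-reports after blocks:",
      paste(x$selfreport_blocks, collapse = ", "), "\n")
  invisible(x)
}

#' Population parameters for synthetic participants
#'
#' Group-level distributions from which [simulate_experiment()] draws each
#' participant's latent profile: unadvised sensitivity d' and criterion c of
#' the equal-variance Gaussian observer, a practice gain added to d' in
#' Session 2, an advice-adoption weight (probability of deferring to advice
#' that conflicts with the own judgment), latent 7-point Likert baselines
#' for the trust/distrust/use items, and the size of the trust-drop /
#' distrust-rise triggered by the error phase.
#'
#' Defaults are scaled to the emulated study: unadvised d' centered at 0.95
#' (SD 0.8), unbiased criteria (SD 0.4), no practice gain, adoption weight
#' Beta with mean 0.4 and concentration 10, trust baseline 4.5, distrust
#' baseline 3.0, error shift 0.5 Likert points, rating noise SD 1.
#'
#' @param dprime_mean,dprime_sd Gaussian for latent Session-1 d'; either
#'   scalars or length-2 vectors named by condition
#'   (`distrust`, `information-only`).
#' @param criterion_mean,criterion_sd Gaussian for the latent criterion.
#' @param practice_gain_mean,practice_gain_sd Gaussian for the Session-2
#'   unaided d' gain.
#' @param adoption_mean,adoption_concentration Beta distribution of the
#'   advice-adoption weight, parameterized as mean and concentration
#'   (shape1 + shape2); concentration `Inf` gives a degenerate point mass.
#' @param trust_baseline_mean,distrust_baseline_mean,use_baseline_mean means
#'   of the latent Likert baselines (clamped to \[1, 7\]).
#' @param baseline_sd between-participant SD of the latent baselines.
#' @param error_shift_mean,error_shift_sd Gaussian (truncated at 0) for the
#'   post-error trust drop / distrust rise.
#' @param likert_noise_sd Gaussian noise added to each latent rating before
#'   rounding to the 1..7 scale.
#' @return an object of class `profile_params`.
#' @export
profile_params <- function(dprime_mean = 0.95, dprime_sd = 0.8,
                           criterion_mean = 0, criterion_sd = 0.4,
                           practice_gain_mean = 0, practice_gain_sd = 0,
                           adoption_mean = 0.4, adoption_concentration = 10,
                           trust_baseline_mean = 4.5,
                           distrust_baseline_mean = 3,
                           use_baseline_mean = 4.5,
                           baseline_sd = 1,
                           error_shift_mean = 0.5, error_shift_sd = 0.25,
                           likert_noise_sd = 1) {
  both <- function(x, what) {
    if (length(x) == 1L) x <- c("distrust" = unname(x),
                                "information-only" = unname(x))
    if (length(x) != 2L)
      stop("`", what, "` must be length 1 or 2", call. = FALSE)
    if (is.null(names(x)) || !setequal(names(x), condition_levels()))
      names(x) <- condition_levels()
    x[condition_levels()]
  }
  if (adoption_mean < 0 || adoption_mean > 1)
    stop("`adoption_mean` must be a probability", call. = FALSE)
  if (any(c(dprime_sd, criterion_sd, practice_gain_sd, baseline_sd,
            error_shift_sd, likert_noise_sd) < 0))
    stop("standard deviations must be non-negative", call. = FALSE)
  structure(
    list(dprime_mean = both(dprime_mean, "dprime_mean"),
         dprime_sd = both(dprime_sd, "dprime_sd"),
         criterion_mean = both(criterion_mean, "criterion_mean"),
         criterion_sd = both(criterion_sd, "criterion_sd"),
         practice_gain_mean = practice_gain_mean,
         practice_gain_sd = practice_gain_sd,
         adoption_mean = both(adoption_mean, "adoption_mean"),
         adoption_concentration = adoption_concentration,
         trust_baseline_mean = trust_baseline_mean,
         distrust_baseline_mean = distrust_baseline_mean,
         use_baseline_mean = use_baseline_mean,
         baseline_sd = baseline_sd,
         error_shift_mean = error_shift_mean,
         error_shift_sd = error_shift_sd,
         likert_noise_sd = likert_noise_sd),
    class = "profile_params")
}

#' Instruction-condition levels
#'
#' The between-subject factor: a distrust instruction (remain skeptical and
#' review each piece of advice) vs. an information-only instruction.
#' @return character vector of the two condition labels.
#' @export
condition_levels <- function() c("distrust", "information-only")

category_levels <- function() c("signal", "noise")
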