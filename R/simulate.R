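#' Sample a Wizard-of-Oz advice-correctness schedule
#'
#' Draws, for every Session-2 trial, whether the scripted advice will be
#' correct: within each block the flags are independent Bernoulli draws with
#' that block's accuracy probability, so the realized proportion of correct
#' advice concentrates around the scheduled accuracy.
#'
#' @param config an [experiment_config()].
#' @param seed optional integer seed (caller RNG state is restored).
#' @return data frame with one row per Session-2 trial: `block_index`,
#'   `trial_in_block`, `p_correct`, `advice_correct` (logical).
#' @examples
#' sched <- sample_advice_schedule(experiment_config(), seed = 1)
#' tapply(sched$advice_correct, sched$block_index, mean)
#' @export
sample_advice_schedule <- function(config, seed = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  p <- rep(config$advice_accuracy, times = config$block_trials)
  with_seed(seed, {
    data.frame(
      block_index = rep(seq_along(config$block_trials),
                        times = config$block_trials),
      trial_in_block = unlist(lapply(config$block_trials, seq_len),
                              use.names = FALSE),
      p_correct = p,
      advice_correct = stats::runif(length(p)) < p)
  })
}

# Equal-variance Gaussian SDT observer: evidence ~ Normal(+d/2 | -d/2, 1),
# respond "signal" iff evidence exceeds the criterion. Inverse of the
# hit/false-alarm reparametrization used by the hierarchical model.
sdt_judgment <- function(dprime, criterion, true_category) {
  mu <- ifelse(true_category == "signal", dprime / 2, -dprime / 2)
  evidence <- stats::rnorm(length(mu), mean = mu, sd = 1)
  ifelse(evidence > criterion, "signal", "noise")
}

#' Simulate one observer's classification responses
#'
#' Two-stage response process: (a) an own judgment from the equal-variance
#' Gaussian SDT observer defined by the profile's latent d' and criterion;
#' (b) if advice is shown and conflicts with the own judgment, the advice is
#' adopted with probability `adoption_weight`, otherwise the own judgment
#' stands. Advice that agrees with the own judgment never changes it.
#'
#' @param profile a single participant profile: a one-row data frame or list
#'   with fields `true_dprime_s1`, `true_dprime_s2_own`, `true_criterion`
#'   and `adoption_weight` (as produced by [simulate_experiment()]).
#' @param true_category character vector of `"signal"`/`"noise"` truths, one
#'   per trial.
#' @param advice_shown `"signal"`, `"noise"` or `"none"` per trial
#'   (recycled).
#' @param session 1 (unadvised latent d') or 2 (unaided Session-2 d', i.e.
#'   including any practice gain).
#' @param seed optional integer seed.
#' @return character vector of responses (`"signal"`/`"noise"`).
#' @export
simulate_response <- function(profile, true_category, advice_shown = "none",
                              session = 2L, seed = NULL) {
  profile <- as.list(profile)
  stopifnot(all(true_category %in% category_levels()),
            all(advice_shown %in% c(category_levels(), "none")),
            session %in% c(1L, 2L))
  a <- profile$adoption_weight
  stopifnot(is.numeric(a), a >= 0, a <= 1)
  d <- if (session == 1L) profile$true_dprime_s1 else profile$true_dprime_s2_own
  n <- length(true_category)
  advice_shown <- rep_len(advice_shown, n)
  with_seed(seed, {
    own <- sdt_judgment(rep_len(d, n), rep_len(profile$true_criterion, n),
                        true_category)
    conflict <- advice_shown != "none" & advice_shown != own
    adopt <- conflict & stats::runif(n) < a
    ifelse(adopt, advice_shown, own)
  })
}

#' Simulate one participant's repeated trust/distrust/use self-reports
#'
#' Latent-trajectory generator: trust and distrust sit at their baselines
#' until the error phase has been experienced, then step down (trust) or up
#' (distrust) by the profile's `selfreport_error_shift` and stay shifted
#' (no recovery). The control item `use` dips only at the onset time point
#' and returns to baseline. Gaussian noise is added to the latent value,
#' which is then rounded and clamped to the 1..7 Likert scale.
#'
#' With the default schedule (queries after blocks 2, 4, 6, 8, 9) the shift
#' onset is time point 3, the first query at or after the final error block.
#'
#' @param profile one-row data frame or list with `participant_id`,
#'   `condition`, `trust_baseline`, `distrust_baseline`, `use_baseline`,
#'   `selfreport_error_shift` and optionally `likert_noise_sd` (default 1).
#' @param config an [experiment_config()].
#' @param seed optional integer seed.
#' @return data frame: `participant_id`, `condition`, `timepoint` (1..5),
#'   `item` (`trust`/`distrust`/`use`), `rating` (integer 1..7).
#' @export
simulate_self_reports <- function(profile, config, seed = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  profile <- as.list(profile)
  noise_sd <- if (is.null(profile$likert_noise_sd)) 1 else profile$likert_noise_sd
  onset <- selfreport_shift_onset(config)
  tp <- seq_along(config$selfreport_blocks)
  shift <- profile$selfreport_error_shift
  latent <- rbind(
    trust    = profile$trust_baseline    - shift * (tp >= onset),
    distrust = profile$distrust_baseline + shift * (tp >= onset),
    use      = profile$use_baseline      - shift * (tp == onset))
  with_seed(seed, {
    noisy <- latent + stats::rnorm(length(latent), sd = noise_sd)
    out <- data.frame(
      participant_id = profile$participant_id,
      condition = profile$condition,
      timepoint = rep(tp, each = nrow(latent)),
      item = rep(rownames(latent), times = length(tp)),
      rating = as.integer(pmin(7, pmax(1, round(as.vector(noisy))))))
    out
  })
}

# First self-report time point at or after the last error block: by then the
# full error phase has been experienced. No error phase => no shift.
selfreport_shift_onset <- function(config) {
  err <- which(config$phases == "error")
  if (length(err) == 0L) return(length(config$selfreport_blocks) + 1L)
  onset <- which(config$selfreport_blocks >= max(err))
  if (length(onset) == 0L) length(config$selfreport_blocks) + 1L else onset[1L]
}

#' Simulate a complete two-session advice cohort
#'
#' Generates an internally consistent synthetic dataset with the structure
#' of the emulated experiment: latent participant profiles drawn from
#' [profile_params()], a shared stimulus set classified unadvised in
#' Session 1 and re-classified under scripted advice in Session 2 (same
#' stimulus identities, per-participant random order, truth balanced within
#' each Session-2 block), a Bernoulli advice-correctness schedule per
#' participant, two-stage responses via [simulate_response()], and repeated
#' Likert self-reports via [simulate_self_reports()].
#'
#' @param config an [experiment_config()].
#' @param params a [profile_params()] object.
#' @param seed integer master seed (defaults to `config$seed`); stage seeds
#'   for profiles, schedules, responses and self-reports are derived from it
#'   deterministically.
#' @return an object of class `reliance_cohort`: a list with data frames
#'   `trials`, `self_reports`, `profiles`, plus the `config`, `params` and
#'   `seed` used.
#' @examples
#' cfg <- experiment_config(n_participants = 4, n_trials_session1 = 8,
#'                          block_trials = c(4L, 4L),
#'                          advice_accuracy = c(0.9, 0.5),
#'                          phases = c("pre-error", "error"),
#'                          selfreport_blocks = c(1L, 1L, 2L, 2L, 2L))
#' cohort <- simulate_experiment(cfg, seed = 1)
#' nrow(cohort$trials)
#' @export
simulate_experiment <- function(config, params = profile_params(),
                                seed = config$seed) {
  stopifnot(inherits(config, "experiment_config"),
            inherits(params, "profile_params"))
  if (is.null(seed))
    stop("a seed is required for a reproducible cohort", call. = FALSE)

  profiles <- draw_profiles(config, params, stage_seed(seed, 1L))
  stimuli <- make_stimuli(config)

  trials <- with_seed(stage_seed(seed, 2L), {
    do.call(rbind, lapply(seq_len(nrow(profiles)), function(i)
      participant_trials(profiles[i, ], config, stimuli)))
  })
  rownames(trials) <- NULL

  reports <- with_seed(stage_seed(seed, 3L), {
    do.call(rbind, lapply(seq_len(nrow(profiles)), function(i)
      simulate_self_reports(profiles[i, ], config)))
  })
  rownames(reports) <- NULL

  structure(list(trials = trials, self_reports = reports,
                 profiles = profiles, config = config, params = params,
                 seed = as.integer(seed)),
            class = "reliance_cohort")
}

#' @export
print.reliance_cohort <- function(x, ...) {
  cat("Synthetic two-session advice cohort\n")
  cat("  participants:", nrow(x$profiles),
      sprintf("(%s)", paste(table(x$profiles$condition)[condition_levels()],
                            condition_levels(), collapse = ", ")), "\n")
  cat("  trials:", nrow(x$trials), " self-reports:", nrow(x$self_reports),
      "\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}

# Latent ground-truth profiles, balanced random condition split.
draw_profiles <- function(config, params, seed) {
  n <- config$n_participants
  with_seed(seed, {
    condition <- sample(rep_len(condition_levels(), n))
    rtrunc01 <- function(x) pmin(1, pmax(0, x))
    a_mean <- params$adoption_mean[condition]
    kappa <- params$adoption_concentration
    adoption <- if (is.infinite(kappa)) a_mean
      else stats::rbeta(n, a_mean * kappa, (1 - a_mean) * kappa)
    d1 <- stats::rnorm(n, params$dprime_mean[condition],
                       params$dprime_sd[condition])
    gain <- stats::rnorm(n, params$practice_gain_mean, params$practice_gain_sd)
    clamp17 <- function(x) pmin(7, pmax(1, x))
    data.frame(
      participant_id = seq_len(n),
      condition = condition,
      true_dprime_s1 = d1,
      true_dprime_s2_own = d1 + gain,
      true_criterion = stats::rnorm(n, params$criterion_mean[condition],
                                    params$criterion_sd[condition]),
      adoption_weight = rtrunc01(adoption),
      trust_baseline = clamp17(stats::rnorm(n, params$trust_baseline_mean,
                                            params$baseline_sd)),
      distrust_baseline = clamp17(stats::rnorm(n, params$distrust_baseline_mean,
                                               params$baseline_sd)),
      use_baseline = clamp17(stats::rnorm(n, params$use_baseline_mean,
                                          params$baseline_sd)),
      selfreport_error_shift = pmax(0, stats::rnorm(n, params$error_shift_mean,
                                                    params$error_shift_sd)),
      likert_noise_sd = params$likert_noise_sd)
  })
}

# Fixed stimulus set shared by all participants and both sessions.
make_stimuli <- function(config) {
  n <- config$n_trials_session1
  n_signal <- round(config$signal_proportion * n)
  data.frame(stimulus_id = seq_len(n),
             true_category = rep(c("signal", "noise"),
                                 times = c(n_signal, n - n_signal)))
}

# Per-block signal counts: largest-remainder apportionment of the signal
# stimuli over blocks, so each block is as truth-balanced as possible.
block_signal_counts <- function(block_trials, n_signal) {
  exact <- block_trials * n_signal / sum(block_trials)
  k <- floor(exact)
  rem <- n_signal - sum(k)
  if (rem > 0) {
    order_rem <- order(exact - k, decreasing = TRUE)
    k[order_rem[seq_len(rem)]] <- k[order_rem[seq_len(rem)]] + 1L
  }
  as.integer(k)
}

# Both sessions for one participant, using the current RNG stream.
participant_trials <- function(profile, config, stimuli) {
  profile <- as.list(profile)
  n <- nrow(stimuli)

  # Session 1: all stimuli, shuffled, no advice
  ord1 <- sample.int(n)
  s1 <- data.frame(
    participant_id = profile$participant_id,
    condition = profile$condition,
    session = 1L,
    block_index = NA_integer_,
    trial_index = seq_len(n),
    phase = "none",
    stimulus_id = stimuli$stimulus_id[ord1],
    true_category = stimuli$true_category[ord1],
    advice_shown = "none",
    advice_correct = NA)
  s1$response <- simulate_response(profile, s1$true_category, session = 1L)

  # Session 2: same stimuli dealt into truth-balanced blocks
  sig <- sample(stimuli$stimulus_id[stimuli$true_category == "signal"])
  noi <- sample(stimuli$stimulus_id[stimuli$true_category == "noise"])
  ks <- block_signal_counts(config$block_trials, length(sig))
  blocks <- lapply(seq_along(config$block_trials), function(b) {
    ids <- c(sig[seq_len(ks[b]) + sum(ks[seq_len(b - 1L)])],
             noi[seq_len(config$block_trials[b] - ks[b]) +
                   sum(config$block_trials[seq_len(b - 1L)] -
                         ks[seq_len(b - 1L)])])
    sample(ids)
  })
  ids2 <- unlist(blocks, use.names = FALSE)
  truth2 <- stimuli$true_category[match(ids2, stimuli$stimulus_id)]
  sched <- sample_advice_schedule(config)
  advice <- ifelse(sched$advice_correct, truth2,
                   ifelse(truth2 == "signal", "noise", "signal"))
  s2 <- data.frame(
    participant_id = profile$participant_id,
    condition = profile$condition,
    session = 2L,
    block_index = sched$block_index,
    trial_index = seq_along(ids2),
    phase = config$phases[sched$block_index],
    stimulus_id = ids2,
    true_category = truth2,
    advice_shown = advice,
    advice_correct = sched$advice_correct)
  s2$response <- simulate_response(profile, truth2, advice, session = 2L)

  out <- rbind(s1, s2)
  out$response_correct <- out$response == out$true_category
  out
}
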