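#' Equal-variance SDT reparametrization
#'
#' Maps sensitivity d' and criterion c to the hit and false-alarm
#' probabilities of the equal-variance Gaussian observer:
#' `h = pnorm(d/2 - c)`, `f = pnorm(-d/2 - c)`.
#'
#' @param d sensitivity d' (vectorized).
#' @param c criterion c (vectorized, recycled).
#' @return data frame with columns `hit_rate` and `false_alarm_rate`.
#' @seealso [sdt_invert()] for the closed-form inverse.
#' @examples
#' sdt_reparam(2, 0) # hit ~ 0.841, false alarm ~ 0.159
#' @export
sdt_reparam <- function(d, c = 0) {
  stopifnot(is.numeric(d), is.numeric(c), all(is.finite(d)), all(is.finite(c)))
  data.frame(hit_rate = stats::pnorm(d / 2 - c),
             false_alarm_rate = stats::pnorm(-d / 2 - c))
}

#' Closed-form inverse of the SDT reparametrization
#'
#' Point estimates `d = qnorm(h) - qnorm(f)` and
#' `c = -(qnorm(h) + qnorm(f)) / 2`. Rates must lie strictly inside (0, 1);
#' apply [loglinear_rates()] first when raw frequencies can reach 0 or the
#' maximum.
#'
#' @param hit_rate,false_alarm_rate rates strictly in (0, 1) (vectorized).
#' @return data frame with columns `d` and `c`.
#' @examples
#' sdt_invert(108.5 / 109, 0.5 / 109) # the +/-5.21 bound at 108+108 trials
#' @export
sdt_invert <- function(hit_rate, false_alarm_rate) {
  if (any(!is.finite(hit_rate)) || any(!is.finite(false_alarm_rate)) ||
      any(hit_rate <= 0) || any(hit_rate >= 1) ||
      any(false_alarm_rate <= 0) || any(false_alarm_rate >= 1))
    stop("rates must lie strictly inside (0, 1); apply loglinear_rates() ",
         "to raw frequencies first", call. = FALSE)
  zh <- stats::qnorm(hit_rate)
  zf <- stats::qnorm(false_alarm_rate)
  data.frame(d = zh - zf, c = -(zh + zf) / 2)
}

#' Log-linear corrected hit and false-alarm rates
#'
#' Adds 0.5 to the hit and false-alarm frequencies and 1 to each trial
#' total, so that empty and full cells yield rates strictly inside (0, 1)
#' and d'/c stay estimable: `(hits + 0.5) / (n_signal + 1)` and
#' `(false_alarms + 0.5) / (n_noise + 1)`.
#'
#' @param counts a data frame with columns `n_signal`, `n_noise`, `hits`,
#'   `false_alarms` (e.g. from [tabulate_counts()]), or a single row of one.
#' @return the input with columns `hit_rate` and `false_alarm_rate`
#'   appended.
#' @examples
#' loglinear_rates(data.frame(n_signal = 108, n_noise = 108,
#'                            hits = 108, false_alarms = 0))
#' @export
loglinear_rates <- function(counts) {
  need <- c("n_signal", "n_noise", "hits", "false_alarms")
  if (!all(need %in% names(counts)))
    stop("`counts` must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(counts$n_signal < 1) || any(counts$n_noise < 1))
    stop("degenerate cell: at least one signal and one noise trial are ",
         "required", call. = FALSE)
  if (any(counts$hits > counts$n_signal) ||
      any(counts$false_alarms > counts$n_noise) ||
      any(counts$hits < 0) || any(counts$false_alarms < 0))
    stop("counts must satisfy 0 <= hits <= n_signal and 0 <= false_alarms ",
         "<= n_noise", call. = FALSE)
  counts$hit_rate <- (counts$hits + 0.5) / (counts$n_signal + 1)
  counts$false_alarm_rate <- (counts$false_alarms + 0.5) / (counts$n_noise + 1)
  counts
}

#' Tabulate SDT counts per participant and analysis cell
#'
#' Counts hits (signal trials answered "signal") and false alarms (noise
#' trials answered "signal") for every participant in every analysis cell.
#' Three grouping schemes are supported, mirroring the analyses the model is
#' fitted for: `"overall"` (one cell per session), `"phase"` (Session-2
#' trials split by experiment phase) and `"advice"` (Session-2 trials split
#' by advice correctness). Session-1 trials always form a single `"all"`
#' cell. Cells with no trials are kept as zero rows so that downstream code
#' can decide how to treat them.
#'
#' @param trials a trial table in the [simulate_experiment()] schema.
#' @param grouping one of `"overall"`, `"phase"`, `"advice"`.
#' @param signal which stimulus category is designated the signal class
#'   (default `"signal"`). A consistent global swap of the designation
#'   leaves d' unchanged and flips the sign of c.
#' @return data frame with one row per participant x session x cell:
#'   `participant_id`, `condition`, `session`, `cell`, `n_signal`,
#'   `n_noise`, `hits`, `false_alarms`.
#' @export
tabulate_counts <- function(trials, grouping = c("overall", "phase", "advice"),
                            signal = "signal") {
  grouping <- match.arg(grouping)
  need <- c("participant_id", "condition", "session", "true_category",
            "response")
  if (!all(need %in% names(trials)))
    stop("`trials` must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!signal %in% category_levels())
    stop("`signal` must be one of ", paste(category_levels(), collapse = ", "),
         call. = FALSE)

  cell <- rep("all", nrow(trials))
  s2 <- trials$session == 2L
  if (grouping == "phase") {
    cell[s2] <- trials$phase[s2]
  } else if (grouping == "advice") {
    cell[s2] <- ifelse(trials$advice_correct[s2],
                       "advice-correct", "advice-incorrect")
  }

  is_signal <- trials$true_category == signal
  said_signal <- trials$response == signal

  key <- interaction(trials$participant_id, trials$session, cell, drop = FALSE,
                     lex.order = TRUE)
  # complete grid over participant x session x cell within each session's
  # cell set, so empty cells appear as zero rows
  cells_by_session <- list(
    "1" = "all",
    "2" = switch(grouping,
                 overall = "all",
                 phase = unique(trials$phase[s2]),
                 advice = c("advice-correct", "advice-incorrect")))
  participants <- sort(unique(trials$participant_id))
  cond <- trials$condition[match(participants, trials$participant_id)]
  grid <- do.call(rbind, lapply(intersect(c(1L, 2L), unique(trials$session)),
    function(s) {
      cs <- cells_by_session[[as.character(s)]]
      data.frame(participant_id = rep(participants, each = length(cs)),
                 condition = rep(cond, each = length(cs)),
                 session = s, cell = rep(cs, times = length(participants)))
    }))

  agg <- function(flag) {
    t <- tapply(flag, list(trials$participant_id, trials$session, cell), sum)
    idx <- cbind(match(grid$participant_id, dimnames(t)[[1]]),
                 match(grid$session, dimnames(t)[[2]]),
                 match(grid$cell, dimnames(t)[[3]]))
    v <- t[idx]
    ifelse(is.na(v), 0L, as.integer(v))
  }
  grid$n_signal <- agg(is_signal)
  grid$n_noise <- agg(!is_signal)
  grid$hits <- agg(is_signal & said_signal)
  grid$false_alarms <- agg(!is_signal & said_signal)
  rownames(grid) <- NULL
  grid
}
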