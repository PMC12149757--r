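#' Acceptance rate of AI advice
#'
#' Fraction of advised Session-2 trials on which the final decision equals
#' the advice, optionally split by advice correctness and/or condition.
#'
#' @param trials_s2 Session-2 trial table (rows with `advice_shown ==
#'   "none"` are ignored).
#' @param group_by character subset of `c("advice_correct", "condition")`.
#' @return a reliance table: `metric`, the grouping columns, `n_not`
#'   (advice not accepted), `n_yes` (accepted), `rate` in \[0, 1\] (`NA`
#'   with zero denominator).
#' @examples
#' # rate from given counts: 2595 accepted vs 3147 not -> 45.19%
#' round(100 * 2595 / (2595 + 3147), 2)
#' @export
acceptance_rate <- function(trials_s2, group_by = character()) {
  t2 <- advised_trials(trials_s2)
  accepted <- t2$response == t2$advice_shown
  reliance_table(t2, accepted, group_by, metric = "acceptance")
}

#' Switch percentage toward AI advice
#'
#' Among advised Session-2 trials on which the participant's unadvised
#' Session-1 decision for the same stimulus differed from the advice, the
#' fraction on which the Session-2 decision equals the advice (i.e. the
#' participant switched to the advice). Trials are paired across sessions
#' by participant and stimulus identity.
#'
#' @param trials_s2 Session-2 trial table.
#' @param trials_s1 Session-1 trial table covering the same participants
#'   and stimuli.
#' @param group_by character subset of `c("advice_correct", "condition")`.
#' @return a reliance table as in [acceptance_rate()] with
#'   `metric = "switch"`; `n_yes` counts switches to the advice.
#' @export
switch_percentage <- function(trials_s2, trials_s1, group_by = character()) {
  t2 <- advised_trials(trials_s2)
  t1 <- trials_s1[trials_s1$session == 1L, , drop = FALSE]
  key2 <- paste(t2$participant_id, t2$stimulus_id)
  key1 <- paste(t1$participant_id, t1$stimulus_id)
  idx <- match(key2, key1)
  if (anyNA(idx)) {
    miss <- unique(key2[is.na(idx)])
    stop("unpairable Session-2 trials (participant stimulus): ",
         paste(utils::head(miss, 5L), collapse = ", "),
         if (length(miss) > 5L) sprintf(" ... and %d more", length(miss) - 5L),
         call. = FALSE)
  }
  s1_response <- t1$response[idx]
  eligible <- s1_response != t2$advice_shown
  t2 <- t2[eligible, , drop = FALSE]
  switched <- t2$response == t2$advice_shown
  reliance_table(t2, switched, group_by, metric = "switch")
}

#' Contingency table of reliance metrics with margins
#'
#' Cell counts and rates for the acceptance rate (and, when Session-1
#' trials are supplied, the switch percentage) split by advice correctness
#' and/or condition, together with marginal totals. Margins are computed by
#' summing cell counts, so `margin == sum of its cells` holds by
#' construction and is auditable from the output.
#'
#' @param trials_s2 Session-2 trial table.
#' @param trials_s1 optional Session-1 table; when given, switch rows are
#'   included.
#' @param split_by character subset of `c("advice_correct", "condition")`.
#' @return data frame with columns `metric`, the split columns (margin rows
#'   carry `"total"`), `n_not`, `n_yes`, `rate`.
#' @export
contingency_table <- function(trials_s2, trials_s1 = NULL,
                              split_by = c("advice_correct", "condition")) {
  check_split(split_by)
  tabs <- list(acceptance_rate(trials_s2, split_by))
  if (!is.null(trials_s1))
    tabs <- c(tabs, list(switch_percentage(trials_s2, trials_s1, split_by)))
  out <- lapply(tabs, function(cells) {
    margins <- lapply(seq_len(length(split_by) - 1L), function(k) {
      keep <- utils::combn(split_by, k, simplify = FALSE)
      do.call(rbind, lapply(keep, function(vars) collapse_cells(cells, vars)))
    })
    total <- collapse_cells(cells, character())
    rbind(cells, do.call(rbind, margins), total)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Pearson correlation with explicit undefined handling
#'
#' Standard product-moment correlation; returns `NA` (with a warning) when
#' either input has zero variance, rather than failing.
#'
#' @param x,y paired numeric vectors, n >= 3, no missing values.
#' @return scalar Pearson r, or `NA` if undefined.
#' @export
correlate <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L)
    stop("at least 3 paired observations are required", call. = FALSE)
  if (anyNA(x) || anyNA(y))
    stop("missing values are not allowed", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("correlation undefined: zero variance", call. = FALSE)
    return(NA_real_)
  }
  stats::cor(x, y)
}

#' Correlations between self-report means and behavioral measures
#'
#' For each participant, the mean trust and distrust rating over the five
#' time points is correlated (Pearson) with each supplied behavioral
#' measure (e.g. Session-2 d', detailed d' differences, acceptance rate,
#' switch percentage).
#'
#' @param self_reports self-report table in the [simulate_experiment()]
#'   schema.
#' @param behavior data frame with `participant_id` plus one numeric column
#'   per behavioral measure.
#' @param items self-report items to correlate against (default trust and
#'   distrust).
#' @return data frame: `measure`, one column of r values per item.
#' @export
selfreport_behavior_correlations <- function(self_reports, behavior,
                                             items = c("trust", "distrust")) {
  stopifnot("participant_id" %in% names(behavior))
  measures <- setdiff(names(behavior), "participant_id")
  out <- data.frame(measure = measures)
  for (it in items) {
    rr <- self_reports[self_reports$item == it, , drop = FALSE]
    mean_rating <- tapply(rr$rating, rr$participant_id, mean)
    m <- mean_rating[as.character(behavior$participant_id)]
    out[[it]] <- vapply(measures, function(v)
      correlate(as.numeric(m), behavior[[v]]), numeric(1))
  }
  out
}

# ---- internal -------------------------------------------------------------

advised_trials <- function(trials) {
  need <- c("participant_id", "condition", "advice_shown", "response")
  if (!all(need %in% names(trials)))
    stop("trial table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  trials[trials$session == 2L & trials$advice_shown != "none", , drop = FALSE]
}

check_split <- function(group_by) {
  allowed <- c("advice_correct", "condition")
  if (length(group_by) && !all(group_by %in% allowed))
    stop("unknown split variable(s): ",
         paste(setdiff(group_by, allowed), collapse = ", "),
         "; allowed: ", paste(allowed, collapse = ", "), call. = FALSE)
  invisible(group_by)
}

reliance_table <- function(trials, success, group_by, metric) {
  check_split(group_by)
  labels <- if ("advice_correct" %in% names(trials))
    ifelse(trials$advice_correct, "correct", "incorrect") else NULL
  keys <- lapply(group_by, function(v)
    if (v == "advice_correct") labels else trials[[v]])
  if (length(keys) == 0L) {
    grid <- data.frame(row.names = 1L)
    yes <- sum(success)
    not <- sum(!success)
    out <- data.frame(metric = metric, n_not = not, n_yes = yes)
  } else {
    names(keys) <- group_by
    yes <- tapply(success, keys, sum, default = 0L)
    not <- tapply(!success, keys, sum, default = 0L)
    grid <- expand.grid(dimnames(yes), KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
    names(grid) <- group_by
    out <- cbind(metric = metric, grid,
                 n_not = as.vector(not), n_yes = as.vector(yes))
  }
  out$rate <- ifelse(out$n_yes + out$n_not > 0,
                     out$n_yes / (out$n_yes + out$n_not), NA_real_)
  rownames(out) <- NULL
  out
}

# sum a cell table over the split variables not in `keep`
collapse_cells <- function(cells, keep) {
  split_cols <- setdiff(names(cells), c("metric", "n_not", "n_yes", "rate"))
  drop_cols <- setdiff(split_cols, keep)
  if (length(keep) == 0L) {
    out <- data.frame(metric = cells$metric[1L],
                      n_not = sum(cells$n_not), n_yes = sum(cells$n_yes))
  } else {
    agg <- stats::aggregate(cells[c("n_not", "n_yes")],
                            by = cells[keep], FUN = sum)
    out <- cbind(metric = cells$metric[1L], agg)
  }
  for (v in drop_cols) out[[v]] <- "total"
  out <- out[c("metric", split_cols, "n_not", "n_yes")]
  out$rate <- ifelse(out$n_yes + out$n_not > 0,
                     out$n_yes / (out$n_yes + out$n_not), NA_real_)
  out
}
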