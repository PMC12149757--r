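# Flat-file interchange for trial and self-report tables. CSV with a header
# row, UTF-8; unknown columns are preserved; categorical fields are
# validated on read with row diagnostics.

trial_schema <- function() {
  list(required = c("participant_id", "condition", "session", "block_index",
                    "trial_index", "phase", "stimulus_id", "true_category",
                    "advice_shown", "advice_correct", "response",
                    "response_correct"),
       levels = list(
         condition = condition_levels(),
         session = c(1L, 2L),
         phase = c("pre-error", "error", "post-error", "none"),
         true_category = category_levels(),
         advice_shown = c(category_levels(), "none"),
         response = category_levels()))
}

report_schema <- function() {
  list(required = c("participant_id", "condition", "timepoint", "item",
                    "rating"),
       levels = list(condition = condition_levels(),
                     timepoint = 1:5,
                     item = c("trust", "distrust", "use"),
                     rating = 1:7))
}

check_schema <- function(df, schema, what, na_ok = character()) {
  missing <- setdiff(schema$required, names(df))
  if (length(missing))
    stop(what, " table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  for (col in names(schema$levels)) {
    v <- df[[col]]
    bad <- !(v %in% schema$levels[[col]])
    if (col %in% na_ok) bad <- bad & !is.na(v)
    if (any(bad))
      stop(what, " table: invalid `", col, "` value(s) ",
           paste(unique(utils::head(v[bad], 3L)), collapse = ", "),
           " at row(s) ", paste(utils::head(which(bad), 5L), collapse = ", "),
           call. = FALSE)
  }
  invisible(df)
}

#' Read and write trial tables
#'
#' Lossless CSV round trip for the trial schema produced by
#' [simulate_experiment()] (identically shaped real data can be read the
#' same way). Reading validates the categorical fields and reports
#' offending rows; extra columns pass through untouched.
#'
#' @param trials a trial table.
#' @param path file path.
#' @return `read_trials()` returns the validated data frame;
#'   `write_trials()` returns `path` invisibly.
#' @export
write_trials <- function(trials, path) {
  check_schema(trials, trial_schema(), "trial",
               na_ok = c("phase", "advice_correct"))
  utils::write.csv(trials, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  df$advice_correct <- as.logical(df$advice_correct)
  df$response_correct <- as.logical(df$response_correct)
  check_schema(df, trial_schema(), "trial",
               na_ok = c("phase", "advice_correct"))
}

#' Read and write self-report tables
#'
#' CSV round trip for the repeated Likert self-reports. Ratings outside
#' 1..7, unknown items or out-of-range time points are rejected with the
#' offending row numbers.
#'
#' @param reports a self-report table.
#' @param path file path.
#' @return `read_reports()` returns the validated data frame;
#'   `write_reports()` returns `path` invisibly.
#' @export
write_reports <- function(reports, path) {
  check_schema(reports, report_schema(), "self-report")
  utils::write.csv(reports, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_reports
#' @export
read_reports <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  check_schema(df, report_schema(), "self-report")
}

#' Published reference contingency counts
#'
#' Reliance contingency counts (advice accepted / switched to advice, by
#' advice correctness and instruction condition) reported by a two-session
#' AI-advice classification study with 131 participants and 216 advised
#' trials each. Shipped as a plain-text fixture so that rate computations
#' and margin arithmetic can be validated against published values without
#' any download.
#'
#' @return data frame: `metric`, `advice_correct`, `condition`, `n_not`,
#'   `n_yes`.
#' @export
reference_reliance_counts <- function() {
  path <- system.file("extdata", "reliance_contingency_counts.csv",
                      package = "relianceSDT", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
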