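#' Run the full analysis pipeline on a synthetic cohort
#'
#' Orchestrates simulate -> tabulate -> fit -> metrics -> report as one
#' reproducible run: generates a synthetic cohort, writes the trial and
#' self-report tables, fits the hierarchical SDT model for Session 1 and
#' for Session 2 (overall, by phase, by advice correctness), forms the
#' overall and detailed d' differences, computes the reliance contingency
#' tables and the self-report regressions for trust and distrust,
#' correlates self-report means with behavioral measures, and writes a
#' human-readable report plus a JSON manifest with per-stage seeds, file
#' hashes, timings and convergence flags.
#'
#' Stage seeds are derived deterministically from the master seed, so a
#' run is fully reproducible and stages can be re-run in isolation. The
#' `"reduced"` MCMC profile (2 chains, 1500 draws, 500 tuning) is a named
#' low-cost profile for smoke runs; `"full"` uses the 4 x 10000/2000
#' configuration.
#'
#' @param out_dir output directory (created if needed).
#' @param config an [experiment_config()].
#' @param params a [profile_params()].
#' @param seed master integer seed.
#' @param profile `"full"` or `"reduced"` MCMC profile.
#' @return the manifest, invisibly (a list; also written as
#'   `manifest.json`).
#' @export
run_pipeline <- function(out_dir, config = experiment_config(),
                         params = profile_params(), seed = 1L,
                         profile = c("full", "reduced")) {
  profile <- match.arg(profile)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  mc <- if (profile == "full")
    list(chains = 4L, draws = 10000L, tune = 2000L)
  else
    list(chains = 2L, draws = 1500L, tune = 500L)

  manifest <- list(profile = profile, seed = as.integer(seed),
                   config = unclass(config), params = unclass(params),
                   stages = list(), outputs = list(), convergence = list())
  done <- function(stage, t0, files = character()) {
    manifest$stages[[stage]] <<- list(
      seed = stage_seed(seed, match(stage, pipeline_stages())),
      seconds = round(as.numeric(Sys.time()) - t0, 3))
    for (f in files)
      manifest$outputs[[basename(f)]] <<- unname(tools::md5sum(f))
  }
  run_stage <- function(stage, expr) {
    t0 <- as.numeric(Sys.time())
    res <- tryCatch(expr, error = function(e) {
      manifest$status <- paste0("failed at stage '", stage, "'")
      write_manifest(manifest, out_dir)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    list(result = res, t0 = t0)
  }
  path <- function(f) file.path(out_dir, f)

  # -- simulate -------------------------------------------------------------
  st <- run_stage("simulate", {
    cohort <- simulate_experiment(config, params,
                                  seed = stage_seed(seed, 1L))
    write_trials(cohort$trials, path("trials.csv"))
    write_reports(cohort$self_reports, path("self_reports.csv"))
    jsonlite::write_json(
      list(seed = cohort$seed, config = unclass(config),
           params = unclass(params), profiles = cohort$profiles),
      path("cohort.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
    cohort
  })
  cohort <- st$result
  done("simulate", st$t0,
       path(c("trials.csv", "self_reports.csv", "cohort.json")))

  trials_s1 <- cohort$trials[cohort$trials$session == 1L, ]
  trials_s2 <- cohort$trials[cohort$trials$session == 2L, ]

  # -- SDT fits -------------------------------------------------------------
  fits <- list()
  fit_files <- character()
  st <- run_stage("fit_sdt", {
    specs <- list(
      s1 = list(counts = tabulate_counts(trials_s1, "overall"), k = 11L),
      s2_overall = list(counts = tabulate_counts(trials_s2, "overall"),
                        k = 12L),
      s2_phase = list(counts = tabulate_counts(trials_s2, "phase"), k = 13L),
      s2_advice = list(counts = tabulate_counts(trials_s2, "advice"),
                       k = 14L))
    for (nm in names(specs)) {
      fits[[nm]] <- fit_hierarchical_sdt(
        specs[[nm]]$counts,
        sdt_model_spec(chains = mc$chains, draws = mc$draws, tune = mc$tune,
                       seed = stage_seed(seed, specs[[nm]]$k)))
      f <- path(sprintf("sdt_%s_group_summary.csv", nm))
      utils::write.csv(group_summary(fits[[nm]]), f, row.names = FALSE)
      g <- path(sprintf("sdt_%s_group_draws.csv", nm))
      utils::write.csv(
        data.frame(group_draws(fits[[nm]], "d"), check.names = FALSE), g,
        row.names = FALSE)
      fit_files <- c(fit_files, f, g)
      manifest$convergence[[nm]] <- fits[[nm]]$status
    }
    fits
  })
  fits <- st$result
  done("fit_sdt", st$t0, fit_files)

  # -- d' differences -------------------------------------------------------
  st <- run_stage("dprime_differences", {
    diffs <- list(
      overall = dprime_difference(fits$s2_overall, fits$s1, "overall"),
      `advice-correct` = dprime_difference(fits$s2_advice, fits$s1,
                                           "advice-correct"),
      `advice-incorrect` = dprime_difference(fits$s2_advice, fits$s1,
                                             "advice-incorrect"))
    tab <- do.call(rbind, lapply(names(diffs), function(v)
      cbind(variant = v, summary(diffs[[v]]))))
    utils::write.csv(tab, path("dprime_differences.csv"), row.names = FALSE)
    diffs
  })
  diffs <- st$result
  done("dprime_differences", st$t0, path("dprime_differences.csv"))

  # -- reliance metrics -----------------------------------------------------
  st <- run_stage("reliance_metrics", {
    ct <- contingency_table(trials_s2, trials_s1,
                            split_by = c("advice_correct", "condition"))
    utils::write.csv(ct, path("reliance_tables.csv"), row.names = FALSE)
    ct
  })
  reliance <- st$result
  done("reliance_metrics", st$t0, path("reliance_tables.csv"))

  # -- self-report regressions ----------------------------------------------
  st <- run_stage("selfreport_regression", {
    reg <- list()
    for (it in c("trust", "distrust")) {
      k <- if (it == "trust") 21L else 22L
      reg[[it]] <- fit_mixed_regression(
        cohort$self_reports,
        regression_spec(item = it, chains = mc$chains, draws = mc$draws,
                        tune = mc$tune, seed = stage_seed(seed, k)))
      utils::write.csv(summarize_coefficients(reg[[it]]),
                       path(sprintf("selfreport_%s_coefficients.csv", it)),
                       row.names = FALSE)
      manifest$convergence[[paste0("selfreport_", it)]] <- reg[[it]]$status
    }
    reg
  })
  reg <- st$result
  done("selfreport_regression", st$t0,
       path(sprintf("selfreport_%s_coefficients.csv",
                    c("trust", "distrust"))))

  # -- correlations ---------------------------------------------------------
  st <- run_stage("correlations", {
    behavior <- participant_behavior(fits, diffs, trials_s2, trials_s1)
    cors <- selfreport_behavior_correlations(cohort$self_reports, behavior)
    utils::write.csv(cors, path("selfreport_behavior_correlations.csv"),
                     row.names = FALSE)
    cors
  })
  cors <- st$result
  done("correlations", st$t0, path("selfreport_behavior_correlations.csv"))

  # -- report ---------------------------------------------------------------
  st <- run_stage("report", {
    write_report(path("report.txt"), fits, diffs, reliance, reg, cors)
  })
  done("report", st$t0, path("report.txt"))

  manifest$status <- "ok"
  write_manifest(manifest, out_dir)
  invisible(manifest)
}

pipeline_stages <- function() {
  c("simulate", "fit_sdt", "dprime_differences", "reliance_metrics",
    "selfreport_regression", "correlations", "report")
}

write_manifest <- function(manifest, out_dir) {
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(manifest)
}

# Per-participant behavioral measures entering the correlation table.
participant_behavior <- function(fits, diffs, trials_s2, trials_s1) {
  d2 <- participant_draws(fits$s2_overall, "d")
  acc <- acceptance_rate_by_participant(trials_s2)
  sw <- switch_by_participant(trials_s2, trials_s1)
  ids <- as.integer(colnames(d2))
  data.frame(
    participant_id = ids,
    dprime_s2 = colMeans(d2),
    dprime_diff_correct =
      colMeans(diffs$`advice-correct`$draws)[as.character(ids)],
    dprime_diff_incorrect =
      colMeans(diffs$`advice-incorrect`$draws)[as.character(ids)],
    acceptance_rate = acc[as.character(ids)],
    switch_percentage = sw[as.character(ids)])
}

acceptance_rate_by_participant <- function(trials_s2) {
  t2 <- advised_trials(trials_s2)
  tapply(t2$response == t2$advice_shown, t2$participant_id, mean)
}

switch_by_participant <- function(trials_s2, trials_s1) {
  t2 <- advised_trials(trials_s2)
  t1 <- trials_s1[trials_s1$session == 1L, ]
  idx <- match(paste(t2$participant_id, t2$stimulus_id),
               paste(t1$participant_id, t1$stimulus_id))
  eligible <- t1$response[idx] != t2$advice_shown
  t2 <- t2[eligible, , drop = FALSE]
  tapply(t2$response == t2$advice_shown, t2$participant_id, mean)
}

write_report <- function(file, fits, diffs, reliance, reg, cors) {
  fmt <- function(m, lo, hi) sprintf("%.2f [%.2f, %.2f]", m, lo, hi)
  con <- file(file, "w", encoding = "UTF-8")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w("Appropriate-reliance analysis report")
  w("====================================")
  w("")
  w("Group-level d' and criterion (posterior mean [95% HDI])")
  for (nm in names(fits)) {
    w("  ", nm, ":")
    gs <- group_summary(fits[[nm]])
    for (i in seq_len(nrow(gs)))
      w(sprintf("    %-10s %-28s %s", gs$parameter[i],
                paste(gs$condition[i], gs$cell[i], sep = " | "),
                fmt(gs$mean[i], gs$hdi_lower[i], gs$hdi_upper[i])))
  }
  w("")
  w("d' differences, Session 2 - Session 1 (cohort average per condition)")
  for (v in names(diffs)) {
    s <- summary(diffs[[v]])
    for (i in seq_len(nrow(s)))
      w(sprintf("  %-17s %-17s %s", v, s$condition[i],
                fmt(s$mean[i], s$hdi_lower[i], s$hdi_upper[i])))
  }
  w("")
  w("Reliance contingency tables (yes / (yes + no))")
  for (i in seq_len(nrow(reliance)))
    w(sprintf("  %-10s advice=%-9s condition=%-16s %6d / %6d  %6.2f%%",
              reliance$metric[i], reliance$advice_correct[i],
              reliance$condition[i], reliance$n_yes[i],
              reliance$n_yes[i] + reliance$n_not[i],
              100 * reliance$rate[i]))
  w("")
  w("Self-report regressions (Estimate [95% CI])")
  for (it in names(reg)) {
    w("  ", it, ":")
    sc <- summarize_coefficients(reg[[it]])
    for (i in seq_len(nrow(sc)))
      w(sprintf("    %-28s %s", sc$coefficient[i],
                fmt(sc$Estimate[i], sc[[4]][i], sc[[5]][i])))
  }
  w("")
  w("Correlations of mean self-reports with behavioral measures (Pearson r)")
  for (i in seq_len(nrow(cors)))
    w(sprintf("  %-24s trust % .3f  distrust % .3f", cors$measure[i],
              cors$trust[i], cors$distrust[i]))
  invisible(file)
}
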