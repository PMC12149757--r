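test_that("published contingency counts reproduce the published rates", {
  counts <- reference_reliance_counts()
  acc <- counts[counts$metric == "acceptance", ]
  # pooled incorrect-advice acceptance: 2,595 of 5,742 -> 45.19%
  inc <- acc[acc$advice_correct == "incorrect", ]
  expect_equal(round(100 * sum(inc$n_yes) / sum(inc$n_yes + inc$n_not), 2),
               45.19)
  # overall margin: 21,883 of 28,296 -> 77.34%
  expect_equal(round(100 * sum(acc$n_yes) / sum(acc$n_yes + acc$n_not), 2),
               77.34)
  # condition x correctness cells cross-check the margins
  expect_identical(sum(inc$n_yes), 2595L)
  expect_identical(inc$n_yes, c(1182L, 1413L))
})

test_that("acceptance rate counts agreement with the shown advice", {
  tr <- data.frame(participant_id = rep(1:2, each = 4), session = 2L,
                   condition = rep(condition_levels(), each = 4),
                   advice_shown = rep(c("signal", "noise"), 4),
                   advice_correct = rep(c(TRUE, FALSE), each = 2),
                   response = c("signal", "noise", "signal", "signal",
                                "noise", "noise", "noise", "signal"))
  all_acc <- acceptance_rate(transform(tr, response = advice_shown))
  expect_equal(all_acc$rate, 1)
  tab <- acceptance_rate(tr, c("advice_correct", "condition"))
  # brute-force recount
  for (i in seq_len(nrow(tab))) {
    sel <- tr[ifelse(tr$advice_correct, "correct", "incorrect") ==
                tab$advice_correct[i] & tr$condition == tab$condition[i], ]
    expect_identical(tab$n_yes[i] + tab$n_not[i], nrow(sel))
    expect_identical(tab$n_yes[i], sum(sel$response == sel$advice_shown))
  }
})

test_that("switch percentage uses the stimulus-paired session-1 decision", {
  t1 <- data.frame(participant_id = 1L, condition = "distrust", session = 1L,
                   stimulus_id = 1:4,
                   response = c("signal", "signal", "noise", "noise"))
  t2 <- data.frame(participant_id = 1L, condition = "distrust", session = 2L,
                   stimulus_id = 1:4,
                   advice_shown = c("noise", "signal", "signal", "noise"),
                   advice_correct = TRUE,
                   response = c("noise", "signal", "noise", "noise"))
  # eligible trials: stimuli 1 and 3 (s1 response differs from advice);
  # switched: stimulus 1 only
  out <- switch_percentage(t2, t1)
  expect_identical(out$n_yes + out$n_not, 2L)
  expect_equal(out$rate, 0.5)
  # no change from session 1 anywhere -> switch percentage 0
  t2b <- t2
  t2b$response <- t1$response
  expect_equal(switch_percentage(t2b, t1)$rate, 0)
  # unpairable stimulus
  expect_error(switch_percentage(transform(t2, stimulus_id = 5:8), t1),
               "unpairable")
})

test_that("a full-reliance cohort accepts and switches everywhere", {
  co <- simulate_experiment(
    tiny_config(n = 6),
    profile_params(adoption_mean = 1, adoption_concentration = Inf),
    seed = 9)
  t1 <- co$trials[co$trials$session == 1L, ]
  t2 <- co$trials[co$trials$session == 2L, ]
  expect_equal(acceptance_rate(t2)$rate, 1)
  sw <- switch_percentage(t2, t1, c("advice_correct", "condition"))
  expect_true(all(sw$rate[!is.na(sw$rate)] == 1))
})

test_that("contingency margins equal their cell sums and rates decompose", {
  co <- simulate_experiment(tiny_config(n = 8), seed = 10)
  t1 <- co$trials[co$trials$session == 1L, ]
  t2 <- co$trials[co$trials$session == 2L, ]
  ct <- contingency_table(t2, t1)
  for (m in unique(ct$metric)) {
    cells <- ct[ct$metric == m & ct$advice_correct != "total" &
                  ct$condition != "total", ]
    total <- ct[ct$metric == m & ct$advice_correct == "total" &
                  ct$condition == "total", ]
    expect_identical(sum(cells$n_yes), total$n_yes)
    expect_identical(sum(cells$n_not), total$n_not)
    for (cond in unique(cells$condition)) {
      margin <- ct[ct$metric == m & ct$advice_correct == "total" &
                     ct$condition == cond, ]
      expect_identical(sum(cells$n_yes[cells$condition == cond]),
                       margin$n_yes)
    }
    # pooled rate = denominator-weighted mean of cell rates
    wts <- cells$n_yes + cells$n_not
    expect_equal(total$rate, sum(cells$rate * wts) / sum(wts))
  }
  # switch denominators never exceed acceptance denominators per cell
  acc <- ct[ct$metric == "acceptance", ]
  sw <- ct[ct$metric == "switch", ]
  key <- function(x) paste(x$advice_correct, x$condition)
  idx <- match(key(sw), key(acc))
  expect_true(all(sw$n_yes + sw$n_not <= acc$n_yes[idx] + acc$n_not[idx]))
  # row order of the input does not matter
  shuffled <- t2[sample.int(nrow(t2)), ]
  expect_equal(contingency_table(shuffled, t1), ct)
  expect_error(contingency_table(t2, split_by = "phase"), "unknown split")
})

test_that("pearson correlation behaves at its edges and at scale", {
  x <- c(1, 3, 7, 2, 5)
  expect_equal(correlate(x, x), 1)
  expect_equal(correlate(x, -2 * x + 4), -1)
  expect_warning(r0 <- correlate(x, rep(1, 5)), "zero variance")
  expect_true(is.na(r0))
  expect_error(correlate(1:2, 1:2), "at least 3")
  set.seed(13)
  n <- 10000
  u <- rnorm(n)
  v <- 0.4 * u + sqrt(1 - 0.16) * rnorm(n)
  expect_lt(abs(correlate(u, v) - 0.4), 0.03)
})
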