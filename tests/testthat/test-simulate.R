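test_that("advice schedule follows the blocked Bernoulli design", {
  cfg <- experiment_config()
  sched <- sample_advice_schedule(cfg, seed = 11)
  expect_identical(nrow(sched), 216L)
  expect_identical(sched$p_correct,
                   rep(cfg$advice_accuracy, times = cfg$block_trials))
  # degenerate blocks are deterministic
  cfg1 <- experiment_config(n_trials_session1 = 48,
                            block_trials = c(24L, 24L),
                            advice_accuracy = c(1, 0),
                            phases = c("pre-error", "error"),
                            selfreport_blocks = c(1, 1, 2, 2, 2))
  s1 <- sample_advice_schedule(cfg1, seed = 3)
  expect_true(all(s1$advice_correct[s1$block_index == 1]))
  expect_false(any(s1$advice_correct[s1$block_index == 2]))
  # reproducible under a fixed seed
  expect_identical(sched, sample_advice_schedule(cfg, seed = 11))
})

test_that("realized advice accuracy concentrates on the block probability", {
  # 10,000 replicate 24-trial blocks at p = 0.75, as one long draw
  n <- 240000L
  cfg <- experiment_config(n_trials_session1 = n, block_trials = n,
                           advice_accuracy = 0.75, phases = "error",
                           selfreport_blocks = rep(1L, 5L))
  sched <- sample_advice_schedule(cfg, seed = 99)
  se <- sqrt(0.75 * 0.25 / n)
  expect_lt(abs(mean(sched$advice_correct) - 0.75), 3 * se)
})

test_that("the SDT observer matches its closed form and the advice limits", {
  prof <- list(true_dprime_s1 = 2, true_dprime_s2_own = 2,
               true_criterion = 0, adoption_weight = 0)
  r <- simulate_response(prof, rep("signal", 50000L), seed = 5)
  se <- sqrt(pnorm(1) * (1 - pnorm(1)) / 50000)
  expect_lt(abs(mean(r == "signal") - pnorm(1)), 3 * se)

  # adoption weight 1: the response always equals shown advice
  prof$adoption_weight <- 1
  truth <- rep(c("signal", "noise"), 500)
  advice <- rep(c("noise", "signal"), each = 500)
  expect_identical(simulate_response(prof, truth, advice, seed = 6), advice)

  # adoption weight 0: advice is ignored, response distribution equals the
  # unadvised observer's closed form
  prof$adoption_weight <- 0
  r0 <- simulate_response(prof, rep("noise", 50000L),
                          advice_shown = "signal", seed = 7)
  f <- pnorm(-1)
  expect_lt(abs(mean(r0 == "signal") - f),
            3 * sqrt(f * (1 - f) / 50000))
})

test_that("self-report trajectories step at the post-error time point", {
  cfg <- experiment_config()
  prof <- list(participant_id = 1L, condition = "distrust",
               trust_baseline = 5, distrust_baseline = 3, use_baseline = 5,
               selfreport_error_shift = 2, likert_noise_sd = 0)
  rep0 <- simulate_self_reports(prof, cfg, seed = 1)
  expect_identical(rep0$rating[rep0$item == "trust"], c(5L, 5L, 3L, 3L, 3L))
  expect_identical(rep0$rating[rep0$item == "distrust"],
                   c(3L, 3L, 5L, 5L, 5L))
  # the control item dips only transiently
  expect_identical(rep0$rating[rep0$item == "use"], c(5L, 5L, 3L, 5L, 5L))
  # zero shift, zero noise: flat at the rounded baseline
  prof$selfreport_error_shift <- 0
  prof$trust_baseline <- 4.4
  flat <- simulate_self_reports(prof, cfg, seed = 1)
  expect_identical(flat$rating[flat$item == "trust"], rep(4L, 5L))
})

test_that("mean trust drop across many simulated raters matches the shift", {
  cfg <- experiment_config()
  ratings <- vapply(1:1000, function(i) {
    prof <- list(participant_id = i, condition = "distrust",
                 trust_baseline = 4.5, distrust_baseline = 3,
                 use_baseline = 4.5, selfreport_error_shift = 0.5,
                 likert_noise_sd = 1)
    r <- simulate_self_reports(prof, cfg, seed = 1000 + i)
    tr <- r$rating[r$item == "trust"]
    c(tr[1L], tr[3L])
  }, numeric(2))
  drop <- mean(ratings[1, ]) - mean(ratings[2, ])
  # rating variance ~ noise + discretization; 3 SE with a conservative bound
  expect_lt(abs(drop - 0.5), 3 * sqrt(2 * 1.2 / 1000))
})

test_that("generated ratings always stay on the 7-point scale", {
  cfg <- tiny_config(n = 8)
  for (s in 1:5) {
    co <- simulate_experiment(cfg, profile_params(likert_noise_sd = 3),
                              seed = s)
    expect_true(all(co$self_reports$rating %in% 1:7))
  }
})

test_that("trial and report counts honor the counting contract", {
  cfg <- experiment_config(n_participants = 2, n_trials_session1 = 4,
                           block_trials = 4L, advice_accuracy = 0.9,
                           phases = "pre-error",
                           selfreport_blocks = rep(1L, 5L))
  co <- simulate_experiment(cfg, seed = 8)
  expect_identical(nrow(co$trials), 2L * (4L + 4L))
  expect_identical(nrow(co$self_reports), 2L * 5L * 3L)
  expect_identical(nrow(co$profiles), 2L)
})

test_that("the default cohort has 131 x 432 trials and consistent records", {
  co <- default_cohort()
  expect_identical(nrow(co$trials), 131L * 432L)
  t1 <- co$trials[co$trials$session == 1L, ]
  t2 <- co$trials[co$trials$session == 2L, ]
  expect_true(all(t1$advice_shown == "none"))
  expect_true(all(t2$advice_shown %in% c("signal", "noise")))
  expect_identical(t2$advice_correct,
                   t2$advice_shown == t2$true_category)
  # same stimulus identities in both sessions, per participant
  by_p <- split(co$trials, co$trials$participant_id)
  p1 <- by_p[[1L]]
  expect_setequal(p1$stimulus_id[p1$session == 1L],
                  p1$stimulus_id[p1$session == 2L])
  # per-block truth balance in session 2
  blk <- t2[t2$participant_id == 1L & t2$block_index == 4L, ]
  expect_identical(sum(blk$true_category == "signal"), 12L)
})

test_that("identical config and seed reproduce the cohort byte for byte", {
  cfg <- tiny_config(n = 4)
  a <- simulate_experiment(cfg, seed = 123)
  b <- simulate_experiment(cfg, seed = 123)
  expect_identical(a$trials, b$trials)
  expect_identical(a$self_reports, b$self_reports)
  expect_identical(a$profiles, b$profiles)
  expect_false(identical(
    a$trials, simulate_experiment(cfg, seed = 124)$trials))
})

test_that("an injected group d' is recovered from unadvised tabulations", {
  cfg <- experiment_config(n_participants = 40)
  params <- profile_params(dprime_mean = 2, dprime_sd = 0,
                           criterion_mean = 0, criterion_sd = 0)
  co <- simulate_experiment(cfg, params, seed = 31)
  cnt <- tabulate_counts(co$trials[co$trials$session == 1L, ], "overall")
  pooled <- loglinear_rates(data.frame(
    n_signal = sum(cnt$n_signal), n_noise = sum(cnt$n_noise),
    hits = sum(cnt$hits), false_alarms = sum(cnt$false_alarms)))
  est <- sdt_invert(pooled$hit_rate, pooled$false_alarm_rate)
  expect_lt(abs(est$d - 2), 0.12)
  expect_lt(abs(est$c - 0), 0.08)
})
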