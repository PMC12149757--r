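test_that("log-linear correction gives the documented extreme rates", {
  base <- data.frame(n_signal = 108, n_noise = 108)
  full <- loglinear_rates(cbind(base, hits = 108, false_alarms = 0))
  expect_equal(full$hit_rate, 108.5 / 109)
  expect_equal(full$false_alarm_rate, 0.5 / 109)
  half <- loglinear_rates(cbind(base, hits = 54, false_alarms = 54))
  expect_equal(half$hit_rate, 0.5)
  expect_true(all(full$hit_rate > 0 & full$hit_rate < 1))
  expect_error(loglinear_rates(data.frame(n_signal = 0, n_noise = 10,
                                          hits = 0, false_alarms = 2)),
               "degenerate")
  expect_error(loglinear_rates(cbind(base, hits = 109, false_alarms = 0)),
               "hits <= n_signal")
})

test_that("reparametrization and inverse agree with normal-table values", {
  expect_equal(as.numeric(sdt_reparam(0, 0)), c(0.5, 0.5))
  expect_equal(as.numeric(sdt_reparam(2, 0)), c(pnorm(1), pnorm(-1)))
  expect_equal(as.numeric(sdt_invert(0.5, 0.5)), c(0, 0))
  ext <- sdt_invert(108.5 / 109, 0.5 / 109)
  expect_equal(round(ext$d, 2), 5.21)
  cmax <- sdt_invert(0.5 / 109, 0.5 / 109)
  expect_equal(cmax$d, 0)
  expect_equal(round(cmax$c, 2), 2.61)
  expect_error(sdt_invert(1, 0.5), "strictly inside")
  expect_error(sdt_invert(0.5, 0), "strictly inside")
})

test_that("the inverse round-trips the reparametrization on the full grid", {
  grid <- expand.grid(d = seq(-5.21, 5.21, length.out = 25),
                      c = seq(-2.61, 2.61, length.out = 25))
  rates <- sdt_reparam(grid$d, grid$c)
  back <- sdt_invert(rates$hit_rate, rates$false_alarm_rate)
  expect_lt(max(abs(back$d - grid$d)), 1e-9)
  expect_lt(max(abs(back$c - grid$c)), 1e-9)
})

test_that("corrected estimates stay inside the theoretical bounds", {
  counts <- expand.grid(hits = c(0L, 1L, 54L, 107L, 108L),
                        false_alarms = c(0L, 1L, 54L, 107L, 108L))
  counts$n_signal <- 108L
  counts$n_noise <- 108L
  est <- with(loglinear_rates(counts),
              sdt_invert(hit_rate, false_alarm_rate))
  expect_lte(max(abs(est$d)), 2 * qnorm(108.5 / 109) + 1e-12)
  expect_lte(max(abs(est$c)), qnorm(108.5 / 109) + 1e-12)
  expect_equal(max(abs(est$d)), 2 * qnorm(108.5 / 109))
  expect_equal(max(abs(est$c)), qnorm(108.5 / 109))
  # monotonicity: more hits at fixed false alarms -> strictly larger d
  hseq <- loglinear_rates(data.frame(n_signal = 108, n_noise = 108,
                                     hits = 0:108, false_alarms = 30))
  dseq <- sdt_invert(hseq$hit_rate, hseq$false_alarm_rate)$d
  expect_true(all(diff(dseq) > 0))
})

test_that("tabulated counts equal an independent nested-loop recount", {
  co <- simulate_experiment(tiny_config(n = 5), seed = 77)
  for (grouping in c("overall", "phase", "advice")) {
    tab <- tabulate_counts(co$trials, grouping)
    # brute-force recount
    for (i in seq_len(nrow(tab))) {
      row <- tab[i, ]
      hits <- 0L; fas <- 0L; nsig <- 0L; nnoi <- 0L
      for (j in seq_len(nrow(co$trials))) {
        tr <- co$trials[j, ]
        if (tr$participant_id != row$participant_id) next
        if (tr$session != row$session) next
        cell_j <- if (tr$session == 1L) "all"
          else switch(grouping,
                      overall = "all",
                      phase = tr$phase,
                      advice = if (tr$advice_correct) "advice-correct"
                               else "advice-incorrect")
        if (cell_j != row$cell) next
        if (tr$true_category == "signal") {
          nsig <- nsig + 1L
          if (tr$response == "signal") hits <- hits + 1L
        } else {
          nnoi <- nnoi + 1L
          if (tr$response == "signal") fas <- fas + 1L
        }
      }
      expect_identical(c(row$n_signal, row$n_noise, row$hits,
                         row$false_alarms),
                       c(nsig, nnoi, hits, fas))
    }
  }
})

test_that("the four-trial textbook example tabulates correctly", {
  tr <- data.frame(participant_id = 1L, condition = "distrust", session = 1L,
                   true_category = c("signal", "signal", "noise", "noise"),
                   response = c("signal", "noise", "signal", "noise"),
                   phase = "none", advice_correct = NA)
  tab <- tabulate_counts(tr, "overall")
  expect_identical(tab$hits, 1L)
  expect_identical(tab$n_signal, 2L)
  expect_identical(tab$false_alarms, 1L)
  expect_identical(tab$n_noise, 2L)
})

test_that("full session-1 cells hold 108 signal and 108 noise trials", {
  co <- default_cohort()
  tab <- tabulate_counts(co$trials[co$trials$session == 1L, ], "overall")
  expect_identical(nrow(tab), 131L)
  expect_true(all(tab$n_signal == 108L))
  expect_true(all(tab$n_noise == 108L))
})

test_that("swapping the signal designation flips c and preserves d", {
  co <- simulate_experiment(tiny_config(n = 6), seed = 41)
  t1 <- co$trials[co$trials$session == 1L, ]
  a <- loglinear_rates(tabulate_counts(t1, "overall", signal = "signal"))
  b <- loglinear_rates(tabulate_counts(t1, "overall", signal = "noise"))
  ea <- sdt_invert(a$hit_rate, a$false_alarm_rate)
  eb <- sdt_invert(b$hit_rate, b$false_alarm_rate)
  expect_equal(ea$d, eb$d)
  expect_equal(ea$c, -eb$c)
})
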