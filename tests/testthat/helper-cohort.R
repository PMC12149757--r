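# Shared fixtures, all generated in code.

# Reduced three-block design: 24 advised trials, all three phases, five
# self-report time points on repeated block indices.
tiny_config <- function(n = 6L, seed = NULL) {
  experiment_config(
    n_participants = n, n_trials_session1 = 24L,
    block_trials = rep(8L, 3L), advice_accuracy = c(0.9, 0.5, 0.9),
    phases = c("pre-error", "error", "post-error"),
    selfreport_blocks = c(1L, 2L, 2L, 3L, 3L), seed = seed)
}

fast_sdt_spec <- function(seed, chains = 2L, draws = 1500L, tune = 500L)
  sdt_model_spec(chains = chains, draws = draws, tune = tune, seed = seed)

fast_reg_spec <- function(item, seed, chains = 2L, draws = 1500L,
                          tune = 500L, coding = "contrasts")
  regression_spec(item = item, coding = coding, chains = chains,
                  draws = draws, tune = tune, seed = seed)

# Default full-scale cohort (131 x 432 trials), computed once per test run.
.fixture_env <- new.env(parent = emptyenv())
default_cohort <- function() {
  if (is.null(.fixture_env$cohort))
    .fixture_env$cohort <- simulate_experiment(experiment_config(), seed = 2024L)
  .fixture_env$cohort
}

# Counts drawn directly from the hierarchical SDT model (binomial
# observations at the Eq.-style reparametrized rates), used for parameter
# recovery; uses the current RNG stream.
simulate_sdt_counts <- function(n_per_group, d_mu, c_mu,
                                sigma_d = 0.8, sigma_c = 0.4,
                                n_signal = 108L, n_noise = 108L) {
  stopifnot(length(d_mu) == length(c_mu))
  groups <- if (is.null(names(d_mu))) condition_levels()[seq_along(d_mu)]
            else names(d_mu)
  names(d_mu) <- groups
  names(c_mu) <- groups
  n <- n_per_group * length(groups)
  cond <- rep(groups, each = n_per_group)
  d <- stats::rnorm(n, d_mu[cond], sigma_d)
  c <- stats::rnorm(n, c_mu[cond], sigma_c)
  rates <- sdt_reparam(d, c)
  data.frame(participant_id = seq_len(n), condition = cond,
             session = 1L, cell = "all",
             n_signal = n_signal, n_noise = n_noise,
             hits = stats::rbinom(n, n_signal, rates$hit_rate),
             false_alarms = stats::rbinom(n, n_noise,
                                          rates$false_alarm_rate))
}

# A fabricated sdt_fit whose participant-level d' draws are given exactly,
# for testing draw-wise arithmetic without MCMC.
fake_sdt_fit <- function(d_draws, condition = "distrust", cell = "all") {
  n <- ncol(d_draws)
  cols <- c(sprintf("D[%d]", seq_len(n)), sprintf("C[%d]", seq_len(n)))
  m <- cbind(d_draws, matrix(0, nrow(d_draws), n))
  colnames(m) <- cols
  units <- data.frame(unit = seq_len(n), participant_id = seq_len(n),
                      condition = rep_len(condition, n), cell = cell)
  structure(list(samples = list(m), units = units,
                 groups = data.frame(g = 1L, condition = condition[1L],
                                     cell = cell,
                                     key = paste(condition[1L], cell,
                                                 sep = " | ")),
                 status = "ok"),
            class = "sdt_fit")
}
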