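#' Specification of the hierarchical Bayesian SDT model
#'
#' Priors and MCMC settings for [fit_hierarchical_sdt()]. The defaults are
#' chosen so that the theoretically possible parameter range under the
#' log-linear correction at 108 + 108 trials (|d'| <= 5.21, |c| <= 2.61)
#' lies within 3 prior SDs of the group-mean priors: Gaussian(0, 1.9) for
#' the group d' means and Gaussian(0, 0.95) for the group criterion means,
#' with Gamma(0.001, 0.001) priors on the two participant-level precisions.
#'
#' @param group_mean_d_scale prior SD of the group-level d' means.
#' @param group_mean_c_scale prior SD of the group-level criterion means.
#' @param precision_shape,precision_rate Gamma prior on the participant-level
#'   precisions lambda_D and lambda_C (two independent parameters).
#' @param chains number of MCMC chains (default 4).
#' @param draws total draws per chain (default 10000).
#' @param tune initial draws per chain discarded as tuning (default 2000);
#'   retained draws per chain are `draws - tune`.
#' @param seed integer seed for the JAGS RNGs.
#' @return an object of class `sdt_model_spec`.
#' @export
sdt_model_spec <- function(group_mean_d_scale = 1.9,
                           group_mean_c_scale = 0.95,
                           precision_shape = 0.001, precision_rate = 0.001,
                           chains = 4L, draws = 10000L, tune = 2000L,
                           seed = NULL) {
  stopifnot(group_mean_d_scale > 0, group_mean_c_scale > 0,
            precision_shape > 0, precision_rate > 0,
            chains >= 1, draws >= 2, tune >= 0)
  if (tune >= draws)
    stop("`tune` must be smaller than `draws`", call. = FALSE)
  structure(list(group_mean_d_scale = group_mean_d_scale,
                 group_mean_c_scale = group_mean_c_scale,
                 precision_shape = precision_shape,
                 precision_rate = precision_rate,
                 chains = as.integer(chains), draws = as.integer(draws),
                 tune = as.integer(tune),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "sdt_model_spec")
}

# Hierarchical equal-variance SDT model. Participant-level sensitivities and
# criteria are Gaussian around their group-cell means with shared
# precisions; (D, C) map to hit/false-alarm probabilities through the
# standard-normal CDF. The observation model is the binomial kernel
# evaluated at the log-linear-corrected frequencies; since corrected
# frequencies are half-integers, the log-likelihood enters through the
# Poisson zeros trick rather than dbin.
sdt_jags_model <- function() {
"model {
  for (r in 1:R) {
    D[r] ~ dnorm(Dmu[g[r]], lambdaD)
    C[r] ~ dnorm(Cmu[g[r]], lambdaC)
    h[r] <- max(min(phi(D[r] / 2 - C[r]), 1 - 1.0E-12), 1.0E-12)
    f[r] <- max(min(phi(-D[r] / 2 - C[r]), 1 - 1.0E-12), 1.0E-12)
    ll[r] <- hstar[r] * log(h[r]) + (nsig[r] - hstar[r]) * log(1 - h[r]) +
             fstar[r] * log(f[r]) + (nnoi[r] - fstar[r]) * log(1 - f[r])
    z[r] ~ dpois(Cz - ll[r])
  }
  for (k in 1:G) {
    Dmu[k] ~ dnorm(0, pow(sdD, -2))
    Cmu[k] ~ dnorm(0, pow(sdC, -2))
  }
  lambdaD ~ dgamma(prShape, prRate)
  lambdaC ~ dgamma(prShape, prRate)
  sigmaD <- 1 / sqrt(lambdaD)
  sigmaC <- 1 / sqrt(lambdaC)
}"
}

#' Fit the hierarchical Bayesian SDT model
#'
#' Fits, by MCMC (JAGS), the hierarchical model in which each participant's
#' sensitivity `D_i` and criterion `C_i` in each analysis cell are drawn
#' from Gaussian group distributions (one mean per condition x cell, two
#' shared precisions), linked to the corrected hit/false-alarm frequencies
#' through the equal-variance reparametrization. One model is fitted per
#' session; pass counts from a single session only.
#'
#' Cells with zero trials on one side (no signal or no noise trials) cannot
#' enter the likelihood even after correction; they are excluded with a
#' warning naming the participant and cell.
#'
#' @param counts a count table from [tabulate_counts()] restricted to one
#'   session.
#' @param spec an [sdt_model_spec()].
#' @return an object of class `sdt_fit` with elements `samples` (a
#'   [coda::mcmc.list] of retained draws), `units` (row-to-participant/cell
#'   map), `groups` (group-cell map), `diagnostics` (split R-hat and
#'   effective sample size for the group-level parameters), `status`
#'   (`"ok"` or `"nonconverged"`), and the `spec`.
#' @export
fit_hierarchical_sdt <- function(counts, spec = sdt_model_spec()) {
  stopifnot(inherits(spec, "sdt_model_spec"))
  if (length(unique(counts$session)) != 1L)
    stop("`counts` must come from a single session; fit sessions separately",
         call. = FALSE)

  bad <- counts$n_signal < 1L | counts$n_noise < 1L
  if (any(bad)) {
    warning("excluding ", sum(bad), " cell(s) with no signal or no noise ",
            "trials: ",
            paste(sprintf("participant %s [%s]", counts$participant_id[bad],
                          counts$cell[bad]), collapse = "; "),
            call. = FALSE)
    counts <- counts[!bad, , drop = FALSE]
  }
  if (nrow(counts) == 0L) stop("no usable cells", call. = FALSE)

  counts <- loglinear_rates(counts)
  group_key <- paste(counts$condition, counts$cell, sep = " | ")
  groups <- unique(data.frame(condition = counts$condition,
                              cell = counts$cell, key = group_key))
  groups <- groups[order(groups$key), , drop = FALSE]
  groups$g <- seq_len(nrow(groups))
  g <- groups$g[match(group_key, groups$key)]
  tab <- table(g)
  if (any(tab < 2L))
    warning("group cell(s) with fewer than 2 participants: ",
            paste(groups$key[as.integer(names(tab)[tab < 2L])],
                  collapse = "; "), call. = FALSE)

  data <- list(R = nrow(counts), G = nrow(groups), g = g,
               hstar = counts$hits + 0.5, nsig = counts$n_signal + 1,
               fstar = counts$false_alarms + 0.5, nnoi = counts$n_noise + 1,
               z = rep(0L, nrow(counts)), Cz = 10000,
               sdD = spec$group_mean_d_scale, sdC = spec$group_mean_c_scale,
               prShape = spec$precision_shape, prRate = spec$precision_rate)

  # start chains at the closed-form point estimates
  pt <- sdt_invert(counts$hit_rate, counts$false_alarm_rate)
  base_inits <- list(
    D = pt$d, C = pt$c,
    Dmu = as.vector(tapply(pt$d, g, mean)),
    Cmu = as.vector(tapply(pt$c, g, mean)),
    lambdaD = 1 / max(stats::var(pt$d), 0.05),
    lambdaC = 1 / max(stats::var(pt$c), 0.05))
  seed <- if (is.null(spec$seed)) sample.int(2^31 - 2, 1L) else spec$seed
  inits <- lapply(seq_len(spec$chains), function(ch)
    c(base_inits, list(.RNG.name = "base::Mersenne-Twister",
                       .RNG.seed = (seed + ch) %% (2^31 - 1))))

  n_adapt <- min(1000L, spec$tune)
  model <- rjags::jags.model(textConnection(sdt_jags_model()), data = data,
                             inits = inits, n.chains = spec$chains,
                             n.adapt = n_adapt, quiet = TRUE)
  if (spec$tune > n_adapt)
    stats::update(model, n.iter = spec$tune - n_adapt, progress.bar = "none")
  monitor <- c("D", "C", "Dmu", "Cmu", "lambdaD", "lambdaC",
               "sigmaD", "sigmaC")
  samples <- rjags::coda.samples(model, variable.names = monitor,
                                 n.iter = spec$draws - spec$tune,
                                 progress.bar = "none")

  units <- data.frame(unit = seq_len(nrow(counts)),
                      participant_id = counts$participant_id,
                      condition = counts$condition, cell = counts$cell)
  diagnostics <- sdt_diagnostics(samples, groups)
  status <- if (any(diagnostics$rhat > 1.01, na.rm = TRUE)) "nonconverged"
            else "ok"
  if (status == "nonconverged")
    warning("split R-hat exceeds 1.01 for at least one group-level ",
            "parameter; inspect `diagnostics`", call. = FALSE)

  structure(list(samples = samples, units = units,
                 groups = groups[, c("g", "condition", "cell", "key")],
                 diagnostics = diagnostics, status = status, spec = spec),
            class = "sdt_fit")
}

sdt_diagnostics <- function(samples, groups) {
  pars <- c(sprintf("Dmu[%d]", groups$g), sprintf("Cmu[%d]", groups$g),
            "lambdaD", "lambdaC")
  labels <- c(sprintf("Dmu (%s)", groups$key), sprintf("Cmu (%s)", groups$key),
              "lambdaD", "lambdaC")
  pars <- vapply(pars, resolve_par, character(1), samples = samples)
  data.frame(parameter = labels,
             rhat = vapply(pars, function(p)
               split_rhat(sapply(samples, function(ch) as.numeric(ch[, p]))),
               numeric(1)),
             ess = vapply(pars, function(p)
               as.numeric(coda::effectiveSize(samples[, p, drop = FALSE])),
               numeric(1)),
             row.names = NULL)
}

#' @export
print.sdt_fit <- function(x, ...) {
  cat("Hierarchical Bayesian SDT fit (", x$status, ")\n", sep = "")
  cat("  units:", nrow(x$units), " group cells:", nrow(x$groups), "\n")
  cat("  chains:", length(x$samples), " retained draws/chain:",
      nrow(x$samples[[1]]), "\n")
  print(group_summary(x), row.names = FALSE)
  invisible(x)
}

# JAGS drops the [1] suffix when a parameter vector has length one
resolve_par <- function(samples, par) {
  vn <- colnames(samples[[1L]])
  if (par %in% vn) return(par)
  alt <- sub("\\[1\\]$", "", par)
  if (alt %in% vn) return(alt)
  stop("parameter '", par, "' not found in the posterior draws",
       call. = FALSE)
}

# pooled draws (chains stacked) for one named JAGS parameter
pooled_draws <- function(fit, par) {
  par <- resolve_par(fit$samples, par)
  do.call(c, lapply(fit$samples, function(ch) as.numeric(ch[, par])))
}

#' Posterior draws of participant-level parameters
#'
#' @param fit an `sdt_fit`.
#' @param parameter `"d"` (sensitivity) or `"c"` (criterion).
#' @param cell analysis cell (default `"all"`).
#' @return matrix of pooled posterior draws, one column per participant
#'   (column names are participant ids).
#' @export
participant_draws <- function(fit, parameter = c("d", "c"), cell = "all") {
  parameter <- match.arg(parameter)
  stopifnot(inherits(fit, "sdt_fit"))
  u <- fit$units[fit$units$cell == cell, , drop = FALSE]
  if (nrow(u) == 0L)
    stop("no units in cell '", cell, "'", call. = FALSE)
  jags_par <- if (parameter == "d") "D" else "C"
  m <- sapply(u$unit, function(r) pooled_draws(fit, sprintf("%s[%d]",
                                                            jags_par, r)))
  colnames(m) <- u$participant_id
  m
}

#' Posterior draws of group-level means
#'
#' @param fit an `sdt_fit`.
#' @param parameter `"d"` or `"c"`.
#' @return matrix of pooled draws, one column per group cell (named
#'   `condition | cell`).
#' @export
group_draws <- function(fit, parameter = c("d", "c")) {
  parameter <- match.arg(parameter)
  jags_par <- if (parameter == "d") "Dmu" else "Cmu"
  m <- sapply(fit$groups$g, function(k)
    pooled_draws(fit, sprintf("%s[%d]", jags_par, k)))
  colnames(m) <- fit$groups$key
  m
}

#' Summary of group-level posteriors
#'
#' @param fit an `sdt_fit`.
#' @param prob HDI mass (default 0.95).
#' @return data frame: condition, cell, parameter, posterior mean and HDI.
#' @export
group_summary <- function(fit, prob = 0.95) {
  out <- lapply(c("d", "c"), function(p) {
    m <- group_draws(fit, p)
    s <- apply(m, 2L, posterior_summary, prob = prob)
    data.frame(condition = fit$groups$condition, cell = fit$groups$cell,
               parameter = p,
               mean = vapply(s, `[[`, numeric(1), "mean"),
               hdi_lower = vapply(s, `[[`, numeric(1), "hdi_lower"),
               hdi_upper = vapply(s, `[[`, numeric(1), "hdi_upper"))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Posterior d' difference between the advised and unadvised session
#'
#' Draw-wise difference `d'_S2(cell) - d'_S1` per participant, the measure
#' of improvement (positive) or worsening (negative) attributable to the
#' advice. The `"overall"` variant uses all Session-2 trials; the detailed
#' variants split Session 2 by advice correctness, which separates
#' appropriate reliance (positive on correct advice, near zero on incorrect
#' advice) from general reliance (positive on correct, negative on
#' incorrect). The two session fits are independent; draws are paired at
#' equal index after pooling chains, so only marginal summaries of the
#' difference should be interpreted.
#'
#' @param fit_s2 `sdt_fit` for Session 2 (grouping matching `variant`).
#' @param fit_s1 `sdt_fit` for Session 1.
#' @param variant `"overall"`, `"advice-correct"` or `"advice-incorrect"`.
#' @return object of class `dprime_difference`: list with `variant`,
#'   `participant_id`, `condition` and `draws` (matrix, one column per
#'   participant).
#' @export
dprime_difference <- function(fit_s2, fit_s1,
                              variant = c("overall", "advice-correct",
                                          "advice-incorrect")) {
  variant <- match.arg(variant)
  cell <- if (variant == "overall") "all" else variant
  m2 <- participant_draws(fit_s2, "d", cell = cell)
  m1 <- participant_draws(fit_s1, "d", cell = "all")
  if (!identical(colnames(m2), colnames(m1)))
    stop("participant mismatch between the two session fits", call. = FALSE)
  if (nrow(m2) != nrow(m1))
    stop("the two fits must retain the same number of draws", call. = FALSE)
  ids <- as.integer(colnames(m2))
  cond <- fit_s2$units$condition[match(ids, fit_s2$units$participant_id)]
  structure(list(variant = variant, participant_id = ids, condition = cond,
                 draws = m2 - m1),
            class = "dprime_difference")
}

#' @export
print.dprime_difference <- function(x, ...) {
  cat("Posterior d' difference (Session 2 [", x$variant,
      "] - Session 1)\n", sep = "")
  print(summary(x), row.names = FALSE)
  invisible(x)
}

#' Summarize a posterior d' difference by condition
#'
#' Per condition, the posterior of the cohort-average difference (mean over
#' participants at each draw) is summarized by its mean and 95% HDI.
#'
#' @param object a `dprime_difference`.
#' @param prob HDI mass.
#' @param ... unused.
#' @return data frame: condition, n, mean, hdi_lower, hdi_upper.
#' @export
summary.dprime_difference <- function(object, prob = 0.95, ...) {
  conds <- unique(object$condition)
  out <- lapply(conds, function(cn) {
    cols <- object$condition == cn
    avg <- rowMeans(object$draws[, cols, drop = FALSE])
    s <- posterior_summary(avg, prob = prob)
    data.frame(condition = cn, n = sum(cols), mean = s$mean,
               hdi_lower = s$hdi_lower, hdi_upper = s$hdi_upper)
  })
  do.call(rbind, out)
}

#' Highest-density interval of a posterior sample
#'
#' The narrowest interval containing a fraction `prob` of the draws,
#' computed by the sorted sliding-window method.
#'
#' @param draws numeric vector of at least 2 finite draws.
#' @param prob interval mass (default 0.95).
#' @return named numeric vector `c(lower, upper)`.
#' @export
hdi <- function(draws, prob = 0.95) {
  draws <- as.numeric(draws)
  if (length(draws) < 2L || any(!is.finite(draws)))
    stop("`draws` must contain at least 2 finite values", call. = FALSE)
  stopifnot(prob > 0, prob <= 1)
  s <- sort(draws)
  n <- length(s)
  k <- max(1L, ceiling(prob * n))
  if (k >= n) return(c(lower = s[1L], upper = s[n]))
  widths <- s[(k + 1L):n] - s[1:(n - k)]
  i <- which.min(widths)
  c(lower = s[i], upper = s[i + k])
}

#' Posterior mean and 95% HDI
#'
#' The reporting convention used throughout: arithmetic posterior mean and
#' the narrowest interval containing 95% of the draws.
#'
#' @param draws numeric vector of posterior draws (>= 2).
#' @param prob HDI mass (default 0.95).
#' @return data frame with columns `mean`, `hdi_lower`, `hdi_upper`.
#' @export
posterior_summary <- function(draws, prob = 0.95) {
  h <- hdi(draws, prob = prob)
  data.frame(mean = mean(draws), hdi_lower = unname(h["lower"]),
             hdi_upper = unname(h["upper"]))
}
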