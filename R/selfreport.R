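#' Planned-contrast weights for the five self-report time points
#'
#' The a-priori comparisons among the five query time points: contrast 1
#' compares time points 1 and 2 (within the baseline advice quality),
#' contrast 2 compares time point 3 (after the error phase) against 1-2,
#' contrast 3 compares time point 3 against 4-5, and contrast 4 compares
#' time points 4 and 5. Each row sums to zero; the rows are not mutually
#' orthogonal (rows 2 and 3 overlap, their dot product is 4), which is why
#' the design columns are derived through the generalized inverse rather
#' than by simple transposition.
#'
#' @return 4 x 5 numeric matrix, rows `contrast1..contrast4`, columns
#'   `tp1..tp5`.
#' @export
query_contrasts <- function() {
  w <- rbind(c(-1,  1, 0,  0,  0),
             c(-1, -1, 2,  0,  0),
             c( 0,  0, 2, -1, -1),
             c( 0,  0, 0,  1, -1))
  dimnames(w) <- list(paste0("contrast", 1:4), paste0("tp", 1:5))
  w
}

#' Build the fixed-effects design matrix for the self-report regression
#'
#' Wide-format design for `rating ~ Condition * queryCount + (1 |
#' participant)`: an intercept, a condition indicator (information-only
#' coded 1, distrust 0, so a positive Condition coefficient means higher
#' ratings in the information-only condition), four time-point columns, and
#' the four interactions. With `coding = "contrasts"` the time-point
#' columns are derived from the planned-contrast weight matrix via its
#' Moore-Penrose generalized inverse, the standard mapping from hypothesis
#' weights to design columns, under which each fitted coefficient equals
#' its weighted combination of time-point means. With
#' `coding = "categorical"` plain treatment dummies for time points 2-5 are
#' used instead.
#'
#' @param records self-report table (`participant_id`, `condition`,
#'   `timepoint`, `item`, `rating`).
#' @param item which item to model (`"trust"`, `"distrust"` or `"use"`).
#' @param scheme contrast weight matrix (default [query_contrasts()]).
#' @param coding `"contrasts"` (planned contrasts) or `"categorical"`.
#' @return list with `X` (n x 10 design matrix with named columns), `y`
#'   (ratings), `participant` (integer index per row), `participant_id`
#'   (id per index), `coef_names`.
#' @export
build_design_matrix <- function(records, item = c("trust", "distrust", "use"),
                                scheme = query_contrasts(),
                                coding = c("contrasts", "categorical")) {
  item <- match.arg(item)
  coding <- match.arg(coding)
  stopifnot(is.matrix(scheme), ncol(scheme) == 5L)
  if (any(abs(rowSums(scheme)) > 1e-10))
    stop("every contrast weight row must sum to zero", call. = FALSE)
  r <- records[records$item == item, , drop = FALSE]
  if (nrow(r) == 0L) stop("no records for item '", item, "'", call. = FALSE)
  tp_count <- table(r$participant_id)
  bad <- names(tp_count)[tp_count != 5L]
  per <- tapply(r$timepoint, r$participant_id,
                function(t) length(unique(t)) == 5L && all(t %in% 1:5))
  bad <- union(bad, names(per)[!per])
  if (length(bad))
    stop("participants without exactly one rating at each of the 5 time ",
         "points: ", paste(utils::head(bad, 5L), collapse = ", "),
         call. = FALSE)

  if (coding == "contrasts") {
    xc <- MASS::ginv(scheme)            # 5 x 4: hypothesis -> design columns
    tp_cols <- xc[r$timepoint, , drop = FALSE]
    tp_names <- rownames(scheme)
  } else {
    tp_cols <- outer(r$timepoint, 2:5, `==`) + 0
    tp_names <- paste0("tp", 2:5)
  }
  cond <- as.numeric(r$condition == "information-only")
  X <- cbind(1, cond, tp_cols, cond * tp_cols)
  coef_names <- c("Intercept", "Condition", tp_names,
                  paste0("Condition:", tp_names))
  colnames(X) <- coef_names
  pid <- factor(r$participant_id)
  list(X = X, y = as.numeric(r$rating), participant = as.integer(pid),
       participant_id = levels(pid), coef_names = coef_names)
}

#' Specification of the Bayesian mixed regression
#'
#' @param item self-report item to model.
#' @param coding time-point coding, see [build_design_matrix()].
#' @param coef_scale SD of the Gaussian(0, scale) priors on all fixed
#'   effects (default 5, weakly informative on a 1-7 scale).
#' @param sd_scale scale of the half-Gaussian priors on the
#'   random-intercept SD and the residual SD (default 5).
#' @param chains,draws,tune,seed MCMC settings as in [sdt_model_spec()].
#' @return an object of class `regression_spec`.
#' @export
regression_spec <- function(item = c("trust", "distrust", "use"),
                            coding = c("contrasts", "categorical"),
                            coef_scale = 5, sd_scale = 5,
                            chains = 4L, draws = 10000L, tune = 2000L,
                            seed = NULL) {
  item <- match.arg(item)
  coding <- match.arg(coding)
  stopifnot(coef_scale > 0, sd_scale > 0, chains >= 1, draws >= 2, tune >= 0)
  if (tune >= draws)
    stop("`tune` must be smaller than `draws`", call. = FALSE)
  structure(list(item = item, coding = coding, coef_scale = coef_scale,
                 sd_scale = sd_scale, chains = as.integer(chains),
                 draws = as.integer(draws), tune = as.integer(tune),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "regression_spec")
}

# Gaussian mixed model with a random intercept per participant. The SD
# priors are truncated below at 1e-3 so that degenerate (constant-response)
# inputs remain fittable.
selfreport_jags_model <- function() {
"model {
  for (n in 1:N) {
    mu[n] <- inprod(X[n, ], beta) + u[pid[n]]
    y[n] ~ dnorm(mu[n], tauE)
  }
  for (j in 1:P) { beta[j] ~ dnorm(0, pow(coefScale, -2)) }
  for (i in 1:I) { u[i] ~ dnorm(0, tauU) }
  sigmaE ~ dnorm(0, pow(sdScale, -2)) T(1.0E-3, )
  sigmaU ~ dnorm(0, pow(sdScale, -2)) T(1.0E-3, )
  tauE <- pow(sigmaE, -2)
  tauU <- pow(sigmaU, -2)
}"
}

#' Fit the Bayesian mixed regression of repeated self-reports
#'
#' Gaussian linear mixed model `rating ~ Condition * queryCount +
#' (1 | participant)` fitted by MCMC (JAGS), with the time-point factor
#' entered through planned contrasts (default) or plain treatment dummies.
#' A coefficient is read as supported when its 95% credible interval
#' excludes zero.
#'
#' @param records self-report table.
#' @param spec a [regression_spec()].
#' @param scheme contrast weight matrix (default [query_contrasts()]).
#' @return object of class `selfreport_fit`: `samples` (coda draws of the
#'   10 coefficients plus `sigma_participant` and `sigma_residual`),
#'   `coef_names`, `diagnostics`, `status`, `spec`.
#' @export
fit_mixed_regression <- function(records, spec = regression_spec(),
                                 scheme = query_contrasts()) {
  stopifnot(inherits(spec, "regression_spec"))
  des <- build_design_matrix(records, item = spec$item, scheme = scheme,
                             coding = spec$coding)
  if (length(unique(records$condition)) < 2L ||
      min(table(unique(records[c("participant_id", "condition")])$condition)) < 2L)
    stop("at least 2 participants per condition are required", call. = FALSE)

  data <- list(N = length(des$y), P = ncol(des$X), I = max(des$participant),
               X = des$X, y = des$y, pid = des$participant,
               coefScale = spec$coef_scale, sdScale = spec$sd_scale)
  seed <- if (is.null(spec$seed)) sample.int(2^31 - 2, 1L) else spec$seed
  ls_beta <- tryCatch(as.numeric(stats::lm.fit(des$X, des$y)$coefficients),
                      error = function(e) rep(0, ncol(des$X)))
  ls_beta[!is.finite(ls_beta)] <- 0
  inits <- lapply(seq_len(spec$chains), function(ch)
    list(beta = ls_beta, u = rep(0, max(des$participant)),
         sigmaE = max(stats::sd(des$y), 0.01), sigmaU = 0.5,
         .RNG.name = "base::Mersenne-Twister",
         .RNG.seed = (seed + ch) %% (2^31 - 1)))

  n_adapt <- min(1000L, spec$tune)
  model <- rjags::jags.model(textConnection(selfreport_jags_model()),
                             data = data, inits = inits,
                             n.chains = spec$chains, n.adapt = n_adapt,
                             quiet = TRUE)
  if (spec$tune > n_adapt)
    stats::update(model, n.iter = spec$tune - n_adapt, progress.bar = "none")
  samples <- rjags::coda.samples(model, c("beta", "sigmaE", "sigmaU"),
                                 n.iter = spec$draws - spec$tune,
                                 progress.bar = "none")

  pars <- c(sprintf("beta[%d]", seq_along(des$coef_names)),
            "sigmaE", "sigmaU")
  labels <- c(des$coef_names, "sigma_residual", "sigma_participant")
  diagnostics <- data.frame(
    parameter = labels,
    rhat = vapply(pars, function(p)
      split_rhat(sapply(samples, function(ch) as.numeric(ch[, p]))),
      numeric(1)),
    ess = vapply(pars, function(p)
      as.numeric(coda::effectiveSize(samples[, p, drop = FALSE])),
      numeric(1)),
    row.names = NULL)
  status <- if (any(diagnostics$rhat > 1.01, na.rm = TRUE)) "nonconverged"
            else "ok"
  if (status == "nonconverged")
    warning("split R-hat exceeds 1.01 for at least one coefficient; ",
            "inspect `diagnostics`", call. = FALSE)

  structure(list(samples = samples, coef_names = des$coef_names,
                 participant_id = des$participant_id,
                 diagnostics = diagnostics, status = status, spec = spec),
            class = "selfreport_fit")
}

#' @export
print.selfreport_fit <- function(x, ...) {
  cat("Bayesian mixed regression of self-reported", x$spec$item,
      paste0("(", x$status, ")\n"))
  print(summarize_coefficients(x), row.names = FALSE, digits = 3)
  invisible(x)
}

#' Coefficient summary table of a self-report regression
#'
#' Posterior mean (Estimate), posterior SD (Est.Error) and equal-tailed 95%
#' credible interval per coefficient, in the fixed order Intercept,
#' Condition, the four time-point terms, their four interactions, then the
#' two variance components.
#'
#' @param fit a `selfreport_fit`.
#' @param prob credible-interval mass (default 0.95).
#' @return data frame with columns `coefficient`, `Estimate`, `Est.Error`,
#'   `l-95% CI`, `u-95% CI`.
#' @export
summarize_coefficients <- function(fit, prob = 0.95) {
  stopifnot(inherits(fit, "selfreport_fit"))
  pars <- c(sprintf("beta[%d]", seq_along(fit$coef_names)),
            "sigmaU", "sigmaE")
  labels <- c(fit$coef_names, "sd(Intercept participant)", "sigma")
  alpha <- (1 - prob) / 2
  rows <- lapply(pars, function(p) {
    dr <- do.call(c, lapply(fit$samples, function(ch) as.numeric(ch[, p])))
    data.frame(Estimate = mean(dr), Est.Error = stats::sd(dr),
               lower = unname(stats::quantile(dr, alpha)),
               upper = unname(stats::quantile(dr, 1 - alpha)))
  })
  out <- cbind(coefficient = labels, do.call(rbind, rows))
  names(out)[4:5] <- c(sprintf("l-%g%% CI", 100 * prob),
                       sprintf("u-%g%% CI", 100 * prob))
  rownames(out) <- NULL
  out
}
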