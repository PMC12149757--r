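# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. seed = NULL uses the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic per-stage seed derivation: stage k of master seed s gets
# (s * 48271 + k) mod (2^31 - 1), a Lehmer-style step keeping values in
# 32-bit integer range. Stages can thus be re-run in isolation.
stage_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer(((as.numeric(seed) %% 2147483647) * 48271 + k) %% 2147483647)
}

#' Split R-hat convergence diagnostic
#'
#' Potential scale reduction factor computed after splitting each chain in
#' half, so within-chain trends are detected as well as between-chain
#' disagreement.
#'
#' @param draws numeric matrix, iterations x chains (or a vector for a
#'   single chain).
#' @return scalar split R-hat; values near 1 indicate convergence.
#' @keywords internal
split_rhat <- function(draws) {
  m <- as.matrix(draws)
  n <- nrow(m)
  if (n < 4L) return(NA_real_)
  half <- floor(n / 2)
  sp <- cbind(m[seq_len(half), , drop = FALSE],
              m[seq.int(n - half + 1L, n), , drop = FALSE])
  w <- mean(apply(sp, 2L, stats::var))
  if (w == 0) return(1)
  b <- half * stats::var(colMeans(sp))
  sqrt(((half - 1) / half * w + b / half) / w)
}

# format a proportion as a percentage with 2 decimals (table convention)
pct <- function(x) round(100 * x, 2)
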