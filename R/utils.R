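#' Derive a stage-specific seed from a master seed
#'
#' All randomness in the package flows from a single master seed; each
#' stochastic stage derives its own sub-seed so that stages can be re-run
#' independently without disturbing one another. The derivation is a small
#' deterministic hash of the stage name folded into the master seed, kept
#' below 2^31 so it is a valid R integer.
#'
#' @param seed master integer seed.
#' @param stage character stage name (e.g. "connectome", "kmeans").
#' @param index optional integer for per-item seeds (e.g. subject index).
#' @return an integer seed.
#' @export
derive_seed <- function(seed, stage, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  val <- (as.numeric(seed) * 48271 + h * 1009 + as.numeric(index) * 7919) %%
    2147483647
  as.integer(val)
}

# Run an expression under a local RNG seed without touching global state.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Abbreviated all.equal for internal tolerance checks.
near <- function(a, b, tol = 1e-9) {
  abs(a - b) <= tol * max(1, abs(a), abs(b))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
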