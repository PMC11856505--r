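# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stage-specific sub-seed from a master seed
#'
#' Every stochastic stage of the pipeline consumes its own sub-seed so that
#' changing one stage's randomness leaves the others untouched. The map is a
#' fixed affine congruential step kept below 2^31.
#'
#' @param seed master integer seed.
#' @param stage integer stage index (any small integer).
#' @return an integer seed in \[1, 2147483562\].
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(stage))
  as.integer((abs(as.numeric(seed)) * 48271 + as.numeric(stage) * 16807) %%
               2147483562) + 1L
}

# truncated normal draws via inverse CDF (exact, vectorized, seed-stable)
rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

# rank-based fingerprint of a training frame; stable across sessions
data_fingerprint <- function(df) {
  digest::digest(lapply(df, function(col) {
    if (is.numeric(col)) round(col, 10) else as.character(col)
  }), algo = "xxhash64")
}

stop_named <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}
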