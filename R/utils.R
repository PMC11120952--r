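# Internal helpers shared across modules.

# Derive a stage-specific RNG seed from a user seed so that independent
# simulation stages do not share RNG streams. Kept inside 32-bit range.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  offsets <- c(
    annotation = 11L, truth = 23L, caller = 37L, phenotype = 53L,
    permutation = 71L, pipeline = 97L
  )
  off <- offsets[[stage]]
  as.integer((as.numeric(seed) * 1009 + off * 9973) %% 2147483647)
}

# Round-half-down integer rounding: 2768.5 -> 2768. Used for per-chromosome
# mean reporting.
round_half_down <- function(x) {
  as.integer(ceiling(x - 0.5))
}

# Lower-median: standard median but .5 values floored, so consensus
# coordinates stay integral and deterministic.
median_lower <- function(x) {
  as.integer(floor(stats::median(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
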