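# Seed plumbing.  All randomness flows through R's global RNG; top-level
# entry points accept a seed, and replicate streams are derived from a master
# seed by a counter so that sweeps are reproducible and loggable.

#' Derive a per-replicate seed from a master seed
#'
#' A documented counter-based derivation: replicate \code{i} of a run seeded
#' with \code{master} uses \code{(master + i * 1000003) mod (2^31 - 2) + 1}.
#' The multiplier is prime, so consecutive counters give well-separated seeds,
#' every derived seed is a positive 32-bit integer, and any replicate can be
#' re-run in isolation from its logged seed.
#'
#' @param master Master seed (integer).
#' @param counter Replicate counter (non-negative integer, vectorised).
#' @return Integer seed(s) in \code{[1, 2^31 - 2]}.
#' @examples
#' derive_seed(42, 0:3)
#' @export
derive_seed <- function(master, counter) {
  stopifnot(is.numeric(master), length(master) == 1L, is.numeric(counter))
  mod <- 2147483646
  as.integer((as.numeric(master) + as.numeric(counter) * 1000003) %% mod + 1)
}

# Seed the global RNG if a seed is supplied (NULL/NA leaves the stream alone).
set_seed_if_given <- function(seed) {
  if (!is.null(seed) && length(seed) == 1L && !is.na(seed)) {
    set.seed(as.integer(seed))
  }
  invisible(NULL)
}
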