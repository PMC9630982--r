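# Portable pseudo-random number generator for the model generator.
#
# Lehmer / Park-Miller multiplicative congruential generator:
#   state <- (state * 48271) %% (2^31 - 1)
# All arithmetic is exact in IEEE doubles (products < 2^47), so the stream
# is identical on every platform and independent of R's global RNG state.

LEHMER_M <- 2147483647  # 2^31 - 1
LEHMER_A <- 48271

new_rng <- function(seed) {
  stopifnot(is_finite_number(seed))
  seed <- floor(abs(seed)) %% LEHMER_M
  if (seed == 0) seed <- 1
  env <- new.env(parent = emptyenv())
  env$state <- seed
  env
}

rng_next <- function(rng) {
  rng$state <- (rng$state * LEHMER_A) %% LEHMER_M
  rng$state
}

# Uniform on (0, 1).
rng_unif <- function(rng, min = 0, max = 1) {
  min + (max - min) * (rng_next(rng) / LEHMER_M)
}

# Integer in [lo, hi].
rng_int <- function(rng, lo, hi) {
  lo + (rng_next(rng) %% (hi - lo + 1))
}

# Log-uniform over [lo, hi].
rng_logunif <- function(rng, lo, hi) {
  exp(rng_unif(rng, log(lo), log(hi)))
}

rng_bool <- function(rng, p = 0.5) rng_unif(rng) < p

rng_pick <- function(rng, xs) xs[[rng_int(rng, 1, length(xs))]]
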