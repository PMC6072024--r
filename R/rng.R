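# Counter-based random streams.
#
# Network builds, synapse placement and Poisson input generation must give
# identical results regardless of iteration order, chunking, or how cells are
# partitioned across logical ranks.  Ordinary sequential generators cannot do
# that, so every random draw here is a pure function of a small integer key
# (seed, stream ids, counter).  The generator is a MurmurHash3-style 32-bit
# avalanche mix applied to the key; two mixed words are combined into one
# 53-bit uniform deviate.  All 32-bit arithmetic is done exactly on doubles
# (products split into 16-bit halves stay below 2^49 < 2^53).

.u32 <- function(x) x %% 4294967296

# unsigned-double <-> signed-int views for the bitwXor round trips
.u32_to_int <- function(x) as.integer(x - (x >= 2147483648) * 4294967296)
.int_to_u32 <- function(i) {
  x <- as.double(i)
  x + (x < 0) * 4294967296
}

.xor32 <- function(a, b) .int_to_u32(bitwXor(.u32_to_int(a), .u32_to_int(b)))

.shr32 <- function(a, n) floor(a / 2^n)

.mul32 <- function(a, b) {
  a_hi <- floor(a / 65536)
  a_lo <- a - a_hi * 65536
  (((a_hi * b) %% 65536) * 65536 + a_lo * b) %% 4294967296
}

# MurmurHash3 fmix32 finalizer: full avalanche on a 32-bit word
.fmix32 <- function(h) {
  h <- .xor32(h, .shr32(h, 16))
  h <- .mul32(h, 2246822507)
  h <- .xor32(h, .shr32(h, 13))
  h <- .mul32(h, 3266489909)
  .xor32(h, .shr32(h, 16))
}

.mix_key <- function(h, k) {
  .fmix32(.xor32(.mul32(h, 2654435761), .u32(k)))
}

#' Deterministic uniform deviates from a counter-based stream
#'
#' Returns uniforms in (0, 1) that are a pure function of the integer key
#' `(seed, k1, k2, k3, counter)`.  All arguments are vectorized with
#' recycling.  Identical keys always give identical deviates, so results do
#' not depend on the order in which keys are evaluated, on chunking, or on
#' the number of logical ranks a simulation is split over.
#'
#' @param seed master seed (non-negative integer).
#' @param k1,k2,k3 stream identifiers, e.g. `(edge_type_id, source_gid,
#'   target_gid)` for connectivity draws or `(gid, 0, 0)` for per-cell
#'   streams.
#' @param counter draw index within the stream; increment it to obtain a
#'   sequence of independent deviates from one stream.
#' @return numeric vector of deviates in the open interval (0, 1).
#' @examples
#' rng_uniform(1, 10, 2, 3, counter = 0:4)
#' @export
rng_uniform <- function(seed, k1 = 0, k2 = 0, k3 = 0, counter = 0) {
  n <- max(length(seed), length(k1), length(k2), length(k3), length(counter))
  h <- .fmix32(.u32(rep_len(as.double(seed), n) + 2654435769))
  h <- .mix_key(h, rep_len(as.double(k1), n))
  h <- .mix_key(h, rep_len(as.double(k2), n))
  h <- .mix_key(h, rep_len(as.double(k3), n))
  h1 <- .mix_key(h, rep_len(as.double(counter), n))
  h2 <- .fmix32(.xor32(h1, 2654435769))
  (floor(h1 / 64) * 134217728 + floor(h2 / 32) + 0.5) / 9007199254740992
}

#' Deterministic uniform integers from a counter-based stream
#'
#' @inheritParams rng_uniform
#' @param lo,hi inclusive integer bounds, `lo <= hi`.
#' @return integer vector with values in `[lo, hi]`.
#' @export
rng_integer <- function(lo, hi, seed, k1 = 0, k2 = 0, k3 = 0, counter = 0) {
  stopifnot(all(lo <= hi))
  u <- rng_uniform(seed, k1, k2, k3, counter)
  as.integer(lo + floor(u * (hi - lo + 1)))
}

# Stable 32-bit hash of a string, used to namespace per-network streams
.hash_string <- function(s) {
  vapply(s, function(one) {
    b <- as.double(utf8ToInt(one))
    h <- 2166136261
    for (k in b) h <- .mul32(.xor32(h, k), 16777619)
    h
  }, numeric(1), USE.NAMES = FALSE)
}

# Fixed offsets separating the independent uses of the master seed
.SEED_BUILD <- 0
.SEED_PLACEMENT <- 1
.SEED_POISSON <- 2

.derive_seed <- function(seed, purpose) .u32(.fmix32(.u32(seed + 1)) + purpose)
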