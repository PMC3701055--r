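#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

# Deterministic 31-bit seed derived from a base seed and a string key.
# Used to give every per-target / per-replicate task its own RNG stream so
# results do not depend on worker scheduling. Plain polynomial hash; the
# modulus is a prime below 2^31 so the result is always a valid R seed.
derive_seed <- function(seed, key) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  m <- 2147483629
  h <- 17
  for (code in utf8ToInt(as.character(key))) {
    h <- (h * 31 + code) %% m
  }
  as.integer((h + (abs(seed) %% m) * 10007) %% m)
}

# mclapply wrapper: `workers` is a user-facing knob that must never change
# results; determinism comes from per-task seeds, not from here.
apply_parallel <- function(X, FUN, workers = 1L) {
  workers <- max(1L, as.integer(workers))
  if (workers == 1L || .Platform$OS.type == "windows") {
    lapply(X, FUN)
  } else {
    parallel::mclapply(X, FUN, mc.cores = workers)
  }
}

# Canonical unordered-pair key (lexicographically smaller ID first).
pair_key <- function(a, b) {
  swap <- b < a
  lo <- ifelse(swap, b, a)
  hi <- ifelse(swap, a, b)
  paste(lo, hi, sep = "\r")
}
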