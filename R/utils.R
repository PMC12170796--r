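# Internal helpers shared across modules.

#' Clip values to a closed interval
#' @noRd
clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Round half away from zero (0.5 -> 1, -0.5 -> -1), unlike base R's
# round-half-even.
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# Deterministic 31-bit hash of a character key; used to derive per-dyad
# RNG substreams from one study seed so each dyad's data are reproducible
# independently of simulation order.
key_hash <- function(key) {
  codes <- utf8ToInt(key)
  h <- 5381
  for (c in codes) h <- (h * 33 + c) %% 2147483647L
  as.integer(h)
}

# Derive a child seed from a parent seed and a string key (< 2^31).
substream_seed <- function(seed, key) {
  as.integer((as.numeric(seed) %% 2147483647 + key_hash(key)) %% 2147483647)
}

# Evaluate `expr` under a seeded RNG substream, restoring the caller's
# RNG state afterwards.
with_substream <- function(seed, key, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, key))
  force(expr)
}

# Stable key for the signal collection.
signal_key <- function(participant, round, modality) {
  paste(participant, round, modality, sep = "|")
}

# Cheap content hash (hex) for manifests; not cryptographic.
content_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  codes <- utf8ToInt(s)
  h1 <- 5381; h2 <- 52711
  for (c in codes) {
    h1 <- (h1 * 33 + c) %% 2147483647
    h2 <- (h2 * 31 + c) %% 2147483629
  }
  sprintf("%08x%08x", as.integer(h1), as.integer(h2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
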