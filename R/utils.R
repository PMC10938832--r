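# Internal helpers: seeded RNG plumbing and integer hashing.

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
# The caller's RNG state is restored afterwards.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(expr)
}

# Deterministic derived seed: combine a master seed with one or more integer
# tags, staying inside 32-bit range (exact in double arithmetic).
derive_seed <- function(seed, ...) {
  tags <- c(...)
  h <- as.double(seed) %% 2147483647
  for (t in tags) {
    h <- (h * 69069 + as.double(t) + 1) %% 2147483647
  }
  as.integer(h)
}

# Deterministic 31-bit hash of a character string (UTF-8 bytes, Horner).
hash_string <- function(x) {
  b <- as.integer(charToRaw(enc2utf8(x)))
  h <- 7
  for (v in b) h <- (h * 131 + v) %% 2147483647
  as.integer(h)
}

# Deterministic 31-bit hash of an integer vector (order-sensitive).
hash_ints <- function(v) {
  h <- 17
  for (x in v) h <- (h * 1000003 + (as.double(x) %% 2147483647)) %% 2147483647
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ctx <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
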