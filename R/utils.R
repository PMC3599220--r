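# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched.  seed = NULL runs `code` on the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) stats::runif(1L)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

# Round-half-up to integer (chart cells): round() would round half to even.
round_half_up <- function(x) floor(x + 0.5)

# Cheap deterministic provenance hash (polynomial hash of the serialized
# object, mod 2^31 - 1), printed as 8 hex digits.
object_hash <- function(x) {
  raw <- as.integer(serialize(x, NULL, version = 2L))
  h <- 0
  m <- 2147483647
  for (chunk in split(raw, ceiling(seq_along(raw) / 4096L))) {
    for (b in chunk) h <- (h * 31 + b) %% m
  }
  sprintf("%08x", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
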