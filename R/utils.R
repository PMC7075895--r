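# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG stream afterwards. Keeps every stochastic stage
# reproducible without clobbering user seeds.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a master seed and a stream label; keeps derived
# seeds inside 32-bit integer range.
derive_seed <- function(seed, ...) {
  lab <- paste(c(seed, ...), collapse = "/")
  # polynomial rolling hash over the label bytes, mod a prime < 2^31
  bytes <- as.integer(charToRaw(lab))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483587
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

# dB of a linear amplitude ratio
amp_db <- function(x, ref = 1) 20 * log10(pmax(x, .Machine$double.xmin) / ref)
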