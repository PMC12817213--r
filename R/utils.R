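# internal helpers shared across modules

# Run code with a temporary RNG seed, restoring the caller's RNG state.
local_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

# Derive a reproducible 31-bit sub-seed from a base seed and stream indices.
derive_seed <- function(seed, ...) {
  idx <- c(seed, ...)
  h <- 0
  for (v in idx) h <- (h * 48271 + as.double(v) + 1) %% 2147483629
  as.integer(h) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
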