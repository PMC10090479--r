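# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state. Generators take an explicit seed so that every synthetic
# object is reproducible bit-for-bit.
local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
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
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic child seed derived from a parent seed and a stream label,
# kept below 2^31 - 1.
child_seed <- function(seed, label) {
  if (is.null(seed)) return(NULL)
  bytes <- utf8ToInt(as.character(label))
  h <- as.double(seed) %% 2147483647
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

rms <- function(x) sqrt(mean(x^2))

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("`%s` must be a positive finite scalar", name), call. = FALSE)
  }
  invisible(x)
}
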