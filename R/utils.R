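# Shared helpers: scoped RNG, reflect padding, seed fan-out.

# Temporarily reseed the global RNG; pair with restore_seed() so library
# code never disturbs the caller's random stream.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

# Derive a named substream seed from a base seed; keeps results reproducible
# when components are re-seeded independently. Stays below 2^31.
derive_seed <- function(seed, stream, index = 0L) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 2654435 + h * 97 + index) %% 2147483647)
}

# Reflect-pad an (H, W, C) array (or matrix) on the bottom/right.
reflect_pad <- function(x, bottom, right) {
  if (bottom == 0L && right == 0L) return(x)
  m <- length(dim(x)) == 2L
  if (m) x <- array(x, c(dim(x), 1L))
  d <- dim(x)
  if (bottom >= d[1L] || right >= d[2L])
    stop("reflect padding wider than the image")
  ri <- c(seq_len(d[1L]), d[1L] - seq_len(bottom))
  ci <- c(seq_len(d[2L]), d[2L] - seq_len(right))
  out <- x[ri, ci, , drop = FALSE]
  if (m) out <- out[, , 1L]
  out
}

# Next multiple of `m` at or above `n`.
align_up <- function(n, m) as.integer(ceiling(n / m) * m)
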