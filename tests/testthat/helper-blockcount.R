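# Shared fixtures and independent brute-force oracles. Oracles are written
# as plain double loops so they share no code with the implementation.

# Density oracle: per-dot truncated Gaussian accumulated cell by cell.
bf_density <- function(dot_grid, sigma, r = ceiling(3 * sigma)) {
  nr <- nrow(dot_grid); nc <- ncol(dot_grid)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (dot_grid[i, j] == 0) next
    w <- 0
    for (y in max(1, i - r):min(nr, i + r))
      for (x in max(1, j - r):min(nc, j + r))
        w <- w + exp(-((y - i)^2 + (x - j)^2) / (2 * sigma^2))
    for (y in max(1, i - r):min(nr, i + r))
      for (x in max(1, j - r):min(nc, j + r))
        out[y, x] <- out[y, x] +
          dot_grid[i, j] * exp(-((y - i)^2 + (x - j)^2) / (2 * sigma^2)) / w
  }
  out
}

# Window-sum oracle for the count map.
bf_count_map <- function(density, block, stride) {
  nr <- nrow(density); nc <- ncol(density)
  gr <- (nr - block) %/% stride + 1L
  gc <- (nc - block) %/% stride + 1L
  out <- matrix(0, gr, gc)
  for (i in seq_len(gr)) for (j in seq_len(gc)) {
    s <- 0
    for (y in seq_len(block)) for (x in seq_len(block))
      s <- s + density[(i - 1L) * stride + y, (j - 1L) * stride + x]
    out[i, j] <- s
  }
  out
}

# Accumulate-then-divide oracle for deredundancy: per-pixel loop over all
# patches covering it.
bf_deredundancy <- function(values, block, stride, rows, cols) {
  gr <- nrow(values); gc <- ncol(values)
  out <- matrix(0, rows, cols)
  for (y in seq_len(rows)) for (x in seq_len(cols)) {
    acc <- 0; times <- 0L
    for (i in seq_len(gr)) for (j in seq_len(gc)) {
      y0 <- (i - 1L) * stride + 1L; x0 <- (j - 1L) * stride + 1L
      if (y >= y0 && y <= y0 + block - 1L && x >= x0 && x <= x0 + block - 1L) {
        acc <- acc + values[i, j] / (block * block)
        times <- times + 1L
      }
    }
    if (times > 0L) out[y, x] <- acc / times
  }
  out
}

# A small annotated scene for fast tests.
tiny_scene <- function(seed = 1L, size = 128L, n = 12L, margin = NULL) {
  render_scene(scene_spec(size = size, n_plants = n, plant_radius = c(4, 8),
                          border_margin = margin, seed = seed))
}

# Heavy trained-model fixture shared between acceptance checks; trained at
# most once per test session.
.bench_env <- new.env(parent = emptyenv())
cached_benchmark <- function() {
  if (is.null(.bench_env$bench))
    .bench_env$bench <- synthetic_benchmark(seed = 1L, verbose = FALSE)
  .bench_env$bench
}
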