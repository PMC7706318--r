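#' Count-interval quantizer specification
#'
#' Parameters of the log-space quantization that turns per-patch counts into
#' count-interval classes. Counts `n` in `(0, e^q)` map to class 1, zero maps
#' to the reserved class 0, and counts above `e^q` fall into geometric
#' intervals of width `s` in log space:
#' `class(n) = max(floor((log n - q)/s) + 2, 1)`, capped at `c_max`.
#'
#' @param s Quantization step in log space (natural logarithm). Default 0.1.
#' @param q Start of the log space; counts below `e^q` share class 1.
#'   Default -2.
#' @param c_max Largest class index (integer, >= 2). Class indices therefore
#'   run over `0:c_max` and there are `c_max + 1` classes.
#' @return An object of class `"bc_quantizer"`.
#' @seealso [quantize_count()], [class_count_value()]
#' @export
quantizer_spec <- function(s = 0.1, q = -2, c_max = 50L) {
  if (!is.numeric(s) || length(s) != 1L || s <= 0)
    stop("'s' must be a single positive number")
  if (!is.numeric(q) || length(q) != 1L)
    stop("'q' must be a single number")
  c_max <- as.integer(c_max)
  if (is.na(c_max) || c_max < 2L)
    stop("'c_max' must be an integer >= 2")
  structure(list(s = s, q = q, c_max = c_max), class = "bc_quantizer")
}

#' @export
print.bc_quantizer <- function(x, ...) {
  cat(sprintf("Log-space count quantizer: s = %g, q = %g, c_max = %d (%d classes)\n",
              x$s, x$q, x$c_max, x$c_max + 1L))
  cat(sprintf("  class 0: n == 0; class 1: 0 < n < e^q = %.5g; class c >= 2: n in [e^{q+(c-2)s}, e^{q+(c-1)s})\n",
              exp(x$q)))
  invisible(x)
}

#' Patch grid over an image
#'
#' Describes the layout of square `block x block` patches placed at offsets
#' `0, stride, 2*stride, ...` (row-major) over an image. Only patches fully
#' contained in the image are kept; no padding is applied.
#'
#' @param rows,cols Image dimensions in pixels.
#' @param block Patch side in pixels.
#' @param stride Patch stride in pixels; `stride <= block` gives overlapping
#'   (redundant) patches.
#' @return An object of class `"bc_grid"` with fields `block`, `stride`,
#'   `n_rows`, `n_cols` (patch grid dimensions), `image_dim`, and
#'   `pixels_per_patch`.
#' @export
patch_grid <- function(rows, cols, block = 32L, stride = 8L) {
  block <- as.integer(block); stride <- as.integer(stride)
  if (stride < 1L || block < stride)
    stop("need block >= stride >= 1")
  if (rows < block || cols < block)
    stop(sprintf("image (%d x %d) smaller than block; need at least %d x %d",
                 rows, cols, block, block))
  structure(list(
    block = block, stride = stride,
    n_rows = (as.integer(rows) - block) %/% stride + 1L,
    n_cols = (as.integer(cols) - block) %/% stride + 1L,
    image_dim = c(as.integer(rows), as.integer(cols)),
    pixels_per_patch = block * block
  ), class = "bc_grid")
}

#' Per-pixel patch coverage of a grid
#'
#' Returns the integer matrix `T(y, x)`: how many patches of the grid cover
#' each pixel of the image. Pixels on the right/bottom margin beyond the last
#' full patch have coverage 0. Coverage is separable, i.e. the outer product
#' of the 1-D coverage profiles along rows and columns.
#'
#' @param grid A [patch_grid()].
#' @return Integer matrix of dimension `grid$image_dim`.
#' @export
coverage_map <- function(grid) {
  cov1d <- function(n_px, n_patch) {
    v <- integer(n_px)
    for (i in seq_len(n_patch)) {
      a <- (i - 1L) * grid$stride + 1L
      v[a:(a + grid$block - 1L)] <- v[a:(a + grid$block - 1L)] + 1L
    }
    v
  }
  outer(cov1d(grid$image_dim[1L], grid$n_rows),
        cov1d(grid$image_dim[2L], grid$n_cols))
}

#' Rasterize dot annotations onto a pixel grid
#'
#' Each annotated point (x = column, y = row; 0-based, origin top-left) is
#' scaled by `scale`, rounded half-up to the nearest pixel, and accumulated:
#' several points landing on the same pixel keep their multiplicity so the
#' grid total always equals the number of points. Points that round outside
#' the grid are clamped to the nearest border pixel with a warning.
#'
#' @param points Two-column matrix or data.frame of (x, y) coordinates, or
#'   NULL / zero-row for an empty annotation.
#' @param shape `c(rows, cols)` of the output grid.
#' @param scale Coordinate scaling ratio (e.g. 0.25 when the image was
#'   downsampled to quarter resolution).
#' @return A `rows x cols` matrix of nonnegative integers summing to
#'   `nrow(points)`.
#' @export
rasterize_dots <- function(points, shape, scale = 1) {
  if (length(shape) != 2L || any(shape < 1))
    stop("'shape' must be two positive integers")
  if (!is.numeric(scale) || scale <= 0)
    stop("'scale' must be positive")
  grid <- matrix(0, nrow = shape[1L], ncol = shape[2L])
  if (is.null(points) || NROW(points) == 0L)
    return(grid)
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  if (any(pts < 0)) stop("negative dot coordinates")
  # half-up rounding: deterministic, unlike round()'s round-half-to-even
  col <- floor(pts[, 1L] * scale + 0.5) + 1L
  row <- floor(pts[, 2L] * scale + 0.5) + 1L
  oob <- col < 1L | col > shape[2L] | row < 1L | row > shape[1L]
  if (any(oob)) {
    warning(sprintf("%d dot(s) rounded outside the grid; clamped to border", sum(oob)))
    col <- pmin(pmax(col, 1L), shape[2L])
    row <- pmin(pmax(row, 1L), shape[1L])
  }
  for (k in seq_along(row))
    grid[row[k], col[k]] <- grid[row[k], col[k]] + 1
  grid
}

#' Density map from a dot map
#'
#' Convolves the dot map with a truncated 2-D Gaussian kernel of standard
#' deviation `sigma`. The kernel of each dot is renormalized after truncation
#' and border clipping so that every dot contributes exactly unit mass:
#' the density map sums to the number of dots regardless of dot placement.
#'
#' @param dot_grid Matrix of nonnegative dot multiplicities
#'   (see [rasterize_dots()]).
#' @param sigma Gaussian standard deviation in pixels (> 0). Default 4.
#' @param truncation_radius Kernel support half-width in pixels; defaults to
#'   `ceiling(3 * sigma)` and must be at least `2 * sigma`.
#' @return Matrix of the same dimension as `dot_grid`; nonnegative, summing
#'   to `sum(dot_grid)` to within 1e-6.
#' @export
density_from_dots <- function(dot_grid, sigma = 4, truncation_radius = NULL) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("'sigma' must be a single positive number")
  if (is.null(truncation_radius)) truncation_radius <- ceiling(3 * sigma)
  if (truncation_radius < 2 * sigma)
    stop("'truncation_radius' must be >= 2 * sigma")
  dot_grid <- as.matrix(dot_grid)
  if (any(dot_grid < 0)) stop("dot grid must be nonnegative")
  r <- as.integer(truncation_radius)
  ax <- (-r):r
  g1 <- exp(-ax^2 / (2 * sigma^2))
  kern <- outer(g1, g1)                     # unnormalized; renormalized per dot
  nr <- nrow(dot_grid); nc <- ncol(dot_grid)
  dens <- matrix(0, nr, nc)
  nz <- which(dot_grid > 0, arr.ind = TRUE)
  for (k in seq_len(nrow(nz))) {
    i <- nz[k, 1L]; j <- nz[k, 2L]
    ri <- max(1L, i - r):min(nr, i + r)
    rj <- max(1L, j - r):min(nc, j + r)
    kw <- kern[ri - i + r + 1L, rj - j + r + 1L, drop = FALSE]
    dens[ri, rj] <- dens[ri, rj] + dot_grid[i, j] * kw / sum(kw)
  }
  dens
}

#' Count map by blockwise summation of a density map
#'
#' Sums the density map over every `block x block` window placed at offsets
#' `0, stride, 2*stride, ...`; only fully contained windows are emitted. With
#' `stride < block` patches overlap and the result is a redundant count map.
#'
#' @param density Density matrix (see [density_from_dots()]).
#' @param block,stride Patch side and stride in pixels (`block >= stride >= 1`).
#' @return An object of class `"bc_count_map"`: list with `values` (the
#'   `n_rows x n_cols` patch-count matrix) and `grid` (a [patch_grid()]).
#' @export
count_map_from_density <- function(density, block = 32L, stride = 8L) {
  density <- as.matrix(density)
  grid <- patch_grid(nrow(density), ncol(density), block, stride)
  # separable window sum: column-direction partial sums, then row direction
  cs <- rbind(0, apply(density, 2L, cumsum))
  r0 <- (seq_len(grid$n_rows) - 1L) * grid$stride
  rows_sum <- cs[r0 + grid$block + 1L, , drop = FALSE] - cs[r0 + 1L, , drop = FALSE]
  cs2 <- cbind(0, t(apply(rows_sum, 1L, cumsum)))
  c0 <- (seq_len(grid$n_cols) - 1L) * grid$stride
  vals <- cs2[, c0 + grid$block + 1L, drop = FALSE] - cs2[, c0 + 1L, drop = FALSE]
  new_count_map(vals, grid)
}

new_count_map <- function(values, grid) {
  structure(list(values = values, grid = grid), class = "bc_count_map")
}

#' @export
print.bc_count_map <- function(x, ...) {
  cat(sprintf("Count map: %d x %d patches (block %d, stride %d) over a %d x %d image; sum = %.4f\n",
              x$grid$n_rows, x$grid$n_cols, x$grid$block, x$grid$stride,
              x$grid$image_dim[1L], x$grid$image_dim[2L], sum(x$values)))
  invisible(x)
}

#' Quantize counts into count-interval classes
#'
#' Maps a nonnegative count to its count-interval class index under the
#' log-space quantizer: 0 for an exactly-zero count, otherwise
#' `min(max(floor((log n - q)/s) + 2, 1), c_max)` with the natural logarithm.
#' Vectorized over `n`.
#'
#' @param n Numeric vector of nonnegative counts.
#' @param spec A [quantizer_spec()].
#' @return Integer vector of class indices in `[0, c_max]`.
#' @export
quantize_count <- function(n, spec) {
  stopifnot(inherits(spec, "bc_quantizer"))
  if (any(n < 0)) stop("counts must be nonnegative")
  cls <- integer(length(n))
  pos <- n > 0
  cls[pos] <- as.integer(
    pmin(pmax(floor((log(n[pos]) - spec$q) / spec$s) + 2, 1), spec$c_max))
  cls
}

#' Representative count of a count-interval class
#'
#' Inverse quantization: class 0 decodes to 0; any other class decodes to the
#' midpoint of its count interval `[Nt(c), Nt(c+1))`, where `Nt(C) = 0` for
#' `C <= 1` and `exp(q + (C - 2) * s)` otherwise. Vectorized over `cls`.
#'
#' @param cls Integer vector of class indices in `[0, c_max]`.
#' @param spec A [quantizer_spec()].
#' @return Numeric vector of representative counts.
#' @export
class_count_value <- function(cls, spec) {
  stopifnot(inherits(spec, "bc_quantizer"))
  if (any(cls < 0 | cls > spec$c_max)) stop("class index out of [0, c_max]")
  nt <- function(cc) ifelse(cc <= 1, 0, exp(spec$q + (cc - 2) * spec$s))
  ifelse(cls == 0, 0, (nt(cls) + nt(cls + 1)) / 2)
}

#' Class map from a count map
#'
#' Applies [quantize_count()] elementwise; the patch grid and quantizer are
#' carried on the result.
#'
#' @param counts A [count_map_from_density()] result.
#' @param spec A [quantizer_spec()].
#' @return An object of class `"bc_class_map"`: list with integer matrix
#'   `values`, `grid`, and `spec`.
#' @export
class_map_from_count_map <- function(counts, spec) {
  stopifnot(inherits(counts, "bc_count_map"))
  v <- quantize_count(as.vector(counts$values), spec)
  structure(list(values = matrix(v, nrow(counts$values), ncol(counts$values)),
                 grid = counts$grid, spec = spec),
            class = "bc_class_map")
}

#' @export
print.bc_class_map <- function(x, ...) {
  cat(sprintf("Class map: %d x %d patches (block %d, stride %d), classes 0..%d\n",
              x$grid$n_rows, x$grid$n_cols, x$grid$block, x$grid$stride, x$spec$c_max))
  invisible(x)
}

#' Decode a class map back into a count map
#'
#' Applies [class_count_value()] elementwise (inverse quantization); the grid
#' is carried through.
#'
#' @param classes A [class_map_from_count_map()] result.
#' @return A `"bc_count_map"`.
#' @export
dequantize_class_map <- function(classes) {
  stopifnot(inherits(classes, "bc_class_map"))
  v <- class_count_value(as.vector(classes$values), classes$spec)
  new_count_map(matrix(v, nrow(classes$values), ncol(classes$values)), classes$grid)
}

#' Deredundancy: overlapping patch counts to a pixel count map
#'
#' Each patch spreads its count evenly over the `block^2` pixels it covers;
#' every pixel then averages the contributions of all patches covering it
#' (division by the coverage `T(y, x)`). Pixels covered by no patch (the
#' right/bottom margin when image dimensions do not align with the grid) are
#' set to 0. The sum of the result is the decoded image total.
#'
#' @param counts A `"bc_count_map"` on an overlapping (or any) patch grid.
#' @return Matrix at pixel resolution (`grid$image_dim`), with attribute
#'   `"total"` holding its sum.
#' @export
deredundancy <- function(counts) {
  stopifnot(inherits(counts, "bc_count_map"))
  g <- counts$grid
  if (g$n_rows < 1L || g$n_cols < 1L || length(counts$values) == 0L)
    stop("empty count map")
  acc <- matrix(0, g$image_dim[1L], g$image_dim[2L])
  per_px <- counts$values / g$pixels_per_patch
  for (i in seq_len(g$n_rows)) {
    ri <- ((i - 1L) * g$stride + 1L):((i - 1L) * g$stride + g$block)
    for (j in seq_len(g$n_cols)) {
      rj <- ((j - 1L) * g$stride + 1L):((j - 1L) * g$stride + g$block)
      acc[ri, rj] <- acc[ri, rj] + per_px[i, j]
    }
  }
  cov <- coverage_map(g)
  out <- matrix(0, g$image_dim[1L], g$image_dim[2L])
  covered <- cov > 0L
  out[covered] <- acc[covered] / cov[covered]
  attr(out, "total") <- sum(out)
  out
}

#' Total count of a pixel count map or non-overlapping count map
#'
#' Sums all cells. For a patch-level count map this is only a count of the
#' image when patches tile it without overlap (`stride == block`); calling it
#' on an overlapping count map is an error directing to [deredundancy()].
#'
#' @param map A pixel count matrix (from [deredundancy()]) or a
#'   `"bc_count_map"` with `stride == block`.
#' @return A single number.
#' @export
total_count <- function(map) {
  if (inherits(map, "bc_count_map")) {
    if (map$grid$stride != map$grid$block)
      stop("count map has overlapping patches; decode with deredundancy() before totaling")
    return(sum(map$values))
  }
  sum(map)
}
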