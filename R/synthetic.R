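#' Synthetic rice-scene specification
#'
#' Parameters of the seeded generator of paddy-like dotted scenes used to
#' exercise the whole pipeline without field data. Scenes emulate the
#' statistical structure of transplanted rice imagery: a greenish-brown
#' paddy background with water-glint speckle and a linear illumination
#' gradient, plants rendered as radial clusters of curved leaf strokes
#' centered on the annotated root dot, and jittered row-grid planting with
#' partial overlap.
#'
#' @param size `c(rows, cols)` in pixels (>= 64).
#' @param n_plants Single count or `c(min, max)` range sampled per scene.
#' @param plant_radius `c(min, max)` plant footprint radius in pixels.
#'   Default 10-38 px, i.e. 80-300 px native footprints at quarter
#'   resolution.
#' @param row_spacing Planting grid spacing in pixels; derived from `size`
#'   and `n_plants` when NULL.
#' @param illumination_gradient Amplitude (0-1) of the linear illumination
#'   ramp across the scene.
#' @param reflection_noise Amplitude (0-1) of water-glint speckle.
#' @param overlap_fraction 0-1; scales down the enforced minimum plant
#'   separation and scales up placement jitter, so neighboring plants
#'   increasingly overlap.
#' @param border_margin Minimum distance of plant centers from the image
#'   border in pixels; defaults to the maximum plant radius plus 2, so no
#'   plant is clipped. Redundant decoding conserves mass exactly only on
#'   the fully patch-covered interior, so codec-conservation studies use a
#'   deeper margin (>= block + stride extra).
#' @param seed Integer seed; scenes are fully seed-deterministic.
#' @return An object of class `"bc_scene_spec"`.
#' @export
scene_spec <- function(size = c(512L, 512L), n_plants = c(100L, 400L),
                       plant_radius = c(10, 38), row_spacing = NULL,
                       illumination_gradient = 0.25, reflection_noise = 0.15,
                       overlap_fraction = 0.2, border_margin = NULL, seed = 1L) {
  if (length(size) == 1L) size <- c(size, size)
  size <- as.integer(size)
  if (any(size < 64L)) stop("scene size must be at least 64 px")
  if (any(n_plants < 0)) stop("n_plants must be nonnegative")
  if (any(plant_radius <= 0)) stop("plant radii must be positive")
  if (is.null(border_margin)) border_margin <- ceiling(max(plant_radius)) + 2
  structure(list(size = size, n_plants = n_plants,
                 plant_radius = range(plant_radius), row_spacing = row_spacing,
                 illumination_gradient = illumination_gradient,
                 reflection_noise = reflection_noise,
                 overlap_fraction = overlap_fraction,
                 border_margin = border_margin,
                 seed = as.integer(seed)),
            class = "bc_scene_spec")
}

#' Scene presets
#'
#' `"tiny"` emits 256 x 256 scenes with 10-60 plants of 6-14 px radius, the
#' CPU-scale configuration used throughout the test-suite benchmarks.
#' `"field"` emits 1068 x 712 scenes (quarter resolution of a
#' 4272 x 2848 capture) with 182-1330 plants, mirroring the count range of
#' an in-field rice dataset.
#'
#' @param preset `"tiny"` or `"field"`.
#' @param seed Integer seed.
#' @return A [scene_spec()].
#' @export
scene_preset <- function(preset = c("tiny", "field"), seed = 1L) {
  preset <- match.arg(preset)
  switch(preset,
         tiny = scene_spec(size = c(256L, 256L), n_plants = c(10L, 60L),
                           plant_radius = c(6, 14), seed = seed),
         field = scene_spec(size = c(712L, 1068L), n_plants = c(182L, 1330L),
                                 plant_radius = c(10, 38), seed = seed))
}

# Alpha-blend a batch of points over the image in one pass. Points are
# blended against the pre-stroke background; on duplicate pixels the last
# point wins. One call per scene keeps this O(image) instead of copying the
# image array per stroke.
paint_pts <- function(img, rr, cc, colors, alpha) {
  d <- dim(img)
  keep <- rr >= 1L & rr <= d[1L] & cc >= 1L & cc <= d[2L]
  if (!any(keep)) return(img)
  idx <- rr[keep] + (cc[keep] - 1L) * d[1L]
  a <- alpha[keep]
  hw <- d[1L] * d[2L]
  for (ch in 1:3) {
    at <- idx + (ch - 1L) * hw
    img[at] <- (1 - a) * img[at] + a * colors[keep, ch]
  }
  img
}

place_plants <- function(spec, n) {
  H <- spec$size[1L]; W <- spec$size[2L]
  if (n == 0L) return(matrix(numeric(0), 0L, 2L))
  margin <- spec$border_margin
  if (H - 2 * margin < 1 || W - 2 * margin < 1)
    stop(sprintf(paste0("cannot place %d plants on a %d x %d scene with border ",
                        "margin %d; reduce plant_radius or border_margin"),
                 n, H, W, margin))
  s <- spec$row_spacing
  if (is.null(s)) s <- max(4, floor(sqrt((H - 2 * margin) * (W - 2 * margin) / n)))
  ys <- seq(margin, H - margin, by = s)
  xs <- seq(margin, W - margin, by = s)
  cells <- expand.grid(y = ys, x = xs)
  if (n > nrow(cells))
    stop(sprintf(paste0("cannot place %d plants on a %d x %d scene at spacing %d; ",
                        "reduce n_plants, row_spacing or plant_radius"),
                 n, H, W, s))
  pick <- cells[sample.int(nrow(cells), n), ]
  jit <- s * (0.25 + 0.5 * spec$overlap_fraction)
  min_sep <- (1 - spec$overlap_fraction) * s * 0.8
  pts <- matrix(0, n, 2L)            # columns (y, x), 1-based continuous
  for (i in seq_len(n)) {
    best <- NULL; best_d <- -Inf
    for (try in 1:15) {
      cand <- c(pick$y[i] + stats::runif(1, -jit, jit),
                pick$x[i] + stats::runif(1, -jit, jit))
      cand[1L] <- min(max(cand[1L], margin), H - margin)
      cand[2L] <- min(max(cand[2L], margin), W - margin)
      dmin <- if (i == 1L) Inf else
        sqrt(min((pts[seq_len(i - 1L), 1L] - cand[1L])^2 +
                 (pts[seq_len(i - 1L), 2L] - cand[2L])^2))
      if (dmin >= min_sep) { best <- cand; break }
      if (dmin > best_d) { best <- cand; best_d <- dmin }
    }
    pts[i, ] <- best
  }
  pts
}

#' Render one synthetic paddy scene
#'
#' Fully seed-deterministic: the same spec (including its seed) yields a
#' bitwise-identical image and annotation. The annotated dot of every plant
#' is the center of its stroke cluster, matching the root-dot annotation
#' convention.
#'
#' @param spec A [scene_spec()].
#' @return An object of class `"bc_scene"`: list with `image` (an
#'   `(H, W, 3)` array in `[0, 1]`), `annotation` (a [dot_annotation()] with
#'   0-based `(x, y)` points), and `spec`.
#' @export
render_scene <- function(spec) {
  stopifnot(inherits(spec, "bc_scene_spec"))
  old <- local_seed(spec$seed)
  on.exit(restore_seed(old), add = TRUE)
  H <- spec$size[1L]; W <- spec$size[2L]

  n <- if (length(spec$n_plants) == 2L)
    sample(spec$n_plants[1L]:spec$n_plants[2L], 1L) else as.integer(spec$n_plants)

  # paddy background: muddy water base + illumination ramp + glint speckle
  base <- c(0.40, 0.42, 0.30) * stats::runif(3, 0.9, 1.1)
  theta <- stats::runif(1, 0, 2 * pi)
  ramp <- outer(seq_len(H) / H - 0.5, rep(1, W)) * sin(theta) +
    outer(rep(1, H), seq_len(W) / W - 0.5) * cos(theta)
  shade <- 1 + spec$illumination_gradient * ramp / max(abs(ramp), 1e-9) * 0.9
  img <- array(0, c(H, W, 3L))
  for (ch in 1:3) img[, , ch] <- base[ch] * shade
  grain <- matrix(stats::rnorm(H * W, 0, 0.06), H, W) * spec$reflection_noise / 0.15
  for (ch in 1:3) img[, , ch] <- img[, , ch] + grain
  n_glint <- round(spec$reflection_noise * 0.004 * H * W)
  if (n_glint > 0L) {
    at <- sample.int(H * W, n_glint)
    gl <- matrix(0, H, W); gl[at] <- stats::runif(n_glint, 0.25, 0.55)
    for (ch in 1:3) img[, , ch] <- img[, , ch] + gl
  }

  pts <- place_plants(spec, n)
  acc_r <- acc_c <- acc_a <- vector("list", n)
  acc_col <- vector("list", n)
  for (i in seq_len(n)) {
    cy <- pts[i, 1L]; cx <- pts[i, 2L]
    r <- stats::runif(1, spec$plant_radius[1L], spec$plant_radius[2L])
    shade_g <- stats::runif(1, 0, 1)
    col_leaf <- c(0.08 + 0.10 * shade_g, 0.30 + 0.25 * shade_g, 0.06 + 0.10 * shade_g)
    rr_i <- cc_i <- integer(0); aa_i <- numeric(0)
    for (k in seq_len(sample(4:9, 1L))) {
      ang <- stats::runif(1, 0, 2 * pi)
      len <- stats::runif(1, 0.55, 1) * r
      curv <- stats::runif(1, -0.5, 0.5)
      tt <- seq(0, 1, length.out = max(6L, ceiling(2.5 * len)))
      px <- cx + tt * len * cos(ang) - curv * tt^2 * len * sin(ang)
      py <- cy + tt * len * sin(ang) + curv * tt^2 * len * cos(ang)
      rr <- as.integer(floor(py + 0.5)); cc <- as.integer(floor(px + 0.5))
      rr_i <- c(rr_i, rr); cc_i <- c(cc_i, cc)
      aa_i <- c(aa_i, rep(0.8, length(rr)))
      if (r > 9) {                       # wider leaves for large plants
        rr_i <- c(rr_i, rr); cc_i <- c(cc_i, cc + 1L)
        aa_i <- c(aa_i, rep(0.45, length(rr)))
      }
    }
    # darker crown at the root pixel itself
    rr0 <- as.integer(floor(cy + 0.5)); cc0 <- as.integer(floor(cx + 0.5))
    rr_i <- c(rr_i, rr0 + c(0L, 0L, 1L, 1L)); cc_i <- c(cc_i, cc0 + c(0L, 1L, 0L, 1L))
    aa_i <- c(aa_i, rep(0.9, 4L))
    acc_r[[i]] <- rr_i; acc_c[[i]] <- cc_i; acc_a[[i]] <- aa_i
    colm <- matrix(col_leaf, length(rr_i), 3L, byrow = TRUE)
    colm[aa_i == 0.9, ] <- colm[aa_i == 0.9, , drop = FALSE] * 0.6
    acc_col[[i]] <- colm
  }
  if (n > 0L)
    img <- paint_pts(img, unlist(acc_r), unlist(acc_c),
                     do.call(rbind, acc_col), unlist(acc_a))
  img <- pmin(pmax(img, 0), 1)

  ann <- dot_annotation(
    image_id = sprintf("scene_seed%d", spec$seed),
    points = if (n > 0L) cbind(x = pts[, 2L] - 1, y = pts[, 1L] - 1)
             else matrix(numeric(0), 0L, 2L, dimnames = list(NULL, c("x", "y"))))
  structure(list(image = img, annotation = ann, spec = spec), class = "bc_scene")
}

#' @export
print.bc_scene <- function(x, ...) {
  cat(sprintf("Synthetic scene %s: %d x %d px, %d plants (seed %d)\n",
              x$annotation$image_id, x$spec$size[1L], x$spec$size[2L],
              nrow(x$annotation$points), x$spec$seed))
  invisible(x)
}

#' Generate a batch of scenes in memory
#'
#' Per-scene seeds are derived from the base seed, so the batch is
#' reproducible as a whole and each scene individually.
#'
#' @param n_scenes Number of scenes (>= 1).
#' @param template A [scene_spec()] whose fields (except `seed`) are reused
#'   for every scene.
#' @param seed Base seed.
#' @return List of `"bc_scene"` objects.
#' @export
generate_scenes <- function(n_scenes, template = scene_spec(), seed = 1L) {
  if (n_scenes < 1L) stop("n_scenes must be >= 1")
  lapply(seq_len(n_scenes), function(i) {
    sp <- template
    sp$seed <- derive_seed(seed, "scene", i)
    sc <- render_scene(sp)
    sc$annotation$image_id <- sprintf("scene_%04d", i)
    sc
  })
}

#' Write a synthetic dataset to disk
#'
#' Renders `n_scenes` scenes and writes PNG images, a dot-annotation CSV
#' (`image,x,y`), and a JSON manifest recording every scene spec and the
#' base seed.
#'
#' @inheritParams generate_scenes
#' @param dir Output directory (created if missing).
#' @return Invisibly, a list with the directory, image paths, annotation CSV
#'   path and manifest path.
#' @export
generate_dataset <- function(n_scenes, template = scene_spec(), seed = 1L,
                             dir = stop("'dir' is required")) {
  scenes <- generate_scenes(n_scenes, template, seed)
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create output directory ", dir)
  paths <- character(n_scenes)
  rows <- list()
  for (i in seq_along(scenes)) {
    sc <- scenes[[i]]
    paths[i] <- file.path(dir, paste0(sc$annotation$image_id, ".png"))
    png::writePNG(sc$image, paths[i])
    p <- sc$annotation$points
    if (nrow(p) > 0L)
      rows[[i]] <- data.frame(image = sc$annotation$image_id,
                              x = p[, "x"], y = p[, "y"])
  }
  ann_path <- file.path(dir, "ann.csv")
  ann <- if (length(rows)) do.call(rbind, rows)
         else data.frame(image = character(0), x = numeric(0), y = numeric(0))
  utils::write.csv(ann, ann_path, row.names = FALSE, quote = FALSE)
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(
    seed = seed, n_scenes = n_scenes,
    template = unclass(template),
    scenes = lapply(scenes, function(s)
      list(image = paste0(s$annotation$image_id, ".png"),
           seed = s$spec$seed, n_plants = nrow(s$annotation$points)))),
    manifest, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(dir = dir, images = paths, annotations = ann_path,
                 manifest = manifest))
}
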