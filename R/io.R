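#' Dot annotation
#'
#' One labeled point per plant root, in pixel coordinates: `x` is the
#' column, `y` the row, both 0-based floats with origin at the top-left.
#' Annotation files store native-resolution coordinates; rescale with the
#' same ratio as the image.
#'
#' @param image_id Image identifier (file stem).
#' @param points Two-column numeric matrix/data.frame `(x, y)`; may have
#'   zero rows.
#' @return An object of class `"bc_annotation"`.
#' @export
dot_annotation <- function(image_id, points) {
  pts <- as.matrix(points)
  if (length(pts) == 0L) pts <- matrix(numeric(0), 0L, 2L)
  if (ncol(pts) != 2L) stop("points must have two columns (x, y)")
  colnames(pts) <- c("x", "y")
  structure(list(image_id = as.character(image_id), points = pts),
            class = "bc_annotation")
}

#' @export
print.bc_annotation <- function(x, ...) {
  cat(sprintf("Dot annotation '%s': %d point(s)\n", x$image_id, nrow(x$points)))
  invisible(x)
}

#' Read dot annotations
#'
#' Accepts either the CSV dialect (`image,x,y` header, one row per dot,
#' duplicates kept with multiplicity) or a JSON object
#' `{image_id: [[x, y], ...]}`. The format is chosen by file extension.
#'
#' @param path CSV or JSON file.
#' @return Named list of [dot_annotation()] objects, one per image id.
#' @export
load_annotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    js <- jsonlite::read_json(path, simplifyVector = TRUE)
    out <- lapply(names(js), function(id) {
      m <- js[[id]]
      if (is.null(dim(m))) m <- matrix(unlist(m), ncol = 2L, byrow = TRUE)
      dot_annotation(id, m)
    })
    names(out) <- names(js)
    return(out)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(tolower(names(df))[1:3], c("image", "x", "y")))
    stop("unknown annotation header: expected 'image,x,y', got '",
         paste(names(df), collapse = ","), "'")
  df$x <- suppressWarnings(as.numeric(df$x))
  df$y <- suppressWarnings(as.numeric(df$y))
  bad <- which(!is.finite(df$x) | !is.finite(df$y))
  if (length(bad))
    stop(sprintf("malformed annotation row at line %d of %s", bad[1L] + 1L, path))
  ids <- unique(df$image)
  out <- lapply(ids, function(id) {
    sub <- df[df$image == id, , drop = FALSE]
    dot_annotation(id, cbind(sub$x, sub$y))
  })
  names(out) <- ids
  out
}

#' Write dot annotations as CSV
#'
#' @param annotations Named list of [dot_annotation()] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  rows <- lapply(annotations, function(a) {
    if (nrow(a$points) == 0L) return(NULL)
    data.frame(image = a$image_id, x = a$points[, "x"], y = a$points[, "y"])
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) df <- data.frame(image = character(0), x = numeric(0), y = numeric(0))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an image as an (H, W, 3) array in [0, 1]
#'
#' PNG files are read with the png package; other formats (JPEG) go through
#' EBImage. Grayscale images are replicated to three channels with a
#' warning; an alpha channel is dropped.
#'
#' @param path Image file.
#' @return `(H, W, 3)` numeric array.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("image not found: ", path)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    img <- png::readPNG(path)
  } else {
    e <- EBImage::readImage(path)
    a <- EBImage::imageData(e)
    img <- if (length(dim(a)) == 2L) t(a) else aperm(a, c(2L, 1L, 3L))
  }
  if (length(dim(img)) == 2L) {
    warning("grayscale input; replicating to 3 channels")
    img <- array(rep(img, 3L), c(dim(img), 3L))
  }
  if (dim(img)[3L] > 3L) img <- img[, , 1:3, drop = FALSE]
  if (dim(img)[3L] == 1L) {
    warning("grayscale input; replicating to 3 channels")
    img <- array(rep(img[, , 1L], 3L), c(dim(img)[1:2], 3L))
  }
  img
}

#' Bilinear image resize by a ratio
#'
#' @param img `(H, W, C)` array or matrix.
#' @param ratio Scaling ratio (0.25 = quarter resolution). Ratio 1 returns
#'   the input unchanged.
#' @return Resized array.
#' @export
resize_image <- function(img, ratio) {
  if (ratio == 1) return(img)
  m <- length(dim(img)) == 2L
  if (m) img <- array(img, c(dim(img), 1L))
  d <- dim(img)
  out_h <- max(1L, as.integer(round(d[1L] * ratio)))
  out_w <- max(1L, as.integer(round(d[2L] * ratio)))
  e <- EBImage::resize(EBImage::Image(aperm(img, c(2L, 1L, 3L)),
                                      colormode = "Color"),
                       w = out_w, h = out_h)
  out <- aperm(EBImage::imageData(e), c(2L, 1L, 3L))
  if (m) out <- out[, , 1L]
  out
}

#' Save / load encoded target maps
#'
#' Stores density, count and class maps for an image as a single compressed
#' archive with a metadata block carrying the codec parameters (block,
#' stride, s, q, c_max, sigma).
#'
#' @param maps Named list, e.g. from [encode_image()].
#' @param path Output file (`.rds`).
#' @return `save_maps` returns `path` invisibly; `load_maps` the list.
#' @export
save_maps <- function(maps, path) {
  saveRDS(maps, path, compress = "gzip")
  invisible(path)
}

#' @rdname save_maps
#' @export
load_maps <- function(path) readRDS(path)

#' Encode one image's annotation into its learning targets
#'
#' Runs the full target codec: rasterized dot map, Gaussian density map,
#' overlapping count map and quantized class map, together with the codec
#' metadata.
#'
#' @param annotation A [dot_annotation()].
#' @param shape `c(rows, cols)` of the (working-resolution) image.
#' @param scale Coordinate scale applied to the annotation (1 if the
#'   annotation is already at working resolution).
#' @param sigma Gaussian standard deviation for the density map.
#' @param block,stride Patch layout of the count map.
#' @param spec A [quantizer_spec()].
#' @return Named list with `dots`, `density`, `counts`, `classes`, `meta`.
#' @export
encode_image <- function(annotation, shape, scale = 1, sigma = 4,
                         block = 32L, stride = 8L, spec = quantizer_spec()) {
  dots <- rasterize_dots(annotation$points, shape, scale)
  dens <- density_from_dots(dots, sigma)
  cm <- count_map_from_density(dens, block, stride)
  cl <- class_map_from_count_map(cm, spec)
  list(dots = dots, density = dens, counts = cm, classes = cl,
       meta = list(image_id = annotation$image_id, block = block,
                   stride = stride, s = spec$s, q = spec$q,
                   c_max = spec$c_max, sigma = sigma, scale = scale))
}
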