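#' Predict the plant count of an image
#'
#' Whole-image inference: the image is resized to working resolution,
#' normalized, reflect-padded on the right/bottom to the next multiple of
#' 32, pushed through the network, and the predicted class map is decoded —
#' argmax with low-index tie-breaks, inverse quantization to patch counts,
#' coverage-weighted deredundancy to a pixel count map. Pixels on the
#' padded margin are discarded before totaling, and the reported total is
#' the sum of the remaining pixel map.
#'
#' @param object A fitted [blockcount()] model (or [rigged_counter()]).
#' @param image `(H, W, 3)` array in `[0, 1]` or an image file path. A
#'   grayscale input is replicated to three channels with a warning.
#' @param image_id Identifier used in reports; defaults to the file stem or
#'   `"image"`.
#' @param ... Unused.
#' @return An object of class `"blockcount_prediction"`: list with
#'   `image_id`, `total`, `pixel_map` (working-resolution count map) and
#'   `class_grid`.
#' @export
predict.blockcount <- function(object, image, image_id = NULL, ...) {
  if (is.character(image)) {
    if (is.null(image_id)) image_id <- sub("\\.[^.]+$", "", basename(image))
    image <- read_image(image)
  }
  if (is.null(image_id)) image_id <- "image"
  if (length(dim(image)) == 2L) {
    warning("grayscale input; replicating to 3 channels")
    image <- array(rep(image, 3L), c(dim(image), 3L))
  }
  if (any(dim(image)[1:2] == 0L)) stop("zero-size input image")
  img <- resize_image(image, object$config$downsample_ratio)
  d0 <- dim(img)[1:2]
  block <- object$codec$block; stride <- object$codec$stride
  Hp <- max(align_up(d0[1L], 32L), block)
  Wp <- max(align_up(d0[2L], 32L), block)
  img <- reflect_pad(img, Hp - d0[1L], Wp - d0[2L])
  grid <- patch_grid(Hp, Wp, block, stride)

  if (!is.null(object$rig)) {
    cls_values <- object$rig(img)
    mode <- "classification"
  } else {
    x <- normalize_image(img, object$norm)
    out <- network_forward(object$model, x, train = FALSE)
    mode <- object$model$mode
    if (mode == "classification") {
      cls_values <- predict_class_map(out$probs)
    } else {
      counts_values <- pmax(matrix(out$logits[1L, , , 1L],
                                   dim(out$logits)[2L]), 0)
    }
  }
  if (mode == "classification") {
    if (!all(dim(cls_values) == c(grid$n_rows, grid$n_cols)))
      stop("class grid does not match the patch grid of the padded image")
    cls <- structure(list(values = cls_values, grid = grid,
                          spec = object$quantizer), class = "bc_class_map")
    cm <- dequantize_class_map(cls)
  } else {
    cls <- NULL
    cm <- new_count_map(counts_values, grid)
  }
  px <- deredundancy(cm)
  px <- px[seq_len(d0[1L]), seq_len(d0[2L]), drop = FALSE]
  structure(list(image_id = image_id, total = sum(px), pixel_map = px,
                 class_grid = cls),
            class = "blockcount_prediction")
}

#' @export
print.blockcount_prediction <- function(x, ...) {
  cat(sprintf("Prediction '%s': total count %.2f (%d) over a %d x %d pixel map\n",
              x$image_id, x$total, round(x$total),
              nrow(x$pixel_map), ncol(x$pixel_map)))
  invisible(x)
}

#' Batch prediction with CSV summary
#'
#' Runs [predict.blockcount()] over a list of images, preserving order.
#' A failing image is reported as a warning and an `NA` row; the batch only
#' errors when every image fails (or the list is empty).
#'
#' @param object A fitted [blockcount()] model.
#' @param images List of arrays, named list, or character vector of paths.
#' @param out_csv Optional path; the summary table (columns `image`,
#'   `total`, `total_rounded`) is written there.
#' @return List with `predictions` (per-image results) and `summary`
#'   (data.frame).
#' @export
predict_batch <- function(object, images, out_csv = NULL) {
  if (length(images) == 0L) stop("empty image list")
  ids <- names(images)
  if (is.null(ids)) {
    ids <- if (is.character(images)) sub("\\.[^.]+$", "", basename(images))
           else sprintf("image_%04d", seq_along(images))
  }
  preds <- vector("list", length(images))
  totals <- rep(NA_real_, length(images))
  for (i in seq_along(images)) {
    preds[[i]] <- tryCatch(
      predict(object, images[[i]], image_id = ids[i]),
      error = function(e) {
        warning(sprintf("prediction failed for '%s': %s", ids[i], conditionMessage(e)))
        NULL
      })
    if (!is.null(preds[[i]])) totals[i] <- preds[[i]]$total
  }
  if (all(is.na(totals))) stop("all images failed to predict")
  summary <- data.frame(image = ids, total = totals,
                        total_rounded = round(totals))
  if (!is.null(out_csv))
    utils::write.csv(summary, out_csv, row.names = FALSE, quote = FALSE)
  list(predictions = preds, summary = summary)
}

#' Rigged counter for pipeline checks
#'
#' A stand-in for a trained model whose "network" is a user-supplied
#' function mapping the padded working-resolution image to a class-map
#' matrix. Useful for exercising the decode path (inverse quantization,
#' deredundancy, totaling) in isolation — e.g. a rig that always emits the
#' ground-truth class map bounds the decode error of the whole pipeline by
#' the quantizer roundtrip error.
#'
#' @param class_fun `function(image)` returning the class-index matrix for
#'   the padded working image.
#' @param quantizer A [quantizer_spec()].
#' @param sigma,block,stride Codec parameters carried on the object.
#' @param downsample_ratio Working-resolution ratio (default 1).
#' @return An object of class `"blockcount"` usable with
#'   [predict.blockcount()] and [evaluate()].
#' @export
rigged_counter <- function(class_fun, quantizer = quantizer_spec(),
                           sigma = 4, block = 32L, stride = 8L,
                           downsample_ratio = 1) {
  structure(list(model = NULL, rig = class_fun, quantizer = quantizer,
                 norm = list(mean = rep(0, 3), std = rep(1, 3)),
                 config = list(downsample_ratio = downsample_ratio,
                               mode = "classification"),
                 codec = list(sigma = sigma, block = block, stride = stride),
                 history = NULL),
            class = "blockcount")
}
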