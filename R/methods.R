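#' @export
print.blockcount <- function(x, ...) {
  cat("Blockwise-classification counting model\n")
  if (!is.null(x$rig)) {
    cat("  rigged decode-only model (no trained network)\n")
  } else {
    print(x$model)
    cat(sprintf("  quantizer: s = %g, q = %g, c_max = %d; density sigma = %g; patches %d/%d\n",
                x$quantizer$s, x$quantizer$q, x$quantizer$c_max,
                x$codec$sigma, x$codec$block, x$codec$stride))
    if (!is.null(x$history))
      cat(sprintf("  trained %d epoch(s), final loss %.4f%s\n",
                  nrow(x$history), x$history$loss[nrow(x$history)],
                  if (!is.na(x$best_epoch))
                    sprintf(" (best validation MAE at epoch %d)", x$best_epoch)
                  else ""))
  }
  invisible(x)
}

#' @export
summary.blockcount <- function(object, ...) {
  print(object)
  if (!is.null(object$history)) {
    cat("\nTraining history (last 5 epochs):\n")
    print(utils::tail(object$history, 5L), row.names = FALSE)
  }
  cat(sprintf("\nNormalization: mean (%s), std (%s)\n",
              paste(sprintf("%.3f", object$norm$mean), collapse = ", "),
              paste(sprintf("%.3f", object$norm$std), collapse = ", ")))
  invisible(object)
}

#' Plot the training history of a counting model
#'
#' Training loss per epoch, with validation MAE overlaid on a secondary
#' axis when a validation split was used.
#'
#' @param x A fitted [blockcount()] object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.blockcount <- function(x, ...) {
  h <- x$history
  if (is.null(h)) stop("model has no training history")
  graphics::plot(h$epoch, h$loss, type = "l", xlab = "epoch",
                 ylab = "training loss", ...)
  if (any(!is.na(h$val_mae))) {
    graphics::par(new = TRUE)
    graphics::plot(h$epoch, h$val_mae, type = "l", col = "firebrick",
                   axes = FALSE, xlab = "", ylab = "")
    graphics::axis(4L, col.axis = "firebrick")
    graphics::mtext("validation MAE", side = 4L, line = 2L, col = "firebrick")
  }
  invisible(x)
}

#' Display a prediction's pixel count map
#'
#' @param x A [predict.blockcount()] result.
#' @param ... Passed to [graphics::image()].
#' @export
plot.blockcount_prediction <- function(x, ...) {
  m <- x$pixel_map
  graphics::image(t(m[nrow(m):1, , drop = FALSE]), axes = FALSE, useRaster = TRUE,
                  main = sprintf("%s: total %.1f", x$image_id, x$total), ...)
  invisible(x)
}
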