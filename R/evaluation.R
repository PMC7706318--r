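#' Counting metrics: MAE, RMSE, rMAE, R squared
#'
#' The standard counting evaluation suite over per-image ground-truth and
#' estimated totals: mean absolute error, root mean square error, mean
#' relative absolute error in percent, and the squared Pearson correlation
#' of ground truth versus estimate (the scatter-plot convention). The
#' `1 - SS_res/SS_tot` coefficient of determination is available via
#' `r2 = "ss"`, and `square_root = FALSE` gives the unrooted mean square
#' error.
#'
#' @param gt,est Equal-length numeric vectors of per-image counts.
#' @param square_root Take the root in the RMSE (default TRUE).
#' @param r2 `"pearson"` (squared correlation, default) or `"ss"`.
#' @return An object of class `"bc_metrics"`: list with `mae`, `rmse`,
#'   `rmae` (percent; `NA` with a warning when any `gt` is 0), `r2`, `n`.
#' @export
compute_metrics <- function(gt, est, square_root = TRUE,
                            r2 = c("pearson", "ss")) {
  r2 <- match.arg(r2)
  if (length(gt) != length(est)) stop("gt and est differ in length")
  if (length(gt) == 0L) stop("empty input")
  err <- est - gt
  mae <- mean(abs(err))
  rmse <- if (square_root) sqrt(mean(err^2)) else mean(err^2)
  if (any(gt == 0)) {
    warning("ground-truth count of 0: rMAE undefined for this run")
    rmae <- NA_real_
  } else {
    rmae <- mean(abs(err) / gt) * 100
  }
  r2v <- if (length(gt) < 2L || stats::sd(gt) == 0 || stats::sd(est) == 0) {
    NA_real_
  } else if (r2 == "pearson") {
    stats::cor(gt, est)^2
  } else {
    1 - sum(err^2) / sum((gt - mean(gt))^2)
  }
  structure(list(mae = mae, rmse = rmse, rmae = rmae, r2 = r2v,
                 n = length(gt)),
            class = "bc_metrics")
}

#' @export
print.bc_metrics <- function(x, ...) {
  cat(sprintf("Counting metrics over %d image(s):\n", x$n))
  cat(sprintf("  MAE  %8.3f\n  RMSE %8.3f\n  rMAE %8.3f %%\n  R2   %8.4f\n",
              x$mae, x$rmse, x$rmae, x$r2))
  invisible(x)
}

#' Evaluate a counting model on an annotated image set
#'
#' Predicts every image, derives ground-truth totals from the dot counts,
#' and reports the metric suite plus a per-image table and the (gt, est)
#' pairs for scatter plotting. Images without an annotation are excluded
#' with a warning and counted in the report.
#'
#' @param object A fitted [blockcount()] model.
#' @param images List of arrays / paths, or list of `"bc_scene"` objects.
#' @param annotations Named list of [dot_annotation()] or a file path;
#'   ignored for scenes.
#' @param out_csv Optional path for the per-image table.
#' @param ... Passed to [compute_metrics()].
#' @return List with `metrics` (a `"bc_metrics"`), `table` (per-image
#'   `image, gt, est, abs_err, rel_err`), and `n_excluded`.
#' @export
evaluate <- function(object, images, annotations = NULL, out_csv = NULL, ...) {
  set <- as_training_set(images, annotations, allow_missing = TRUE)
  n_excl <- 0L
  keep <- !vapply(set, function(e) is.null(e$annotation), TRUE)
  ids <- rep(NA_character_, length(set))
  ids[keep] <- vapply(set[keep], function(e) e$annotation$image_id, "")
  if (!all(keep)) {
    n_excl <- sum(!keep)
    warning(sprintf("%d image(s) without annotation excluded", n_excl))
    set <- set[keep]; ids <- ids[keep]
  }
  res <- predict_batch(object, stats::setNames(lapply(set, `[[`, "image"), ids))
  gt <- vapply(set, function(e) nrow(e$annotation$points), 1L)
  est <- res$summary$total
  tab <- data.frame(image = ids, gt = gt, est = est,
                    abs_err = abs(est - gt),
                    rel_err = ifelse(gt > 0, abs(est - gt) / gt, NA_real_))
  if (!is.null(out_csv))
    utils::write.csv(tab, out_csv, row.names = FALSE, quote = FALSE)
  ok <- !is.na(est)
  metrics <- compute_metrics(gt[ok], est[ok], ...)
  list(metrics = metrics, table = tab, n_excluded = n_excl)
}
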