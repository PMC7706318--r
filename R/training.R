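#' Training configuration
#'
#' Defaults follow the reference recipe for field-scale imagery: images are
#' downsampled to quarter resolution, one random 384 x 384 crop per image
#' per epoch, batches of 8, SGD with initial learning rate 1e-2 decreased by
#' a factor of 10 every 200 epochs, 600 epochs in total. Momentum 0.9 and
#' weight decay 1e-4 are standard SGD settings surfaced here. Scale `crop`,
#' `epochs` and `downsample_ratio` down for CPU-sized experiments.
#'
#' @param downsample_ratio Working-resolution ratio applied to images and
#'   annotations. Default 0.25.
#' @param crop Square crop side in pixels; must be divisible by 32.
#' @param batch Batch size (>= 1).
#' @param lr0 Initial learning rate.
#' @param lr_decay_factor,lr_decay_every Learning-rate schedule: divide by
#'   `lr_decay_factor` every `lr_decay_every` epochs.
#' @param epochs Number of epochs.
#' @param momentum,weight_decay SGD momentum and L2 weight decay.
#' @param seed Master seed; all random components (crops, shuffling,
#'   initialization) derive from it.
#' @param mode `"classification"` (count-interval classes, cross-entropy)
#'   or `"regression"` (raw patch counts, l1 loss ablation).
#' @return An object of class `"bc_train_config"`.
#' @export
train_config <- function(downsample_ratio = 0.25, crop = 384L, batch = 8L,
                         lr0 = 1e-2, lr_decay_factor = 10, lr_decay_every = 200L,
                         epochs = 600L, momentum = 0.9, weight_decay = 1e-4,
                         seed = 1L, mode = c("classification", "regression")) {
  mode <- match.arg(mode)
  crop <- as.integer(crop)
  if (crop %% 32L != 0L) stop("'crop' must be divisible by 32")
  if (batch < 1L) stop("'batch' must be >= 1")
  structure(list(downsample_ratio = downsample_ratio, crop = crop,
                 batch = as.integer(batch), lr0 = lr0,
                 lr_decay_factor = lr_decay_factor,
                 lr_decay_every = as.integer(lr_decay_every),
                 epochs = as.integer(epochs), momentum = momentum,
                 weight_decay = weight_decay, seed = as.integer(seed),
                 mode = mode),
            class = "bc_train_config")
}

#' Per-channel normalization statistics of a training set
#'
#' Mean and standard deviation per channel over all pixels of all images at
#' working resolution. A degenerate (zero) standard deviation is replaced by
#' 1 with a warning.
#'
#' @param images List of `(H, W, 3)` arrays.
#' @return List with numeric `mean` and `std`, each length 3.
#' @export
compute_normalization <- function(images) {
  if (length(images) == 0L) stop("empty training set")
  s <- s2 <- numeric(3L); n <- 0
  for (img in images) {
    d <- dim(img)
    m <- matrix(img, ncol = d[3L])
    s <- s + colSums(m)
    s2 <- s2 + colSums(m * m)
    n <- n + d[1L] * d[2L]
  }
  mean <- s / n
  std <- sqrt(pmax(s2 / n - mean^2, 0))
  if (any(std == 0)) {
    warning("degenerate per-channel std of 0 replaced by 1")
    std[std == 0] <- 1
  }
  list(mean = mean, std = std)
}

normalize_image <- function(img, stats) {
  for (ch in 1:3) img[, , ch] <- (img[, , ch] - stats$mean[ch]) / stats$std[ch]
  img
}

#' Build one training sample (crop + target)
#'
#' Resizes the image and its dots to working resolution, reflect-pads images
#' smaller than the crop, draws a uniform random crop offset from the
#' current RNG stream, and encodes the crop's targets: the density map is
#' computed on the full working-resolution image and cropped, then summed
#' over the overlapping 32/8 patch grid; classification mode quantizes the
#' counts into a class map. For a 384 crop the target grid is 45 x 45.
#'
#' @param image `(H, W, 3)` array at native resolution.
#' @param annotation Matching [dot_annotation()] (native coordinates).
#' @param cfg A [train_config()].
#' @param spec A [quantizer_spec()].
#' @param sigma Density Gaussian standard deviation.
#' @param block,stride Patch layout (32/8 by default).
#' @return List with `image` (crop), `counts`, `classes`, `offset`.
#' @export
make_sample <- function(image, annotation, cfg, spec = quantizer_spec(),
                        sigma = 4, block = 32L, stride = 8L) {
  img <- resize_image(image, cfg$downsample_ratio)
  d <- dim(img)
  pad_b <- max(0L, cfg$crop - d[1L]); pad_r <- max(0L, cfg$crop - d[2L])
  if (pad_b > 0L || pad_r > 0L) img <- reflect_pad(img, pad_b, pad_r)
  d <- dim(img)
  oy <- sample.int(d[1L] - cfg$crop + 1L, 1L) - 1L
  ox <- sample.int(d[2L] - cfg$crop + 1L, 1L) - 1L
  crop <- img[oy + seq_len(cfg$crop), ox + seq_len(cfg$crop), , drop = FALSE]

  dots <- rasterize_dots(annotation$points, d[1:2], cfg$downsample_ratio)
  dens <- density_from_dots(dots, sigma)
  dens_c <- dens[oy + seq_len(cfg$crop), ox + seq_len(cfg$crop), drop = FALSE]
  cm <- count_map_from_density(dens_c, block, stride)
  cl <- class_map_from_count_map(cm, spec)
  list(image = crop, counts = cm, classes = cl, offset = c(oy, ox))
}

loss_values <- function(x) if (inherits(x, "bc_count_map")) x$values else x

#' Cross-entropy classification loss on a class-probability map
#'
#' Mean over grid cells of the negative log-probability assigned to the
#' ground-truth count-interval class. With `gradient = TRUE` the analytic
#' gradient with respect to the probabilities is returned as well.
#'
#' @param probs `(C, Hg, Wg)` (or `(C, Hg, Wg, N)`) channels-first
#'   probability array.
#' @param target Integer matrix (or array) of ground-truth classes in
#'   `0..C-1`, spatial dims matching `probs`; a `"bc_class_map"` is also
#'   accepted.
#' @param gradient Return the gradient alongside the loss.
#' @return Scalar loss, or `list(loss, gradient)`.
#' @export
classification_loss <- function(probs, target, gradient = FALSE) {
  if (inherits(target, "bc_class_map")) target <- target$values
  d <- dim(probs)
  if (length(d) == 3L) { probs <- array(probs, c(d, 1L)); d <- dim(probs) }
  td <- dim(target)
  if (length(td) == 2L) target <- array(target, c(td, 1L))
  if (!all(dim(target) == d[c(2L, 3L, 4L)]))
    stop("probability map and target grids are misaligned: ",
         paste(d[c(2, 3, 4)], collapse = "x"), " vs ",
         paste(dim(target), collapse = "x"))
  C <- d[1L]; M <- d[2L] * d[3L] * d[4L]
  pm <- matrix(probs, nrow = C)
  sel <- cbind(as.integer(target) + 1L, seq_len(M))
  loss <- -mean(log(pmax(pm[sel], 1e-12)))
  if (!gradient) return(loss)
  g <- matrix(0, C, M)
  g[sel] <- -1 / (M * pmax(pm[sel], 1e-12))
  grad <- array(g, d)
  if (length(td) == 2L) grad <- grad[, , , 1L, drop = TRUE]
  list(loss = loss, gradient = grad)
}

#' l1 regression loss on patch counts
#'
#' Mean absolute difference over grid cells; the regression ablation's
#' training loss. With `gradient = TRUE`, returns the analytic subgradient
#' `sign(pred - target) / n_cells`.
#'
#' @param pred,target Count matrices (or `"bc_count_map"` objects) on the
#'   same grid.
#' @param gradient Return the gradient alongside the loss.
#' @return Scalar loss, or `list(loss, gradient)`.
#' @export
regression_loss <- function(pred, target, gradient = FALSE) {
  p <- loss_values(pred); t_ <- loss_values(target)
  if (!all(dim(p) == dim(t_)))
    stop("prediction and target grids are misaligned: ",
         paste(dim(p), collapse = "x"), " vs ", paste(dim(t_), collapse = "x"))
  loss <- mean(abs(p - t_))
  if (!gradient) return(loss)
  list(loss = loss, gradient = sign(p - t_) / length(p))
}

epoch_lr <- function(cfg, epoch)
  cfg$lr0 / cfg$lr_decay_factor^((epoch - 1L) %/% cfg$lr_decay_every)

as_training_set <- function(images, annotations, allow_missing = FALSE) {
  if (length(images) && inherits(images[[1L]], "bc_scene"))
    return(lapply(images, function(s) list(image = s$image, annotation = s$annotation)))
  if (is.character(images)) {
    paths <- images
    images <- lapply(paths, read_image)
    names(images) <- sub("\\.[^.]+$", "", basename(paths))
  }
  if (is.character(annotations)) annotations <- load_annotations(annotations)
  ids <- names(images)
  if (is.null(ids)) {
    if (length(images) != length(annotations))
      stop("images and annotations differ in length and images are unnamed")
    return(Map(function(i, a) list(image = i, annotation = a), images, annotations))
  }
  missing <- setdiff(ids, names(annotations))
  if (length(missing) && !allow_missing)
    stop("no annotation for image(s): ", paste(missing, collapse = ", "))
  lapply(ids, function(id) list(image = images[[id]],
                                annotation = annotations[[id]]))
}

#' Fit a blockwise-classification counting model
#'
#' The main fitting function: encodes dot annotations into count-interval
#' class maps on an overlapping 32/8 patch grid, and trains a fully
#' convolutional classifier on random crops with SGD. In `"regression"`
#' mode the head is a single-channel count regressor trained with l1 loss
#' (the ablation baseline); both modes consume identical crops given the
#' same seed. The quantizer's `c_max` is set from the training data as the
#' class of the largest observed patch count plus one, and is stored with
#' the model.
#'
#' @param images Training images: list of `(H, W, 3)` arrays, character
#'   vector of file paths, or list of `"bc_scene"` objects (annotations then
#'   come from the scenes).
#' @param annotations Named list of [dot_annotation()] objects or a path to
#'   an annotation file; ignored when `images` are scenes.
#' @param config A [train_config()].
#' @param backbone A [backbone_spec()].
#' @param n_layers Number of fused feature-pyramid layers (default 3).
#' @param sigma Density-map Gaussian standard deviation (default 4).
#' @param s,q Quantizer step and log-space start (defaults 0.1, -2).
#' @param block,stride Patch layout (defaults 32, 8).
#' @param validation Optional integer indices of `images` held out for
#'   per-epoch validation (best-by-validation-MAE weights are kept).
#' @param log_path Optional JSONL file receiving one record per epoch.
#' @param verbose Print per-epoch progress.
#' @return An object of class `"blockcount"` with the trained network, the
#'   quantizer, normalization statistics, configuration and per-epoch
#'   history.
#' @export
blockcount <- function(images, annotations = NULL, config = train_config(),
                       backbone = backbone_spec("tiny"), n_layers = 3L,
                       sigma = 4, s = 0.1, q = -2, block = 32L, stride = 8L,
                       validation = NULL, log_path = NULL, verbose = TRUE) {
  cl_call <- match.call()
  set <- as_training_set(images, annotations)
  if (length(set) == 0L) stop("empty training set")
  old <- local_seed(derive_seed(config$seed, "train"))
  on.exit(restore_seed(old), add = TRUE)

  # cache working-resolution images once; annotations stay native and are
  # rescaled inside make_sample via the config ratio
  val_idx <- as.integer(validation)
  train_idx <- setdiff(seq_along(set), val_idx)
  if (length(train_idx) == 0L) stop("validation split leaves no training images")

  stats <- compute_normalization(lapply(set[train_idx], function(e)
    resize_image(e$image, config$downsample_ratio)))

  # c_max from the largest observed patch count over the training targets
  max_count <- 0
  for (i in train_idx) {
    img_d <- dim(resize_image(set[[i]]$image, config$downsample_ratio))
    dots <- rasterize_dots(set[[i]]$annotation$points, img_d[1:2],
                           config$downsample_ratio)
    if (sum(dots) == 0) next
    dens <- density_from_dots(dots, sigma)
    if (img_d[1L] >= block && img_d[2L] >= block)
      max_count <- max(max_count, max(count_map_from_density(dens, block, stride)$values))
  }
  c_max <- if (max_count > 0)
    max(floor((log(max_count) - q) / s) + 2, 1) + 1L else 2L
  spec <- quantizer_spec(s = s, q = q, c_max = c_max)

  model <- build_network(backbone, n_layers = n_layers, n_out = c_max + 1L,
                         mode = config$mode,
                         seed = derive_seed(config$seed, "init"))

  n_train <- length(train_idx)
  history <- vector("list", config$epochs)
  epoch1_samples <- list()     # crop stream record; modes must agree on it
  best <- list(mae = Inf, params = NULL, epoch = NA_integer_)
  fitted_obj <- function(mdl) structure(list(
    model = mdl, quantizer = spec, norm = stats, config = config,
    codec = list(sigma = sigma, block = block, stride = stride),
    history = NULL, call = cl_call), class = "blockcount")

  for (epoch in seq_len(config$epochs)) {
    lr <- epoch_lr(config, epoch)
    order <- train_idx[sample.int(n_train)]
    ep_loss <- 0; n_batches <- 0L
    for (b0 in seq(1L, n_train, by = config$batch)) {
      idx <- order[b0:min(b0 + config$batch - 1L, n_train)]
      B <- length(idx)
      xb <- array(0, c(3L, config$crop, config$crop, B))
      gdim <- config$crop %/% stride - (block %/% stride - 1L)
      tb <- array(0, c(gdim, gdim, B))
      for (k in seq_len(B)) {
        sm <- make_sample(set[[idx[k]]]$image, set[[idx[k]]]$annotation,
                          config, spec, sigma, block, stride)
        xb[, , , k] <- aperm(normalize_image(sm$image, stats), c(3L, 1L, 2L))
        tb[, , k] <- if (config$mode == "classification")
          sm$classes$values else sm$counts$values
        if (epoch == 1L)
          epoch1_samples[[length(epoch1_samples) + 1L]] <-
            list(index = idx[k], offset = sm$offset)
      }
      out <- network_forward(model, xb, train = TRUE)
      if (config$mode == "classification") {
        ce <- softmax_ce(out$logits, tb)
        loss <- ce$loss; dlogits <- ce$dlogits
      } else {
        pred <- array(out$logits[1L, , , ], dim(tb))
        loss <- mean(abs(pred - tb))
        dlogits <- array(sign(pred - tb) / length(tb),
                         c(1L, gdim, gdim, B))
      }
      if (!is.finite(loss))
        stop(sprintf(paste0("non-finite loss at epoch %d (lr %.3g): batch mean %.3g,",
                            " sd %.3g; lower the learning rate"),
                     epoch, lr, mean(xb), stats::sd(xb)))
      zero_grads(model$layers)
      network_backward(model, dlogits)
      sgd_step(model$layers, lr, config$momentum, config$weight_decay)
      ep_loss <- ep_loss + loss; n_batches <- n_batches + 1L
    }
    rec <- list(epoch = epoch, loss = ep_loss / n_batches, lr = lr)
    if (length(val_idx)) {
      tmp <- fitted_obj(model)
      gt <- est <- numeric(length(val_idx))
      for (j in seq_along(val_idx)) {
        e <- set[[val_idx[j]]]
        gt[j] <- nrow(e$annotation$points)
        est[j] <- predict(tmp, e$image)$total
      }
      rec$val_mae <- mean(abs(gt - est))
      if (rec$val_mae < best$mae)
        best <- list(mae = rec$val_mae, params = collect_params(model$layers),
                     epoch = epoch)
    }
    history[[epoch]] <- rec
    if (!is.null(log_path))
      cat(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), "\n",
          sep = "", file = log_path, append = epoch > 1L)
    if (verbose)
      message(sprintf("epoch %3d/%d  loss %.4f  lr %.2g%s", epoch,
                      config$epochs, rec$loss, lr,
                      if (!is.null(rec$val_mae))
                        sprintf("  val MAE %.2f", rec$val_mae) else ""))
  }

  last_params <- collect_params(model$layers)
  if (length(val_idx) && !is.null(best$params))
    restore_params(model$layers, best$params)

  obj <- fitted_obj(model)
  obj$history <- do.call(rbind, lapply(history, function(r)
    data.frame(epoch = r$epoch, loss = r$loss, lr = r$lr,
               val_mae = if (is.null(r$val_mae)) NA_real_ else r$val_mae)))
  obj$last_params <- last_params
  obj$best_epoch <- best$epoch
  obj$n_train <- n_train
  obj$epoch1_samples <- epoch1_samples
  obj
}
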