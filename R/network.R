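#' Backbone specification
#'
#' Describes the staged feature extractor: tap points at output strides
#' 8/16/32 with one channel width per tap. Two presets are provided:
#' `"tiny"`, a small randomly initialized extractor for CPU-scale work, and
#' `"mixnet_l"`, which mirrors the tap channel widths of the MixNet-L
#' backbone (56/160/264) and can load weights from an optional file. Only
#' the tap strides and widths of MixNet-L are mirrored; its internal block
#' structure is not re-derived.
#'
#' @param name `"tiny"` or `"mixnet_l"`.
#' @param stage_strides Strictly increasing downsample rates of the tap
#'   points; each must double the previous. Default `c(8, 16, 32)`.
#' @param stage_channels One channel width per tap; defaults depend on
#'   `name`.
#' @param pretrained_weights Optional path to an RDS checkpoint whose
#'   parameters are loaded into the backbone.
#' @return An object of class `"bc_backbone_spec"`.
#' @export
backbone_spec <- function(name = c("tiny", "mixnet_l"),
                          stage_strides = c(8L, 16L, 32L),
                          stage_channels = NULL,
                          pretrained_weights = NULL) {
  name <- match.arg(name)
  stage_strides <- as.integer(stage_strides)
  if (any(diff(stage_strides) <= 0)) stop("stage strides must be strictly increasing")
  if (is.null(stage_channels))
    stage_channels <- switch(name,
                             tiny = c(24L, 32L, 48L),
                             mixnet_l = c(56L, 160L, 264L))
  stage_channels <- as.integer(stage_channels)
  if (length(stage_channels) != length(stage_strides))
    stop("need one channel width per tap point")
  structure(list(name = name, stage_strides = stage_strides,
                 stage_channels = stage_channels,
                 pretrained_weights = pretrained_weights),
            class = "bc_backbone_spec")
}

# Convolutional stage: conv/BN/ReLU blocks reducing stride by `factor` (a
# power of two), ending at `cout` channels. A stage with factor >= 4 opens
# with a 5x5/stride-4 convolution — one wide-receptive-field layer instead
# of two stride-2 layers at the most expensive resolutions.
make_stage <- function(cin, cout, factor, extra_conv = FALSE,
                       first_stage = FALSE) {
  layers <- list()
  n_down <- as.integer(round(log2(factor)))
  if (2^n_down != factor) stop("stage stride factor must be a power of two")
  steps <- if (n_down >= 2L) c(4L, rep(2L, n_down - 2L)) else rep(2L, n_down)
  widths <- if (length(steps) > 1L)
    c(pmax(8L, as.integer(cout / 2^((length(steps) - 1L):1L))), cout)
  else cout
  cur <- cin
  for (i in seq_along(steps)) {
    ig <- !(first_stage && i == 1L)
    layers <- c(layers, if (steps[i] == 4L)
      list(nn_conv(cur, widths[i], k = 5L, stride = 4L, pad = 2L, input_grad = ig),
           nn_bn(widths[i]), nn_relu())
    else
      list(nn_conv(cur, widths[i], k = 3L, stride = 2L, pad = 1L, input_grad = ig),
           nn_bn(widths[i]), nn_relu()))
    cur <- widths[i]
  }
  if (extra_conv)
    layers <- c(layers, list(nn_conv(cur, cout, k = 3L, stride = 1L, pad = 1L),
                             nn_bn(cout), nn_relu()))
  layers
}

make_fuse_block <- function(high_ch, low_ch) {
  list(proj = nn_conv(high_ch, 2L * low_ch, k = 1L),
       proj_bn = nn_bn(2L * low_ch),
       up = nn_upsample2(),
       red = nn_conv(3L * low_ch, 2L * low_ch, k = 1L),
       red_bn = nn_bn(2L * low_ch),
       red_relu = nn_relu())
}

#' Build the blockwise-classification counting network
#'
#' Assembles the staged backbone, `n_layers - 1` multilayer fusion blocks
#' applied from the deepest tap downward, and the redundant head (unpadded
#' average pooling plus a 1x1 projection to class logits). The head emits
#' one cell per 32x32 input patch at a stride equal to the stride of the
#' shallowest fused tap (8 when fusing three layers).
#'
#' @param backbone A [backbone_spec()].
#' @param n_layers Number of taps fused (1 = deepest tap only). Default 3.
#' @param n_out Number of output channels: `c_max + 1` class logits in
#'   classification mode, 1 in regression mode.
#' @param mode `"classification"` or `"regression"`.
#' @param seed Integer seed for Xavier initialization.
#' @return An object of class `"bc_network"`.
#' @export
build_network <- function(backbone = backbone_spec("tiny"), n_layers = 3L,
                          n_out = 51L, mode = c("classification", "regression"),
                          seed = 1L) {
  mode <- match.arg(mode)
  n_taps <- length(backbone$stage_strides)
  n_layers <- as.integer(n_layers)
  if (n_layers < 1L || n_layers > n_taps)
    stop(sprintf("n_layers must be in 1..%d (taps available)", n_taps))
  if (mode == "regression") n_out <- 1L
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)

  extra <- backbone$name == "mixnet_l"
  stages <- list()
  prev_ch <- 3L; prev_stride <- 1L
  for (k in seq_len(n_taps)) {
    stages[[k]] <- make_stage(prev_ch, backbone$stage_channels[k],
                              backbone$stage_strides[k] %/% prev_stride,
                              extra_conv = extra, first_stage = k == 1L)
    prev_ch <- backbone$stage_channels[k]
    prev_stride <- backbone$stage_strides[k]
  }

  fuse <- list()
  high_ch <- backbone$stage_channels[n_taps]
  if (n_layers > 1L) {
    for (k in (n_taps - 1L):(n_taps - n_layers + 1L)) {
      low_ch <- backbone$stage_channels[k]
      fuse[[length(fuse) + 1L]] <- make_fuse_block(high_ch, low_ch)
      high_ch <- 2L * low_ch
    }
  }
  fused_stride <- backbone$stage_strides[n_taps - n_layers + 1L]
  pool_k <- max(1L, 32L %/% fused_stride)

  head <- list(pool = nn_avgpool(pool_k),
               proj = nn_conv(high_ch, as.integer(n_out), k = 1L))

  model <- structure(list(
    backbone = backbone, n_layers = n_layers, mode = mode,
    n_out = as.integer(n_out), fused_stride = fused_stride, pool_k = pool_k,
    stages = stages, fuse = fuse, head = head, seed = as.integer(seed)
  ), class = "bc_network")
  model$layers <- network_layers(model)
  if (!is.null(backbone$pretrained_weights)) {
    ck <- readRDS(backbone$pretrained_weights)
    restore_params(model$layers, ck$params)
  }
  model
}

network_layers <- function(model) {
  ls <- unlist(model$stages, recursive = FALSE)
  for (b in model$fuse)
    ls <- c(ls, list(b$proj, b$proj_bn, b$red, b$red_bn))
  c(ls, list(model$head$proj))
}

#' @export
print.bc_network <- function(x, ...) {
  np <- sum(vapply(collect_params(x$layers), length, 1L))
  cat(sprintf("Fully convolutional counter (%s backbone, %d fused layer(s), %s mode)\n",
              x$backbone$name, x$n_layers, x$mode))
  cat(sprintf("  taps at strides %s; head at stride %d (32x32 patches, pool %d); %d output channel(s); %d parameters\n",
              paste(x$backbone$stage_strides, collapse = "/"),
              x$fused_stride, x$pool_k, x$n_out, np))
  invisible(x)
}

# images come in as (H, W, 3) rasters; features run channels-first
as_input <- function(image) {
  d <- dim(image)
  if (length(d) == 3L) array(aperm(image, c(3L, 1L, 2L)), c(d[3L], d[1L], d[2L], 1L))
  else aperm(image, c(3L, 1L, 2L, 4L))
}

as_batch <- function(x) {
  if (length(dim(x)) == 3L) array(x, c(dim(x), 1L)) else x
}

stage_forward <- function(stage, x, train) {
  for (l in stage) x <- l$forward(x, train)
  x
}

stage_backward <- function(stage, dy) {
  for (l in rev(stage)) dy <- l$backward(dy)
  dy
}

#' Extract the backbone feature pyramid
#'
#' Runs the staged extractor and returns the tapped feature maps, ordered
#' shallow (low stride) to deep (high stride). Input spatial dimensions must
#' be divisible by the deepest stride; pad beforehand if they are not.
#'
#' @param model A [build_network()] model.
#' @param image `(H, W, 3)` array (or `(H, W, 3, N)` batch) of normalized
#'   pixel values.
#' @param train Use batch statistics (TRUE) or running statistics (FALSE)
#'   in normalization layers.
#' @return List of `(channels, H/stride, W/stride, N)` arrays.
#' @export
extract_features <- function(model, image, train = FALSE) {
  x <- if (dim(image)[1L] == 3L && length(dim(image)) == 4L) image else as_input(image)
  d <- dim(x)
  smax <- max(model$backbone$stage_strides)
  if (d[2L] %% smax != 0L || d[3L] %% smax != 0L)
    stop(sprintf("input dims (%d x %d) must be divisible by %d; pad the image first",
                 d[2L], d[3L], smax))
  taps <- vector("list", length(model$stages))
  for (k in seq_along(model$stages)) {
    x <- stage_forward(model$stages[[k]], x, train)
    taps[[k]] <- x
  }
  taps
}

#' One multilayer-fusion step
#'
#' Fuses a high-level feature map with the next lower-level map: the high
#' map is channel-projected (1x1 convolution + batch normalization) to twice
#' the low map's channel count, bilinearly upsampled x2, concatenated with
#' the low map, and reduced by a 1x1 convolution + batch normalization +
#' rectifier back to twice the low channel count, so high-level semantics
#' dominate the fused map.
#'
#' @param block Fuse-block layer bundle (an element of `model$fuse`).
#' @param high `(C1, H1, W1, N)` array (channels first).
#' @param low `(C2, 2*H1, 2*W1, N)` array.
#' @param train Batch-statistics flag as in [extract_features()].
#' @return `(2*C2, 2*H1, 2*W1, N)` array.
#' @export
fuse_step <- function(block, high, low, train = FALSE) {
  dh <- dim(as_batch(high)); dl <- dim(as_batch(low))
  if (dl[2L] != 2L * dh[2L] || dl[3L] != 2L * dh[3L])
    stop("low-level map dims must be exactly double the high-level dims")
  high <- as_batch(high); low <- as_batch(low)
  h <- block$proj_bn$forward(block$proj$forward(high, train), train)
  h <- block$up$forward(h, train)
  z <- abind4(h, low)
  block$red_relu$forward(block$red_bn$forward(block$red$forward(z, train), train), train)
}

fuse_step_backward <- function(block, dy) {
  dz <- block$red$backward(block$red_bn$backward(block$red_relu$backward(dy)))
  s <- 2L * dim(dz)[1L] %/% 3L              # concat was [projected high | low]
  dh <- dz[seq_len(s), , , , drop = FALSE]
  dlow <- dz[(s + 1L):dim(dz)[1L], , , , drop = FALSE]
  dh <- block$proj$backward(block$proj_bn$backward(block$up$backward(dh)))
  list(high = dh, low = dlow)
}

# concatenate two channels-first tensors along the channel dimension
abind4 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1L] + db[1L], da[2L], da[3L], da[4L]))
  out[seq_len(da[1L]), , , ] <- a
  out[da[1L] + seq_len(db[1L]), , , ] <- b
  out
}

#' Fuse the feature pyramid
#'
#' Applies [fuse_step()] iteratively from the deepest tap downward over
#' `model$n_layers` taps; with a single layer the deepest map is returned
#' unchanged. The output stride is the stride of the shallowest fused tap
#' (8 when fusing three taps at strides 8/16/32).
#'
#' @param model A [build_network()] model.
#' @param taps Feature pyramid from [extract_features()].
#' @param train Batch-statistics flag.
#' @return Fused `(channels, H/stride, W/stride, N)` array.
#' @export
fuse_pyramid <- function(model, taps, train = FALSE) {
  n_taps <- length(taps)
  cur <- taps[[n_taps]]
  if (model$n_layers > 1L)
    for (i in seq_along(model$fuse)) {
      low <- taps[[n_taps - i]]
      cur <- fuse_step(model$fuse[[i]], cur, low, train)
    }
  cur
}

#' Redundant classification head
#'
#' Unpadded average pooling (kernel `model$pool_k`, stride 1) aggregates
#' stride-8 features into one cell per overlapping 32x32 input patch, a 1x1
#' convolution maps each cell to count-interval logits, and a per-cell
#' softmax yields class probabilities. For an input of `H x W` pixels at
#' stride 8 the class grid is `(H/8 - 3) x (W/8 - 3)`.
#'
#' @param model A [build_network()] model.
#' @param fused Fused feature map from [fuse_pyramid()].
#' @param train Batch-statistics flag.
#' @return List with `logits` and (classification mode) `probs`, both
#'   `(n_out, Hg, Wg, N)` arrays.
#' @export
redundant_head <- function(model, fused, train = FALSE) {
  z <- model$head$pool$forward(fused, train)
  logits <- model$head$proj$forward(z, train)
  if (model$mode == "classification")
    list(logits = logits, probs = softmax_channels(logits))
  else
    list(logits = logits, probs = NULL)
}

#' Full network forward pass
#'
#' @param model A [build_network()] model.
#' @param image `(H, W, 3)` array or `(H, W, 3, N)` batch; dims divisible
#'   by the deepest backbone stride.
#' @param train Batch-statistics flag (TRUE during optimization).
#' @return List with `logits`, `probs` (classification only), and `taps`.
#' @export
network_forward <- function(model, image, train = FALSE) {
  taps <- extract_features(model, image, train)
  fused <- fuse_pyramid(model, taps, train)
  out <- redundant_head(model, fused, train)
  out$taps <- taps
  out$fused <- fused
  out
}

# Backward pass mirroring network_forward; dlogits from the loss.
network_backward <- function(model, dlogits) {
  dz <- model$head$proj$backward(dlogits)
  dfused <- model$head$pool$backward(dz)
  n_taps <- length(model$stages)
  dtaps <- vector("list", n_taps)
  cur <- dfused
  if (model$n_layers > 1L) {
    for (i in rev(seq_along(model$fuse))) {
      g <- fuse_step_backward(model$fuse[[i]], cur)
      dtaps[[n_taps - i]] <- g$low
      cur <- g$high
    }
  }
  dtaps[[n_taps]] <- cur
  g <- NULL
  for (k in rev(seq_len(n_taps))) {
    if (!is.null(dtaps[[k]])) g <- if (is.null(g)) dtaps[[k]] else g + dtaps[[k]]
    g <- stage_backward(model$stages[[k]], g)
  }
  invisible(NULL)
}

#' Argmax decode of a class-probability map
#'
#' Per-cell argmax over the class dimension; ties are broken toward the
#' lower class index so outputs are deterministic.
#'
#' @param probs `(C, Hg, Wg)` or `(C, Hg, Wg, 1)` probability array.
#' @param grid Optional [patch_grid()] carried onto the result.
#' @param spec Optional [quantizer_spec()] carried onto the result.
#' @return Integer matrix of class indices, or a `"bc_class_map"` when both
#'   `grid` and `spec` are given.
#' @export
predict_class_map <- function(probs, grid = NULL, spec = NULL) {
  if (length(dim(probs)) == 4L) probs <- probs[, , , 1L, drop = TRUE]
  d <- dim(probs)
  m <- matrix(probs, nrow = d[1L])
  cls <- matrix(max.col(t(m), ties.method = "first") - 1L, d[2L], d[3L])
  if (!is.null(grid) && !is.null(spec))
    structure(list(values = cls, grid = grid, spec = spec), class = "bc_class_map")
  else cls
}

# ---- checkpoints ------------------------------------------------------------

#' Save / load a model checkpoint
#'
#' A checkpoint is a single RDS file with the flattened parameter arrays and
#' a metadata block (backbone spec, fused-layer count, quantizer, density
#' sigma, normalization statistics, mode, seed) sufficient to rebuild the
#' network and run inference.
#'
#' @param model A `"bc_network"` (or fitted [blockcount()] object).
#' @param path File path.
#' @param meta Extra metadata list stored alongside (quantizer, sigma,
#'   normalization stats, ...).
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns a list with the rebuilt `model` and the `meta` block.
#' @export
save_checkpoint <- function(model, path, meta = list()) {
  stopifnot(inherits(model, "bc_network"))
  ck <- list(params = collect_params(model$layers),
             backbone = model$backbone, n_layers = model$n_layers,
             mode = model$mode, n_out = model$n_out, seed = model$seed,
             meta = meta)
  saveRDS(ck, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  bk <- ck$backbone
  bk$pretrained_weights <- NULL
  model <- build_network(bk, n_layers = ck$n_layers, n_out = ck$n_out,
                         mode = ck$mode, seed = ck$seed)
  restore_params(model$layers, ck$params)
  list(model = model, meta = ck$meta)
}
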