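# Backbone taps, multilayer fusion, redundant head, argmax decode.

test_that("feature pyramid taps follow the stage strides", {
  m <- build_network(backbone_spec("tiny"), n_layers = 3, n_out = 5, seed = 2)
  x <- array(stats::rnorm(3 * 128 * 128), c(3, 128, 128, 1))
  taps <- extract_features(m, x)
  expect_equal(vapply(taps, function(t) dim(t)[2], 1), c(16, 8, 4))
  expect_equal(vapply(taps, function(t) dim(t)[1], 1),
               as.numeric(m$backbone$stage_channels))
  bad <- array(0, c(3, 100, 128, 1))
  expect_error(extract_features(m, bad), "pad")
})

test_that("fuse_step honors the 2H x 2W x 2C2 output contract", {
  blk <- blockcount:::make_fuse_block(8L, 4L)
  high <- array(stats::rnorm(8 * 4 * 4), c(8, 4, 4, 1))
  low <- array(stats::rnorm(4 * 8 * 8), c(4, 8, 8, 1))
  out <- fuse_step(blk, high, low)
  expect_equal(dim(out), c(8L, 8L, 8L, 1L))
  expect_error(fuse_step(blk, high, array(0, c(4, 4, 4, 1))), "double")
})

test_that("a pass-through reduction reproduces the upsampled projection", {
  blk <- blockcount:::make_fuse_block(6L, 4L)
  # reduction passes the 8 projected-high channels, zeroes the 4 low ones
  blk$red$W <- cbind(diag(8), matrix(0, 8, 4))
  blk$red$b <- rep(0, 8)
  blk$proj$b <- rep(5, 8)              # keep activations positive for ReLU
  high <- array(abs(stats::rnorm(6 * 4 * 4)), c(6, 4, 4, 1))
  low <- array(stats::rnorm(4 * 8 * 8), c(4, 8, 8, 1))
  expected <- blk$up$forward(
    blk$proj_bn$forward(blk$proj$forward(high, FALSE), FALSE), FALSE)
  got <- fuse_step(blk, high, low, train = FALSE)
  # the reduction's normalization layer rescales by 1/sqrt(1 + eps)
  expect_equal(got, expected, tolerance = 1e-4)
})

test_that("fusing 1, 2 or 3 layers yields output strides 32, 16, 8", {
  x <- array(stats::rnorm(3 * 96 * 96), c(3, 96, 96, 1))
  for (cfg in list(c(1, 32), c(2, 16), c(3, 8))) {
    m <- build_network(backbone_spec("tiny"), n_layers = cfg[1], n_out = 4, seed = 3)
    fused <- fuse_pyramid(m, extract_features(m, x, train = TRUE), train = TRUE)
    expect_equal(96 / dim(fused)[2], cfg[2])
  }
  expect_error(build_network(backbone_spec("tiny"), n_layers = 4), "1..3")
})

test_that("redundant head emits one normalized cell per 32x32/8 patch", {
  m <- build_network(backbone_spec("tiny"), n_layers = 3, n_out = 7, seed = 4)
  x <- array(stats::rnorm(3 * 96 * 96), c(3, 96, 96, 1))
  out <- network_forward(m, x, train = TRUE)
  expect_equal(dim(out$logits), c(7L, 9L, 9L, 1L))     # 96/8 - 3
  sums <- apply(out$probs, c(2, 3, 4), sum)
  expect_true(max(abs(sums - 1)) < 1e-5)

  # spatially constant fused input -> spatially constant probabilities
  # (pooling and the 1x1 projection are translation invariant)
  fc <- array(0.7, c(48, 12, 12, 1))
  pc <- redundant_head(m, fc)$probs
  expect_true(max(apply(pc, 1, function(ch) diff(range(ch)))) < 1e-10)

  small <- build_network(backbone_spec("tiny"), n_layers = 3, n_out = 4, seed = 1)
  expect_error(
    redundant_head(small, array(0, c(48, 2, 2, 1))), ">= 4")
})

test_that("shape contract holds across input sizes", {
  m <- build_network(backbone_spec("tiny"), n_layers = 3, n_out = 4, seed = 5)
  for (hw in list(c(64, 96), c(128, 64))) {
    out <- network_forward(m, array(0.1, c(3, hw[1], hw[2], 1)), train = TRUE)
    expect_equal(dim(out$logits)[2:3], c(hw[1] / 8 - 3, hw[2] / 8 - 3))
  }
})

test_that("forward passes are deterministic in eval mode", {
  m <- build_network(backbone_spec("tiny"), n_layers = 3, n_out = 5, seed = 6)
  x <- array(stats::rnorm(3 * 64 * 64), c(3, 64, 64, 1))
  expect_identical(network_forward(m, x)$logits, network_forward(m, x)$logits)
})

test_that("argmax decode breaks ties toward the lower class", {
  p <- array(0, c(3, 2, 2))
  p[2, 1, 1] <- 1; p[1, 1, 2] <- 1; p[3, 2, 1] <- 1; p[1, 2, 2] <- 1
  expect_equal(predict_class_map(p), matrix(c(1L, 2L, 0L, 0L), 2, 2))

  uni <- array(1 / 4, c(4, 3, 3))
  expect_true(all(predict_class_map(uni) == 0L))

  set.seed(8)
  r <- array(stats::runif(5 * 4 * 4), c(5, 4, 4))
  oracle <- apply(r, c(2, 3), which.max) - 1L
  expect_equal(predict_class_map(r), oracle)
})

test_that("checkpoints round-trip weights and metadata", {
  m <- build_network(backbone_spec("tiny"), n_layers = 2, n_out = 6, seed = 7)
  x <- array(stats::rnorm(3 * 64 * 64), c(3, 64, 64, 1))
  ref <- network_forward(m, x)$logits
  path <- tempfile(fileext = ".rds")
  save_checkpoint(m, path, meta = list(note = "fixture"))
  got <- load_checkpoint(path)
  expect_equal(network_forward(got$model, x)$logits, ref)
  expect_equal(got$meta$note, "fixture")
})
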