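# Whole-image prediction and the decode path.

test_that("a rig emitting class 0 everywhere predicts a zero total", {
  rig <- rigged_counter(function(img) {
    g <- patch_grid(nrow(img), ncol(img), 32, 8)
    matrix(0L, g$n_rows, g$n_cols)
  })
  sc <- tiny_scene(seed = 81, size = 128, n = 10)
  p <- predict(rig, sc$image)
  expect_equal(p$total, 0)
  expect_true(all(p$pixel_map == 0))
})

test_that("ground-truth class maps decode to totals near the true count", {
  qs <- quantizer_spec(s = 0.1, q = -2, c_max = 60)
  for (seed in c(5, 6)) {
    sc <- render_scene(scene_spec(size = 256, n_plants = 50,
                                  plant_radius = c(6, 14),
                                  border_margin = 52, seed = seed))
    rig <- rigged_counter(function(img) {
      enc <- encode_image(sc$annotation, dim(img)[1:2], spec = qs)
      enc$classes$values
    }, quantizer = qs)
    p <- predict(rig, sc$image)
    expect_lt(abs(p$total - 50) / 50, (exp(0.1) - 1) / 2)
  }
})

test_that("predictions are deterministic and consistent with their maps", {
  sc <- tiny_scene(seed = 83, size = 96, n = 8)
  cfg <- train_config(downsample_ratio = 1, crop = 64, batch = 2, epochs = 1,
                      seed = 5)
  f <- blockcount(list(sc, tiny_scene(84, 96, 8)), config = cfg, verbose = FALSE)
  p1 <- predict(f, sc$image); p2 <- predict(f, sc$image)
  expect_equal(p1$total, p2$total)
  expect_equal(p1$total, sum(p1$pixel_map), tolerance = 1e-4)
  expect_equal(dim(p1$pixel_map), c(96L, 96L))
})

test_that("unaligned images are padded and cropped back transparently", {
  rig <- rigged_counter(function(img) {
    g <- patch_grid(nrow(img), ncol(img), 32, 8)
    matrix(2L, g$n_rows, g$n_cols)
  })
  sc <- tiny_scene(seed = 85, size = 128, n = 6)
  aligned <- predict(rig, sc$image)
  # identical content padded by reflection must not change the total
  repad <- predict(rig, blockcount:::reflect_pad(sc$image, 0L, 0L))
  expect_lt(abs(aligned$total - repad$total), 1e-6)
  # a 120 x 123 crop runs through the pad-forward-crop path
  odd <- predict(rig, sc$image[1:120, 1:123, , drop = FALSE])
  expect_equal(dim(odd$pixel_map), c(120L, 123L))
  expect_true(is.finite(odd$total))
})

test_that("grayscale inputs are replicated and empty inputs rejected", {
  rig <- rigged_counter(function(img) {
    g <- patch_grid(nrow(img), ncol(img), 32, 8)
    matrix(0L, g$n_rows, g$n_cols)
  })
  gray <- matrix(stats::runif(64 * 64), 64, 64)
  expect_warning(p <- predict(rig, gray), "grayscale")
  expect_equal(p$total, 0)
  expect_error(predict(rig, array(0, c(0, 10, 3))), "zero-size")
})

test_that("predict_batch preserves order and survives per-image failures", {
  rig <- rigged_counter(function(img) {
    if (nrow(img) < 64) stop("too small to trust")
    g <- patch_grid(nrow(img), ncol(img), 32, 8)
    matrix(1L, g$n_rows, g$n_cols)
  })
  imgs <- list(a = tiny_scene(91, 96, 5)$image,
               b = tiny_scene(92, 96, 5)$image,
               c = tiny_scene(93, 96, 5)$image)
  res <- predict_batch(rig, imgs)
  expect_equal(res$summary$image, c("a", "b", "c"))
  singles <- vapply(imgs, function(i) predict(rig, i)$total, 1)
  expect_equal(res$summary$total, unname(singles))
  expect_equal(res$summary$total_rounded, round(res$summary$total))

  imgs$b <- imgs$b[1:32, 1:32, , drop = FALSE]   # pads to 32 < 64: rig fails
  expect_warning(res2 <- predict_batch(rig, imgs), "failed")
  expect_true(is.na(res2$summary$total[2]))
  expect_false(anyNA(res2$summary$total[c(1, 3)]))

  expect_error(predict_batch(rig, list()), "empty")
})
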