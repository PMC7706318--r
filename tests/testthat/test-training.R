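# Normalization, sample building, losses, the SGD loop.

test_that("normalization statistics match population moments", {
  flat <- array(0.5, c(20, 20, 3))
  expect_warning(st <- compute_normalization(list(flat)), "std")
  expect_equal(st$mean, rep(0.5, 3))
  expect_equal(st$std, rep(1, 3))

  set.seed(21)
  noise <- array(stats::runif(200 * 200 * 3), c(200, 200, 3))
  st2 <- compute_normalization(list(noise))
  expect_equal(st2$mean, rep(0.5, 3), tolerance = 0.01)
  expect_equal(st2$std, rep(sqrt(1 / 12), 3), tolerance = 0.01)

  a <- array(stats::runif(32 * 32 * 3), c(32, 32, 3))
  b <- array(stats::runif(48 * 48 * 3), c(48, 48, 3))
  expect_equal(compute_normalization(list(a, b)),
               compute_normalization(list(b, a)))
  expect_error(compute_normalization(list()), "empty")
})

test_that("make_sample is seed-deterministic and grid-consistent", {
  sc <- tiny_scene(seed = 31, size = 160, n = 10)
  cfg <- train_config(downsample_ratio = 1, crop = 96, epochs = 1, seed = 1)
  set.seed(99); s1 <- make_sample(sc$image, sc$annotation, cfg)
  set.seed(99); s2 <- make_sample(sc$image, sc$annotation, cfg)
  expect_identical(s1$offset, s2$offset)
  expect_identical(s1$image, s2$image)
  expect_equal(s1$counts$values, s2$counts$values)
  expect_equal(dim(s1$classes$values), c(96 / 8 - 3, 96 / 8 - 3))

  # classes are the quantized counts: mode parity before/after quantization
  expect_equal(s1$classes$values,
               matrix(quantize_count(as.vector(s1$counts$values),
                                     s1$classes$spec),
                      nrow(s1$counts$values)))

  # a dot-free scene yields an all-zero target
  empty <- render_scene(scene_spec(size = 128, n_plants = 0, seed = 5))
  cfg2 <- train_config(downsample_ratio = 1, crop = 128, epochs = 1)
  s3 <- make_sample(empty$image, empty$annotation, cfg2)
  expect_true(all(s3$classes$values == 0))
})

test_that("a 384 crop at quarter resolution yields the 45 x 45 target grid", {
  sc <- render_scene(scene_spec(size = c(392, 392), n_plants = 30,
                                plant_radius = c(5, 9), seed = 8))
  # image plays the role of a 1568 px native capture already downsampled
  cfg <- train_config(downsample_ratio = 1, crop = 384, epochs = 1)
  s <- make_sample(sc$image, sc$annotation, cfg)
  expect_equal(dim(s$classes$values), c(45L, 45L))
})

test_that("classification loss matches its closed forms and an oracle", {
  C <- 5
  tgt <- matrix(c(0L, 3L), 1, 2)
  onehot <- array(0, c(C, 1, 2))
  onehot[1, 1, 1] <- 1; onehot[4, 1, 2] <- 1
  expect_equal(classification_loss(onehot, tgt), 0)

  uni <- array(1 / C, c(C, 1, 2))
  expect_equal(classification_loss(uni, tgt), log(C))

  set.seed(13)
  p <- array(stats::runif(C * 3 * 4), c(C, 3, 4))
  p <- sweep(p, c(2, 3), apply(p, c(2, 3), sum), "/")
  t2 <- matrix(sample(0:(C - 1), 12, TRUE), 3, 4)
  hand <- 0
  for (i in 1:3) for (j in 1:4) hand <- hand - log(p[t2[i, j] + 1, i, j])
  expect_equal(classification_loss(p, t2), hand / 12, tolerance = 1e-7)

  expect_error(classification_loss(p, matrix(0L, 2, 2)), "misaligned")
})

test_that("regression loss is the mean absolute cell difference", {
  a <- matrix(stats::rnorm(12), 3, 4)
  expect_equal(regression_loss(a, a), 0)
  expect_equal(regression_loss(a + 0.7, a), 0.7)
  b <- matrix(stats::rnorm(12), 3, 4)
  expect_equal(regression_loss(a, b), mean(abs(a - b)), tolerance = 1e-12)
  expect_error(regression_loss(a, matrix(0, 2, 2)), "misaligned")
})

test_that("loss gradients agree with finite differences on a toy grid", {
  C <- 4
  set.seed(17)
  p <- array(stats::runif(C * 1 * 2, 0.05, 1), c(C, 1, 2))
  p <- sweep(p, c(2, 3), apply(p, c(2, 3), sum), "/")
  tgt <- matrix(c(1L, 3L), 1, 2)
  g <- classification_loss(p, tgt, gradient = TRUE)$gradient
  eps <- 1e-6
  for (j in seq_along(p)) {
    pp <- p; pp[j] <- pp[j] + eps
    pm <- p; pm[j] <- pm[j] - eps
    fd <- (classification_loss(pp, tgt) - classification_loss(pm, tgt)) / (2 * eps)
    expect_equal(g[j], fd, tolerance = 1e-4)
  }

  pred <- matrix(c(0.4, -0.2), 1, 2)
  tgtr <- matrix(c(0.1, 0.3), 1, 2)
  gr <- regression_loss(pred, tgtr, gradient = TRUE)$gradient
  for (j in seq_along(pred)) {
    pp <- pred; pp[j] <- pp[j] + eps
    pm <- pred; pm[j] <- pm[j] - eps
    fd <- (regression_loss(pp, tgtr) - regression_loss(pm, tgtr)) / (2 * eps)
    expect_equal(gr[j], fd, tolerance = 1e-4)
  }
})

test_that("the learning-rate schedule decays by 10 every 200 epochs", {
  cfg <- train_config()
  lr <- vapply(c(1, 199, 200, 201, 400, 401, 600), blockcount:::epoch_lr,
               1, cfg = cfg)
  expect_equal(lr, c(1e-2, 1e-2, 1e-2, 1e-3, 1e-3, 1e-4, 1e-4))
})

test_that("fitting runs, logs and is seed-reproducible", {
  scenes <- lapply(c(41, 42), function(s) tiny_scene(seed = s, size = 64, n = 6))
  cfg <- train_config(downsample_ratio = 1, crop = 64, batch = 2, epochs = 2,
                      lr0 = 1e-2, seed = 7)
  log <- tempfile(fileext = ".jsonl")
  f1 <- blockcount(scenes, config = cfg, log_path = log, verbose = FALSE)
  expect_s3_class(f1, "blockcount")
  expect_equal(nrow(f1$history), 2L)
  expect_true(all(is.finite(f1$history$loss)))
  expect_equal(length(readLines(log)), 2L)

  f2 <- blockcount(scenes, config = cfg, verbose = FALSE)
  expect_equal(f1$history$loss[1], f2$history$loss[1])
  expect_identical(lapply(f1$epoch1_samples, `[[`, "offset"),
                   lapply(f2$epoch1_samples, `[[`, "offset"))
})

test_that("classification and regression consume identical crop streams", {
  scenes <- lapply(c(51, 52), function(s) tiny_scene(seed = s, size = 96, n = 8))
  mk <- function(mode) blockcount(
    scenes, config = train_config(downsample_ratio = 1, crop = 64, batch = 2,
                                  epochs = 1, seed = 3, mode = mode),
    verbose = FALSE)
  fc <- mk("classification"); fr <- mk("regression")
  expect_identical(lapply(fc$epoch1_samples, function(e) e[c("index", "offset")]),
                   lapply(fr$epoch1_samples, function(e) e[c("index", "offset")]))
})

test_that("training reduces the loss on a fixed small set", {
  scenes <- lapply(c(61, 62, 63, 64),
                   function(s) tiny_scene(seed = s, size = 64, n = 8))
  cfg <- train_config(downsample_ratio = 1, crop = 64, batch = 4, epochs = 25,
                      lr0 = 5e-3, seed = 11)
  f <- blockcount(scenes, config = cfg, verbose = FALSE)
  expect_lt(mean(utils::tail(f$history$loss, 3)),
            mean(utils::head(f$history$loss, 3)))
})

test_that("validation tracking keeps the best epoch", {
  scenes <- lapply(71:74, function(s) tiny_scene(seed = s, size = 64, n = 6))
  cfg <- train_config(downsample_ratio = 1, crop = 64, batch = 2, epochs = 2,
                      seed = 13)
  f <- blockcount(scenes, config = cfg, validation = c(3L, 4L), verbose = FALSE)
  expect_true(all(is.finite(f$history$val_mae)))
  expect_false(is.na(f$best_epoch))
  expect_equal(f$n_train, 2L)
})
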