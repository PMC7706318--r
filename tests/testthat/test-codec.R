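# Dot rasterization, density maps, count maps, deredundancy.

test_that("rasterize_dots places, accumulates and clamps points", {
  expect_equal(rasterize_dots(NULL, c(8, 8)), matrix(0, 8, 8))

  g <- rasterize_dots(cbind(3.2, 5.7), c(8, 8))
  expect_equal(sum(g), 1)
  expect_equal(g[7, 4], 1)             # 0-based (row 6, col 3)

  g2 <- rasterize_dots(rbind(c(2, 2), c(2, 2)), c(4, 4))
  expect_equal(g2[3, 3], 2)
  expect_equal(sum(g2), 2)

  # scaling rescales coordinates before rounding
  g3 <- rasterize_dots(cbind(10, 20), c(8, 8), scale = 0.25)
  expect_equal(g3[6, 4], 1)            # (x=2.5, y=5) -> col 3, row 6 (1-based)

  expect_warning(g4 <- rasterize_dots(cbind(12, 3), c(8, 8)), "clamped")
  expect_equal(sum(g4), 1)
  expect_equal(g4[4, 8], 1)

  expect_error(rasterize_dots(cbind(-1, 2), c(8, 8)), "negative")
  expect_error(rasterize_dots(cbind(1, 2), c(0, 8)))
})

test_that("density maps conserve unit mass per dot everywhere", {
  g <- matrix(0, 33, 33); g[17, 17] <- 1
  d <- density_from_dots(g, 4)
  expect_equal(sum(d), 1, tolerance = 1e-9)
  expect_equal(which.max(d), which.max(g))

  corner <- matrix(0, 16, 16); corner[1, 1] <- 1
  expect_equal(sum(density_from_dots(corner, 4)), 1, tolerance = 1e-9)

  expect_error(density_from_dots(g, -1), "sigma")
  expect_error(density_from_dots(g, 4, truncation_radius = 5), "truncation")
})

test_that("density map matches the per-dot brute-force oracle", {
  set.seed(42)
  g <- matrix(0, 64, 64)
  at <- sample(64 * 64, 7)
  g[at] <- 1
  d <- density_from_dots(g, 4)
  expect_equal(sum(d), 7, tolerance = 1e-6)
  expect_equal(d, bf_density(g, 4), tolerance = 1e-10)
})

test_that("count maps sum density blockwise, overlapping or not", {
  u <- matrix(0.03, 16, 16)
  cm <- count_map_from_density(u, block = 8, stride = 8)
  expect_equal(dim(cm$values), c(2L, 2L))
  expect_true(all(abs(cm$values - 64 * 0.03) < 1e-12))

  cm2 <- count_map_from_density(u, block = 8, stride = 4)
  expect_equal(dim(cm2$values), c(3L, 3L))
  expect_true(all(abs(cm2$values - 64 * 0.03) < 1e-12))

  set.seed(7)
  d <- matrix(runif(40 * 40), 40, 40)
  cm3 <- count_map_from_density(d, block = 32, stride = 8)
  expect_equal(dim(cm3$values), c(2L, 2L))
  expect_equal(cm3$values, bf_count_map(d, 32, 8), tolerance = 1e-9)

  expect_error(count_map_from_density(matrix(1, 16, 16), block = 32),
               "at least 32")
})

test_that("non-overlapping count maps partition the density mass", {
  sc <- tiny_scene(seed = 9, size = 128, n = 15)
  dens <- density_from_dots(rasterize_dots(sc$annotation$points, c(128, 128)), 4)
  cm <- count_map_from_density(dens, block = 32, stride = 32)
  expect_equal(sum(cm$values), sum(dens), tolerance = 1e-6)
  expect_equal(total_count(cm), 15, tolerance = 1e-6)
})

test_that("coverage map is the outer product of 1-D profiles", {
  g <- patch_grid(48, 56, block = 16, stride = 8)
  cov <- coverage_map(g)
  expect_equal(dim(cov), c(48L, 56L))
  # interior coverage equals (block/stride)^2
  expect_true(all(cov[17:32, 17:40] == 4))
  expect_true(all(cov >= 1))           # 48, 56 align with the stride
})

test_that("deredundancy averages overlapping patch counts per pixel", {
  one <- new_count_map(matrix(4), patch_grid(4, 4, block = 4, stride = 4))
  px <- deredundancy(one)
  expect_true(all(abs(px - 0.25) < 1e-12))
  expect_equal(attr(px, "total"), 4)

  # uniform overlapping field: interior pixels get k / block^2
  g <- patch_grid(64, 64, block = 32, stride = 8)
  uni <- new_count_map(matrix(5, g$n_rows, g$n_cols), g)
  pxu <- deredundancy(uni)
  expect_true(all(abs(pxu[25:40, 25:40] - 5 / 1024) < 1e-12))

  set.seed(11)
  g2 <- patch_grid(12, 12, block = 8, stride = 4)
  cm <- new_count_map(matrix(runif(4), 2, 2), g2)
  expect_equal(deredundancy(cm),
               bf_deredundancy(cm$values, 8, 4, 12, 12),
               tolerance = 1e-9, ignore_attr = TRUE)

  empty <- new_count_map(matrix(numeric(0), 0, 0), patch_grid(8, 8, 8, 8))
  expect_error(deredundancy(empty), "empty")
})

test_that("margin pixels not covered by any full patch decode to zero", {
  # 70 x 70 with block 32 stride 8: last patch ends at 64; pixels 65..70
  # are uncovered
  g <- patch_grid(70, 70, block = 32, stride = 8)
  cm <- new_count_map(matrix(1, g$n_rows, g$n_cols), g)
  px <- deredundancy(cm)
  expect_true(all(px[65:70, ] == 0))
  expect_true(all(px[, 65:70] == 0))
  expect_true(all(px[1:64, 1:64] > 0))
})

test_that("total_count guards against overlapping grids", {
  expect_equal(total_count(matrix(0, 5, 5)), 0)
  g <- patch_grid(64, 64, block = 32, stride = 8)
  cm <- new_count_map(matrix(1, g$n_rows, g$n_cols), g)
  expect_error(total_count(cm), "deredundancy")
})

test_that("exact patch counts decode to the dot total on interior scenes", {
  for (seed in c(3, 14, 25)) {
    sc <- render_scene(scene_spec(size = 256, n_plants = 40,
                                  plant_radius = c(5, 10),
                                  border_margin = 70, seed = seed))
    dens <- density_from_dots(rasterize_dots(sc$annotation$points, c(256, 256)), 4)
    cm <- count_map_from_density(dens, 32, 8)
    expect_equal(sum(deredundancy(cm)), 40, tolerance = 0.5)
  }
})
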