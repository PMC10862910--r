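test_that("enhancement keeps constant channels and zeroes sub-threshold ones", {
  img <- matrix(7, 30, 40)
  expect_equal(enhance_channel(img), img)         # SD = 0: threshold = mean

  # half 0s / half 1s: mean + 6 SD is far above 1, everything is zeroed
  img2 <- matrix(rep(c(0, 1), 200), 20, 20)
  expect_true(all(enhance_channel(img2) == 0))

  expect_error(enhance_channel(matrix(c(1, NA, 2, 3), 2)), "non-finite")
})

test_that("max filter matches the brute-force sliding-window oracle", {
  set.seed(1)
  x <- matrix(rnorm(25 * 18), 25, 18)
  for (size in c(3, 10))
    expect_equal(proust:::max_filter(x, size), max_filter_oracle(x, size))

  # a single bright pixel dilates to a full 10x10 block
  y <- matrix(0, 40, 40)
  y[20, 20] <- 5
  f <- proust:::max_filter(y, 10)
  expect_equal(sum(f == 5), 100)
  expect_equal(sum(f != 0), 100)
})

test_that("grid extraction preserves constants and area-averages blocks", {
  # constant channel -> constant grids with the same value
  co <- cbind(pixel_row = c(50, 60), pixel_col = c(50, 70))
  imgs <- list(CH1 = matrix(3.5, 120, 120))
  gt <- extract_spot_grids(imgs, co, spot_diameter_px = 40)
  expect_equal(dim(gt$grids), c(2, 1, 48, 48))
  expect_true(all(abs(gt$grids - 3.5) < 1e-12))

  # 96x96 window of 2x2-block checkerboard resized to 48x48 -> all 0.5
  blocks <- matrix(c(0, 1, 1, 0), 2, 2)[rep(1:2, 48), rep(1:2, 48)]
  gt2 <- extract_spot_grids(list(CH1 = blocks), cbind(pixel_row = 48, pixel_col = 48),
                            spot_diameter_px = 96)
  expect_true(all(abs(gt2$grids - 0.5) < 1e-12))
})

test_that("windows overhanging the border are zero-padded", {
  img <- matrix(1, 200, 200)
  gt <- extract_spot_grids(list(a = img), cbind(pixel_row = 5, pixel_col = 100),
                           spot_diameter_px = 100)
  expect_equal(dim(gt$grids)[3:4], c(48, 48))
  g <- gt$grids[1, 1, , ]
  expect_true(any(abs(g) < 1e-12))                # padded region visible
  expect_true(any(abs(g - 1) < 1e-9))             # interior intact
  expect_error(extract_spot_grids(list(a = img), cbind(1, 1), 0), "positive")
})

test_that("range normalisation maps endpoints, midpoints and constants", {
  co <- cbind(pixel_row = 60, pixel_col = 60)
  img <- matrix(0, 120, 120)
  img[1:120, 1:60] <- 255
  img[60, 60] <- 127.5
  gt <- extract_spot_grids(list(a = img, b = matrix(9, 120, 120)), co, 40)
  fake_expr <- structure(list(values = cbind(c(-3, 10))), class = "expression_matrix")
  # give the grid channel the full 0..255 range by construction
  gt$grids[1, 1, 1, 1] <- 0
  gt$grids[1, 1, 1, 2] <- 255
  gt$grids[1, 1, 1, 3] <- 127.5
  gn <- normalize_grid_range(gt, fake_expr)
  expect_equal(gn$grids[1, 1, 1, 1], -3)
  expect_equal(gn$grids[1, 1, 1, 2], 10)
  expect_equal(gn$grids[1, 1, 1, 3], 3.5)
  expect_true(all(abs(gn$grids[1, 2, , ] - 3.5) < 1e-12))  # constant -> midpoint
})

test_that("autoencoder features have the documented shape and are reproducible", {
  sim <- simulate_spots(n_rows = 2, k_domains = 2, n_cols = 4, n_genes = 10, seed = 3)
  gt <- extract_spot_grids(sim$dataset$images, sim$dataset$coords,
                           sim$dataset$spot_diameter_px)
  gt <- normalize_grid_range(gt, matrix(c(-2, 8), 1))
  f1 <- train_image_autoencoder(gt, iters = 30, seed = 5)
  f2 <- train_image_autoencoder(gt, iters = 30, seed = 5)
  # two 5x5 same convs + two 2x-pools: 48 -> 24 -> 12, 4 maps -> F = 576
  expect_equal(dim(f1$features), c(8, 2, 576))
  expect_identical(f1$features, f2$features)      # bitwise, seeded
  expect_lt(f1$loss_history[30], f1$loss_history[1])
})

test_that("autoencoder features are equivariant to spot permutation", {
  sim <- simulate_spots(n_rows = 2, k_domains = 2, n_cols = 3, n_genes = 10, seed = 8)
  gt <- extract_spot_grids(sim$dataset$images, sim$dataset$coords,
                           sim$dataset$spot_diameter_px)
  gt <- normalize_grid_range(gt, matrix(c(-2, 8), 1))
  perm <- c(4, 1, 6, 2, 5, 3)
  gtp <- gt
  gtp$grids <- gt$grids[perm, , , , drop = FALSE]
  # gradient accumulation order differs under permutation, so allow
  # floating-point-level discrepancy only
  f <- train_image_autoencoder(gt, iters = 3, seed = 2)
  fp <- train_image_autoencoder(gtp, iters = 3, seed = 2)
  expect_equal(fp$features, f$features[perm, , , drop = FALSE], tolerance = 1e-8)
})

test_that("constant grids are learned almost exactly", {
  gt <- structure(list(grids = array(2.5, dim = c(6, 1, 48, 48)),
                       features = NULL, channel_names = "c",
                       grid_px = 48L, d = 89L),
                  class = "image_grid_tensor")
  fit <- train_image_autoencoder(gt, iters = 800, seed = 1)
  expect_lt(fit$loss_history[800], 0.01 * fit$loss_history[1])
})
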