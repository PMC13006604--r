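# Classical filters: normalization, median, unsharp, CLAHE, resampling,
# seam-free tiling.

test_that("percentile normalization maps the window to [0,1] and clips", {
  set.seed(3)
  x <- matrix(runif(10000, 2, 7), 100, 100)
  n <- normalize_marker(x, 1, 99)
  qs <- quantile(x, c(0.01, 0.99), names = FALSE)
  expect_equal(n[which(x <= qs[1])], rep(0, sum(x <= qs[1])))
  expect_equal(n[which(x >= qs[2])], rep(1, sum(x >= qs[2])))
  mid <- x > qs[1] & x < qs[2]
  expect_equal(n[mid], ((x - qs[1]) / (qs[2] - qs[1]))[mid])
  # constant plane maps to zeros
  expect_equal(normalize_marker(matrix(5, 4, 4)), matrix(0, 4, 4))
  # a single extreme hot pixel is clipped to 1 and the body rescaled by p99
  y <- matrix(runif(400), 20, 20)
  y[7, 9] <- 1000
  ny <- normalize_marker(y)
  expect_equal(ny[7, 9], 1)
  expect_true(max(ny[-((9 - 1) * 20 + 7)]) <= 1)
  expect_error(normalize_marker(matrix(numeric(0), 0, 0)), "empty")
})

test_that("median filter removes isolated hot pixels and matches brute force", {
  flat <- matrix(0.5, 9, 9)
  flat[5, 5] <- 1
  expect_equal(denoise_median(flat, 1), matrix(0.5, 9, 9))
  # constant image unchanged
  expect_equal(denoise_median(matrix(0.3, 6, 6), 2), matrix(0.3, 6, 6))
  # brute-force oracle on random 9x9, radii 1 and 2
  m <- rand_matrix(9, seed = 17)
  for (r in 1:2) {
    expect_equal(denoise_median(m, r), brute_median(m, r))
  }
})

test_that("unsharp masking is identity at amount 0 and boosts edge strength", {
  m <- rand_matrix(16, seed = 5)
  expect_identical(sharpen_unsharp(m, amount = 0), m)
  expect_equal(sharpen_unsharp(matrix(0.4, 8, 8), 1, 1), matrix(0.4, 8, 8))
  # step edge: Sobel magnitude must not decrease
  step <- cbind(matrix(0.2, 32, 16), matrix(0.8, 32, 16))
  sob <- function(x) {
    gx <- virtualstain:::conv3x3(x, matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1),
                                           3, 3, byrow = TRUE))
    gy <- virtualstain:::conv3x3(x, matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1),
                                           3, 3, byrow = TRUE))
    mean(sqrt(gx^2 + gy^2))
  }
  expect_gte(sob(sharpen_unsharp(step, 1, 1)), sob(step))
})

test_that("adaptive equalization evens out regional dynamic range", {
  set.seed(9)
  tex <- matrix(runif(128 * 128, -0.05, 0.05), 128, 128)
  plane <- tex + cbind(matrix(0.2, 128, 64), matrix(0.8, 128, 64))
  plane <- pmin(pmax(plane, 0), 1)
  eq <- equalize_adaptive(plane, tile = 32, clip = 0.05)
  expect_true(all(eq >= 0 & eq <= 1))
  sd_lo <- sd(eq[, 1:48]); sd_hi <- sd(eq[, 81:128])
  expect_lt(max(sd_lo, sd_hi) / min(sd_lo, sd_hi), 2)
  # entropy of a low-contrast textured plane does not decrease
  low <- 0.45 + 0.1 * rand_matrix(128, seed = 30)
  ent <- function(x) {
    p <- tabulate(pmin(floor(x * 64) + 1, 64), 64)
    p <- p[p > 0] / sum(p)
    -sum(p * log(p))
  }
  expect_gte(ent(equalize_adaptive(low, tile = 32)), ent(low) - 1e-9)
  # constant plane stays constant
  expect_equal(equalize_adaptive(matrix(0.6, 64, 64)), matrix(0.6, 64, 64))
  # sub-tile plane falls back to global equalization with warning
  expect_warning(g <- equalize_adaptive(rand_matrix(16, seed = 2), tile = 64),
                 "global")
  expect_true(all(g >= 0 & g <= 1))
})

test_that("spline resampling follows the pixel-center convention", {
  m <- rand_matrix(12, seed = 6)
  # identity at equal pixel size
  expect_equal(resample_spline(m, 1, pixel_size_um = 1), m)
  # constant stays constant under any factor
  cst <- matrix(0.7, 16, 16)
  for (tgt in c(0.5, 0.33, 2)) {
    out <- resample_spline(cst, tgt, pixel_size_um = 1, order = 3)
    expect_equal(unique(as.vector(out)), 0.7, tolerance = 1e-9)
  }
  # a linear ramp upsampled x2 (order 3) reproduces the ramp in the interior
  ramp <- outer(seq_len(20), seq_len(20), function(i, j) (i + 2 * j) / 80)
  up <- resample_spline(ramp, 0.5, pixel_size_um = 1, order = 3)
  expect_equal(dim(up), c(40, 40))
  ii <- 5:32; jj <- 5:32  # interior output pixels
  expected <- outer(ii, jj, function(i, j) {
    ((i - 1) * 0.5 + 1 + 2 * ((j - 1) * 0.5 + 1)) / 80
  })
  expect_equal(up[ii, jj], expected, tolerance = 1e-6)
  # rgb images update their pixel-size metadata
  rg <- rand_rgb(16, seed = 3, pixel_size_um = 1)
  up2 <- resample_spline(rg, 0.5)
  expect_equal(up2$pixel_size_um, c(0.5, 0.5))
  expect_equal(dim(up2$data)[1:2], c(32, 32))
  expect_error(resample_spline(m, 1000, pixel_size_um = 1), "empty")
})

test_that("tiled execution is bit-identical to untiled for median and unsharp", {
  m <- rand_matrix(256, seed = 8)
  med <- function(x) virtualstain:::median_filter_plane(x, 1L)
  expect_identical(tiled_apply(m, med, tile = 96, margin = 1), med(m))
  sharp <- function(x) sharpen_unsharp(x, 1, 1)
  expect_identical(tiled_apply(m, sharp, tile = 96, margin = 3), sharp(m))
})

test_that("filters preserve range and shape", {
  rg <- rand_rgb(32, seed = 10)
  for (out in list(denoise_median(rg, 1), sharpen_unsharp(rg, 2, 1.5))) {
    expect_equal(dim(out$data), dim(rg$data))
    expect_true(all(out$data >= 0 & out$data <= 1))
  }
})
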