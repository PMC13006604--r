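# Degradation simulator: color deconvolution, noise statistics, resolution
# artifacts, training pairs, sliding window.

test_that("color deconvolution solves the stain basis exactly", {
  sp <- stain_space()
  # pure white has zero optical density in every component
  white <- rgb_image(array(1, c(2, 2, 3)))
  expect_equal(color_deconvolve(white, sp), array(0, c(2, 2, 3)))
  # pixel = exp(-1 * hematoxylin vector) has stain coordinates (1, 0, 0);
  # oracle: independent 3x3 solve of the optical densities
  hvec <- sp$matrix[1, ]
  px <- exp(-hvec)
  img <- rgb_image(array(rep(px, each = 4), c(2, 2, 3)))
  conc <- color_deconvolve(img, sp)
  oracle <- unname(solve(t(sp$matrix), -log(px)))
  expect_equal(oracle, c(1, 0, 0), tolerance = 1e-12)
  expect_equal(conc[1, 1, ], c(1, 0, 0), tolerance = 1e-10)
  # round trip on a random image
  set.seed(2)
  x <- rgb_image(array(runif(300, 0.05, 1), c(10, 10, 3)))
  rec <- color_reconstruct(color_deconvolve(x, sp), sp)
  expect_lt(max(abs(rec$data - x$data)), 1e-4)
  expect_error(stain_space(matrix(1, 3, 3)), "singular")
})

test_that("a fully disabled degradation spec is the identity", {
  x <- rand_rgb(16, seed = 4)
  spec <- degradation_spec(seed = 1)
  expect_equal(apply_noise(x, spec)$data, x$data)
  pair <- make_training_pair(x, spec)
  expect_equal(pair$input$data, pair$target$data)
  expect_equal(pair$target$data, x$data)
})

test_that("hot-pixel counts follow the binomial model", {
  n <- 1000L
  rate <- 0.01
  plane <- matrix(0.5, n, n)
  spec <- degradation_spec(hot_pixel_rate = rate, hot_pixel_value = 1,
                           noise_space = "rgb", seed = 99)
  out <- apply_noise(plane, spec)
  hits <- sum(out == 1)
  expected <- rate * n^2
  sigma <- sqrt(n^2 * rate * (1 - rate))
  expect_lt(abs(hits - expected), 3 * sigma)
})

test_that("Poisson noise preserves the mean within sampling error", {
  set.seed(5)
  plane <- matrix(runif(256 * 256, 0.2, 0.8), 256, 256)
  lambda <- 50
  spec <- degradation_spec(poisson_scale = lambda, noise_space = "rgb",
                           seed = 123)
  out <- apply_noise(plane, spec)
  tol <- 3 * sqrt(mean(plane) / (lambda * length(plane)))
  expect_lt(abs(mean(out) - mean(plane)), tol)
})

test_that("noise in deconvolved space at zero strength is identity within tolerance", {
  x <- rand_rgb(16, seed = 6)
  x$data <- 0.05 + 0.9 * x$data  # keep transmissions representable
  spec <- degradation_spec(noise_space = "hed", seed = 1)
  expect_lt(max(abs(apply_noise(x, spec)$data - x$data)), 1e-4)
  # hed on a bare plane is an error
  expect_error(apply_noise(matrix(0.5, 4, 4), spec), "RGB")
})

test_that("stochastic corruption is a pure function of input, spec and seed", {
  x <- rand_rgb(24, seed = 7)
  spec <- degradation_spec(gaussian_sigma = 0.05, poisson_scale = 100,
                           hot_pixel_rate = 0.01, noise_space = "hsv",
                           seed = 11)
  expect_identical(apply_noise(x, spec)$data, apply_noise(x, spec)$data)
  diff_seed <- apply_noise(x, spec, seed = 12)
  expect_gt(max(abs(diff_seed$data - apply_noise(x, spec)$data)), 0)
})

test_that("resolution artifact produces constant blocks and is idempotent", {
  expect_identical(simulate_resolution_artifact(rand_matrix(8, seed = 2), 1),
                   rand_matrix(8, seed = 2))
  ramp <- matrix(seq(0, 1, length.out = 16), 4, 4)
  out <- simulate_resolution_artifact(ramp, 2)
  for (bi in c(1, 3)) {
    for (bj in c(1, 3)) {
      expect_length(unique(as.vector(out[bi:(bi + 1), bj:(bj + 1)])), 1)
    }
  }
  m <- rand_matrix(32, seed = 3)
  once <- simulate_resolution_artifact(m, 4)
  expect_identical(simulate_resolution_artifact(once, 4), once)
  # unique-value bound
  expect_lte(length(unique(as.vector(once))), ceiling(32 / 4)^2)
  f3 <- simulate_resolution_artifact(rand_matrix(20, seed = 4), 3)
  expect_lte(length(unique(as.vector(f3))), ceiling(20 / 3)^2)
})

test_that("training pairs are seeded-deterministic dihedral transforms", {
  x <- rand_rgb(16, seed = 9)
  spec <- degradation_spec(downscale_range = c(1.5, 3), blur_sigma_range = c(0.5, 1),
                           gaussian_sigma = 0.02, rotate = TRUE, flip = TRUE,
                           jitter = TRUE, seed = 21)
  p1 <- make_training_pair(x, spec)
  p2 <- make_training_pair(x, spec)
  expect_identical(p1$input$data, p2$input$data)
  expect_identical(p1$target$data, p2$target$data)
  # target is one of the 8 dihedral transforms of the clean image
  match_any <- any(vapply(1:8, function(k) {
    tr <- virtualstain:::dihedral_transform(x$data, k)
    identical(dim(tr), dim(p1$target$data)) && all(tr == p1$target$data)
  }, logical(1)))
  expect_true(match_any)
})

test_that("training-pair directories ship a manifest with per-pair seeds", {
  dir <- withr::local_tempdir()
  x <- rand_rgb(24, seed = 2)
  man <- write_training_pairs(x, degradation_spec(downscale_range = c(2, 2),
                                                  gaussian_sigma = 0.02,
                                                  seed = 100), n = 2, dir = dir)
  expect_length(man$pairs, 2)
  expect_equal(vapply(man$pairs, `[[`, numeric(1), "seed"), c(101, 102))
  for (p in man$pairs) {
    expect_true(file.exists(file.path(dir, "degraded", p$input)))
    expect_true(file.exists(file.path(dir, "clean", p$target)))
  }
  expect_true(file.exists(file.path(dir, "manifest.json")))
})

test_that("sliding window blending is exact for agreeing tiles", {
  x <- rand_rgb(50, seed = 13)
  out <- sliding_window_apply(x, 16, 4, identity)
  expect_equal(out$data, x$data)
  # constant-offset fn blends exactly too
  out2 <- sliding_window_apply(x$data[, , 1], 16, 4, function(t) t * 0 + 0.1)
  expect_equal(out2, matrix(0.1, 50, 50), ignore_attr = TRUE)
  # tile count per axis
  expect_equal(attr(out, "tiles"), rep(ceiling((50 - 4) / (16 - 4)), 2))
  # window larger than image: single call
  small <- sliding_window_apply(x$data[, , 1], 128, 16, identity)
  expect_equal(attr(small, "tiles"), c(1L, 1L))
  expect_equal(small, x$data[, , 1], ignore_attr = TRUE)
})
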