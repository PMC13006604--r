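# Shared fixture builders for the test suite.

rand_matrix <- function(n, m = n, seed = 1) {
  set.seed(seed)
  matrix(runif(n * m), n, m)
}

rand_rgb <- function(n, m = n, seed = 1, pixel_size_um = 1) {
  set.seed(seed)
  rgb_image(array(runif(n * m * 3), c(n, m, 3)), pixel_size_um = pixel_size_um)
}

# Single-class profile with explicit color/scaling for closed-form checks.
one_class_profile <- function(color = c(0, 0, 0), scaling = 1) {
  stain_profile("test", list(
    stain_class("a", color = color, scaling = scaling, markers = "m")
  ))
}

stack_of <- function(...) {
  planes <- list(...)
  structure(list(planes = planes), class = "intensity_stack")
}

# Independent re-implementation of the enhancement-efficiency terms:
# direct 2D Sobel convolution and Gaussian high-pass with explicit loops
# over kernel offsets and mirror indexing. Shares no code with the package.
oracle_efficiency_terms <- function(rgb, sigma_hf = 1) {
  a <- if (inherits(rgb, "rgb_image")) rgb$data else rgb
  lum <- 0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3]
  n <- nrow(lum); p <- ncol(lum)
  mirror <- function(i, k) ifelse(i < 1, 1 - i, ifelse(i > k, 2 * k - i + 1, i))
  convolve_k <- function(kern) {
    r <- (nrow(kern) - 1) / 2
    out <- matrix(0, n, p)
    for (di in -r:r) {
      for (dj in -r:r) {
        out <- out + kern[di + r + 1, dj + r + 1] *
          lum[mirror(seq_len(n) + di, n), mirror(seq_len(p) + dj, p)]
      }
    }
    out
  }
  gx <- convolve_k(matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE))
  gy <- convolve_k(matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3, byrow = TRUE))
  edge <- mean(sqrt(gx^2 + gy^2))
  r <- max(1, ceiling(3 * sigma_hf))
  g1 <- exp(-(-r:r)^2 / (2 * sigma_hf^2)); g1 <- g1 / sum(g1)
  blur <- convolve_k(outer(g1, g1))
  noise <- sd(lum - blur)
  list(edge = edge, noise = noise)
}

# Independent brute-force median filter: per-pixel neighborhood sort with
# mirror indexing (edge-repeating reflection), written without any shared
# helper from the package.
brute_median <- function(m, r) {
  n <- nrow(m); p <- ncol(m)
  mirror <- function(i, k) {
    if (i < 1) i <- 1 - i  # reflect across edge, repeating the border
    if (i > k) i <- 2 * k - i + 1
    i
  }
  out <- matrix(0, n, p)
  for (i in seq_len(n)) {
    for (j in seq_len(p)) {
      vals <- c()
      for (di in -r:r) {
        for (dj in -r:r) {
          vals <- c(vals, m[mirror(i + di, n), mirror(j + dj, p)])
        }
      }
      out[i, j] <- sort(vals)[(length(vals) + 1) / 2]
    }
  }
  out
}
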