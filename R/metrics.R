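# Image-quality metrics: the enhancement-efficiency index (ratio of
# relative edge preservation to relative noise retention) and paired
# reference/test quality metrics (PCC, MSE, MS-SSIM, PSNR, EMD).

#' Luminance of an RGB image
#'
#' Rec. 601 weights: `0.299 R + 0.587 G + 0.114 B`. A plain matrix is
#' returned unchanged (already a single intensity plane).
#'
#' @param x matrix, h x w x 3 array or [rgb_image()].
#' @return numeric matrix.
#' @export
luminance <- function(x) {
  a <- as_image_array(x)
  if (is.matrix(a)) return(a)
  0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3]
}

sobel_magnitude <- function(m) {
  gx <- conv3x3(m, matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE))
  gy <- conv3x3(m, matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3, byrow = TRUE))
  sqrt(gx^2 + gy^2)
}

#' Enhancement-efficiency index
#'
#' Quantifies the trade-off an enhancement filter strikes between edge
#' preservation and noise suppression, relative to the unfiltered image:
#'
#'   E = (edge_f / edge_u) / (noise_f / noise_u)
#'
#' where `edge` is the mean Sobel gradient magnitude of the luminance and
#' `noise` is the standard deviation of high-frequency residuals (luminance
#' minus its Gaussian blur, `sigma_hf` pixels). E > 1 means the filter
#' removed proportionally more noise than edge signal.
#'
#' @param unfiltered,filtered images of identical shape (matrix, array or
#'   [rgb_image()]).
#' @param sigma_hf standard deviation of the Gaussian high-pass (pixels).
#' @return a one-row tibble with columns `edge_f`, `edge_u`, `noise_f`,
#'   `noise_u`, `E`.
#' @export
enhancement_efficiency <- function(unfiltered, filtered, sigma_hf = 1) {
  lu <- luminance(unfiltered); lf <- luminance(filtered)
  if (!identical(dim(lu), dim(lf))) {
    stop("images must have identical shape", call. = FALSE)
  }
  edge_u <- mean(sobel_magnitude(lu))
  edge_f <- mean(sobel_magnitude(lf))
  noise_u <- stats::sd(lu - blur_gaussian(lu, sigma_hf))
  noise_f <- stats::sd(lf - blur_gaussian(lf, sigma_hf))
  if (edge_u == 0 || noise_u == 0) {
    stop("enhancement efficiency undefined: unfiltered image has zero edge ",
         "or noise term", call. = FALSE)
  }
  tibble::tibble(edge_f = edge_f, edge_u = edge_u,
                 noise_f = noise_f, noise_u = noise_u,
                 E = (edge_f / edge_u) / (noise_f / noise_u))
}

ssim_terms <- function(x, y, sigma = 1.5, radius = 5L, data_range = 1) {
  k <- gaussian_kernel_1d(sigma, radius)
  C1 <- (0.01 * data_range)^2
  C2 <- (0.03 * data_range)^2
  mx <- conv_separable(x, k); my <- conv_separable(y, k)
  sxx <- conv_separable(x * x, k) - mx^2
  syy <- conv_separable(y * y, k) - my^2
  sxy <- conv_separable(x * y, k) - mx * my
  l <- (2 * mx * my + C1) / (mx^2 + my^2 + C1)
  cs <- (2 * sxy + C2) / (sxx + syy + C2)
  list(l = l, cs = cs)
}

downsample2 <- function(m) {
  nr <- floor(nrow(m) / 2); nc <- floor(ncol(m) / 2)
  m <- m[seq_len(2 * nr), seq_len(2 * nc), drop = FALSE]
  (m[seq(1, 2 * nr, 2), seq(1, 2 * nc, 2)] +
   m[seq(2, 2 * nr, 2), seq(1, 2 * nc, 2)] +
   m[seq(1, 2 * nr, 2), seq(2, 2 * nc, 2)] +
   m[seq(2, 2 * nr, 2), seq(2, 2 * nc, 2)]) / 4
}

#' Multi-scale structural similarity (MS-SSIM)
#'
#' Standard five-scale MS-SSIM with weights (0.0448, 0.2856, 0.3001, 0.2363,
#' 0.1333) on the luminance plane; contrast/structure terms enter at every
#' scale and the luminance term at the coarsest. For small images the number
#' of scales is reduced so the coarsest scale still covers the filter
#' window, and the weights are renormalized.
#'
#' @param x,y images (matrix, array or [rgb_image()]) in \[0,1\].
#' @param max_levels cap on the number of scales.
#' @return scalar in \[-1,1\] (1 for identical images).
#' @export
ms_ssim <- function(x, y, max_levels = 5) {
  wx <- luminance(x); wy <- luminance(y)
  stopifnot(identical(dim(wx), dim(wy)))
  weights <- c(0.0448, 0.2856, 0.3001, 0.2363, 0.1333)
  levels <- min(max_levels, length(weights),
                max(1, floor(log2(min(dim(wx)) / 11)) + 1))
  weights <- weights[seq_len(levels)]
  weights <- weights / sum(weights)
  vals <- numeric(levels)
  for (lev in seq_len(levels)) {
    t <- ssim_terms(wx, wy)
    vals[lev] <- if (lev == levels) mean(t$l * t$cs) else mean(t$cs)
    if (lev < levels) {
      wx <- downsample2(wx); wy <- downsample2(wy)
    }
  }
  prod(sign(vals) * abs(vals)^weights)
}

# 1-D Wasserstein distance between 256-bin channel histograms, in 8-bit
# gray-level units: sum of absolute CDF differences times unit bin width.
emd_histogram <- function(a, b) {
  ha <- tabulate(as.vector(to_uint8(a)) + 1L, nbins = 256L)
  hb <- tabulate(as.vector(to_uint8(b)) + 1L, nbins = 256L)
  pa <- ha / sum(ha); pb <- hb / sum(hb)
  sum(abs(cumsum(pa) - cumsum(pb)))
}

#' Paired image-quality metrics
#'
#' Computes, for a reference/test image pair of identical shape: Pearson
#' correlation over all flattened pixel values, mean squared error on the
#' 8-bit scale, PSNR derived from that MSE (capped at `psnr_cap` dB when
#' MSE is 0), MS-SSIM on the luminance, and the Earth Mover's Distance
#' averaged over the R, G, B 256-bin histograms (8-bit gray-level units).
#'
#' @param reference,test images (matrix, array or [rgb_image()]) in \[0,1\].
#' @param psnr_cap PSNR reported for a perfect reconstruction (dB).
#' @return a one-row tibble with columns `pcc`, `mse`, `msssim`, `psnr`,
#'   `emd`.
#' @export
paired_quality_metrics <- function(reference, test, psnr_cap = 100) {
  ra <- as_image_array(reference); ta <- as_image_array(test)
  if (!identical(dim(ra), dim(ta))) {
    stop("reference and test must have identical shape", call. = FALSE)
  }
  rv <- as.vector(ra); tv <- as.vector(ta)
  pcc <- if (stats::sd(rv) == 0 || stats::sd(tv) == 0) {
    warning("constant image: Pearson correlation undefined", call. = FALSE)
    NaN
  } else {
    stats::cor(rv, tv)
  }
  mse <- mean((rv * 255 - tv * 255)^2)
  psnr <- if (mse == 0) psnr_cap else min(psnr_cap, 10 * log10(255^2 / mse))
  chans <- function(a) if (is.matrix(a)) list(a) else
    lapply(seq_len(dim(a)[3]), function(c) a[, , c])
  emd <- mean(mapply(emd_histogram, chans(ra), chans(ta)))
  tibble::tibble(pcc = pcc, mse = mse, msssim = ms_ssim(ra, ta),
                 psnr = psnr, emd = emd)
}

#' Region-averaged paired metrics
#'
#' Whole-slide pairs are evaluated by splitting both images into square
#' regions, computing the metrics per region and averaging — the mean of
#' per-region metrics, not the metric of the concatenation.
#'
#' @inheritParams paired_quality_metrics
#' @param region_size region side in pixels.
#' @return a list with `per_region` (tibble, one row per region with `row`
#'   and `col` indices) and `mean` (one-row tibble of column means).
#' @export
paired_quality_metrics_regions <- function(reference, test, region_size = 8192) {
  ra <- as_image_array(reference); ta <- as_image_array(test)
  stopifnot(identical(dim(ra), dim(ta)))
  d <- dim(ra)
  ys <- seq(1L, d[1], by = region_size)
  xs <- seq(1L, d[2], by = region_size)
  rows <- list()
  for (iy in seq_along(ys)) {
    for (ix in seq_along(xs)) {
      y1 <- min(ys[iy] + region_size - 1L, d[1])
      x1 <- min(xs[ix] + region_size - 1L, d[2])
      sub <- function(a) if (is.matrix(a)) a[ys[iy]:y1, xs[ix]:x1, drop = FALSE]
        else a[ys[iy]:y1, xs[ix]:x1, , drop = FALSE]
      m <- paired_quality_metrics(sub(ra), sub(ta))
      rows[[length(rows) + 1L]] <- cbind(tibble::tibble(row = iy, col = ix), m)
    }
  }
  per_region <- do.call(rbind, rows)
  list(per_region = per_region,
       mean = tibble::as_tibble(as.list(colMeans(per_region[, -(1:2)]))))
}
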