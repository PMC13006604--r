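# Classical pre/post-processing: percentile normalization, median denoising,
# unsharp sharpening, contrast-limited adaptive histogram equalization and
# spline resampling. All operators preserve the internal [0,1] value range
# and use symmetric-reflection boundary handling.

#' Percentile-normalize a raw marker plane
#'
#' Linearly maps the low/high percentiles of the input to 0/1 and clips.
#' The default 1st-99th percentile window is robust to the isolated hot
#' pixels typical of imaging mass cytometry. A constant plane maps to all
#' zeros.
#'
#' @param plane numeric matrix (or 3D array) of raw channel values.
#' @param low_pct,high_pct percentiles in \[0,100\] with `low_pct < high_pct`.
#' @return plane rescaled into \[0,1\].
#' @export
normalize_marker <- function(plane, low_pct = 1, high_pct = 99) {
  if (length(plane) == 0) stop("empty plane", call. = FALSE)
  stopifnot(low_pct >= 0, high_pct <= 100, low_pct < high_pct)
  qs <- stats::quantile(plane, c(low_pct, high_pct) / 100, names = FALSE)
  if (qs[2] <= qs[1]) {
    out <- plane * 0
    return(out)
  }
  clip01((plane - qs[1]) / (qs[2] - qs[1]))
}

#' Normalize every channel of a multiplex image
#'
#' @param image a [multiplex_image()].
#' @inheritParams normalize_marker
#' @return a [multiplex_image()] with planes in \[0,1\].
#' @export
normalize_multiplex <- function(image, low_pct = 1, high_pct = 99) {
  stopifnot(inherits(image, "multiplex_image"))
  image$channels <- lapply(image$channels, normalize_marker,
                           low_pct = low_pct, high_pct = high_pct)
  image
}

apply_per_plane <- function(x, fn) {
  if (inherits(x, "rgb_image")) {
    out <- x$data
    for (ch in 1:3) out[, , ch] <- fn(x$data[, , ch])
    rgb_image(out, pixel_size_um = x$pixel_size_um)
  } else if (is.matrix(x)) {
    fn(x)
  } else if (is.array(x) && length(dim(x)) == 3) {
    out <- x
    for (ch in seq_len(dim(x)[3])) out[, , ch] <- fn(x[, , ch])
    out
  } else {
    stop("expected a matrix, 3D array or rgb_image", call. = FALSE)
  }
}

#' Median-filter an image
#'
#' Square-window median of side `2*radius + 1` per channel, edges handled by
#' symmetric reflection. Removes the isolated hot pixels typical of IMC.
#'
#' @param x matrix, 3D array or [rgb_image()] with values in \[0,1\].
#' @param radius window radius in pixels (>= 1).
#' @return filtered image of the same type and shape.
#' @export
denoise_median <- function(x, radius = 1) {
  stopifnot(radius >= 1)
  radius <- as.integer(radius)
  apply_per_plane(x, function(m) median_filter_plane(m, radius))
}

median_filter_plane <- function(m, r) {
  p <- pad_reflect(m, r)
  nr <- nrow(m); nc <- ncol(m)
  k <- (2L * r + 1L)^2
  stackm <- matrix(0, nr * nc, k)
  idx <- 1L
  for (di in 0:(2L * r)) {
    for (dj in 0:(2L * r)) {
      stackm[, idx] <- as.vector(p[(1L + di):(nr + di), (1L + dj):(nc + dj)])
      idx <- idx + 1L
    }
  }
  # median of k values per row; k is odd so this is the order statistic
  mid <- (k + 1L) / 2L
  med <- apply(stackm, 1L, function(v) sort.int(v, partial = mid)[mid])
  matrix(med, nr, nc)
}

#' Unsharp-mask sharpening
#'
#' `out = in + amount * (in - gaussian_blur(in, radius))`, clipped to \[0,1\].
#' De-blurs the diffuse signal typical of fluorescence imaging.
#'
#' @param x matrix, 3D array or [rgb_image()] in \[0,1\].
#' @param amount nonnegative strength; 0 is the identity.
#' @param radius Gaussian standard deviation in pixels.
#' @return sharpened image of the same type and shape.
#' @export
sharpen_unsharp <- function(x, amount = 1, radius = 1) {
  stopifnot(amount >= 0, radius > 0)
  if (amount == 0) return(x)
  apply_per_plane(x, function(m) {
    clip01(m + amount * (m - blur_gaussian(m, radius)))
  })
}

#' Contrast-limited adaptive histogram equalization of one plane
#'
#' Applied to the nuclear class intensity before rendering, CLAHE evens out
#' staining strength so all nuclei reach a similar dynamic range across the
#' tissue. Planes smaller than one tile fall back to global histogram
#' equalization with a warning.
#'
#' @param plane numeric matrix in \[0,1\].
#' @param tile tile side in pixels (>= 8).
#' @param clip clip limit as a fraction of the tile histogram (counts above
#'   `clip * tile^2` per bin are redistributed).
#' @return equalized plane in \[0,1\].
#' @export
equalize_adaptive <- function(plane, tile = 64, clip = 0.01) {
  stopifnot(is.matrix(plane), tile >= 8, clip > 0)
  rng <- range(plane)
  if (rng[2] - rng[1] <= 0) return(plane)  # constant stays constant
  if (min(dim(plane)) < tile) {
    warning("plane smaller than one tile; falling back to global equalization",
            call. = FALSE)
    e <- stats::ecdf(plane)
    return(matrix(e(plane), nrow(plane), ncol(plane)))
  }
  bins <- 256L
  nx <- max(2L, floor(ncol(plane) / tile))
  ny <- max(2L, floor(nrow(plane) / tile))
  out <- EBImage::clahe(plane, nx = nx, ny = ny, bins = bins,
                        limit = clip * bins, keep.range = FALSE)
  clip01(as.matrix(out))
}

#' Spline resampling to a target pixel size
#'
#' Separable resampling under the pixel-center convention (the center of
#' pixel (0,0) maps to the center of pixel (0,0); no half-pixel shift).
#' `order` 0 is nearest neighbor, 1 linear, 3 cubic spline. Downscaling
#' applies a Gaussian anti-alias prefilter with sigma proportional to the
#' reduction factor.
#'
#' @param x matrix, 3D array or [rgb_image()].
#' @param target_pixel_size_um desired pixel size (scalar, micrometres).
#' @param pixel_size_um current pixel size; taken from `x` when it is an
#'   [rgb_image()].
#' @param order interpolation order: 0, 1 or 3.
#' @return resampled image; for [rgb_image()] input the pixel-size metadata
#'   is updated to `target_pixel_size_um`.
#' @export
resample_spline <- function(x, target_pixel_size_um, pixel_size_um = NULL,
                            order = 3) {
  stopifnot(order %in% c(0, 1, 3), target_pixel_size_um > 0)
  if (inherits(x, "rgb_image")) {
    ps <- x$pixel_size_um
    out <- x$data
    res <- resample_array(out, ps, rep(target_pixel_size_um, 2), order)
    return(rgb_image(res, pixel_size_um = target_pixel_size_um))
  }
  if (is.null(pixel_size_um)) stop("`pixel_size_um` required for raw arrays")
  ps <- rep(as.numeric(pixel_size_um), length.out = 2)
  resample_array(x, ps, rep(target_pixel_size_um, 2), order)
}

resample_array <- function(a, src_ps, tgt_ps, order) {
  is_mat <- is.matrix(a)
  if (is_mat) a <- array(a, c(dim(a), 1L))
  d <- dim(a)
  new_h <- floor(d[1] * src_ps[1] / tgt_ps[1] + 0.5)
  new_w <- floor(d[2] * src_ps[2] / tgt_ps[2] + 0.5)
  if (new_h < 1 || new_w < 1) stop("resampling would produce an empty image",
                                   call. = FALSE)
  if (new_h == d[1] && new_w == d[2]) {
    return(if (is_mat) a[, , 1] else a)
  }
  # output pixel centers expressed in source pixel index units (0-based)
  yi <- (seq_len(new_h) - 1) * tgt_ps[1] / src_ps[1]
  xi <- (seq_len(new_w) - 1) * tgt_ps[2] / src_ps[2]
  out <- array(0, c(new_h, new_w, d[3]))
  for (ch in seq_len(d[3])) {
    m <- a[, , ch]
    # anti-alias prefilter when reducing
    fy <- tgt_ps[1] / src_ps[1]; fx <- tgt_ps[2] / src_ps[2]
    s <- max(0, (max(fy, fx) - 1) / 2)
    if (s > 0) m <- blur_gaussian(m, s)
    m2 <- interp_axis(m, yi, order, along = 1L)
    out[, , ch] <- interp_axis(m2, xi, order, along = 2L)
  }
  out <- clip01(out)
  if (is_mat && dim(out)[3] == 1L) out[, , 1] else out
}

# Interpolate along one axis at (0-based) positions `pos`.
interp_axis <- function(m, pos, order, along) {
  if (along == 2L) return(t(interp_axis(t(m), pos, order, along = 1L)))
  n <- nrow(m)
  grid <- seq_len(n) - 1
  if (order == 0) {
    idx <- pmin(pmax(floor(pos + 0.5), 0), n - 1) + 1
    return(m[idx, , drop = FALSE])
  }
  pos <- pmin(pmax(pos, 0), n - 1)
  out <- matrix(0, length(pos), ncol(m))
  for (j in seq_len(ncol(m))) {
    out[, j] <- if (order == 1 || n < 4) {
      stats::approx(grid, m[, j], xout = pos, rule = 2)$y
    } else {
      stats::splinefun(grid, m[, j], method = "natural")(pos)
    }
  }
  out
}

#' Apply a filter tile-wise with seam-free overlap margins
#'
#' Splits a large image into tiles, runs `fn` on each tile extended by a
#' margin at least equal to the filter's kernel radius, and crops the
#' margins back off. For translation-equivariant filters with kernel radius
#' `<= margin` the result is bit-identical to running `fn` on the whole
#' image.
#'
#' @param x matrix or [rgb_image()].
#' @param fn filter taking and returning a matrix (applied per channel for
#'   RGB input).
#' @param tile tile side in pixels.
#' @param margin overlap margin in pixels (kernel radius of `fn`).
#' @return filtered image of the same type and shape.
#' @export
tiled_apply <- function(x, fn, tile = 2048, margin = 1) {
  stopifnot(tile > 2 * margin)
  apply_per_plane(x, function(m) tiled_apply_plane(m, fn, tile, margin))
}

tiled_apply_plane <- function(m, fn, tile, margin) {
  nr <- nrow(m); nc <- ncol(m)
  if (nr <= tile && nc <= tile) return(fn(m))
  p <- pad_reflect(m, margin)
  out <- matrix(0, nr, nc)
  ys <- seq(1L, nr, by = tile)
  xs <- seq(1L, nc, by = tile)
  for (y0 in ys) {
    for (x0 in xs) {
      y1 <- min(y0 + tile - 1L, nr)
      x1 <- min(x0 + tile - 1L, nc)
      # tile plus margin in padded coordinates
      sub <- p[y0:(y1 + 2L * margin), x0:(x1 + 2L * margin), drop = FALSE]
      res <- fn(sub)
      out[y0:y1, x0:x1] <- res[(margin + 1L):(margin + y1 - y0 + 1L),
                               (margin + 1L):(margin + x1 - x0 + 1L)]
    }
  }
  out
}
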