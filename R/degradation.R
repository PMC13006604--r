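# Degradation simulator: the corruptions used to build restoration training
# pairs — resolution stair-step artifacts, blur, and Gaussian / Poisson /
# hot-pixel noise applied in RGB, HSV or stain-deconvolved (HED) space —
# plus the sliding-window application contract for tiled restorers.

#' Stain space for color deconvolution
#'
#' Holds the 3x3 absorbance matrix whose rows are unit-length stain vectors
#' and its inverse. The default is the classic hematoxylin / eosin / DAB
#' basis of brightfield color deconvolution.
#'
#' @param vectors 3x3 matrix, rows = stain absorbance vectors (normalized
#'   internally).
#' @return an object of class `stain_space`.
#' @export
stain_space <- function(vectors = NULL) {
  if (is.null(vectors)) {
    vectors <- rbind(
      h = c(0.650, 0.704, 0.286),
      e = c(0.072, 0.990, 0.105),
      d = c(0.268, 0.570, 0.776)
    )
  }
  vectors <- as.matrix(vectors)
  stopifnot(all(dim(vectors) == c(3, 3)))
  norms <- sqrt(rowSums(vectors^2))
  if (any(norms == 0)) stop("zero stain vector", call. = FALSE)
  vectors <- vectors / norms
  inv <- tryCatch(solve(vectors), error = function(e) {
    stop("stain matrix is singular", call. = FALSE)
  })
  structure(list(matrix = vectors, inverse = inv), class = "stain_space")
}

#' Decompose an RGB image into stain optical-density components
#'
#' Converts transmission to optical density, `OD_c = -log(rgb_c / c_c)`
#' (values floored at a small epsilon before the logarithm), and projects
#' through the inverse stain matrix to per-stain concentration planes.
#'
#' @param rgb an [rgb_image()] or h x w x 3 array with values in (0,1\].
#' @param space a [stain_space()].
#' @param background RGB background transmission triple.
#' @param eps floor applied before the logarithm.
#' @return h x w x 3 array of stain concentration planes (order = rows of
#'   the stain matrix).
#' @export
color_deconvolve <- function(rgb, space = stain_space(),
                             background = c(1, 1, 1), eps = 1e-6) {
  a <- as_image_array(rgb)
  stopifnot(length(dim(a)) == 3, dim(a)[3] == 3)
  d <- dim(a)
  od <- matrix(0, d[1] * d[2], 3)
  for (c in 1:3) od[, c] <- -log(pmax(a[, , c], eps) / background[c])
  conc <- od %*% space$inverse
  array(conc, d)
}

#' Reconstruct RGB from stain concentration planes
#'
#' Inverse of [color_deconvolve()]: `rgb_c = c_c * exp(-(S M)_c)`.
#'
#' @param conc h x w x 3 stain concentration array.
#' @param space a [stain_space()].
#' @param background RGB background transmission triple.
#' @param pixel_size_um pixel size for the resulting [rgb_image()].
#' @return an [rgb_image()].
#' @export
color_reconstruct <- function(conc, space = stain_space(),
                              background = c(1, 1, 1), pixel_size_um = 1) {
  d <- dim(conc)
  od <- matrix(conc, d[1] * d[2], 3) %*% space$matrix
  out <- array(0, d)
  for (c in 1:3) out[, , c] <- background[c] * exp(-matrix(od[, c], d[1], d[2]))
  rgb_image(clip01(out), pixel_size_um = pixel_size_um)
}

#' Specify a degradation
#'
#' All corruptions default to "off" so the default spec is the identity.
#'
#' @param downscale_range range of random downscale factors (>= 1) for the
#'   resolution stair-step artifact.
#' @param blur_sigma_range range of random Gaussian blur sigmas (pixels).
#' @param noise_space space in which noise is applied: `"rgb"`, `"hsv"` or
#'   `"hed"` (hematoxylin/eosin/DAB-deconvolved).
#' @param gaussian_sigma standard deviation of additive zero-mean Gaussian
#'   noise (component units).
#' @param poisson_scale photons at unit intensity for Poisson (shot) noise;
#'   `Inf` disables it.
#' @param hot_pixel_rate Bernoulli rate of hot pixels per component plane.
#' @param hot_pixel_value value hot pixels are set to (salt default 1).
#' @param jitter,flip,rotate toggles for color jitter and dihedral
#'   (flip/rotation) augmentation of training pairs.
#' @param seed integer seed making every draw reproducible.
#' @return an object of class `degradation_spec`.
#' @export
degradation_spec <- function(downscale_range = c(1, 1),
                             blur_sigma_range = c(0, 0),
                             noise_space = c("rgb", "hsv", "hed"),
                             gaussian_sigma = 0,
                             poisson_scale = Inf,
                             hot_pixel_rate = 0,
                             hot_pixel_value = 1,
                             jitter = FALSE, flip = FALSE, rotate = FALSE,
                             seed = 1L) {
  noise_space <- match.arg(noise_space)
  downscale_range <- rep(as.numeric(downscale_range), length.out = 2)
  blur_sigma_range <- rep(as.numeric(blur_sigma_range), length.out = 2)
  stopifnot(all(downscale_range >= 1), all(blur_sigma_range >= 0),
            gaussian_sigma >= 0, poisson_scale > 0,
            hot_pixel_rate >= 0, hot_pixel_rate < 1)
  structure(list(downscale_range = downscale_range,
                 blur_sigma_range = blur_sigma_range,
                 noise_space = noise_space,
                 gaussian_sigma = gaussian_sigma,
                 poisson_scale = poisson_scale,
                 hot_pixel_rate = hot_pixel_rate,
                 hot_pixel_value = hot_pixel_value,
                 jitter = isTRUE(jitter), flip = isTRUE(flip),
                 rotate = isTRUE(rotate), seed = as.integer(seed)),
            class = "degradation_spec")
}

hsv_to_rgb_planes <- function(h, s, v) {
  h6 <- (h %% 1) * 6
  i <- floor(h6)
  f <- h6 - i
  p <- v * (1 - s); q <- v * (1 - s * f); t <- v * (1 - s * (1 - f))
  r <- g <- b <- v
  sel <- i == 0; r[sel] <- v[sel]; g[sel] <- t[sel]; b[sel] <- p[sel]
  sel <- i == 1; r[sel] <- q[sel]; g[sel] <- v[sel]; b[sel] <- p[sel]
  sel <- i == 2; r[sel] <- p[sel]; g[sel] <- v[sel]; b[sel] <- t[sel]
  sel <- i == 3; r[sel] <- p[sel]; g[sel] <- q[sel]; b[sel] <- v[sel]
  sel <- i == 4; r[sel] <- t[sel]; g[sel] <- p[sel]; b[sel] <- v[sel]
  sel <- i >= 5; r[sel] <- v[sel]; g[sel] <- p[sel]; b[sel] <- q[sel]
  list(r = r, g = g, b = b)
}

to_noise_space <- function(a, spec) {
  switch(spec$noise_space,
    rgb = a,
    hsv = {
      d <- dim(a)
      hsv <- grDevices::rgb2hsv(as.vector(a[, , 1]), as.vector(a[, , 2]),
                                as.vector(a[, , 3]), maxColorValue = 1)
      array(c(hsv[1, ], hsv[2, ], hsv[3, ]), d)
    },
    hed = color_deconvolve(a)
  )
}

from_noise_space <- function(comp, spec, dims) {
  switch(spec$noise_space,
    rgb = comp,
    hsv = {
      pl <- hsv_to_rgb_planes(as.vector(comp[, , 1]),
                              pmin(pmax(as.vector(comp[, , 2]), 0), 1),
                              pmin(pmax(as.vector(comp[, , 3]), 0), 1))
      array(c(pl$r, pl$g, pl$b), dims)
    },
    hed = color_reconstruct(comp)$data
  )
}

#' Apply simulated noise to an image
#'
#' In the chosen color space, each component plane receives additive
#' zero-mean Gaussian noise, Poisson (shot) noise (`v -> Poisson(v * scale)
#' / scale`), and a Bernoulli subset of pixels set to the hot-pixel value.
#' The image is then converted back to RGB and clipped to \[0,1\]. The
#' result is a pure function of (input, spec, seed).
#'
#' @param image an [rgb_image()] or h x w x 3 array in \[0,1\] (a plain
#'   matrix is allowed for `noise_space = "rgb"`).
#' @param spec a [degradation_spec()].
#' @param seed overrides `spec$seed` when given.
#' @return image of the same type, corrupted.
#' @export
apply_noise <- function(image, spec, seed = NULL) {
  stopifnot(inherits(spec, "degradation_spec"))
  seed <- seed %||% spec$seed
  a <- as_image_array(image)
  is_mat <- is.matrix(a)
  if (is_mat) {
    if (spec$noise_space != "rgb") {
      stop("noise space '", spec$noise_space,
           "' requires an RGB image, got a single plane", call. = FALSE)
    }
    a <- array(a, c(dim(a), 1L))
  }
  d <- dim(a)
  out <- with_rng_seed(seed, {
    comp <- if (d[3] == 3L) to_noise_space(a, spec) else a
    n <- length(comp)
    if (spec$gaussian_sigma > 0) {
      comp <- comp + stats::rnorm(n, 0, spec$gaussian_sigma)
    }
    if (is.finite(spec$poisson_scale)) {
      lam <- pmax(comp, 0) * spec$poisson_scale
      comp <- array(stats::rpois(n, as.vector(lam)) / spec$poisson_scale, dim(comp))
    }
    if (spec$hot_pixel_rate > 0) {
      mask <- stats::runif(n) < spec$hot_pixel_rate
      comp[mask] <- spec$hot_pixel_value
    }
    if (d[3] == 3L) from_noise_space(comp, spec, d) else comp
  })
  out <- clip01(out)
  if (is_mat) out <- out[, , 1]
  if (inherits(image, "rgb_image")) {
    rgb_image(out, pixel_size_um = image$pixel_size_um)
  } else {
    out
  }
}

#' Simulate resolution stair-step artifacts
#'
#' Downscales by `factor` and upscales back to the original shape with
#' nearest-neighbor interpolation, producing the piecewise-constant blocks
#' a super-resolution restorer learns to undo. Exact `factor x factor`
#' blocks appear when `factor` divides the shape; the operation is
#' idempotent for a fixed divisible factor.
#'
#' @param image matrix, 3D array or [rgb_image()].
#' @param factor downscale factor (>= 1; need not be an integer).
#' @return image of the same type and shape.
#' @export
simulate_resolution_artifact <- function(image, factor) {
  stopifnot(factor >= 1)
  if (factor == 1) return(image)
  apply_per_plane(image, function(m) {
    nr <- nrow(m); nc <- ncol(m)
    dn_r <- max(1L, floor(nr / factor + 0.5))
    dn_c <- max(1L, floor(nc / factor + 0.5))
    # nearest-neighbor subsample (pixel-center mapping), then nearest upscale
    ri <- pmin(floor((seq_len(dn_r) - 0.5) * nr / dn_r) + 1L, nr)
    ci <- pmin(floor((seq_len(dn_c) - 0.5) * nc / dn_c) + 1L, nc)
    small <- m[ri, ci, drop = FALSE]
    ro <- pmin(floor((seq_len(nr) - 0.5) * dn_r / nr) + 1L, dn_r)
    co <- pmin(floor((seq_len(nc) - 0.5) * dn_c / nc) + 1L, dn_c)
    small[ro, co, drop = FALSE]
  })
}

dihedral_transform <- function(a, k) {
  # k in 1..8: 4 rotations x optional transpose-flip
  rot90 <- function(m) t(m[nrow(m):1, , drop = FALSE])
  per_plane <- function(m) {
    if (k > 4) m <- t(m)
    r <- (k - 1) %% 4
    for (i in seq_len(r)) m <- rot90(m)
    m
  }
  if (is.matrix(a)) return(per_plane(a))
  d <- dim(per_plane(a[, , 1]))
  out <- array(0, c(d, dim(a)[3]))
  for (ch in seq_len(dim(a)[3])) out[, , ch] <- per_plane(a[, , ch])
  out
}

#' Build one restoration training pair
#'
#' The target is a (possibly flipped/rotated) copy of the clean image; the
#' input is the same geometric transform followed by the resolution
#' artifact, Gaussian blur, noise and optional color jitter. Identical
#' seeds give byte-identical pairs.
#'
#' @param clean an [rgb_image()].
#' @param spec a [degradation_spec()].
#' @return list with elements `input` and `target` (both [rgb_image()]) and
#'   `params` (the realized random draws).
#' @export
make_training_pair <- function(clean, spec) {
  stopifnot(inherits(clean, "rgb_image"), inherits(spec, "degradation_spec"))
  draws <- with_rng_seed(derive_seed(spec$seed, "draws"), {
    list(
      transform = if (spec$rotate || spec$flip) {
        if (spec$rotate && spec$flip) sample.int(8L, 1L)
        else if (spec$rotate) sample.int(4L, 1L)
        else sample(c(1L, 5L), 1L)
      } else 1L,
      factor = stats::runif(1, spec$downscale_range[1], spec$downscale_range[2]),
      blur_sigma = stats::runif(1, spec$blur_sigma_range[1],
                                spec$blur_sigma_range[2]),
      jitter_gain = if (spec$jitter) stats::runif(3, 0.9, 1.1) else c(1, 1, 1),
      jitter_offset = if (spec$jitter) stats::runif(1, -0.05, 0.05) else 0
    )
  })
  target_a <- dihedral_transform(clean$data, draws$transform)
  x <- target_a
  if (draws$factor > 1) x <- simulate_resolution_artifact(x, draws$factor)
  if (draws$blur_sigma > 0) x <- blur_gaussian(x, draws$blur_sigma)
  x <- clip01(x)
  x_img <- apply_noise(rgb_image(x, clean$pixel_size_um), spec,
                       seed = derive_seed(spec$seed, "noise"))
  x <- x_img$data
  if (spec$jitter) {
    for (c in 1:3) x[, , c] <- x[, , c] * draws$jitter_gain[c] + draws$jitter_offset
    x <- clip01(x)
  }
  list(input = rgb_image(x, clean$pixel_size_um),
       target = rgb_image(target_a, clean$pixel_size_um),
       params = draws)
}

#' Write a set of training pairs to paired image directories
#'
#' Produces `degraded/` and `clean/` 8-bit RGB OME-TIFFs plus a JSON
#' manifest recording per-pair seeds and the degradation spec, the layout
#' any image-restoration trainer can consume.
#'
#' @param clean an [rgb_image()] (tiles are drawn from it) or list of them.
#' @param spec a [degradation_spec()]; `spec$seed` seeds pair `i` as
#'   `seed + i`.
#' @param n number of pairs.
#' @param dir output directory.
#' @return the manifest, invisibly.
#' @export
write_training_pairs <- function(clean, spec, n, dir) {
  if (inherits(clean, "rgb_image")) clean <- list(clean)
  dir.create(file.path(dir, "degraded"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "clean"), recursive = TRUE, showWarnings = FALSE)
  manifest <- vector("list", n)
  for (i in seq_len(n)) {
    src <- clean[[(i - 1L) %% length(clean) + 1L]]
    spi <- spec
    spi$seed <- spec$seed + i
    pair <- make_training_pair(src, spi)
    fin <- file.path(dir, "degraded", sprintf("pair_%04d.ome.tiff", i))
    fta <- file.path(dir, "clean", sprintf("pair_%04d.ome.tiff", i))
    write_rgb(pair$input, fin)
    write_rgb(pair$target, fta)
    manifest[[i]] <- list(index = i, seed = spi$seed, input = basename(fin),
                          target = basename(fta))
  }
  man <- list(spec = unclass(spec), pairs = manifest)
  jsonlite::write_json(man, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(man)
}

#' Apply a function over sliding windows with feathered blending
#'
#' Tiles the image into `window`-sized patches overlapping by `overlap`
#' pixels, applies `fn` to each patch, and blends overlapping outputs with
#' linear feathering (triangular weights normalized per pixel). When `fn`
#' is the identity the output equals the input exactly. A window larger
#' than the image results in a single full-image call.
#'
#' @param image matrix or [rgb_image()].
#' @param window window side in pixels.
#' @param overlap overlap in pixels, `0 <= overlap < window`.
#' @param fn function mapping a patch to an equally-shaped patch.
#' @return processed image with attribute `tiles = c(ny, nx)`.
#' @export
sliding_window_apply <- function(image, window, overlap, fn) {
  stopifnot(window > overlap, overlap >= 0)
  a <- as_image_array(image)
  is_mat <- is.matrix(a)
  if (is_mat) a <- array(a, c(dim(a), 1L))
  d <- dim(a)
  if (window >= d[1] && window >= d[2]) {
    res <- a
    for (ch in seq_len(d[3])) res[, , ch] <- fn(a[, , ch])
    out <- if (is_mat) res[, , 1] else res
    out <- restore_image_type(out, image)
    attr(out, "tiles") <- c(1L, 1L)
    return(out)
  }
  starts <- function(n) {
    if (window >= n) return(1L)
    s <- seq(1L, n - window + 1L, by = window - overlap)
    if (s[length(s)] + window - 1L < n) s <- c(s, n - window + 1L)
    s
  }
  ys <- starts(d[1]); xs <- starts(d[2])
  ramp <- function(len) {
    if (overlap == 0) return(rep(1, len))
    w <- pmin(seq_len(len), rev(seq_len(len)), overlap + 1) / (overlap + 1)
    w
  }
  acc <- array(0, d)
  wacc <- matrix(0, d[1], d[2])
  for (y0 in ys) {
    for (x0 in xs) {
      y1 <- min(y0 + window - 1L, d[1]); x1 <- min(x0 + window - 1L, d[2])
      wy <- ramp(y1 - y0 + 1L); wx <- ramp(x1 - x0 + 1L)
      w <- outer(wy, wx)
      for (ch in seq_len(d[3])) {
        patch <- fn(a[y0:y1, x0:x1, ch])
        acc[y0:y1, x0:x1, ch] <- acc[y0:y1, x0:x1, ch] + patch * w
      }
      wacc[y0:y1, x0:x1] <- wacc[y0:y1, x0:x1] + w
    }
  }
  for (ch in seq_len(d[3])) acc[, , ch] <- acc[, , ch] / wacc
  out <- if (is_mat) acc[, , 1] else acc
  out <- restore_image_type(out, image)
  attr(out, "tiles") <- c(length(ys), length(xs))
  out
}

restore_image_type <- function(data, template) {
  if (inherits(template, "rgb_image")) {
    rgb_image(data, pixel_size_um = template$pixel_size_um)
  } else {
    data
  }
}
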