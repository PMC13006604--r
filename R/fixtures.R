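# Seeded synthetic multiplex fixtures: spatially structured marker channels
# with known ground truth (nucleus centers, structure masks), emulating
# IMC-style (hot-pixel noise, ~1 um pixels) or IF-style (optical blur) data.
# Channel names carry realistic isotope-tagged aliases so lexicon matching
# is exercised end to end.

#' Specify a synthetic multiplex fixture
#'
#' @param size image size in pixels, length 2 (rows, cols) or scalar.
#' @param pixel_size_um pixel size in micrometres (IMC-style default 1).
#' @param n_cells number of nuclei to place (non-overlapping).
#' @param nucleus_radius_um nucleus radius range in micrometres.
#' @param modality `"imc"` (adds hot pixels) or `"if"` (adds optical blur).
#' @param hot_pixel_rate per-pixel hot-pixel rate for IMC-style noise.
#' @param blur_sigma_um optical blur sigma for IF-style fixtures.
#' @param panel named character vector mapping structure roles (`nuclear`,
#'   `ecm`, `epithelial`, `erythrocyte`, `vessel`) to channel names.
#' @param seed integer seed; the fixture is a pure function of the spec.
#' @return an object of class `fixture_spec`.
#' @export
fixture_spec <- function(size = c(256, 256), pixel_size_um = 1, n_cells = 80,
                         nucleus_radius_um = c(3, 5),
                         modality = c("imc", "if"),
                         hot_pixel_rate = 5e-4, blur_sigma_um = 1,
                         panel = c(nuclear = "DNA1_Ir191",
                                   ecm = "Col1A1_Tm169",
                                   epithelial = "panCK_Eu153",
                                   erythrocyte = "Ter119_Sm154",
                                   vessel = "CD31_Pt195"),
                         seed = 1L) {
  modality <- match.arg(modality)
  size <- rep(as.integer(size), length.out = 2)
  stopifnot(all(size >= 32), n_cells >= 0, all(nucleus_radius_um > 0),
            hot_pixel_rate >= 0, hot_pixel_rate < 1, blur_sigma_um >= 0,
            all(c("nuclear", "ecm", "epithelial", "erythrocyte", "vessel")
                %in% names(panel)))
  structure(list(size = size, pixel_size_um = as.numeric(pixel_size_um),
                 n_cells = as.integer(n_cells),
                 nucleus_radius_um = as.numeric(nucleus_radius_um),
                 modality = modality, hot_pixel_rate = hot_pixel_rate,
                 blur_sigma_um = blur_sigma_um, panel = panel,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

# Smooth nonnegative random field in [0,1]: blurred white noise, rescaled.
smooth_field <- function(nr, nc, sigma) {
  f <- blur_gaussian(matrix(stats::runif(nr * nc), nr, nc), sigma)
  rng <- range(f)
  if (rng[2] - rng[1] <= 0) return(matrix(0, nr, nc))
  (f - rng[1]) / (rng[2] - rng[1])
}

# Dart-throwing of non-overlapping discs; error after bounded attempts.
place_nuclei <- function(nr, nc, n, r_range, max_factor = 100L) {
  centers <- matrix(0, 0, 2)
  radii <- numeric(0)
  attempts <- 0L
  max_attempts <- max_factor * max(n, 1L)
  while (nrow(centers) < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      stop(sprintf("could not place %d non-overlapping nuclei in %dx%d px after %d attempts",
                   n, nr, nc, max_attempts), call. = FALSE)
    }
    r <- stats::runif(1, r_range[1], r_range[2])
    y <- stats::runif(1, 1 + r, nr - r)
    x <- stats::runif(1, 1 + r, nc - r)
    if (nrow(centers) > 0) {
      dd <- sqrt((centers[, 1] - y)^2 + (centers[, 2] - x)^2)
      if (any(dd < radii + r + 1)) next
    }
    centers <- rbind(centers, c(y, x))
    radii <- c(radii, r)
  }
  list(centers = centers, radii = radii)
}

# Soft disc profile: quadratic falloff, maximum at the center.
stamp_nuclei <- function(nr, nc, centers, radii, intensities) {
  plane <- matrix(0, nr, nc)
  for (i in seq_len(nrow(centers))) {
    r <- radii[i]
    y0 <- max(1L, floor(centers[i, 1] - r)); y1 <- min(nr, ceiling(centers[i, 1] + r))
    x0 <- max(1L, floor(centers[i, 2] - r)); x1 <- min(nc, ceiling(centers[i, 2] + r))
    yy <- y0:y1; xx <- x0:x1
    d2 <- outer((yy - centers[i, 1])^2, (xx - centers[i, 2])^2, `+`)
    bump <- pmax(0, 1 - d2 / r^2) * intensities[i]
    plane[yy, xx] <- pmax(plane[yy, xx], bump)
  }
  plane
}

# Sinusoidal vessel ribbon mask of given half-width.
vessel_mask <- function(nr, nc, half_width, phase, amp, period) {
  xs <- seq_len(nc)
  center_row <- nr / 2 + amp * sin(2 * pi * xs / period + phase)
  rows <- matrix(seq_len(nr), nr, nc)
  abs(rows - matrix(center_row, nr, nc, byrow = TRUE)) <= half_width
}

#' Generate a synthetic multiplex fixture
#'
#' Builds named marker channels with spatially structured nonnegative
#' signal: soft-disc nuclei at non-overlapping sampled centers, smooth
#' random ECM fields, thresholded epithelial regions, small erythrocyte
#' clusters and sinusoidal vessel ribbons, plus modality-style noise (hot
#' pixels for IMC, Gaussian blur for IF). Deterministic per seed.
#'
#' @param spec a [fixture_spec()].
#' @return a list with `image` (a [multiplex_image()], raw nonnegative
#'   values) and `truth` (list: `centers` tibble with y/x/radius, `masks`
#'   list of logical structure masks).
#' @export
generate_fixture <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  nr <- spec$size[1]; nc <- spec$size[2]
  r_px <- spec$nucleus_radius_um / spec$pixel_size_um
  with_rng_seed(spec$seed, {
    nuc <- place_nuclei(nr, nc, spec$n_cells, r_px)
    n <- nrow(nuc$centers)
    intensities <- 0.6 + 0.4 * stats::rbeta(max(n, 1), 5, 1.5)[seq_len(n)]
    nuclear <- stamp_nuclei(nr, nc, nuc$centers, nuc$radii, intensities)

    epi_field <- smooth_field(nr, nc, sigma = 16)
    epi_mask <- epi_field > stats::quantile(epi_field, 0.6)
    epithelial <- smooth_field(nr, nc, sigma = 4) * epi_mask

    ecm <- smooth_field(nr, nc, sigma = 8) * (1 - 0.7 * epi_mask)

    ery_mask <- matrix(FALSE, nr, nc)
    n_ery <- 5L
    ery <- matrix(0, nr, nc)
    for (i in seq_len(n_ery)) {
      cy <- stats::runif(1, 8, nr - 8); cx <- stats::runif(1, 8, nc - 8)
      rr <- stats::runif(1, 2, 4)
      yy <- max(1, floor(cy - rr)):min(nr, ceiling(cy + rr))
      xx <- max(1, floor(cx - rr)):min(nc, ceiling(cx + rr))
      d2 <- outer((yy - cy)^2, (xx - cx)^2, `+`)
      ery[yy, xx] <- pmax(ery[yy, xx], pmax(0, 1 - d2 / rr^2))
      ery_mask[yy, xx] <- ery_mask[yy, xx] | (d2 <= rr^2)
    }

    vmask <- vessel_mask(nr, nc, half_width = 2.5,
                         phase = stats::runif(1, 0, 2 * pi),
                         amp = nr / 6, period = nc / 1.5)
    vessel <- vmask * (0.6 + 0.4 * smooth_field(nr, nc, sigma = 3))

    chans <- list(nuclear = nuclear, ecm = ecm, epithelial = epithelial,
                  erythrocyte = ery, vessel = vessel)
    if (spec$modality == "if" && spec$blur_sigma_um > 0) {
      s <- spec$blur_sigma_um / spec$pixel_size_um
      chans <- lapply(chans, blur_gaussian, sigma = s)
    }
    if (spec$modality == "imc" && spec$hot_pixel_rate > 0) {
      chans <- lapply(chans, function(p) {
        mask <- stats::runif(length(p)) < spec$hot_pixel_rate
        p[mask] <- max(max(p), 1) * 5
        p
      })
    }
    names(chans) <- unname(spec$panel[c("nuclear", "ecm", "epithelial",
                                        "erythrocyte", "vessel")])
    image <- multiplex_image(chans, pixel_size_um = spec$pixel_size_um)
    truth <- list(
      centers = tibble::tibble(y = nuc$centers[, 1], x = nuc$centers[, 2],
                               radius = nuc$radii),
      masks = list(epithelial = epi_mask, erythrocyte = ery_mask,
                   vessel = vmask)
    )
    list(image = image, truth = truth)
  })
}

#' Write a fixture to disk (OME-TIFF plus ground-truth sidecar)
#'
#' @param spec a [fixture_spec()].
#' @param path output OME-TIFF path; ground truth goes to
#'   `<path>.truth.json`.
#' @return list with `image_path` and `truth_path`, invisibly.
#' @export
write_fixture <- function(spec, path) {
  fx <- generate_fixture(spec)
  write_multiplex(fx$image, path)
  truth_path <- paste0(path, ".truth.json")
  jsonlite::write_json(
    list(centers = fx$truth$centers,
         spec = unclass(spec)[setdiff(names(unclass(spec)), "panel")],
         panel = as.list(spec$panel)),
    truth_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(image_path = path, truth_path = truth_path))
}
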