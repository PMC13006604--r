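# Core S3 containers: multiplex images, stain profiles, render settings,
# intensity stacks and rendered RGB images.

#' Create a multiplex image
#'
#' A multiplex image is an ordered, named collection of nonnegative channel
#' planes (one per molecular marker) sharing a common shape, plus physical
#' pixel size. Planes may be 2D matrices or, for volumetric data, 3D arrays
#' of shape height x width x n_slices.
#'
#' @param channels named list of numeric matrices (or 3D arrays, all with the
#'   same dimensions) holding nonnegative marker signal.
#' @param pixel_size_um in-plane pixel size in micrometres; length 1
#'   (isotropic) or 2 (y, x).
#' @param slice_spacing_um distance between slices in micrometres for 3D
#'   stacks, `NA` for 2D images.
#' @return an object of class `multiplex_image`.
#' @examples
#' img <- multiplex_image(list(DNA1 = matrix(runif(16), 4, 4)), pixel_size_um = 1)
#' img
#' @export
multiplex_image <- function(channels, pixel_size_um = 1, slice_spacing_um = NA_real_) {
  if (!is.list(channels) || length(channels) == 0) {
    stop("`channels` must be a non-empty named list of planes", call. = FALSE)
  }
  nms <- names(channels)
  if (is.null(nms) || any(!nzchar(nms))) {
    stop("every channel must be named", call. = FALSE)
  }
  if (anyDuplicated(nms)) {
    stop("channel names must be unique; duplicated: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  }
  dims <- lapply(channels, function(p) dim(p) %||% length(p))
  ref <- dims[[1]]
  if (!all(vapply(dims, function(d) identical(d, ref), logical(1)))) {
    stop("all channel planes must share an identical shape", call. = FALSE)
  }
  if (!length(ref) %in% c(2L, 3L)) {
    stop("channel planes must be 2D matrices or 3D arrays", call. = FALSE)
  }
  for (nm in nms) {
    v <- channels[[nm]]
    if (!is.numeric(v)) stop("channel '", nm, "' is not numeric", call. = FALSE)
    if (anyNA(v) || min(v) < 0) {
      stop("channel '", nm, "' contains NA or negative values", call. = FALSE)
    }
  }
  pixel_size_um <- as.numeric(pixel_size_um)
  if (length(pixel_size_um) == 1) pixel_size_um <- rep(pixel_size_um, 2)
  if (length(pixel_size_um) != 2 || any(!is.finite(pixel_size_um)) ||
      any(pixel_size_um <= 0)) {
    stop("`pixel_size_um` must be 1 or 2 positive numbers", call. = FALSE)
  }
  structure(
    list(channels = channels, pixel_size_um = pixel_size_um,
         slice_spacing_um = as.numeric(slice_spacing_um)),
    class = "multiplex_image"
  )
}

#' @export
print.multiplex_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  nz <- n_slices(x)
  cat(sprintf("<multiplex_image> %d channels, %d x %d px%s, pixel %g x %g um\n",
              length(x$channels), d[1], d[2],
              if (nz > 1) sprintf(" x %d slices", nz) else "",
              x$pixel_size_um[1], x$pixel_size_um[2]))
  cat("channels:", paste(names(x$channels), collapse = ", "), "\n")
  invisible(x)
}

#' Number of slices in a multiplex image
#' @param image a [multiplex_image()].
#' @return integer, 1 for 2D images.
#' @export
n_slices <- function(image) {
  d <- dim(image$channels[[1]])
  if (length(d) == 3L) d[3] else 1L
}

#' Names of the channels in a multiplex image
#' @param image a [multiplex_image()].
#' @export
channel_names <- function(image) names(image$channels)

# Extract slice s of every channel as a 2D multiplex image.
slice_multiplex <- function(image, s) {
  if (n_slices(image) == 1L) return(image)
  ch <- lapply(image$channels, function(p) p[, , s])
  multiplex_image(ch, pixel_size_um = image$pixel_size_um)
}

#' Define a stain class
#'
#' A stain class is one colored component of a virtual stain: a name, an RGB
#' reference color (the transmitted color of the fully developed stain), a
#' scaling constant controlling overall staining strength, and the list of
#' marker names that drive it.
#'
#' @param name class name, e.g. `"nuclei"`.
#' @param color RGB triple in \[0,1\]: transmission of the pure stain.
#' @param scaling nonnegative scaling constant (staining strength); larger
#'   values darken the class, emulating heavier staining.
#' @param markers character vector of marker aliases assigned to this class.
#' @param description free-text description used in prompts and documentation.
#' @return an object of class `stain_class`.
#' @export
stain_class <- function(name, color, scaling = 1, markers = character(),
                        description = "") {
  stopifnot(is.character(name), length(name) == 1, nzchar(name))
  color <- as.numeric(color)
  if (length(color) != 3 || any(!is.finite(color)) || any(color < 0) ||
      any(color > 1)) {
    stop("`color` must be an RGB triple in [0,1]", call. = FALSE)
  }
  assert_scalar_num(scaling, "scaling", min = 0)
  structure(
    list(name = name, color = color, scaling = scaling,
         markers = as.character(markers), description = description),
    class = "stain_class"
  )
}

#' Rendering settings: background, floor and method
#'
#' The background triple is the white illumination (maximum transmission);
#' the floor is the minimum transmission of the detector (typically black).
#'
#' @param background RGB maximum-transmission triple in \[0,1\].
#' @param floor RGB minimum-transmission triple in \[0,1\], componentwise
#'   less than or equal to `background`.
#' @param method `"physical"` (exponential light absorption) or `"additive"`
#'   (linear subtraction).
#' @return an object of class `render_settings`.
#' @export
render_settings <- function(background = c(1, 1, 1), floor = c(0, 0, 0),
                            method = c("physical", "additive")) {
  method <- match.arg(method)
  background <- as.numeric(background); floor <- as.numeric(floor)
  ok3 <- function(v) length(v) == 3 && all(is.finite(v)) && all(v >= 0) && all(v <= 1)
  if (!ok3(background) || !ok3(floor)) {
    stop("`background` and `floor` must be RGB triples in [0,1]", call. = FALSE)
  }
  if (any(floor > background)) {
    stop("`floor` must not exceed `background` in any channel", call. = FALSE)
  }
  structure(list(background = background, floor = floor, method = method),
            class = "render_settings")
}

#' Define a stain profile
#'
#' A stain profile is an ordered list of stain classes together with default
#' render settings. Shipped presets (H&E, IHC, Masson trichrome, PAS, Jones
#' silver, toluidine blue) can be loaded with [stain_preset()].
#'
#' @param name profile name.
#' @param classes list of [stain_class()] objects with unique names.
#' @param settings default [render_settings()].
#' @param description free text.
#' @return an object of class `stain_profile`.
#' @export
stain_profile <- function(name, classes, settings = render_settings(),
                          description = "") {
  stopifnot(is.character(name), length(name) == 1, nzchar(name))
  if (!is.list(classes) || length(classes) < 1 ||
      !all(vapply(classes, inherits, logical(1), "stain_class"))) {
    stop("`classes` must be a non-empty list of stain_class objects", call. = FALSE)
  }
  nms <- vapply(classes, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("class names must be unique", call. = FALSE)
  names(classes) <- nms
  stopifnot(inherits(settings, "render_settings"))
  structure(list(name = name, classes = classes, settings = settings,
                 description = description),
            class = "stain_profile")
}

#' @export
print.stain_profile <- function(x, ...) {
  cat(sprintf("<stain_profile> '%s' (%d classes, method %s)\n", x$name,
              length(x$classes), x$settings$method))
  for (cl in x$classes) {
    cat(sprintf("  %-16s color (%.2f, %.2f, %.2f)  k=%.2g  markers: %s\n",
                cl$name, cl$color[1], cl$color[2], cl$color[3], cl$scaling,
                if (length(cl$markers)) paste(utils::head(cl$markers, 6), collapse = ", ")
                else "(none)"))
  }
  invisible(x)
}

#' Class names of a stain profile
#' @param profile a [stain_profile()].
#' @export
stain_class_names <- function(profile) {
  vapply(profile$classes, `[[`, character(1), "name")
}

# Intensity stack: one plane per stain class.
intensity_stack <- function(planes, class_names) {
  names(planes) <- class_names
  structure(list(planes = planes), class = "intensity_stack")
}

#' @export
print.intensity_stack <- function(x, ...) {
  d <- dim(x$planes[[1]])
  cat(sprintf("<intensity_stack> %d classes, %d x %d px: %s\n",
              length(x$planes), d[1], d[2],
              paste(names(x$planes), collapse = ", ")))
  invisible(x)
}

#' Create an RGB image
#'
#' Values live in \[0,1\] internally; conversion to 8-bit happens only at
#' export, rounding half away from zero.
#'
#' @param data numeric array of shape height x width x 3, clipped to \[0,1\].
#' @param pixel_size_um physical pixel size (length 1 or 2, micrometres).
#' @return an object of class `rgb_image`.
#' @export
rgb_image <- function(data, pixel_size_um = 1) {
  if (!is.array(data) || length(dim(data)) != 3 || dim(data)[3] != 3) {
    stop("`data` must be a height x width x 3 array", call. = FALSE)
  }
  pixel_size_um <- as.numeric(pixel_size_um)
  if (length(pixel_size_um) == 1) pixel_size_um <- rep(pixel_size_um, 2)
  stopifnot(length(pixel_size_um) == 2, all(pixel_size_um > 0))
  structure(list(data = clip01(data), pixel_size_um = pixel_size_um),
            class = "rgb_image")
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<rgb_image> %d x %d px, pixel %g x %g um, range [%.3f, %.3f]\n",
              d[1], d[2], x$pixel_size_um[1], x$pixel_size_um[2],
              min(x$data), max(x$data)))
  invisible(x)
}

#' Display an RGB image
#'
#' @param x an [rgb_image()].
#' @param y unused.
#' @param ... unused.
#' @export
plot.rgb_image <- function(x, y, ...) {
  op <- graphics::par(mar = c(0, 0, 0, 0))
  on.exit(graphics::par(op))
  graphics::plot.new()
  graphics::rasterImage(grDevices::as.raster(x$data), 0, 0, 1, 1,
                        interpolate = FALSE)
  invisible(x)
}

# Coerce matrix / rgb_image to the raw data array.
as_image_array <- function(x) {
  if (inherits(x, "rgb_image")) x$data else x
}
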