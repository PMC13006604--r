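# Light-absorption stain model.
#
# Each stain class i has a reference transmission color S_i = (S_iR, S_iG,
# S_iB), a scaling constant k_i and an intensity image I_i averaged from its
# assigned marker channels. Per color channel c with background transmission
# c_c and floor d_c:
#
#   additive:  out_c = c_c - sum_i k_i I_i (c_c - S_ic)          (clipped)
#   physical:  out_c = d_c + (c_c - d_c) exp(-sum_i k_i I_i (c_c - S_ic))
#
# The physical method follows the Beer-Lambert law: transmitted light decays
# exponentially with the amount of absorber along the optical path, so the
# output approaches the floor monotonically as stain amount grows.

#' Compute per-class intensity images
#'
#' For every stain class, averages the normalized marker channels assigned
#' to it into a single intensity plane. A class with no assigned channels
#' contributes an all-zero plane (zero absorption) rather than an error,
#' since real panels often lack markers for some class.
#'
#' @param image a [multiplex_image()] with planes normalized to \[0,1\]
#'   (see [normalize_marker()]).
#' @param assignment a `channel_assignment` mapping class names to channel
#'   names, e.g. from [assign_by_lexicon()].
#' @param profile a [stain_profile()].
#' @return an `intensity_stack` with one plane per class of `profile`.
#' @examples
#' img <- multiplex_image(list(DNA1 = matrix(0.5, 4, 4)))
#' prof <- stain_preset("h_and_e")
#' asn <- assign_by_lexicon(channel_names(img), "h_and_e")
#' compute_intensity_stack(img, asn, prof)
#' @export
compute_intensity_stack <- function(image, assignment, profile) {
  stopifnot(inherits(image, "multiplex_image"),
            inherits(profile, "stain_profile"))
  amap <- assignment_map(assignment)
  d <- dim(image$channels[[1]])[1:2]
  zero <- matrix(0, d[1], d[2])
  planes <- lapply(stain_class_names(profile), function(cls) {
    chans <- amap[[cls]] %||% character()
    if (length(chans) == 0) return(zero)
    missing <- setdiff(chans, channel_names(image))
    if (length(missing)) {
      stop(sprintf("channel '%s' assigned to class '%s' not found in image",
                   missing[1], cls), call. = FALSE)
    }
    Reduce(`+`, image$channels[chans]) / length(chans)
  })
  intensity_stack(planes, stain_class_names(profile))
}

# Attenuation coefficients (c_c - S_ic), clamped at zero: a stain color
# brighter than the background would un-physically brighten the image.
attenuation_coefs <- function(profile, settings) {
  coefs <- lapply(profile$classes, function(cl) settings$background - cl$color)
  clamped <- vapply(coefs, function(v) any(v < 0), logical(1))
  if (any(clamped)) {
    warning("stain color exceeds background transmission for class(es) ",
            paste(names(profile$classes)[clamped], collapse = ", "),
            "; attenuation clamped at 0", call. = FALSE)
    coefs <- lapply(coefs, pmax, 0)
  }
  coefs
}

#' Render an intensity stack to a virtual brightfield RGB image
#'
#' Applies the additive or physical (exponential absorption) stain model to
#' per-class intensity planes.
#'
#' @param intensities an `intensity_stack` from [compute_intensity_stack()].
#' @param profile a [stain_profile()] supplying colors and scalings.
#' @param settings a [render_settings()]; defaults to the profile's own.
#' @param pixel_size_um pixel size carried into the output image.
#' @return an [rgb_image()] with values in \[0,1\].
#' @export
render <- function(intensities, profile, settings = profile$settings,
                   pixel_size_um = 1) {
  stopifnot(inherits(intensities, "intensity_stack"),
            inherits(profile, "stain_profile"),
            inherits(settings, "render_settings"))
  if (length(intensities$planes) != length(profile$classes)) {
    stop("intensity stack has ", length(intensities$planes),
         " planes but profile defines ", length(profile$classes), " classes",
         call. = FALSE)
  }
  dims <- unique(lapply(intensities$planes, dim))
  if (length(dims) != 1) stop("intensity planes differ in shape", call. = FALSE)
  d <- dims[[1]]
  coefs <- attenuation_coefs(profile, settings)
  ks <- vapply(profile$classes, `[[`, numeric(1), "scaling")
  out <- array(0, c(d[1], d[2], 3))
  for (c in 1:3) {
    expo <- matrix(0, d[1], d[2])
    for (i in seq_along(profile$classes)) {
      a <- ks[i] * coefs[[i]][c]
      if (a != 0) expo <- expo + a * intensities$planes[[i]]
    }
    cc <- settings$background[c]; dc <- settings$floor[c]
    out[, , c] <- switch(settings$method,
      additive = cc - expo,
      physical = dc + (cc - dc) * exp(-expo)
    )
  }
  rgb_image(out, pixel_size_um = pixel_size_um)
}

#' Render a multiplex image in one call
#'
#' Convenience wrapper: channel assignment (lexicon by default), intensity
#' computation and rendering.
#'
#' @inheritParams compute_intensity_stack
#' @param assignment optional pre-computed assignment; defaults to lexicon
#'   matching against the profile's marker lists.
#' @param settings render settings (defaults to the profile's).
#' @return an [rgb_image()].
#' @export
render_multiplex <- function(image, profile, assignment = NULL,
                             settings = profile$settings) {
  if (is.null(assignment)) {
    assignment <- assign_by_lexicon(channel_names(image), profile = profile)
  }
  stack <- compute_intensity_stack(image, assignment, profile)
  render(stack, profile, settings, pixel_size_um = image$pixel_size_um)
}

#' Render a 3D multiplex volume slice-wise
#'
#' Each slice is rendered independently with the 2D pipeline; slice spacing
#' metadata is passed through.
#'
#' @param volume a [multiplex_image()] with `n_slices > 1` (3D channel arrays).
#' @inheritParams render_multiplex
#' @return a list of [rgb_image()] objects, one per slice, with attribute
#'   `slice_spacing_um`.
#' @export
render_volume <- function(volume, profile, assignment = NULL,
                          settings = profile$settings) {
  stopifnot(inherits(volume, "multiplex_image"))
  nz <- n_slices(volume)
  slices <- lapply(seq_len(nz), function(s) {
    render_multiplex(slice_multiplex(volume, s), profile,
                     assignment = assignment, settings = settings)
  })
  attr(slices, "slice_spacing_um") <- volume$slice_spacing_um
  slices
}
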