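# OME-TIFF input/output. Multiplex images are stored as one 32-bit float
# page per channel (per slice), rendered RGB images as a single 8-bit
# interleaved page; channel names and physical pixel sizes travel in an
# OME-XML ImageDescription. Reading goes through tiff::readTIFF; writing
# uses the package's own minimal baseline-TIFF writer (uncompressed,
# little-endian, byte-deterministic for fixed input).

ome_namespace <- "http://www.openmicroscopy.org/Schemas/OME/2016-06"

build_ome_xml <- function(size_x, size_y, size_c, size_z, type, channel_names,
                          pixel_size_um, slice_spacing_um = NA_real_,
                          interleaved = FALSE, name = "virtualstain") {
  doc <- xml2::xml_new_root("OME", xmlns = ome_namespace)
  img <- xml2::xml_add_child(doc, "Image", ID = "Image:0", Name = name)
  px_attrs <- list(
    ID = "Pixels:0", DimensionOrder = "XYCZT", Type = type,
    SizeX = as.character(size_x), SizeY = as.character(size_y),
    SizeC = as.character(size_c), SizeZ = as.character(size_z), SizeT = "1",
    PhysicalSizeX = format(pixel_size_um[2], digits = 10),
    PhysicalSizeY = format(pixel_size_um[1], digits = 10),
    PhysicalSizeXUnit = "µm", PhysicalSizeYUnit = "µm",
    Interleaved = if (interleaved) "true" else "false"
  )
  if (is.finite(slice_spacing_um)) {
    px_attrs$PhysicalSizeZ <- format(slice_spacing_um, digits = 10)
    px_attrs$PhysicalSizeZUnit <- "µm"
  }
  px <- xml2::xml_add_child(img, "Pixels")
  do.call(xml2::xml_set_attrs, c(list(px), list(unlist(px_attrs))))
  if (interleaved) {
    xml2::xml_add_child(px, "Channel", ID = "Channel:0:0",
                        SamplesPerPixel = "3")
  } else {
    for (i in seq_along(channel_names)) {
      xml2::xml_add_child(px, "Channel",
                          ID = sprintf("Channel:0:%d", i - 1L),
                          Name = channel_names[i], SamplesPerPixel = "1")
    }
  }
  xml2::xml_add_child(px, "TiffData")
  as.character(doc)
}

# --- minimal baseline TIFF writer ------------------------------------------
# Tag constants
.tag <- list(width = 256L, height = 257L, bps = 258L, compression = 259L,
             photometric = 262L, description = 270L, strip_offsets = 273L,
             spp = 277L, rows_per_strip = 278L, strip_bytes = 279L,
             planar = 284L, sample_format = 339L)
.type_short <- 3L; .type_long <- 4L; .type_ascii <- 2L

write_tiff_pages <- function(pages, path, kind = c("float", "rgb8"),
                             description = NULL) {
  kind <- match.arg(kind)
  con <- file(path, "wb")
  on.exit(close(con))
  w16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")

  n <- length(pages)
  dims <- lapply(pages, function(p) dim(p)[1:2])
  strip_bytes <- vapply(seq_len(n), function(i) {
    h <- dims[[i]][1]; w <- dims[[i]][2]
    if (kind == "float") h * w * 4 else h * w * 3
  }, numeric(1))
  data_offsets <- 8 + cumsum(c(0, strip_bytes[-n]))

  desc_bytes <- if (!is.null(description)) {
    c(charToRaw(enc2utf8(description)), as.raw(0L))
  } else raw(0)

  n_entries <- function(i) {
    base <- 10L  # float: SampleFormat; rgb: PlanarConfig
    if (i == 1L && length(desc_bytes)) base + 1L else base
  }
  ifd_core_size <- function(i) 2 + 12 * n_entries(i) + 4
  extra_size <- function(i) {
    sz <- 0
    if (kind == "rgb8") sz <- sz + 6                       # 3 x SHORT bits
    if (i == 1L && length(desc_bytes) > 4) sz <- sz + length(desc_bytes)
    sz
  }
  ifd_offsets <- numeric(n)
  cursor <- 8 + sum(strip_bytes)
  for (i in seq_len(n)) {
    ifd_offsets[i] <- cursor
    cursor <- cursor + ifd_core_size(i) + extra_size(i)
  }

  # header
  writeBin(charToRaw("II"), con)
  w16(42L)
  w32(ifd_offsets[1])

  # image data
  for (i in seq_len(n)) {
    p <- pages[[i]]
    if (kind == "float") {
      # row-major pixel order
      writeBin(as.numeric(t(p)), con, size = 4, endian = "little")
    } else {
      v <- as.integer(aperm(p, c(3, 2, 1)))  # RGB interleaved, row-major
      writeBin(as.raw(v), con)
    }
  }

  entry <- function(tag, type, count, value) {
    w16(tag); w16(type); w32(count); w32(value)
  }
  for (i in seq_len(n)) {
    h <- dims[[i]][1]; w <- dims[[i]][2]
    after_core <- ifd_offsets[i] + ifd_core_size(i)
    bps_offset <- after_core
    desc_offset <- after_core + (if (kind == "rgb8") 6 else 0)
    has_desc <- i == 1L && length(desc_bytes) > 0
    ents <- list()
    add <- function(...) ents[[length(ents) + 1L]] <<- list(...)
    add(.tag$width, .type_long, 1L, w)
    add(.tag$height, .type_long, 1L, h)
    if (kind == "float") add(.tag$bps, .type_short, 1L, 32L)
    else add(.tag$bps, .type_short, 3L, bps_offset)
    add(.tag$compression, .type_short, 1L, 1L)
    add(.tag$photometric, .type_short, 1L, if (kind == "float") 1L else 2L)
    if (has_desc) {
      nd <- length(desc_bytes)
      add(.tag$description, .type_ascii, nd,
          if (nd <= 4) sum(as.integer(desc_bytes) * 256^(seq_len(nd) - 1))
          else desc_offset)
    }
    add(.tag$strip_offsets, .type_long, 1L, data_offsets[i])
    add(.tag$spp, .type_short, 1L, if (kind == "float") 1L else 3L)
    add(.tag$rows_per_strip, .type_long, 1L, h)
    add(.tag$strip_bytes, .type_long, 1L, strip_bytes[i])
    if (kind == "rgb8") add(.tag$planar, .type_short, 1L, 1L)
    if (kind == "float") add(.tag$sample_format, .type_short, 1L, 3L)
    # entries must be sorted by tag
    ord <- order(vapply(ents, `[[`, integer(1), 1L))
    w16(length(ents))
    for (e in ents[ord]) entry(e[[1]], e[[2]], e[[3]], e[[4]])
    w32(if (i < n) ifd_offsets[i + 1L] else 0L)
    if (kind == "rgb8") w16(c(8L, 8L, 8L))
    if (has_desc && length(desc_bytes) > 4) writeBin(desc_bytes, con)
  }
  invisible(path)
}

# --- public API -------------------------------------------------------------

#' Write a multiplex image as OME-TIFF
#'
#' One 32-bit float page per channel (and per slice for 3D stacks, channels
#' fastest per the XYCZT dimension order), with channel names and pixel
#' sizes embedded as OME-XML.
#'
#' @param image a [multiplex_image()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_multiplex <- function(image, path) {
  stopifnot(inherits(image, "multiplex_image"))
  nz <- n_slices(image)
  d <- dim(image$channels[[1]])
  pages <- list()
  for (z in seq_len(nz)) {
    for (ch in image$channels) {
      pages[[length(pages) + 1L]] <- if (nz == 1L) ch else ch[, , z]
    }
  }
  desc <- build_ome_xml(size_x = d[2], size_y = d[1],
                        size_c = length(image$channels), size_z = nz,
                        type = "float", channel_names = channel_names(image),
                        pixel_size_um = image$pixel_size_um,
                        slice_spacing_um = image$slice_spacing_um)
  write_tiff_pages(pages, path, kind = "float", description = desc)
  invisible(path)
}

#' Write an RGB image as 8-bit interleaved OME-TIFF
#'
#' Values are converted to 8-bit rounding half away from zero; pixel size
#' metadata is preserved in the OME-XML. Output bytes are deterministic for
#' fixed input.
#'
#' @param image an [rgb_image()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rgb <- function(image, path) {
  stopifnot(inherits(image, "rgb_image"))
  d <- dim(image$data)
  desc <- build_ome_xml(size_x = d[2], size_y = d[1], size_c = 3L, size_z = 1L,
                        type = "uint8", channel_names = c("R", "G", "B"),
                        pixel_size_um = image$pixel_size_um,
                        interleaved = TRUE)
  write_tiff_pages(list(to_uint8(image$data)), path, kind = "rgb8",
                   description = desc)
  invisible(path)
}

parse_ome_description <- function(desc) {
  if (is.null(desc) || !nzchar(desc)) return(NULL)
  doc <- tryCatch(xml2::read_xml(desc), error = function(e) NULL)
  if (is.null(doc)) return(NULL)
  xml2::xml_ns_strip(doc)
  px <- xml2::xml_find_first(doc, ".//Pixels")
  if (inherits(px, "xml_missing")) return(NULL)
  at <- function(n) xml2::xml_attr(px, n)
  chs <- xml2::xml_find_all(doc, ".//Channel")
  list(
    size_c = as.integer(at("SizeC")), size_z = as.integer(at("SizeZ")) %||% 1L,
    type = at("Type"),
    physical_x = suppressWarnings(as.numeric(at("PhysicalSizeX"))),
    physical_y = suppressWarnings(as.numeric(at("PhysicalSizeY"))),
    physical_z = suppressWarnings(as.numeric(at("PhysicalSizeZ"))),
    channel_names = xml2::xml_attr(chs, "Name"),
    interleaved = identical(at("Interleaved"), "true")
  )
}

#' Read a multiplex OME-TIFF
#'
#' Channel names and pixel sizes are taken from the embedded OME-XML;
#' missing channel names are synthesized as `channel_<index>` with a
#' warning. Integer data are scaled to \[0,1\] by the dtype maximum on
#' read; float data are taken as stored. 2D and multi-slice (XYCZT,
#' channels fastest) layouts are supported.
#'
#' @param path path to an OME-TIFF.
#' @return a [multiplex_image()].
#' @export
read_multiplex <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  pages <- tryCatch(
    suppressWarnings(tiff::readTIFF(path, all = TRUE, info = TRUE)),
    error = function(e) stop("cannot read TIFF '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (!is.list(pages)) pages <- list(pages)
  meta <- parse_ome_description(attr(pages[[1]], "description"))
  n_pages <- length(pages)
  if (is.null(meta)) {
    warning("no OME-XML metadata found; synthesizing channel names and ",
            "assuming 1 um pixels", call. = FALSE)
    meta <- list(size_c = n_pages, size_z = 1L,
                 physical_x = 1, physical_y = 1, physical_z = NA_real_,
                 channel_names = rep(NA_character_, n_pages))
  }
  size_c <- meta$size_c
  size_z <- meta$size_z %||% 1L
  if (is.na(size_z)) size_z <- 1L
  if (is.na(size_c) || size_c * size_z != n_pages) {
    stop(sprintf("metadata declares %s channels x %s slices but file has %d planes",
                 size_c, size_z, n_pages), call. = FALSE)
  }
  nms <- meta$channel_names
  if (length(nms) != size_c) nms <- rep(NA_character_, size_c)
  if (anyNA(nms) || any(!nzchar(nms))) {
    fill <- is.na(nms) | !nzchar(nms)
    nms[fill] <- sprintf("channel_%d", which(fill))
    warning("missing channel name(s) synthesized: ",
            paste(nms[fill], collapse = ", "), call. = FALSE)
  }
  planes <- lapply(pages, function(p) {
    m <- unclass(p)
    attributes(m) <- list(dim = dim(m))
    if (length(dim(m)) == 3L) m[, , 1] else m
  })
  channels <- lapply(seq_len(size_c), function(ci) {
    if (size_z == 1L) {
      planes[[ci]]
    } else {
      slc <- lapply(seq_len(size_z), function(z) planes[[(z - 1L) * size_c + ci]])
      array(unlist(slc), c(dim(slc[[1]]), size_z))
    }
  })
  names(channels) <- nms
  psy <- meta$physical_y; psx <- meta$physical_x
  if (is.na(psy) || is.na(psx)) { psy <- 1; psx <- 1 }
  multiplex_image(channels, pixel_size_um = c(psy, psx),
                  slice_spacing_um = meta$physical_z %||% NA_real_)
}

#' Read an RGB OME-TIFF written by [write_rgb()]
#'
#' @param path path to the file.
#' @return an [rgb_image()].
#' @export
read_rgb <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  p <- tryCatch(suppressWarnings(tiff::readTIFF(path, info = TRUE)),
                error = function(e) stop("cannot read TIFF '", path, "': ",
                                         conditionMessage(e), call. = FALSE))
  meta <- parse_ome_description(attr(p, "description"))
  d <- dim(p)
  if (length(d) != 3L || d[3] < 3L) {
    stop("not an RGB image: ", path, call. = FALSE)
  }
  a <- unclass(p)[, , 1:3, drop = FALSE]
  attributes(a) <- list(dim = dim(a))
  ps <- c(meta$physical_y %||% 1, meta$physical_x %||% 1)
  if (anyNA(ps)) ps <- c(1, 1)
  rgb_image(a, pixel_size_um = ps)
}
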