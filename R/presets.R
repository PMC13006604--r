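# Stain presets: human-editable YAML profiles shipped under inst/profiles.

preset_dir <- function() system.file("profiles", package = "virtualstain")

#' List shipped stain presets
#'
#' @return character vector of preset names usable with [stain_preset()].
#' @export
list_stain_presets <- function() {
  sort(tools::file_path_sans_ext(list.files(preset_dir(), pattern = "\\.ya?ml$")))
}

#' Load a shipped stain preset
#'
#' @param name preset name, one of [list_stain_presets()].
#' @param palette optional named alternative color set defined in the preset
#'   file (emulating different microscope/scanner systems).
#' @return a [stain_profile()].
#' @examples
#' stain_preset("h_and_e")
#' @export
stain_preset <- function(name, palette = NULL) {
  stopifnot(is.character(name), length(name) == 1)
  path <- file.path(preset_dir(), paste0(name, ".yaml"))
  if (!file.exists(path)) {
    stop(sprintf("unknown stain '%s'; available presets: %s", name,
                 paste(list_stain_presets(), collapse = ", ")), call. = FALSE)
  }
  read_stain_profile(path, palette = palette)
}

#' Read a stain profile from a YAML config file
#'
#' The file format matches the shipped presets: fields `name`, `description`,
#' `method`, `background`, `floor` and `classes` (each with `name`,
#' `description`, `color`, `scaling`, `markers`), plus optional named
#' `palettes` overriding class colors.
#'
#' @param path path to a YAML profile.
#' @param palette optional palette name defined in the file.
#' @return a [stain_profile()].
#' @export
read_stain_profile <- function(path, palette = NULL) {
  cfg <- yaml::read_yaml(path)
  required <- c("name", "classes")
  missing <- setdiff(required, names(cfg))
  if (length(missing)) {
    stop("profile file lacks field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  pal <- NULL
  if (!is.null(palette)) {
    pal <- cfg$palettes[[palette]]
    if (is.null(pal)) {
      stop(sprintf("palette '%s' not defined in profile '%s'; available: %s",
                   palette, cfg$name,
                   paste(names(cfg$palettes), collapse = ", ")), call. = FALSE)
    }
  }
  classes <- lapply(cfg$classes, function(cl) {
    color <- if (!is.null(pal) && !is.null(pal[[cl$name]])) pal[[cl$name]] else cl$color
    stain_class(
      name = cl$name,
      color = as.numeric(color),
      scaling = cl$scaling %||% 1,
      markers = as.character(unlist(cl$markers %||% character())),
      description = cl$description %||% ""
    )
  })
  settings <- render_settings(
    background = cfg$background %||% c(1, 1, 1),
    floor = cfg$floor %||% c(0, 0, 0),
    method = cfg$method %||% "physical"
  )
  stain_profile(cfg$name, classes, settings = settings,
                description = cfg$description %||% "")
}

#' Write a stain profile to a YAML config file
#'
#' @param profile a [stain_profile()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stain_profile <- function(profile, path) {
  stopifnot(inherits(profile, "stain_profile"))
  cfg <- list(
    name = profile$name,
    description = profile$description,
    method = profile$settings$method,
    background = profile$settings$background,
    floor = profile$settings$floor,
    classes = lapply(unname(profile$classes), function(cl) {
      list(name = cl$name, description = cl$description,
           color = cl$color, scaling = cl$scaling,
           markers = as.list(cl$markers))
    })
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}
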