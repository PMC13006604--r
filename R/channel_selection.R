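# Channel selection: mapping multiplex channel names to stain classes,
# either by curated alias lexicons or through a pluggable LLM provider, plus
# the multi-model consensus Jaccard agreement statistic.

# Metal isotope tags used by mass-cytometry panels: element symbol + 3-digit
# mass, optionally wrapped in parentheses or attached with separators
# ("DNA1_Ir191", "aSMA (Pt196)", "141Pr-Col1A1"). Only removed when the tag
# is delimited, so marker names like CD103 survive.
.isotope_elements <- c(
  "la", "ce", "pr", "nd", "pm", "sm", "eu", "gd", "tb", "dy", "ho", "er",
  "tm", "yb", "lu", "in", "ir", "pt", "pd", "cd", "sn", "sb", "te", "ba",
  "os", "ru", "rh", "re", "au", "tl", "pb", "bi", "xe", "cs", "w", "y"
)

#' Canonicalize a channel or marker name
#'
#' Lexicon matching operates on canonical tokens: case-folded, with metal
#' isotope tags removed (element symbol plus 3-digit mass, in any of the
#' common delimited spellings), Greek-letter prefixes transliterated
#' (alpha/beta/gamma to a/b/g) and all non-alphanumeric characters stripped.
#'
#' @param name character vector of channel names.
#' @return character vector of canonical tokens.
#' @examples
#' normalize_channel_name(c("CD31", "DNA1_Ir191", "aSMA (Pt196)"))
#' @export
normalize_channel_name <- function(name) {
  if (length(name) == 0) return(character())
  if (!is.character(name) || any(is.na(name)) || any(!nzchar(name))) {
    stop("channel names must be non-empty strings", call. = FALSE)
  }
  vapply(name, function(x) {
    x0 <- x
    x <- chartr("αβγ", "abg", x)
    elems <- paste(.isotope_elements, collapse = "|")
    # delimited suffix/prefix tags: Ir191, (Pt196), 141Pr
    tag1 <- sprintf("(?i)(?<![a-z0-9])(%s)\\s*-?\\s*([0-9]{3})(?![0-9])", elems)
    tag2 <- sprintf("(?i)(?<![a-z0-9])([0-9]{3})\\s*-?\\s*(%s)(?![a-z])", elems)
    stripped <- gsub(tag2, "", gsub(tag1, "", x, perl = TRUE), perl = TRUE)
    tok <- tolower(gsub("[^[:alnum:]]", "", stripped))
    if (!nzchar(tok)) tok <- tolower(gsub("[^[:alnum:]]", "", x))
    tok
  }, character(1), USE.NAMES = FALSE)
}

#' Construct a channel assignment
#'
#' Maps stain-class names to sets of channel names (kept in their original,
#' un-normalized spelling). A channel may appear in more than one class;
#' `unassigned` holds the channels matching no class.
#'
#' @param assignment named list: class name -> character vector of channels.
#' @param unassigned character vector of ignored channel names.
#' @param stain optional stain name the assignment belongs to.
#' @return an object of class `channel_assignment`.
#' @export
channel_assignment <- function(assignment, unassigned = character(),
                               stain = NA_character_) {
  stopifnot(is.list(assignment))
  if (length(assignment) && (is.null(names(assignment)) ||
                             any(!nzchar(names(assignment))))) {
    stop("`assignment` must be a fully named list", call. = FALSE)
  }
  assignment <- lapply(assignment, function(v) unique(as.character(v)))
  structure(list(assignment = assignment,
                 unassigned = unique(as.character(unassigned)),
                 stain = stain),
            class = "channel_assignment")
}

assignment_map <- function(x) {
  if (inherits(x, "channel_assignment")) x$assignment
  else if (is.list(x)) x
  else stop("expected a channel_assignment", call. = FALSE)
}

#' @export
print.channel_assignment <- function(x, ...) {
  cat(sprintf("<channel_assignment>%s\n",
              if (!is.na(x$stain)) paste0(" stain '", x$stain, "'") else ""))
  for (cls in names(x$assignment)) {
    cat(sprintf("  %-16s %s\n", cls,
                if (length(x$assignment[[cls]]))
                  paste(x$assignment[[cls]], collapse = ", ") else "(none)"))
  }
  if (length(x$unassigned)) {
    cat("  unassigned:     ", paste(x$unassigned, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tidy a channel assignment into a tibble
#'
#' @param x a `channel_assignment`.
#' @param ... unused.
#' @return a tibble with columns `class` and `channel` (class `"(unassigned)"`
#'   for ignored channels).
#' @export
tidy.channel_assignment <- function(x, ...) {
  rows <- c(
    lapply(names(x$assignment), function(cls) {
      if (length(x$assignment[[cls]]))
        tibble::tibble(class = cls, channel = x$assignment[[cls]])
    }),
    if (length(x$unassigned))
      list(tibble::tibble(class = "(unassigned)", channel = x$unassigned))
  )
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(tibble::tibble(class = character(), channel = character()))
  do.call(rbind, rows)
}

# Lexicon of a profile: class name -> canonical alias tokens.
profile_lexicon <- function(profile) {
  lex <- lapply(profile$classes, function(cl) {
    unique(normalize_channel_name(cl$markers))
  })
  names(lex) <- stain_class_names(profile)
  lex
}

#' Assign channels to stain classes by lexicon lookup
#'
#' Each channel name is canonicalized with [normalize_channel_name()] and
#' compared against the curated alias list of every class of the stain;
#' matching channels join that class, the rest are ignored.
#'
#' @param channel_names character vector of channel names from the image.
#' @param stain name of a shipped stain preset (see [list_stain_presets()]).
#' @param profile a [stain_profile()]; overrides `stain` when given.
#' @return a [channel_assignment()].
#' @examples
#' assign_by_lexicon(c("DNA1_Ir191", "CD31", "Vimentin"), "h_and_e")
#' @export
assign_by_lexicon <- function(channel_names, stain = NULL, profile = NULL) {
  if (is.null(profile)) {
    if (is.null(stain)) stop("give either `stain` or `profile`", call. = FALSE)
    profile <- stain_preset(stain)
  }
  lex <- profile_lexicon(profile)
  toks <- normalize_channel_name(channel_names)
  asn <- lapply(lex, function(aliases) channel_names[toks %in% aliases])
  matched <- unique(unlist(asn, use.names = FALSE))
  channel_assignment(asn, unassigned = setdiff(channel_names, matched),
                     stain = profile$name)
}

#' Build the channel-selection prompt for an LLM
#'
#' The prompt states the task, the stain name, every class with its
#' description and display color, the complete channel list, and a strict
#' JSON output schema. It is byte-deterministic in its inputs.
#'
#' @param stain stain name.
#' @param classes list of [stain_class()] objects (or a [stain_profile()]).
#' @param channel_names character vector of channel names.
#' @return a single string.
#' @export
build_llm_prompt <- function(stain, classes, channel_names) {
  if (inherits(classes, "stain_profile")) classes <- classes$classes
  stopifnot(length(classes) >= 1, length(channel_names) >= 1)
  hex <- vapply(classes, function(cl) {
    grDevices::rgb(cl$color[1], cl$color[2], cl$color[3])
  }, character(1))
  cls_lines <- vapply(seq_along(classes), function(i) {
    cl <- classes[[i]]
    sprintf("%d. \"%s\": %s (display color %s)", i, cl$name,
            if (nzchar(cl$description)) cl$description else "no description",
            hex[i])
  }, character(1))
  key_list <- paste(sprintf('"%s"', vapply(classes, `[[`, character(1), "name")),
                    collapse = ", ")
  paste0(
    "Task: you are selecting channels of a multiplex microscopy image to ",
    "simulate a brightfield stain. Assign each relevant channel name to the ",
    "stain class whose biological structure it marks; ignore channels that ",
    "fit no class.\n",
    "Stain: ", stain, "\n",
    "Classes:\n", paste(cls_lines, collapse = "\n"), "\n",
    "Channels:\n", paste(sprintf("- %s", channel_names), collapse = "\n"), "\n",
    "Output format: respond with a single JSON object and nothing else, ",
    "with exactly these keys: ", key_list, ". Each key maps to an array of ",
    "channel names copied verbatim from the channel list above. A channel ",
    "may appear under more than one class; omit channels that fit no class.\n"
  )
}

#' Parse an LLM channel-selection response
#'
#' Accepts the JSON response schema produced for [build_llm_prompt()]: one
#' object mapping class names to arrays of channel names. Channels absent
#' from `channel_names` are dropped with a warning; missing class keys are
#' treated as empty.
#'
#' @param response raw response text (may contain surrounding prose or code
#'   fences; the first JSON object found is used).
#' @param classes list of [stain_class()] objects or a [stain_profile()].
#' @param channel_names the channel names that were offered in the prompt.
#' @return a [channel_assignment()].
#' @export
parse_llm_response <- function(response, classes, channel_names) {
  if (inherits(classes, "stain_profile")) classes <- classes$classes
  stopifnot(is.character(response), length(response) == 1, nzchar(response))
  first <- regexpr("\\{", response)
  last <- max(gregexpr("\\}", response)[[1]])
  parsed <- NULL
  if (first > 0 && last > first) {
    json <- substr(response, first, last)
    parsed <- tryCatch(jsonlite::fromJSON(json, simplifyVector = TRUE),
                       error = function(e) NULL)
  }
  if (is.null(parsed) || !is.list(parsed)) {
    cnd <- simpleError(paste0("response does not contain a parseable JSON ",
                              "object mapping classes to channel lists"))
    cnd$raw_response <- response
    class(cnd) <- c("virtualstain_parse_error", class(cnd))
    stop(cnd)
  }
  cls_names <- vapply(classes, `[[`, character(1), "name")
  dropped <- character()
  asn <- lapply(cls_names, function(cls) {
    v <- as.character(unlist(parsed[[cls]], use.names = FALSE))
    bad <- setdiff(v, channel_names)
    if (length(bad)) dropped <<- union(dropped, bad)
    intersect(v, channel_names)
  })
  names(asn) <- cls_names
  if (length(dropped)) {
    warning("response named channel(s) not present in the image, dropped: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  matched <- unique(unlist(asn, use.names = FALSE))
  channel_assignment(asn, unassigned = setdiff(channel_names, matched))
}

#' Serialize a channel assignment in the LLM response schema
#'
#' Inverse of [parse_llm_response()]: renders the JSON object the prompt
#' asks for. Useful for testing providers and for the offline mock.
#'
#' @param assignment a [channel_assignment()].
#' @return a JSON string.
#' @export
format_llm_response <- function(assignment) {
  amap <- assignment_map(assignment)
  jsonlite::toJSON(lapply(amap, as.character), auto_unbox = FALSE)
}

#' Offline mock LLM provider
#'
#' Returns a provider function (`function(prompt) -> response text`) that
#' deterministically answers channel-selection prompts from the shipped
#' lexicon of the named stain: it reads the stain and channel list back out
#' of the prompt, runs [assign_by_lexicon()], and formats the result in the
#' response schema. Real remote providers plug in behind the same
#' one-function interface.
#'
#' @param profile optional [stain_profile()] to answer from; by default the
#'   preset named in the prompt's `Stain:` line is used.
#' @return a function of one argument (the prompt) returning response text.
#' @export
llm_mock_provider <- function(profile = NULL) {
  force(profile)
  function(prompt) {
    lines <- strsplit(prompt, "\n", fixed = TRUE)[[1]]
    stain <- sub("^Stain: ", "", grep("^Stain: ", lines, value = TRUE)[1])
    chan_start <- match("Channels:", lines)
    if (is.na(chan_start)) stop("mock provider: no channel list in prompt")
    chans <- character()
    for (ln in lines[(chan_start + 1):length(lines)]) {
      if (!startsWith(ln, "- ")) break
      chans <- c(chans, substring(ln, 3))
    }
    prof <- profile %||% stain_preset(stain)
    asn <- assign_by_lexicon(chans, profile = prof)
    as.character(format_llm_response(asn))
  }
}

#' Select channels for a stain
#'
#' Front door for channel selection: lexicon lookup (default), an LLM
#' provider, or a manual assignment passed through unchanged.
#'
#' @param channel_names channel names of the image.
#' @param stain stain preset name.
#' @param method `"lexicon"`, `"llm"` or `"manual"`.
#' @param profile optional [stain_profile()] (overrides `stain`).
#' @param provider LLM provider function for `method = "llm"`; defaults to
#'   the offline [llm_mock_provider()].
#' @param manual a [channel_assignment()] for `method = "manual"`.
#' @return a [channel_assignment()].
#' @export
select_channels <- function(channel_names, stain = NULL,
                            method = c("lexicon", "llm", "manual"),
                            profile = NULL, provider = NULL, manual = NULL) {
  method <- match.arg(method)
  if (is.null(profile) && !is.null(stain)) profile <- stain_preset(stain)
  switch(method,
    lexicon = assign_by_lexicon(channel_names, profile = profile),
    llm = {
      if (is.null(profile)) stop("`llm` selection needs a stain or profile")
      provider <- provider %||% llm_mock_provider()
      prompt <- build_llm_prompt(profile$name, profile$classes, channel_names)
      resp <- provider(prompt)
      out <- parse_llm_response(resp, profile$classes, channel_names)
      out$stain <- profile$name
      out
    },
    manual = {
      if (is.null(manual)) stop("`manual` selection needs `manual` assignment")
      manual
    }
  )
}

jaccard_index <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0 && length(b) == 0) return(1)
  length(intersect(a, b)) / length(union(a, b))
}

#' Consensus Jaccard agreement between channel assignments
#'
#' Builds a consensus assignment per class (channels chosen by a strict
#' majority of models), scores each model as the mean over classes of the
#' Jaccard similarity between its class sets and the consensus (with
#' J(empty, empty) = 1), and averages the per-model scores.
#'
#' @param assignments list of at least two [channel_assignment()] objects over
#'   the same classes.
#' @return a list with elements `consensus` (a [channel_assignment()]),
#'   `per_model` (numeric vector), `mean` (scalar) and `scores` (a tibble with
#'   per-model, per-class Jaccard values).
#' @examples
#' a <- channel_assignment(list(k = c("A", "B")))
#' b <- channel_assignment(list(k = c("A", "B")))
#' d <- channel_assignment(list(k = c("A", "C")))
#' consensus_jaccard(list(a, b, d))$mean  # 7/9
#' @export
consensus_jaccard <- function(assignments) {
  stopifnot(is.list(assignments), length(assignments) >= 2)
  maps <- lapply(assignments, assignment_map)
  cls <- names(maps[[1]])
  same <- vapply(maps, function(m) setequal(names(m), cls), logical(1))
  if (!all(same)) stop("assignments cover different class sets", call. = FALSE)
  n <- length(maps)
  consensus <- lapply(cls, function(cl) {
    tab <- table(unlist(lapply(maps, `[[`, cl), use.names = FALSE))
    names(tab)[tab > n / 2]
  })
  names(consensus) <- cls
  score_tbl <- do.call(rbind, lapply(seq_len(n), function(i) {
    tibble::tibble(
      model = i, class = cls,
      jaccard = vapply(cls, function(cl) {
        jaccard_index(maps[[i]][[cl]], consensus[[cl]])
      }, numeric(1))
    )
  }))
  per_model <- vapply(split(score_tbl$jaccard, score_tbl$model), mean, numeric(1))
  list(consensus = channel_assignment(consensus),
       per_model = unname(per_model),
       mean = mean(per_model),
       scores = score_tbl)
}
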