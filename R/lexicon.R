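#' Concept lexicons
#'
#' An `hl_lexicon` bundles the concept schema driving the whole pipeline:
#' concept classes, their attributes with surface-form dictionaries, and the
#' three term lists used for corpus construction (inclusion variants of
#' "hodgkin", exclusion variants of "non hodgkin", and false-positive
#' namesake phrases such as "dorothy hodgkin").
#'
#' Surface forms and term lists are stored *post-normalization* (see
#' [normalize_text()]) so the dictionary and the posts live in the same
#' string space.
#'
#' @param classes data.frame with columns `class_id`, `name`, `description`.
#' @param attributes data.frame with columns `attribute_id`, `class_id`,
#'   `name`, `is_nonspecific` and a list column `surface_forms`.
#' @param inclusion_terms,exclusion_terms,fp_terms character vectors of
#'   normalized phrases.
#' @param name optional lexicon name.
#' @return an object of class `hl_lexicon`.
#' @seealso [load_lexicon()], [builtin_hl_lexicon()], [validate_lexicon()]
#' @export
hl_lexicon <- function(classes, attributes, inclusion_terms = character(),
                       exclusion_terms = character(), fp_terms = character(),
                       name = "unnamed") {
  classes <- as.data.frame(classes, stringsAsFactors = FALSE)
  attributes <- as.data.frame(attributes, stringsAsFactors = FALSE)
  if (is.null(classes$description)) classes$description <- ""
  lex <- structure(
    list(
      name = name,
      classes = classes[, c("class_id", "name", "description")],
      attributes = attributes[, c("attribute_id", "class_id", "name",
                                  "is_nonspecific", "surface_forms")],
      inclusion_terms = as.character(inclusion_terms),
      exclusion_terms = as.character(exclusion_terms),
      fp_terms = as.character(fp_terms)
    ),
    class = "hl_lexicon"
  )
  lex
}

#' @export
print.hl_lexicon <- function(x, ...) {
  cat(sprintf("<hl_lexicon '%s'>\n", x$name))
  cat(sprintf("  %d classes, %d attributes, %d surface forms\n",
              nrow(x$classes), nrow(x$attributes),
              length(unlist(x$attributes$surface_forms))))
  cat(sprintf("  inclusion: %d, exclusion: %d, false-positive: %d terms\n",
              length(x$inclusion_terms), length(x$exclusion_terms),
              length(x$fp_terms)))
  invisible(x)
}

#' Flatten a lexicon into a term table
#'
#' One row per (surface form, attribute) pair; the matcher's dictionary.
#'
#' @param lex an `hl_lexicon`.
#' @return data.frame with columns `term`, `attribute_id`, `class_id`,
#'   `is_nonspecific`.
#' @export
lexicon_terms <- function(lex) {
  stopifnot(inherits(lex, "hl_lexicon"))
  n <- lengths(lex$attributes$surface_forms)
  data.frame(
    term = unlist(lex$attributes$surface_forms, use.names = FALSE),
    attribute_id = rep(lex$attributes$attribute_id, n),
    class_id = rep(lex$attributes$class_id, n),
    is_nonspecific = rep(lex$attributes$is_nonspecific, n),
    stringsAsFactors = FALSE
  )
}

#' Load a lexicon from a config file
#'
#' Two plain-text formats are supported. `"json"` is the documented schema:
#' top-level `classes` (objects with `class_id`, `name`, `description`),
#' `attributes` (objects with `attribute_id`, `class_id`, `name`,
#' `nonspecific`, `surface_forms`), and `inclusion_terms` /
#' `exclusion_terms` / `fp_terms` arrays. `"tsv"` is a tabular alternative:
#' columns `type` (`class`, `attribute`, `inclusion`, `exclusion`, `fp`),
#' `id`, `class_id`, `name`, `nonspecific`, `surface_forms`
#' (semicolon-separated).
#'
#' All surface forms and term lists are passed through [normalize_text()] on
#' load, and the result is validated; invariant violations are an error.
#'
#' @param path path to the config file.
#' @param format `"json"` or `"tsv"`.
#' @return a validated `hl_lexicon`.
#' @export
load_lexicon <- function(path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_input("lexicon file does not exist: %s", path)
  if (format == "json") {
    cfg <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                    error = function(e)
                      stop_input("failed to parse lexicon config %s: %s",
                                 path, conditionMessage(e)))
    classes <- do.call(rbind, lapply(cfg$classes, function(cl)
      data.frame(class_id = cl$class_id, name = cl$name,
                 description = cl$description %||% "",
                 stringsAsFactors = FALSE)))
    attributes <- do.call(rbind, lapply(cfg$attributes, function(at)
      data.frame(attribute_id = at$attribute_id, class_id = at$class_id,
                 name = at$name,
                 is_nonspecific = isTRUE(at$nonspecific),
                 surface_forms = I(list(unlist(at$surface_forms))),
                 stringsAsFactors = FALSE)))
    lex <- hl_lexicon(classes, attributes,
                      inclusion_terms = unlist(cfg$inclusion_terms),
                      exclusion_terms = unlist(cfg$exclusion_terms),
                      fp_terms = unlist(cfg$fp_terms),
                      name = cfg$name %||% basename(path))
  } else {
    tab <- tryCatch(read.csv(path, sep = "\t", stringsAsFactors = FALSE,
                             na.strings = character()),
                    error = function(e)
                      stop_input("failed to parse lexicon table %s: %s",
                                 path, conditionMessage(e)))
    need <- c("type", "id", "class_id", "name", "nonspecific", "surface_forms")
    if (!all(need %in% names(tab)))
      stop_input("lexicon table %s must have columns: %s", path,
                 paste(need, collapse = ", "))
    cls <- tab[tab$type == "class", ]
    att <- tab[tab$type == "attribute", ]
    classes <- data.frame(class_id = cls$id, name = cls$name,
                          description = cls$surface_forms,
                          stringsAsFactors = FALSE)
    attributes <- data.frame(
      attribute_id = att$id, class_id = att$class_id, name = att$name,
      is_nonspecific = att$nonspecific %in% c("TRUE", "true", "1"),
      surface_forms = I(strsplit(att$surface_forms, ";", fixed = TRUE)),
      stringsAsFactors = FALSE)
    lex <- hl_lexicon(classes, attributes,
                      inclusion_terms = tab$id[tab$type == "inclusion"],
                      exclusion_terms = tab$id[tab$type == "exclusion"],
                      fp_terms = tab$id[tab$type == "fp"],
                      name = basename(path))
  }
  lex$attributes$surface_forms <- I(lapply(lex$attributes$surface_forms,
                                           normalize_text))
  lex$inclusion_terms <- normalize_text(lex$inclusion_terms)
  lex$exclusion_terms <- normalize_text(lex$exclusion_terms)
  lex$fp_terms <- normalize_text(lex$fp_terms)
  viol <- validate_lexicon(lex)
  if (length(viol) > 0)
    stop_input("invalid lexicon %s:\n  %s", path, paste(viol, collapse = "\n  "))
  lex
}

#' Save a lexicon to a config file
#'
#' Inverse of [load_lexicon()]; round-trips field by field.
#'
#' @param lex an `hl_lexicon`.
#' @param path output path.
#' @param format `"json"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
save_lexicon <- function(lex, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(lex, "hl_lexicon"))
  if (format == "json") {
    cfg <- list(
      name = lex$name,
      classes = lapply(seq_len(nrow(lex$classes)), function(i)
        list(class_id = lex$classes$class_id[i], name = lex$classes$name[i],
             description = lex$classes$description[i])),
      attributes = lapply(seq_len(nrow(lex$attributes)), function(i)
        list(attribute_id = lex$attributes$attribute_id[i],
             class_id = lex$attributes$class_id[i],
             name = lex$attributes$name[i],
             nonspecific = lex$attributes$is_nonspecific[i],
             surface_forms = lex$attributes$surface_forms[[i]])),
      inclusion_terms = lex$inclusion_terms,
      exclusion_terms = lex$exclusion_terms,
      fp_terms = lex$fp_terms
    )
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    rows <- rbind(
      data.frame(type = "class", id = lex$classes$class_id,
                 class_id = "", name = lex$classes$name, nonspecific = "",
                 surface_forms = lex$classes$description,
                 stringsAsFactors = FALSE),
      data.frame(type = "attribute", id = lex$attributes$attribute_id,
                 class_id = lex$attributes$class_id,
                 name = lex$attributes$name,
                 nonspecific = as.character(lex$attributes$is_nonspecific),
                 surface_forms = vapply(lex$attributes$surface_forms,
                                        paste, "", collapse = ";"),
                 stringsAsFactors = FALSE),
      data.frame(type = "inclusion", id = lex$inclusion_terms, class_id = "",
                 name = "", nonspecific = "", surface_forms = "",
                 stringsAsFactors = FALSE),
      data.frame(type = "exclusion", id = lex$exclusion_terms, class_id = "",
                 name = "", nonspecific = "", surface_forms = "",
                 stringsAsFactors = FALSE),
      data.frame(type = "fp", id = lex$fp_terms, class_id = "", name = "",
                 nonspecific = "", surface_forms = "",
                 stringsAsFactors = FALSE)
    )
    write.table(rows, path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' The bundled Hodgkin lymphoma lexicon
#'
#' Nine concept classes (HL classification; stages and progression; age;
#' etiopathology; site and region involvements; diagnosis and monitoring;
#' symptoms; diseases and conditions; treatment), each with its attribute
#' dictionary plus a non-specific fallback where the schema defines one.
#' Inclusion terms are the lexical variants of "hodgkin"; exclusion terms
#' the "non hodgkin" variants; the false-positive list is a bundled
#' *synthetic stand-in* of namesake phrases (scientists, places) since the
#' original curated list is not distributed with the package.
#'
#' @return a validated `hl_lexicon` with 9 classes.
#' @export
#' @examples
#' lex <- builtin_hl_lexicon()
#' nrow(lex$classes)  # 9
builtin_hl_lexicon <- function() {
  if (is.null(.hlner_env$builtin)) {
    path <- system.file("extdata", "hl_lexicon.json", package = "hlner")
    .hlner_env$builtin <- load_lexicon(path, format = "json")
  }
  .hlner_env$builtin
}

.hlner_env <- new.env(parent = emptyenv())

#' Validate a lexicon against its invariants
#'
#' Violations are returned as data, not raised: unique class/attribute ids,
#' resolvable class references, non-empty normalized surface forms, exactly
#' one non-specific attribute per class that declares one, disjoint
#' inclusion/exclusion lists, every exclusion term containing an inclusion
#' term as substring, and normalized fp terms.
#'
#' @param lex an `hl_lexicon`.
#' @return character vector of violation messages; empty if valid.
#' @export
validate_lexicon <- function(lex) {
  v <- character()
  cl <- lex$classes
  at <- lex$attributes
  if (anyDuplicated(cl$class_id))
    v <- c(v, sprintf("duplicate class_id: %s",
                      paste(unique(cl$class_id[duplicated(cl$class_id)]),
                            collapse = ", ")))
  if (any(!nzchar(cl$name)))
    v <- c(v, sprintf("class with empty name: %s",
                      paste(cl$class_id[!nzchar(cl$name)], collapse = ", ")))
  if (anyDuplicated(at$attribute_id))
    v <- c(v, sprintf("duplicate attribute_id: %s",
                      paste(unique(at$attribute_id[duplicated(at$attribute_id)]),
                            collapse = ", ")))
  bad_ref <- !(at$class_id %in% cl$class_id)
  if (any(bad_ref))
    v <- c(v, sprintf("attribute '%s' references unknown class '%s'",
                      at$attribute_id[bad_ref], at$class_id[bad_ref]))
  for (i in seq_len(nrow(at))) {
    sf <- at$surface_forms[[i]]
    if (length(sf) == 0 || any(!nzchar(sf))) {
      v <- c(v, sprintf("attribute '%s' has empty surface forms",
                        at$attribute_id[i]))
      next
    }
    bad <- sf[sf != normalize_text(sf)]
    if (length(bad) > 0)
      v <- c(v, sprintf("attribute '%s' has non-normalized surface form(s): %s",
                        at$attribute_id[i], paste(bad, collapse = ", ")))
  }
  ns <- tapply(at$is_nonspecific, at$class_id, sum)
  multi <- names(ns)[ns > 1]
  if (length(multi) > 0)
    v <- c(v, sprintf("class '%s' declares more than one non-specific attribute",
                      multi))
  overlap <- intersect(lex$inclusion_terms, lex$exclusion_terms)
  if (length(overlap) > 0)
    v <- c(v, sprintf("inclusion and exclusion lists overlap: %s",
                      paste(overlap, collapse = ", ")))
  for (ex in lex$exclusion_terms) {
    if (!any(vapply(lex$inclusion_terms, grepl, TRUE, x = ex, fixed = TRUE)))
      v <- c(v, sprintf("exclusion term '%s' contains no inclusion term", ex))
  }
  bad_fp <- lex$fp_terms[lex$fp_terms != normalize_text(lex$fp_terms)]
  if (length(bad_fp) > 0)
    v <- c(v, sprintf("non-normalized fp term(s): %s",
                      paste(bad_fp, collapse = ", ")))
  v
}
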