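# Readers and writers for the pipeline's plain-text exchange formats:
# JSONL posts/clean posts/gold, CSV mentions/summaries/reports, and the
# simplified eHOST-style XML gold dialect. CSV artifacts carry a '#'
# provenance header; JSONL artifacts carry a leading {"_meta": ...} line.

.provenance <- function(seed = NULL, config = NULL) {
  h <- NA_character_
  if (!is.null(config)) {
    tmp <- tempfile()
    saveRDS(config, tmp)
    h <- unname(tools::md5sum(tmp))
    unlink(tmp)
  }
  list(tool = "hlner",
       version = as.character(utils::packageVersion("hlner")),
       seed = seed, config_hash = h)
}

.write_csv_meta <- function(df, path, meta = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(meta))
    writeLines(sprintf("# %s", jsonlite::toJSON(meta, auto_unbox = TRUE,
                                                null = "null")), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

.read_csv_meta <- function(path) {
  read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Read posts from JSONL or CSV
#'
#' JSONL: one object per line with fields `post_id` (or `id`), `text` and
#' optional extras (`created_at`, ...). A leading `{"_meta": ...}`
#' provenance line is skipped. CSV: a header with at least `post_id` and
#' `text` columns.
#'
#' @param path input file.
#' @param format `"jsonl"` or `"csv"` (guessed from the extension by
#'   default).
#' @return data.frame of raw posts.
#' @export
read_posts <- function(path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  if (format == "csv") {
    df <- .read_csv_meta(path)
    if (!"post_id" %in% names(df) && "id" %in% names(df))
      names(df)[names(df) == "id"] <- "post_id"
    return(df)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  rows <- lapply(seq_along(lines), function(i) {
    obj <- tryCatch(jsonlite::fromJSON(lines[i]),
                    error = function(e)
                      stop_input("%s:%d: malformed JSON: %s", path, i,
                                 conditionMessage(e)))
    if (!is.null(obj[["_meta"]])) return(NULL)
    id <- obj$post_id %||% obj$id
    if (is.null(id) || is.null(obj$text))
      stop_input("%s:%d: post object needs post_id and text", path, i)
    data.frame(post_id = as.character(id), text = as.character(obj$text),
               created_at = as.character(obj$created_at %||% NA),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(post_id = character(), text = character(),
                      created_at = character(), stringsAsFactors = FALSE)
  out
}

#' Write posts (or clean posts) as JSONL
#'
#' @param posts data.frame with `post_id`, `text` and optional columns.
#' @param path output path.
#' @param meta optional provenance list written as a `{"_meta": ...}`
#'   first line.
#' @return `path`, invisibly.
#' @export
write_posts <- function(posts, path, meta = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(meta))
    writeLines(jsonlite::toJSON(list(`_meta` = meta), auto_unbox = TRUE,
                                null = "null"), con)
  cols <- setdiff(names(posts), "gold")
  for (i in seq_len(nrow(posts))) {
    rec <- as.list(posts[i, cols, drop = FALSE])
    rec <- rec[!vapply(rec, function(x) is.na(x) || is.null(x), TRUE)]
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null"), con)
  }
  invisible(path)
}

#' Write a mention table as CSV
#'
#' @param mentions mention data.frame.
#' @param path output path.
#' @param meta optional provenance list (written as a `#` comment line).
#' @return `path`, invisibly.
#' @export
write_mentions <- function(mentions, path, meta = NULL) {
  .write_csv_meta(mentions, path, meta)
}

#' Read a mention table written by [write_mentions()]
#'
#' @param path input path.
#' @return mention data.frame.
#' @export
read_mentions <- function(path) .read_csv_meta(path)

#' Read gold annotations
#'
#' Reads the JSONL gold dialect (one object per line: `post_id`, `labels`
#' array) or a directory of simplified eHOST-style XML files written by
#' [write_gold()]. When a lexicon is supplied, labels that do not resolve
#' to a (class, attribute) pair are dropped with a warning and returned in
#' the `rejects` attribute rather than silently discarded.
#'
#' @param path JSONL file or XML directory.
#' @param format `"jsonl"` or `"ehost-xml"` (guessed: directories are XML).
#' @param lex optional `hl_lexicon` for label validation.
#' @return data.frame `post_id`, `class_id`, `attribute_id`, `start`,
#'   `end`, `text`; one row per label, zero-label posts contribute the
#'   post id to the `post_ids` attribute only.
#' @export
read_annotations <- function(path, format = NULL, lex = NULL) {
  if (is.null(format)) format <- if (dir.exists(path)) "ehost-xml" else "jsonl"
  rows <- list()
  post_ids <- character()
  if (format == "jsonl") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    for (i in seq_along(lines)) {
      obj <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
                      error = function(e)
                        stop_input("%s:%d: malformed JSON: %s", path, i,
                                   conditionMessage(e)))
      if (!is.null(obj[["_meta"]])) next
      if (is.null(obj$post_id))
        stop_input("%s:%d: gold object needs post_id", path, i)
      post_ids <- c(post_ids, obj$post_id)
      for (lb in obj$labels) {
        rows[[length(rows) + 1]] <- data.frame(
          post_id = obj$post_id, class_id = lb$class_id,
          attribute_id = lb$attribute_id,
          start = as.integer(lb$start %||% NA),
          end = as.integer(lb$end %||% NA),
          text = as.character(lb$text %||% NA), stringsAsFactors = FALSE)
      }
    }
  } else {
    files <- sort(list.files(path, pattern = "\\.xml$", full.names = TRUE))
    for (f in files) {
      doc <- tryCatch(xml2::read_xml(f),
                      error = function(e)
                        stop_input("%s: malformed XML: %s", f,
                                   conditionMessage(e)))
      id <- xml2::xml_attr(doc, "id")
      post_ids <- c(post_ids, id)
      for (node in xml2::xml_find_all(doc, ".//annotation")) {
        rows[[length(rows) + 1]] <- data.frame(
          post_id = id,
          class_id = xml2::xml_attr(node, "class_id"),
          attribute_id = xml2::xml_attr(node, "attribute_id"),
          start = as.integer(xml2::xml_attr(node, "start")),
          end = as.integer(xml2::xml_attr(node, "end")),
          text = xml2::xml_text(node), stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(post_id = character(), class_id = character(),
                      attribute_id = character(), start = integer(),
                      end = integer(), text = character(),
                      stringsAsFactors = FALSE)
  rejects <- out[0, ]
  if (!is.null(lex) && nrow(out) > 0) {
    at <- lex$attributes
    ok <- paste(out$class_id, out$attribute_id) %in%
      paste(at$class_id, at$attribute_id)
    if (any(!ok)) {
      rejects <- out[!ok, , drop = FALSE]
      warning(sprintf("%d label(s) do not resolve in the lexicon; see attr(.., 'rejects')",
                      sum(!ok)))
      out <- out[ok, , drop = FALSE]
    }
  }
  rownames(out) <- NULL
  attr(out, "post_ids") <- unique(post_ids)
  attr(out, "rejects") <- rejects
  out
}
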