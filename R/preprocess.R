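#' Normalize post text
#'
#' Standardizes raw social-media text into the pipeline's working alphabet
#' `[a-z0-9 ]`. Applied rules, in order: lowercase; drop `@`-prefixed
#' username tokens; drop URLs (`http(s)://...`, `www....`); drop emoji and
#' all other non-ASCII characters; replace remaining non-alphanumeric
#' characters by spaces; collapse runs of whitespace; trim. The function is
#' idempotent, and lexicon surface forms are stored in the same space.
#'
#' @param text character vector of raw texts.
#' @return character vector of normalized texts.
#' @export
#' @examples
#' normalize_text("Check @user http://t.co/x My PET scan!!")
normalize_text <- function(text) {
  x <- tolower(as.character(text))
  x <- gsub("@\\S+", " ", x, perl = TRUE)
  x <- gsub("(https?://\\S+|www\\.\\S+)", " ", x, perl = TRUE)
  x <- iconv(x, from = "UTF-8", to = "ASCII", sub = "")
  x[is.na(x)] <- ""
  x <- gsub("[^a-z0-9]+", " ", x, perl = TRUE)
  x <- gsub("^ +| +$", "", x, perl = TRUE)
  x
}

# All [start, end) 0-based occurrence spans of fixed `patterns` in `text`.
.term_spans <- function(text, patterns) {
  out <- list()
  for (p in patterns) {
    m <- gregexpr(p, text, fixed = TRUE)[[1]]
    if (m[1] == -1) next
    out[[length(out) + 1]] <-
      cbind(start = as.integer(m) - 1L,
            end = as.integer(m) + attr(m, "match.length") - 1L)
  }
  if (length(out) == 0) return(matrix(integer(), ncol = 2,
                                      dimnames = list(NULL, c("start", "end"))))
  do.call(rbind, out)
}

#' Inclusion/exclusion query filter
#'
#' A normalized post matches when it contains at least one occurrence of an
#' inclusion term that does not lie inside an occurrence of any exclusion
#' term. Because "non hodgkin" contains the string "hodgkin", exclusion
#' occurrences mask the inclusion hits inside them: a post whose only
#' "hodgkin" strings sit inside "non hodgkin" spans does not match, while a
#' standalone "hodgkin" elsewhere in the same post still does.
#'
#' @param text character vector of normalized texts.
#' @param lex an `hl_lexicon`.
#' @return character vector, `"match"` or `"no_match"` per input.
#' @export
query_filter <- function(text, lex) {
  stopifnot(inherits(lex, "hl_lexicon"))
  vapply(text, function(tx) {
    inc <- .term_spans(tx, lex$inclusion_terms)
    if (nrow(inc) == 0) return("no_match")
    exc <- .term_spans(tx, lex$exclusion_terms)
    if (nrow(exc) == 0) return("match")
    masked <- vapply(seq_len(nrow(inc)), function(i)
      any(exc[, "start"] <= inc[i, "start"] & inc[i, "end"] <= exc[, "end"]),
      TRUE)
    if (all(masked)) "no_match" else "match"
  }, "", USE.NAMES = FALSE)
}

#' False-positive namesake filter
#'
#' Post-level exclusion of namesake "hodgkin" posts: a post is excluded
#' when any false-positive term of the lexicon (for example
#' "dorothy hodgkin") occurs in its normalized text, even if the post also
#' carries genuine disease content. This replicates dropping whole
#' false-positive posts rather than masking the offending span.
#'
#' @param text character vector of normalized texts (query matches).
#' @param lex an `hl_lexicon`.
#' @return character vector, `"keep"` or `"exclude_fp"` per input.
#' @export
fp_post_filter <- function(text, lex) {
  stopifnot(inherits(lex, "hl_lexicon"))
  if (length(lex$fp_terms) == 0) return(rep("keep", length(text)))
  hit <- Reduce(`|`, lapply(lex$fp_terms, grepl, x = text, fixed = TRUE))
  ifelse(hit, "exclude_fp", "keep")
}

#' Mark duplicate posts
#'
#' Within rows whose `status` is `"retained"`, groups of identical
#' normalized texts keep the first row (stable input order); later rows are
#' excluded with reason `"duplicate"`. Duplicate comparison happens after
#' standardization, so raw texts differing only by an emoji are duplicates.
#'
#' @param posts a clean-post data.frame with columns `post_id`, `text`,
#'   `status`, `exclusion_reason`.
#' @return the data.frame with duplicates marked.
#' @export
dedupe <- function(posts) {
  ret <- which(posts$status == "retained")
  dup <- ret[duplicated(posts$text[ret])]
  posts$status[dup] <- "excluded"
  posts$exclusion_reason[dup] <- "duplicate"
  posts
}

#' Run the full corpus-construction pipeline
#'
#' Applies, in order: [normalize_text()], the inclusion/exclusion
#' [query_filter()], [dedupe()], and the namesake [fp_post_filter()]. Each
#' post ends up either retained or excluded with exactly one reason
#' (`empty_after_normalization`, `no_inclusion_match`, `exclusion_only`,
#' `duplicate`, `fp_hodgkin`).
#'
#' @param posts data.frame of raw posts with columns `post_id`, `text`
#'   (additional columns such as `created_at` are carried through).
#' @param lex an `hl_lexicon`.
#' @return list with `posts` (clean-post data.frame with `post_id`, `text`,
#'   `status`, `exclusion_reason`, carried-through extras) and `summary`
#'   (data.frame of counts per outcome).
#' @export
preprocess_corpus <- function(posts, lex) {
  stopifnot(inherits(lex, "hl_lexicon"))
  posts <- as.data.frame(posts, stringsAsFactors = FALSE)
  if (!all(c("post_id", "text") %in% names(posts)))
    stop_input("`posts` must have columns post_id and text")
  if (anyDuplicated(posts$post_id))
    stop_input("duplicate post_id in input: %s",
               paste(unique(posts$post_id[duplicated(posts$post_id)]),
                     collapse = ", "))
  extra <- setdiff(names(posts), c("post_id", "text"))
  n <- nrow(posts)
  out <- data.frame(post_id = posts$post_id,
                    text = normalize_text(posts$text),
                    status = rep("retained", n),
                    exclusion_reason = rep(NA_character_, n),
                    stringsAsFactors = FALSE)
  for (col in extra) out[[col]] <- posts[[col]]

  empty <- !nzchar(out$text)
  out$status[empty] <- "excluded"
  out$exclusion_reason[empty] <- "empty_after_normalization"

  todo <- which(out$status == "retained")
  if (length(todo) > 0) {
    qf <- query_filter(out$text[todo], lex)
    no_match <- todo[qf == "no_match"]
    if (length(no_match) > 0) {
      has_inc <- Reduce(`|`, lapply(lex$inclusion_terms, grepl,
                                    x = out$text[no_match], fixed = TRUE))
      out$status[no_match] <- "excluded"
      out$exclusion_reason[no_match] <-
        ifelse(has_inc, "exclusion_only", "no_inclusion_match")
    }
  }

  out <- dedupe(out)

  todo <- which(out$status == "retained")
  if (length(todo) > 0) {
    fp <- fp_post_filter(out$text[todo], lex)
    drop <- todo[fp == "exclude_fp"]
    out$status[drop] <- "excluded"
    out$exclusion_reason[drop] <- "fp_hodgkin"
  }

  reasons <- c("retained", "no_inclusion_match", "exclusion_only",
               "duplicate", "fp_hodgkin", "empty_after_normalization")
  lab <- ifelse(out$status == "retained", "retained", out$exclusion_reason)
  summary <- data.frame(outcome = reasons,
                        n = vapply(reasons, function(r) sum(lab == r), 0L),
                        stringsAsFactors = FALSE)
  stopifnot(sum(summary$n) == nrow(out))
  list(posts = out, summary = summary)
}
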