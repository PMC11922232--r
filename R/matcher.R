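#' Matcher configuration
#'
#' Controls the approximate dictionary matcher. The distance budget grows
#' with the length of the *lexicon term*: terms shorter than
#' `distance_breaks[1]` characters must match exactly (distance 0), which
#' protects short forms like "chl" or "mri" from spurious fuzzy hits; the
#' defaults allow one edit for terms of 5-9 characters and two edits for
#' terms of 10 or more.
#'
#' @param distance_breaks increasing integer term lengths at which the
#'   allowed distance steps up.
#' @param distance_values allowed distances; `length(distance_breaks) + 1`
#'   non-decreasing integers, the first of which must be 0 (exact matching
#'   below the first break).
#' @param max_ngram maximum number of tokens per candidate phrase (the
#'   longest bundled surface form has 4 tokens).
#' @param use_lemmas also test the lemmatized form of each candidate
#'   n-gram against the dictionary.
#' @return an object of class `hl_match_config`.
#' @export
match_config <- function(distance_breaks = c(5L, 10L),
                         distance_values = c(0L, 1L, 2L),
                         max_ngram = 4L, use_lemmas = TRUE) {
  distance_breaks <- as.integer(distance_breaks)
  distance_values <- as.integer(distance_values)
  if (length(distance_values) != length(distance_breaks) + 1)
    stop_input("need length(distance_values) == length(distance_breaks) + 1")
  if (is.unsorted(distance_breaks, strictly = TRUE))
    stop_input("distance_breaks must be strictly increasing")
  if (is.unsorted(distance_values))
    stop_input("allowed distance must be non-decreasing in term length")
  if (distance_values[1] != 0)
    stop_input("terms below the first break must require exact matches")
  structure(list(distance_breaks = distance_breaks,
                 distance_values = distance_values,
                 max_ngram = as.integer(max_ngram),
                 use_lemmas = isTRUE(use_lemmas)),
            class = "hl_match_config")
}

#' Allowed edit distance for a term length
#'
#' @param term_len integer vector of term lengths (characters).
#' @param cfg an `hl_match_config`.
#' @return integer vector of allowed distances.
#' @export
allowed_distance <- function(term_len, cfg) {
  idx <- findInterval(term_len, cfg$distance_breaks) + 1L
  cfg$distance_values[idx]
}

#' Damerau-Levenshtein (optimal string alignment) distance
#'
#' Minimal number of single-character insertions, deletions, substitutions,
#' and adjacent transpositions converting `a` into `b`, under the
#' restriction that no substring is edited more than once (the "optimal
#' string alignment" variant, i.e. Levenshtein plus transposition).
#'
#' @param a,b character vectors (recycled to a common length).
#' @return integer vector of distances.
#' @export
#' @examples
#' dl_distance("hogdkin", "hodgkin")  # 1 (one transposition)
dl_distance <- function(a, b) {
  n <- max(length(a), length(b))
  .osa_dist_cpp(rep_len(as.character(a), n), rep_len(as.character(b), n))
}

#' Rule-based lemmatizer
#'
#' Intentionally small suffix-stripping rules adequate for the lexicon's
#' vocabulary: `-ies -> -y`, `-sses -> -ss`, strip `-ing`, `-ed -> -e`,
#' strip plural `-s` (not `-ss`). Numbers pass through unchanged.
#'
#' @param tokens character vector of lowercase tokens.
#' @return character vector of lemmas.
#' @export
#' @examples
#' lemmatize("relapsed")  # "relapse"
lemmatize <- function(tokens) {
  out <- tokens
  num <- grepl("^[0-9]+$", out)
  ies <- !num & grepl("ies$", out) & nchar(out) > 4
  out[ies] <- sub("ies$", "y", out[ies])
  sses <- !num & grepl("sses$", out)
  out[sses] <- sub("sses$", "ss", out[sses])
  ing <- !num & grepl("ing$", out) & nchar(out) > 5
  out[ing] <- sub("ing$", "", out[ing])
  ed <- !num & grepl("ed$", out) & nchar(out) > 4
  out[ed] <- sub("d$", "", out[ed])
  s <- !num & grepl("[^s]s$", out) & nchar(out) > 3
  out[s] <- sub("s$", "", out[s])
  out
}

#' Tokenize normalized text
#'
#' Whitespace tokenization over the normalized alphabet, with 0-based
#' half-open character offsets into the input, plus a rule-based lemma and
#' a coarse part-of-speech tag per token (`NUM` for digit tokens, `VERB`
#' for `-ing`/`-ed` forms, `NOUN` otherwise).
#'
#' @param text a single normalized string.
#' @return data.frame with columns `text`, `lemma`, `pos`, `start`, `end`.
#' @export
tokenize <- function(text) {
  stopifnot(length(text) == 1)
  empty <- data.frame(text = character(), lemma = character(),
                      pos = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
  if (is.na(text) || !nzchar(text)) return(empty)
  m <- gregexpr("[^ ]+", text)[[1]]
  if (m[1] == -1) return(empty)
  start <- as.integer(m) - 1L
  end <- start + attr(m, "match.length")
  words <- regmatches(text, gregexpr("[^ ]+", text))[[1]]
  pos <- ifelse(grepl("^[0-9]+$", words), "NUM",
                ifelse(grepl("(ing|ed)$", words) & nchar(words) > 4,
                       "VERB", "NOUN"))
  data.frame(text = words, lemma = lemmatize(words), pos = pos,
             start = start, end = end, stringsAsFactors = FALSE)
}

#' Approximate match of a phrase against a lexicon term
#'
#' A hit when the optimal-string-alignment distance between phrase and term
#' does not exceed the budget that `cfg` allows for the term's length.
#'
#' @param phrase,term normalized strings.
#' @param cfg an `hl_match_config`.
#' @return the integer distance on a hit, `NA_integer_` on a miss.
#' @export
#' @examples
#' approx_match("chemotherpay", "chemotherapy", match_config())  # 1
approx_match <- function(phrase, term, cfg = match_config()) {
  d <- dl_distance(phrase, term)
  ok <- d <= allowed_distance(nchar(term), cfg)
  ifelse(ok, d, NA_integer_)
}

.empty_mentions <- function() {
  data.frame(post_id = character(), class_id = character(),
             attribute_id = character(), start = integer(), end = integer(),
             matched_text = character(), lexicon_term = character(),
             distance = integer(), stringsAsFactors = FALSE)
}

#' Extract concept mentions from one post
#'
#' Slides token n-grams (1..`max_ngram`) over the post; each n-gram is
#' tested as its surface string and (optionally) its lemmatized form
#' against every attribute surface form with [approx_match()]. Candidate
#' hits whose span lies inside an occurrence of a false-positive namesake
#' term never produce mentions. Overlapping hits *within a class* are
#' resolved lowest-distance-first (exact matches take priority over fuzzy
#' ones), then longest span, then leftmost; hits in different classes may
#' overlap (posts are multi-label).
#'
#' @param post a list or one-row data.frame with `post_id` and normalized
#'   `text` (a retained clean post).
#' @param lex an `hl_lexicon`.
#' @param cfg an `hl_match_config`.
#' @return mention data.frame with columns `post_id`, `class_id`,
#'   `attribute_id`, `start`, `end` (0-based half-open), `matched_text`,
#'   `lexicon_term`, `distance`.
#' @export
extract_mentions <- function(post, lex, cfg = match_config()) {
  stopifnot(inherits(lex, "hl_lexicon"))
  text <- as.character(post$text)
  post_id <- as.character(post$post_id)
  toks <- tokenize(text)
  nt <- nrow(toks)
  if (nt == 0) return(.empty_mentions())

  terms <- lexicon_terms(lex)
  maxd <- allowed_distance(nchar(terms$term), cfg)

  # enumerate n-gram candidates: surface substring and lemma join
  cand_start <- integer(); cand_end <- integer(); cand_str <- character()
  for (n in seq_len(min(cfg$max_ngram, nt))) {
    for (i in seq_len(nt - n + 1L)) {
      s <- toks$start[i]; e <- toks$end[i + n - 1L]
      surf <- substr(text, s + 1L, e)
      cand_start <- c(cand_start, s); cand_end <- c(cand_end, e)
      cand_str <- c(cand_str, surf)
      if (cfg$use_lemmas) {
        lem <- paste(toks$lemma[i:(i + n - 1L)], collapse = " ")
        if (lem != surf) {
          cand_start <- c(cand_start, s); cand_end <- c(cand_end, e)
          cand_str <- c(cand_str, lem)
        }
      }
    }
  }

  hits <- .osa_match_cpp(cand_str, terms$term, maxd)
  if (nrow(hits) == 0) return(.empty_mentions())

  res <- data.frame(
    post_id = post_id,
    class_id = terms$class_id[hits$term],
    attribute_id = terms$attribute_id[hits$term],
    start = cand_start[hits$cand],
    end = cand_end[hits$cand],
    matched_text = substr(rep(text, nrow(hits)),
                          cand_start[hits$cand] + 1L, cand_end[hits$cand]),
    lexicon_term = terms$term[hits$term],
    distance = hits$distance,
    stringsAsFactors = FALSE
  )

  # surface and lemma variants of a span may both hit: keep the best per
  # (span, attribute, term)
  key <- paste(res$start, res$end, res$attribute_id, res$lexicon_term)
  res <- res[order(key, res$distance), ]
  res <- res[!duplicated(paste(res$start, res$end, res$attribute_id,
                               res$lexicon_term)), ]

  # false-positive namesake spans never yield mentions
  fp <- .term_spans(text, lex$fp_terms)
  if (nrow(fp) > 0) {
    inside <- vapply(seq_len(nrow(res)), function(i)
      any(fp[, "start"] <= res$start[i] & res$end[i] <= fp[, "end"]), TRUE)
    res <- res[!inside, ]
  }
  if (nrow(res) == 0) return(.empty_mentions())

  # per-class overlap resolution: lowest distance first (an exact hit is
  # never displaced by a longer fuzzy one), then longest span, then leftmost
  keep <- logical(nrow(res))
  for (cl in unique(res$class_id)) {
    idx <- which(res$class_id == cl)
    span <- res$end[idx] - res$start[idx]
    ord <- idx[order(res$distance[idx], -span, res$start[idx])]
    taken_s <- integer(); taken_e <- integer()
    for (i in ord) {
      if (!any(res$start[i] < taken_e & taken_s < res$end[i])) {
        keep[i] <- TRUE
        taken_s <- c(taken_s, res$start[i]); taken_e <- c(taken_e, res$end[i])
      }
    }
  }
  res <- res[keep, ]
  res <- res[order(res$start, res$class_id, res$attribute_id), ]
  rownames(res) <- NULL
  res
}

#' Extract mentions from a whole corpus
#'
#' Concatenates [extract_mentions()] over the retained posts, in
#' deterministic `(post_id, start)` order.
#'
#' @param posts clean-post data.frame (rows with `status != "retained"` are
#'   skipped; a data.frame without a `status` column is taken as all
#'   retained).
#' @param lex an `hl_lexicon`.
#' @param cfg an `hl_match_config`.
#' @return mention data.frame (see [extract_mentions()]).
#' @export
annotate_corpus <- function(posts, lex, cfg = match_config()) {
  posts <- as.data.frame(posts, stringsAsFactors = FALSE)
  if (!is.null(posts$status)) posts <- posts[posts$status == "retained", ]
  if (nrow(posts) == 0) return(.empty_mentions())
  res <- do.call(rbind, lapply(seq_len(nrow(posts)), function(i)
    extract_mentions(posts[i, ], lex, cfg)))
  res <- res[order(res$post_id, res$start, res$class_id, res$attribute_id), ]
  rownames(res) <- NULL
  res
}
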