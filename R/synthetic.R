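# Filler vocabulary for synthetic posts: neutral words verified (by test)
# to stay outside every surface form's fuzzy-match budget.
.filler_words <- c(
  "today", "friend", "sharing", "update", "journey", "family", "support",
  "love", "hope", "news", "week", "month", "year", "grateful", "thankful",
  "community", "everyone", "story", "strong", "please", "thoughts",
  "prayers", "morning", "evening", "finally", "amazing", "wonderful",
  "husband", "wife", "brother", "sister", "colleague"
)

# Filler words whose surface/lemma unigrams, ordered pairs, and triples all
# stay outside every surface form's distance budget; random adjacency of
# safe filler can then never fabricate a dictionary hit.
.safe_filler <- function(lex, cfg) {
  words <- .filler_words
  terms <- lexicon_terms(lex)
  maxd <- allowed_distance(nchar(terms$term), cfg)
  collides <- function(cand) {
    hits <- .osa_match_cpp(cand, terms$term, maxd)
    unique(hits$cand)
  }
  # unigrams (surface and lemma)
  bad <- union(collides(words), collides(lemmatize(words)))
  if (length(bad) > 0) words <- words[-bad]
  # ordered pairs and triples: greedily drop the word in most collisions
  repeat {
    pairs <- expand.grid(a = words, b = words, stringsAsFactors = FALSE)
    cand2 <- paste(pairs$a, pairs$b)
    trip <- expand.grid(a = words, b = words, c = words,
                        stringsAsFactors = FALSE)
    cand3 <- paste(trip$a, trip$b, trip$c)
    hit2 <- collides(cand2)
    hit3 <- collides(cand3)
    if (length(hit2) == 0 && length(hit3) == 0) break
    involved <- c(pairs$a[hit2], pairs$b[hit2],
                  trip$a[hit3], trip$b[hit3], trip$c[hit3])
    worst <- names(sort(table(involved), decreasing = TRUE))[1]
    words <- setdiff(words, worst)
    if (length(words) < 5)
      stop_input("filler vocabulary collapsed against this lexicon")
  }
  words
}

# TRUE when no token n-gram crossing a unit boundary falls within any
# lexicon term's distance budget (surface or lemma form). Unit-internal
# n-grams are covered by safe_surface_forms() / .safe_filler(); boundary
# crossings are the remaining way a random arrangement could fabricate or
# disturb a mention, so arrangements failing this check are re-shuffled.
.boundary_safe <- function(unit_texts, terms, maxd, max_ngram = 4L) {
  tok_unit <- rep(seq_along(unit_texts),
                  vapply(strsplit(unit_texts, " ", fixed = TRUE), length, 0L))
  text <- paste(unit_texts, collapse = " ")
  toks <- tokenize(text)
  nt <- nrow(toks)
  cands <- character()
  for (n in 2:max_ngram) {
    if (n > nt) break
    for (i in seq_len(nt - n + 1L)) {
      if (tok_unit[i] == tok_unit[i + n - 1L]) next
      surf <- substr(text, toks$start[i] + 1L, toks$end[i + n - 1L])
      cands <- c(cands, surf,
                 paste(toks$lemma[i:(i + n - 1L)], collapse = " "))
    }
  }
  if (length(cands) == 0) return(TRUE)
  nrow(.osa_match_cpp(unique(cands), terms, maxd)) == 0
}

#' Synthetic-corpus generator configuration
#'
#' The generator emulates the conditions the corpus-construction pipeline
#' must survive: posts carrying lexicon concepts with an inclusion anchor,
#' spelling noise on mention surfaces, "non hodgkin" exclusion traps,
#' namesake false-positive distractors, irrelevant posts, and exact
#' duplicates.
#'
#' @param n_posts number of posts to generate.
#' @param class_mix named probability vector over class ids (defaults to
#'   uniform over the lexicon's classes); must sum to 1.
#' @param attributes_per_post integer vector of allowed mention counts per
#'   relevant post (uniformly sampled; default 1-3).
#' @param typo_rate probability that a sampled mention surface of at least
#'   5 characters receives `typo_edits` random edits.
#' @param typo_edits number of edits applied when a typo fires.
#' @param typo_ops named weights for the edit operations `insert`,
#'   `delete`, `substitute`, `transpose`.
#' @param fp_rate fraction of namesake-distractor posts.
#' @param irrelevant_rate fraction of posts with no inclusion term.
#' @param trap_rate fraction of "non hodgkin" exclusion-trap posts.
#' @param duplicate_rate fraction of posts duplicating an earlier relevant
#'   post verbatim.
#' @param seed mandatory integer seed; all randomness derives from it.
#' @return an object of class `hl_gen_config`.
#' @export
gen_config <- function(n_posts, class_mix = NULL, attributes_per_post = 1:3,
                       typo_rate = 0.1, typo_edits = 1L,
                       typo_ops = c(insert = 1, delete = 1, substitute = 1,
                                    transpose = 1),
                       fp_rate = 0.05, irrelevant_rate = 0.1,
                       trap_rate = 0.05, duplicate_rate = 0.05, seed) {
  if (missing(seed)) stop_input("`seed` is mandatory")
  rates <- c(typo_rate, fp_rate, irrelevant_rate, trap_rate, duplicate_rate)
  if (any(rates < 0 | rates > 1)) stop_input("rates must be in [0, 1]")
  if (fp_rate + irrelevant_rate + trap_rate + duplicate_rate > 1)
    stop_input("category rates must sum to at most 1")
  if (!is.null(class_mix)) {
    if (abs(sum(class_mix) - 1) > 1e-8) stop_input("class_mix must sum to 1")
    if (is.null(names(class_mix))) stop_input("class_mix must be named by class_id")
  }
  structure(list(n_posts = as.integer(n_posts), class_mix = class_mix,
                 attributes_per_post = as.integer(attributes_per_post),
                 typo_rate = typo_rate, typo_edits = as.integer(typo_edits),
                 typo_ops = typo_ops, fp_rate = fp_rate,
                 irrelevant_rate = irrelevant_rate, trap_rate = trap_rate,
                 duplicate_rate = duplicate_rate, seed = as.integer(seed)),
            class = "hl_gen_config")
}

.with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  code
}

#' Inject random spelling edits into a phrase
#'
#' Applies `k` random single-character edits (insert, delete, substitute,
#' adjacent transposition, sampled by `ops` weights), constrained so the
#' result stays in the normalized alphabet with single internal spaces.
#' The result is always within optimal-string-alignment distance `k` of
#' the input.
#'
#' @param term a normalized phrase.
#' @param k number of edits (`k = 0` returns the phrase unchanged).
#' @param ops named weights for `insert`, `delete`, `substitute`,
#'   `transpose`.
#' @param seed optional seed for reproducibility in isolation; when `NULL`
#'   the surrounding RNG stream is used.
#' @return the corrupted phrase.
#' @export
inject_typos <- function(term, k = 1L,
                         ops = c(insert = 1, delete = 1, substitute = 1,
                                 transpose = 1),
                         seed = NULL) {
  if (k < 0) stop_input("k must be >= 0")
  if (k > nchar(term)) stop_input("k exceeds phrase length")
  if (k == 0) return(term)
  op_names <- c("insert", "delete", "substitute", "transpose")
  w <- ops[op_names]; w[is.na(w)] <- 0
  .with_seed(seed, {
    cur <- term
    for (edit in seq_len(k)) {
      for (try in 1:50) {
        op <- sample(op_names, 1, prob = w)
        n <- nchar(cur)
        cand <- switch(op,
          insert = {
            pos <- sample(0:n, 1)
            paste0(substr(cur, 1, pos), sample(letters, 1),
                   substr(cur, pos + 1, n))
          },
          delete = if (n <= 1) NA_character_ else {
            pos <- sample(seq_len(n), 1)
            paste0(substr(cur, 1, pos - 1), substr(cur, pos + 1, n))
          },
          substitute = {
            pos <- sample(seq_len(n), 1)
            ch <- sample(setdiff(letters, substr(cur, pos, pos)), 1)
            paste0(substr(cur, 1, pos - 1), ch, substr(cur, pos + 1, n))
          },
          transpose = if (n < 2) NA_character_ else {
            pos <- sample(seq_len(n - 1), 1)
            paste0(substr(cur, 1, pos - 1), substr(cur, pos + 1, pos + 1),
                   substr(cur, pos, pos), substr(cur, pos + 2, n))
          })
        if (!is.na(cand) && nzchar(cand) && cand == normalize_text(cand)) {
          cur <- cand
          break
        }
      }
    }
    cur
  })
}

#' Surface forms safe for unambiguous gold construction
#'
#' A surface form is "safe" when no contiguous token sub-span of it (as
#' surface or lemmatized string) lies within the fuzzy-match budget of any
#' surface form belonging to a *different class*. Mentions built from safe
#' forms can be labeled exactly by construction: cross-class collisions are
#' impossible and same-class overlaps are resolved in the matcher's
#' longest-span-first pass.
#'
#' @param lex an `hl_lexicon`.
#' @param cfg an `hl_match_config`.
#' @return data.frame `term`, `attribute_id`, `class_id` of safe forms.
#' @export
safe_surface_forms <- function(lex, cfg = match_config()) {
  terms <- lexicon_terms(lex)
  maxd <- allowed_distance(nchar(terms$term), cfg)
  safe <- vapply(seq_len(nrow(terms)), function(i) {
    toks <- strsplit(terms$term[i], " ", fixed = TRUE)[[1]]
    spans <- character()
    for (n in seq_along(toks)) {
      for (s in seq_len(length(toks) - n + 1)) {
        sub <- toks[s:(s + n - 1)]
        spans <- c(spans, paste(sub, collapse = " "),
                   paste(lemmatize(sub), collapse = " "))
      }
    }
    other <- terms$class_id != terms$class_id[i]
    hits <- .osa_match_cpp(unique(spans), terms$term[other], maxd[other])
    nrow(hits) == 0
  }, TRUE)
  terms[safe, c("term", "attribute_id", "class_id")]
}

#' Generate a synthetic annotated corpus
#'
#' Builds `cfg$n_posts` posts from neutral filler templates. Relevant posts
#' carry the inclusion anchor "hodgkins lymphoma" (gold-labeled as
#' non-specific HL classification) plus 1-3 sampled attribute surface
#' forms, each gold-labeled with exact character spans; mention surfaces of
#' 5+ characters are corrupted with probability `typo_rate`. Exclusion
#' traps are built only from the lexicon's "non hodgkin" variants;
#' distractors from its false-positive namesake list; irrelevant posts from
#' filler alone; duplicates repeat an earlier relevant post verbatim. Text
#' is emitted pre-normalized, so [normalize_text()] is the identity on it
#' and gold spans survive preprocessing. At a fixed seed the random stream
#' does not depend on `typo_rate`, so corpora at different typo rates are
#' identical except that the set of corrupted mentions grows with the rate
#' (nested coupling).
#'
#' @param lex an `hl_lexicon`.
#' @param cfg an `hl_gen_config`.
#' @param match_cfg the `hl_match_config` used to compute the safe
#'   surface-form pool (see [safe_surface_forms()]).
#' @return data.frame with columns `post_id`, `text`, `category` and a
#'   list column `gold` of per-post label data.frames (`class_id`,
#'   `attribute_id`, `start`, `end`, `text`); the generating config is
#'   attached as attribute `gen_config`.
#' @export
generate_corpus <- function(lex, cfg, match_cfg = match_config()) {
  stopifnot(inherits(lex, "hl_lexicon"), inherits(cfg, "hl_gen_config"))
  if (nrow(lex$attributes) == 0) stop_input("empty lexicon")
  safe <- safe_surface_forms(lex, match_cfg)
  if (nrow(safe) == 0) stop_input("lexicon has no safe surface forms")
  classes <- intersect(lex$classes$class_id, unique(safe$class_id))
  mix <- cfg$class_mix
  if (is.null(mix)) {
    mix <- rep(1 / length(classes), length(classes))
    names(mix) <- classes
  } else {
    bad <- setdiff(names(mix), classes)
    if (length(bad) > 0)
      stop_input("class_mix names not generatable classes: %s",
                 paste(bad, collapse = ", "))
    mix <- mix[names(mix) %in% classes]
    mix <- mix / sum(mix)
  }
  anchor <- "hodgkins lymphoma"
  anchor_label <- c("hl_classification", "hl_nonspecific")
  filler_pool <- .safe_filler(lex, match_cfg)
  term_tab <- lexicon_terms(lex)
  term_maxd <- allowed_distance(nchar(term_tab$term), match_cfg)

  .with_seed(cfg$seed, {
    ids <- sprintf("p%06d", seq_len(cfg$n_posts))
    texts <- character(cfg$n_posts)
    cats <- character(cfg$n_posts)
    golds <- vector("list", cfg$n_posts)
    relevant_idx <- integer()

    empty_gold <- data.frame(class_id = character(),
                             attribute_id = character(), start = integer(),
                             end = integer(), text = character(),
                             stringsAsFactors = FALSE)

    pick <- function(x) if (length(x) == 1) x else sample(x, 1)

    for (i in seq_len(cfg$n_posts)) {
      r <- runif(1)
      cat_i <- if (r < cfg$trap_rate) "exclusion_trap"
      else if (r < cfg$trap_rate + cfg$fp_rate) "fp_distractor"
      else if (r < cfg$trap_rate + cfg$fp_rate + cfg$irrelevant_rate) "irrelevant"
      else if (r < cfg$trap_rate + cfg$fp_rate + cfg$irrelevant_rate +
               cfg$duplicate_rate) "duplicate"
      else "relevant"
      if (cat_i == "duplicate" && length(relevant_idx) == 0) cat_i <- "relevant"

      if (cat_i == "duplicate") {
        src <- pick(relevant_idx)
        texts[i] <- texts[src]
        golds[[i]] <- golds[[src]]
        cats[i] <- "duplicate"
        next
      }

      if (cat_i == "relevant") {
        arranged <- FALSE
        for (resample in 1:5) {
          filler <- sample(filler_pool, sample(3:8, 1), replace = TRUE)
          units <- lapply(filler, function(w)
            list(text = w, clean = w, label = NULL))
          units <- c(units, list(list(text = anchor, clean = anchor,
                                      label = anchor_label)))
          n_att <- pick(cfg$attributes_per_post)
          for (j in seq_len(n_att)) {
            cl <- sample(names(mix), 1, prob = mix)
            pool <- safe[safe$class_id == cl, , drop = FALSE]
            row <- pool[pick(seq_len(nrow(pool))), ]
            # the corrupted form and the typo decision are always drawn, so
            # a fixed seed couples corpora across typo rates: the typo'd
            # mention set at a lower rate is a subset of that at a higher
            # rate, making recall degradation monotone in typo_rate
            surface <- row$term
            if (nchar(surface) >= 5) {
              u <- runif(1)
              corrupted <- inject_typos(surface, cfg$typo_edits, cfg$typo_ops)
              if (u < cfg$typo_rate) surface <- corrupted
            }
            units <- c(units, list(list(text = surface, clean = row$term,
                                        label = c(cl, row$attribute_id))))
          }
          # arrangement rejection: boundary collisions are checked on the
          # clean surfaces, so the RNG stream (and hence the corpus) does
          # not depend on typo_rate
          for (attempt in 1:30) {
            ord <- sample(length(units))
            if (.boundary_safe(vapply(units[ord], `[[`, "", "clean"),
                               term_tab$term, term_maxd,
                               match_cfg$max_ngram)) {
              units <- units[ord]
              arranged <- TRUE
              break
            }
          }
          if (arranged) break
        }
        if (!arranged)
          stop_input("post %d: no boundary-safe arrangement found", i)
      } else {
        filler <- sample(filler_pool, sample(3:8, 1), replace = TRUE)
        units <- lapply(filler, function(w) list(text = w, label = NULL))
        if (cat_i == "exclusion_trap") {
          trap <- paste0(pick(lex$exclusion_terms),
                         pick(c(" lymphoma", "")))
          units <- c(units, list(list(text = trap, label = NULL)))
        } else if (cat_i == "fp_distractor") {
          units <- c(units, list(list(text = pick(lex$fp_terms), label = NULL)))
        }
        units <- units[sample(length(units))]
      }
      offset <- 0L
      gold <- empty_gold
      parts <- character(length(units))
      for (u in seq_along(units)) {
        txt <- units[[u]]$text
        s <- offset
        e <- offset + nchar(txt)
        parts[u] <- txt
        if (!is.null(units[[u]]$label)) {
          gold <- rbind(gold, data.frame(class_id = units[[u]]$label[1],
                                         attribute_id = units[[u]]$label[2],
                                         start = s, end = e, text = txt,
                                         stringsAsFactors = FALSE))
        }
        offset <- e + 1L  # the joining space
      }
      texts[i] <- paste(parts, collapse = " ")
      golds[[i]] <- gold
      cats[i] <- cat_i
      if (cat_i == "relevant") relevant_idx <- c(relevant_idx, i)
    }

    out <- data.frame(post_id = ids, text = texts, category = cats,
                      stringsAsFactors = FALSE)
    out$gold <- golds
    attr(out, "gen_config") <- cfg
    out
  })
}

#' Flatten a synthetic corpus' gold labels
#'
#' @param corpus data.frame from [generate_corpus()].
#' @return data.frame `post_id`, `class_id`, `attribute_id`, `start`,
#'   `end`, `text` (one row per gold label).
#' @export
corpus_gold <- function(corpus) {
  rows <- lapply(seq_len(nrow(corpus)), function(i) {
    g <- corpus$gold[[i]]
    if (is.null(g) || nrow(g) == 0) return(NULL)
    cbind(post_id = corpus$post_id[i], g, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(post_id = character(), class_id = character(),
                      attribute_id = character(), start = integer(),
                      end = integer(), text = character(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Serialize gold labels
#'
#' Writes gold annotations either as JSONL (one object per post with a
#' `labels` array) or as a directory of simplified eHOST-style XML files
#' (one `<post>` document per post, one `<annotation>` element per label
#' with 0-based half-open `start`/`end` attributes and the spanned text as
#' element text). Both round-trip through [read_annotations()]. Spanned
#' text is checked against `text[start:end]` during serialization.
#'
#' @param posts data.frame with `post_id`, `text` and a `gold` list column
#'   (as produced by [generate_corpus()]).
#' @param format `"jsonl"` or `"ehost-xml"`.
#' @param path output file (jsonl) or directory (ehost-xml).
#' @return `path`, invisibly.
#' @export
write_gold <- function(posts, format = c("jsonl", "ehost-xml"), path) {
  format <- match.arg(format)
  for (i in seq_len(nrow(posts))) {
    g <- posts$gold[[i]]
    if (is.null(g) || nrow(g) == 0) next
    span_txt <- substr(rep(posts$text[i], nrow(g)), g$start + 1L, g$end)
    if (!all(span_txt == g$text))
      stop_input("gold span text mismatch in post %s", posts$post_id[i])
  }
  if (format == "jsonl") {
    con <- file(path, open = "wt")
    on.exit(close(con))
    for (i in seq_len(nrow(posts))) {
      g <- posts$gold[[i]]
      labels <- if (is.null(g) || nrow(g) == 0) list() else
        lapply(seq_len(nrow(g)), function(j)
          list(class_id = g$class_id[j], attribute_id = g$attribute_id[j],
               start = g$start[j], end = g$end[j], text = g$text[j]))
      writeLines(jsonlite::toJSON(list(post_id = posts$post_id[i],
                                       labels = labels),
                                  auto_unbox = TRUE), con)
    }
  } else {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    for (i in seq_len(nrow(posts))) {
      doc <- xml2::xml_new_root("post", id = posts$post_id[i])
      g <- posts$gold[[i]]
      if (!is.null(g)) {
        for (j in seq_len(nrow(g))) {
          node <- xml2::xml_add_child(doc, "annotation",
                                      class_id = g$class_id[j],
                                      attribute_id = g$attribute_id[j],
                                      start = as.character(g$start[j]),
                                      end = as.character(g$end[j]))
          xml2::xml_text(node) <- g$text[j]
        }
      }
      xml2::write_xml(doc, file.path(path, paste0(posts$post_id[i], ".xml")))
    }
  }
  invisible(path)
}
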