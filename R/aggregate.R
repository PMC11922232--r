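#' Frequency table of classes and attributes
#'
#' Counts, per attribute, either the number of distinct posts containing at
#' least one mention of the attribute (`unit = "posts"`, the default) or
#' the raw number of mention events (`unit = "mentions"`). Attribute
#' percentages are shares of the class total; class totals count distinct
#' posts (or mentions) across all attributes of the class and, when a
#' corpus `denominator` is supplied, carry a corpus-level percentage.
#' All percentages are rounded half-up.
#'
#' @param mentions mention data.frame (`post_id`, `class_id`,
#'   `attribute_id`, ...).
#' @param lex an `hl_lexicon`.
#' @param unit counting unit, `"posts"` or `"mentions"`.
#' @param denominator optional corpus size for class-level percentages
#'   (e.g. the number of retained posts).
#' @param decimals decimal places for percentages.
#' @return an `hl_freq_table`: data.frame with columns `class_id`,
#'   `attribute_id`, `count`, `percent` and attributes `class_totals`
#'   (data.frame `class_id`, `total`, `percent_of_corpus`), `unit`,
#'   `denominator`, `post_sets`.
#' @export
count_frequencies <- function(mentions, lex, unit = c("posts", "mentions"),
                              denominator = NULL, decimals = 2) {
  unit <- match.arg(unit)
  stopifnot(inherits(lex, "hl_lexicon"))
  terms <- lex$attributes
  bad <- setdiff(unique(mentions$attribute_id), terms$attribute_id)
  if (length(bad) > 0)
    stop_input("mention table has unknown attribute(s): %s",
               paste(bad, collapse = ", "))
  bad_cl <- setdiff(unique(mentions$class_id), lex$classes$class_id)
  if (length(bad_cl) > 0)
    stop_input("mention table has unknown class(es): %s",
               paste(bad_cl, collapse = ", "))

  post_sets <- list()
  rows <- lapply(seq_len(nrow(terms)), function(i) {
    at <- terms$attribute_id[i]; cl <- terms$class_id[i]
    m <- mentions[mentions$attribute_id == at, , drop = FALSE]
    ids <- unique(m$post_id)
    post_sets[[paste(cl, at, sep = "|")]] <<- ids
    data.frame(class_id = cl, attribute_id = at,
               count = if (unit == "posts") length(ids) else nrow(m),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)

  class_totals <- do.call(rbind, lapply(lex$classes$class_id, function(cl) {
    m <- mentions[mentions$class_id == cl, , drop = FALSE]
    total <- if (unit == "posts") length(unique(m$post_id)) else nrow(m)
    data.frame(class_id = cl, total = total,
               percent_of_corpus = if (is.null(denominator)) NA_real_
                                   else if (total == 0) 0
                                   else percent(total, denominator, decimals),
               stringsAsFactors = FALSE)
  }))

  tot <- class_totals$total[match(tab$class_id, class_totals$class_id)]
  tab$percent <- ifelse(tot > 0, percent(pmax(tab$count, 0),
                                         ifelse(tot > 0, tot, 1), decimals), NA)
  structure(tab,
            class_totals = class_totals, unit = unit,
            denominator = denominator, decimals = decimals,
            post_sets = post_sets,
            class = c("hl_freq_table", class(tab)))
}

#' Merge attribute rows of a frequency table
#'
#' Applies grouping rules such as "stages I and II plus non-specific early
#' mentions count as early stage". With `unit = "posts"` merged counts are
#' distinct-post unions, not naive sums, so a post mentioning two source
#' attributes is counted once.
#'
#' @param table an `hl_freq_table` from [count_frequencies()].
#' @param rules list of rules, each a list with `target` (new attribute
#'   id), `class_id`, and `sources` (attribute ids to merge).
#' @return a new `hl_freq_table` with merged rows.
#' @export
apply_grouping <- function(table, rules) {
  stopifnot(inherits(table, "hl_freq_table"))
  unit <- attr(table, "unit")
  post_sets <- attr(table, "post_sets")
  decimals <- attr(table, "decimals")
  class_totals <- attr(table, "class_totals")
  tab <- as.data.frame(table)
  for (rule in rules) {
    miss <- setdiff(rule$sources, tab$attribute_id[tab$class_id == rule$class_id])
    if (length(miss) > 0)
      stop_input("grouping rule '%s' references missing attribute(s): %s",
                 rule$target, paste(miss, collapse = ", "))
    sel <- tab$class_id == rule$class_id & tab$attribute_id %in% rule$sources
    if (unit == "posts") {
      ids <- unique(unlist(post_sets[paste(rule$class_id, rule$sources,
                                           sep = "|")]))
      count <- length(ids)
      post_sets[[paste(rule$class_id, rule$target, sep = "|")]] <- ids
    } else {
      count <- sum(tab$count[sel])
    }
    tab <- tab[!sel, , drop = FALSE]
    tab <- rbind(tab, data.frame(class_id = rule$class_id,
                                 attribute_id = rule$target,
                                 count = count, percent = NA_real_,
                                 stringsAsFactors = FALSE))
  }
  tot <- class_totals$total[match(tab$class_id, class_totals$class_id)]
  tab$percent <- ifelse(tot > 0, percent(tab$count, ifelse(tot > 0, tot, 1),
                                         decimals), NA)
  rownames(tab) <- NULL
  structure(tab, class_totals = class_totals, unit = unit,
            denominator = attr(table, "denominator"), decimals = decimals,
            post_sets = post_sets,
            class = c("hl_freq_table", "data.frame"))
}

#' Frequency-table class totals
#'
#' @param table an `hl_freq_table`.
#' @return data.frame `class_id`, `total`, `percent_of_corpus`.
#' @export
class_totals <- function(table) {
  stopifnot(inherits(table, "hl_freq_table"))
  attr(table, "class_totals")
}
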