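#' Split gold annotations into train/test/validation sets
#'
#' Reproducible seeded partition of the distinct `post_id`s into three
#' disjoint subsets of exactly the requested sizes.
#'
#' @param gold data.frame of gold annotations with a `post_id` column, or a
#'   character vector of post ids.
#' @param n_train,n_test,n_valid subset sizes; must sum to at most the
#'   number of distinct posts.
#' @param seed integer RNG seed.
#' @return list with `train`, `test`, `valid`: if `gold` is a data.frame,
#'   the subsets of its rows (empty subsets allowed); otherwise character
#'   vectors of post ids.
#' @export
split_gold <- function(gold, n_train, n_test, n_valid, seed) {
  ids <- if (is.data.frame(gold)) unique(gold$post_id) else unique(gold)
  n <- length(ids)
  if (n_train + n_test + n_valid > n)
    stop_input("requested %d posts but only %d available",
               n_train + n_test + n_valid, n)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  perm <- sample(ids, n_train + n_test + n_valid)
  parts <- list(train = perm[seq_len(n_train)],
                test = perm[n_train + seq_len(n_test)],
                valid = perm[n_train + n_test + seq_len(n_valid)])
  if (is.data.frame(gold)) {
    lapply(parts, function(p) gold[gold$post_id %in% p, , drop = FALSE])
  } else parts
}

#' Post-level confusion counts for one class
#'
#' The evaluation unit is the post x class binary decision: a post is
#' positive for a class when at least one of its (gold or predicted) labels
#' belongs to that class.
#'
#' @param gold data.frame of gold labels (`post_id`, `class_id`, ...).
#' @param predicted data.frame of predicted labels/mentions (`post_id`,
#'   `class_id`, ...).
#' @param class_id the class to score.
#' @param universe character vector of all evaluated post ids (defines the
#'   negatives). Every predicted post must belong to it.
#' @return list with integer fields `tp`, `fp`, `fn`, `tn`.
#' @export
confusion <- function(gold, predicted, class_id, universe) {
  universe <- unique(as.character(universe))
  extraneous <- setdiff(unique(predicted$post_id), universe)
  if (length(extraneous) > 0)
    stop_input("predictions for posts outside the gold universe: %s",
               paste(head(extraneous, 5), collapse = ", "))
  if (length(setdiff(unique(gold$post_id), universe)) > 0)
    stop_input("gold annotations outside the declared universe")
  g <- universe %in% gold$post_id[gold$class_id == class_id]
  p <- universe %in% predicted$post_id[predicted$class_id == class_id]
  list(tp = sum(g & p), fp = sum(!g & p), fn = sum(g & !p), tn = sum(!g & !p))
}

#' The nine-metric performance suite
#'
#' Sensitivity (recall), specificity, precision (PPV), NPV, FPR, FDR, FNR,
#' accuracy and F1 from post-level confusion counts. Ratios with a zero
#' denominator are reported as `NA`, never coerced to 0.
#'
#' @param c list or one-row data.frame with `tp`, `fp`, `fn`, `tn`.
#' @return named list of the nine proportions.
#' @export
#' @examples
#' metrics(list(tp = 8, fp = 2, fn = 1, tn = 9))
metrics <- function(c) {
  tp <- c$tp; fp <- c$fp; fn <- c$fn; tn <- c$tn
  total <- tp + fp + fn + tn
  if (total == 0) stop_input("all confusion counts are zero")
  rat <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- rat(tp, tp + fn)
  spec <- rat(tn, tn + fp)
  prec <- rat(tp, tp + fp)
  list(sensitivity = sens,
       specificity = spec,
       precision = prec,
       npv = rat(tn, tn + fn),
       fpr = rat(fp, fp + tn),
       fdr = rat(fp, fp + tp),
       fnr = rat(fn, fn + tp),
       accuracy = (tp + tn) / total,
       f1 = f1_from_pr(prec, sens))
}

#' Cohen's kappa inter-annotator agreement
#'
#' Chance-corrected agreement between two annotators who labeled the same
#' items: `kappa = (p_o - p_e) / (1 - p_e)` with observed agreement `p_o`
#' and chance agreement `p_e` from the product of the annotators' marginal
#' label distributions. Degenerate marginals (`p_e = 1`) yield `NA`.
#'
#' @param a,b equal-length vectors of labels, item-aligned.
#' @param categories label universe; defaults to the union of observed
#'   labels.
#' @return list with `observed` (p_o), `expected` (p_e), `kappa`, `n`.
#' @export
cohen_kappa <- function(a, b, categories = NULL) {
  a <- as.character(a); b <- as.character(b)
  if (length(a) != length(b)) stop_input("annotation sets differ in length")
  n <- length(a)
  if (n == 0) stop_input("no items to compare")
  if (is.null(categories)) categories <- sort(unique(c(a, b)))
  p_o <- mean(a == b)
  pa <- vapply(categories, function(k) mean(a == k), 0)
  pb <- vapply(categories, function(k) mean(b == k), 0)
  p_e <- sum(pa * pb)
  kappa <- if (p_e >= 1) NA_real_ else (p_o - p_e) / (1 - p_e)
  list(observed = p_o, expected = p_e, kappa = kappa, n = n)
}

#' Per-class kappa for one class (present/absent)
#'
#' Restricts two annotation sets to one class and computes binary kappa
#' over the item universe.
#'
#' @param a,b annotation data.frames (`post_id`, `class_id`).
#' @param class_id the class.
#' @param universe all annotated post ids.
#' @return as [cohen_kappa()].
#' @export
class_kappa <- function(a, b, class_id, universe) {
  universe <- unique(as.character(universe))
  av <- universe %in% a$post_id[a$class_id == class_id]
  bv <- universe %in% b$post_id[b$class_id == class_id]
  cohen_kappa(av, bv, categories = c("TRUE", "FALSE"))
}

.metric_names <- c("sensitivity", "specificity", "precision", "npv",
                   "fpr", "fdr", "fnr", "accuracy", "f1")

#' Full per-class evaluation report
#'
#' Confusion counts and the nine-metric suite for every class of the
#' lexicon, plus an `overall` column computed by micro-averaging (pooling
#' tp/fp/fn/tn over classes before applying the formulas). A macro average
#' (mean of per-class metrics, `NA`s removed) is attached for transparency.
#'
#' @param gold gold annotation data.frame (`post_id`, `class_id`, ...).
#' @param predicted predicted mention data.frame (`post_id`, `class_id`, ...).
#' @param lex an `hl_lexicon`.
#' @param universe all evaluated post ids; defaults to the union of post
#'   ids seen in `gold` and `predicted`.
#' @return list with `counts` (per-class data.frame of tp/fp/fn/tn),
#'   `table` (wide data.frame, measures x (overall + classes)),
#'   `overall_micro` and `overall_macro` (metric lists).
#' @export
evaluate_all <- function(gold, predicted, lex,
                         universe = union(gold$post_id, predicted$post_id)) {
  stopifnot(inherits(lex, "hl_lexicon"))
  classes <- lex$classes$class_id
  counts <- lapply(classes, function(cl) confusion(gold, predicted, cl, universe))
  names(counts) <- classes
  per_class <- lapply(counts, metrics)
  pooled <- list(tp = sum(vapply(counts, `[[`, 0, "tp")),
                 fp = sum(vapply(counts, `[[`, 0, "fp")),
                 fn = sum(vapply(counts, `[[`, 0, "fn")),
                 tn = sum(vapply(counts, `[[`, 0, "tn")))
  micro <- metrics(pooled)
  macro <- lapply(.metric_names, function(m)
    mean(vapply(per_class, function(x) x[[m]], 0), na.rm = TRUE))
  names(macro) <- .metric_names

  tab <- data.frame(measure = .metric_names, stringsAsFactors = FALSE)
  tab$overall <- vapply(.metric_names, function(m) micro[[m]], 0)
  for (cl in classes)
    tab[[cl]] <- vapply(.metric_names, function(m) per_class[[cl]][[m]], 0)

  counts_df <- data.frame(class_id = classes,
                          tp = vapply(counts, `[[`, 0, "tp"),
                          fp = vapply(counts, `[[`, 0, "fp"),
                          fn = vapply(counts, `[[`, 0, "fn"),
                          tn = vapply(counts, `[[`, 0, "tn"),
                          stringsAsFactors = FALSE,
                          row.names = NULL)
  list(counts = counts_df, table = tab,
       overall_micro = micro, overall_macro = macro)
}

#' Micro precision/recall/F1 over (post, class, attribute) labels
#'
#' Pools the distinct label triples of gold and predicted sets; used by the
#' synthetic end-to-end recovery checks.
#'
#' @param gold,predicted data.frames with `post_id`, `class_id`,
#'   `attribute_id`.
#' @return list with `precision`, `recall`, `f1`, `n_gold`, `n_pred`.
#' @export
label_prf <- function(gold, predicted) {
  g <- unique(paste(gold$post_id, gold$class_id, gold$attribute_id, sep = "\r"))
  p <- unique(paste(predicted$post_id, predicted$class_id,
                    predicted$attribute_id, sep = "\r"))
  tp <- length(intersect(g, p))
  prec <- if (length(p) == 0) NA_real_ else tp / length(p)
  rec <- if (length(g) == 0) NA_real_ else tp / length(g)
  list(precision = prec, recall = rec, f1 = f1_from_pr(prec, rec),
       n_gold = length(g), n_pred = length(p))
}
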