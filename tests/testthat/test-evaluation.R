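test_that("split_gold partitions reproducibly with exact sizes", {
  ids <- sprintf("p%04d", 1:2000)
  sp <- split_gold(ids, 1200, 300, 500, seed = 42)
  expect_length(sp$train, 1200)
  expect_length(sp$test, 300)
  expect_length(sp$valid, 500)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_length(intersect(sp$train, sp$valid), 0)
  expect_length(intersect(sp$test, sp$valid), 0)
  expect_identical(sp, split_gold(ids, 1200, 300, 500, seed = 42))
  expect_false(identical(sp$train, split_gold(ids, 1200, 300, 500,
                                              seed = 43)$train))
  # degenerate: everything in validation
  sp0 <- split_gold(ids[1:10], 0, 0, 10, seed = 1)
  expect_length(sp0$valid, 10)
  expect_error(split_gold(ids[1:10], 8, 2, 1, seed = 1), "only 10")
})

test_that("confusion counts post-level class decisions", {
  fx <- fixture_confusion()
  cc <- confusion(fx$gold, fx$pred, "A", fx$universe)
  expect_equal(cc, list(tp = 8L, fp = 2L, fn = 1L, tn = 9L))
  # trivial cases
  g1 <- data.frame(post_id = "p1", class_id = "A", stringsAsFactors = FALSE)
  expect_equal(confusion(g1, g1, "A", c("p1", "p2")),
               list(tp = 1L, fp = 0L, fn = 0L, tn = 1L))
  empty <- g1[0, ]
  expect_equal(confusion(g1, empty, "A", c("p1", "p2"))$fp, 0L)
  expect_error(confusion(g1, data.frame(post_id = "zz", class_id = "A"),
                         "A", c("p1", "p2")), "outside the gold universe")
})

test_that("metrics reproduces the hand-computed fixture and perfect case", {
  m <- metrics(list(tp = 8, fp = 2, fn = 1, tn = 9))
  expect_equal(m$precision, 0.8)
  expect_equal(m$sensitivity, 8 / 9)
  expect_equal(m$accuracy, 0.85)
  expect_equal(m$f1, 2 * 0.8 * (8 / 9) / (0.8 + 8 / 9))

  p <- metrics(list(tp = 5, fp = 0, fn = 0, tn = 0))
  expect_equal(p$sensitivity, 1)
  expect_equal(p$precision, 1)
  expect_equal(p$accuracy, 1)
  expect_equal(p$f1, 1)
  expect_equal(p$fdr, 0)
  expect_equal(p$fnr, 0)
  expect_true(is.na(p$specificity))  # no negatives -> undefined, not 0

  expect_error(metrics(list(tp = 0, fp = 0, fn = 0, tn = 0)), "zero")
})

test_that("metric identities hold on random confusion counts", {
  set.seed(11)
  for (i in 1:1000) {
    cc <- as.list(setNames(rpois(4, 10), c("tp", "fp", "fn", "tn")))
    if (sum(unlist(cc)) == 0) next
    m <- metrics(cc)
    if (!is.na(m$precision)) expect_equal(m$precision + m$fdr, 1)
    if (!is.na(m$sensitivity)) expect_equal(m$sensitivity + m$fnr, 1)
    if (!is.na(m$specificity)) expect_equal(m$specificity + m$fpr, 1)
    if (!is.na(m$f1)) {
      expect_equal(m$f1, 2 / (1 / m$precision + 1 / m$sensitivity))
      expect_gte(m$f1, min(m$precision, m$sensitivity) - 1e-12)
      expect_lte(m$f1, max(m$precision, m$sensitivity) + 1e-12)
    }
  }
  # f1 monotone in tp with fp, fn fixed
  f1s <- vapply(1:20, function(tp)
    metrics(list(tp = tp, fp = 3, fn = 2, tn = 5))$f1, 0)
  expect_true(all(diff(f1s) > 0))
})

test_that("cohen_kappa matches hand calculation and is symmetric/relabel-invariant", {
  # 2x2 agreement table a=20 (A,A), b=5 (A,B), c=10 (B,A), d=15 (B,B)
  r1 <- rep(c("A", "A", "B", "B"), c(20, 5, 10, 15))
  r2 <- rep(c("A", "B", "A", "B"), c(20, 5, 10, 15))
  k <- cohen_kappa(r1, r2)
  expect_equal(k$observed, 0.7)
  expect_equal(k$expected, 0.5)
  expect_equal(k$kappa, 0.4)
  expect_equal(cohen_kappa(r2, r1)$kappa, k$kappa)
  # relabeling categories leaves kappa unchanged
  relab <- c(A = "X", B = "Y")
  expect_equal(cohen_kappa(relab[r1], relab[r2])$kappa, k$kappa)
  # identical annotations with >= 2 categories
  expect_equal(cohen_kappa(r1, r1)$kappa, 1)
  # degenerate single-category marginals
  expect_true(is.na(cohen_kappa(rep("A", 5), rep("A", 5))$kappa))
})

test_that("evaluate_all pools counts so Overall equals metrics of the sums", {
  lex <- builtin_hl_lexicon()
  set.seed(21)
  universe <- sprintf("p%03d", 1:150)
  classes <- lex$classes$class_id
  mk <- function() {
    n <- sample(50:120, 1)
    data.frame(post_id = sample(universe, n, replace = TRUE),
               class_id = sample(classes, n, replace = TRUE),
               attribute_id = "x", stringsAsFactors = FALSE)
  }
  gold <- mk(); pred <- mk()
  ev <- evaluate_all(gold, pred, lex, universe = universe)
  pooled <- metrics(list(tp = sum(ev$counts$tp), fp = sum(ev$counts$fp),
                         fn = sum(ev$counts$fn), tn = sum(ev$counts$tn)))
  expect_equal(ev$overall_micro, pooled)
  expect_equal(ev$table$overall, unlist(pooled, use.names = FALSE))
  # single-class input: overall column equals that class
  g1 <- gold[gold$class_id == classes[1], ]
  p1 <- pred[pred$class_id == classes[1], ]
  lex1 <- lex; lex1$classes <- lex$classes[1, ]
  lex1$attributes <- lex$attributes[lex$attributes$class_id == classes[1], ]
  ev1 <- evaluate_all(g1, p1, lex1, universe = universe)
  expect_equal(ev1$table$overall, ev1$table[[classes[1]]])
  # perfect predictions
  evp <- evaluate_all(gold, gold, lex, universe = universe)
  expect_equal(evp$overall_micro$f1, 1)
  expect_equal(evp$overall_micro$accuracy, 1)
  expect_equal(evp$overall_micro$fdr, 0)
})
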