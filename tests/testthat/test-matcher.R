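test_that("tokenize yields offsets, lemmas and tags over the normalized alphabet", {
  toks <- tokenize("stage iv hodgkin lymphoma")
  expect_equal(nrow(toks), 4L)
  expect_equal(toks$start, c(0L, 6L, 9L, 17L))
  expect_equal(toks$end, c(5L, 8L, 16L, 25L))
  expect_equal(nrow(tokenize("")), 0L)
  expect_identical(tokenize("relapsed")$lemma, "relapse")
  expect_identical(lemmatize(c("biopsies", "coughing", "stages", "tests")),
                   c("biopsy", "cough", "stage", "test"))
  expect_identical(tokenize("42 xrays")$pos, c("NUM", "NOUN"))
})

test_that("dl_distance agrees with frozen worked examples", {
  expect_equal(dl_distance("hodgkin", "hodgkin"), 0L)
  expect_equal(dl_distance("hodgkins", "hodgkin"), 1L)   # one deletion
  expect_equal(dl_distance("hogdkin", "hodgkin"), 1L)    # one transposition
  expect_equal(dl_distance("chemotherpay", "chemotherapy"), 1L)
  # OSA restriction: "ca" -> "abc" needs 3 edits (no double-edit of a span)
  expect_equal(dl_distance("ca", "abc"), 3L)
})

test_that("dl_distance matches the recursive oracle exhaustively on small pairs", {
  strs <- all_strings(c("a", "b"), 3)   # 15 strings, 225 pairs
  for (a in strs) for (b in strs)
    expect_identical(dl_distance(a, b), osa_oracle(a, b))
})

test_that("dl_distance is a symmetric pre-metric on random pairs", {
  set.seed(7)
  alpha <- c("a", "c", "g", "t")
  for (i in 1:200) {
    a <- paste(sample(alpha, sample(0:8, 1), replace = TRUE), collapse = "")
    b <- paste(sample(alpha, sample(0:8, 1), replace = TRUE), collapse = "")
    d <- dl_distance(a, b)
    expect_gte(d, 0L)
    expect_identical(d, dl_distance(b, a))
    expect_identical(d == 0L, a == b)
    expect_identical(d, osa_oracle(a, b))
  }
})

test_that("approx_match applies the term-length distance budget", {
  cfg <- match_config()
  expect_equal(approx_match("chemotherpay", "chemotherapy", cfg), 1L)
  expect_equal(approx_match("remission", "remission", cfg), 0L)
  expect_true(is.na(approx_match("pets", "pet", cfg)))  # short terms exact
  expect_true(is.na(approx_match("chemxxxapy", "chemotherapy", cfg)))
  expect_equal(allowed_distance(c(3, 5, 9, 10, 25), cfg),
               c(0L, 1L, 1L, 2L, 2L))
  expect_error(match_config(distance_values = c(1, 1, 2)), "exact")
  expect_error(match_config(distance_values = c(0, 2, 1)), "non-decreasing")
})

test_that("extract_mentions finds the worked example spans", {
  lex <- builtin_hl_lexicon()
  m1 <- extract_mentions(list(
    post_id = "ex1",
    text = paste("finally got pathology report diagnosis stage hodgkin",
                 "nodular sclerosing lymphoma treatable start therapy tonight")),
    lex)
  hit <- m1[m1$class_id == "hl_classification", ]
  expect_true(any(hit$attribute_id == "classical_hl" &
                  hit$matched_text == "nodular sclerosing"))

  m2 <- extract_mentions(list(
    post_id = "ex2",
    text = "yo stage iv classical hodgkin lymphoma treated brentuximab vedotin"),
    lex)
  keys <- paste(m2$class_id, m2$attribute_id)
  expect_true("stages_progression advanced_stage" %in% keys)
  expect_true("treatment immunotherapy" %in% keys)

  expect_equal(nrow(extract_mentions(
    list(post_id = "ex3", text = "nothing relevant in here"), lex)), 0L)
})

test_that("within-class overlaps resolve to exact hits and longest spans", {
  lex <- builtin_hl_lexicon()
  # "stage iv": the nested non-specific "stage" hit must lose to the span
  m <- extract_mentions(list(post_id = "x", text = "stage iv disease"), lex)
  st <- m[m$class_id == "stages_progression", ]
  expect_equal(st$attribute_id, "advanced_stage")
  # a longer fuzzy candidate must not displace adjacent exact mentions
  m2 <- extract_mentions(list(post_id = "x",
                              text = "stage i beaten cancer hodgkins lymphoma"),
                         lex)
  keys <- paste(m2$class_id, m2$attribute_id)
  expect_true("stages_progression early_stage" %in% keys)
  expect_true("stages_progression cured" %in% keys)
  # spans within one class never overlap
  st2 <- m2[m2$class_id == "stages_progression", ]
  if (nrow(st2) > 1) {
    st2 <- st2[order(st2$start), ]
    expect_true(all(st2$start[-1] >= st2$end[-nrow(st2)]))
  }
})

test_that("namesake spans never produce mentions", {
  lex <- builtin_hl_lexicon()
  m <- extract_mentions(list(post_id = "x",
                             text = "about thomas hodgkin and hodgkin disease"),
                        lex)
  # "hodgkin disease" is a real mention, "thomas hodgkin" is not
  expect_true(all(m$start >= 21))
  expect_true("hl_nonspecific" %in% m$attribute_id)
})

test_that("every returned mention is within its configured distance budget", {
  lex <- builtin_hl_lexicon()
  cfg <- match_config()
  posts <- generate_corpus(lex, gen_config(n_posts = 60, typo_rate = 0.5,
                                           seed = 5))
  men <- annotate_corpus(preprocess_corpus(posts[, c("post_id", "text")],
                                           lex)$posts, lex, cfg)
  expect_true(all(men$distance <= allowed_distance(nchar(men$lexicon_term),
                                                   cfg)))
})

test_that("annotate_corpus is deterministic and monotone in the distance budget", {
  lex <- builtin_hl_lexicon()
  posts <- generate_corpus(lex, gen_config(n_posts = 40, typo_rate = 0.3,
                                           seed = 9))
  clean <- preprocess_corpus(posts[, c("post_id", "text")], lex)$posts
  tight <- match_config(distance_values = c(0L, 0L, 0L))
  def <- match_config()
  loose <- match_config(distance_breaks = c(4L, 8L),
                        distance_values = c(0L, 2L, 3L))
  n_tight <- nrow(annotate_corpus(clean, lex, tight))
  n_def <- nrow(annotate_corpus(clean, lex, def))
  n_loose <- nrow(annotate_corpus(clean, lex, loose))
  expect_lte(n_tight, n_def)
  expect_lte(n_def, n_loose)
  expect_identical(annotate_corpus(clean, lex, def),
                   annotate_corpus(clean, lex, def))
  # composition: corpus table equals union of per-post extractions
  per_post <- do.call(rbind, lapply(seq_len(nrow(clean)), function(i)
    if (clean$status[i] == "retained")
      extract_mentions(clean[i, ], lex, def)))
  per_post <- per_post[order(per_post$post_id, per_post$start,
                             per_post$class_id, per_post$attribute_id), ]
  rownames(per_post) <- NULL
  expect_identical(annotate_corpus(clean, lex, def), per_post)
})
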