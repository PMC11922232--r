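test_that("generate_corpus is seed-deterministic and respects construction rules", {
  lex <- builtin_hl_lexicon()
  cfg <- gen_config(n_posts = 120, seed = 7)
  c1 <- generate_corpus(lex, cfg)
  c2 <- generate_corpus(lex, cfg)
  expect_identical(c1, c2)
  expect_false(identical(generate_corpus(lex, gen_config(n_posts = 120,
                                                         seed = 8))$text,
                         c1$text))
  # generated text is already normalized (gold spans survive preprocessing)
  expect_identical(normalize_text(c1$text), c1$text)
  # relevant posts carry an inclusion term; gold spans index their text
  for (i in seq_len(nrow(c1))) {
    g <- c1$gold[[i]]
    if (c1$category[i] == "relevant")
      expect_match(c1$text[i], "hodgkin")
    if (nrow(g) > 0)
      expect_identical(substr(rep(c1$text[i], nrow(g)), g$start + 1, g$end),
                       g$text)
  }
  expect_error(gen_config(n_posts = 10), "seed")
})

test_that("typo_rate = 0 keeps every gold surface verbatim", {
  lex <- builtin_hl_lexicon()
  corp <- generate_corpus(lex, gen_config(n_posts = 80, typo_rate = 0,
                                          seed = 3))
  gold <- corpus_gold(corp)
  terms <- lexicon_terms(lex)$term
  expect_true(all(gold$text %in% c(terms, "hodgkins lymphoma")))
})

test_that("distractor count falls in the binomial 99% interval", {
  lex <- builtin_hl_lexicon()
  cfg <- gen_config(n_posts = 1000, fp_rate = 0.1, trap_rate = 0,
                    irrelevant_rate = 0, duplicate_rate = 0, seed = 13)
  corp <- generate_corpus(lex, cfg)
  n_fp <- sum(corp$category == "fp_distractor")
  expect_gte(n_fp, qbinom(0.005, 1000, 0.1))
  expect_lte(n_fp, qbinom(0.995, 1000, 0.1))
})

test_that("inject_typos stays within the claimed edit distance", {
  expect_identical(inject_typos("chemotherapy", 0), "chemotherapy")
  expect_error(inject_typos("ab", 3), "exceeds")
  expect_identical(inject_typos("pet scan", 1, seed = 5),
                   inject_typos("pet scan", 1, seed = 5))
  set.seed(99)
  for (i in 1:100) {
    term <- sample(c("chemotherapy", "remission", "stage iv", "pet scan",
                     "reed sternberg cells"), 1)
    k <- sample(0:2, 1)
    out <- inject_typos(term, k)
    expect_lte(dl_distance(term, out), k)
    expect_identical(out, normalize_text(out))  # stays normalized
  }
  # transpose-only corruption of a long term is exactly one edit away
  out <- inject_typos("chemotherapy", 1,
                      ops = c(insert = 0, delete = 0, substitute = 0,
                              transpose = 1), seed = 2)
  expect_lte(dl_distance("chemotherapy", out), 1)
})

test_that("gold labels round-trip through both serialization formats", {
  lex <- builtin_hl_lexicon()
  corp <- generate_corpus(lex, gen_config(n_posts = 12, seed = 4))
  gold <- corpus_gold(corp)

  jl <- tempfile(fileext = ".jsonl")
  write_gold(corp, "jsonl", jl)
  back <- read_annotations(jl, lex = lex)
  expect_equal(back[order(back$post_id, back$start), names(gold)],
               gold[order(gold$post_id, gold$start), ],
               ignore_attr = TRUE)

  xd <- tempfile()
  write_gold(corp, "ehost-xml", xd)
  backx <- read_annotations(xd, lex = lex)
  expect_equal(backx[order(backx$post_id, backx$start), names(gold)],
               gold[order(gold$post_id, gold$start), ],
               ignore_attr = TRUE)
  # zero-label posts still contribute a (valid, empty) document
  expect_setequal(attr(backx, "post_ids")[attr(backx, "post_ids") %in%
                                            corp$post_id],
                  corp$post_id)
  unlink(jl); unlink(xd, recursive = TRUE)
})

test_that("unresolvable labels are warned about and listed, not dropped silently", {
  lex <- builtin_hl_lexicon()
  corp <- generate_corpus(lex, gen_config(n_posts = 5, trap_rate = 0,
                                          fp_rate = 0, irrelevant_rate = 0,
                                          duplicate_rate = 0, seed = 6))
  corp$gold[[1]]$class_id[1] <- "bogus_class"
  jl <- tempfile(fileext = ".jsonl")
  write_gold(corp, "jsonl", jl)
  expect_warning(back <- read_annotations(jl, lex = lex), "do not resolve")
  expect_equal(nrow(attr(back, "rejects")), 1L)
  expect_false("bogus_class" %in% back$class_id)
  unlink(jl)
})

test_that("safe surface forms cover all classes and exclude cross-class collisions", {
  lex <- builtin_hl_lexicon()
  safe <- safe_surface_forms(lex)
  expect_setequal(unique(safe$class_id), lex$classes$class_id)
  # a known cross-class collision: "swollen lymph node" (symptoms) contains
  # "lymph node" (site) within budget
  expect_false("swollen lymph node" %in% safe$term)
  expect_true("lymphadenopathy" %in% safe$term)
})
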