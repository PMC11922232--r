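test_that("normalize_text applies the documented rules in order", {
  expect_identical(
    normalize_text("Check @user http://t.co/x My PET scan!! \U0001F397"),
    "check my pet scan")
  expect_identical(normalize_text(""), "")
  expect_identical(normalize_text("hodgkin"), "hodgkin")
  expect_identical(normalize_text("#HodgkinLymphoma"), "hodgkinlymphoma")
  expect_identical(normalize_text("café résumé"), "caf rsum")
  expect_identical(normalize_text("visit www.example.com now"), "visit now")
})

test_that("normalize_text is idempotent with output alphabet [a-z0-9 ]", {
  set.seed(42)
  pieces <- c("Hello!", "@WHO", "https://x.co/a1", "éü", "STAGE-IV",
              "#tag", "42%", ":)", "\U0001F600", "  ", "non-Hodgkin's")
  for (i in 1:50) {
    raw <- paste(sample(pieces, sample(1:8, 1), replace = TRUE),
                 collapse = " ")
    norm <- normalize_text(raw)
    expect_identical(normalize_text(norm), norm)
    expect_false(grepl("[^a-z0-9 ]", norm))
    expect_false(grepl("^ | $|  ", norm))
  }
})

test_that("query_filter masks inclusion hits inside exclusion spans", {
  lex <- builtin_hl_lexicon()
  expect_identical(query_filter("non hodgkin lymphoma awareness week", lex),
                   "no_match")
  expect_identical(query_filter("diagnosed with hodgkins lymphoma today", lex),
                   "match")
  expect_identical(query_filter("hodgkin and non hodgkin lymphomas differ", lex),
                   "match")
  expect_identical(query_filter("no lymphoma words here", lex), "no_match")
  # every bundled exclusion term alone fails the query
  for (ex in lex$exclusion_terms)
    expect_identical(query_filter(ex, lex), "no_match")
})

test_that("fp_post_filter excludes namesake posts at post level", {
  lex <- builtin_hl_lexicon()
  expect_identical(fp_post_filter("dorothy hodgkin won the nobel prize", lex),
                   "exclude_fp")
  expect_identical(fp_post_filter("stage iv hodgkin lymphoma remission", lex),
                   "keep")
  # mixed post: namesake term present alongside true disease content
  expect_identical(
    fp_post_filter("lecture in hodgkin hall about hodgkins lymphoma", lex),
    "exclude_fp")
})

test_that("dedupe keeps the first of each normalized-identical group", {
  df <- data.frame(
    post_id = c("a", "b", "c", "d"),
    text = c("hodgkin lymphoma", "other text", "hodgkin lymphoma", "unique"),
    status = "retained", exclusion_reason = NA_character_,
    stringsAsFactors = FALSE)
  out <- dedupe(df)
  expect_identical(out$status, c("retained", "retained", "excluded", "retained"))
  expect_identical(out$exclusion_reason[3], "duplicate")
  # all-distinct corpus unchanged; stable under repetition
  expect_identical(dedupe(out), out)
})

test_that("preprocess_corpus on the 10-post fixture yields 5 retained with known reasons", {
  lex <- builtin_hl_lexicon()
  res <- preprocess_corpus(fixture_raw_posts(), lex)
  s <- setNames(res$summary$n, res$summary$outcome)
  expect_equal(s[["retained"]], 5L)
  expect_equal(s[["exclusion_only"]], 2L)
  expect_equal(s[["duplicate"]], 1L)
  expect_equal(s[["fp_hodgkin"]], 1L)
  expect_equal(s[["no_inclusion_match"]], 1L)
  # raw texts t01/t06 differ only in punctuation/case -> duplicates
  expect_identical(res$posts$exclusion_reason[res$posts$post_id == "t06"],
                   "duplicate")
  # conservation: retained + all exclusions = input size
  expect_equal(sum(res$summary$n), 10L)
  # retained texts are normalized fixed points
  ret <- res$posts$text[res$posts$status == "retained"]
  expect_identical(normalize_text(ret), ret)
})

test_that("preprocess_corpus handles degenerate inputs", {
  lex <- builtin_hl_lexicon()
  empty <- data.frame(post_id = character(), text = character(),
                      stringsAsFactors = FALSE)
  res <- preprocess_corpus(empty, lex)
  expect_equal(nrow(res$posts), 0L)
  expect_true(all(res$summary$n == 0L))

  one <- data.frame(post_id = "x", text = "hodgkins lymphoma remission",
                    stringsAsFactors = FALSE)
  expect_equal(sum(preprocess_corpus(one, lex)$posts$status == "retained"), 1L)

  dup_id <- data.frame(post_id = c("x", "x"), text = c("a", "b"),
                       stringsAsFactors = FALSE)
  expect_error(preprocess_corpus(dup_id, lex), "duplicate post_id")
})
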