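# Independent brute-force oracle for the optimal-string-alignment distance:
# top-down recursion over edit sequences (match/substitute, insert, delete,
# adjacent transposition), memoized on prefix lengths. Independent of the
# package's iterative C++ dynamic program.
osa_oracle <- function(a, b) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  la <- length(av); lb <- length(bv)
  memo <- matrix(NA_integer_, la + 1, lb + 1)
  rec <- function(i, j) {
    if (i == 0) return(as.integer(j))
    if (j == 0) return(as.integer(i))
    if (!is.na(memo[i + 1, j + 1])) return(memo[i + 1, j + 1])
    best <- rec(i - 1, j - 1) + (if (av[i] == bv[j]) 0L else 1L)
    del <- rec(i - 1, j) + 1L
    if (del < best) best <- del
    ins <- rec(i, j - 1) + 1L
    if (ins < best) best <- ins
    if (i > 1 && j > 1 && av[i] == bv[j - 1] && av[i - 1] == bv[j]) {
      tr <- rec(i - 2, j - 2) + 1L
      if (tr < best) best <- tr
    }
    memo[i + 1, j + 1] <<- best
    best
  }
  rec(la, lb)
}

# All strings of length 0..max_len over `alphabet`
all_strings <- function(alphabet, max_len) {
  out <- ""
  prev <- ""
  for (k in seq_len(max_len)) {
    prev <- as.vector(outer(prev, alphabet, paste0))
    out <- c(out, prev)
  }
  out
}

# Ten-post raw fixture: 6 relevant (one of which is a normalized duplicate),
# 2 posts that mention hodgkin only inside "non hodgkin", 1 namesake, and
# 1 post with no inclusion term at all -> 5 retained.
fixture_raw_posts <- function() {
  data.frame(
    post_id = sprintf("t%02d", 1:10),
    text = c(
      "Diagnosed with Hodgkins Lymphoma today, starting ABVD chemo",
      "My PET scan came back clean! #HodgkinLymphoma remission",
      "stage iv hodgkin lymphoma but staying strong",
      "Non-Hodgkin lymphoma awareness week everyone",
      "support for non hodgkins lymphoma research",
      "Diagnosed with Hodgkins Lymphoma today starting abvd CHEMO!!",
      "Dorothy Hodgkin won the Nobel Prize in chemistry",
      "hodgkins survivor five years cancer free",
      "my brother has hodgkin disease stage ii",
      "radiation therapy done, feeling hopeful"
    ),
    stringsAsFactors = FALSE
  )
}

# A small deterministic gold/predicted pair over a 20-post universe with
# tp=8, fp=2, fn=1, tn=9 for class "A"
fixture_confusion <- function() {
  universe <- sprintf("p%02d", 1:20)
  gold_pos <- universe[1:9]           # 9 gold positives
  pred_pos <- c(universe[1:8], universe[10:11])  # 8 tp, 2 fp, 1 fn
  list(
    gold = data.frame(post_id = gold_pos, class_id = "A",
                      attribute_id = "a1", stringsAsFactors = FALSE),
    pred = data.frame(post_id = pred_pos, class_id = "A",
                      attribute_id = "a1", stringsAsFactors = FALSE),
    universe = universe
  )
}
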