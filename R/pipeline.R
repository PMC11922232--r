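#' Run the pipeline stages from a single configuration
#'
#' Ties the stages together the way the command-line interface does:
#' `simulate` writes a synthetic corpus and its gold labels; `preprocess`
#' turns raw posts into clean posts plus an attrition summary; `extract`
#' runs the approximate matcher over retained posts; `evaluate` scores the
#' mention table against gold labels; `report` emits the frequency table.
#' Stages always execute in that canonical order. Every artifact carries a
#' provenance header (tool version, config hash, seed), and a stage whose
#' input is missing fails with a configuration error naming the stage,
#' leaving earlier artifacts intact.
#'
#' @param cfg a list with components: `lexicon` (path or `hl_lexicon`;
#'   default the bundled schema), `seed`, `match` (arguments for
#'   [match_config()]), `gen` (arguments for [gen_config()], `simulate`
#'   only), `denominator` and `unit` (for `report`), and `paths`, a named
#'   list of artifact locations: `posts`, `gold`, `clean_posts`, `summary`,
#'   `mentions`, `eval_report`, `freq_report`.
#' @param stages character subset of
#'   `c("simulate", "preprocess", "extract", "evaluate", "report")`.
#' @return invisibly, a list with the artifact paths and per-stage record
#'   counts.
#' @export
run_pipeline <- function(cfg, stages) {
  all_stages <- c("simulate", "preprocess", "extract", "evaluate", "report")
  stages <- all_stages[all_stages %in% stages]
  if (length(stages) == 0) stop_input("no valid stages requested")
  paths <- cfg$paths %||% list()
  lex <- cfg$lexicon %||% builtin_hl_lexicon()
  if (is.character(lex)) lex <- load_lexicon(lex)
  mcfg <- do.call(match_config, cfg$match %||% list())
  seed <- cfg$seed %||% 1L
  # hash the semantic configuration only, not artifact locations, so reruns
  # into different directories stay byte-identical
  meta <- .provenance(seed = seed,
                      config = cfg[setdiff(names(cfg), "paths")])
  counts <- list()
  need <- function(stage, what, p) {
    if (is.null(p))
      stop_input("configuration error in stage '%s': no path for %s", stage, what)
    p
  }
  need_file <- function(stage, what, p) {
    p <- need(stage, what, p)
    if (!file.exists(p))
      stop_input("configuration error in stage '%s': missing input %s (%s)",
                 stage, what, p)
    p
  }

  for (stage in stages) {
    if (stage == "simulate") {
      gen_args <- cfg$gen %||% list()
      if (is.null(gen_args$seed)) gen_args$seed <- seed
      gcfg <- do.call(gen_config, gen_args)
      corpus <- generate_corpus(lex, gcfg, mcfg)
      write_posts(corpus, need("simulate", "posts output", paths$posts),
                  meta = meta)
      write_gold(corpus, "jsonl", need("simulate", "gold output", paths$gold))
      counts$simulate <- nrow(corpus)
    } else if (stage == "preprocess") {
      posts <- read_posts(need_file("preprocess", "posts", paths$posts))
      res <- preprocess_corpus(posts, lex)
      write_posts(res$posts,
                  need("preprocess", "clean posts output", paths$clean_posts),
                  meta = meta)
      if (!is.null(paths$summary))
        .write_csv_meta(res$summary, paths$summary, meta)
      counts$preprocess <- c(input = nrow(posts),
                             retained = sum(res$posts$status == "retained"))
    } else if (stage == "extract") {
      clean <- read_posts(need_file("extract", "clean posts", paths$clean_posts))
      mentions <- annotate_corpus(clean, lex, mcfg)
      write_mentions(mentions,
                     need("extract", "mentions output", paths$mentions),
                     meta = meta)
      counts$extract <- nrow(mentions)
    } else if (stage == "evaluate") {
      gold <- read_annotations(need_file("evaluate", "gold", paths$gold),
                               lex = lex)
      mentions <- read_mentions(need_file("evaluate", "mentions",
                                          paths$mentions))
      clean_path <- paths$clean_posts
      universe <- if (!is.null(clean_path) && file.exists(clean_path)) {
        cp <- read_posts(clean_path)
        if (!is.null(cp$status)) cp$post_id[cp$status == "retained"]
        else cp$post_id
      } else union(attr(gold, "post_ids"), mentions$post_id)
      gold <- gold[gold$post_id %in% universe, , drop = FALSE]
      ev <- evaluate_all(gold, mentions, lex, universe = universe)
      .write_csv_meta(ev$table,
                      need("evaluate", "evaluation output", paths$eval_report),
                      meta)
      counts$evaluate <- length(universe)
    } else if (stage == "report") {
      mentions <- read_mentions(need_file("report", "mentions", paths$mentions))
      tab <- count_frequencies(mentions, lex, unit = cfg$unit %||% "posts",
                               denominator = cfg$denominator)
      tot <- class_totals(tab)
      out <- rbind(as.data.frame(tab),
                   data.frame(class_id = tot$class_id,
                              attribute_id = "_class_total",
                              count = tot$total,
                              percent = tot$percent_of_corpus,
                              stringsAsFactors = FALSE))
      .write_csv_meta(out,
                      need("report", "report output", paths$freq_report), meta)
      counts$report <- nrow(tab)
    }
  }
  invisible(list(paths = paths, counts = counts, meta = meta))
}
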