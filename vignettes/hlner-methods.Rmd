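---
title: "Methods: lexicon-driven concept extraction from short health posts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lexicon-driven concept extraction from short health posts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hlner)
```

## The problem

Hodgkin lymphoma (HL) is a rare B-cell malignancy — classical HL with its
subtypes (nodular sclerosis, mixed cellularity, lymphocyte-rich,
lymphocyte-depleted) plus the minor nodular lymphocyte-predominant form —
whose patients and caregivers discuss diagnosis, stage, symptoms and
treatment on public microblogging platforms. `hlner` implements a
dictionary-driven named-entity-recognition pipeline for such short posts:
corpus construction (query filtering, normalization, deduplication,
namesake removal), fuzzy lexicon matching, post-level evaluation, and
frequency reporting, together with a synthetic-corpus generator so that
the whole pipeline is testable with no external data.

## The concept schema

The bundled lexicon (`builtin_hl_lexicon()`) has nine classes: HL
classification; stages and progression; age associated with HL;
etiopathology; site and region involvements; diagnosis and monitoring;
symptoms; diseases and conditions; treatment. Each class carries
attributes (e.g. treatment: chemotherapy, immunotherapy, radiation
therapy, stem cell transplants, treatment aid, plus a *non-specific*
fallback) and each attribute a dictionary of normalized surface forms.
Non-specific attributes are ordinary attributes with their own surface
forms ("treatment received", "medication", "novel therapies"), not a
residual rule, because that is how such posts actually evoke a class
without naming a specific attribute.

Three term lists drive corpus construction:

* **inclusion terms** — lexical variants of "hodgkin";
* **exclusion terms** — "non hodgkin" variants, needed because every
  occurrence of "non hodgkin" contains the string "hodgkin";
* **false-positive (fp) terms** — namesake phrases ("dorothy hodgkin",
  "hodgkin hall") that mention Hodgkin the person or place, not the
  disease. The bundled fp list is a **synthetic stand-in**: the original
  curated list is not distributed, so the package ships a best-effort
  namesake list and the schema is fully config-extensible (JSON or TSV).

Two curation details are deliberate. First, surface forms are stored
post-normalization so dictionary and text live in one string space.
Second, the inclusion list omits the normalized apostrophe variant
"hodgkin s": every text containing it also contains "hodgkin", so the
variant adds no recall, while its cross-word matches ("hodgkin sister")
can poke out of an exclusion span and falsely rescue a "non hodgkin"
post.

## Preprocessing

`normalize_text()` lowercases, strips `@`-usernames, URLs, emoji and all
other non-ASCII characters ("non-English characters" is read as
non-ASCII — the simplest testable interpretation), maps remaining
non-alphanumerics to spaces and collapses whitespace; it is idempotent
with output alphabet `[a-z0-9 ]`. The pipeline order is fixed:
normalize, inclusion/exclusion query filter, deduplication, namesake
filter. The stages are reported separately so the attrition narrative
(collected, retained, excluded per reason) is reproducible.

Two asymmetric semantics are intentional:

* `query_filter()` works by **span masking**: inclusion occurrences
  inside an exclusion occurrence do not count, but a standalone
  occurrence elsewhere in the same post still matches. Mixed posts
  ("hodgkin and non hodgkin lymphomas differ") survive.
* `fp_post_filter()` is **post-level**: any fp-term occurrence drops the
  whole post, even if genuine disease content co-occurs. This replicates
  excluding false-positive posts outright and knowingly sacrifices mixed
  posts.

Duplicates are defined on normalized text (comparison happens after
standardization); the first post in stable input order is kept.

## Approximate matching

The matcher slides token n-grams (1–4 tokens by default; the longest
bundled surface form has 4 tokens) over each retained post and compares
each n-gram — as its surface substring and as a lemmatized form — against
every surface form under the **optimal string alignment (OSA)
Damerau-Levenshtein distance**: insertions, deletions, substitutions and
adjacent transpositions, with no substring edited twice. "Levenshtein
plus transposition" is taken in its standard restricted (OSA) reading.
The distance kernel is authored in C++ (rolling rows, band early-exit)
because fuzzy dictionary sweeps dominate runtime.

The distance budget depends on the *term* length: exact below 5
characters, 1 edit for 5–9, 2 edits for 10+ (`match_config()`, fully
configurable, non-decreasing by construction). Short forms like "chl",
"mri" or "abvd" must match exactly; one budget step per length band is
standard fuzzy-lexicon practice balancing misspelling recall against
short-term precision.

Overlapping candidate hits within one class are resolved
**lowest-distance-first, then longest span, then leftmost**; classes are
independent (posts are multi-label). Distance-first is a deliberate
choice made after observing that longest-first lets a longer *fuzzy*
candidate straddling two adjacent exact mentions ("stage i beaten
cancer" contains the distance-2 candidate "i beaten cancer" for "beaten
cancer") suppress both exact hits; an exact hit should never be
displaced by a fuzzier one. Nested specific/non-specific hits of one
class ("stage iv" vs "stage") still resolve to the longer specific span
because nested candidates tie at distance 0 and the longer span wins.

The lemmatizer and part-of-speech tagger are intentionally small rule
systems (`-ies→-y`, strip `-ing`, `-ed→-e`, plural `-s`; digit/verb/noun
tags). Dependency parsing is *not* used: no downstream role for parse
relations in the matching step is specified anywhere, so the package
records token-level lemma/POS only and matches on surface plus lemma
forms (both, since the original choice between them is unstated).

## Evaluation

The evaluation unit is the **post × class binary decision**. The
reported metric suite includes specificity, NPV and the false-positive
rate, all of which require true negatives, and negatives only exist at
post level — span-level scoring is therefore out of scope.
`metrics()` computes sensitivity, specificity, precision, NPV, FPR, FDR,
FNR, accuracy and F1 from tp/fp/fn/tn; ratios with zero denominators are
`NA`, never 0, to avoid silently corrupted tables. The "overall" column
micro-averages (pools counts before applying formulas); a macro average
is attached for transparency since the original averaging method is
unstated. Display rounding is half-up to two decimals
(`round_half_up()`), matching how the reference tables print.

Inter-annotator agreement is Cohen's kappa,
$\kappa = (p_o - p_e)/(1 - p_e)$, with $p_e$ from the product of the two
annotators' marginal label distributions; degenerate marginals
($p_e = 1$) give `NA`. `split_gold()` partitions post ids into
train/test/validation by explicit counts (e.g. 1200/300/500 of 2000) —
the percentages printed alongside those counts in the source material
(65%/15%/25%) sum to 105% and are ignored in favour of the counts.

## The synthetic corpus: what it emulates, and what a green test proves

`generate_corpus()` builds posts from neutral filler templates plus an
inclusion anchor ("hodgkins lymphoma", gold-labeled non-specific HL
classification) and 1–3 sampled attribute surface forms with exact
character spans. Five post categories emulate the conditions the
pipeline must survive: relevant posts, "non hodgkin" exclusion traps,
namesake distractors, irrelevant posts, and exact duplicates. Defaults
(`typo_rate = 0.1`, `fp_rate = 0.05`, `irrelevant_rate = 0.1`,
`trap_rate = 0.05`, `duplicate_rate = 0.05`, 1–3 mentions per post) are
fixed once as a plausible stressed regime; acceptance runs use the
specific settings each criterion states (e.g. all rates 0 for the
exact-recovery check).

Gold labels must be exact *by construction*, which requires three
safeguards against the fuzzy matcher itself:

1. **Safe surface forms** (`safe_surface_forms()`): a form is sampled
   only if none of its token sub-spans (surface or lemma) falls within
   the budget of a term of *another* class. Same-class collisions are
   harmless because within-class overlap resolution always prefers the
   exact, longer own-term hit. Example of an excluded form: "swollen
   lymph node" (symptoms) contains "lymph node" (site).
2. **Safe filler**: filler unigrams, ordered pairs and triples are
   checked against every term's budget; colliding words are dropped
   greedily ("family story" is within distance 2 of "family history").
3. **Boundary rejection sampling**: even safe units can collide across a
   boundary ("hereditary cancer" followed by "reed sternberg cells"
   yields the crossing bigram "cancer reed", within distance 2 of
   "cancer free"), so unit arrangements are re-shuffled until no
   boundary-crossing n-gram hits any term.

Typos corrupt mention surfaces of ≥ 5 characters (shorter terms require
exact matches, so corrupting them only tests the trivial miss) with `k`
random edits drawn from insert/delete/substitute/transpose weights,
constrained to keep the phrase normalized; the result is always within
OSA distance `k`. The corrupted form and the typo decision are drawn
whether or not the typo fires, so a fixed seed yields corpora that are
identical across typo rates except that the corrupted-mention set grows
with the rate — recall degradation is monotone in `typo_rate` by
construction, not by luck.

What the generator does **not** emulate: real discourse (threads,
sarcasm, negation, person attribution), class imbalance of real streams,
out-of-lexicon paraphrases, and spelling noise beyond character edits. A
green end-to-end test therefore establishes that the machinery is
self-consistent — preprocessing preserves exactly the posts it should,
the matcher recovers planted surface forms within its budgets, and the
metric code is arithmetically correct — not that real-corpus performance
figures are reproduced. The published headline numbers depend on an
external corpus that is not redistributable; the acceptance suite
instead reproduces the in-table arithmetic exactly and validates the
pipeline's properties on the synthetic world.

## Numerical and degenerate-input choices

* Half-up rounding everywhere a percentage is displayed; a small epsilon
  guards against binary under-representation of exact halves.
* `percent()` refuses zero denominators; frequency tables show 0 for
  empty classes only when the count is genuinely zero.
* Empty posts normalize to `""` and are excluded as
  `empty_after_normalization` before any term logic runs.
* Offsets are 0-based half-open everywhere (tokens, mentions, gold
  spans, XML attributes).
* `dl_distance` of any string with the empty string is the string's
  length; the exhaustive oracle test covers the empty string.
* Frequency counting defaults to distinct posts (`unit = "posts"`) with
  mention-event counting available, because the source tables alternate
  between "posts" and "times mentioned" and cannot be disambiguated;
  outputs label the unit.
* Stage grouping ("stages I and II plus non-specific early mentions count
  as early") merges by distinct-post union, never naive sums, so posts
  mentioning two merged attributes are not double-counted.

## Known limitations

* Post-level evaluation cannot credit partially correct spans.
* The namesake filter drops mixed posts containing both a namesake and
  genuine disease content, mirroring the reference behaviour.
* The rule lemmatizer over-stems rare forms ("sclerosing" → "scleros");
  harmless here because matching always also uses the surface form.
* The bundled surface-form dictionaries are seeded from published tables
  and result narratives, not from the original (undistributed)
  supplementary term lists; treat them as a faithful skeleton to extend
  via the config file, not a verbatim reproduction.
* κ is computed per label vector; weighting schemes for ordinal labels
  are not implemented.
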