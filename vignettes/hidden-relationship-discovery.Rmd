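---
title: "Discovering hidden biomedical relationships from co-publication scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering hidden biomedical relationships from co-publication scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(litdisc)
library(dplyr)
```

## The problem

A large share of biomedical knowledge never appears in any single abstract.
If disease A is repeatedly studied together with genes B1...Bk, and those
same genes are studied together with compound C, the literature may imply an
A–C relationship that no paper has stated — a *hidden relationship* in the
classic ABC sense. litdisc implements a complete document-level pipeline for
finding and validating such relationships in dated abstract corpora: keyword
tagging against curated thesauri, co-occurrence scoring, open/closed ABC
discovery, and a time-sliced ROC evaluation.

## Tagging concepts in abstracts

Concepts (genes, diseases, drugs, pathways, biological processes, liver
pathologies) are described by typed keywords: a full name, a symbol, and
aliases. Full names are normalized before matching — parenthesized
qualifiers are deleted (innermost first, so nesting resolves
deterministically) and commas become spaces. Gene symbols of length two are
discarded outright, and longer symbols that collide with a pinned
common-English word list ("AND", "CELL", ...) are discarded as well. The
word list ships with the package so the filter is reproducible; it applies
to gene symbols and aliases only, since that is where the ambiguity lies —
disease or drug names are meaningful even when they contain common words.

Matching uses a fixed boundary contract: a keyword occurrence must be
delimited by one of `] [ . - ) ( , : ;`, a space, or the string boundary; a
trailing plural "s" is absorbed; and inside multi-word names every space
also matches a dash ("cell death" matches "cell-death"). Full names and all
non-gene keywords match case-insensitively; gene symbols match
case-sensitively and without the plural rule (symbols are case-conventional,
and case-folding would reintroduce the English-word collisions the filter
just removed). Hits are deduplicated per document and concept.

A gene hit supported only by its symbol is ambiguous: many short symbols
are also initials, cell-line names or ordinary words. Such hits are retained
only when at least one qualifying word of the gene's full name (length at
least 4; numerals and function words excluded) occurs somewhere in the same
document; otherwise the hit is discarded. The "at least one word" reading is
the weakest defensible version of matching "parts of the full name", and the
length guard keeps trivial words from vouching for a symbol; both are
configurable.

## Scoring co-occurrence

For concepts A and B mentioned in `n_a` and `n_b` of `N` documents and
co-mentioned in `n_ab`,

* the mutual-information ratio is `S = (n_ab/N) / ((n_a/N)(n_b/N))`,
* the relative score is `R = log10 S`, zero exactly at independence,
* and the R-scaled score maps R affinely onto 1–100 against the extremes of
  the co-publication list: `R' = 1 + 99 (R - Rmin)/(Rmax - Rmin)`.

Pairs that never co-occur are unscored rather than scored at the bottom:
the logarithm is undefined at zero, and "never co-mentioned" is exactly the
property the discovery stage treats as structural, not as a low score. The
scale extremes are taken globally over the retained score table (the
simplest reading of "the co-publication list"); a per-category option was
considered and rejected as a default because it makes scores incomparable
across category pairs. If every retained pair has the same R the scale is
degenerate; all scores are then set to 100 with a warning. Scores above 40
are flagged as biologically significant; the threshold is configurable.

## ABC discovery

A hidden relationship between A and C requires **zero** direct
co-occurrence — sub-threshold co-mention is still co-mention, and treating
it as hidden would let the discovery stage rediscover weak known links. An
intermediate B qualifies when both links (A–B and B–C) clear the inclusion
criteria: at least 3 co-publications and an R-scaled score of at least 20
per link, with B drawn from the allowed categories (genes and biological
processes by default; both thresholds and categories configurable, e.g. 2
co-publications or drug intermediates for other search settings).

The inferred score of the relationship is, under the reference `min_link`
scheme, the mean over intermediates of each intermediate's weakest link —
a conservative choice: an intermediate is only as informative as its
weaker connection. Two alternative aggregations are provided for
sensitivity analysis, `mean_link` (mean of both links) and `top_k_mean`
(weakest-link mean over the 5 strongest intermediates, k configurable).
`min_link` can never exceed `mean_link` for the same links, and adding an
intermediate weaker than the current score always lowers it — both
properties are asserted in the test suite.

Open discovery ranks every allowed-category concept with no direct
co-occurrence to the start concept; ties break by intermediate count, then
lexicographic id, so rankings are fully deterministic.

## Validation by literature partitioning

The corpus is split at a date: documents strictly before the split form the
background, documents from the split up to an end date (half-open window)
form the test set. Candidate pairs are drawn from the background under
three criteria: never co-mentioned, each member in at least 10 abstracts,
and at least 5 shared qualifying intermediates. The third criterion leaves
open which thresholds define an "intermediate" at selection time; litdisc
uses the same link criteria as the scoring stage, so every candidate has a
well-defined inferred score.

A candidate is a true positive when the test slice asserts it: at least 3
co-occurrences and a test-set R-scaled score strictly above 40, computed on
the test slice's own scale (the background scale has no standing in the
later literature). All other candidates are false positives, including
pairs never co-mentioned in the test window. Sweeping the inferred-score
threshold over all observed values gives an exact stepped ROC whose
trapezoid AUC equals the rank statistic (probability a random TP outranks a
random FP, ties half) — the equivalence is tested against a brute-force
rank-counting oracle. The operating cutoff is the smallest threshold whose
FPR stays within a bound (0.1 by default), i.e. the most permissive cutoff
honouring the bound.

For a validated relationship, the *time lag* is the gap in years between
the mean publication date of the documents supporting its A–B/B–C links and
the first document co-mentioning A and C. Each supporting document is
counted once even when it supports several links. Dates with year-only
precision resolve to July 1 (month-only to the 15th) so coarse dates do not
bias mean-date arithmetic.

## The synthetic study

Desk-scale evaluation needs a corpus whose hidden structure is known, so
the generator plants it. `study_config()` builds a 2,000-document corpus
(1,900 dated uniformly over 1990 to May 2007, plus 100 assertion
documents) over 60 concepts:

* **21 disease targets**, at most one per document (documents have one
  clinical topic), so no two targets co-occur before a planted assertion
  and every target pair is a legitimate candidate;
* **5 ubiquitous biological-process hubs** present in every document.
  These model the promiscuous, uninformative concepts ("cell",
  "in vitro") that plague literature-based discovery: because they appear
  everywhere, every target–hub link sits exactly at independence (S = 1,
  R = 0) and all 210 candidate pairs share the same hub-only baseline
  score. Spurious candidates are connected *only* through them;
* **32 dedicated genes**: each of the 20 planted hidden pairs owns one or
  two genes that appear only alongside its two targets (strong, specific
  links; the first 12 pairs get two genes, the rest one);
* **3 borrowed medium links**: three genes additionally link, weakly, to a
  disjoint distractor pair each. A borrowed gene elevates its designed
  distractor pair and the four owner-target x distractor-target side pairs,
  so 15 of the 190 false-positive pairs (about 8%) score above the hub
  baseline — giving the FP distribution a realistic tail while staying
  below the 10% FPR bound the cutoff is asked to honour;
* **2 anticorrelated drug concepts** (two large, mutually exclusive
  treatment literatures, co-occurring at a fifth of the independence rate)
  anchoring the low end of the R scale, so the hub baseline lands well
  above the minimum score and hub links pass the R' >= 20 inclusion
  criterion.

Each planted pair is asserted after 2000-01-01 by 5 co-mention documents,
so the test slice labels exactly the planted pairs as true positives. Under
these conditions the planted pairs separate cleanly from the distractors
(AUC near 1), the FPR-bounded cutoff generalizes to an independent
replicate, and the mean time lag (first assertion around 2001–2002 versus
background support centred in the mid-1990s) lands at around six to seven
years. Keyword strings are unique pseudoword phrases rendered with seeded
cosmetic variation (dashes, plurals, wrapping punctuation) that exercises
the full matching contract, and filler text comes from a disjoint
pseudoword lexicon checked against both the keywords and the English
dictionary at generation time, so the planted concordance is exactly
recoverable and the tagger can be held to byte-exact agreement with it.

What the generator does **not** emulate: linguistic context (keywords are
embedded in nonsense filler, so there are no genuinely ambiguous usages
beyond the constructed fixtures), citation structure, growth of the
literature over time, or the heavy-tailed frequency distribution of real
vocabularies. Passing tests therefore demonstrate the correctness of the
counting, scoring, ranking and validation machinery under known ground
truth — not tagging accuracy on natural prose.

```{r study, eval = FALSE}
res <- run_validation_study(seed = 1)
glance(res$roc)
autoplot(res$roc)
cutoff_at_max_fpr(res$roc, 0.1)
```

## Numerical and design notes

* Scores are plain double arithmetic; formula implementations are tested
  against independent direct evaluations at 1e-12 on random count tuples.
* The ROC sweep uses all distinct observed scores plus a `+Inf` sentinel —
  no binning; a pair counts as positive when its score is at or above the
  threshold.
* Duplicate document ids keep the first record (deterministic, auditable);
  records without an id are skipped with a count.
* Problem sizes in the tests (random graphs of 6–14 concepts for the
  brute-force discovery oracle, 2,000-document study corpora, 1,000
  ROC shuffles) were chosen so the whole suite exercises every contract in
  about a minute on one core while keeping each oracle comparison exact.
* Known limitations: no sentence-level co-occurrence, no relation typing or
  direction, no species disambiguation, no intermediate-interconnectivity
  weighting. These are deliberate scope boundaries, not roadmap gaps.
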