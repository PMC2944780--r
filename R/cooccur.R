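#' Count concept occurrences and pairwise co-occurrences
#'
#' Counts, over a mention index, the number of documents mentioning each
#' concept and each unordered concept pair. Pairs that never co-occur are
#' absent from the pair table. Supporting document ids and the mean
#' publication year of the supporting documents are carried per pair.
#'
#' @param index A `mention_index` from [build_concordance()].
#' @return An `occurrence_counts` object: list with `N` (total documents in
#'   the corpus slice), `concept_counts` (tibble `concept_id`, `category`,
#'   `n_docs`), `pair_counts` (tibble `a`, `b`, `n_ab`, `doc_ids` list-column,
#'   `mean_year`) and `concepts`.
#' @export
count_occurrences <- function(index) {
  stopifnot(inherits(index, "mention_index"))
  m <- index$mentions
  concept_counts <- m |>
    dplyr::count(.data$concept_id, .data$category, name = "n_docs") |>
    dplyr::arrange(.data$concept_id)

  pairs <- dplyr::inner_join(
    m[, c("doc_id", "concept_id")], m[, c("doc_id", "concept_id", "date")],
    by = "doc_id", relationship = "many-to-many", suffix = c("_a", "_b")
  ) |>
    dplyr::filter(.data$concept_id_a < .data$concept_id_b) |>
    dplyr::group_by(a = .data$concept_id_a, b = .data$concept_id_b) |>
    dplyr::summarise(
      n_ab = dplyr::n(),
      doc_ids = list(.data$doc_id),
      mean_year = mean(decimal_year(.data$date)),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$a, .data$b)

  structure(
    list(
      N = index$n_docs,
      concept_counts = concept_counts,
      pair_counts = pairs,
      concepts = index$concepts
    ),
    class = "occurrence_counts"
  )
}

#' @export
print.occurrence_counts <- function(x, ...) {
  cat(sprintf(
    "<occurrence_counts> N=%d documents, %d concept(s), %d co-occurring pair(s)\n",
    x$N, nrow(x$concept_counts), nrow(x$pair_counts)
  ))
  invisible(x)
}

#' Mutual-information ratio of a concept pair
#'
#' Computes `S = P_AB / (P_A * P_B)` where `P_A = n_a/N`, `P_B = n_b/N` and
#' `P_AB = n_ab/N` are document frequencies. `S = 1` marks statistical
#' independence; `S > 1` marks concepts published together more often than
#' their individual frequencies predict.
#'
#' @param n_a,n_b Documents mentioning each concept (>= 1).
#' @param n_ab Documents mentioning both (>= 1).
#' @param N Total documents (>= 1).
#' @return The (vectorised) ratio `S`, strictly positive.
#' @examples
#' mim_score(10, 20, 5, 100) # 2.5
#' @export
mim_score <- function(n_a, n_b, n_ab, N) {
  if (any(n_a < 1) || any(n_b < 1) || any(N < 1)) {
    abort("mim_score requires n_a, n_b and N >= 1")
  }
  if (any(n_ab < 1)) {
    abort("mim_score requires n_ab >= 1; pairs without co-occurrence are unscored")
  }
  (n_ab / N) / ((n_a / N) * (n_b / N))
}

#' Relative score R: log10 of the mutual-information ratio
#'
#' @param S Mutual-information ratio from [mim_score()], strictly positive.
#' @return `log10(S)`; zero exactly at independence.
#' @export
log_score <- function(S) {
  if (any(S <= 0)) abort("log_score requires S > 0")
  log10(S)
}

#' Rescale R onto the 1-100 score range
#'
#' Affine map of a relative score onto `[1, 100]` against the extremes of
#' the co-publication list it belongs to:
#' `R' = 1 + 99 * (R - R_min) / (R_max - R_min)`.
#'
#' @param R Relative score(s), each within `[r_min, r_max]`.
#' @param r_min,r_max Lowest and highest `R` present in the co-publication
#'   list.
#' @return Scores in `[1, 100]`. A degenerate scale (`r_min == r_max`) maps
#'   every score to 100 with a warning: all co-occurrences in a one-value
#'   list are equally (maximally) surprising.
#' @export
rescale_r <- function(R, r_min, r_max) {
  if (r_min > r_max) abort("r_min must not exceed r_max")
  if (any(R < r_min) || any(R > r_max)) {
    abort("R outside the [r_min, r_max] scale")
  }
  if (r_min == r_max) {
    warn("degenerate score scale (r_min == r_max); all scores set to 100")
    return(rep(100, length(R)))
  }
  1 + 99 * (R - r_min) / (r_max - r_min)
}

#' Build the scored co-publication table
#'
#' Retains every pair with at least `min_copubs` co-occurrence documents,
#' scores each with S / R / R-scaled, taking the scale extremes over the
#' retained list, and flags pairs above the biological-significance
#' threshold.
#'
#' @param counts An `occurrence_counts` object.
#' @param min_copubs Minimum co-occurrence count for a pair to be scored.
#' @param significance_cutoff R-scaled score above which a co-occurrence is
#'   flagged significant (default 40).
#' @return A `copub_scores` object: list with `pairs` (tibble `a`, `b`,
#'   `n_a`, `n_b`, `n_ab`, `S`, `R`, `R_scaled`, `significant`, `mean_year`,
#'   `doc_ids`), `r_min`, `r_max`, `N`, `min_copubs`, `counts` (the full
#'   unfiltered counts, kept so zero-co-occurrence checks remain exact) and
#'   `concepts`.
#' @export
build_score_table <- function(counts, min_copubs = 1,
                              significance_cutoff = 40) {
  stopifnot(inherits(counts, "occurrence_counts"))
  if (min_copubs < 1) abort("min_copubs must be >= 1")
  n_lookup <- counts$concept_counts
  pairs <- counts$pair_counts |>
    dplyr::filter(.data$n_ab >= min_copubs) |>
    dplyr::left_join(
      dplyr::select(n_lookup, "concept_id", n_a = "n_docs"),
      by = c(a = "concept_id")
    ) |>
    dplyr::left_join(
      dplyr::select(n_lookup, "concept_id", n_b = "n_docs"),
      by = c(b = "concept_id")
    )
  degenerate <- FALSE
  if (nrow(pairs) == 0) {
    warn("no pairs retained; score table is empty with an undefined scale")
    pairs <- tibble::tibble(
      a = character(), b = character(), n_a = integer(), n_b = integer(),
      n_ab = integer(), S = double(), R = double(), R_scaled = double(),
      significant = logical(), mean_year = double(), doc_ids = list()
    )
    r_min <- r_max <- NA_real_
  } else {
    pairs$S <- mim_score(pairs$n_a, pairs$n_b, pairs$n_ab, counts$N)
    pairs$R <- log_score(pairs$S)
    r_min <- min(pairs$R)
    r_max <- max(pairs$R)
    if (r_min == r_max) degenerate <- TRUE
    pairs$R_scaled <- rescale_r(pairs$R, r_min, r_max)
    pairs$significant <- pairs$R_scaled > significance_cutoff
    pairs <- pairs[, c("a", "b", "n_a", "n_b", "n_ab", "S", "R", "R_scaled",
      "significant", "mean_year", "doc_ids")]
  }
  structure(
    list(
      pairs = tibble::as_tibble(pairs),
      r_min = r_min, r_max = r_max,
      N = counts$N, min_copubs = min_copubs,
      significance_cutoff = significance_cutoff,
      degenerate_scale = degenerate,
      counts = counts,
      concepts = counts$concepts
    ),
    class = "copub_scores"
  )
}

#' Score the co-publication list of a mention index
#'
#' Convenience wrapper: [count_occurrences()] then [build_score_table()].
#'
#' @inheritParams build_score_table
#' @param index A `mention_index`.
#' @return A `copub_scores` object.
#' @export
score_pairs <- function(index, min_copubs = 1, significance_cutoff = 40) {
  build_score_table(count_occurrences(index), min_copubs, significance_cutoff)
}

#' @export
print.copub_scores <- function(x, ...) {
  cat(sprintf(
    "<copub_scores> %d scored pair(s) over N=%d documents (min_copubs=%d)\n",
    nrow(x$pairs), x$N, x$min_copubs
  ))
  if (!is.na(x$r_min)) {
    cat(sprintf("  R scale: [%.4f, %.4f] -> [1, 100]\n", x$r_min, x$r_max))
  }
  print(dplyr::select(x$pairs, -"doc_ids"), n = 5)
  invisible(x)
}

#' Tidy a score table into its pair tibble
#'
#' @param x A `copub_scores` object.
#' @param ... Unused.
#' @return The pair tibble without the list-column of document ids.
#' @method tidy copub_scores
#' @export
tidy.copub_scores <- function(x, ...) {
  dplyr::select(x$pairs, -"doc_ids")
}

#' One-row summary of a score table
#'
#' @param x A `copub_scores` object.
#' @param ... Unused.
#' @return A one-row tibble: `n_pairs`, `n_significant`, `r_min`, `r_max`,
#'   `n_docs`, `min_copubs`.
#' @method glance copub_scores
#' @export
glance.copub_scores <- function(x, ...) {
  tibble::tibble(
    n_pairs = nrow(x$pairs),
    n_significant = sum(x$pairs$significant),
    r_min = x$r_min,
    r_max = x$r_max,
    n_docs = x$N,
    min_copubs = x$min_copubs
  )
}

#' Write a score table to TSV
#'
#' @param scores A `copub_scores` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scores_tsv <- function(scores, path) {
  readr::write_tsv(tidy(scores), path)
  invisible(path)
}
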