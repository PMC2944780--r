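#' Partition a mention index at a date
#'
#' Splits a dated mention index into a background slice (documents strictly
#' before `split_date`) and a test slice (documents in
#' `[split_date, test_end_date)`, half-open). Documents dated outside both
#' windows are excluded; documents without a resolvable date are excluded
#' with a warning. Relationships inferred from the background slice can
#' then be checked against the test slice.
#'
#' @param index A `mention_index`.
#' @param split_date,test_end_date `Date`s (or strings coercible to dates)
#'   with `split_date < test_end_date`.
#' @return A list with `background` and `test`, each a `mention_index`
#'   whose document universe (`n_docs`) is the number of corpus documents
#'   in its window.
#' @export
partition_corpus <- function(index, split_date, test_end_date) {
  stopifnot(inherits(index, "mention_index"))
  split_date <- as.Date(split_date)
  test_end_date <- as.Date(test_end_date)
  if (!split_date < test_end_date) {
    abort("split_date must be earlier than test_end_date")
  }
  dates <- index$doc_dates
  undated <- is.na(dates$date)
  if (any(undated)) {
    warn(sprintf("excluding %d undated document(s)", sum(undated)))
    dates <- dates[!undated, ]
  }
  slice_index <- function(keep_ids) {
    new_mention_index(
      dplyr::filter(index$mentions, .data$doc_id %in% keep_ids),
      dplyr::filter(dates, .data$doc_id %in% keep_ids),
      index$concepts
    )
  }
  bg_ids <- dates$doc_id[dates$date < split_date]
  test_ids <- dates$doc_id[dates$date >= split_date & dates$date < test_end_date]
  list(
    background = slice_index(bg_ids),
    test = slice_index(test_ids)
  )
}

#' Select candidate hidden pairs from a background slice
#'
#' Enumerates every unordered concept pair meeting the three candidate
#' criteria in the background literature: (1) the members never co-occur in
#' any abstract, (2) each member occurs in at least `min_occurrences`
#' distinct abstracts, (3) the members share at least
#' `min_shared_intermediates` intermediates under the link inclusion
#' criteria of `config`.
#'
#' @param scores A `copub_scores` object built on the background slice.
#' @param config A [discovery_config()]; its `target_categories` restricts
#'   which concepts can form a pair (`NULL` = any).
#' @param min_occurrences Minimum distinct abstracts per member.
#' @param min_shared_intermediates Minimum shared qualifying intermediates.
#' @return A tibble `a`, `c`, `n_shared_intermediates`, enumerated
#'   deterministically (lexicographic in `a`, then `c`).
#' @export
select_candidate_pairs <- function(scores, config = discovery_config(),
                                   min_occurrences = 10,
                                   min_shared_intermediates = 5) {
  stopifnot(inherits(scores, "copub_scores"))
  cc <- scores$counts$concept_counts
  eligible <- cc |>
    dplyr::filter(.data$n_docs >= min_occurrences)
  if (!is.null(config$target_categories)) {
    eligible <- dplyr::filter(
      eligible, .data$category %in% config$target_categories
    )
  }
  if (nrow(eligible) < 2) {
    return(tibble::tibble(
      a = character(), c = character(), n_shared_intermediates = integer()
    ))
  }
  edges <- qualifying_edges(scores, config)
  allowed <- scores$concepts$concept_id[
    scores$concepts$category %in% config$intermediate_categories
  ]
  # target -> qualifying intermediate adjacency
  adj <- edges |>
    dplyr::filter(
      .data$from %in% eligible$concept_id, .data$to %in% allowed
    ) |>
    dplyr::distinct(target = .data$from, b = .data$to)
  shared <- dplyr::inner_join(
    adj, adj,
    by = "b", relationship = "many-to-many", suffix = c("_1", "_2")
  ) |>
    dplyr::filter(.data$target_1 < .data$target_2) |>
    dplyr::filter(.data$b != .data$target_1, .data$b != .data$target_2) |>
    dplyr::count(a = .data$target_1, c = .data$target_2,
      name = "n_shared_intermediates") |>
    dplyr::filter(.data$n_shared_intermediates >= min_shared_intermediates)
  # criterion 1: zero direct co-occurrence anywhere in the background
  raw <- scores$counts$pair_counts
  shared |>
    dplyr::anti_join(raw, by = c("a", "c" = "b")) |>
    dplyr::arrange(.data$a, .data$c)
}

#' Score candidate pairs with the inferred relationship score
#'
#' @param scores Background `copub_scores`.
#' @param pairs Candidate pairs from [select_candidate_pairs()].
#' @param config A [discovery_config()].
#' @return `pairs` with `ri` and `n_intermediates` columns added, plus an
#'   `intermediates` list-column of supporting links.
#' @export
score_candidates <- function(scores, pairs, config = discovery_config()) {
  scored <- purrr::map2(
    pairs$a, pairs$c,
    function(a, c) {
      links <- find_intermediates(scores, a, c, config)
      tibble::tibble(
        ri = infer_ri(links, config$aggregation, config$top_k),
        n_intermediates = nrow(links),
        intermediates = list(links)
      )
    }
  ) |>
    dplyr::bind_rows()
  dplyr::bind_cols(pairs, scored)
}

#' Label candidate pairs against the test literature
#'
#' A candidate pair is a true positive (TP) when the test slice asserts the
#' relationship: at least `min_copubs` co-occurrences in the test set AND a
#' test-set R-scaled score strictly above `min_rscaled`. Every other pair —
#' including pairs never co-mentioned in the test set — is a false positive
#' (FP). The R-scaled score comes from the test slice's own co-publication
#' scale.
#'
#' @param pairs Scored candidate pairs (columns `a`, `c`, `ri`).
#' @param test_scores A `copub_scores` object built on the test slice.
#' @param min_copubs Minimum test-set co-occurrences for a TP (default 3).
#' @param min_rscaled Strict lower bound on the test-set R-scaled score for
#'   a TP (default 40).
#' @return `pairs` with `n_ac_test`, `r_scaled_test` and `label`
#'   (`"TP"`/`"FP"`) columns added.
#' @export
label_pairs <- function(pairs, test_scores, min_copubs = 3, min_rscaled = 40) {
  stopifnot(inherits(test_scores, "copub_scores"))
  raw <- test_scores$counts$pair_counts
  scored <- test_scores$pairs
  key <- order_pair(pairs$a, pairs$c)
  idx_raw <- match(paste(key$a, key$b), paste(raw$a, raw$b))
  idx_sc <- match(paste(key$a, key$b), paste(scored$a, scored$b))
  pairs |>
    dplyr::mutate(
      n_ac_test = dplyr::coalesce(raw$n_ab[idx_raw], 0L),
      r_scaled_test = scored$R_scaled[idx_sc],
      label = dplyr::if_else(
        .data$n_ac_test >= min_copubs &
          !is.na(.data$r_scaled_test) & .data$r_scaled_test > min_rscaled,
        "TP", "FP"
      )
    )
}

#' ROC curve over the inferred-score sweep
#'
#' Sweeps a classification threshold over every distinct inferred score in
#' the labeled set (plus a `+Inf` sentinel where nothing is called
#' positive); a pair is called positive when its score is at or above the
#' threshold. TPR = TP/(TP+FN) and FPR = FP/(FP+TN) at each threshold; the
#' AUC is the trapezoid area under the stepped curve and equals the
#' probability that a random true relationship outranks a random spurious
#' one (ties counted half).
#'
#' @param labeled A labeled pair tibble from [label_pairs()] with `ri` and
#'   `label` columns.
#' @return A `roc_curve` object: list with `points` (tibble `threshold`,
#'   `tp`, `fp`, `tn`, `fn`, `tpr`, `fpr`, ordered from high to low
#'   threshold), `auc`, `n_tp`, `n_fp`.
#' @export
compute_roc <- function(labeled) {
  assert_columns(labeled, c("ri", "label"), "labeled pairs")
  pos <- labeled$ri[labeled$label == "TP"]
  neg <- labeled$ri[labeled$label == "FP"]
  if (length(pos) == 0 || length(neg) == 0) {
    abort("ROC undefined: need at least one TP and one FP")
  }
  thresholds <- c(Inf, sort(unique(labeled$ri), decreasing = TRUE))
  tp <- vapply(thresholds, function(t) sum(pos >= t), integer(1))
  fp <- vapply(thresholds, function(t) sum(neg >= t), integer(1))
  pts <- tibble::tibble(
    threshold = thresholds,
    tp = tp, fp = fp,
    fn = length(pos) - tp, tn = length(neg) - fp,
    tpr = tp / length(pos), fpr = fp / length(neg)
  )
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
  structure(
    list(points = pts, auc = auc, n_tp = length(pos), n_fp = length(neg)),
    class = "roc_curve"
  )
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf(
    "<roc_curve> AUC = %.4f over %d TP / %d FP pair(s), %d threshold(s)\n",
    x$auc, x$n_tp, x$n_fp, nrow(x$points)
  ))
  invisible(x)
}

#' Tidy an ROC curve into its point table
#'
#' @param x A `roc_curve`.
#' @param ... Unused.
#' @return The points tibble.
#' @method tidy roc_curve
#' @export
tidy.roc_curve <- function(x, ...) x$points

#' One-row ROC summary
#'
#' @param x A `roc_curve`.
#' @param ... Unused.
#' @return A one-row tibble: `auc`, `n_tp`, `n_fp`, `n_thresholds`.
#' @method glance roc_curve
#' @export
glance.roc_curve <- function(x, ...) {
  tibble::tibble(
    auc = x$auc, n_tp = x$n_tp, n_fp = x$n_fp, n_thresholds = nrow(x$points)
  )
}

#' Score cutoff at a false-positive-rate bound
#'
#' Returns the smallest swept threshold whose FPR stays at or below the
#' bound, i.e. the most permissive cutoff (maximal TPR) still honouring the
#' FPR constraint.
#'
#' @param curve A `roc_curve`.
#' @param max_fpr Bound in (0, 1].
#' @return The threshold (a score value).
#' @export
cutoff_at_max_fpr <- function(curve, max_fpr) {
  stopifnot(inherits(curve, "roc_curve"))
  if (max_fpr <= 0 || max_fpr > 1) abort("max_fpr must lie in (0, 1]")
  pts <- dplyr::filter(curve$points, is.finite(.data$threshold),
    .data$fpr <= max_fpr)
  if (nrow(pts) == 0) {
    abort("no finite threshold satisfies the FPR bound")
  }
  min(pts$threshold)
}

#' Export an ROC curve to TSV
#'
#' Writes the per-cutoff confusion counts and rates (TP, FP, TN, FN,
#' TPR = TP/(TP+FN), FPR = FP/(FP+TN)).
#'
#' @param curve A `roc_curve`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_roc_tsv <- function(curve, path) {
  readr::write_tsv(curve$points, path)
  invisible(path)
}

#' Time lag between intermediate literature and first co-mention
#'
#' For a discovered hidden relationship, computes the lag in fractional
#' years between the mean publication date of the documents supporting its
#' A-B and B-C links and the date of the first document co-mentioning A and
#' C anywhere in the full index. A positive lag means the intermediate
#' literature predates the first explicit co-mention — the head start a
#' discovery method could have provided. The lag can be negative.
#'
#' @param relationship A one-row hidden-relationship tibble (from
#'   [closed_discovery()] or one row of [open_discovery()] /
#'   [score_candidates()] output) with an `intermediates` list-column.
#' @param index The full-corpus `mention_index` used to date the first A-C
#'   co-mention.
#' @return The lag in years, or `NA` with a warning when A and C never
#'   co-occur in the index.
#' @export
time_lag <- function(relationship, index) {
  stopifnot(inherits(index, "mention_index"), nrow(relationship) == 1)
  links <- relationship$intermediates[[1]]
  support_docs <- unique(c(
    unlist(links$docs_ab), unlist(links$docs_bc)
  ))
  dates <- index$doc_dates
  support_dates <- dates$date[dates$doc_id %in% support_docs]
  if (length(support_dates) == 0) abort("no supporting documents found in index")
  m <- index$mentions
  a_docs <- m$doc_id[m$concept_id == relationship$a]
  c_docs <- m$doc_id[m$concept_id == relationship$c]
  co_docs <- intersect(a_docs, c_docs)
  if (length(co_docs) == 0) {
    warn(sprintf(
      "%s and %s never co-occur in the index; time lag undefined",
      relationship$a, relationship$c
    ))
    return(NA_real_)
  }
  first_co <- min(dates$date[dates$doc_id %in% co_docs])
  decimal_year(first_co) - mean(decimal_year(support_dates))
}

#' Run the full literature-partitioning validation
#'
#' End-to-end evaluation on a dated mention index: partition at the split
#' date, score the background co-publication list, select and score
#' candidate hidden pairs, label them against the test slice, and compute
#' the ROC over the inferred score.
#'
#' @param index A `mention_index` over the full corpus.
#' @param split_date,test_end_date Partition boundaries, see
#'   [partition_corpus()].
#' @param config A [discovery_config()].
#' @param min_occurrences,min_shared_intermediates Candidate criteria, see
#'   [select_candidate_pairs()].
#' @param tp_min_copubs,tp_min_rscaled TP criteria, see [label_pairs()].
#' @return A `partition_validation` list: `labeled` (scored, labeled pairs),
#'   `roc`, `background_scores`, `test_scores`, `partition` and the
#'   parameters used.
#' @export
partition_validation <- function(index,
                                 split_date, test_end_date,
                                 config = discovery_config(),
                                 min_occurrences = 10,
                                 min_shared_intermediates = 5,
                                 tp_min_copubs = 3,
                                 tp_min_rscaled = 40) {
  parts <- partition_corpus(index, split_date, test_end_date)
  bg_scores <- score_pairs(parts$background)
  test_scores <- score_pairs(parts$test)
  candidates <- select_candidate_pairs(
    bg_scores, config, min_occurrences, min_shared_intermediates
  )
  if (nrow(candidates) == 0) abort("no candidate pairs in background slice")
  labeled <- score_candidates(bg_scores, candidates, config) |>
    label_pairs(test_scores, tp_min_copubs, tp_min_rscaled)
  roc <- compute_roc(labeled)
  structure(
    list(
      labeled = labeled,
      roc = roc,
      background_scores = bg_scores,
      test_scores = test_scores,
      partition = parts,
      config = config,
      split_date = as.Date(split_date),
      test_end_date = as.Date(test_end_date)
    ),
    class = "partition_validation"
  )
}

#' @export
print.partition_validation <- function(x, ...) {
  cat(sprintf(
    "<partition_validation> %d candidate pair(s): %d TP, %d FP; AUC = %.4f\n",
    nrow(x$labeled), x$roc$n_tp, x$roc$n_fp, x$roc$auc
  ))
  invisible(x)
}
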