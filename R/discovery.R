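#' Discovery configuration
#'
#' Bundles the intermediate inclusion criteria and ranking options for
#' hidden-relationship discovery. Defaults follow the settings used for
#' disease-gene style searches: at least 3 co-publications and an R-scaled
#' score of at least 20 on each link, genes and biological processes as
#' intermediates.
#'
#' @param min_copubs_link Minimum co-occurrence documents on each A-B and
#'   B-C link.
#' @param min_rscaled_link Minimum R-scaled score on each link.
#' @param intermediate_categories Categories a B concept may come from.
#' @param target_categories Categories an open-discovery C concept may come
#'   from (`NULL` = any category).
#' @param min_intermediates Minimum number of qualifying intermediates for a
#'   relationship to be reported.
#' @param aggregation How per-intermediate link scores combine into the
#'   inferred score: `"min_link"` (mean of each intermediate's weakest link,
#'   the reference scheme), `"mean_link"` (mean of each intermediate's two
#'   link scores), or `"top_k_mean"` (`min_link` over the `top_k` strongest
#'   intermediates).
#' @param top_k Number of intermediates kept under `top_k_mean`.
#' @param ri_cutoff Minimum inferred score for an open-discovery hit.
#' @return A `discovery_config` list.
#' @export
discovery_config <- function(min_copubs_link = 3,
                             min_rscaled_link = 20,
                             intermediate_categories = c("gene", "biological_process"),
                             target_categories = NULL,
                             min_intermediates = 1,
                             aggregation = c("min_link", "mean_link", "top_k_mean"),
                             top_k = 5,
                             ri_cutoff = 1) {
  aggregation <- match.arg(aggregation)
  stopifnot(min_intermediates >= 1, min_copubs_link >= 1, top_k >= 1)
  if (ri_cutoff < 1 || ri_cutoff > 100) abort("ri_cutoff must lie in [1, 100]")
  bad <- setdiff(intermediate_categories, CONCEPT_CATEGORIES)
  if (length(bad) > 0) abort(sprintf("unknown category: %s", bad[1]))
  if (!is.null(target_categories)) {
    bad <- setdiff(target_categories, CONCEPT_CATEGORIES)
    if (length(bad) > 0) abort(sprintf("unknown category: %s", bad[1]))
  }
  structure(
    list(
      min_copubs_link = min_copubs_link,
      min_rscaled_link = min_rscaled_link,
      intermediate_categories = intermediate_categories,
      target_categories = target_categories,
      min_intermediates = min_intermediates,
      aggregation = aggregation,
      top_k = top_k,
      ri_cutoff = ri_cutoff
    ),
    class = "discovery_config"
  )
}

#' Inferred score over a set of intermediate links
#'
#' Aggregates per-intermediate link scores into the inferred R-scaled score
#' of a hidden A-C relationship. Under the reference `min_link` scheme the
#' score is the sum over intermediates of the weakest of the two link
#' scores, divided by the number of intermediates; `mean_link` replaces the
#' weakest link by the mean of both links; `top_k_mean` applies `min_link`
#' to the `top_k` strongest intermediates only (all of them when fewer).
#'
#' @param links A tibble with columns `r_ab` and `r_bc` (R-scaled link
#'   scores), one row per intermediate.
#' @param aggregation See [discovery_config()].
#' @param top_k Used by `top_k_mean`.
#' @return The inferred score, a scalar in `[1, 100]`.
#' @examples
#' infer_ri(tibble::tibble(r_ab = 80, r_bc = 40)) # 40
#' @export
infer_ri <- function(links, aggregation = "min_link", top_k = 5) {
  if (nrow(links) == 0) abort("infer_ri requires at least one intermediate link")
  weakest <- pmin(links$r_ab, links$r_bc)
  switch(aggregation,
    min_link = mean(weakest),
    mean_link = mean((links$r_ab + links$r_bc) / 2),
    top_k_mean = mean(sort(weakest, decreasing = TRUE)[
      seq_len(min(top_k, length(weakest)))
    ]),
    abort(sprintf("unknown aggregation '%s'", aggregation))
  )
}

# Edge list of links meeting the per-link inclusion criteria.
#' @noRd
qualifying_edges <- function(scores, config) {
  ok <- scores$pairs |>
    dplyr::filter(
      .data$n_ab >= config$min_copubs_link,
      .data$R_scaled >= config$min_rscaled_link
    )
  # both directions so every concept can be looked up as an endpoint
  dplyr::bind_rows(
    dplyr::select(ok, from = "a", to = "b", r = "R_scaled", docs = "doc_ids"),
    dplyr::select(ok, from = "b", to = "a", r = "R_scaled", docs = "doc_ids")
  )
}

#' @noRd
check_known_concept <- function(scores, id) {
  if (!id %in% scores$concepts$concept_id) {
    abort(sprintf("unknown concept id: %s", id))
  }
}

#' Intermediates shared by two concepts
#'
#' Returns every concept B of an allowed intermediate category whose links
#' to both `a` and `c` meet the inclusion criteria (minimum co-publications
#' and minimum R-scaled score on each link).
#'
#' @param scores A `copub_scores` object.
#' @param a,c Concept ids.
#' @param config A [discovery_config()].
#' @return A tibble with one row per intermediate: `b`, `r_ab`, `r_bc`,
#'   `link_score` (the weakest of the two), `docs_ab`, `docs_bc`
#'   (list-columns of supporting document ids), ordered by `b`.
#' @export
find_intermediates <- function(scores, a, c, config = discovery_config()) {
  stopifnot(inherits(scores, "copub_scores"))
  if (a == c) abort("a and c must differ")
  edges <- qualifying_edges(scores, config)
  cats <- scores$concepts
  allowed <- cats$concept_id[cats$category %in% config$intermediate_categories]
  ea <- dplyr::filter(edges, .data$from == a, .data$to %in% allowed)
  ec <- dplyr::filter(edges, .data$from == c, .data$to %in% allowed)
  out <- dplyr::inner_join(
    dplyr::select(ea, b = "to", r_ab = "r", docs_ab = "docs"),
    dplyr::select(ec, b = "to", r_bc = "r", docs_bc = "docs"),
    by = "b"
  ) |>
    dplyr::filter(.data$b != a, .data$b != c) |>
    dplyr::mutate(link_score = pmin(.data$r_ab, .data$r_bc)) |>
    dplyr::select("b", "r_ab", "r_bc", "link_score", "docs_ab", "docs_bc") |>
    dplyr::arrange(.data$b)
  out
}

#' @noRd
direct_cooccurrence <- function(scores, a, c) {
  key <- order_pair(a, c)
  raw <- scores$counts$pair_counts
  any(raw$a == key$a & raw$b == key$b)
}

#' Closed discovery: test a hypothesised A-C pair
#'
#' Collects the intermediates connecting a hypothesised pair and scores the
#' hidden relationship. The pair only qualifies as hidden when A and C have
#' zero direct co-occurrence documents in the source index (sub-threshold
#' co-occurrence does not count as hidden) and share at least
#' `min_intermediates` qualifying intermediates; otherwise the result is
#' empty.
#'
#' @inheritParams find_intermediates
#' @return A hidden-relationship tibble with zero or one row: `a`, `c`,
#'   `ri`, `n_intermediates`, `intermediates` (list-column holding the
#'   [find_intermediates()] tibble).
#' @export
closed_discovery <- function(scores, a, c, config = discovery_config()) {
  check_known_concept(scores, a)
  check_known_concept(scores, c)
  empty <- tibble::tibble(
    a = character(), c = character(), ri = double(),
    n_intermediates = integer(), intermediates = list()
  )
  if (direct_cooccurrence(scores, a, c)) return(empty)
  links <- find_intermediates(scores, a, c, config)
  if (nrow(links) < config$min_intermediates) return(empty)
  tibble::tibble(
    a = a, c = c,
    ri = infer_ri(links, config$aggregation, config$top_k),
    n_intermediates = nrow(links),
    intermediates = list(links)
  )
}

#' Open discovery: rank hidden partners of a start concept
#'
#' Enumerates every concept of an allowed target category that never
#' co-occurs with the start concept, scores each candidate's hidden
#' relationship through the qualifying intermediates, and returns the
#' candidates at or above the score cutoff ranked by inferred score
#' (ties: more intermediates first, then lexicographic id).
#'
#' @param scores A `copub_scores` object.
#' @param a The start concept id.
#' @param config A [discovery_config()]; `target_categories = NULL` admits
#'   candidates of every category.
#' @return A hidden-relationship tibble (see [closed_discovery()]) with one
#'   row per reported candidate, ranked.
#' @export
open_discovery <- function(scores, a, config = discovery_config()) {
  check_known_concept(scores, a)
  cats <- scores$concepts
  targets <- if (is.null(config$target_categories)) {
    cats$concept_id
  } else {
    cats$concept_id[cats$category %in% config$target_categories]
  }
  targets <- setdiff(targets, a)
  # drop candidates with any direct co-occurrence with a
  raw <- scores$counts$pair_counts
  direct <- c(raw$b[raw$a == a], raw$a[raw$b == a])
  targets <- setdiff(targets, direct)
  if (length(targets) == 0) {
    return(tibble::tibble(
      a = character(), c = character(), ri = double(),
      n_intermediates = integer(), intermediates = list()
    ))
  }

  edges <- qualifying_edges(scores, config)
  allowed <- cats$concept_id[cats$category %in% config$intermediate_categories]
  ea <- dplyr::filter(edges, .data$from == a, .data$to %in% allowed,
    .data$to != a)
  linked <- dplyr::inner_join(
    dplyr::select(ea, b = "to", r_ab = "r", docs_ab = "docs"),
    dplyr::select(
      dplyr::filter(edges, .data$from %in% targets, .data$to %in% ea$to),
      c = "from", b = "to", r_bc = "r", docs_bc = "docs"
    ),
    by = "b", relationship = "many-to-many"
  ) |>
    dplyr::filter(.data$b != .data$c) |>
    dplyr::mutate(link_score = pmin(.data$r_ab, .data$r_bc))

  rels <- linked |>
    dplyr::arrange(.data$c, .data$b) |>
    tidyr::nest(intermediates = c("b", "r_ab", "r_bc", "link_score",
      "docs_ab", "docs_bc")) |>
    dplyr::mutate(
      ri = purrr::map_dbl(.data$intermediates, infer_ri,
        aggregation = config$aggregation, top_k = config$top_k),
      n_intermediates = purrr::map_int(.data$intermediates, nrow)
    ) |>
    dplyr::filter(
      .data$n_intermediates >= config$min_intermediates,
      .data$ri >= config$ri_cutoff
    ) |>
    dplyr::mutate(a = a) |>
    dplyr::select("a", "c", "ri", "n_intermediates", "intermediates") |>
    dplyr::arrange(
      dplyr::desc(.data$ri), dplyr::desc(.data$n_intermediates), .data$c
    )
  rels
}

#' Export hidden relationships to TSV
#'
#' Writes one row per (relationship, intermediate) with the pair score and
#' the per-intermediate evidence, mirroring the information content of a
#' ranked hidden-relationship table with its supporting links.
#'
#' @param relationships A hidden-relationship tibble from
#'   [open_discovery()] or [closed_discovery()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_relationships_tsv <- function(relationships, path) {
  flat <- relationships |>
    tidyr::unnest("intermediates") |>
    dplyr::mutate(
      docs_ab = purrr::map_chr(.data$docs_ab, paste, collapse = "|"),
      docs_bc = purrr::map_chr(.data$docs_bc, paste, collapse = "|")
    )
  readr::write_tsv(flat, path)
  invisible(path)
}
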