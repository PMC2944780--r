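#' Configuration of the synthetic partition-validation study
#'
#' Builds the [synthetic_config()] used to evaluate hidden-relationship
#' discovery by literature partitioning at a realistic desk scale: 2,000
#' documents spanning 1990 to May 2007 over 60 concepts.
#'
#' The concept population mirrors the structure of a real co-publication
#' network:
#' \itemize{
#'   \item `n_targets` disease concepts, at most one per document (distinct
#'     clinical topics), so no two targets ever co-occur before a planted
#'     assertion — every target pair is a legitimate hidden-pair candidate;
#'   \item `n_hubs` ubiquitous biological-process concepts present in every
#'     document — the uninformative, promiscuous concepts ("cell"-like
#'     terms) that connect everything to everything at exactly the
#'     independence rate and are the classic source of spurious hits;
#'   \item dedicated gene intermediates that appear only alongside the two
#'     targets of their planted hidden pair (strong, specific links);
#'   \item a handful of "medium" distractor pairs whose shared gene links
#'     are real but weaker, giving the false-positive score distribution a
#'     tail above the hub baseline;
#'   \item one anticorrelated drug pair (two large, mutually exclusive
#'     treatment literatures) anchoring the low end of the R scale.
#' }
#' Each of the `n_hidden` planted pairs is asserted after the split date by
#' `n_assert_docs` co-mention documents, so the test slice labels exactly
#' those pairs as true relationships.
#'
#' @param n_docs Regular (non-assertion) documents.
#' @param n_targets Disease target concepts.
#' @param n_hubs Ubiquitous process concepts.
#' @param n_hidden Planted hidden pairs (asserted post-split).
#' @param n_medium Medium-strength distractor pairs.
#' @param n_assert_docs Assertion documents per hidden pair.
#' @param target_doc_rate Fraction of documents mentioning some target.
#' @param strong_rate Link rate of a dedicated gene given its target.
#' @param medium_rate Link rate of a borrowed gene given a medium-pair
#'   target.
#' @param date_start,split_date,date_end Corpus window and partition split.
#' @return A list with `config` (a `synthetic_config`), `planted` (tibble of
#'   hidden pairs), `medium_pairs`, `split_date`, `test_end_date` and the
#'   `discovery_config` matching the study.
#' @export
study_config <- function(n_docs = 1900,
                         n_targets = 21,
                         n_hubs = 5,
                         n_hidden = 20,
                         n_medium = 3,
                         n_assert_docs = 5,
                         target_doc_rate = 0.9,
                         strong_rate = 0.7,
                         medium_rate = 0.2,
                         date_start = "1990-01-01",
                         split_date = "2000-01-01",
                         date_end = "2007-05-01") {
  targets <- sprintf("DIS%02d", seq_len(n_targets))
  hubs <- sprintf("PROC%02d", seq_len(n_hubs))
  # two genes for the first ceiling(n_hidden/2)-ish pairs, one for the rest,
  # within a fixed pool; pool size = n_hidden + number of two-gene pairs
  two_gene <- min(n_hidden, 12L)
  n_genes <- n_hidden + two_gene
  genes <- sprintf("GENE%02d", seq_len(n_genes))
  fillers <- c("DRUGX", "DRUGY")

  concepts <- dplyr::bind_rows(
    tibble::tibble(
      concept_id = targets, category = "disease",
      base_rate = target_doc_rate / n_targets, exclusive_group = "target"
    ),
    tibble::tibble(
      concept_id = hubs, category = "biological_process",
      base_rate = 1, exclusive_group = NA_character_
    ),
    tibble::tibble(
      concept_id = genes, category = "gene",
      base_rate = 0, exclusive_group = NA_character_
    ),
    tibble::tibble(
      concept_id = fillers, category = "drug",
      base_rate = 0.5, exclusive_group = NA_character_
    )
  )

  # planted hidden pairs: a fixed, deterministic pairing over the targets
  pair_idx <- tibble::tibble(
    i = ((seq_len(n_hidden) - 1L) %% n_targets) + 1L,
    j = ((seq_len(n_hidden) + (seq_len(n_hidden) - 1L) %/% n_targets) %% n_targets) + 1L
  )
  planted <- tibble::tibble(
    a = pmin(targets[pair_idx$i], targets[pair_idx$j]),
    c = pmax(targets[pair_idx$i], targets[pair_idx$j]),
    pair = seq_len(n_hidden)
  )
  if (anyDuplicated(paste(planted$a, planted$c)) > 0) {
    abort("degenerate planted pairing; adjust n_targets/n_hidden")
  }

  # dedicated genes: pair k owns gene k (and gene n_hidden + k if two-gene)
  gene_owner <- tibble::tibble(
    gene = genes,
    pair = c(seq_len(n_hidden), seq_len(two_gene))
  )
  links <- gene_owner |>
    dplyr::left_join(planted, by = "pair") |>
    tidyr::pivot_longer(c("a", "c"), values_to = "parent") |>
    dplyr::transmute(parent = .data$parent, child = .data$gene,
      rate = strong_rate)

  # medium distractor pairs: reuse one single-gene pair's gene with weak
  # links to a disjoint target pair (offset keeps them off planted pairs)
  medium_pairs <- NULL
  if (n_medium > 0) {
    offset <- 7L
    mi <- ((seq_len(n_medium) - 1L + offset) %% n_targets) + 1L
    mj <- ((mi + 9L) %% n_targets) + 1L
    medium_pairs <- tibble::tibble(
      a = pmin(targets[mi], targets[mj]),
      c = pmax(targets[mi], targets[mj]),
      gene = genes[two_gene + seq_len(n_medium)]
    )
    overlap <- dplyr::inner_join(medium_pairs, planted, by = c("a", "c"))
    if (nrow(overlap) > 0) abort("medium pair collides with a planted pair")
    med_links <- medium_pairs |>
      tidyr::pivot_longer(c("a", "c"), values_to = "parent") |>
      dplyr::transmute(parent = .data$parent, child = .data$gene,
        rate = medium_rate)
    links <- dplyr::bind_rows(links, med_links)
  }

  hidden <- tibble::tibble(
    a = planted$a, c = planted$c,
    assert_after = as.Date(split_date),
    n_assert_docs = n_assert_docs
  )
  anticorrelated <- tibble::tibble(a = "DRUGX", b = "DRUGY", p_both = 0.05)

  config <- synthetic_config(
    n_docs = n_docs,
    date_start = date_start, date_end = date_end,
    concepts = concepts,
    links = links,
    anticorrelated = anticorrelated,
    hidden = hidden
  )
  list(
    config = config,
    planted = planted,
    medium_pairs = medium_pairs,
    split_date = as.Date(split_date),
    test_end_date = as.Date(date_end),
    discovery_config = discovery_config(
      min_copubs_link = 3,
      min_rscaled_link = 20,
      intermediate_categories = c("gene", "biological_process"),
      target_categories = "disease"
    )
  )
}

#' Run the synthetic partition-validation study
#'
#' Generates a synthetic corpus from [study_config()], tags it with its own
#' thesaurus, and runs the full literature-partitioning validation:
#' candidate hidden pairs from the background slice, inferred scores,
#' labels from the test slice, ROC.
#'
#' @param seed Integer seed.
#' @param study A [study_config()] list.
#' @return The [partition_validation()] result, with the generated corpus
#'   attached as `generated` and the planted pairs as `planted`.
#' @export
run_validation_study <- function(seed, study = study_config()) {
  gen <- generate_corpus(study$config, seed)
  index <- build_concordance(gen$corpus, gen$thesaurus)
  out <- partition_validation(
    index,
    split_date = study$split_date,
    test_end_date = study$test_end_date,
    config = study$discovery_config
  )
  out$generated <- gen
  out$planted <- study$planted
  out$index <- index
  out
}
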