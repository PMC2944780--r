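# Shared fixtures and independent oracles.

suppressPackageStartupMessages({
  library(dplyr)
  library(tibble)
})

# -- small hand-built inputs -------------------------------------------------

mini_thesaurus <- function() {
  tibble::tibble(
    concept_id = c("G1", "G1", "G2", "D1", "P1"),
    category = c("gene", "gene", "gene", "disease", "biological_process"),
    keyword_type = c("full_name", "symbol", "full_name", "full_name", "full_name"),
    keyword = c(
      "programmed cell death 1 (PDCD1)", "PDCD1",
      "insulin receptor", "graves disease", "cell proliferation"
    )
  )
}

mini_corpus <- function() {
  tibble::tibble(
    doc_id = as.character(1:4),
    year = c(1998L, 1999L, 2001L, 2003L),
    title = c("one", "two", "three", "four"),
    body = c(
      "a role of programmed cell-death 1 in autoimmunity",
      "insulin receptor signalling and cell proliferation",
      "graves disease involves cell proliferations",
      "PDCD1 and programmed death signals"
    ),
    substances = ""
  )
}

# mention index built directly from a mention table (bypasses the tagger)
index_from_mentions <- function(mentions, years = NULL, n_extra_docs = 0) {
  doc_ids <- unique(mentions$doc_id)
  if (n_extra_docs > 0) {
    doc_ids <- c(doc_ids, paste0("pad", seq_len(n_extra_docs)))
  }
  if (is.null(years)) years <- rep(2000L, length(doc_ids))
  doc_dates <- tibble::tibble(
    doc_id = doc_ids,
    year = as.integer(years),
    date = litdisc:::doc_date(as.integer(years))
  )
  concepts <- dplyr::distinct(mentions, concept_id, category)
  m <- mentions |>
    dplyr::left_join(doc_dates, by = "doc_id") |>
    dplyr::arrange(doc_id, concept_id)
  litdisc:::new_mention_index(m, doc_dates, concepts)
}

# quick mention table builder: docs is a named list doc_id -> concept ids
mentions_from_list <- function(docs, categories) {
  purrr::imap(docs, function(cids, did) {
    tibble::tibble(doc_id = did, concept_id = cids,
      category = unname(categories[cids]))
  }) |>
    dplyr::bind_rows()
}

# -- independent oracles -----------------------------------------------------

BOUNDARY_CHARS <- c("]", "[", ".", "-", ")", "(", ",", ":", ";", " ")

# character-by-character matcher implementing the boundary contract
naive_match <- function(text, keyword, symbol_style = FALSE,
                        allow_plural = !symbol_style) {
  if (!symbol_style) {
    text <- tolower(text)
    keyword <- tolower(keyword)
  }
  tc <- strsplit(text, "")[[1]]
  kc <- strsplit(keyword, "")[[1]]
  n <- length(tc)
  k <- length(kc)
  for (start in seq_len(max(n - k + 1, 0))) {
    ok <- TRUE
    for (j in seq_len(k)) {
      t_ch <- tc[start + j - 1]
      k_ch <- kc[j]
      if (k_ch == " " && !symbol_style) {
        if (!t_ch %in% c(" ", "-")) { ok <- FALSE; break }
      } else if (t_ch != k_ch) { ok <- FALSE; break }
    }
    if (!ok) next
    end <- start + k - 1
    if (allow_plural && end < n && tc[end + 1] == "s") end <- end + 1
    before_ok <- start == 1 || tc[start - 1] %in% BOUNDARY_CHARS
    after_ok <- end == n || tc[end + 1] %in% BOUNDARY_CHARS
    if (before_ok && after_ok) return(TRUE)
  }
  FALSE
}

# direct-evaluation score oracles
oracle_s <- function(n_a, n_b, n_ab, N) (n_ab / N) / ((n_a / N) * (n_b / N))
oracle_rescale <- function(R, rmin, rmax) 1 + 99 * (R - rmin) / (rmax - rmin)

# rank-pair-counting AUC (ties count half)
oracle_auc <- function(ri, label) {
  pos <- ri[label == "TP"]
  neg <- ri[label == "FP"]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}

# exhaustive triple enumeration over a score table
brute_force_relationships <- function(scores, config) {
  ids <- sort(scores$concepts$concept_id)
  cat_of <- setNames(scores$concepts$category, scores$concepts$concept_id)
  pairs <- scores$pairs
  raw <- scores$counts$pair_counts
  get_pair <- function(x, y) {
    k <- if (x < y) c(x, y) else c(y, x)
    pairs[pairs$a == k[1] & pairs$b == k[2], ]
  }
  has_direct <- function(x, y) {
    k <- if (x < y) c(x, y) else c(y, x)
    any(raw$a == k[1] & raw$b == k[2])
  }
  out <- list()
  for (a in ids) {
    for (cc in ids) {
      if (a >= cc) next
      if (has_direct(a, cc)) next
      links <- list()
      for (b in ids) {
        if (b == a || b == cc) next
        if (!cat_of[b] %in% config$intermediate_categories) next
        pab <- get_pair(a, b)
        pbc <- get_pair(b, cc)
        if (nrow(pab) == 0 || nrow(pbc) == 0) next
        if (pab$n_ab < config$min_copubs_link || pbc$n_ab < config$min_copubs_link) next
        if (pab$R_scaled < config$min_rscaled_link || pbc$R_scaled < config$min_rscaled_link) next
        links[[length(links) + 1]] <- tibble::tibble(
          b = b, r_ab = pab$R_scaled, r_bc = pbc$R_scaled
        )
      }
      if (length(links) < config$min_intermediates) next
      links <- dplyr::bind_rows(links)
      weakest <- pmin(links$r_ab, links$r_bc)
      ri <- switch(config$aggregation,
        min_link = mean(weakest),
        mean_link = mean((links$r_ab + links$r_bc) / 2),
        top_k_mean = mean(sort(weakest, decreasing = TRUE)[
          seq_len(min(config$top_k, length(weakest)))
        ])
      )
      if (ri < config$ri_cutoff) next
      out[[length(out) + 1]] <- tibble::tibble(
        a = a, c = cc, ri = ri, n_intermediates = nrow(links)
      )
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(a = character(), c = character(), ri = double(),
      n_intermediates = integer()))
  }
  dplyr::bind_rows(out) |> dplyr::arrange(a, c)
}

# random mention index over a small concept universe (consistent by
# construction: counts derive from actual document memberships)
random_index <- function(seed, n_concepts = 12, n_docs = 40) {
  withr::with_seed(seed, {
    ids <- sprintf("C%02d", seq_len(n_concepts))
    cats <- sample(c("gene", "disease", "biological_process", "drug"),
      n_concepts, replace = TRUE)
    names(cats) <- ids
    docs <- lapply(seq_len(n_docs), function(i) {
      k <- sample(0:4, 1)
      if (k == 0) character(0) else sample(ids, k)
    })
    names(docs) <- sprintf("d%03d", seq_len(n_docs))
    docs <- docs[lengths(docs) > 0]
    mentions <- mentions_from_list(docs, cats)
    idx <- index_from_mentions(
      mentions,
      years = 1990L + (seq_along(unique(mentions$doc_id)) %% 15)
    )
    # pad the universe so N reflects all n_docs even if some are empty
    idx$n_docs <- n_docs
    idx
  })
}

# small run-pipeline config file
write_pipeline_config <- function(path, n_docs = 400, discover_a = "DIS01") {
  writeLines(c(
    "[simulate]",
    sprintf("n_docs = %d", n_docs),
    "[tag]",
    "[score]",
    "min_copubs = 1",
    "[discover]",
    "mode = open",
    sprintf("a = %s", discover_a),
    "target_categories = disease",
    "ri_cutoff = 1"
  ), path)
  path
}

# small planted ABC graph: A connected to C1 via genes B1, B2 (and to C2 via
# B2 only); DRG is a drug intermediate, excluded by category; C3 co-occurs
# with A directly
abc_index <- function() {
  cats <- c(A = "disease", C1 = "disease", C2 = "disease", C3 = "disease",
    B1 = "gene", B2 = "gene", DRG = "drug")
  docs <- list()
  add <- function(docs, concepts, times) {
    for (i in seq_len(times)) docs[[length(docs) + 1]] <- concepts
    docs
  }
  docs <- add(docs, c("A", "B1"), 3)
  docs <- add(docs, c("B1", "C1"), 4)
  docs <- add(docs, c("A", "B2"), 5)
  docs <- add(docs, c("B2", "C1"), 3)
  docs <- add(docs, c("B2", "C2"), 3)
  docs <- add(docs, c("A", "DRG"), 3)
  docs <- add(docs, c("DRG", "C1"), 3)
  docs <- add(docs, c("A", "C3"), 2)
  docs <- add(docs, "C2", 4)
  names(docs) <- sprintf("d%02d", seq_along(docs))
  index_from_mentions(mentions_from_list(docs, cats), n_extra_docs = 10)
}

abc_config <- function(min_rscaled_link = 1, ...) {
  discovery_config(
    min_copubs_link = 3, min_rscaled_link = min_rscaled_link,
    intermediate_categories = "gene", target_categories = "disease", ...
  )
}


make_test_scores <- function(n_ac, r_scaled_target) {
  # builds a test-slice score table where pair (A, C) has the requested
  # co-occurrence count; r_scaled is controlled by construction below
  cats <- c(A = "disease", C = "disease", X = "gene", Y = "gene")
  docs <- list()
  add <- function(docs, concepts, times) {
    for (i in seq_len(times)) docs[[length(docs) + 1]] <- concepts
    docs
  }
  if (n_ac > 0) docs <- add(docs, c("A", "C"), n_ac)
  docs <- add(docs, c("X", "Y"), 2) # scale anchor pairs
  docs <- add(docs, c("A", "X"), 1)
  docs <- add(docs, "X", 20)
  docs <- add(docs, "Y", 20)
  docs <- add(docs, "A", 3)
  docs <- add(docs, "C", 3)
  names(docs) <- sprintf("t%03d", seq_along(docs))
  score_pairs(index_from_mentions(mentions_from_list(docs, cats),
    n_extra_docs = 30))
}

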