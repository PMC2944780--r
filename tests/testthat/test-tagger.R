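match_kw <- function(text, keyword, keyword_type = "full_name",
                     category = "gene") {
  p <- compile_pattern(keyword, keyword_type, category)
  stringr::str_detect(text, stringr::regex(p$pattern, ignore_case = p$ignore_case))
}

test_that("pattern contract: boundaries, plural s, whitespace-dash", {
  expect_true(match_kw("a role of cell-death 1 in x", "cell death 1"))
  expect_true(match_kw("observed (cell deaths) here", "cell death"))
  expect_false(match_kw("mycell death", "cell death"))
  expect_false(match_kw("cell deathly", "cell death"))
  expect_true(match_kw("cell death", "cell death")) # string boundaries
  expect_true(match_kw("x; cell death: y", "cell death"))
  expect_true(match_kw("[cell death]", "cell death"))
})

test_that("gene symbols match case-sensitively and without plural", {
  expect_true(match_kw("the PDCD1 gene", "PDCD1", "symbol"))
  expect_false(match_kw("the pdcd1 gene", "PDCD1", "symbol"))
  expect_false(match_kw("the PDCD1s gene", "PDCD1", "symbol"))
  # non-gene keywords stay case-insensitive with plural
  expect_true(match_kw("Graves Diseases here", "graves disease",
    "full_name", "disease"))
})

test_that("tagger agrees with a naive character-level matcher", {
  keywords <- c("cell death 1", "insulin receptor", "graves disease", "abc")
  texts <- withr::with_seed(42, {
    pieces <- c(
      keywords, "celldeath", "cell", "death", "receptor", "xyz",
      "(cell death 1)", "insulin-receptor", "graves diseases", "abcs", "ABC"
    )
    replicate(60, paste(sample(pieces, sample(2:6, 1), replace = TRUE),
      collapse = " "))
  })
  for (kw in keywords) {
    p <- compile_pattern(kw, "full_name", "disease")
    got <- stringr::str_detect(texts, stringr::regex(p$pattern, ignore_case = TRUE))
    want <- vapply(texts, naive_match, logical(1), keyword = kw)
    expect_equal(unname(got), unname(want), info = kw)
  }
})

test_that("tag_document deduplicates hits per concept and searches substances", {
  th <- mini_thesaurus()
  patterns <- compile_patterns(clean_thesaurus(th))
  doc <- tibble::tibble(
    doc_id = "x", year = 2000L,
    title = "programmed cell death 1 study",
    body = "the PDCD1 protein, i.e. programmed cell death 1",
    substances = "insulin receptor|something"
  )
  hits <- tag_document(doc, patterns)
  # G1 hit via both symbol and full name, G2 via substances
  expect_setequal(unique(hits$concept_id), c("G1", "G2"))
  expect_equal(sum(hits$concept_id == "G1" & hits$keyword_type == "full_name"), 1)

  empty_doc <- tibble::tibble(doc_id = "y", year = 2000L, title = "nothing",
    body = "relevant words absent", substances = "")
  expect_equal(nrow(tag_document(empty_doc, patterns)), 0)
})

test_that("symbol-only hits need a full-name word in the document", {
  th <- clean_thesaurus(mini_thesaurus())
  patterns <- compile_patterns(th)
  doc_bare <- tibble::tibble(doc_id = "1", year = 2000L, title = "t",
    body = "PDCD1 alone with unrelated text", substances = "")
  doc_word <- tibble::tibble(doc_id = "2", year = 2000L, title = "t",
    body = "PDCD1 in the death pathway", substances = "")
  hits_bare <- tag_document(doc_bare, patterns)
  hits_word <- tag_document(doc_word, patterns)
  expect_equal(
    nrow(disambiguate_symbol_hits(doc_bare, hits_bare, th)), 0
  )
  expect_equal(
    disambiguate_symbol_hits(doc_word, hits_word, th)$concept_id, "G1"
  )
  # full-name hits bypass the check
  doc_full <- tibble::tibble(doc_id = "3", year = 2000L, title = "t",
    body = "programmed cell death 1 alone", substances = "")
  hits_full <- tag_document(doc_full, patterns)
  expect_true("G1" %in% disambiguate_symbol_hits(doc_full, hits_full, th)$concept_id)
})

test_that("concordance has exact inverse maps and ignores document order", {
  corpus <- mini_corpus()
  th <- mini_thesaurus()
  idx <- build_concordance(corpus, th)
  m <- idx$mentions
  # doc -> concepts and concept -> docs views contain the same edges
  by_doc <- m |> dplyr::arrange(doc_id, concept_id)
  by_concept <- m |> dplyr::arrange(concept_id, doc_id) |>
    dplyr::arrange(doc_id, concept_id)
  expect_identical(by_doc, by_concept)

  shuffled <- corpus[c(3, 1, 4, 2), ]
  idx2 <- build_concordance(shuffled, th)
  expect_identical(idx$mentions, idx2$mentions)

  # removing a document removes it from the index entirely
  idx3 <- build_concordance(corpus[corpus$doc_id != "3", ], th)
  expect_false("3" %in% idx3$mentions$doc_id)
  expect_false("3" %in% idx3$doc_dates$doc_id)
})

test_that("empty corpus yields an empty index; empty thesaurus errors", {
  empty <- mini_corpus()[0, ]
  idx <- build_concordance(empty, mini_thesaurus())
  expect_equal(nrow(idx$mentions), 0)
  expect_equal(idx$n_docs, 0)
  expect_error(
    build_concordance(mini_corpus(), mini_thesaurus()[0, ]),
    "empty thesaurus"
  )
})
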