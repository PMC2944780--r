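test_that("inferred score follows the weakest-link aggregation rules", {
  one <- tibble::tibble(r_ab = 80, r_bc = 40)
  expect_equal(infer_ri(one, "min_link"), 40)
  two <- tibble::tibble(r_ab = c(80, 60), r_bc = c(40, 90))
  expect_equal(infer_ri(two, "min_link"), 50) # (40 + 60) / 2
  expect_equal(infer_ri(two, "mean_link"), (60 + 75) / 2)
  sat <- tibble::tibble(r_ab = c(100, 100), r_bc = c(100, 100))
  for (agg in c("min_link", "mean_link", "top_k_mean")) {
    expect_equal(infer_ri(sat, agg), 100)
  }
  # top-k keeps the k strongest weakest-links
  many <- tibble::tibble(r_ab = c(90, 80, 70, 60), r_bc = c(85, 95, 65, 50))
  expect_equal(infer_ri(many, "top_k_mean", top_k = 2), mean(c(85, 80)))
  expect_equal(infer_ri(many, "top_k_mean", top_k = 10), infer_ri(many, "min_link"))
  expect_error(infer_ri(one[0, ]), "at least one")
})

test_that("mean_link dominates min_link and weak links dilute the score", {
  withr::with_seed(9, {
    for (i in 1:20) {
      links <- tibble::tibble(r_ab = runif(5, 1, 100), r_bc = runif(5, 1, 100))
      expect_lte(infer_ri(links, "min_link"), infer_ri(links, "mean_link"))
      ri <- infer_ri(links, "min_link")
      diluted <- dplyr::bind_rows(links,
        tibble::tibble(r_ab = ri / 2, r_bc = ri / 2))
      expect_lt(infer_ri(diluted, "min_link"), ri)
    }
  })
})

test_that("find_intermediates honours category and per-link thresholds", {
  scores <- score_pairs(abc_index())
  config <- abc_config()
  links <- find_intermediates(scores, "A", "C1", config)
  expect_setequal(links$b, c("B1", "B2")) # DRG excluded by category
  expect_equal(links$link_score, pmin(links$r_ab, links$r_bc))

  # raising the score threshold just above a link's R' drops that intermediate
  r_b1 <- min(links$r_ab[links$b == "B1"], links$r_bc[links$b == "B1"])
  tighter <- abc_config(min_rscaled_link = r_b1 + 1e-6)
  links2 <- find_intermediates(scores, "A", "C1", tighter)
  expect_false("B1" %in% links2$b)

  # one-sided connection is not an intermediate: B2 links A but not C3
  expect_equal(nrow(find_intermediates(scores, "B1", "C2", config)), 0)
})

test_that("closed discovery returns planted pairs and rejects direct ones", {
  scores <- score_pairs(abc_index())
  config <- abc_config()
  rel <- closed_discovery(scores, "A", "C1", config)
  expect_equal(nrow(rel), 1)
  expect_setequal(rel$intermediates[[1]]$b, c("B1", "B2"))
  expect_equal(rel$ri, infer_ri(rel$intermediates[[1]], "min_link"))

  # direct co-occurrence, even sub-threshold, disqualifies the pair
  expect_equal(nrow(closed_discovery(scores, "A", "C3", config)), 0)
  # no shared intermediates (C3 has no gene links at all)
  expect_equal(nrow(closed_discovery(scores, "C2", "C3", config)), 0)
  expect_error(closed_discovery(scores, "A", "NOPE", config), "unknown concept")
})

test_that("closed discovery is symmetric in its arguments", {
  scores <- score_pairs(abc_index())
  config <- abc_config()
  ac <- closed_discovery(scores, "A", "C1", config)
  ca <- closed_discovery(scores, "C1", "A", config)
  expect_equal(ac$ri, ca$ri)
  expect_identical(
    ac$intermediates[[1]][, c("b", "link_score")],
    ca$intermediates[[1]][, c("b", "link_score")]
  )
})

test_that("open discovery ranks candidates and matches closed discovery", {
  scores <- score_pairs(abc_index())
  config <- abc_config()
  hits <- open_discovery(scores, "A", config)
  # C1 and C2 are hidden partners; C3 co-occurs, A itself excluded
  expect_setequal(hits$c, c("C1", "C2"))
  expect_equal(hits$ri, sort(hits$ri, decreasing = TRUE))
  for (i in seq_len(nrow(hits))) {
    closed <- closed_discovery(scores, "A", hits$c[i], config)
    expect_equal(hits$ri[i], closed$ri)
    expect_identical(hits$intermediates[[i]], closed$intermediates[[1]])
  }
  # a cutoff above every score empties the ranking
  high <- abc_config(ri_cutoff = 100)
  if (max(hits$ri) < 100) {
    expect_equal(nrow(open_discovery(scores, "A", high)), 0)
  }
})

test_that("open discovery equals exhaustive triple enumeration on random graphs", {
  for (seed in 1:10) {
    idx <- random_index(seed, n_concepts = 12, n_docs = 40)
    scores <- score_pairs(idx)
    for (agg in c("min_link", "mean_link", "top_k_mean")) {
      config <- discovery_config(
        min_copubs_link = 1, min_rscaled_link = 1,
        intermediate_categories = c("gene", "biological_process", "drug"),
        target_categories = NULL, aggregation = agg, top_k = 3
      )
      want <- brute_force_relationships(scores, config)
      got <- purrr::map(
        sort(scores$concepts$concept_id),
        function(a) {
          rels <- open_discovery(scores, a, config)
          rels[rels$c > a, c("a", "c", "ri", "n_intermediates")]
        }
      ) |>
        dplyr::bind_rows() |>
        dplyr::arrange(a, c)
      expect_equal(got, want, info = paste(seed, agg))
    }
  }
})

test_that("ranking ties break by intermediate count then concept id", {
  ranked <- tibble::tibble(
    a = "A", c = c("C2", "C1", "C3"), ri = c(50, 50, 50),
    n_intermediates = c(2L, 3L, 2L), intermediates = list(NULL, NULL, NULL)
  ) |>
    dplyr::arrange(dplyr::desc(ri), dplyr::desc(n_intermediates), c)
  expect_equal(ranked$c, c("C1", "C2", "C3"))
})
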