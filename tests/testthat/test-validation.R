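test_that("partitioning uses half-open date windows", {
  cats <- c(X = "gene", Y = "disease")
  mentions <- mentions_from_list(
    list(d1 = c("X", "Y"), d2 = c("X", "Y"), d3 = c("X", "Y"), d4 = "X"),
    cats
  )
  idx <- index_from_mentions(mentions, years = c(1998L, 2003L, 2008L, 2000L))
  # year-only dates resolve to July 1, so the 2000 doc lands in the test set
  parts <- partition_corpus(idx, "2000-01-01", "2007-05-01")
  expect_setequal(unique(parts$background$mentions$doc_id), "d1")
  expect_setequal(unique(parts$test$mentions$doc_id), c("d2", "d4"))
  expect_equal(parts$background$n_docs, 1)
  expect_equal(parts$test$n_docs, 2)

  # all documents pre-split leaves an empty test index
  early <- partition_corpus(idx, "2050-01-01", "2060-01-01")
  expect_equal(early$test$n_docs, 0)
  expect_equal(early$background$n_docs, 4)

  # a document dated exactly at the split boundary belongs to the test set
  idx2 <- index_from_mentions(mentions_from_list(list(d1 = "X"), cats))
  idx2$doc_dates$date <- as.Date("2000-01-01")
  parts2 <- partition_corpus(idx2, "2000-01-01", "2007-05-01")
  expect_equal(parts2$test$n_docs, 1)
  expect_equal(parts2$background$n_docs, 0)

  expect_error(partition_corpus(idx, "2005-01-01", "2001-01-01"), "earlier")
})

test_that("candidate pairs honour the three background criteria", {
  cats <- c(A = "disease", C = "disease", E = "disease",
    B1 = "gene", B2 = "gene", B3 = "gene", B4 = "gene", B5 = "gene")
  docs <- list()
  add <- function(docs, concepts, times) {
    for (i in seq_len(times)) docs[[length(docs) + 1]] <- concepts
    docs
  }
  # A and C share five intermediates and never co-occur; both frequent
  for (b in c("B1", "B2", "B3", "B4", "B5")) {
    docs <- add(docs, c("A", b), 2)
    docs <- add(docs, c("C", b), 2)
  }
  # E shares intermediates with A but is rare (only 4 abstracts)
  docs <- add(docs, c("E", "B1"), 1)
  docs <- add(docs, c("E", "B2"), 1)
  docs <- add(docs, c("E", "B3"), 1)
  docs <- add(docs, c("E", "B4"), 1)
  names(docs) <- sprintf("d%03d", seq_along(docs))
  idx <- index_from_mentions(mentions_from_list(docs, cats), n_extra_docs = 5)
  scores <- score_pairs(idx)
  config <- discovery_config(
    min_copubs_link = 1, min_rscaled_link = 1,
    intermediate_categories = "gene", target_categories = "disease"
  )
  pairs <- select_candidate_pairs(scores, config,
    min_occurrences = 10, min_shared_intermediates = 5)
  expect_equal(pairs$a, "A")
  expect_equal(pairs$c, "C")
  expect_equal(pairs$n_shared_intermediates, 5L)

  # direct co-occurrence disqualifies: add one shared abstract
  docs2 <- add(docs, c("A", "C"), 1)
  names(docs2) <- sprintf("d%03d", seq_along(docs2))
  idx2 <- index_from_mentions(mentions_from_list(docs2, cats), n_extra_docs = 5)
  pairs2 <- select_candidate_pairs(score_pairs(idx2), config,
    min_occurrences = 10, min_shared_intermediates = 5)
  expect_equal(nrow(pairs2), 0)

  # one fewer shared intermediate disqualifies
  pairs3 <- select_candidate_pairs(scores, config,
    min_occurrences = 10, min_shared_intermediates = 6)
  expect_equal(nrow(pairs3), 0)
})

test_that("TP labeling applies the strict co-occurrence and score rule", {
  pairs <- tibble::tibble(a = "A", c = "C", ri = 50)

  ts <- make_test_scores(n_ac = 3, r_scaled = NA)
  lab <- label_pairs(pairs, ts)
  expect_gt(lab$r_scaled_test, 40) # rare pair, high S by construction
  expect_equal(lab$label, "TP")

  # floor on test co-occurrences: 2 is not enough however high the score
  lab2 <- label_pairs(pairs, make_test_scores(n_ac = 2, r_scaled = NA))
  expect_gt(lab2$r_scaled_test, 40)
  expect_equal(lab2$label, "FP")

  # never co-mentioned in the test slice
  lab3 <- label_pairs(pairs, make_test_scores(n_ac = 0, r_scaled = NA))
  expect_equal(lab3$n_ac_test, 0L)
  expect_equal(lab3$label, "FP")

  # the score bound is strict: exactly 40 fails, just above 40 passes
  lab4 <- label_pairs(pairs, ts, min_rscaled = lab$r_scaled_test)
  expect_equal(lab4$label, "FP")
  lab5 <- label_pairs(pairs, ts, min_rscaled = lab$r_scaled_test - 1e-9)
  expect_equal(lab5$label, "TP")
})

test_that("labeling is a pure function of the test table", {
  withr::with_seed(31, {
    pairs <- tibble::tibble(
      a = rep("A", 4), c = c("C", "X", "Y", "NOPE"), ri = runif(4)
    )
    ts <- make_test_scores(3, NA)
    lab <- label_pairs(pairs, ts)
    shuffled <- label_pairs(pairs[c(3, 1, 4, 2), ], ts)
    expect_identical(
      dplyr::arrange(lab, c), dplyr::arrange(shuffled, c)
    )
  })
})

test_that("ROC matches the rank-counting AUC oracle, including ties", {
  expect_equal(
    compute_roc(tibble::tibble(
      ri = c(3, 1, 2, 0), label = c("TP", "TP", "FP", "FP")
    ))$auc,
    0.75
  )
  withr::with_seed(77, {
    for (i in 1:40) {
      n <- sample(8:40, 1)
      labeled <- tibble::tibble(
        ri = round(runif(n, 1, 100), sample(c(0, 1), 1)), # ties likely
        label = sample(c("TP", "FP"), n, replace = TRUE)
      )
      if (length(unique(labeled$label)) < 2) next
      expect_equal(compute_roc(labeled)$auc, oracle_auc(labeled$ri, labeled$label),
        tolerance = 1e-12)
    }
  })
})

test_that("ROC endpoints, monotonicity and degenerate input", {
  perfect <- tibble::tibble(ri = c(9, 8, 2, 1),
    label = c("TP", "TP", "FP", "FP"))
  roc <- compute_roc(perfect)
  expect_equal(roc$auc, 1)
  pts <- roc$points
  expect_true(all(diff(pts$fpr) >= 0))
  expect_true(all(diff(pts$tpr) >= 0))
  expect_equal(pts$fpr[1], 0)
  expect_equal(pts$tpr[nrow(pts)], 1)
  expect_error(
    compute_roc(tibble::tibble(ri = 1:3, label = c("TP", "TP", "TP"))),
    "at least one"
  )
})

test_that("AUC is invariant under strictly monotone transforms of the score", {
  withr::with_seed(5, {
    labeled <- tibble::tibble(
      ri = runif(50, 1, 100),
      label = sample(c("TP", "FP"), 50, replace = TRUE, prob = c(0.3, 0.7))
    )
    base <- compute_roc(labeled)$auc
    for (f in list(function(x) x^2, function(x) log(x), function(x) 5 * x - 3)) {
      expect_equal(compute_roc(dplyr::mutate(labeled, ri = f(ri)))$auc, base)
    }
  })
})

test_that("the FPR-bounded cutoff picks the most permissive safe threshold", {
  labeled <- tibble::tibble(
    ri = c(50, 45, 40, 34, 30, 20, 10),
    label = c("TP", "TP", "TP", "TP", "FP", "FP", "FP")
  )
  curve <- compute_roc(labeled)
  # threshold 34 keeps every TP and no FP: FPR 0 <= 0.1
  expect_equal(cutoff_at_max_fpr(curve, 0.1), 34)
  # a permissive bound returns the smallest swept threshold
  expect_equal(cutoff_at_max_fpr(curve, 1), min(labeled$ri))
  # a bound below the smallest nonzero FPR still yields a valid threshold
  # above every FP score
  tight <- cutoff_at_max_fpr(curve, 0.2)
  expect_gt(tight, max(labeled$ri[labeled$label == "FP"]))
  expect_error(cutoff_at_max_fpr(curve, 0), "max_fpr")
})

test_that("time lag is the gap from intermediate literature to first co-mention", {
  cats <- c(A = "disease", C = "disease", B = "gene")
  docs <- list(s1 = c("A", "B"), s2 = c("B", "C"), s3 = c("A", "C"), s4 = "A")
  idx <- index_from_mentions(mentions_from_list(docs, cats),
    years = c(1995L, 1997L, 2002L, 1990L))
  rel <- tibble::tibble(
    a = "A", c = "C", ri = 50, n_intermediates = 1L,
    intermediates = list(tibble::tibble(
      b = "B", r_ab = 50, r_bc = 50, link_score = 50,
      docs_ab = list("s1"), docs_bc = list("s2")
    ))
  )
  # supporting docs mean mid-1996, first co-mention mid-2002
  expect_equal(time_lag(rel, idx), 6, tolerance = 0.01)

  # negative when the co-mention predates the intermediate literature
  idx2 <- index_from_mentions(mentions_from_list(docs, cats),
    years = c(2005L, 2007L, 2002L, 1990L))
  expect_lt(time_lag(rel, idx2), 0)

  # zero when the single supporting doc is the first co-mention date
  idx3 <- index_from_mentions(mentions_from_list(docs, cats),
    years = c(2002L, 2002L, 2002L, 1990L))
  expect_equal(time_lag(rel, idx3), 0)

  # undefined without any co-mention
  idx4 <- index_from_mentions(
    mentions_from_list(list(s1 = c("A", "B"), s2 = c("B", "C")), cats),
    years = c(1995L, 1997L)
  )
  expect_warning(lag <- time_lag(rel, idx4), "never co-occur")
  expect_true(is.na(lag))
})
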