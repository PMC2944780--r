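# Deterministic pseudoword vocabularies. Keyword words and filler words come
# from disjoint syllable sets, so filler text can never produce a keyword hit
# and no pseudoword collides with the English dictionary.
KEYWORD_SYLLABLES <- c(
  "bra", "del", "fex", "gor", "hul", "jam", "kor", "lin", "mep", "nov",
  "pag", "qui", "rud", "sel", "tam", "ver", "wex", "yol", "zan", "cus"
)
FILLER_SYLLABLES <- c(
  "blo", "cri", "dra", "esh", "fro", "gli", "hax", "itz", "jop", "kev",
  "lur", "mon", "nis", "ost", "pru", "que", "rok", "ste", "tul", "vos"
)

#' @noRd
pseudoword <- function(i, syllables) {
  n <- length(syllables)
  paste0(
    syllables[(i - 1) %% n + 1],
    syllables[((i - 1) %/% n) %% n + 1],
    syllables[((i - 1) %/% (n * n)) %% n + 1]
  )
}

#' @noRd
filler_lexicon <- function(n = 60) {
  purrr::map_chr(seq_len(n), pseudoword, syllables = FILLER_SYLLABLES)
}

#' Synthetic corpus configuration
#'
#' Describes the generative model for a seeded synthetic corpus: per-concept
#' document occurrence rates, optional exclusive groups (at most one member
#' per document — topic-like concepts), conditional parent-child links,
#' coupled pairs with a planted joint rate, anticorrelated pairs, and
#' hidden A-C relationships asserted only after a date.
#'
#' @param n_docs Number of regular documents (assertion documents for hidden
#'   pairs are generated on top of these).
#' @param date_start,date_end Calendar window for regular document dates
#'   (uniform).
#' @param concepts Tibble `concept_id`, `category`, `base_rate` (per-document
#'   occurrence probability in `[0, 1]`; 1 makes the concept ubiquitous),
#'   optional `exclusive_group` (`NA` = independent).
#' @param links Optional tibble `parent`, `child`, `rate`: the child appears
#'   with probability `rate` in every document containing the parent (on top
#'   of the child's own base rate).
#' @param planted_pairs Optional tibble `a`, `b`, `joint_rate`: the pair
#'   co-occurs in a fraction `joint_rate` of documents while each member
#'   keeps its base rate (requires `joint_rate <= min(base_a, base_b)` and
#'   `base_a + base_b - joint_rate <= 1`).
#' @param anticorrelated Optional tibble `a`, `b`, `p_both`: like
#'   `planted_pairs` but with `p_both` below the independence product, for
#'   planting below-chance co-occurrence.
#' @param hidden Optional tibble `a`, `c`, `assert_after` (`Date`),
#'   `n_assert_docs`: each pair gets `n_assert_docs` extra co-mention
#'   documents dated uniformly in `[assert_after, date_end)`, and any chance
#'   co-mention before `assert_after` is suppressed (the `c` mention is
#'   dropped), so the pair is strictly hidden before the assertion date.
#' @return A `synthetic_config` list, validated.
#' @export
synthetic_config <- function(n_docs,
                             date_start, date_end,
                             concepts,
                             links = NULL,
                             planted_pairs = NULL,
                             anticorrelated = NULL,
                             hidden = NULL) {
  date_start <- as.Date(date_start)
  date_end <- as.Date(date_end)
  stopifnot(n_docs >= 1, date_start < date_end)
  assert_columns(concepts, c("concept_id", "category", "base_rate"), "concepts")
  if (!"exclusive_group" %in% names(concepts)) {
    concepts$exclusive_group <- NA_character_
  }
  if (anyDuplicated(concepts$concept_id)) abort("duplicate concept_id")
  if (any(concepts$base_rate < 0 | concepts$base_rate > 1)) {
    abort("base_rate must lie in [0, 1]")
  }
  bad_cat <- setdiff(concepts$category, CONCEPT_CATEGORIES)
  if (length(bad_cat)) abort(sprintf("unknown category: %s", bad_cat[1]))
  rate_of <- function(id) concepts$base_rate[match(id, concepts$concept_id)]
  known <- function(id) {
    miss <- setdiff(id, concepts$concept_id)
    if (length(miss)) abort(sprintf("unknown concept in config: %s", miss[1]))
  }
  if (!is.null(links)) {
    assert_columns(links, c("parent", "child", "rate"), "links")
    known(c(links$parent, links$child))
    if (any(links$rate <= 0 | links$rate > 1)) abort("link rate must be in (0, 1]")
  }
  coupled <- dplyr::bind_rows(
    if (!is.null(planted_pairs)) {
      assert_columns(planted_pairs, c("a", "b", "joint_rate"), "planted_pairs")
      dplyr::rename(planted_pairs, p_both = "joint_rate")
    },
    if (!is.null(anticorrelated)) {
      assert_columns(anticorrelated, c("a", "b", "p_both"), "anticorrelated")
      anticorrelated
    }
  )
  if (!is.null(coupled) && nrow(coupled) > 0) {
    known(c(coupled$a, coupled$b))
    members <- c(coupled$a, coupled$b)
    if (anyDuplicated(members)) {
      abort("a concept may belong to at most one coupled pair")
    }
    pa <- rate_of(coupled$a)
    pb <- rate_of(coupled$b)
    if (any(coupled$p_both > pmin(pa, pb))) {
      abort("joint rate exceeds a member's base rate: infeasible")
    }
    if (any(pa + pb - coupled$p_both > 1)) {
      abort("pair marginals leave no probability for neither member")
    }
    if (any(!is.na(concepts$exclusive_group[match(members, concepts$concept_id)]))) {
      abort("coupled-pair members cannot be in an exclusive group")
    }
  }
  if (!is.null(hidden)) {
    assert_columns(hidden, c("a", "c", "assert_after", "n_assert_docs"), "hidden")
    known(c(hidden$a, hidden$c))
    hidden$assert_after <- as.Date(hidden$assert_after)
    if (any(hidden$assert_after >= date_end)) {
      abort("assert_after must precede date_end")
    }
  }
  structure(
    list(
      n_docs = n_docs, date_start = date_start, date_end = date_end,
      concepts = tibble::as_tibble(concepts),
      links = if (is.null(links)) NULL else tibble::as_tibble(links),
      coupled = if (is.null(coupled) || nrow(coupled) == 0) NULL else coupled,
      hidden = if (is.null(hidden)) NULL else tibble::as_tibble(hidden)
    ),
    class = "synthetic_config"
  )
}

# Thesaurus derived deterministically from concept ids: every concept gets a
# unique two-pseudoword full name; genes additionally get a symbol.
#' @noRd
synthetic_thesaurus <- function(concepts) {
  n <- nrow(concepts)
  w1 <- purrr::map_chr(seq_len(n) * 2 - 1, pseudoword, syllables = KEYWORD_SYLLABLES)
  w2 <- purrr::map_chr(seq_len(n) * 2, pseudoword, syllables = KEYWORD_SYLLABLES)
  full <- tibble::tibble(
    concept_id = concepts$concept_id,
    category = concepts$category,
    keyword_type = "full_name",
    keyword = paste(w1, w2)
  )
  genes <- concepts$category == "gene"
  symbols <- tibble::tibble(
    concept_id = concepts$concept_id[genes],
    category = "gene",
    keyword_type = "symbol",
    keyword = paste0("QZ", toupper(substr(w1[genes], 1, 2)), which(genes))
  )
  dplyr::bind_rows(full, symbols)
}

#' @noRd
random_dates <- function(n, from, to) {
  from + floor(stats::runif(n) * as.numeric(to - from))
}

# Render a keyword into text honoring the boundary contract, with seeded
# cosmetic variation (wrapping punctuation, dash for a space, plural "s").
#' @noRd
render_keyword <- function(keyword, fullname_style) {
  n <- length(keyword)
  out <- keyword
  dash <- fullname_style & stats::runif(n) < 0.25
  out[dash] <- stringr::str_replace(out[dash], " ", "-")
  plural <- fullname_style & stats::runif(n) < 0.15
  out[plural] <- paste0(out[plural], "s")
  wrap <- sample(c("plain", "paren", "comma", "colon"), n, replace = TRUE,
    prob = c(0.7, 0.1, 0.1, 0.1))
  out[wrap == "paren"] <- paste0("(", out[wrap == "paren"], ")")
  out[wrap == "comma"] <- paste0(out[wrap == "comma"], ",")
  out[wrap == "colon"] <- paste0(out[wrap == "colon"], ":")
  out
}

#' Generate a seeded synthetic corpus with ground truth
#'
#' Draws document dates and concept presences from the generative model in
#' the configuration, renders each present concept as its full-name keyword
#' embedded in filler text that honours the matching boundary contract, and
#' returns the corpus, its thesaurus and the planted ground truth. The same
#' seed always reproduces byte-identical output.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed for all randomness.
#' @return A `synthetic_corpus` list: `corpus`, `thesaurus`, `gold_mentions`
#'   (tibble `doc_id`, `concept_id`, `category`), `doc_dates`, `config`,
#'   `seed`.
#' @export
generate_corpus <- function(config, seed) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(as.integer(seed), generate_corpus_impl(config))
}

#' @noRd
generate_corpus_impl <- function(config) {
  concepts <- config$concepts
  thesaurus <- synthetic_thesaurus(concepts)
  fillers <- filler_lexicon()
  # guard: generated keywords must stay disjoint from filler and dictionary
  kw_words <- unique(unlist(strsplit(tolower(thesaurus$keyword), " ")))
  stopifnot(
    length(intersect(kw_words, fillers)) == 0,
    length(intersect(toupper(kw_words), english_words())) == 0,
    length(intersect(toupper(fillers), english_words())) == 0
  )

  n_assert <- if (is.null(config$hidden)) 0L else sum(config$hidden$n_assert_docs)
  n_total <- config$n_docs + n_assert
  dates <- random_dates(config$n_docs, config$date_start, config$date_end)

  present <- matrix(FALSE, nrow = config$n_docs, ncol = nrow(concepts),
    dimnames = list(NULL, concepts$concept_id))

  # exclusive groups: at most one member per document
  for (grp in unique(stats::na.omit(concepts$exclusive_group))) {
    members <- which(concepts$exclusive_group == grp)
    rates <- concepts$base_rate[members]
    if (sum(rates) > 1) abort("exclusive group rates sum above 1")
    pick <- findInterval(stats::runif(config$n_docs), cumsum(c(0, rates)))
    hit <- pick >= 1 & pick <= length(members)
    present[cbind(which(hit), members[pick[hit]])] <- TRUE
  }

  # coupled pairs: exact joint probability, exact marginals
  coupled_ids <- character()
  if (!is.null(config$coupled)) {
    for (k in seq_len(nrow(config$coupled))) {
      a <- config$coupled$a[k]; b <- config$coupled$b[k]
      pa <- concepts$base_rate[match(a, concepts$concept_id)]
      pb <- concepts$base_rate[match(b, concepts$concept_id)]
      pj <- config$coupled$p_both[k]
      u <- stats::runif(config$n_docs)
      present[, a] <- u < pa
      present[, b] <- u < pj | (u >= pa & u < pa + pb - pj)
      coupled_ids <- c(coupled_ids, a, b)
    }
  }

  # independent concepts
  indep <- which(
    is.na(concepts$exclusive_group) & !concepts$concept_id %in% coupled_ids
  )
  for (j in indep) {
    r <- concepts$base_rate[j]
    if (r >= 1) {
      present[, j] <- TRUE
    } else if (r > 0) {
      present[, j] <- stats::runif(config$n_docs) < r
    }
  }

  # conditional links: child joins documents containing the parent
  if (!is.null(config$links)) {
    for (k in seq_len(nrow(config$links))) {
      parent <- config$links$parent[k]
      child <- config$links$child[k]
      rate <- config$links$rate[k]
      in_parent <- which(present[, parent])
      if (length(in_parent) > 0) {
        add <- in_parent[stats::runif(length(in_parent)) < rate]
        present[add, child] <- TRUE
      }
    }
  }

  # hidden pairs: suppress chance co-mentions before the assertion date
  if (!is.null(config$hidden)) {
    for (k in seq_len(nrow(config$hidden))) {
      a <- config$hidden$a[k]; cc <- config$hidden$c[k]
      early <- dates < config$hidden$assert_after[k]
      both <- present[, a] & present[, cc] & early
      present[both, cc] <- FALSE
    }
  }

  # assertion documents: forced A-C co-mentions after the assertion date,
  # with ubiquitous concepts and links applied as in regular documents
  assert_present <- NULL
  assert_dates <- as.Date(character())
  if (n_assert > 0) {
    assert_present <- matrix(FALSE, nrow = n_assert, ncol = nrow(concepts),
      dimnames = list(NULL, concepts$concept_id))
    row0 <- 0L
    for (k in seq_len(nrow(config$hidden))) {
      nk <- config$hidden$n_assert_docs[k]
      if (nk == 0) next
      rows <- row0 + seq_len(nk)
      assert_present[rows, config$hidden$a[k]] <- TRUE
      assert_present[rows, config$hidden$c[k]] <- TRUE
      assert_dates <- c(
        assert_dates,
        random_dates(nk, config$hidden$assert_after[k], config$date_end)
      )
      row0 <- row0 + nk
    }
    assert_present[, concepts$base_rate >= 1] <- TRUE
    if (!is.null(config$links)) {
      for (k in seq_len(nrow(config$links))) {
        in_parent <- which(assert_present[, config$links$parent[k]])
        if (length(in_parent) > 0) {
          add <- in_parent[stats::runif(length(in_parent)) < config$links$rate[k]]
          assert_present[add, config$links$child[k]] <- TRUE
        }
      }
    }
    present <- rbind(present, assert_present)
    dates <- c(dates, assert_dates)
  }

  doc_ids <- sprintf("d%05d", seq_len(n_total))
  hits <- which(present, arr.ind = TRUE)
  gold <- tibble::tibble(
    doc_id = doc_ids[hits[, 1]],
    concept_id = concepts$concept_id[hits[, 2]],
    category = concepts$category[hits[, 2]]
  ) |>
    dplyr::arrange(.data$doc_id, .data$concept_id)

  # render text: full-name keyword per mention, shuffled among filler words
  full_names <- thesaurus |>
    dplyr::filter(.data$keyword_type == "full_name")
  gold_kw <- gold |>
    dplyr::mutate(
      keyword = full_names$keyword[match(.data$concept_id, full_names$concept_id)],
      rendered = render_keyword(.data$keyword, fullname_style = TRUE)
    )
  kw_by_doc <- split(gold_kw$rendered, factor(gold_kw$doc_id, levels = doc_ids))
  n_fill <- 4 + floor(stats::runif(n_total) * 6)
  bodies <- purrr::map_chr(seq_len(n_total), function(i) {
    tokens <- c(
      kw_by_doc[[i]],
      sample(fillers, n_fill[i], replace = TRUE)
    )
    paste(sample(tokens), collapse = " ")
  })
  titles <- purrr::map_chr(seq_len(n_total), function(i) {
    paste(sample(fillers, 2, replace = TRUE), collapse = " ")
  })

  corpus <- tibble::tibble(
    doc_id = doc_ids,
    year = as.integer(lubridate::year(dates)),
    month = as.integer(lubridate::month(dates)),
    day = as.integer(lubridate::day(dates)),
    title = titles,
    body = bodies,
    substances = ""
  )
  structure(
    list(
      corpus = corpus,
      thesaurus = thesaurus,
      gold_mentions = gold,
      doc_dates = tibble::tibble(
        doc_id = doc_ids, year = corpus$year, date = dates
      ),
      config = config
    ),
    class = "synthetic_corpus"
  )
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  cat(sprintf(
    "<synthetic_corpus> %d document(s), %d concept(s), %d planted mention(s)\n",
    nrow(x$corpus), nrow(x$config$concepts), nrow(x$gold_mentions)
  ))
  invisible(x)
}

#' Gold-standard concordance of a synthetic corpus
#'
#' Builds the mention index the tagger is expected to reproduce exactly,
#' straight from the planted ground truth.
#'
#' @param gen A `synthetic_corpus` from [generate_corpus()].
#' @return A `mention_index`.
#' @export
make_gold_concordance <- function(gen) {
  stopifnot(inherits(gen, "synthetic_corpus"))
  mentions <- gen$gold_mentions |>
    dplyr::left_join(gen$doc_dates, by = "doc_id") |>
    dplyr::arrange(.data$doc_id, .data$concept_id)
  new_mention_index(
    mentions,
    gen$doc_dates,
    dplyr::distinct(gen$config$concepts[, c("concept_id", "category")])
  )
}

#' Ambiguity fixture for the symbol-disambiguation rule
#'
#' Generates a small corpus that exercises gene-symbol disambiguation: a
#' gene with a symbol and a full name appears (i) as a bare symbol with no
#' full-name evidence (must be discarded), (ii) as a symbol next to one
#' full-name word (must be retained), (iii) as its full name (retained,
#' check not applicable), and (iv) as a lone full-name word without the
#' symbol (no hit at all). The gold mentions encode the expected outcome.
#'
#' @param n_per_mode Documents per mode.
#' @param seed Integer seed.
#' @param year Publication year for all documents.
#' @return A `synthetic_corpus`-like list with `corpus`, `thesaurus`,
#'   `gold_mentions`, `doc_dates`.
#' @export
ambiguity_fixture <- function(n_per_mode = 5, seed = 1, year = 1999) {
  withr::with_seed(as.integer(seed), {
    thesaurus <- tibble::tibble(
      concept_id = "G1",
      category = "gene",
      keyword_type = c("full_name", "symbol"),
      keyword = c("brakel mordin receptor", "QZBR9")
    )
    fillers <- filler_lexicon()
    modes <- rep(c("symbol_only", "symbol_plus_word", "full_name", "word_only"),
      each = n_per_mode)
    n <- length(modes)
    bodies <- purrr::map_chr(modes, function(mode) {
      fill <- sample(fillers, 5, replace = TRUE)
      tokens <- switch(mode,
        symbol_only = c("QZBR9", fill),
        symbol_plus_word = c("QZBR9", "mordin", fill),
        full_name = c("brakel mordin receptor", fill),
        word_only = c("mordin", fill)
      )
      paste(sample(tokens), collapse = " ")
    })
    doc_ids <- sprintf("amb%03d", seq_len(n))
    corpus <- tibble::tibble(
      doc_id = doc_ids, year = as.integer(year),
      month = NA_integer_, day = NA_integer_,
      title = purrr::map_chr(seq_len(n), ~ paste(sample(fillers, 2), collapse = " ")),
      body = bodies, substances = ""
    )
    expected <- modes %in% c("symbol_plus_word", "full_name")
    gold <- tibble::tibble(
      doc_id = doc_ids[expected], concept_id = "G1", category = "gene"
    )
    dates <- doc_date(corpus$year)
    list(
      corpus = corpus,
      thesaurus = thesaurus,
      gold_mentions = gold,
      doc_dates = tibble::tibble(doc_id = doc_ids, year = corpus$year, date = dates),
      modes = modes
    )
  })
}
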