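#' Read a Medline-dialect XML corpus
#'
#' Parses a constrained Medline-style XML file into a corpus tibble. The
#' dialect expects one `<Citation>` element per document containing `<PMID>`,
#' `<ArticleTitle>`, `<AbstractText>`, `<PubDate>` (with `<Year>` and optional
#' `<Month>`/`<Day>`) and an optional `<ChemicalList>` whose
#' `<NameOfSubstance>` children are collected as substance terms.
#'
#' Citations without an abstract are kept with an empty `body`. Citations
#' without a PMID are skipped with a warning reporting how many were dropped;
#' duplicated PMIDs keep the first record seen and drop the rest, again with
#' a warning.
#'
#' @param path Path to the XML file.
#' @return A corpus tibble with columns `doc_id`, `year`, `month`, `day`,
#'   `title`, `body`, `substances` (substance terms joined by `"|"`).
#' @seealso [read_corpus_tsv()] for the plain-text equivalent.
#' @export
read_medline_xml <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  doc <- xml2::read_xml(path)
  cites <- xml2::xml_find_all(doc, ".//Citation")

  field <- function(node, xpath) {
    val <- xml2::xml_text(xml2::xml_find_first(node, xpath))
    ifelse(is.na(val), "", val)
  }
  records <- purrr::map(cites, function(node) {
    subs <- xml2::xml_text(
      xml2::xml_find_all(node, ".//ChemicalList/Chemical/NameOfSubstance")
    )
    month <- field(node, ".//PubDate/Month")
    day <- field(node, ".//PubDate/Day")
    tibble::tibble(
      doc_id = field(node, ".//PMID"),
      year = suppressWarnings(as.integer(field(node, ".//PubDate/Year"))),
      month = suppressWarnings(if (nzchar(month)) as.integer(month) else NA_integer_),
      day = suppressWarnings(if (nzchar(day)) as.integer(day) else NA_integer_),
      title = field(node, ".//ArticleTitle"),
      body = field(node, ".//AbstractText"),
      substances = paste(subs, collapse = "|")
    )
  })
  corpus <- dplyr::bind_rows(records)
  if (nrow(corpus) == 0) {
    corpus <- tibble::tibble(
      doc_id = character(), year = integer(), month = integer(),
      day = integer(), title = character(), body = character(),
      substances = character()
    )
  }
  n_missing <- sum(!nzchar(corpus$doc_id))
  if (n_missing > 0) {
    warn(sprintf("skipped %d citation(s) lacking a PMID", n_missing))
    corpus <- dplyr::filter(corpus, nzchar(.data$doc_id))
  }
  validate_corpus(corpus)
}

#' Read a corpus from TSV
#'
#' Reads a tab-separated corpus with header columns `doc_id`, `year`,
#' `title`, `body`, `substances` (substance terms joined by `"|"`). This is
#' the test-friendly plain-text equivalent of [read_medline_xml()]: the same
#' content read through either format yields identical downstream results.
#'
#' @param path Path to the TSV file.
#' @return A corpus tibble (see [read_medline_xml()] for columns); `month`
#'   and `day` are `NA` since the TSV carries year precision only.
#' @export
read_corpus_tsv <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  header <- strsplit(readr::read_lines(path, n_max = 1), "\t")[[1]]
  assert_columns(
    stats::setNames(data.frame(matrix(ncol = length(header), nrow = 0)), header),
    c("doc_id", "year", "title", "body", "substances"), "corpus TSV"
  )
  corpus <- readr::read_tsv(
    path,
    col_types = readr::cols(
      doc_id = readr::col_character(),
      year = readr::col_integer(),
      title = readr::col_character(),
      body = readr::col_character(),
      substances = readr::col_character()
    )
  )
  assert_columns(corpus, c("doc_id", "year", "title", "body", "substances"),
    "corpus TSV")
  corpus <- dplyr::mutate(
    corpus,
    dplyr::across(c("title", "body", "substances"), ~ dplyr::coalesce(.x, "")),
    month = NA_integer_, day = NA_integer_
  )
  validate_corpus(corpus[, c("doc_id", "year", "month", "day", "title",
    "body", "substances")])
}

#' Write a corpus to TSV
#'
#' Writes the year-precision TSV encoding read back by [read_corpus_tsv()].
#' Month/day precision, when present, is not representable in this format
#' and is dropped.
#'
#' @param corpus A corpus tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_corpus_tsv <- function(corpus, path) {
  corpus <- validate_corpus(corpus)
  readr::write_tsv(
    corpus[, c("doc_id", "year", "title", "body", "substances")],
    path
  )
  invisible(path)
}

#' @noRd
validate_corpus <- function(corpus) {
  assert_columns(corpus, c("doc_id", "year", "title", "body", "substances"),
    "corpus")
  if (!"month" %in% names(corpus)) corpus$month <- NA_integer_
  if (!"day" %in% names(corpus)) corpus$day <- NA_integer_
  if (nrow(corpus) == 0) return(tibble::as_tibble(corpus))
  if (any(!nzchar(corpus$doc_id))) abort("corpus contains empty doc_id")
  dup <- duplicated(corpus$doc_id)
  if (any(dup)) {
    warn(sprintf(
      "corpus contains %d duplicated doc_id(s); keeping first occurrence",
      sum(dup)
    ))
    corpus <- corpus[!dup, ]
  }
  check_year(corpus$year, corpus$doc_id)
  tibble::as_tibble(corpus)
}

#' Read a keyword thesaurus
#'
#' Reads a tab-separated thesaurus with header columns `concept_id`,
#' `category`, `keyword_type`, `keyword`: one keyword per row, grouped into
#' concepts by `concept_id`. Categories must come from the closed six-category
#' set (`gene`, `disease`, `drug`, `pathway`, `biological_process`,
#' `liver_pathology`) and keyword types from `full_name`/`symbol`/`alias`.
#'
#' @param path Path to the TSV file.
#' @return A thesaurus tibble with the four columns above.
#' @export
read_thesaurus <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  th <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character())
  )
  assert_columns(th, c("concept_id", "category", "keyword_type", "keyword"),
    "thesaurus TSV")
  validate_thesaurus(th)
}

#' Write a keyword thesaurus to TSV
#'
#' @param thesaurus A thesaurus tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_thesaurus <- function(thesaurus, path) {
  thesaurus <- validate_thesaurus(thesaurus)
  readr::write_tsv(
    thesaurus[, c("concept_id", "category", "keyword_type", "keyword")],
    path
  )
  invisible(path)
}

#' @noRd
validate_thesaurus <- function(th) {
  assert_columns(th, c("concept_id", "category", "keyword_type", "keyword"),
    "thesaurus")
  bad_cat <- setdiff(unique(th$category), CONCEPT_CATEGORIES)
  if (length(bad_cat) > 0) {
    abort(sprintf(
      "unknown thesaurus category: %s (must be one of %s)",
      paste(bad_cat, collapse = ", "), paste(CONCEPT_CATEGORIES, collapse = ", ")
    ))
  }
  bad_type <- setdiff(unique(th$keyword_type), KEYWORD_TYPES)
  if (length(bad_type) > 0) {
    abort(sprintf("unknown keyword_type: %s", paste(bad_type, collapse = ", ")))
  }
  multi_cat <- th |>
    dplyr::distinct(.data$concept_id, .data$category) |>
    dplyr::count(.data$concept_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(multi_cat) > 0) {
    abort(sprintf(
      "concept(s) with more than one category: %s",
      paste(multi_cat$concept_id, collapse = ", ")
    ))
  }
  empty <- !nzchar(trimws(th$keyword))
  if (any(empty)) abort("thesaurus contains empty keyword(s)")
  tibble::as_tibble(th)
}
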