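# Boundary characters allowed before/after a keyword occurrence, plus the
# string boundary itself.
BOUNDARY_CLASS <- "[\\]\\[.)(,:; -]"

# Function words never accepted as disambiguating full-name evidence.
DISAMBIG_STOPWORDS <- c(
  "with", "from", "into", "onto", "over", "under", "this", "that", "then",
  "than", "when", "where", "which", "whose", "type", "like"
)

#' Compile a keyword into a boundary-aware match pattern
#'
#' Builds the regular expression implementing the matching contract: the
#' character before and after the keyword must be one of `] [ . - ) ( , : ;`
#' or a space or the string boundary; an optional trailing "s" absorbs simple
#' plurals; and for full-name-style keywords every internal space also
#' matches a dash. Full names and all non-gene keywords match
#' case-insensitively; gene symbols and aliases match case-sensitively and,
#' by default, without the plural "s".
#'
#' @param keyword Cleaned (normalized) keyword text.
#' @param keyword_type One of `"full_name"`, `"symbol"`, `"alias"`.
#' @param category Concept category; gene symbols/aliases get the stricter
#'   symbol treatment.
#' @param symbol_plural Allow the optional trailing "s" on gene symbols too
#'   (off by default).
#' @return A one-row tibble with columns `keyword`, `keyword_type`,
#'   `pattern`, `ignore_case`.
#' @examples
#' p <- compile_pattern("cell death 1", "full_name", "gene")
#' stringr::str_detect("a role of cell-death 1 in x", stringr::regex(p$pattern))
#' @export
compile_pattern <- function(keyword, keyword_type = "full_name",
                            category = "gene", symbol_plural = FALSE) {
  keyword_type <- match.arg(keyword_type, KEYWORD_TYPES)
  symbol_style <- category == "gene" && keyword_type %in% c("symbol", "alias")
  escaped <- stringr::str_split_1(keyword, stringr::fixed(" ")) |>
    purrr::map_chr(escape_regex)
  body <- if (symbol_style) {
    paste(escaped, collapse = " ")
  } else {
    # internal whitespace may appear as whitespace or a dash in running text
    paste(escaped, collapse = "[ -]")
  }
  plural <- if (!symbol_style || symbol_plural) "s?" else ""
  pattern <- paste0(
    "(?:^|", BOUNDARY_CLASS, ")", body, plural, "(?=$|", BOUNDARY_CLASS, ")"
  )
  tibble::tibble(
    keyword = keyword,
    keyword_type = keyword_type,
    pattern = pattern,
    ignore_case = !symbol_style
  )
}

#' @noRd
escape_regex <- function(x) {
  stringr::str_replace_all(x, "([\\\\.^$|()\\[\\]{}*+?])", "\\\\\\1")
}

#' Compile all usable keywords of a cleaned thesaurus
#'
#' @param cleaned A cleaned thesaurus from [clean_thesaurus()] (a raw
#'   thesaurus is cleaned on the fly with the default dictionary).
#' @param symbol_plural Passed to [compile_pattern()].
#' @return A pattern tibble with one row per usable keyword: `concept_id`,
#'   `category`, `keyword_type`, `keyword` (normalized), `pattern`,
#'   `ignore_case`.
#' @export
compile_patterns <- function(cleaned, symbol_plural = FALSE) {
  if (!"dropped" %in% names(cleaned)) cleaned <- clean_thesaurus(cleaned)
  usable <- dplyr::filter(cleaned, .data$dropped == "none")
  if (nrow(usable) == 0) abort("no usable keywords in thesaurus")
  pats <- purrr::pmap(
    list(usable$normalized, usable$keyword_type, usable$category),
    function(kw, kt, cat) compile_pattern(kw, kt, cat, symbol_plural)
  ) |>
    dplyr::bind_rows()
  tibble::tibble(
    concept_id = usable$concept_id,
    category = usable$category,
    keyword_type = usable$keyword_type,
    keyword = pats$keyword,
    pattern = pats$pattern,
    ignore_case = pats$ignore_case
  )
}

#' @noRd
searchable_text <- function(corpus) {
  # title + body + substances joined by single spaces; the "|" separator of
  # the substances field becomes a space so each term stands alone
  stringr::str_squish(paste(
    corpus$title, corpus$body,
    stringr::str_replace_all(corpus$substances, stringr::fixed("|"), " ")
  ))
}

#' Tag a single document
#'
#' Matches every compiled pattern against a document's searchable text
#' (title + body + substances) and returns the deduplicated concept hits.
#' Gene-symbol disambiguation is a separate step; see
#' [disambiguate_symbol_hits()].
#'
#' @param doc A one-row corpus tibble.
#' @param patterns A pattern tibble from [compile_patterns()].
#' @return A tibble with distinct `concept_id`, `keyword_type` hits.
#' @export
tag_document <- function(doc, patterns) {
  stopifnot(nrow(doc) == 1)
  text <- searchable_text(doc)
  hit <- purrr::map2_lgl(
    patterns$pattern, patterns$ignore_case,
    function(p, ic) stringr::str_detect(text, stringr::regex(p, ignore_case = ic))
  )
  dplyr::distinct(
    patterns[hit, c("concept_id", "keyword_type")]
  )
}

#' Words of a concept's full name usable as disambiguation evidence
#'
#' @noRd
fullname_evidence_words <- function(cleaned, min_word_len = 4) {
  cleaned |>
    dplyr::filter(
      .data$keyword_type == "full_name", .data$dropped == "none"
    ) |>
    dplyr::mutate(word = stringr::str_split(tolower(.data$normalized), " ")) |>
    tidyr::unnest("word") |>
    dplyr::filter(
      nchar(.data$word) >= min_word_len,
      !.data$word %in% DISAMBIG_STOPWORDS,
      !stringr::str_detect(.data$word, "^[0-9]+$")
    ) |>
    dplyr::distinct(.data$concept_id, .data$word)
}

#' Disambiguate gene-symbol hits with full-name evidence
#'
#' A gene hit supported only by symbol/alias matches is kept only when at
#' least one qualifying word of that gene's full name (length >= 4,
#' stopwords and numerals excluded) also occurs in the document text under
#' the boundary contract; otherwise the symbol hit is discarded as
#' ambiguous. Hits supported by a full-name match, non-gene hits, and genes
#' without any full name on record bypass the check.
#'
#' @param doc A one-row corpus tibble.
#' @param hits Hits for this document from [tag_document()].
#' @param cleaned The cleaned thesaurus the patterns came from.
#' @param min_word_len Minimum length of a qualifying full-name word.
#' @return The hits tibble restricted to retained concepts.
#' @export
disambiguate_symbol_hits <- function(doc, hits, cleaned, min_word_len = 4) {
  categories <- dplyr::distinct(cleaned, .data$concept_id, .data$category)
  per_concept <- hits |>
    dplyr::left_join(categories, by = "concept_id") |>
    dplyr::group_by(.data$concept_id, .data$category) |>
    dplyr::summarise(
      symbol_only = !any(.data$keyword_type == "full_name"), .groups = "drop"
    )
  suspect <- per_concept$concept_id[
    per_concept$symbol_only & per_concept$category == "gene"
  ]
  if (length(suspect) == 0) return(hits)
  evidence <- fullname_evidence_words(
    dplyr::filter(cleaned, .data$concept_id %in% suspect), min_word_len
  )
  text <- searchable_text(doc)
  has_word <- function(word) {
    p <- compile_pattern(word, "full_name", "gene")
    stringr::str_detect(text, stringr::regex(p$pattern, ignore_case = TRUE))
  }
  supported <- evidence |>
    dplyr::mutate(present = purrr::map_lgl(.data$word, has_word)) |>
    dplyr::group_by(.data$concept_id) |>
    dplyr::summarise(ok = any(.data$present), .groups = "drop")
  # symbol-only genes with a full name but no supporting word are discarded;
  # genes with no full name at all have no evidence to check and are kept
  discard <- supported$concept_id[!supported$ok]
  dplyr::filter(hits, !.data$concept_id %in% discard)
}

#' Build the document-concept concordance of a corpus
#'
#' Runs every usable thesaurus keyword over every document, makes the hits
#' non-redundant at the concept level, applies gene-symbol disambiguation,
#' and returns the mention index linking documents to the concepts they
#' mention, with publication dates carried along.
#'
#' @param corpus A corpus tibble.
#' @param thesaurus A thesaurus tibble (raw or cleaned).
#' @param dictionary English word set used if the thesaurus still needs
#'   cleaning.
#' @param symbol_plural Passed to [compile_patterns()].
#' @param min_word_len Passed to the disambiguation step.
#' @return A `mention_index`: a list with `mentions` (tibble `doc_id`,
#'   `concept_id`, `category`, `year`, `date`), `doc_dates` (tibble of all
#'   corpus documents with dates), `n_docs` and `concepts` (tibble
#'   `concept_id`, `category`).
#' @export
build_concordance <- function(corpus, thesaurus,
                              dictionary = english_words(),
                              symbol_plural = FALSE, min_word_len = 4) {
  corpus <- validate_corpus(corpus)
  if (nrow(thesaurus) == 0) abort("empty thesaurus")
  if (!"dropped" %in% names(thesaurus)) {
    thesaurus <- clean_thesaurus(thesaurus, dictionary)
  }
  patterns <- compile_patterns(thesaurus, symbol_plural)
  texts <- searchable_text(corpus)

  # vectorised over documents, one pass per pattern
  hit_rows <- purrr::pmap(
    list(
      patterns$pattern, patterns$ignore_case,
      patterns$concept_id, patterns$keyword_type
    ),
    function(p, ic, cid, kt) {
      idx <- which(stringr::str_detect(texts, stringr::regex(p, ignore_case = ic)))
      if (length(idx) == 0) return(NULL)
      tibble::tibble(doc_id = corpus$doc_id[idx], concept_id = cid,
        keyword_type = kt)
    }
  ) |>
    dplyr::bind_rows()

  categories <- dplyr::distinct(thesaurus, .data$concept_id, .data$category)

  if (nrow(hit_rows) > 0) {
    hit_rows <- dplyr::distinct(hit_rows)
    # disambiguation: gene concepts supported only by symbol/alias hits in a
    # document need a full-name word in that document's text
    status <- hit_rows |>
      dplyr::left_join(categories, by = "concept_id") |>
      dplyr::group_by(.data$doc_id, .data$concept_id, .data$category) |>
      dplyr::summarise(
        symbol_only = !any(.data$keyword_type == "full_name"), .groups = "drop"
      )
    suspect <- dplyr::filter(
      status, .data$symbol_only, .data$category == "gene"
    )
    keep <- dplyr::anti_join(
      status, suspect, by = c("doc_id", "concept_id")
    )
    if (nrow(suspect) > 0) {
      evidence <- fullname_evidence_words(
        dplyr::filter(thesaurus, .data$concept_id %in% unique(suspect$concept_id)),
        min_word_len
      )
      word_patterns <- evidence |>
        dplyr::distinct(.data$word) |>
        dplyr::mutate(
          pattern = purrr::map_chr(
            .data$word, ~ compile_pattern(.x, "full_name", "gene")$pattern
          )
        )
      doc_pos <- match(suspect$doc_id, corpus$doc_id)
      word_in_doc <- word_patterns |>
        dplyr::mutate(
          docs = purrr::map(.data$pattern, function(p) {
            corpus$doc_id[
              stringr::str_detect(texts, stringr::regex(p, ignore_case = TRUE))
            ]
          })
        ) |>
        dplyr::select("word", "docs") |>
        tidyr::unnest("docs") |>
        dplyr::rename(doc_id = "docs")
      retained <- suspect |>
        dplyr::inner_join(evidence, by = "concept_id",
          relationship = "many-to-many") |>
        dplyr::semi_join(word_in_doc, by = c("doc_id", "word")) |>
        dplyr::distinct(.data$doc_id, .data$concept_id, .data$category,
          .data$symbol_only)
      # genes without any usable full name cannot be checked and are kept
      no_fullname <- dplyr::anti_join(
        suspect, dplyr::distinct(evidence, .data$concept_id), by = "concept_id"
      )
      keep <- dplyr::bind_rows(keep, retained, no_fullname)
    }
    mentions <- keep |>
      dplyr::select("doc_id", "concept_id", "category") |>
      dplyr::distinct()
  } else {
    mentions <- tibble::tibble(
      doc_id = character(), concept_id = character(), category = character()
    )
  }

  doc_dates <- tibble::tibble(
    doc_id = corpus$doc_id,
    year = corpus$year,
    date = doc_date(corpus$year, corpus$month, corpus$day)
  )
  mentions <- mentions |>
    dplyr::left_join(doc_dates, by = "doc_id") |>
    dplyr::arrange(.data$doc_id, .data$concept_id)

  new_mention_index(mentions, doc_dates, categories)
}

#' @noRd
new_mention_index <- function(mentions, doc_dates, concepts) {
  structure(
    list(
      mentions = tibble::as_tibble(mentions),
      doc_dates = tibble::as_tibble(doc_dates),
      concepts = tibble::as_tibble(concepts),
      n_docs = nrow(doc_dates)
    ),
    class = "mention_index"
  )
}

#' @export
print.mention_index <- function(x, ...) {
  cat(sprintf(
    "<mention_index> %d mention(s) of %d concept(s) in %d document(s)\n",
    nrow(x$mentions), dplyr::n_distinct(x$mentions$concept_id), x$n_docs
  ))
  print(x$mentions, n = 5)
  invisible(x)
}

#' Tidy a mention index into its mention table
#'
#' @param x A `mention_index`.
#' @param ... Unused.
#' @return The mentions tibble (`doc_id`, `concept_id`, `category`, `year`,
#'   `date`).
#' @method tidy mention_index
#' @export
tidy.mention_index <- function(x, ...) x$mentions

#' Write a concordance to TSV
#'
#' @param index A `mention_index`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_concordance_tsv <- function(index, path) {
  readr::write_tsv(
    index$mentions[, c("doc_id", "concept_id", "category", "year")], path
  )
  invisible(path)
}
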