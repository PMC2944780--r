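#' Normalize a full concept name into a searchable phrase
#'
#' Full gene names as curated in nomenclature resources are poor direct
#' search terms: they carry parenthesized qualifiers and inverted comma
#' phrases ("receptor, insulin"). Normalization deletes every parenthesized
#' span (innermost-first, so nesting resolves deterministically), replaces
#' each comma with a single space, collapses whitespace runs and trims.
#'
#' @param name Character vector of full names.
#' @return Character vector of normalized phrases; an empty string marks a
#'   name with no searchable text left.
#' @examples
#' normalize_full_name("programmed cell death 1 (PDCD1)")
#' normalize_full_name("receptor, insulin")
#' @export
normalize_full_name <- function(name) {
  out <- name
  # innermost-to-outermost removal until no parenthesized span remains
  repeat {
    nxt <- stringr::str_remove_all(out, "\\([^()]*\\)")
    if (identical(nxt, out)) break
    out <- nxt
  }
  # orphan parentheses (unbalanced input) are stripped as well
  out <- stringr::str_remove_all(out, "[()]")
  out <- stringr::str_replace_all(out, ",", " ")
  stringr::str_squish(out)
}

#' Load the pinned English word list
#'
#' Returns the common-English lexicon shipped with the package, used to drop
#' gene symbols that collide with ordinary words ("AND", "CELL", ...). The
#' list is uppercase-normalized; membership tests are case-insensitive.
#'
#' @param path Optional path to an alternative dictionary file (one word per
#'   line, UTF-8).
#' @return Character vector of uppercase words.
#' @export
english_words <- function(path = NULL) {
  path <- path %||%
    system.file("extdata", "english_words.txt", package = "litdisc")
  if (!nzchar(path) || !file.exists(path)) {
    abort("English dictionary file not found")
  }
  words <- readr::read_lines(path)
  toupper(words[nzchar(words)])
}

#' Filter gene symbols against length and dictionary rules
#'
#' Two-letter symbols are ambiguous beyond repair (element names, initials,
#' statistical abbreviations) and are dropped outright; longer symbols whose
#' uppercase form is a common English word are dropped as well. All other
#' symbols are retained. The filter is idempotent.
#'
#' @param symbols Character vector of gene symbols or aliases.
#' @param dictionary Uppercase word set, see [english_words()].
#' @param keyword_type Keyword type recorded in the result (`"symbol"` or
#'   `"alias"`).
#' @return A tibble with columns `original`, `normalized`, `keyword_type`,
#'   `dropped` (one of `none`, `two_letter`, `english_word`,
#'   `empty_after_normalization`).
#' @export
filter_symbols <- function(symbols, dictionary = english_words(),
                           keyword_type = "symbol") {
  keyword_type <- match.arg(keyword_type, c("symbol", "alias"))
  normalized <- stringr::str_squish(symbols)
  dropped <- dplyr::case_when(
    !nzchar(normalized) ~ "empty_after_normalization",
    nchar(normalized) == 2 ~ "two_letter",
    toupper(normalized) %in% dictionary ~ "english_word",
    .default = "none"
  )
  tibble::tibble(
    original = symbols,
    normalized = normalized,
    keyword_type = keyword_type,
    dropped = dropped
  )
}

#' Clean a thesaurus for matching
#'
#' Applies the keyword-cleaning rules to a raw thesaurus: full names are
#' normalized with [normalize_full_name()]; gene symbols and aliases pass
#' through [filter_symbols()] (two-letter and common-English symbols are
#' removed). Non-gene keywords are whitespace-normalized only — the
#' dictionary filter targets gene symbol ambiguity specifically.
#'
#' @param thesaurus A thesaurus tibble (`concept_id`, `category`,
#'   `keyword_type`, `keyword`).
#' @param dictionary Uppercase English word set.
#' @return A cleaned-thesaurus tibble with columns `concept_id`, `category`,
#'   `keyword_type`, `keyword` (the original text), `normalized`, `dropped`.
#'   Rows with `dropped != "none"` take no part in matching. Concepts left
#'   with zero usable keywords trigger a warning.
#' @export
clean_thesaurus <- function(thesaurus, dictionary = english_words()) {
  thesaurus <- validate_thesaurus(thesaurus)
  cleaned <- thesaurus |>
    dplyr::mutate(
      is_gene_symbol = .data$category == "gene" &
        .data$keyword_type %in% c("symbol", "alias"),
      normalized = dplyr::if_else(
        .data$keyword_type == "full_name",
        normalize_full_name(.data$keyword),
        stringr::str_squish(.data$keyword)
      ),
      dropped = dplyr::case_when(
        !nzchar(.data$normalized) ~ "empty_after_normalization",
        .data$is_gene_symbol & nchar(.data$normalized) == 2 ~ "two_letter",
        .data$is_gene_symbol & toupper(.data$normalized) %in% dictionary ~
          "english_word",
        .default = "none"
      )
    ) |>
    dplyr::select(-"is_gene_symbol")
  lost <- cleaned |>
    dplyr::group_by(.data$concept_id) |>
    dplyr::summarise(usable = sum(.data$dropped == "none"), .groups = "drop") |>
    dplyr::filter(.data$usable == 0)
  if (nrow(lost) > 0) {
    warn(sprintf(
      "%d concept(s) have no usable keywords after cleaning: %s",
      nrow(lost), paste(utils::head(lost$concept_id, 5), collapse = ", ")
    ))
  }
  cleaned
}
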