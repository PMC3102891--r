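# Lexical mapping: normalize preferred names, index them, and emit exact
# cross-ontology matches.

#' Normalize a preferred-name label for matching
#'
#' Case-folds to lower case and removes every character that is not a letter
#' or digit (spaces, underscores, hyphens, parentheses, punctuation —
#' delimiters of any kind). Non-ASCII letters are case-folded and retained;
#' combining marks count as delimiters. Idempotent.
#'
#' @param label Character vector; may be empty strings.
#' @return Character vector of normalized labels.
#' @examples
#' normalize_label("Biological_Process")  # "biologicalprocess"
#' normalize_label("T-cell (mature)")     # "tcellmature"
#' @export
normalize_label <- function(label) {
  stringr::str_remove_all(stringr::str_to_lower(label), "[^\\p{L}\\p{N}]")
}

#' Build the corpus-wide label index
#'
#' One entry per indexable term: non-obsolete (unless the corpus was loaded
#' with `include_obsolete = TRUE`) and with a non-empty preferred name.
#' Entries whose normalized label is shorter than three characters are kept
#' in the index but flagged ineligible for matching — very short strings
#' produce spurious matches.
#'
#' @param corpus An `ortho_corpus` from [load_corpus()].
#' @param min_chars Minimum normalized-label length for match eligibility.
#' @return A tibble with columns `ontology_key`, `term_id`,
#'   `original_label`, `normalized_label`, `eligible`.
#' @export
build_label_index <- function(corpus, min_chars = 3L) {
  terms <- corpus$terms
  if (!isTRUE(corpus$include_obsolete)) {
    terms <- terms[!terms$is_obsolete, ]
  }
  terms <- terms[nzchar(terms$preferred_name), ]
  idx <- tibble(
    ontology_key = terms$ontology_key,
    term_id = terms$term_id,
    original_label = terms$preferred_name,
    normalized_label = normalize_label(terms$preferred_name)
  )
  idx$eligible <- nchar(idx$normalized_label) >= min_chars
  idx
}

#' Find exact cross-ontology lexical mappings
#'
#' Emits one canonical mapping per unordered cross-ontology term pair whose
#' eligible normalized labels are equal. Within-ontology matches are never
#' emitted. A term matching k terms across other ontologies yields k
#' mappings. Side A of each mapping precedes side B in
#' (ontology_key, term_id) lexicographic order, and the mapping set is
#' sorted, so output is invariant under permutation of the input.
#'
#' @param index Label index from [build_label_index()].
#' @return A tibble with columns `ont_a`, `term_a`, `ont_b`, `term_b`,
#'   `normalized_label`.
#' @export
find_mappings <- function(index) {
  e <- index[index$eligible, c("ontology_key", "term_id", "normalized_label")]
  empty <- tibble(ont_a = character(), term_a = character(),
                  ont_b = character(), term_b = character(),
                  normalized_label = character())
  if (nrow(e) == 0L) return(empty)
  # restrict to labels seen in >1 ontology before the self-join
  keep <- e |>
    distinct(.data$normalized_label, .data$ontology_key) |>
    count(.data$normalized_label) |>
    filter(.data$n > 1L)
  e <- e[e$normalized_label %in% keep$normalized_label, ]
  if (nrow(e) == 0L) return(empty)
  m <- inner_join(e, e, by = "normalized_label", suffix = c("_a", "_b"),
                  relationship = "many-to-many")
  m <- m[m$ontology_key_a < m$ontology_key_b, ]
  out <- tibble(ont_a = m$ontology_key_a, term_a = m$term_id_a,
                ont_b = m$ontology_key_b, term_b = m$term_id_b,
                normalized_label = m$normalized_label)
  out <- distinct(out)
  out[radix_order(out$ont_a, out$term_a, out$ont_b, out$term_b), ]
}

#' Export or import the label index and mapping set as TSV
#'
#' @param index,mappings Tibbles as produced by [build_label_index()] and
#'   [find_mappings()].
#' @param path File path.
#' @name mapping_io
#' @export
write_label_index <- function(index, path) {
  utils::write.table(index, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname mapping_io
#' @export
read_label_index <- function(path) {
  df <- utils::read.delim(path, sep = "\t", quote = "",
                          colClasses = c("character", "character",
                                         "character", "character",
                                         "logical"),
                          fileEncoding = "UTF-8")
  as_tibble(df)
}

#' @rdname mapping_io
#' @export
write_mappings <- function(mappings, path) {
  utils::write.table(mappings, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname mapping_io
#' @export
read_mappings <- function(path) {
  as_tibble(utils::read.delim(path, sep = "\t", quote = "",
                              colClasses = "character",
                              fileEncoding = "UTF-8"))
}
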