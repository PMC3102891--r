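# Partition the mapping set into explicit term reuse (three cases) and
# overlap.
#
# Reuse cases, in precedence order:
#   SAME_ID     — the two terms carry the same id.
#   INTENDED_ID — the ids differ as written but were clearly intended to be
#                 the same (doubled prefix like MP:MP_0002216, retired or
#                 alias prefixes such as span:/snap: for bfo, underscore for
#                 colon).
#   XREF        — one term cross-references the other's id via xref.
# Everything else with a matching name is OVERLAP: independent definition.

#' Identifier alias configuration
#'
#' Tables driving [canonicalize_id()]: alternate prefixes that denote the
#' same ontology (the Basic Formal Ontology historically used `span:`,
#' `snap:` and `bfo`), prefixes that were retired and replaced, and the set
#' of id prefixes known to belong to corpus ontologies (used to recognize
#' doubled-prefix malformations without mangling ordinary underscored ids).
#'
#' @param prefix_aliases Named character vector, alternate prefix ->
#'   canonical prefix. Default maps `span` and `snap` to `bfo`.
#' @param retired_prefixes Named character vector, old prefix -> current
#'   prefix.
#' @param known_prefixes Character vector of prefixes owned by corpus
#'   ontologies. [classify_mappings()] fills this from the corpus
#'   automatically.
#' @return A list of class `alias_config`.
#' @export
alias_config <- function(prefix_aliases = c(span = "bfo", snap = "bfo"),
                         retired_prefixes = character(),
                         known_prefixes = character()) {
  stopifnot(is.character(prefix_aliases), is.character(retired_prefixes),
            is.character(known_prefixes))
  combined <- c(retired_prefixes, prefix_aliases)
  if (length(combined)) {
    names(combined) <- tolower(names(combined))
    # alias resolution must terminate: follow each chain with a step cap
    lookup <- function(key) {
      if (key %in% names(combined)) unname(combined[[key]]) else NA_character_
    }
    for (p in names(combined)) {
      cur <- p
      for (step in seq_len(length(combined) + 1L)) {
        nxt <- lookup(cur)
        if (is.na(nxt) || tolower(nxt) == cur) break
        cur <- tolower(nxt)
        if (identical(cur, p)) stop("alias cycle involving prefix '", p, "'")
      }
      nxt <- lookup(cur)
      if (!is.na(nxt) && tolower(nxt) != cur) {
        stop("alias chain for prefix '", p, "' does not terminate")
      }
    }
  }
  structure(list(prefix_aliases = prefix_aliases,
                 retired_prefixes = retired_prefixes,
                 known_prefixes = known_prefixes),
            class = "alias_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# lower-cased lookup table old-prefix -> replacement (retired first, then
# aliases; both are applied to fixpoint)
alias_table <- function(config) {
  tab <- c(config$retired_prefixes, config$prefix_aliases)
  if (length(tab)) names(tab) <- tolower(names(tab))
  tab
}

resolve_prefix <- function(prefix, tab) {
  if (!length(tab)) return(prefix)
  for (step in seq_len(length(tab) + 1L)) {
    key <- tolower(prefix)
    if (!(key %in% names(tab))) break
    repl <- unname(tab[[key]])
    if (tolower(repl) == key) break
    prefix <- repl
  }
  prefix
}

#' Canonicalize a term identifier
#'
#' Repairs the malformations observed in intended term reuse and applies
#' prefix aliases, so that ids meant to denote the same term compare equal:
#' \itemize{
#'   \item doubled prefixes `A:B_N` or `A:B:N` (B a known ontology prefix, N
#'     numeric) collapse to `B:N` — e.g. `MP:MP_0002216` to `MP:0002216`;
#'   \item `PREFIX_N` with a known prefix normalizes to `PREFIX:N`;
#'   \item alias and retired prefixes are replaced by their canonical prefix
#'     (`snap:Quality` to `bfo:Quality` under the default table).
#' }
#' Unrecognized ids are returned unchanged; the function is idempotent.
#'
#' @param raw_id Character vector of term ids.
#' @param config An [alias_config()].
#' @param known_prefixes Extra known prefixes to merge with the config's.
#' @return Character vector of canonical ids.
#' @examples
#' cfg <- alias_config(known_prefixes = c("MP", "GO"))
#' canonicalize_id("MP:MP_0002216", cfg)  # "MP:0002216"
#' canonicalize_id("GO:0008150", cfg)     # unchanged
#' @export
canonicalize_id <- function(raw_id, config = alias_config(),
                            known_prefixes = character()) {
  stopifnot(inherits(config, "alias_config"))
  known <- tolower(unique(c(config$known_prefixes, known_prefixes)))
  tab <- alias_table(config)
  vapply(raw_id, function(id) {
    if (!nzchar(id)) stop("empty term id")
    if (grepl(":", id, fixed = TRUE)) {
      prefix <- sub(":.*$", "", id)
      local <- sub("^[^:]*:", "", id)
      # doubled-prefix malformation: local part is itself PREFIX_N / PREFIX:N
      m <- regmatches(local,
                      regexec("^([A-Za-z][A-Za-z0-9.-]*)[_:]([0-9]+)$", local))[[1]]
      if (length(m) == 3L && tolower(m[2]) %in% known) {
        prefix <- m[2]
        local <- m[3]
      }
    } else {
      m <- regmatches(id,
                      regexec("^([A-Za-z][A-Za-z0-9.-]*)_([0-9]+)$", id))[[1]]
      if (length(m) == 3L && tolower(m[2]) %in% known) {
        prefix <- m[2]
        local <- m[3]
      } else {
        return(id)  # bare token, not a recognizable CURIE variant
      }
    }
    paste0(resolve_prefix(prefix, tab), ":", local)
  }, "", USE.NAMES = FALSE)
}

# prefix-case-insensitive form used for id equality
fold_id_prefix <- function(id) {
  has <- grepl(":", id, fixed = TRUE)
  id[has] <- paste0(tolower(sub(":.*$", "", id[has])), ":",
                    sub("^[^:]*:", "", id[has]))
  id
}

# prefix (lower-cased) -> owning ontology_key; contested prefixes resolved by
# key match, then by number of terms carried under the prefix
prefix_owner_map <- function(corpus) {
  claims <- tidyr::unnest(
    tibble(ontology_key = corpus$ontologies$ontology_key,
           prefix = corpus$ontologies$native_prefixes),
    "prefix")
  claims$prefix <- tolower(claims$prefix)
  claims <- distinct(claims)
  term_counts <- corpus$terms |>
    mutate(prefix = tolower(id_prefix(.data$term_id))) |>
    filter(!is.na(.data$prefix)) |>
    count(.data$ontology_key, .data$prefix, name = "n_terms")
  claims <- left_join(claims, term_counts,
                      by = c("ontology_key", "prefix")) |>
    mutate(n_terms = tidyr::replace_na(.data$n_terms, 0L),
           key_match = tolower(.data$ontology_key) == .data$prefix)
  claims |>
    arrange(.data$prefix, dplyr::desc(.data$key_match),
            dplyr::desc(.data$n_terms), .data$ontology_key) |>
    group_by(.data$prefix) |>
    summarise(owner = dplyr::first(.data$ontology_key),
              contested = n() > 1L, .groups = "drop")
}

#' Extract cross-ontology xref links from a corpus
#'
#' One row per xref whose canonicalized target id carries a prefix owned by a
#' different corpus ontology. Xrefs pointing outside the corpus (literature
#' ids, external databases) are ignored.
#'
#' @param corpus An `ortho_corpus`.
#' @param config An [alias_config()].
#' @return A tibble with columns `ontology_key`, `term_id`, `target_id`
#'   (canonical), `target_ontology`.
#' @export
extract_xref_links <- function(corpus, config = alias_config()) {
  owners <- prefix_owner_map(corpus)
  known <- unique(unlist(corpus$ontologies$native_prefixes))
  xr <- corpus$terms[, c("ontology_key", "term_id", "xrefs")]
  xr <- tidyr::unnest(xr, "xrefs")
  if (nrow(xr) == 0L) {
    return(tibble(ontology_key = character(), term_id = character(),
                  target_id = character(), target_ontology = character()))
  }
  xr$target_id <- canonicalize_id(xr$xrefs, config, known_prefixes = known)
  xr$prefix <- tolower(id_prefix(xr$target_id))
  xr <- left_join(xr, owners[, c("prefix", "owner")], by = "prefix")
  xr <- xr[!is.na(xr$owner) & xr$owner != xr$ontology_key, ]
  out <- distinct(tibble(ontology_key = xr$ontology_key,
                         term_id = xr$term_id,
                         target_id = xr$target_id,
                         target_ontology = xr$owner))
  out[radix_order(out$ontology_key, out$term_id, out$target_id), ]
}

#' Classify lexical mappings into reuse cases and overlap
#'
#' Assigns every mapping exactly one kind by first-match precedence
#' `SAME_ID` > `INTENDED_ID` > `XREF` > `OVERLAP`:
#' \itemize{
#'   \item `SAME_ID` — the raw ids are equal (prefix compared
#'     case-insensitively);
#'   \item `INTENDED_ID` — the canonical ids are equal but the raw ids
#'     differ;
#'   \item `XREF` — either term carries an xref whose canonical target
#'     equals the other term's canonical id;
#'   \item `OVERLAP` — none of the above: independent definition.
#' }
#' Direction: for id-based reuse the source is the ontology owning the
#' shared id's prefix and the reuser is the other side; for xref reuse the
#' reuser is the xref-bearing side (mutual xrefs count once, with the
#' lexicographically smaller ontology key taken as reuser and a message
#' emitted). An id-based reuse pair whose prefix neither side owns is kept
#' but its direction is left unresolved (`NA`) with a warning.
#'
#' @param mappings Mapping set from [find_mappings()].
#' @param corpus The `ortho_corpus` the mappings were derived from.
#' @param config An [alias_config()]; its `known_prefixes` are augmented
#'   with the corpus's native prefixes.
#' @return The mapping tibble with added columns `kind` (factor with levels
#'   SAME_ID, INTENDED_ID, XREF, OVERLAP), `reuser`, `source` (`NA` for
#'   OVERLAP and unresolved directions).
#' @export
classify_mappings <- function(mappings, corpus, config = alias_config()) {
  kinds <- c("SAME_ID", "INTENDED_ID", "XREF", "OVERLAP")
  known <- unique(unlist(corpus$ontologies$native_prefixes))
  owners <- prefix_owner_map(corpus)
  xlinks <- extract_xref_links(corpus, config)
  xkeys <- paste(xlinks$ontology_key, xlinks$term_id,
                 fold_id_prefix(xlinks$target_id), sep = "\r")

  m <- as_tibble(mappings)
  if (nrow(m) == 0L) {
    return(mutate(m, kind = factor(character(), levels = kinds),
                  reuser = character(), source = character()))
  }
  can_a <- canonicalize_id(m$term_a, config, known_prefixes = known)
  can_b <- canonicalize_id(m$term_b, config, known_prefixes = known)
  raw_eq <- fold_id_prefix(m$term_a) == fold_id_prefix(m$term_b)
  can_eq <- fold_id_prefix(can_a) == fold_id_prefix(can_b)
  a_refs_b <- paste(m$ont_a, m$term_a, fold_id_prefix(can_b),
                    sep = "\r") %in% xkeys
  b_refs_a <- paste(m$ont_b, m$term_b, fold_id_prefix(can_a),
                    sep = "\r") %in% xkeys

  kind <- ifelse(raw_eq, "SAME_ID",
          ifelse(can_eq, "INTENDED_ID",
          ifelse(a_refs_b | b_refs_a, "XREF", "OVERLAP")))

  reuser <- rep(NA_character_, nrow(m))
  src <- rep(NA_character_, nrow(m))

  id_based <- kind %in% c("SAME_ID", "INTENDED_ID")
  if (any(id_based)) {
    pref <- tolower(id_prefix(can_a[id_based]))
    own <- owners$owner[match(pref, owners$prefix)]
    ia <- which(id_based)
    owner_is_a <- !is.na(own) & own == m$ont_a[ia]
    owner_is_b <- !is.na(own) & own == m$ont_b[ia]
    src[ia[owner_is_a]] <- m$ont_a[ia[owner_is_a]]
    reuser[ia[owner_is_a]] <- m$ont_b[ia[owner_is_a]]
    src[ia[owner_is_b]] <- m$ont_b[ia[owner_is_b]]
    reuser[ia[owner_is_b]] <- m$ont_a[ia[owner_is_b]]
    unresolved <- ia[!(owner_is_a | owner_is_b)]
    if (length(unresolved)) {
      warning(sprintf(
        "%d id-based reuse pair(s) with a prefix neither ontology owns; direction left unresolved",
        length(unresolved)))
    }
  }
  is_x <- kind == "XREF"
  if (any(is_x)) {
    mutual <- is_x & a_refs_b & b_refs_a
    if (any(mutual)) {
      message(sprintf(
        "%d mutual xref pair(s); direction assigned to the lexicographically smaller ontology key",
        sum(mutual)))
    }
    # mutual: ont_a < ont_b by mapping canonicality, so A is the reuser
    a_side <- is_x & a_refs_b
    b_side <- is_x & b_refs_a & !a_refs_b
    reuser[a_side] <- m$ont_a[a_side]
    src[a_side] <- m$ont_b[a_side]
    reuser[b_side] <- m$ont_b[b_side]
    src[b_side] <- m$ont_a[b_side]
  }

  m$kind <- factor(kind, levels = kinds)
  m$reuser <- reuser
  m$source <- src
  m
}

#' @rdname mapping_io
#' @param classified Classified mapping tibble from [classify_mappings()].
#' @export
write_classified <- function(classified, path) {
  out <- classified
  out$kind <- as.character(out$kind)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}
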