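# Reading ontology files into a normalized in-memory corpus, plus the
# corpus-level hygiene rules (configured exclusions, duplicate-name policy).

#' Corpus loading configuration
#'
#' Options controlling [load_corpus()]: which ontologies to exclude outright,
#' what to do with ontologies that carry duplicate preferred names, whether
#' obsolete terms count toward ontology size and label indexing, and
#' per-ontology overrides of the id prefixes an ontology owns.
#'
#' @param exclusions Character vector of ontology keys to drop from the
#'   analysis (they are recorded in the corpus `excluded` table).
#' @param duplicate_name_policy `"exclude"` (default) drops any ontology in
#'   which two or more non-obsolete terms share a normalized preferred name
#'   — a single foreign name would map ambiguously to several of its classes.
#'   `"keep"` retains the ontology and flags the duplicates in the load
#'   report.
#' @param include_obsolete If `TRUE`, obsolete terms count toward ontology
#'   size and are indexed for matching. Default `FALSE`: deprecated terms
#'   would inflate apparent overlap.
#' @param native_prefixes Named list, ontology key -> character vector of id
#'   prefixes that ontology owns. Overrides the default (the prefixes
#'   observed among the ontology's own term ids). An override is needed when
#'   a file contains foreign-prefix terms, which is exactly what same-id
#'   reuse looks like.
#' @return A list of class `corpus_config`.
#' @export
corpus_config <- function(exclusions = character(),
                          duplicate_name_policy = c("exclude", "keep"),
                          include_obsolete = FALSE,
                          native_prefixes = list()) {
  duplicate_name_policy <- match.arg(duplicate_name_policy)
  stopifnot(is.character(exclusions), is.logical(include_obsolete),
            is.list(native_prefixes))
  structure(
    list(exclusions = exclusions,
         duplicate_name_policy = duplicate_name_policy,
         include_obsolete = include_obsolete,
         native_prefixes = native_prefixes),
    class = "corpus_config"
  )
}

strip_obo_comment <- function(x) {
  # trailing OBO comment: text after an unescaped " ! "
  sub("\\s!.*$", "", x)
}

id_prefix <- function(id) {
  ifelse(grepl(":", id, fixed = TRUE), sub(":.*$", "", id), NA_character_)
}

#' Parse one OBO 1.2 flat file into a term snapshot
#'
#' Reads `[Term]` stanzas only; `[Typedef]` and `[Instance]` stanzas are
#' ignored. For each term the id, preferred name, xrefs and obsolete flag are
#' captured; trailing `!` comments are stripped from id and xref values, and
#' the optional quoted description after an xref id is dropped. A stanza with
#' no id is recorded as a parse error and skipped; the file as a whole still
#' parses.
#'
#' @param source Path to an OBO file, a connection, or a character vector of
#'   lines.
#' @param ontology_key Short acronym identifying the ontology.
#' @param snapshot_date Date of the snapshot this file represents.
#' @param native_prefixes Optional character vector of id prefixes this
#'   ontology owns; default is the set of prefixes observed in the stanza
#'   ids.
#' @return A tibble of class `ortho_snapshot` with columns `ontology_key`,
#'   `term_id`, `preferred_name`, `xrefs` (list column), `is_obsolete`; term
#'   order equals stanza order. Attributes: `ontology_key`,
#'   `native_prefixes`, `snapshot_date`, `parse_errors` (character vector).
#' @examples
#' txt <- c("[Term]", "id: GO:0008150", "name: biological_process")
#' snap <- parse_obo(txt, "GO", as.Date("2010-09-01"))
#' snap$term_id
#' @export
parse_obo <- function(source, ontology_key, snapshot_date = Sys.Date(),
                      native_prefixes = NULL) {
  stopifnot(is.character(ontology_key), length(ontology_key) == 1L,
            nzchar(ontology_key))
  lines <- if (is.character(source) && length(source) == 1L &&
               !grepl("\n", source, fixed = TRUE) && file.exists(source)) {
    readLines(source, warn = FALSE, encoding = "UTF-8")
  } else if (inherits(source, "connection")) {
    readLines(source, warn = FALSE, encoding = "UTF-8")
  } else if (is.character(source)) {
    unlist(strsplit(source, "\n", fixed = TRUE), use.names = FALSE)
  } else {
    stop("`source` must be a file path, connection, or character vector")
  }

  stanza_starts <- grep("^\\[", lines)
  term_starts <- grep("^\\[Term\\]\\s*$", lines)
  errors <- character()
  records <- vector("list", length(term_starts))

  for (i in seq_along(term_starts)) {
    from <- term_starts[i] + 1L
    nxt <- stanza_starts[stanza_starts > term_starts[i]]
    to <- if (length(nxt)) min(nxt) - 1L else length(lines)
    body <- if (from > to) character() else lines[from:to]

    tags <- regmatches(body, regexec("^([A-Za-z_-]+):\\s*(.*)$", body))
    keys <- vapply(tags, function(m) if (length(m) == 3L) m[2] else "", "")
    vals <- vapply(tags, function(m) if (length(m) == 3L) m[3] else "", "")

    id <- vals[keys == "id"]
    id <- if (length(id)) trimws(strip_obo_comment(id[1])) else ""
    if (!nzchar(id) || grepl("\\s", id)) {
      errors <- c(errors, sprintf(
        "stanza at line %d: missing or malformed id; stanza skipped",
        term_starts[i]))
      next
    }
    nm <- vals[keys == "name"]
    nm <- if (length(nm)) trimws(nm[1]) else ""
    xr <- vals[keys == "xref"]
    if (length(xr)) {
      xr <- strip_obo_comment(xr)
      xr <- sub("\\s+\"[^\"]*\"\\s*$", "", xr)     # drop quoted description
      xr <- vapply(strsplit(trimws(xr), "\\s+"),
                   function(t) if (length(t)) t[1] else "", "")
      xr <- unique(xr[nzchar(xr)])
    } else {
      xr <- character()
    }
    obs <- vals[keys == "is_obsolete"]
    obs <- length(obs) > 0L && identical(trimws(obs[1]), "true")
    records[[i]] <- list(term_id = id, preferred_name = nm,
                         xrefs = list(xr), is_obsolete = obs)
  }

  records <- records[!vapply(records, is.null, TRUE)]
  terms <- if (length(records)) {
    tibble(
      ontology_key = ontology_key,
      term_id = vapply(records, `[[`, "", "term_id"),
      preferred_name = vapply(records, `[[`, "", "preferred_name"),
      xrefs = lapply(records, function(r) r$xrefs[[1]]),
      is_obsolete = vapply(records, `[[`, TRUE, "is_obsolete")
    )
  } else {
    tibble(ontology_key = character(), term_id = character(),
           preferred_name = character(), xrefs = list(),
           is_obsolete = logical())
  }
  if (anyDuplicated(terms$term_id)) {
    stop(sprintf("ontology '%s': duplicate term ids in one snapshot",
                 ontology_key))
  }
  if (is.null(native_prefixes)) {
    native_prefixes <- sort(unique(stats::na.omit(id_prefix(terms$term_id))))
  }
  structure(terms,
            class = c("ortho_snapshot", class(terms)),
            ontology_key = ontology_key,
            native_prefixes = native_prefixes,
            snapshot_date = as.Date(snapshot_date),
            parse_errors = errors)
}

#' Read and write the plain term-table format
#'
#' A TSV dialect for non-OBO sources: header
#' `term_id preferred_name xrefs is_obsolete`, xrefs pipe-separated, UTF-8,
#' LF line endings. Round-trips a parsed snapshot field-for-field.
#'
#' @param path File path.
#' @inheritParams parse_obo
#' @return `read_term_table()` returns an `ortho_snapshot` tibble as
#'   [parse_obo()] does.
#' @export
read_term_table <- function(path, ontology_key, snapshot_date = Sys.Date(),
                            native_prefixes = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          colClasses = "character", fileEncoding = "UTF-8",
                          check.names = FALSE)
  need <- c("term_id", "preferred_name", "xrefs", "is_obsolete")
  if (!all(need %in% names(df))) {
    stop("term table must have columns: ", paste(need, collapse = ", "))
  }
  terms <- tibble(
    ontology_key = rep(ontology_key, nrow(df)),
    term_id = df$term_id,
    preferred_name = df$preferred_name,
    xrefs = lapply(df$xrefs, function(x) {
      if (!nzchar(x)) character() else strsplit(x, "|", fixed = TRUE)[[1]]
    }),
    is_obsolete = df$is_obsolete %in% c("true", "TRUE", "1")
  )
  if (any(!nzchar(terms$term_id)) || any(grepl("\\s", terms$term_id))) {
    stop("term table contains empty or whitespace-bearing term ids")
  }
  if (anyDuplicated(terms$term_id)) {
    stop(sprintf("ontology '%s': duplicate term ids in one snapshot",
                 ontology_key))
  }
  if (is.null(native_prefixes)) {
    native_prefixes <- sort(unique(stats::na.omit(id_prefix(terms$term_id))))
  }
  structure(terms,
            class = c("ortho_snapshot", class(terms)),
            ontology_key = ontology_key,
            native_prefixes = native_prefixes,
            snapshot_date = as.Date(snapshot_date),
            parse_errors = character())
}

#' @rdname read_term_table
#' @param snapshot An `ortho_snapshot` (or any term tibble with the same
#'   columns).
#' @export
write_term_table <- function(snapshot, path) {
  out <- data.frame(
    term_id = snapshot$term_id,
    preferred_name = snapshot$preferred_name,
    xrefs = vapply(snapshot$xrefs, paste, "", collapse = "|"),
    is_obsolete = ifelse(snapshot$is_obsolete, "true", "false"),
    stringsAsFactors = FALSE
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(paste(names(out), collapse = "\t"),
               do.call(paste, c(unname(out), sep = "\t"))),
             con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Write a snapshot back to OBO 1.2 flat-file text
#'
#' Deterministic output (no timestamps), so identical snapshots produce
#' byte-identical files.
#'
#' @param snapshot An `ortho_snapshot` or compatible term tibble.
#' @param path Output path.
#' @param ontology_key Value for the `ontology:` header line; defaults to the
#'   snapshot attribute.
#' @export
write_obo <- function(snapshot, path,
                      ontology_key = attr(snapshot, "ontology_key")) {
  if (is.null(ontology_key)) ontology_key <- snapshot$ontology_key[1]
  header <- c("format-version: 1.2",
              paste0("ontology: ", tolower(ontology_key)), "")
  stanzas <- purrr::pmap(
    list(snapshot$term_id, snapshot$preferred_name, snapshot$xrefs,
         snapshot$is_obsolete),
    function(id, nm, xr, obs) {
      c("[Term]",
        paste0("id: ", id),
        if (nzchar(nm)) paste0("name: ", nm),
        if (length(xr)) paste0("xref: ", xr),
        if (obs) "is_obsolete: true",
        "")
    })
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(enc2utf8(c(header, unlist(stanzas))), con, sep = "\n",
             useBytes = TRUE)
  invisible(path)
}

#' Find duplicate preferred names within one ontology
#'
#' Groups the non-obsolete terms of a snapshot by normalized preferred name
#' (see [normalize_label()]) and reports every name borne by two or more
#' terms. The check is independent of the three-character matching filter:
#' short duplicate names are still reported.
#'
#' @param snapshot An `ortho_snapshot` or any tibble with `term_id`,
#'   `preferred_name`, `is_obsolete` columns.
#' @return A tibble with columns `normalized_name`, `term_ids` (list column),
#'   `n_terms`; zero rows when all names are distinct.
#' @export
detect_duplicate_names <- function(snapshot) {
  active <- snapshot[!snapshot$is_obsolete & nzchar(snapshot$preferred_name), ]
  if (nrow(active) == 0L) {
    return(tibble(normalized_name = character(), term_ids = list(),
                  n_terms = integer()))
  }
  tibble(normalized_name = normalize_label(active$preferred_name),
         term_id = active$term_id) |>
    group_by(.data$normalized_name) |>
    summarise(term_ids = list(sort(.data$term_id)), n_terms = n(),
              .groups = "drop") |>
    filter(.data$n_terms >= 2L) |>
    arrange(.data$normalized_name)
}

#' Load a dated corpus of ontology files
#'
#' Reads each file (OBO flat file, or term-table TSV when the extension is
#' `.tsv`/`.txt`), applies configured exclusions, and enforces the
#' duplicate-name policy: an ontology in which several non-obsolete terms
#' share a normalized preferred name is excluded (default) or kept and
#' flagged, because a foreign term with that name would map ambiguously.
#'
#' @param paths A data frame with columns `path` and `ontology_key`, or a
#'   named character vector of paths (names are ontology keys).
#' @param config A [corpus_config()].
#' @param snapshot_date Date of this corpus snapshot.
#' @return An object of class `ortho_corpus`: a list with `terms` (one
#'   tibble over all active ontologies), `ontologies` (key, native prefixes,
#'   active term count), `excluded` (key, reason), `duplicate_names`,
#'   `parse_errors`, `snapshot_date`, `include_obsolete`.
#' @export
load_corpus <- function(paths, config = corpus_config(),
                        snapshot_date = Sys.Date()) {
  if (is.character(paths)) {
    if (is.null(names(paths)) || any(!nzchar(names(paths)))) {
      stop("`paths` given as a character vector must be named by ontology key")
    }
    paths <- tibble(path = unname(paths), ontology_key = names(paths))
  }
  paths <- as_tibble(paths)
  stopifnot(all(c("path", "ontology_key") %in% names(paths)))
  if (anyDuplicated(paths$ontology_key)) {
    stop("duplicate ontology_key in corpus input")
  }
  snapshot_date <- as.Date(snapshot_date)

  excluded <- tibble(ontology_key = character(), reason = character())
  snaps <- list()
  dup_flags <- list()
  errors <- character()

  for (i in seq_len(nrow(paths))) {
    key <- paths$ontology_key[i]
    if (key %in% config$exclusions) {
      excluded <- bind_rows(excluded,
                            tibble(ontology_key = key,
                                   reason = "configured exclusion"))
      next
    }
    override <- config$native_prefixes[[key]]
    snap <- if (grepl("\\.(tsv|txt)$", paths$path[i], ignore.case = TRUE)) {
      read_term_table(paths$path[i], key, snapshot_date,
                      native_prefixes = override)
    } else {
      parse_obo(paths$path[i], key, snapshot_date,
                native_prefixes = override)
    }
    errors <- c(errors, attr(snap, "parse_errors"))
    dups <- detect_duplicate_names(snap)
    if (nrow(dups) > 0L) {
      if (config$duplicate_name_policy == "exclude") {
        excluded <- bind_rows(excluded,
                              tibble(ontology_key = key,
                                     reason = "duplicate preferred names"))
        next
      }
      dup_flags[[key]] <- mutate(dups, ontology_key = key, .before = 1L)
    }
    snaps[[key]] <- snap
  }

  if (length(snaps) == 0L) stop("empty corpus: no active ontologies loaded")

  include_obsolete <- config$include_obsolete
  ontologies <- purrr::map_dfr(snaps, function(s) {
    tibble(ontology_key = attr(s, "ontology_key"),
           native_prefixes = list(attr(s, "native_prefixes")),
           n_terms = if (include_obsolete) nrow(s) else sum(!s$is_obsolete))
  })
  terms <- bind_rows(lapply(snaps, function(s) as_tibble(unclass(s))))

  structure(
    list(terms = terms,
         ontologies = ontologies,
         excluded = excluded,
         duplicate_names = if (length(dup_flags)) bind_rows(dup_flags) else
           tibble(ontology_key = character(), normalized_name = character(),
                  term_ids = list(), n_terms = integer()),
         parse_errors = errors,
         snapshot_date = snapshot_date,
         include_obsolete = include_obsolete),
    class = "ortho_corpus"
  )
}

#' @export
print.ortho_corpus <- function(x, ...) {
  cat(sprintf("<ortho_corpus> %s: %d ontologies, %d active terms",
              format(x$snapshot_date), nrow(x$ontologies),
              sum(x$ontologies$n_terms)), "\n")
  if (nrow(x$excluded)) {
    cat("excluded:", paste0(x$excluded$ontology_key, " (", x$excluded$reason,
                            ")", collapse = "; "), "\n")
  }
  invisible(x)
}

#' Total active terms in a corpus
#'
#' Sum of per-ontology term counts over the non-excluded ontologies.
#' @param corpus An `ortho_corpus`.
#' @export
total_terms <- function(corpus) sum(corpus$ontologies$n_terms)

#' Write the corpus load report as JSON
#'
#' Records per-ontology term counts, exclusions with reasons, duplicate-name
#' flags and parse errors.
#'
#' @param corpus An `ortho_corpus`.
#' @param path Output path for the JSON report.
#' @export
write_load_report <- function(corpus, path) {
  report <- list(
    snapshot_date = format(corpus$snapshot_date),
    n_ontologies = nrow(corpus$ontologies),
    total_terms = total_terms(corpus),
    ontologies = lapply(seq_len(nrow(corpus$ontologies)), function(i) {
      list(ontology_key = corpus$ontologies$ontology_key[i],
           n_terms = corpus$ontologies$n_terms[i],
           native_prefixes = corpus$ontologies$native_prefixes[[i]])
    }),
    excluded = purrr::pmap(corpus$excluded, list),
    duplicate_name_flags = if (nrow(corpus$duplicate_names)) {
      lapply(seq_len(nrow(corpus$duplicate_names)), function(i) {
        list(ontology_key = corpus$duplicate_names$ontology_key[i],
             normalized_name = corpus$duplicate_names$normalized_name[i],
             term_ids = corpus$duplicate_names$term_ids[[i]])
      })
    } else list(),
    parse_errors = corpus$parse_errors
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
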