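# Aggregate outputs: corpus summary statistics, per-ontology tables, reuse
# and threshold-overlap graphs, reuse composition, and snapshot diffs.

#' Percentage with exact half-up rounding
#'
#' `100 * numerator / denominator`, rounded half-up at `decimals` places.
#' Rounding is carried out in integer arithmetic (exact for counts below
#' 2^53), never on an intermediate floating-point value, so ties round
#' predictably: `percent(1, 8, 1)` is 12.5, `percent(1, 8, 0)` is 13.
#'
#' @param numerator,denominator Non-negative counts; `denominator` must be
#'   positive (a zero denominator signals an empty ontology and is an
#'   error).
#' @param decimals Number of decimal places (>= 0).
#' @return Numeric vector of percentages.
#' @examples
#' percent(412, 817, 0)    # 50
#' percent(12, 29983, 2)   # 0.04
#' @export
percent <- function(numerator, denominator, decimals = 0L) {
  stopifnot(is.numeric(numerator), is.numeric(denominator),
            length(decimals) == 1L, decimals >= 0,
            all(numerator >= 0))
  if (any(denominator <= 0)) {
    stop("denominator must be positive (empty ontology?)")
  }
  scale <- 10^decimals
  scaled <- numerator * 100 * scale
  q <- scaled %/% denominator
  r <- scaled %% denominator
  (q + (2 * r >= denominator)) / scale
}

#' Summarize a classified corpus
#'
#' Computes the corpus-level totals, the per-ontology statistics, the
#' directed reuse edges, and the directed overlap fractions.
#'
#' Counting convention: the corpus-level `overlap_count` counts mapping
#' PAIRS; the per-ontology `overlapping_term_count` counts DISTINCT terms of
#' that ontology involved in at least one overlap pair. A term of A
#' overlapping two B terms contributes two pairs but one overlapping A term.
#' `reused_pair_count` for an ontology counts the reuse pairs in which it is
#' the reuser.
#'
#' @param classified Classified mappings from [classify_mappings()].
#' @param corpus The `ortho_corpus` they came from.
#' @param decimals Decimal places for the percent columns.
#' @return An object of class `ortho_report`: a list with `snapshot_date`,
#'   `total_terms`, `total_mappings`, `reuse_counts` (named: SAME_ID,
#'   INTENDED_ID, XREF), `overlap_count`, `ontology_stats` (tibble),
#'   `reuse_edges` (tibble reuser/source/n_pairs), `overlap_fractions`
#'   (tibble ont_from/ont_to/n_terms/fraction over distinct ont_from terms).
#' @export
summarize_corpus <- function(classified, corpus, decimals = 0L) {
  kinds <- c("SAME_ID", "INTENDED_ID", "XREF")
  cl <- as_tibble(classified)
  reuse_counts <- vapply(kinds, function(k) sum(cl$kind == k), 0L)
  overlap <- cl[cl$kind == "OVERLAP", ]
  reuse <- cl[cl$kind != "OVERLAP", ]

  onts <- corpus$ontologies[, c("ontology_key", "n_terms")]
  names(onts)[2] <- "size"

  reused_by <- reuse |>
    filter(!is.na(.data$reuser)) |>
    count(.data$reuser, name = "reused_pair_count")
  sources_by <- reuse |>
    filter(!is.na(.data$reuser)) |>
    group_by(.data$reuser) |>
    summarise(reuse_sources = list(sort(unique(.data$source))),
              .groups = "drop")

  # distinct terms per ontology appearing in >=1 overlap pair
  ov_terms <- bind_rows(
    tibble(ontology_key = overlap$ont_a, term_id = overlap$term_a),
    tibble(ontology_key = overlap$ont_b, term_id = overlap$term_b)
  ) |> distinct()
  ov_by <- count(ov_terms, .data$ontology_key, name = "overlapping_term_count")

  stats <- onts |>
    left_join(reused_by, by = c(ontology_key = "reuser")) |>
    left_join(sources_by, by = c(ontology_key = "reuser")) |>
    left_join(ov_by, by = "ontology_key") |>
    mutate(
      reused_pair_count = tidyr::replace_na(.data$reused_pair_count, 0L),
      overlapping_term_count = tidyr::replace_na(.data$overlapping_term_count, 0L),
      reuse_sources = purrr::map(.data$reuse_sources,
                                 function(s) s %||% character()),
      percent_reused = ifelse(
        .data$size > 0,
        percent(.data$reused_pair_count, pmax(.data$size, 1L), decimals),
        NA_real_),
      percent_overlapping = ifelse(
        .data$size > 0,
        percent(.data$overlapping_term_count, pmax(.data$size, 1L), decimals),
        NA_real_)
    ) |>
    arrange(.data$ontology_key)

  reuse_edges <- reuse |>
    filter(!is.na(.data$reuser)) |>
    count(.data$reuser, .data$source, name = "n_pairs") |>
    arrange(.data$reuser, .data$source)

  # directed overlap fractions over distinct ont_from terms
  ov_dir <- bind_rows(
    tibble(ont_from = overlap$ont_a, term_id = overlap$term_a,
           ont_to = overlap$ont_b),
    tibble(ont_from = overlap$ont_b, term_id = overlap$term_b,
           ont_to = overlap$ont_a)
  ) |>
    distinct() |>
    count(.data$ont_from, .data$ont_to, name = "n_terms") |>
    left_join(onts, by = c(ont_from = "ontology_key")) |>
    mutate(fraction = .data$n_terms / .data$size) |>
    select("ont_from", "ont_to", "n_terms", "fraction") |>
    arrange(.data$ont_from, .data$ont_to)

  structure(
    list(snapshot_date = corpus$snapshot_date,
         n_ontologies = nrow(onts),
         total_terms = total_terms(corpus),
         total_mappings = nrow(cl),
         reuse_counts = reuse_counts,
         overlap_count = nrow(overlap),
         ontology_stats = stats,
         reuse_edges = reuse_edges,
         overlap_fractions = ov_dir),
    class = "ortho_report"
  )
}

#' @export
print.ortho_report <- function(x, ...) {
  cat(sprintf(
    "<ortho_report> %s: %d ontologies, %s terms, %s mappings (%s reuse + %s overlap)\n",
    format(x$snapshot_date), x$n_ontologies,
    format(x$total_terms, big.mark = ","),
    format(x$total_mappings, big.mark = ","),
    format(sum(x$reuse_counts), big.mark = ","),
    format(x$overlap_count, big.mark = ",")))
  cat("reuse by kind:",
      paste(names(x$reuse_counts), x$reuse_counts, sep = "=",
            collapse = ", "), "\n")
  invisible(x)
}

#' @rdname summarize_corpus
#' @param x An `ortho_report`.
#' @param ... Unused.
#' @export
tidy.ortho_report <- function(x, ...) {
  x$ontology_stats
}

#' @rdname summarize_corpus
#' @export
glance.ortho_report <- function(x, ...) {
  tibble(snapshot_date = x$snapshot_date,
         n_ontologies = x$n_ontologies,
         total_terms = x$total_terms,
         total_mappings = x$total_mappings,
         same_id = unname(x$reuse_counts["SAME_ID"]),
         intended_id = unname(x$reuse_counts["INTENDED_ID"]),
         xref = unname(x$reuse_counts["XREF"]),
         reused = sum(x$reuse_counts),
         overlap = x$overlap_count)
}

#' Share of mappings that represent reuse
#'
#' Percentage of the mapping set classified as reuse (any of the three
#' kinds) rather than overlap, rounded half-up to whole percent by default.
#'
#' @param report An `ortho_report`.
#' @param decimals Decimal places.
#' @export
reuse_fraction_of_mappings <- function(report, decimals = 0L) {
  if (report$total_mappings <= 0) stop("report has no mappings")
  percent(sum(report$reuse_counts), report$total_mappings, decimals)
}

#' Reuse composition by kind
#'
#' Counts of SAME_ID, INTENDED_ID and XREF reuse pairs (zero-filled), which
#' sum to the total reuse for the snapshot.
#'
#' @param classified Classified mappings.
#' @return A tibble with columns `kind`, `n_pairs`.
#' @export
reuse_composition <- function(classified) {
  kinds <- c("SAME_ID", "INTENDED_ID", "XREF")
  k <- factor(as.character(classified$kind[classified$kind != "OVERLAP"]),
              levels = kinds)
  tibble(kind = kinds, n_pairs = as.integer(table(k)))
}

#' Directed reuse graph
#'
#' One node per active ontology; an edge reuser -> source whenever at least
#' one reuse pair links them, weighted by the pair count. Graph attributes
#' `n_reusers` and `n_sources` give the number of ontologies with out-degree
#' respectively in-degree of at least one.
#'
#' @param report An `ortho_report`.
#' @return An igraph directed graph.
#' @export
build_reuse_graph <- function(report) {
  edges <- report$reuse_edges
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$reuser, to = edges$source,
               weight = edges$n_pairs),
    directed = TRUE,
    vertices = data.frame(name = report$ontology_stats$ontology_key))
  g <- igraph::set_graph_attr(g, "n_reusers",
                              sum(igraph::degree(g, mode = "out") >= 1))
  igraph::set_graph_attr(g, "n_sources",
                         sum(igraph::degree(g, mode = "in") >= 1))
}

#' Threshold overlap graph
#'
#' An edge O1 -> O2 whenever at least `threshold` of O1's terms (distinct
#' terms, active denominator) overlap with terms of O2. The comparison is
#' inclusive (`>=`), and fractions are directional, so edges may be
#' asymmetric: a small ontology can clear the threshold against a large one
#' whose reciprocal fraction is negligible.
#'
#' @param report An `ortho_report`.
#' @param threshold Fraction in (0, 1].
#' @return An igraph directed graph with graph attribute `threshold` and
#'   edge attributes `n_terms`, `fraction`.
#' @export
build_overlap_graph <- function(report, threshold) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L,
            threshold > 0, threshold <= 1)
  keep <- report$overlap_fractions[
    report$overlap_fractions$fraction >= threshold, ]
  g <- igraph::graph_from_data_frame(
    data.frame(from = keep$ont_from, to = keep$ont_to,
               n_terms = keep$n_terms, fraction = keep$fraction),
    directed = TRUE,
    vertices = data.frame(name = report$ontology_stats$ontology_key))
  igraph::set_graph_attr(g, "threshold", threshold)
}

#' Compare two corpus snapshots
#'
#' Deltas of the reuse/overlap/mapping totals between an earlier and a later
#' report, plus the set differences of directed reuse relationships and of
#' threshold overlap-graph edges.
#'
#' @param earlier,later `ortho_report` objects.
#' @param thresholds Overlap-graph thresholds at which edge churn is
#'   reported.
#' @return An object of class `ortho_diff`.
#' @export
diff_snapshots <- function(earlier, later, thresholds = c(0.10, 0.30)) {
  keys_a <- earlier$ontology_stats$ontology_key
  keys_b <- later$ontology_stats$ontology_key
  restricted <- FALSE
  if (!setequal(keys_a, keys_b)) {
    warning("snapshots cover different ontology sets; ",
            "edge diffs restricted to the intersection")
    restricted <- TRUE
  }
  common <- intersect(keys_a, keys_b)

  rel <- function(r) {
    e <- distinct(r$reuse_edges[, c("reuser", "source")])
    e[e$reuser %in% common & e$source %in% common, ]
  }
  rel_a <- rel(earlier); rel_b <- rel(later)

  thr_edges <- function(r, thr) {
    e <- r$overlap_fractions[r$overlap_fractions$fraction >= thr,
                             c("ont_from", "ont_to")]
    e[e$ont_from %in% common & e$ont_to %in% common, ]
  }
  overlap_edge_diffs <- lapply(thresholds, function(thr) {
    ea <- thr_edges(earlier, thr); eb <- thr_edges(later, thr)
    list(threshold = thr,
         added = anti_join(eb, ea, by = c("ont_from", "ont_to")),
         removed = anti_join(ea, eb, by = c("ont_from", "ont_to")))
  })
  names(overlap_edge_diffs) <- paste0("threshold_", thresholds)

  structure(
    list(earlier_date = earlier$snapshot_date,
         later_date = later$snapshot_date,
         delta_total_terms = later$total_terms - earlier$total_terms,
         delta_reused = sum(later$reuse_counts) - sum(earlier$reuse_counts),
         delta_overlap = later$overlap_count - earlier$overlap_count,
         delta_mappings = later$total_mappings - earlier$total_mappings,
         delta_reuse_counts = later$reuse_counts - earlier$reuse_counts,
         added_reuse_relationships =
           anti_join(rel_b, rel_a, by = c("reuser", "source")),
         removed_reuse_relationships =
           anti_join(rel_a, rel_b, by = c("reuser", "source")),
         overlap_edge_diffs = overlap_edge_diffs,
         restricted_to_intersection = restricted),
    class = "ortho_diff"
  )
}

#' @export
print.ortho_diff <- function(x, ...) {
  cat(sprintf("<ortho_diff> %s -> %s\n", format(x$earlier_date),
              format(x$later_date)))
  cat(sprintf("  terms %+d, mappings %+d, reused %+d, overlap %+d\n",
              x$delta_total_terms, x$delta_mappings, x$delta_reused,
              x$delta_overlap))
  cat(sprintf("  reuse relationships: +%d / -%d\n",
              nrow(x$added_reuse_relationships),
              nrow(x$removed_reuse_relationships)))
  invisible(x)
}

#' @rdname diff_snapshots
#' @param x An `ortho_diff`.
#' @param ... Unused.
#' @export
glance.ortho_diff <- function(x, ...) {
  tibble(earlier_date = x$earlier_date, later_date = x$later_date,
         delta_total_terms = x$delta_total_terms,
         delta_reused = x$delta_reused,
         delta_overlap = x$delta_overlap,
         delta_mappings = x$delta_mappings,
         added_reuse_relationships = nrow(x$added_reuse_relationships),
         removed_reuse_relationships = nrow(x$removed_reuse_relationships))
}

# ---- report tables (the shapes of the published summary tables) ----------

#' Per-ontology reuse-extent table
#'
#' Ontologies reusing at least `min_percent` of their terms, with the
#' ontologies they draw from, sorted by percent reused.
#'
#' @param report An `ortho_report`.
#' @param min_percent Inclusion cutoff on `percent_reused`.
#' @return A tibble: `ontology_key`, `reuses_from`, `n_terms_reused`,
#'   `ontology_size`, `percent_reused`.
#' @export
table_reuse_extent <- function(report, min_percent = 10) {
  report$ontology_stats |>
    filter(.data$percent_reused >= min_percent) |>
    mutate(reuses_from = vapply(.data$reuse_sources, paste, "",
                                collapse = ", ")) |>
    select("ontology_key", "reuses_from",
           n_terms_reused = "reused_pair_count",
           ontology_size = "size",
           "percent_reused") |>
    arrange(dplyr::desc(.data$percent_reused), .data$ontology_key)
}

#' Per-ontology overlap table
#'
#' Distinct overlapping terms per ontology with size and percent, sorted by
#' percent overlapping.
#'
#' @param report An `ortho_report`.
#' @param min_percent Inclusion cutoff on `percent_overlapping` (default 0:
#'   all ontologies).
#' @return A tibble: `ontology_key`, `n_overlapping_terms`,
#'   `ontology_size`, `percent_overlapping`.
#' @export
table_overlap <- function(report, min_percent = 0) {
  report$ontology_stats |>
    filter(.data$percent_overlapping >= min_percent) |>
    select("ontology_key",
           n_overlapping_terms = "overlapping_term_count",
           ontology_size = "size",
           "percent_overlapping") |>
    arrange(dplyr::desc(.data$percent_overlapping), .data$ontology_key)
}

#' Cross-snapshot summary table
#'
#' One column block per report: total terms, reused pairs (with percent of
#' total terms), overlap pairs (with percent) — the corpus trend over time.
#'
#' @param reports A list of `ortho_report` objects, in chronological order.
#' @param decimals Decimal places for the percent columns.
#' @return A tibble with one row per snapshot.
#' @export
table_trend <- function(reports, decimals = 1L) {
  purrr::map_dfr(reports, function(r) {
    tibble(snapshot_date = r$snapshot_date,
           total_terms = r$total_terms,
           reused = sum(r$reuse_counts),
           percent_reused = percent(sum(r$reuse_counts), r$total_terms,
                                    decimals),
           overlap = r$overlap_count,
           percent_overlap = percent(r$overlap_count, r$total_terms,
                                     decimals),
           total_mappings = r$total_mappings)
  })
}

# ---- JSON round-trip ------------------------------------------------------

#' Write or read a corpus report as JSON
#'
#' The JSON form round-trips: `read_report(write_report(r, p))` rebuilds an
#' equivalent `ortho_report`.
#'
#' @param report An `ortho_report`.
#' @param path File path.
#' @export
write_report <- function(report, path) {
  obj <- list(
    snapshot_date = format(report$snapshot_date),
    n_ontologies = report$n_ontologies,
    total_terms = report$total_terms,
    total_mappings = report$total_mappings,
    reuse_counts = as.list(report$reuse_counts),
    overlap_count = report$overlap_count,
    ontology_stats = lapply(seq_len(nrow(report$ontology_stats)), function(i) {
      s <- report$ontology_stats[i, ]
      list(ontology_key = s$ontology_key, size = s$size,
           reused_pair_count = s$reused_pair_count,
           reuse_sources = s$reuse_sources[[1]],
           overlapping_term_count = s$overlapping_term_count,
           percent_reused = s$percent_reused,
           percent_overlapping = s$percent_overlapping)
    }),
    reuse_edges = purrr::pmap(report$reuse_edges, list),
    overlap_fractions = purrr::pmap(report$overlap_fractions, list)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  stats <- purrr::map_dfr(obj$ontology_stats, function(s) {
    tibble(ontology_key = s$ontology_key, size = as.integer(s$size),
           reused_pair_count = as.integer(s$reused_pair_count),
           reuse_sources = list(as.character(unlist(s$reuse_sources))),
           overlapping_term_count = as.integer(s$overlapping_term_count),
           percent_reused = as.numeric(s$percent_reused),
           percent_overlapping = as.numeric(s$percent_overlapping))
  })
  edges <- if (length(obj$reuse_edges)) {
    purrr::map_dfr(obj$reuse_edges, function(e) {
      tibble(reuser = e$reuser, source = e$source,
             n_pairs = as.integer(e$n_pairs))
    })
  } else tibble(reuser = character(), source = character(),
                n_pairs = integer())
  fr <- if (length(obj$overlap_fractions)) {
    purrr::map_dfr(obj$overlap_fractions, function(e) {
      tibble(ont_from = e$ont_from, ont_to = e$ont_to,
             n_terms = as.integer(e$n_terms),
             fraction = as.numeric(e$fraction))
    })
  } else tibble(ont_from = character(), ont_to = character(),
                n_terms = integer(), fraction = numeric())
  structure(
    list(snapshot_date = as.Date(obj$snapshot_date),
         n_ontologies = as.integer(obj$n_ontologies),
         total_terms = as.integer(obj$total_terms),
         total_mappings = as.integer(obj$total_mappings),
         reuse_counts = c(SAME_ID = as.integer(obj$reuse_counts$SAME_ID),
                          INTENDED_ID = as.integer(obj$reuse_counts$INTENDED_ID),
                          XREF = as.integer(obj$reuse_counts$XREF)),
         overlap_count = as.integer(obj$overlap_count),
         ontology_stats = stats,
         reuse_edges = edges,
         overlap_fractions = fr),
    class = "ortho_report"
  )
}

#' Write a diff as JSON
#'
#' @param diff An `ortho_diff`.
#' @param path File path.
#' @export
write_diff <- function(diff, path) {
  obj <- list(
    earlier_date = format(diff$earlier_date),
    later_date = format(diff$later_date),
    delta_total_terms = diff$delta_total_terms,
    delta_reused = diff$delta_reused,
    delta_overlap = diff$delta_overlap,
    delta_mappings = diff$delta_mappings,
    delta_reuse_counts = as.list(diff$delta_reuse_counts),
    added_reuse_relationships =
      purrr::pmap(diff$added_reuse_relationships, list),
    removed_reuse_relationships =
      purrr::pmap(diff$removed_reuse_relationships, list),
    overlap_edge_diffs = lapply(diff$overlap_edge_diffs, function(d) {
      list(threshold = d$threshold,
           added = purrr::pmap(d$added, list),
           removed = purrr::pmap(d$removed, list))
    }),
    restricted_to_intersection = diff$restricted_to_intersection
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
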