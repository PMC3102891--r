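# Shared fixtures and independent oracles.

# Run the whole pipeline on a set of ontology files.
run_pipeline <- function(paths, config = corpus_config(),
                         snapshot_date = as.Date("2010-09-01"),
                         aliases = alias_config()) {
  corpus <- load_corpus(paths, config, snapshot_date)
  index <- build_label_index(corpus)
  mappings <- find_mappings(index)
  classified <- classify_mappings(mappings, corpus, aliases)
  report <- summarize_corpus(classified, corpus)
  list(corpus = corpus, index = index, mappings = mappings,
       classified = classified, report = report)
}

# Independent oracle for find_mappings: compare every cross-ontology term
# pair directly, O(n^2).
brute_force_mappings <- function(index) {
  e <- index[index$eligible, ]
  rows <- list()
  n <- nrow(e)
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (e$ontology_key[i] == e$ontology_key[j]) next
        if (e$normalized_label[i] != e$normalized_label[j]) next
        a <- i; b <- j
        if (e$ontology_key[a] > e$ontology_key[b] ||
            (e$ontology_key[a] == e$ontology_key[b] &&
             e$term_id[a] > e$term_id[b])) {
          tmp <- a; a <- b; b <- tmp
        }
        rows[[length(rows) + 1L]] <- data.frame(
          ont_a = e$ontology_key[a], term_a = e$term_id[a],
          ont_b = e$ontology_key[b], term_b = e$term_id[b],
          normalized_label = e$normalized_label[a],
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) unique(do.call(rbind, rows)) else
    data.frame(ont_a = character(), term_a = character(),
               ont_b = character(), term_b = character(),
               normalized_label = character())
  out[order(out$ont_a, out$term_a, out$ont_b, out$term_b,
            method = "radix"), , drop = FALSE]
}

# Independent character-by-character normalization oracle.
oracle_normalize <- function(x) {
  vapply(x, function(s) {
    chars <- strsplit(tolower(s), "")[[1]]
    paste(chars[grepl("[[:alnum:]]", chars)], collapse = "")
  }, "", USE.NAMES = FALSE)
}

# Exact half-up verification: r is the correct rounding of 100*n/d at k
# decimals iff 100*n/d lies in [r - 0.5/10^k, r + 0.5/10^k), checked by
# integer cross-multiplication (no floating division).
verify_half_up <- function(n, d, k, r) {
  lhs <- 200 * n * 10^k          # 2 * (100 n) * 10^k
  lo <- (2 * r * 10^k - 1) * d   # 2*(r - 0.5/10^k)*10^k * d
  hi <- (2 * r * 10^k + 1) * d
  lhs >= lo & lhs < hi
}

# A small hand-built corpus exercising all four classification outcomes:
#   GO    defines GO:0008150 "biological_process"
#   QO    contains the same id and name               -> SAME_ID, reuser QO
#   SOPHARM has MP:MP_0002216 matching MP's MP:0002216 -> INTENDED_ID
#   XAO   has its own term with xref to ZFA's heart    -> XREF, reuser XAO
#   AO/BO both define "lung" independently             -> OVERLAP
micro_corpus <- function(dir) {
  write_micro_corpus(dir, list(
    GO = c("[Term]", "id: GO:0008150", "name: biological_process"),
    QO = c("[Term]", "id: GO:0008150", "name: Biological Process", "",
           "[Term]", "id: QO:1", "name: quality"),
    MP = c("[Term]", "id: MP:0002216", "name: abnormal seizure response"),
    SOPHARM = c("[Term]", "id: MP:MP_0002216",
                "name: Abnormal seizure response"),
    XAO = c("[Term]", "id: XAO:0000010", "name: heart",
            "xref: ZFA:0000050"),
    ZFA = c("[Term]", "id: ZFA:0000050", "name: Heart"),
    AO = c("[Term]", "id: AO:1", "name: lung"),
    BO = c("[Term]", "id: BO:1", "name: Lung")))
}

# Write a tiny hand-built OBO corpus; returns named path vector.
write_micro_corpus <- function(dir, files) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(names(files), function(k) {
    p <- file.path(dir, paste0(tolower(k), ".obo"))
    writeLines(files[[k]], p)
    p
  }, "")
  paths
}
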