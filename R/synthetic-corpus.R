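# Seeded generator of OBO-format fixture corpora with a ground-truth
# manifest: every reuse/overlap pair the pipeline should recover is planted
# explicitly, along with distractors that must never match.

# human-readable anatomy/process-flavoured vocabulary; combined as
# "modifier noun" bigrams, giving ~2000 globally unique labels
synth_modifiers <- c(
  "dorsal", "ventral", "anterior", "posterior", "proximal", "distal",
  "lateral", "medial", "apical", "basal", "cranial", "caudal", "superior",
  "inferior", "primary", "secondary", "embryonic", "larval", "adult",
  "ciliated", "squamous", "cuboidal", "columnar", "stratified", "glandular",
  "vascular", "neural", "epithelial", "muscular", "skeletal", "cardiac",
  "hepatic", "renal", "pulmonary", "dermal", "olfactory", "optic",
  "pharyngeal", "pectoral", "pelvic", "caudate", "striated", "smooth",
  "radial", "axial")

synth_nouns <- c(
  "lobe", "membrane", "process", "cell", "duct", "tubule", "ganglion",
  "nerve", "vessel", "artery", "vein", "cartilage", "bone", "muscle",
  "fin", "gland", "epithelium", "mesenchyme", "somite", "placode",
  "primordium", "bud", "plate", "fold", "groove", "pouch", "arch",
  "chamber", "valve", "septum", "nucleus", "tract", "fiber", "bundle",
  "sheath", "capsule", "cortex", "medulla", "papilla", "follicle",
  "sinus", "canal", "fissure", "sulcus")

#' Parameters for the synthetic corpus generator
#'
#' Defaults describe a small multi-ontology corpus with every phenomenon the
#' pipeline must handle: same-id reuse, malformed-id (intended) reuse, xref
#' reuse, name-only overlap, sub-three-character labels, near-miss labels
#' one character away from a real label, and (optionally) an ontology with
#' duplicate preferred names.
#'
#' @param n_ontologies Number of ontologies (2..26).
#' @param terms_per_ontology Base terms per ontology, before plants.
#' @param n_same_id,n_intended_id,n_xref,n_overlap Planted pair counts.
#' @param n_short_labels Distractor terms whose normalized label has fewer
#'   than three characters; the same short label is planted in more than one
#'   ontology so the eligibility filter is exercised.
#' @param n_near_miss Distractor terms whose label differs from a real label
#'   by exactly one alphanumeric character.
#' @param include_duplicate_name_ontology Add an extra ontology carrying two
#'   terms with the same normalized preferred name (triggers the
#'   duplicate-name policy on load).
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return A list of class `synth_params`.
#' @export
synth_params <- function(n_ontologies = 6L, terms_per_ontology = 40L,
                         n_same_id = 5L, n_intended_id = 3L, n_xref = 4L,
                         n_overlap = 6L, n_short_labels = 2L,
                         n_near_miss = 3L,
                         include_duplicate_name_ontology = FALSE,
                         seed = 1L) {
  p <- list(n_ontologies = as.integer(n_ontologies),
            terms_per_ontology = as.integer(terms_per_ontology),
            n_same_id = as.integer(n_same_id),
            n_intended_id = as.integer(n_intended_id),
            n_xref = as.integer(n_xref),
            n_overlap = as.integer(n_overlap),
            n_short_labels = as.integer(n_short_labels),
            n_near_miss = as.integer(n_near_miss),
            include_duplicate_name_ontology =
              isTRUE(include_duplicate_name_ontology),
            seed = as.integer(seed))
  counts <- c(p$n_same_id, p$n_intended_id, p$n_xref, p$n_overlap,
              p$n_short_labels, p$n_near_miss)
  if (any(counts < 0)) stop("planted counts must be >= 0")
  if (p$n_ontologies < 2L || p$n_ontologies > 26L) {
    stop("n_ontologies must be between 2 and 26")
  }
  n_plants <- p$n_same_id + p$n_intended_id + p$n_xref + p$n_overlap
  if (n_plants > p$n_ontologies * p$terms_per_ontology / 2) {
    stop("infeasible params: planted pairs exceed half the term budget")
  }
  n_names <- p$n_ontologies * p$terms_per_ontology + p$n_near_miss + 10L
  if (n_names > length(synth_modifiers) * length(synth_nouns)) {
    stop("infeasible params: term budget exceeds the label vocabulary")
  }
  structure(p, class = "synth_params")
}

# normalization-preserving label variants: what the matcher is contracted to
# collapse (case and delimiter changes only, token order untouched)
vary_label <- function(label) {
  style <- sample(5L, 1L)
  words <- strsplit(label, " ", fixed = TRUE)[[1]]
  switch(style,
    label,
    toupper(label),
    paste(vapply(words, function(w) {
      paste0(toupper(substr(w, 1, 1)), substr(w, 2, nchar(w)))
    }, ""), collapse = " "),
    paste(words, collapse = "_"),
    if (length(words) > 1L) {
      paste0(paste(words[-length(words)], collapse = " "), " (",
             words[length(words)], ")")
    } else {
      paste0(label, "-")
    })
}

# in-memory corpus under construction: per-ontology tibbles + id counters +
# remaining vocabulary
synth_build <- function(params) {
  p <- params
  keys <- paste0(LETTERS[seq_len(p$n_ontologies)], "AO")
  vocab <- as.vector(outer(synth_modifiers, synth_nouns, paste))
  vocab <- sample(vocab)

  counters <- stats::setNames(rep(0L, length(keys)), keys)
  next_id <- function(key) {
    counters[[key]] <<- counters[[key]] + 1L
    sprintf("%s:%07d", key, counters[[key]])
  }
  vi <- 0L
  next_name <- function() {
    vi <<- vi + 1L
    if (vi > length(vocab)) stop("vocabulary exhausted")
    vocab[[vi]]
  }

  onts <- stats::setNames(vector("list", length(keys)), keys)
  for (k in keys) {
    onts[[k]] <- tibble(
      ontology_key = k,
      term_id = vapply(seq_len(p$terms_per_ontology), function(i) next_id(k), ""),
      preferred_name = vapply(seq_len(p$terms_per_ontology),
                              function(i) next_name(), ""),
      xrefs = rep(list(character()), p$terms_per_ontology),
      is_obsolete = FALSE
    )
  }

  # source terms for plants: disjoint across kinds, never reused twice
  used_sources <- character()
  pick_source <- function(exclude_key = NULL) {
    repeat {
      sk <- sample(setdiff(keys, exclude_key), 1L)
      avail <- onts[[sk]]$term_id[seq_len(p$terms_per_ontology)]
      avail <- setdiff(avail, used_sources)
      if (length(avail)) {
        sid <- sample(avail, 1L)
        used_sources <<- c(used_sources, sid)
        return(list(key = sk, id = sid,
                    name = onts[[sk]]$preferred_name[
                      match(sid, onts[[sk]]$term_id)]))
      }
    }
  }
  add_term <- function(key, id, name, xrefs = character()) {
    onts[[key]] <<- bind_rows(onts[[key]],
                              tibble(ontology_key = key, term_id = id,
                                     preferred_name = name,
                                     xrefs = list(xrefs),
                                     is_obsolete = FALSE))
  }

  planted <- list()
  plant <- function(kind, preferred_pair = NULL) {
    src <- pick_source()
    reuser <- if (!is.null(preferred_pair) && preferred_pair[2] == src$key) {
      preferred_pair[1]
    } else {
      sample(setdiff(keys, src$key), 1L)
    }
    label <- vary_label(src$name)
    rid <- switch(kind,
      SAME_ID = src$id,
      INTENDED_ID = {
        local <- sub("^[^:]*:", "", src$id)
        if (stats::runif(1) < 0.5) paste0(src$key, ":", src$key, "_", local)
        else paste0(src$key, "_", local)
      },
      XREF = next_id(reuser),
      OVERLAP = next_id(reuser))
    xr <- if (kind == "XREF") {
      if (stats::runif(1) < 0.3) {
        paste0(src$key, ":", src$key, "_", sub("^[^:]*:", "", src$id))
      } else src$id
    } else character()
    add_term(reuser, rid, label, xr)
    planted[[length(planted) + 1L]] <<- tibble(
      kind = kind, source = src$key, source_id = src$id,
      reuser = reuser, reuser_id = rid, label = label)
  }

  for (i in seq_len(p$n_same_id)) plant("SAME_ID")
  for (i in seq_len(p$n_intended_id)) plant("INTENDED_ID")
  for (i in seq_len(p$n_xref)) plant("XREF")
  for (i in seq_len(p$n_overlap)) plant("OVERLAP")

  planted <- if (length(planted)) bind_rows(planted) else
    tibble(kind = character(), source = character(),
           source_id = character(), reuser = character(),
           reuser_id = character(), label = character())

  # distractors
  distractors <- list()
  short_pool <- c("GO", "ab", "X1", "pq", "zz", "q7")
  for (i in seq_len(p$n_short_labels)) {
    k <- keys[((i - 1L) %% length(keys)) + 1L]
    lbl <- short_pool[((i - 1L) %/% length(keys)) %% length(short_pool) + 1L]
    id <- next_id(k)
    add_term(k, id, lbl)
    distractors[[length(distractors) + 1L]] <-
      tibble(type = "short_label", ontology_key = k, term_id = id,
             label = lbl)
  }
  all_norm <- function() {
    normalize_label(unlist(lapply(onts, `[[`, "preferred_name")))
  }
  for (i in seq_len(p$n_near_miss)) {
    base <- if (nrow(planted)) planted$label[sample(nrow(planted), 1L)]
            else onts[[1]]$preferred_name[1]
    taken <- all_norm()
    variant <- NULL
    for (try in 1:50) {
      chars <- strsplit(base, "")[[1]]
      alnum <- grep("[A-Za-z0-9]", chars)
      pos <- sample(alnum, 1L)
      chars[pos] <- sample(setdiff(letters, tolower(chars[pos])), 1L)
      cand <- paste(chars, collapse = "")
      if (!(normalize_label(cand) %in% taken)) { variant <- cand; break }
    }
    if (is.null(variant)) stop("could not construct a near-miss distractor")
    k <- sample(keys, 1L)
    id <- next_id(k)
    add_term(k, id, variant)
    distractors[[length(distractors) + 1L]] <-
      tibble(type = "near_miss", ontology_key = k, term_id = id,
             label = variant)
  }
  distractors <- if (length(distractors)) bind_rows(distractors) else
    tibble(type = character(), ontology_key = character(),
           term_id = character(), label = character())

  if (p$include_duplicate_name_ontology) {
    k <- "DUP"
    dup_terms <- tibble(
      ontology_key = k,
      term_id = sprintf("DUP:%07d", 1:4),
      preferred_name = c("Cell", "cell", next_name(), next_name()),
      xrefs = rep(list(character()), 4),
      is_obsolete = FALSE)
    onts[[k]] <- dup_terms
  }

  list(params = p, ontologies = onts, planted = planted,
       distractors = distractors,
       state = list(counters = counters, vocab_index = vi, vocab = vocab))
}

synth_manifest <- function(build) {
  counts <- vapply(c("SAME_ID", "INTENDED_ID", "XREF", "OVERLAP"),
                   function(k) sum(build$planted$kind == k), 0L)
  list(params = build$params,
       ontology_sizes = tibble(
         ontology_key = names(build$ontologies),
         n_terms = vapply(build$ontologies, nrow, 0L)),
       planted = build$planted,
       distractors = build$distractors,
       expected_counts = counts,
       expected_mappings = sum(counts))
}

write_synth_build <- function(build, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(names(build$ontologies), function(k) {
    path <- file.path(dir, paste0(tolower(k), ".obo"))
    snap <- build$ontologies[[k]]
    write_obo(snap, path, ontology_key = k)
    path
  }, "")
  manifest <- synth_manifest(build)
  jsonlite::write_json(
    list(params = unclass(manifest$params),
         ontology_sizes = purrr::pmap(manifest$ontology_sizes, list),
         planted = purrr::pmap(manifest$planted, list),
         distractors = purrr::pmap(manifest$distractors, list),
         expected_counts = as.list(manifest$expected_counts),
         expected_mappings = manifest$expected_mappings),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  list(paths = paths, manifest = manifest)
}

#' Generate a synthetic OBO corpus with a ground-truth manifest
#'
#' Writes one OBO file per ontology plus `manifest.json` into `dir`.
#' Deterministic: the same parameters and seed produce byte-identical
#' files. The manifest records every planted pair with its intended
#' classification and direction, the distractor inventory, and per-ontology
#' sizes; a correct pipeline recovers the planted counts exactly.
#'
#' @param params A [synth_params()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with `paths` (named by ontology key, manifest
#'   excluded) and `manifest`.
#' @export
generate_corpus <- function(params, dir = tempfile("synth")) {
  stopifnot(inherits(params, "synth_params"))
  build <- withr::with_seed(params$seed, synth_build(params))
  out <- write_synth_build(build, dir)
  invisible(out)
}

#' Generate a temporal pair of corpora with a planted delta
#'
#' Builds a first corpus from `params_t1`, applies the planted changes, and
#' writes both corpora (subdirectories `t1/` and `t2/` of `dir`) plus a diff
#' manifest holding the expected deltas.
#'
#' @param params_t1 A [synth_params()] for the earlier snapshot.
#' @param delta A list with any of: `add_same_id`, `add_xref`, `add_overlap`
#'   (new planted pairs), `convert_overlap_to_xref` (existing overlap pairs
#'   upgraded to explicit xref reuse), `add_terms` (plain new terms).
#' @param dir Output directory.
#' @param seed Seed for the delta's randomness; defaults to
#'   `params_t1$seed + 1`.
#' @return Invisibly, a list with `t1`, `t2` (each as from
#'   [generate_corpus()]) and `diff_manifest` (expected deltas and the added
#'   reuse relationships).
#' @export
generate_temporal_pair <- function(params_t1, delta = list(),
                                   dir = tempfile("synthpair"),
                                   seed = params_t1$seed + 1L) {
  stopifnot(inherits(params_t1, "synth_params"))
  d <- utils::modifyList(
    list(add_same_id = 0L, add_xref = 0L, add_overlap = 0L,
         convert_overlap_to_xref = 0L, add_terms = 0L),
    lapply(delta, as.integer))
  if (any(unlist(d) < 0)) stop("delta counts must be >= 0")
  if (d$convert_overlap_to_xref > params_t1$n_overlap) {
    stop("infeasible delta: cannot convert more overlap pairs than planted")
  }

  build1 <- withr::with_seed(params_t1$seed, synth_build(params_t1))
  build2 <- withr::with_seed(seed, apply_delta(build1, d))

  t1 <- write_synth_build(build1, file.path(dir, "t1"))
  t2 <- write_synth_build(build2, file.path(dir, "t2"))

  rel <- function(m) distinct(m$planted[m$planted$kind != "OVERLAP",
                                        c("reuser", "source")])
  added_rel <- anti_join(rel(t2$manifest), rel(t1$manifest),
                         by = c("reuser", "source"))
  diff_manifest <- list(
    delta_reused = d$add_same_id + d$add_xref + d$convert_overlap_to_xref,
    delta_overlap = d$add_overlap - d$convert_overlap_to_xref,
    delta_mappings = d$add_same_id + d$add_xref + d$add_overlap,
    added_reuse_relationships = added_rel,
    delta = d)
  jsonlite::write_json(
    list(delta_reused = diff_manifest$delta_reused,
         delta_overlap = diff_manifest$delta_overlap,
         delta_mappings = diff_manifest$delta_mappings,
         added_reuse_relationships = purrr::pmap(added_rel, list),
         delta = d),
    file.path(dir, "diff_manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(list(t1 = t1, t2 = t2, diff_manifest = diff_manifest))
}

# apply a planted delta to a finished build, continuing its id counters and
# vocabulary
apply_delta <- function(build, d) {
  p <- build$params
  onts <- build$ontologies
  keys <- paste0(LETTERS[seq_len(p$n_ontologies)], "AO")
  counters <- build$state$counters
  vocab <- build$state$vocab
  vi <- build$state$vocab_index
  planted <- build$planted

  next_id <- function(key) {
    counters[[key]] <<- counters[[key]] + 1L
    sprintf("%s:%07d", key, counters[[key]])
  }
  next_name <- function() {
    vi <<- vi + 1L
    if (vi > length(vocab)) stop("vocabulary exhausted")
    vocab[[vi]]
  }
  add_term <- function(key, id, name, xrefs = character()) {
    onts[[key]] <<- bind_rows(onts[[key]],
                              tibble(ontology_key = key, term_id = id,
                                     preferred_name = name,
                                     xrefs = list(xrefs),
                                     is_obsolete = FALSE))
  }

  # convert existing overlap plants to explicit xref reuse
  ov_idx <- which(planted$kind == "OVERLAP")
  conv <- utils::head(ov_idx, d$convert_overlap_to_xref)
  for (i in conv) {
    k <- planted$reuser[i]
    row <- match(planted$reuser_id[i], onts[[k]]$term_id)
    onts[[k]]$xrefs[[row]] <- union(onts[[k]]$xrefs[[row]],
                                    planted$source_id[i])
    planted$kind[i] <- "XREF"
  }

  # new plants on fresh source terms, preferring ontology pairs without an
  # existing reuse relationship (so the diff shows new relationships)
  used_sources <- unique(planted$source_id)
  existing_rel <- distinct(planted[planted$kind != "OVERLAP",
                                   c("reuser", "source")])
  new_plant <- function(kind) {
    cand <- expand.grid(reuser = keys, source = keys,
                        stringsAsFactors = FALSE)
    cand <- cand[cand$reuser != cand$source, ]
    fresh <- anti_join(as_tibble(cand), existing_rel,
                       by = c("reuser", "source"))
    pair <- if (kind != "OVERLAP" && nrow(fresh)) {
      fresh[sample(nrow(fresh), 1L), ]
    } else {
      cand[sample(nrow(cand), 1L), ]
    }
    sk <- pair$source; rk <- pair$reuser
    avail <- setdiff(onts[[sk]]$term_id[seq_len(p$terms_per_ontology)],
                     used_sources)
    if (!length(avail)) stop("infeasible delta: no free source terms")
    sid <- sample(avail, 1L)
    used_sources <<- c(used_sources, sid)
    sname <- onts[[sk]]$preferred_name[match(sid, onts[[sk]]$term_id)]
    rid <- switch(kind, SAME_ID = sid,
                  XREF = next_id(rk), OVERLAP = next_id(rk))
    xr <- if (kind == "XREF") sid else character()
    label <- vary_label(sname)
    add_term(rk, rid, label, xr)
    planted <<- bind_rows(planted,
                          tibble(kind = kind, source = sk, source_id = sid,
                                 reuser = rk, reuser_id = rid,
                                 label = label))
    if (kind != "OVERLAP") {
      existing_rel <<- bind_rows(existing_rel,
                                 tibble(reuser = rk, source = sk))
    }
  }
  for (i in seq_len(d$add_same_id)) new_plant("SAME_ID")
  for (i in seq_len(d$add_xref)) new_plant("XREF")
  for (i in seq_len(d$add_overlap)) new_plant("OVERLAP")
  for (i in seq_len(d$add_terms)) {
    k <- sample(keys, 1L)
    add_term(k, next_id(k), next_name())
  }

  list(params = p, ontologies = onts, planted = planted,
       distractors = build$distractors,
       state = list(counters = counters, vocab_index = vi, vocab = vocab))
}
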