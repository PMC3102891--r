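test_that("parse_obo captures id, name, xrefs and obsolete flag per stanza", {
  txt <- c(
    "format-version: 1.2", "",
    "[Term]", "id: GO:0008150", "name: biological_process", "",
    "[Term]", "id: XAO:0000010", "name: heart",
    "xref: ZFA:0000123", "xref: ZFA:0000123", 'xref: FMA:7088 "heart"', "",
    "[Typedef]", "id: part_of", "name: part of", "",
    "[Term]", "id: GO:0000001 ! mitochondrion inheritance",
    "name: mitochondrion inheritance", "is_obsolete: true", "")
  snap <- parse_obo(txt, "GO", as.Date("2010-09-01"))

  expect_s3_class(snap, "ortho_snapshot")
  expect_equal(snap$term_id, c("GO:0008150", "XAO:0000010", "GO:0000001"))
  expect_equal(snap$preferred_name[1], "biological_process")
  expect_equal(snap$xrefs[[1]], character())
  # duplicates collapse; quoted description stripped
  expect_equal(snap$xrefs[[2]], c("ZFA:0000123", "FMA:7088"))
  expect_false(snap$is_obsolete[2])
  expect_true(snap$is_obsolete[3])
  # trailing comment stripped from id
  expect_equal(snap$term_id[3], "GO:0000001")
  # typedef stanzas ignored
  expect_false("part_of" %in% snap$term_id)
  # native prefixes default to observed stanza-id prefixes
  expect_setequal(attr(snap, "native_prefixes"), c("GO", "XAO"))
})

test_that("a stanza without an id is skipped with a recorded error", {
  txt <- c("[Term]", "name: orphan term", "",
           "[Term]", "id: AO:1", "name: kept term")
  snap <- parse_obo(txt, "AO")
  expect_equal(snap$term_id, "AO:1")
  expect_length(attr(snap, "parse_errors"), 1)
  expect_match(attr(snap, "parse_errors"), "skipped")
})

test_that("term-table TSV round-trips a parsed snapshot field-wise", {
  txt <- c("[Term]", "id: ZFA:0000050", "name: heart",
           "xref: XAO:0000010", "xref: FMA:7088", "",
           "[Term]", "id: ZFA:0000999", "name: old fin", "is_obsolete: true")
  snap <- parse_obo(txt, "ZFA", as.Date("2009-09-01"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_term_table(snap, path)
  back <- read_term_table(path, "ZFA", as.Date("2009-09-01"))
  expect_equal(back$term_id, snap$term_id)
  expect_equal(back$preferred_name, snap$preferred_name)
  expect_equal(back$xrefs, snap$xrefs)
  expect_equal(back$is_obsolete, snap$is_obsolete)
})

test_that("write_obo/parse_obo round-trips and is byte-deterministic", {
  txt <- c("[Term]", "id: AAO:0000001", "name: dorsal fin",
           "xref: ZFA:0000001", "",
           "[Term]", "id: AAO:0000002", "name: ventral fin")
  snap <- parse_obo(txt, "AAO")
  p1 <- withr::local_tempfile(fileext = ".obo")
  p2 <- withr::local_tempfile(fileext = ".obo")
  write_obo(snap, p1); write_obo(snap, p2)
  expect_identical(readLines(p1), readLines(p2))
  back <- parse_obo(p1, "AAO")
  expect_equal(back$term_id, snap$term_id)
  expect_equal(back$xrefs, snap$xrefs)
})

test_that("detect_duplicate_names groups by normalized name, any length", {
  snap <- tibble::tibble(
    ontology_key = "EHDA",
    term_id = sprintf("EHDA:%d", 1:6),
    preferred_name = c("Cell", "cell", "AB", "ab", "liver", "old heart"),
    xrefs = rep(list(character()), 6),
    is_obsolete = c(rep(FALSE, 5), TRUE))
  dups <- detect_duplicate_names(snap)
  expect_equal(nrow(dups), 2)
  expect_setequal(dups$normalized_name, c("cell", "ab"))
  # the 2-character duplicate is still reported: duplication is independent
  # of the 3-character matching filter
  expect_equal(dups$term_ids[dups$normalized_name == "ab"][[1]],
               c("EHDA:3", "EHDA:4"))
  # obsolete terms do not participate
  expect_false("oldheart" %in% dups$normalized_name)
  snap$preferred_name <- sprintf("unique name %d", 1:6)
  expect_equal(nrow(detect_duplicate_names(snap)), 0)
})

test_that("load_corpus applies exclusions and the duplicate-name policy", {
  dir <- withr::local_tempdir()
  paths <- write_micro_corpus(dir, list(
    AO = c("[Term]", "id: AO:1", "name: lung"),
    BO = c("[Term]", "id: BO:1", "name: liver"),
    CO = c("[Term]", "id: CO:1", "name: Cell", "",
           "[Term]", "id: CO:2", "name: cell")))

  corpus <- load_corpus(paths, corpus_config(exclusions = "BO"))
  # BO excluded by config, CO by the duplicate-name policy
  expect_equal(corpus$ontologies$ontology_key, "AO")
  expect_setequal(corpus$excluded$ontology_key, c("BO", "CO"))
  expect_equal(
    corpus$excluded$reason[corpus$excluded$ontology_key == "CO"],
    "duplicate preferred names")
  # excluded ontologies contribute zero terms downstream
  expect_equal(total_terms(corpus), 1)
  expect_false(any(corpus$terms$ontology_key %in% c("BO", "CO")))

  kept <- load_corpus(paths, corpus_config(duplicate_name_policy = "keep"))
  expect_true("CO" %in% kept$ontologies$ontology_key)
  expect_equal(kept$duplicate_names$ontology_key, "CO")

  expect_error(load_corpus(paths[c(1, 1)], corpus_config()),
               "duplicate ontology_key")
  expect_error(load_corpus(paths["CO"], corpus_config()), "empty corpus")
})

test_that("obsolete terms are excluded from size unless opted in", {
  dir <- withr::local_tempdir()
  paths <- write_micro_corpus(dir, list(
    AO = c("[Term]", "id: AO:1", "name: lung", "",
           "[Term]", "id: AO:2", "name: gone", "is_obsolete: true"),
    BO = c("[Term]", "id: BO:1", "name: liver")))
  expect_equal(total_terms(load_corpus(paths, corpus_config())), 2)
  expect_equal(
    total_terms(load_corpus(paths, corpus_config(include_obsolete = TRUE))),
    3)
})

test_that("parse order is preserved and the load report is valid JSON", {
  dir <- withr::local_tempdir()
  stanzas <- unlist(lapply(10:1, function(i) {
    c("[Term]", sprintf("id: AO:%07d", i), sprintf("name: term %d", i), "")
  }))
  paths <- write_micro_corpus(dir, list(AO = stanzas,
                                        BO = c("[Term]", "id: BO:1",
                                               "name: other")))
  corpus <- load_corpus(paths, corpus_config())
  ao <- corpus$terms$term_id[corpus$terms$ontology_key == "AO"]
  expect_equal(ao, sprintf("AO:%07d", 10:1))
  rp <- file.path(dir, "load.json")
  write_load_report(corpus, rp)
  parsed <- jsonlite::read_json(rp)
  expect_equal(parsed$total_terms, 11)
  expect_equal(parsed$n_ontologies, 2)
})
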