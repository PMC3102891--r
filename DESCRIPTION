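Package: orthoscan
Title: Lexical Analysis of Term Reuse and Overlap Across Biomedical Ontologies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how orthogonal a corpus of biomedical ontologies is.
    Reads OBO 1.2 flat files (or a plain term-table format) into a dated
    corpus, builds an index of normalized preferred names, produces exact
    cross-ontology lexical mappings, and partitions every mapping into
    explicit term reuse (same identifier, malformed-but-intended identifier,
    or xref cross-reference) versus independent overlap. Reports per-ontology
    and corpus-level statistics, directed reuse graphs, threshold overlap
    graphs, and deltas between corpus snapshots taken at different dates.
    Includes a seeded synthetic-corpus generator with a ground-truth manifest
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stringr,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
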