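test_that("percent rounds half-up exactly at the requested precision", {
  expect_equal(percent(412, 817, 0), 50)
  expect_equal(percent(48, 48, 0), 100)
  expect_equal(percent(109, 135, 0), 81)
  expect_equal(percent(12, 29983, 2), 0.04)
  expect_equal(percent(1, 8, 1), 12.5)
  expect_equal(percent(1, 8, 0), 13)       # tie rounds up
  expect_equal(percent(1, 800, 1), 0.1)
  expect_error(percent(1, 0), "positive")
})

test_that("percent agrees with the exact rational oracle on random pairs", {
  withr::local_seed(2024)
  n <- sample(0:100000, 10000, replace = TRUE)
  d <- sample(1:100000, 10000, replace = TRUE)
  k <- sample(0:3, 10000, replace = TRUE)
  for (kk in 0:3) {
    sel <- k == kk
    r <- percent(n[sel], d[sel], kk)
    expect_true(all(verify_half_up(n[sel], d[sel], kk, r)))
  }
})

# fixture: AO's "heart" overlaps two BO terms (two pairs, one distinct AO
# term); CO reuses AO's "lung" by same id
stats_fixture <- function(dir) {
  paths <- write_micro_corpus(dir, list(
    AO = c("[Term]", "id: AO:1", "name: heart", "",
           "[Term]", "id: AO:2", "name: lung", "",
           "[Term]", "id: AO:3", "name: spare a"),
    BO = c("[Term]", "id: BO:1", "name: Heart", "",
           "[Term]", "id: BO:2", "name: HEART"),
    CO = c("[Term]", "id: AO:2", "name: lung", "",
           "[Term]", "id: CO:2", "name: spare c")))
  # BO deliberately carries a duplicate normalized name ("Heart"/"HEART") to
  # produce one-term-to-two-terms overlap, so it is loaded under the keep
  # policy
  run_pipeline(paths,
               config = corpus_config(duplicate_name_policy = "keep",
                                      native_prefixes =
                                        list(AO = "AO", BO = "BO",
                                             CO = "CO")))
}

test_that("summarize_corpus counts pairs at corpus level, distinct terms per ontology", {
  dir <- withr::local_tempdir()
  res <- stats_fixture(dir)
  rep <- res$report
  # identity: reuse + overlap == mappings
  expect_equal(sum(rep$reuse_counts) + rep$overlap_count,
               rep$total_mappings)
  # AO:1 "heart" overlaps BO:1 and BO:2 -> two pairs, one distinct AO term
  st <- rep$ontology_stats
  expect_equal(st$overlapping_term_count[st$ontology_key == "AO"], 1)
  expect_equal(st$overlapping_term_count[st$ontology_key == "BO"], 2)
  # CO reuses AO:2 by same id and lung pairs with AO
  expect_equal(st$reused_pair_count[st$ontology_key == "CO"],
               sum(rep$reuse_counts))
  expect_true("AO" %in% st$reuse_sources[st$ontology_key == "CO"][[1]])
  # ontology with no mappings gets a zero row
  expect_equal(st$reused_pair_count[st$ontology_key == "AO"], 0)
})

test_that("reuse_fraction_of_mappings reproduces published-style ratios", {
  stub <- function(reused, overlap) {
    structure(list(total_mappings = reused + overlap,
                   reuse_counts = c(SAME_ID = reused, INTENDED_ID = 0L,
                                    XREF = 0L),
                   overlap_count = overlap),
              class = "ortho_report")
  }
  expect_equal(reuse_fraction_of_mappings(stub(17067, 9992)), 63)
  expect_equal(reuse_fraction_of_mappings(stub(10972, 9598)), 53)
  expect_equal(reuse_fraction_of_mappings(stub(0, 10)), 0)
})

test_that("reuse graph carries weights and reuser/source degrees", {
  dir <- withr::local_tempdir()
  res <- stats_fixture(dir)
  g <- build_reuse_graph(res$report)
  expect_s3_class(g, "igraph")
  expect_equal(igraph::gorder(g), 3)
  el <- igraph::as_edgelist(g)
  expect_true(all(el[, 1] == "CO"))
  expect_equal(igraph::graph_attr(g, "n_reusers"), 1)
  expect_equal(igraph::graph_attr(g, "n_sources"), nrow(unique(el)))
  # no reuse -> edgeless graph
  rep0 <- res$report
  rep0$reuse_edges <- rep0$reuse_edges[0, ]
  expect_equal(igraph::gsize(build_reuse_graph(rep0)), 0)
})

test_that("overlap graph thresholds are inclusive, asymmetric, monotone", {
  rep <- structure(list(
    snapshot_date = as.Date("2010-09-01"),
    ontology_stats = tibble::tibble(ontology_key = c("AO", "BO")),
    overlap_fractions = tibble::tibble(
      ont_from = c("AO", "BO"), ont_to = c("BO", "AO"),
      n_terms = c(3L, 5L), fraction = c(0.30, 0.05))),
    class = "ortho_report")
  expect_equal(igraph::gsize(build_overlap_graph(rep, 0.30)), 1)  # >= is in
  expect_equal(igraph::gsize(build_overlap_graph(rep, 0.31)), 0)
  expect_equal(igraph::gsize(build_overlap_graph(rep, 0.05)), 2)
  # monotone non-increasing in threshold
  sizes <- vapply(seq(0.01, 1, by = 0.01),
                  function(t) igraph::gsize(build_overlap_graph(rep, t)), 0)
  expect_true(all(diff(sizes) <= 0))
  expect_error(build_overlap_graph(rep, 0))
})

test_that("diff of a report with itself is zero; count deltas anti-symmetric", {
  dir <- withr::local_tempdir()
  res <- stats_fixture(dir)
  d0 <- diff_snapshots(res$report, res$report)
  expect_equal(d0$delta_reused, 0)
  expect_equal(d0$delta_overlap, 0)
  expect_equal(d0$delta_mappings, 0)
  expect_equal(nrow(d0$added_reuse_relationships), 0)
  expect_equal(nrow(d0$removed_reuse_relationships), 0)
  # anti-symmetry against a perturbed report
  rep2 <- res$report
  rep2$reuse_counts["SAME_ID"] <- rep2$reuse_counts["SAME_ID"] + 5L
  rep2$overlap_count <- rep2$overlap_count + 2L
  rep2$total_mappings <- rep2$total_mappings + 7L
  fwd <- diff_snapshots(res$report, rep2)
  bwd <- diff_snapshots(rep2, res$report)
  expect_equal(fwd$delta_reused, -bwd$delta_reused)
  expect_equal(fwd$delta_overlap, -bwd$delta_overlap)
  expect_equal(fwd$delta_mappings, -bwd$delta_mappings)
})

test_that("published-style deltas come out of diff_snapshots", {
  stub <- function(date, total, reused, overlap) {
    structure(list(
      snapshot_date = as.Date(date), total_terms = total,
      total_mappings = reused + overlap,
      reuse_counts = c(SAME_ID = reused, INTENDED_ID = 0L, XREF = 0L),
      overlap_count = overlap,
      ontology_stats = tibble::tibble(ontology_key = character()),
      reuse_edges = tibble::tibble(reuser = character(),
                                   source = character(),
                                   n_pairs = integer()),
      overlap_fractions = tibble::tibble(ont_from = character(),
                                         ont_to = character(),
                                         n_terms = integer(),
                                         fraction = numeric())),
      class = "ortho_report")
  }
  sep09 <- stub("2009-09-01", 272168L, 10972L, 9598L)
  sep10 <- stub("2010-09-01", 318872L, 17067L, 9992L)
  d <- diff_snapshots(sep09, sep10)
  expect_equal(d$delta_reused, 6095)
  expect_equal(d$delta_overlap, 394)
  expect_equal(d$delta_total_terms, 46704)
})

test_that("reuse_composition sums to total reuse and ignores order", {
  dir <- withr::local_tempdir()
  res <- run_pipeline(micro_corpus(dir))
  comp <- reuse_composition(res$classified)
  expect_equal(comp$kind, c("SAME_ID", "INTENDED_ID", "XREF"))
  expect_equal(sum(comp$n_pairs),
               sum(res$classified$kind != "OVERLAP"))
  withr::local_seed(4)
  shuffled <- res$classified[sample(nrow(res$classified)), ]
  expect_equal(reuse_composition(shuffled), comp)
})

test_that("report JSON round-trips through write_report/read_report", {
  dir <- withr::local_tempdir()
  res <- stats_fixture(dir)
  path <- file.path(dir, "report.json")
  write_report(res$report, path)
  back <- read_report(path)
  expect_equal(glance(back), glance(res$report))
  expect_equal(as.data.frame(tidy(back)), as.data.frame(tidy(res$report)))
  expect_equal(back$reuse_edges, res$report$reuse_edges)
  expect_equal(back$overlap_fractions, res$report$overlap_fractions,
               tolerance = 1e-12)
})

test_that("summary tables have the published shapes", {
  dir <- withr::local_tempdir()
  res <- stats_fixture(dir)
  tr <- table_reuse_extent(res$report, min_percent = 10)
  expect_true(all(tr$percent_reused >= 10))
  expect_named(tr, c("ontology_key", "reuses_from", "n_terms_reused",
                     "ontology_size", "percent_reused"))
  to <- table_overlap(res$report)
  expect_named(to, c("ontology_key", "n_overlapping_terms",
                     "ontology_size", "percent_overlapping"))
  trend <- table_trend(list(res$report, res$report))
  expect_equal(nrow(trend), 2)
  expect_equal(trend$reused[1], sum(res$report$reuse_counts))
})

test_that("autoplot and graph plots return ggplot objects", {
  dir <- withr::local_tempdir()
  res <- stats_fixture(dir)
  expect_s3_class(ggplot2::autoplot(res$report), "ggplot")
  expect_s3_class(ggplot2::autoplot(res$report, type = "overlap"), "ggplot")
  expect_s3_class(plot_reuse_graph(res$report), "ggplot")
  expect_s3_class(plot_overlap_graph(res$report, 0.3), "ggplot")
})
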