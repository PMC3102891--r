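---
title: "Measuring term reuse and overlap across an ontology corpus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring term reuse and overlap across an ontology corpus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthoscan)
```

## The problem

Coordinated ontology collections such as the OBO Foundry aim at
*orthogonality*: each concept is defined in exactly one ontology, and every
other ontology that needs the concept refers to that definition instead of
writing its own. Two failure modes are visible in the flat files
themselves:

* **term reuse** — one ontology incorporates another's term, either by
  carrying the foreign identifier directly, by carrying an identifier that
  was clearly *meant* to be the foreign one but is malformed, or by
  attaching an `xref` cross-reference to the foreign identifier. Reuse is
  the desired behaviour.
* **overlap** — two ontologies independently define terms with the same
  preferred name, with no explicit link between them. Overlap is the debt
  that stands between a corpus and orthogonality.

`orthoscan` measures both from a dated corpus of OBO 1.2 flat files, and
compares corpora taken at different dates.

## The procedure

1. **Load** (`load_corpus()`). Each file is parsed into a term table
   (identifier, preferred name, xrefs, obsolete flag). An ontology in which
   several non-obsolete terms share a normalized preferred name is excluded
   by default: one foreign name would map ambiguously to several of its
   classes, and a single such pair of intrinsically overlapping ontologies
   can dominate the whole corpus count. The `keep` policy retains and flags
   them instead.

2. **Index and normalize** (`build_label_index()`, `normalize_label()`).
   Every active term's preferred name is lower-cased and stripped of all
   non-alphanumeric characters. Entries whose normalized label has fewer
   than three characters stay in the index but are ineligible for matching
   — short strings ("GO", "pH") match promiscuously and destroy precision.

3. **Map** (`find_mappings()`). A mapping is an unordered cross-ontology
   pair of terms with identical normalized labels. Matching is exact
   equality on the normalized string: no stemming, no token reordering, no
   synonyms. Only preferred names take part. This is a deliberately
   high-precision, lower-recall design: the resulting counts are a lower
   bound on true overlap.

4. **Classify** (`classify_mappings()`). Each mapping is assigned exactly
   one kind by first-match precedence:
   `SAME_ID` (raw ids equal) → `INTENDED_ID` (canonical ids equal, raw ids
   differ) → `XREF` (either side xrefs the other's canonical id) →
   `OVERLAP`. Precedence makes the three reuse kinds disjoint portions of
   total reuse, so they can be stacked in a composition plot and summed.

5. **Summarize and compare** (`summarize_corpus()`, `diff_snapshots()`,
   `build_reuse_graph()`, `build_overlap_graph()`).

## Identifier canonicalization

Real corpora contain identifiers that were intended to reference a foreign
term but are malformed. `canonicalize_id()` repairs exactly three shapes:

* doubled prefixes: `MP:MP_0002216` → `MP:0002216` — accepted only when the
  embedded prefix is a *known corpus prefix*, so ordinary underscored local
  ids (`OBI:IAO_0000030`-style foreign curies aside) are never mangled;
* separator variants: `MP_0002216` → `MP:0002216`, same known-prefix guard;
* alias and retired prefixes: `snap:`/`span:` → `bfo` by default, with
  user-extensible alias and retired-prefix tables; resolution follows
  chains to a fixpoint and cycles are rejected at configuration time.

Prefixes are compared case-insensitively (observed OBO practice mixes
`bfo`/`BFO`); local parts case-sensitively. Canonicalization is idempotent,
which classification relies on.

### Direction of reuse

For id-based reuse the *source* is the ontology that owns the shared
identifier's prefix and the *reuser* is the other side. Ownership is not
trivially derivable from the files: the reuser's file necessarily contains
terms under the source's prefix — that is what same-id reuse *is* — so the
observed-prefix default makes most reused prefixes contested. Contested
prefixes are resolved by (1) preferring the ontology whose key equals the
prefix case-insensitively, then (2) the ontology carrying the most terms
under that prefix. Explicit `native_prefixes` overrides in the corpus
config short-circuit the heuristic. A pair whose prefix no side owns is
kept but left direction-unresolved with a warning, and such pairs are
excluded from per-ontology reuser statistics while still counting toward
corpus totals.

For xref reuse the reuser is the xref-bearing side; mutual xrefs count once
and the lexicographically smaller ontology key is taken as reuser (a
deterministic tie-break, logged when it fires).

Classification applies to lexically matched pairs only. A pair of terms
sharing an id but bearing different names never enters the mapping set and
is therefore not counted — id-sharing without name agreement is more often
a versioning accident than reuse, and counting it would make the reuse and
overlap columns incomparable.

## Counting conventions

* Corpus-level `overlap_count` counts **pairs**; per-ontology
  `overlapping_term_count` counts **distinct terms** of that ontology in at
  least one overlap pair. These are different numbers by design: one term
  of a small ontology overlapping five terms elsewhere is five pairs but
  one overlapping term.
* `reused_pair_count` for an ontology counts pairs in which it is the
  reuser; `percent_reused` divides by the ontology's active size.
* A *reuse relationship* is a directed ontology pair with at least one
  reuse pair; the reuse graph has one weighted edge per relationship.
* Overlap-graph fractions are directional: the edge O1 → O2 exists when at
  least the threshold fraction of O1's distinct active terms overlap with
  O2, so edges between a small and a large ontology are typically
  asymmetric. The comparison is inclusive (`>=`), and edge sets are
  monotonically non-increasing in the threshold. Default thresholds are
  0.10 and 0.30.
* Denominators use active (non-obsolete) term counts. Obsolete terms are
  excluded from indexing and size by default (an `include_obsolete` flag
  reverses this); counting deprecated terms would inflate overlap.

### Rounding

All displayed percentages go through `percent()`, which rounds half-up at
the requested precision using exact integer arithmetic — never floating
division followed by `round()`, whose banker's rounding makes ties
unpredictable. Published tables of this kind are not internally consistent
about rounding (some rows behave as truncation, others as rounding); one
convention had to be fixed, and half-up is the one that agrees with the
majority of worked ratios.

## The synthetic corpus generator

`generate_corpus()` builds a corpus in which every phenomenon above is
*planted* and recorded in a manifest, so the pipeline's counts can be
checked exactly rather than approximately:

* same-id plants copy a source term's (id, name) into a foreign ontology;
* intended-id plants malform the source id (doubled prefix or underscore
  separator);
* xref plants give a foreign term its own native id, a matching name, and
  an xref to the source id (occasionally a malformed xref, which the
  canonicalizer must repair);
* overlap plants share a name under unrelated native ids;
* near-miss distractors differ from a planted label by one alphanumeric
  character and must never match;
* short-label distractors normalize to under three characters and are
  planted with the *same* label in two ontologies, so a correct eligibility
  filter is the only thing keeping them out of the mapping set;
* optionally, an ontology with duplicate preferred names, to exercise the
  load-time policy.

Labels are "modifier noun" bigrams from a bundled anatomy/process-flavoured
vocabulary (globally unique outside the plants), names of matched pairs are
perturbed only by transformations normalization is contracted to collapse
(case changes, delimiter swaps, a parenthesized trailing word), and all
randomness flows from one seed, making generated files byte-reproducible.

Defaults (6 ontologies × 40 base terms; 5/3/4/6 planted
same-id/intended-id/xref/overlap pairs; 2 short labels; 3 near-misses)
keep a full pipeline run well under a second while exercising every code
path; the test suite sweeps randomized parameters across 20+ seeds. What
the generator does *not* emulate: `is_a` hierarchies (irrelevant to a
name-based analysis), synonym blocks, real-world label messiness beyond
case/delimiters (Unicode variants, British/American spelling), and scale.
Exact recovery on synthetic corpora therefore validates the mechanics of
mapping and classification, not lexical recall on real ontologies — on
real data exact name matching is known to miss semantically equal terms,
which is why its counts are lower bounds.

`generate_temporal_pair()` derives a second corpus by a planted delta (new
reuse pairs, overlap pairs upgraded to xref reuse, plain growth) so
`diff_snapshots()` can be validated against known deltas, emulating how
reuse typically enters a living corpus: an existing overlap pair gains an
explicit cross-reference.

## Numerical and degenerate-input choices

* `percent()` refuses a zero denominator (an empty ontology is an error,
  not a 0%).
* Mapping sides are ordered lexicographically (radix order, locale
  independent), and all output tables are sorted, so identical inputs give
  byte-identical outputs regardless of input order or platform locale.
* Empty corpora are fatal at load; empty mapping sets flow through
  classification and summary as zero-row tibbles.
* Digits are retained by normalization and purely numeric labels may
  match; the three-character rule applies to the *normalized* string.

## Limitations

* Exact preferred-name matching misses synonyms, spelling variants and
  morphological variation; reuse via OWL imports or semantic equivalence
  axioms is invisible in OBO term stanzas.
* The intended-id heuristic only recognizes numeric local parts under
  known prefixes; exotic malformations pass through unchanged and fall
  into overlap.
* Direction resolution is heuristic when prefix ownership is genuinely
  ambiguous and no override is supplied.
* No statistical testing of temporal trends is attempted; deltas are
  reported as-is.

## A worked run

```{r example, eval = FALSE}
out <- generate_corpus(synth_params(seed = 1))
corpus <- load_corpus(out$paths, corpus_config(), as.Date("2010-09-01"))
classified <- classify_mappings(find_mappings(build_label_index(corpus)),
                                corpus)
report <- summarize_corpus(classified, corpus)
glance(report)
autoplot(report)                 # reuse composition
plot_overlap_graph(report, 0.1)  # threshold overlap graph
```
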