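---
title: "Molecular species identification against a reference library: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Molecular species identification against a reference library: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcodeid)
```

## The identification model

`barcodeid` assigns species names to query sequences by local alignment
against a Reference Sequences Library (RSL): a curated multi-FASTA holding
one single-marker sequence per described or candidate species, each with a
unique identifier from which the species-level lineage name is parsed. The
method rests on two standard DNA-barcoding assumptions:

* the marker shows a *barcoding gap* — intraspecific divergence is clearly
  smaller than interspecific divergence, so a single percent-identity
  threshold can separate "same species" from "different species"; and
* the RSL is taxonomically reliable and reasonably complete for the group
  of interest, so the nearest reference is the correct name.

For every query, hits at or above the identity cutoff are filtered, the
highest-identity hit is retained, and the identification is either accepted
or tagged for expert checking.

### Filters and flags

For each hit the query coverage is recomputed from the alignment
coordinates (1-based, inclusive):

$$qcov = \frac{qend - qstart + 1}{qlen} \times 100$$

The aligner's own per-subject coverage column (`qcovs`) is carried along
for reference but deliberately not used: `qcovs` aggregates all HSPs of a
query–subject pair, whereas the filters below operate on single alignment
rows, and the row-level formula is the defined behaviour. Two filters
remove hits whose high identity is an artifact of a short alignment:

* query coverage **below 75%** (a hit covering exactly 75.0% survives);
* alignment length **below 90% of the subject length** (exactly 90%
  survives). The product $0.9 \times slen$ is computed in floating point
  and compared with a $10^{-9}$ guard so representable-length boundaries
  never fail spuriously.

Each surviving query's best match is the maximum-identity hit; ties break
by bitscore, then alignment length (both descending), then subject
identifier (ascending). The tie-break chain is a design choice — any
deterministic rule would do, but this one prefers the statistically
stronger alignment and makes reports byte-reproducible across platforms
and input orders. Multiple HSPs of one query–subject pair compete as
independent rows, consistent with the row-level coverage formula.

A best match is tagged for checking when its identity is *strictly* below
the similarity threshold

$$\text{similarity threshold} = 100 - intersp\_div$$

or its coverage is below 75%. Strict inequality at the threshold is an
open call (a match at exactly the threshold identity is accepted); we
chose strict because the threshold is defined as the divergence that
*separates* taxa. Tag patterns from the optional CSV are matched
case-sensitively as substrings of the subject identifier — patterns are
identifier fragments (a genus name, a collection acronym) — with a switch
for case-insensitive matching and an option to match lineage names
instead.

### Parameters

| parameter | units | default | meaning |
|---|---|---|---|
| `cutoff_pident` | % identity | 90 | search-time floor; hits below it are never reported, and queries with no hit above it are pooled as "outgroups" |
| `intersp_div` | % divergence | 3 | interspecific divergence of the marker; identifications below `100 − intersp_div` identity are tagged |
| coverage floor | % of query | 75 (fixed) | minimum fraction of the query an acceptable hit must span |
| length floor | % of subject | 90 (fixed) | minimum alignment length relative to the reference |

`cutoff_pident` and `intersp_div` are the two scientific dials; a single
`intersp_div` per run is assumed (heterogeneous groups should be split and
run separately with their own thresholds — a usage pattern, not a code
path). The 75% and 90% floors are part of the method's definition.

### Summary statistics

A run reports: total RSL lineages; taxonomic coverage
$= 100 \times \text{matched lineages} / \text{total lineages}$; taxa
without a sample; total input sequences; percent processed (100 on any
correct run — every query lands in exactly one of the best-match set or
the below-cutoff pool, a partition the code asserts); and the outgroup
count. Percentages print as integers when whole, else to one decimal.

## Synthetic data: what it emulates and what it does not

The fixture generator builds the entire test universe in code:

* `sim_rsl()` — `n_lineages` random sequences (default 25) of
  `ref_length` bp (default 600, a typical barcode fragment length for
  mitochondrial markers) with binomial-style identifiers;
* `sim_queries()` — matched queries derived from references by an exact
  number of point substitutions, `round(d · L / 100)` for divergence *d*,
  plus fresh random outgroup sequences. Substitution-only mutation keeps
  the percent identity available in closed form, $100(1 - subs/L)$,
  independent of any aligner; indels would make identity
  alignment-dependent. Substitutions stay 25 bp clear of both sequence
  ends so that a local aligner recovers the full end-to-end alignment and
  the closed form holds in aligner mode too. The defaults — divergences
  (0, 0, 0.5, 1, 1.5, 2, 4, 5, 6)% cycling over 7 source lineages, one
  outgroup — emulate a small identification batch in which three
  identifications fall in the "check me" band between `cutoff_pident` 90
  and the 97% threshold;
* `sim_hit_table()` — the extended tabular file the aligner would
  produce: one full-length hit per matched query at the constructed
  identity, optional lower-identity "secondary" competitors and
  low-coverage "decoy" rows that the filters must remove, and no rows for
  outgroups.

What passing on these fixtures shows: the parsing, filtering, selection,
flagging, aggregation and reporting logic is exact. What it does not
show: behaviour on real sequences with indels, heterogeneous rate
variation, chimeras, or references of unequal length — there the aligner's
alignments (and hence identities and coverages) are approximations the
generator does not model. The aligner-mode tests close part of that gap by
checking that `blastn` on substitution-only queries reproduces the
hit-table-mode report and the closed-form identities to within 0.01.

## Numerical and interface choices

* **Tabular, not XML** aligner output: smaller, diffable, parseable line
  by line with per-line error reporting. The field order is the 12
  standard tabular fields plus `qlen slen gaps qcovs`.
* Writing hits mirrors the aligner's precision (identity to 3 decimals,
  bitscore to 1), so write–read round-trips are lossless at that
  precision; the round-trip is property-tested on randomized tables.
* The identity cutoff is enforced twice: at the aligner via
  `-perc_identity` and again when a pre-computed table is read, so
  external files obey the same contract.
* In hit-table mode the pipeline additionally needs the full query-id
  universe (`query_ids` or a query FASTA) to count no-hit queries;
  without it, ids absent from the table would be invisible and the
  outgroup pool undercounted.
* Degenerate inputs are defined, not errors: an empty query set or empty
  hit table yields a complete report with empty bodies and
  `percent processed = 100`; an RSL lineage with no sample appears with
  an empty query list.
* The XLSX report is produced by a small built-in writer (stored-entry
  ZIP container, inline-string worksheets, CRC-32 via `digest`); rows
  tagged for identity are filled red, rows tagged only for coverage or by
  a CSV warning amber — the colour for non-identity tags is a choice, as
  only "red for identity" is conventional. A `flag` column carries the
  same information machine-readably, and the four-file TSV mode is
  byte-stable for diff-based comparison. Sheet names (`BestMatches`,
  `ToCheck`, `Lineages`, `Summary`) are this package's own.
* Lineage parsing defaults to the first two underscore tokens of the
  identifier (binomial headers); a whole-identifier convention and a
  user regex cover candidate-species naming schemes, which is why no
  fixed rule is imposed.

## Problem sizes in the test suite

The suite runs entirely on generated data: the study-scale scenario
(25 references, 10 queries), write–read round-trips on a few dozen
randomized tables, best-match selection checked against a brute-force
oracle on 1000 small randomized tables, and two end-to-end `blastn` runs
(skipped automatically when BLAST+ is absent). These sizes exercise every
code path while keeping the default run fast; the pipeline itself is
linear in the number of hits and has no practical scale limit below
memory.

## Known limitations

* One `intersp_div` per run; no per-taxon thresholds.
* No multi-marker orchestration, no protein-space search, no remote BLAST.
* No phylogenetic placement or barcoding-gap estimation: the threshold is
  an input, not something the package infers.
* Identification quality is bounded by the RSL: an incomplete or
  misidentified reference library propagates directly into the output,
  which is why the per-lineage roll-up and the checking flags exist.
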