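# barcodeid

Automated molecular species identification from local BLAST searches
against a curated Reference Sequences Library (RSL).

## The problem

DNA-barcoding studies routinely need to assign species names to hundreds of
newly generated marker sequences. Searching public databases is error-prone
(mislabelled or taxonomically outdated entries), and hand-filtering web
BLAST output does not scale. When a taxonomically reliable RSL is available
— one single-marker sequence per described or candidate species, each with
a unique identifier — the whole assignment becomes a reproducible local
workflow. `barcodeid` automates it in five steps:

1. build a local nucleotide database from the RSL (`makeblastdb`);
2. run local `blastn` of the input sequences with an extended 16-field
   tabular output (the 12 standard fields plus `qlen`, `slen`, `gaps`,
   `qcovs`), keeping hits with identity ≥ the user's `cutoff_pident`;
3. parse and filter the hits: recompute the query coverage as
   `qcov = (qend − qstart + 1) / qlen × 100` and drop hits with
   `qcov < 75%` or alignment length `< 90%` of the subject length, then
   sort by percent identity and retrieve the best match per query;
4. tag matches for further checking when their identity falls below the
   similarity threshold `100 − intersp_div` (with `intersp_div` the
   interspecific divergence of the marker) or when a user-supplied CSV of
   taxon-specific warnings applies;
5. write a four-sheet spreadsheet report (best matches; all hits of the
   tagged queries; a per-lineage roll-up plus the pool of sequences below
   the cutoff, the "outgroups"; summary statistics including the taxonomic
   coverage of the RSL).

The filtering/reporting core also runs on pre-computed hit tables, so the
pipeline works (and is tested) without the external aligner installed.

## Worked example

A synthetic batch emulating a typical identification run: a 25-lineage RSL,
nine in-group queries drawn from seven lineages (three of them more than 3%
diverged from their reference) and one unrelated outgroup sequence.

```r
library(barcodeid)

rsl  <- sim_rsl(n_lineages = 25, ref_length = 600, seed = 5)
qs   <- sim_queries(rsl, seed = 6)                 # 9 matched + 1 outgroup
hits <- sim_hit_table(qs$truth, rsl)               # stands in for blastn

res <- run_identification(rsl, hits = hits, query_ids = qs$queries$seq_id,
                          cutoff_pident = 90, intersp_div = 3)
res
#> Molecular species identification
#>   cutoff_pident 90%, intersp_div 3% (similarity threshold 97%)
#>   10 input sequences: 9 best matches (3 tagged for checking), 1 below cutoff
#>   taxonomic coverage 28% (7 of 25 lineages), 18 taxa without a sample

write_report(res$report, "results.xlsx")           # or format = "tsv"
```

The nine queries each get their true source lineage back at the exact
constructed identity; the three matches below the 97% similarity threshold
are flagged (red rows in the workbook), and the outgroup — which has no
retained hit at ≥ 90% identity — is pooled below the cutoff, so 100% of the
sequences are processed. `tidy(res)` returns the best-match tibble,
`glance(res)` the one-row summary, `autoplot(res)` an identity-vs-coverage
overview.

The same run from a shell, with the real aligner:

```sh
inst/cli/barcodeid run --rsl rsl.fasta --queries queries.fasta \
    --cutoff-pident 90 --intersp-div 3 --tags Check_tags.csv \
    --out results.xlsx
```

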