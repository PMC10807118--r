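# Shared fixture builders and the independent best-match oracle.

tiny_rsl <- function(n = 5, L = 200, seed = 42) sim_rsl(n, L, seed = seed)

# one hit row with sensible defaults, overridable field-by-field
make_hit <- function(qseqid = "q1", sseqid = "s1", pident = 99,
                     aln_len = 100L, mismatch = 1L, gapopen = 0L,
                     qstart = 1L, qend = 100L, sstart = 1L, send = 100L,
                     evalue = 1e-50, bitscore = 180, qlen = 100L,
                     slen = 100L, gaps = 0L, qcovs = 100) {
  tibble::tibble(qseqid = qseqid, sseqid = sseqid, pident = pident,
                 aln_len = as.integer(aln_len), mismatch = as.integer(mismatch),
                 gapopen = as.integer(gapopen), qstart = as.integer(qstart),
                 qend = as.integer(qend), sstart = as.integer(sstart),
                 send = as.integer(send), evalue = evalue, bitscore = bitscore,
                 qlen = as.integer(qlen), slen = as.integer(slen),
                 gaps = as.integer(gaps), qcovs = qcovs)
}

# random hit table at aligner precision (pident 3 dp, bitscore 1 dp,
# evalue a power of ten), so tabular writing round-trips losslessly
random_hit_table <- function(n_rows, n_queries = 3, n_subjects = 4) {
  qlen <- sample(80:400, n_rows, replace = TRUE)
  qstart <- vapply(qlen, function(L) sample.int(L, 1), integer(1))
  # sample() would misbehave on a length-1 range, so index explicitly
  qend <- vapply(seq_len(n_rows), function(i) {
    rng <- qstart[i]:qlen[i]
    rng[sample.int(length(rng), 1)]
  }, integer(1))
  slen <- sample(80:400, n_rows, replace = TRUE)
  aln <- pmax(1L, qend - qstart + 1L)
  tibble::tibble(
    qseqid = sample(sprintf("q%d", seq_len(n_queries)), n_rows, replace = TRUE),
    sseqid = sample(sprintf("s%d", seq_len(n_subjects)), n_rows, replace = TRUE),
    pident = round(stats::runif(n_rows, 80, 100), 3),
    aln_len = aln,
    mismatch = sample(0:10, n_rows, replace = TRUE),
    gapopen = sample(0:2, n_rows, replace = TRUE),
    qstart = qstart, qend = qend,
    sstart = rep(1L, n_rows), send = slen,
    evalue = 10^-sample(5:100, n_rows, replace = TRUE),
    bitscore = round(stats::runif(n_rows, 50, 700), 1),
    qlen = qlen, slen = slen,
    gaps = sample(0:3, n_rows, replace = TRUE),
    qcovs = round(100 * aln / qlen)
  )
}

# brute-force oracle: per query, scan every retained hit for max pident,
# breaking ties by bitscore desc, aln_len desc, sseqid asc
oracle_best <- function(evaluated) {
  out <- list()
  for (q in unique(evaluated$qseqid)) {
    rows <- evaluated[evaluated$qseqid == q, ]
    best <- rows[1, ]
    for (i in seq_len(nrow(rows))[-1]) {
      r <- rows[i, ]
      better <- (r$pident > best$pident) ||
        (r$pident == best$pident && r$bitscore > best$bitscore) ||
        (r$pident == best$pident && r$bitscore == best$bitscore &&
           r$aln_len > best$aln_len) ||
        (r$pident == best$pident && r$bitscore == best$bitscore &&
           r$aln_len == best$aln_len && r$sseqid < best$sseqid)
      if (better) best <- r
    }
    out[[q]] <- best
  }
  dplyr::bind_rows(out)
}

# the standard small study scenario: 25-lineage RSL, 9 matched queries
# over 7 lineages (3 of them in [90, 97)), 1 outgroup
scenario_fixture <- function(seed = 7, ...) {
  rsl <- sim_rsl(seed = seed)
  qs <- sim_queries(rsl, seed = seed + 1)
  hits <- sim_hit_table(qs$truth, rsl, seed = seed + 2, ...)
  list(rsl = rsl, queries = qs$queries, truth = qs$truth, hits = hits)
}

empty_best_matches_for_test <- function() {
  best_match_per_query(evaluate_hits(random_hit_table(0)), tiny_rsl(), 97)
}

# read one stored (uncompressed) entry of a workbook archive as text
unz_sheet <- function(zip_path, entry) {
  con <- unz(zip_path, entry, open = "rb")
  on.exit(close(con))
  rawToChar(readBin(con, "raw", 10e6))
}

HIT_FIELDS_for_test <- function() {
  c("qseqid", "sseqid", "pident", "aln_len", "mismatch", "gapopen",
    "qstart", "qend", "sstart", "send", "evalue", "bitscore",
    "qlen", "slen", "gaps", "qcovs")
}
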