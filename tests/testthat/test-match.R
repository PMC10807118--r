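test_that("query coverage follows the stated formula", {
  expect_equal(compute_qcov(1, 100, 100), 100)
  expect_equal(compute_qcov(26, 100, 100), 75)
  expect_equal(compute_qcov(11, 17, 20), 35)
  expect_equal(compute_qcov(1, 74, 100), 74)
  expect_error(compute_qcov(0, 10, 20), class = "barcodeid_bad_parameter")
  expect_error(compute_qcov(10, 5, 20), class = "barcodeid_bad_parameter")
  expect_error(compute_qcov(1, 30, 20), class = "barcodeid_bad_parameter")
})

test_that("similarity threshold is 100 minus the interspecific divergence", {
  expect_equal(similarity_threshold(3), 97)
  expect_equal(similarity_threshold(0), 100)
  expect_equal(similarity_threshold(12.5), 87.5)
  expect_error(similarity_threshold(-1), class = "barcodeid_bad_parameter")
  expect_error(similarity_threshold(100), class = "barcodeid_bad_parameter")
})

test_that("filters drop low-coverage and short-alignment hits, keeping boundaries", {
  hits <- dplyr::bind_rows(
    make_hit(qseqid = "below_cov", qstart = 1L, qend = 74L, aln_len = 74L),
    make_hit(qseqid = "at_cov", qstart = 26L, qend = 100L, aln_len = 75L,
             slen = 80L, send = 80L),
    make_hit(qseqid = "short_aln", aln_len = 89L, qstart = 1L, qend = 89L,
             slen = 100L),
    make_hit(qseqid = "at_len", aln_len = 90L, qstart = 1L, qend = 90L,
             slen = 100L),
    make_hit(qseqid = "clean")
  )
  kept <- filter_hits(hits)
  expect_equal(kept$qseqid, c("at_cov", "at_len", "clean"))
  expect_true(all(kept$qcov >= 75))
  expect_true(all(kept$aln_len >= 0.90 * kept$slen - 1e-9))
  # annotated flags agree with retention
  ev <- evaluate_hits(hits)
  expect_equal(ev$passes_qcov_filter & ev$passes_length_filter,
               hits$qseqid %in% kept$qseqid)
  # idempotent, order-preserving, empty-safe
  expect_equal(filter_hits(kept[names(hits)]), kept)
  expect_equal(nrow(filter_hits(hits[0, ])), 0)
})

test_that("the 90%-of-subject-length boundary is float-safe", {
  # 0.9 * 610 = 549 cannot be represented exactly in binary floating point
  h <- make_hit(aln_len = 549L, qstart = 1L, qend = 549L,
                qlen = 610L, slen = 610L)
  expect_equal(nrow(filter_hits(h)), 1)
})

test_that("best match takes max identity with deterministic tie-breaks", {
  rsl <- tiny_rsl()
  hits <- dplyr::bind_rows(
    make_hit(qseqid = "q1", sseqid = rsl$seq_id[1], pident = 99.1),
    make_hit(qseqid = "q1", sseqid = rsl$seq_id[2], pident = 96.0),
    make_hit(qseqid = "q2", sseqid = rsl$seq_id[1], pident = 98, bitscore = 100),
    make_hit(qseqid = "q2", sseqid = rsl$seq_id[2], pident = 98, bitscore = 150),
    make_hit(qseqid = "q3", sseqid = rsl$seq_id[3], pident = 98, bitscore = 150),
    make_hit(qseqid = "q3", sseqid = rsl$seq_id[2], pident = 98, bitscore = 150)
  )
  best <- best_match_per_query(evaluate_hits(hits), rsl, threshold = 97)
  expect_equal(best$qseqid, c("q1", "q2", "q3"))
  expect_equal(best$pident[best$qseqid == "q1"], 99.1)
  expect_false(best$check_identity[best$qseqid == "q1"])
  expect_equal(best$sseqid[best$qseqid == "q2"], rsl$seq_id[2])  # bitscore wins
  expect_equal(best$sseqid[best$qseqid == "q3"], rsl$seq_id[2])  # sseqid asc
  expect_equal(best$lineage, rsl$lineage[match(best$sseqid, rsl$seq_id)])
})

test_that("identity below the similarity threshold is flagged, strictly", {
  rsl <- tiny_rsl()
  ev <- evaluate_hits(dplyr::bind_rows(
    make_hit(qseqid = "low", sseqid = rsl$seq_id[1], pident = 95.0),
    make_hit(qseqid = "at", sseqid = rsl$seq_id[2], pident = 97.0)
  ))
  best <- best_match_per_query(ev, rsl, threshold = 97)
  expect_true(best$check_identity[best$qseqid == "low"])
  expect_false(best$check_identity[best$qseqid == "at"])
  expect_false(any(best$check_coverage))
})

test_that("unresolvable subject identifiers fall back to sseqid with a note", {
  rsl <- tiny_rsl()
  ev <- evaluate_hits(make_hit(qseqid = "q1", sseqid = "not_in_rsl_X"))
  best <- best_match_per_query(ev, rsl, threshold = 97)
  expect_equal(best$lineage, "not_in_rsl_X")
  expect_match(best$notes[[1]], "not found in RSL")
})

test_that("best-match selection agrees with the brute-force oracle", {
  withr::local_seed(202)
  rsl <- tiny_rsl()
  for (rep in 1:50) {
    ev <- filter_hits(random_hit_table(sample(2:30, 1)))
    if (nrow(ev) == 0) next
    best <- best_match_per_query(ev, rsl, threshold = 97)
    oracle <- oracle_best(ev)
    oracle <- oracle[match(best$qseqid, oracle$qseqid), ]
    expect_equal(best$sseqid, oracle$sseqid)
    expect_equal(best$pident, oracle$pident)
  }
})

test_that("check tags load from CSV, with and without header", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("pattern,message", "Mantella,genus-level id only",
               "MRSN,check voucher"), p)
  tags <- read_check_tags(p)
  expect_equal(nrow(tags), 2)
  expect_equal(tags$pattern, c("Mantella", "MRSN"))

  p2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("Mantella,genus-level id only"), p2)
  expect_equal(nrow(read_check_tags(p2)), 1)

  expect_equal(nrow(read_check_tags(NULL)), 0)
  expect_equal(nrow(read_check_tags(file.path(tempdir(), "absent.csv"))), 0)

  p3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("A,ok", ",missing pattern"), p3)
  expect_error(read_check_tags(p3), "row 2", class = "barcodeid_bad_tags")
})

test_that("tag patterns match subject identifiers as substrings", {
  rsl <- tibble::tibble(seq_id = "Mantella_aurantiaca_MRSN1234",
                        lineage = "Mantella_aurantiaca",
                        sequence = "ACGT")
  best <- best_match_per_query(
    evaluate_hits(make_hit(qseqid = "q1", sseqid = rsl$seq_id[1])),
    rsl, threshold = 97)
  tags <- tibble::tibble(pattern = c("Mantella", "MRSN", "mantella"),
                         message = c("genus-level id only", "check voucher",
                                     "lowercase should not hit"))
  tagged <- apply_check_tags(best, tags)
  expect_equal(tagged$notes[[1]], c("genus-level id only", "check voucher"))
  # case-insensitive switch
  loose <- apply_check_tags(best, tags, case_sensitive = FALSE)
  expect_equal(length(loose$notes[[1]]), 3)
  # no tags -> unchanged
  expect_identical(apply_check_tags(best, read_check_tags(NULL)), best)
})

test_that("lineage roll-up covers every RSL lineage and pools unmatched queries", {
  fix <- scenario_fixture()
  res <- run_identification(fix$rsl, hits = fix$hits,
                            query_ids = fix$queries$seq_id)
  agg <- aggregate_by_lineage(res$best_matches, fix$rsl, fix$queries$seq_id)
  expect_equal(nrow(agg$rollup), 25)
  expect_equal(sum(agg$rollup$n_queries > 0), 7)
  expect_equal(sum(agg$rollup$n_queries == 0), 18)
  expect_setequal(unlist(agg$rollup$query_ids), res$best_matches$qseqid)
  expect_equal(agg$below_cutoff, "OUT01")
  # no queries at all
  empty <- aggregate_by_lineage(empty_best_matches_for_test(), fix$rsl,
                                character(0))
  expect_equal(nrow(empty$rollup), 25)
  expect_true(all(empty$rollup$n_queries == 0))
  expect_equal(length(empty$below_cutoff), 0)
})

test_that("summary statistics satisfy their defining identities", {
  fix <- scenario_fixture()
  res <- run_identification(fix$rsl, hits = fix$hits,
                            query_ids = fix$queries$seq_id)
  s <- res$summary
  expect_equal(s$taxonomic_coverage, 100 * s$lineages_matched / s$total_lineages)
  expect_equal(s$taxa_without_sample, s$total_lineages - s$lineages_matched)
  expect_equal(s$percent_processed, 100)
  expect_equal(s$n_best_matches + s$n_below_cutoff, s$total_queries)
  # inconsistent inputs are an internal error
  expect_error(
    compute_summary(fix$rsl, res$best_matches, res$below_cutoff,
                    total_queries = 2),
    class = "barcodeid_internal_error"
  )
  # zero matches of L lineages -> coverage 0
  s0 <- compute_summary(fix$rsl, empty_best_matches_for_test(), "q1", 1)
  expect_equal(s0$taxonomic_coverage, 0)
  expect_equal(s0$taxa_without_sample, 25)
})

test_that("raising intersp_div never increases the identity-flag count", {
  fix <- scenario_fixture()
  ev <- filter_hits(fix$hits)
  flags <- vapply(seq(0, 10, by = 0.5), function(div) {
    best <- best_match_per_query(ev, fix$rsl, similarity_threshold(div))
    sum(best$check_identity)
  }, numeric(1))
  expect_true(all(diff(flags) <= 0))
})
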