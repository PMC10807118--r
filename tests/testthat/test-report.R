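scenario_result <- function(seed = 7, tags = NULL, ...) {
  fix <- scenario_fixture(seed = seed, ...)
  run_identification(fix$rsl, hits = fix$hits,
                     query_ids = fix$queries$seq_id, tags = tags)
}

test_that("the bundle holds four consistent sheets", {
  res <- scenario_result()
  b <- res$report
  expect_s3_class(b, "report_bundle")
  expect_named(b, c("best_matches", "to_check", "lineages", "summary"))
  expect_equal(nrow(b$best_matches), 9)
  expect_equal(sum(grepl("identity", b$best_matches$flag)), 3)
  # sheet 2 only carries flagged queries, ordered by identity
  flagged <- b$best_matches$qseqid[nzchar(b$best_matches$flag)]
  expect_true(all(b$to_check$qseqid %in% flagged))
  expect_true(all(diff(b$to_check$pident) <= 0))
  # sheet 1 rows + below-cutoff pool = total queries
  expect_equal(nrow(b$best_matches) + res$summary$n_below_cutoff,
               res$summary$total_queries)
})

test_that("a run with no queries still yields four sheets with stats", {
  rsl <- tiny_rsl()
  res <- run_identification(rsl, hits = random_hit_table(0),
                            query_ids = character(0))
  b <- res$report
  expect_equal(nrow(b$best_matches), 0)
  expect_equal(nrow(b$to_check), 0)
  expect_equal(nrow(b$lineages), nrow(rsl))
  expect_equal(nrow(b$summary), 8)
  expect_equal(res$summary$percent_processed, 100)
})

test_that("clean matches leave the checking sheet empty", {
  fix <- scenario_fixture()
  clean_truth <- fix$truth[!is.na(fix$truth$n_subs) & fix$truth$n_subs == 0, ]
  hits <- sim_hit_table(clean_truth, fix$rsl)
  res <- run_identification(fix$rsl, hits = hits,
                            query_ids = clean_truth$query_id)
  expect_equal(nrow(res$report$to_check), 0)
  expect_true(all(res$report$best_matches$flag == ""))
})

test_that("the workbook reproduces the bundle's cell values on read-back", {
  res <- scenario_result()
  path <- withr::local_tempfile(fileext = ".xlsx")
  write_report(res$report, path)
  sheets <- readxl::excel_sheets(path)
  expect_equal(sheets, c("BestMatches", "ToCheck", "Lineages", "Summary"))
  for (pair in list(c("BestMatches", "best_matches"), c("ToCheck", "to_check"),
                    c("Lineages", "lineages"), c("Summary", "summary"))) {
    got <- readxl::read_xlsx(path, sheet = pair[1])
    want <- res$report[[pair[2]]]
    expect_equal(dim(got), dim(want))
    expect_equal(names(got), names(want))
    for (col in names(want)) {
      w <- want[[col]]
      g <- got[[col]]
      if (is.character(w)) {
        w[!nzchar(w)] <- NA_character_  # empty cells come back as NA
        expect_equal(as.character(g), w)
      } else {
        expect_equal(as.numeric(g), as.numeric(w))
      }
    }
  }
})

test_that("TSV mode writes four byte-stable sheet files", {
  res <- scenario_result()
  d <- withr::local_tempdir()
  p1 <- write_report(res$report, file.path(d, "run1.tsv"), format = "tsv")
  p2 <- write_report(res$report, file.path(d, "run2.tsv"), format = "tsv")
  expect_equal(basename(p1),
               paste0("run1_", c("BestMatches", "ToCheck", "Lineages",
                                 "Summary"), ".tsv"))
  for (i in seq_along(p1)) {
    expect_identical(readBin(p1[i], "raw", file.size(p1[i])),
                     readBin(p2[i], "raw", file.size(p2[i])))
  }
})

test_that("identity flags colour rows red, tag/coverage flags amber", {
  tagf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("pattern,message", "Genus1_,marker lacks resolution here"), tagf)
  res <- scenario_result(tags = tagf)
  path <- withr::local_tempfile(fileext = ".xlsx")
  write_report(res$report, path)
  # styles live in sheet1's XML: s="2" red fill, s="3" amber fill
  con <- unz_sheet(path, "xl/worksheets/sheet1.xml")
  n_red_rows <- lengths(regmatches(con, gregexpr('<row r="\\d+"><c[^>]* s="2"', con)))
  n_amber_rows <- lengths(regmatches(con, gregexpr('<row r="\\d+"><c[^>]* s="3"', con)))
  expect_equal(n_red_rows, sum(grepl("identity", res$report$best_matches$flag)))
  expect_equal(n_amber_rows,
               sum(nzchar(res$report$best_matches$flag) &
                     !grepl("identity", res$report$best_matches$flag)))
  expect_gt(n_amber_rows, 0)
})
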