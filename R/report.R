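SHEET_NAMES <- c("BestMatches", "ToCheck", "Lineages", "Summary")

flag_label <- function(matches) {
  purrr::pmap_chr(
    list(matches$check_identity, matches$check_coverage,
         lengths(matches$notes) > 0L),
    function(id, cov, tag) {
      paste(c(if (id) "identity", if (cov) "coverage", if (tag) "tag"),
            collapse = ";")
    }
  )
}

#' Assemble the four-sheet report bundle
#'
#' Sheet 1 lists every input sequence with its best match and the alignment
#' metrics needed to evaluate it; a machine-readable `flag` column mirrors
#' the spreadsheet colouring so tab-separated output loses no information.
#' Sheet 2 repeats all retained hits for the queries tagged for further
#' checking, ordered by identity. Sheet 3 is the per-lineage roll-up plus
#' the below-cutoff pool. Sheet 4 holds the summary statistics.
#'
#' @param matches Best matches from [best_match_per_query()] (after
#'   [apply_check_tags()]).
#' @param evaluated_hits Retained hits from [filter_hits()] (used to fill
#'   sheet 2 for flagged queries).
#' @param rollup_result List from [aggregate_by_lineage()].
#' @param stats One-row tibble from [compute_summary()].
#' @return An object of class `report_bundle`: a named list of four tibbles
#'   (`best_matches`, `to_check`, `lineages`, `summary`).
#' @export
build_report <- function(matches, evaluated_hits, rollup_result, stats) {
  flags <- flag_label(matches)
  sheet1 <- tibble::tibble(
    qseqid = matches$qseqid,
    sseqid = matches$sseqid,
    lineage = matches$lineage,
    pident = matches$pident,
    qcov = matches$qcov,
    qlen = matches$qlen,
    slen = matches$slen,
    aln_len = matches$aln_len,
    evalue = matches$evalue,
    flag = flags,
    notes = purrr::map_chr(matches$notes, paste, collapse = "; ")
  )
  flagged_q <- matches$qseqid[is_flagged(matches)]
  sheet2 <- evaluated_hits |>
    dplyr::filter(.data$qseqid %in% flagged_q) |>
    dplyr::arrange(dplyr::desc(.data$pident), .data$qseqid, .data$sseqid) |>
    dplyr::select("qseqid", "sseqid", "pident", "qcov", "qlen", "slen",
                  "aln_len", "evalue", "bitscore")
  below <- rollup_result$below_cutoff
  sheet3 <- tibble::tibble(
    lineage = c(rollup_result$rollup$lineage,
                if (length(below) > 0L) "[below cutoff_pident]"),
    query_ids = c(purrr::map_chr(rollup_result$rollup$query_ids,
                                 paste, collapse = ", "),
                  if (length(below) > 0L) paste(below, collapse = ", ")),
    n_queries = c(rollup_result$rollup$n_queries,
                  if (length(below) > 0L) length(below))
  )
  sheet4 <- tibble::tibble(
    statistic = c("Total lineages in RSL", "Lineages matched",
                  "Taxonomic coverage (%)", "Taxa without a sample",
                  "Total input sequences", "Best matches reported",
                  "Sequences below cutoff_pident", "Sequences processed (%)"),
    value = as.numeric(c(stats$total_lineages, stats$lineages_matched,
                         stats$taxonomic_coverage, stats$taxa_without_sample,
                         stats$total_queries, stats$n_best_matches,
                         stats$n_below_cutoff, stats$percent_processed))
  )
  if (!all(sheet2$qseqid %in% flagged_q)) {
    rlang::abort("Internal inconsistency: sheet 2 contains unflagged queries.",
                 class = "barcodeid_internal_error")
  }
  if (nrow(sheet1) + length(below) != stats$total_queries) {
    rlang::abort(
      "Internal inconsistency: best matches + below-cutoff pool != total queries.",
      class = "barcodeid_internal_error"
    )
  }
  structure(
    list(best_matches = sheet1, to_check = sheet2,
         lineages = sheet3, summary = sheet4),
    class = "report_bundle"
  )
}

#' Write the report to disk
#'
#' Either a single XLSX workbook with four named sheets (`BestMatches`,
#' `ToCheck`, `Lineages`, `Summary`), identity-flagged rows filled red,
#' coverage- or tag-flagged rows amber, header row frozen — or four
#' tab-separated files (suffix `_<SheetName>.tsv`), which are byte-stable
#' across runs and convenient for diffing.
#'
#' @param bundle A `report_bundle` from [build_report()].
#' @param path Output path. In TSV mode, used as the prefix of the four
#'   files (a trailing `.tsv`/`.xlsx` is stripped).
#' @param format `"xlsx"` or `"tsv"`.
#' @return Invisibly, the path(s) written.
#' @export
write_report <- function(bundle, path, format = c("xlsx", "tsv")) {
  format <- rlang::arg_match(format)
  stopifnot(inherits(bundle, "report_bundle"))
  sheets <- rlang::set_names(
    list(bundle$best_matches, bundle$to_check, bundle$lineages, bundle$summary),
    SHEET_NAMES
  )
  if (format == "tsv") {
    prefix <- sub("\\.(tsv|xlsx)$", "", path)
    paths <- purrr::imap_chr(sheets, function(df, name) {
      p <- paste0(prefix, "_", name, ".tsv")
      readr::write_tsv(df, p, progress = FALSE)
      p
    })
    return(invisible(unname(paths)))
  }
  # row styles: 1 = red (identity), 2 = amber (coverage or tag note)
  s1_style <- ifelse(grepl("identity", bundle$best_matches$flag), 1L,
                     ifelse(nzchar(bundle$best_matches$flag), 2L, 0L))
  styles <- list(
    BestMatches = s1_style,
    ToCheck = integer(nrow(bundle$to_check)),
    Lineages = integer(nrow(bundle$lineages)),
    Summary = integer(nrow(bundle$summary))
  )
  xlsx_write(sheets, path, row_styles = styles)
  invisible(path)
}
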