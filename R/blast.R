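#' @importFrom rlang %||% .data
NULL

# The extended tabular format: the 12 standard outfmt-6 fields plus
# qlen, slen, gaps and qcovs, in that order.
HIT_FIELDS <- c("qseqid", "sseqid", "pident", "aln_len", "mismatch", "gapopen",
                "qstart", "qend", "sstart", "send", "evalue", "bitscore",
                "qlen", "slen", "gaps", "qcovs")
HIT_CHARACTER <- c("qseqid", "sseqid")
HIT_INTEGER <- c("aln_len", "mismatch", "gapopen", "qstart", "qend",
                 "sstart", "send", "qlen", "slen", "gaps")

#' The extended tabular output format specifier
#'
#' The `-outfmt` string passed to `blastn`: the 12 standard tabular fields
#' plus query length, subject length, gap count and aligner-reported query
#' coverage per subject.
#'
#' @return A single string suitable for `blastn -outfmt`.
#' @export
blast_outfmt <- function() {
  paste("6 qseqid sseqid pident length mismatch gapopen qstart qend",
        "sstart send evalue bitscore qlen slen gaps qcovs")
}

validate_hits <- function(hits, where = "hit table") {
  err <- function(msg, cls) {
    rlang::abort(sprintf("%s: %s", where, msg), class = cls)
  }
  with(hits, {
    if (any(pident < 0 | pident > 100))
      err("pident outside [0, 100]", "barcodeid_bad_hit")
    if (any(aln_len < 1L))
      err("alignment length < 1", "barcodeid_bad_hit")
    if (any(qstart < 1L | qstart > qend | qend > qlen))
      err("query coordinates violate 1 <= qstart <= qend <= qlen",
          "barcodeid_bad_hit")
    if (any(sstart < 1L | sstart > slen | send < 1L | send > slen))
      err("subject coordinates outside [1, slen]", "barcodeid_bad_hit")
    if (any(evalue < 0) || any(bitscore < 0))
      err("negative evalue or bitscore", "barcodeid_bad_hit")
  })
  invisible(hits)
}

#' Read an extended tabular hit file
#'
#' Parses the 16-field tab-separated alignment result (see [blast_outfmt()]).
#' Comment lines starting with `#` are skipped; row order is preserved.
#' Rows with the wrong field count or unparseable numerics are reported with
#' their line number.
#'
#' @param path Path to the tabular file.
#' @return A tibble with one row per hit and the 16 columns `qseqid`,
#'   `sseqid`, `pident`, `aln_len`, `mismatch`, `gapopen`, `qstart`, `qend`,
#'   `sstart`, `send`, `evalue`, `bitscore`, `qlen`, `slen`, `gaps`, `qcovs`.
#' @seealso [write_hit_table()], [run_blastn()]
#' @export
read_hit_table <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("Hit table not found: %s", path),
                 class = "barcodeid_missing_file")
  }
  lines <- readr::read_lines(path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) return(empty_hit_table())
  parts <- stringr::str_split(lines, stringr::fixed("\t"))
  nf <- lengths(parts)
  if (any(nf != 16L)) {
    bad <- which(nf != 16L)[1L]
    rlang::abort(
      sprintf("Line %d of '%s' has %d tab-separated fields; 16 expected.",
              lineno[bad], path, nf[bad]),
      class = "barcodeid_bad_columns"
    )
  }
  m <- matrix(unlist(parts), ncol = 16L, byrow = TRUE)
  colnames(m) <- HIT_FIELDS
  hits <- tibble::as_tibble(m)
  for (col in setdiff(HIT_FIELDS, HIT_CHARACTER)) {
    val <- suppressWarnings(as.numeric(hits[[col]]))
    if (anyNA(val)) {
      bad <- which(is.na(val))[1L]
      rlang::abort(
        sprintf("Line %d of '%s': field '%s' value '%s' is not numeric.",
                lineno[bad], path, col, hits[[col]][bad]),
        class = "barcodeid_bad_numeric"
      )
    }
    hits[[col]] <- if (col %in% HIT_INTEGER) as.integer(val) else val
  }
  validate_hits(hits, where = path)
  hits
}

empty_hit_table <- function() {
  hits <- tibble::as_tibble(rlang::set_names(
    lapply(HIT_FIELDS, function(col) {
      if (col %in% HIT_CHARACTER) character(0)
      else if (col %in% HIT_INTEGER) integer(0)
      else numeric(0)
    }),
    HIT_FIELDS
  ))
  hits
}

#' Write hits to the extended tabular format
#'
#' Tab-separated, no header, one row per hit, field order exactly as in
#' [read_hit_table()]. Numeric formatting mirrors the aligner's: `pident`
#' with three decimals, `bitscore` with one, `evalue` in compact scientific
#' notation, so files written at that precision round-trip losslessly.
#'
#' @param hits Tibble of hits (16 columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path) {
  if (nrow(hits) == 0L) {
    readr::write_lines(character(0), path)
    return(invisible(path))
  }
  validate_hits(hits)
  rows <- sprintf(
    "%s\t%s\t%.3f\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%s\t%.1f\t%d\t%d\t%d\t%s",
    hits$qseqid, hits$sseqid, hits$pident, hits$aln_len, hits$mismatch,
    hits$gapopen, hits$qstart, hits$qend, hits$sstart, hits$send,
    sprintf("%.6g", hits$evalue), hits$bitscore, hits$qlen, hits$slen,
    hits$gaps, sprintf("%.6g", hits$qcovs)
  )
  readr::write_lines(rows, path)
  invisible(path)
}

#' Run local blastn against an RSL database
#'
#' Searches the query FASTA against a database built with
#' [build_blast_db()], writing the extended 16-field tabular result. Only
#' hits with percent identity at or above `cutoff_pident` are emitted
#' (enforced through the aligner's `-perc_identity` option; the same floor
#' is re-applied by the pipeline when reading pre-computed files).
#'
#' @param query_fasta Path to the query multi-FASTA.
#' @param db Database prefix (string) or the handle from [build_blast_db()].
#' @param cutoff_pident Percent-identity floor in `[0, 100]`.
#' @param out_path Path for the tabular result file.
#' @param task blastn task (`"megablast"` is the aligner default;
#'   `"blastn"` uses a shorter word size and tolerates more divergence).
#' @param extra_args Additional command-line arguments passed through to
#'   `blastn` (e.g. `c("-max_target_seqs", "50")`).
#' @param blastn Path to the `blastn` executable.
#' @return `out_path`, invisibly.
#' @export
run_blastn <- function(query_fasta, db, cutoff_pident, out_path,
                       task = "megablast", extra_args = character(),
                       blastn = Sys.which("blastn")) {
  if (!is.numeric(cutoff_pident) || length(cutoff_pident) != 1L ||
      is.na(cutoff_pident) || cutoff_pident < 0 || cutoff_pident > 100) {
    rlang::abort("`cutoff_pident` must be a single value in [0, 100].",
                 class = "barcodeid_bad_parameter")
  }
  if (!file.exists(query_fasta)) {
    rlang::abort(sprintf("Query file not found: %s", query_fasta),
                 class = "barcodeid_missing_file")
  }
  if (is.list(db)) db <- db$prefix
  if (!nzchar(blastn)) {
    rlang::abort(
      "The external tool 'blastn' (NCBI BLAST+) was not found on PATH; install BLAST+ or pass its location via `blastn`.",
      class = "barcodeid_missing_tool"
    )
  }
  out <- suppressWarnings(system2(
    blastn,
    c("-query", shQuote(query_fasta), "-db", shQuote(db),
      "-task", task,
      "-perc_identity", format(cutoff_pident),
      "-outfmt", shQuote(blast_outfmt()),
      "-out", shQuote(out_path), extra_args),
    stdout = TRUE, stderr = TRUE
  ))
  status <- attr(out, "status") %||% 0L
  if (status != 0L) {
    rlang::abort(
      sprintf("blastn failed (exit %d):\n%s", status, paste(out, collapse = "\n")),
      class = "barcodeid_tool_error"
    )
  }
  invisible(out_path)
}
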