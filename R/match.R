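#' Query coverage of an alignment
#'
#' The fraction of the query spanned by a hit, on 1-based inclusive
#' coordinates:
#' \deqn{qcov = \frac{qend - qstart + 1}{qlen} \times 100}
#' This recomputed value (not the aligner's per-subject `qcovs` column)
#' drives coverage filtering and flagging throughout the pipeline.
#'
#' @param qstart,qend 1-based inclusive query coordinates, `qstart <= qend`.
#' @param qlen Query length in bp.
#' @return Percent coverage in `(0, 100]`, real-valued, not rounded.
#' @examples
#' compute_qcov(1, 100, 100)  # 100
#' compute_qcov(26, 100, 100) # 75, the filter boundary
#' @export
compute_qcov <- function(qstart, qend, qlen) {
  if (any(qstart < 1 | qstart > qend | qend > qlen)) {
    rlang::abort("Require 1 <= qstart <= qend <= qlen.",
                 class = "barcodeid_bad_parameter")
  }
  (qend - qstart + 1) / qlen * 100
}

#' Similarity threshold from interspecific divergence
#'
#' A best match is only considered a confident species-level identification
#' when its percent identity reaches `100 - intersp_div`, where
#' `intersp_div` is the interspecific sequence divergence (percent) of the
#' marker in the studied group — i.e. the divergence that separates taxa.
#'
#' @param intersp_div Interspecific divergence percent, in `[0, 100)`.
#' @return The similarity threshold (percent identity).
#' @examples
#' similarity_threshold(3) # 97
#' @export
similarity_threshold <- function(intersp_div) {
  if (!is.numeric(intersp_div) || length(intersp_div) != 1L ||
      is.na(intersp_div) || intersp_div < 0 || intersp_div >= 100) {
    rlang::abort("`intersp_div` must be a single value in [0, 100).",
                 class = "barcodeid_bad_parameter")
  }
  100 - intersp_div
}

# float-safe boundary: aln_len >= 0.9 * slen, retained at exact equality
passes_length <- function(aln_len, slen) aln_len >= 0.90 * slen - 1e-9

#' Annotate hits with computed query coverage and filter flags
#'
#' Adds `qcov` (recomputed per [compute_qcov()]) and the two pass/fail
#' flags: `passes_qcov_filter` (`qcov >= 75`) and `passes_length_filter`
#' (`aln_len >= 0.90 * slen`). No rows are dropped; see [filter_hits()].
#'
#' @param hits Hit tibble as from [read_hit_table()].
#' @return The same tibble with three columns appended; input order kept.
#' @export
evaluate_hits <- function(hits) {
  validate_hits(hits)
  dplyr::mutate(
    hits,
    qcov = compute_qcov(.data$qstart, .data$qend, .data$qlen),
    passes_qcov_filter = .data$qcov >= 75,
    passes_length_filter = passes_length(.data$aln_len, .data$slen)
  )
}

#' Filter hits by query coverage and alignment length
#'
#' Removes hits with query coverage below 75% or alignment length below
#' 90% of the subject length — hits whose high identity rests on too short
#' an alignment. Both boundaries are inclusive on the retained side
#' (`qcov = 75` and `aln_len = 0.9 * slen` survive). Idempotent; input
#' order preserved.
#'
#' @inheritParams evaluate_hits
#' @return The retained rows, annotated as by [evaluate_hits()].
#' @export
filter_hits <- function(hits) {
  ev <- evaluate_hits(hits)
  dplyr::filter(ev, .data$passes_qcov_filter & .data$passes_length_filter)
}

#' Best match per query
#'
#' Sorts the retained hits of each query by percent identity (descending)
#' and retrieves the top one. Ties on identity break by bitscore, then
#' alignment length (both descending), then subject identifier
#' (lexicographic), so the result is deterministic across platforms and
#' input orders. Each best match carries two check flags:
#' `check_identity` when `pident` falls below the similarity threshold and
#' `check_coverage` when `qcov < 75`.
#'
#' @param evaluated Annotated hits from [evaluate_hits()] or
#'   [filter_hits()].
#' @param rsl RSL tibble from [read_rsl()], used to resolve subject
#'   identifiers to lineages. Unresolvable identifiers keep `sseqid` as
#'   lineage and gain a warning note.
#' @param threshold Similarity threshold from [similarity_threshold()].
#' @return A tibble with one row per query (first-appearance order):
#'   `qseqid`, `sseqid`, `lineage`, `pident`, `qcov`, `qlen`, `slen`,
#'   `aln_len`, `evalue`, `bitscore`, `check_identity`, `check_coverage`,
#'   `notes` (list-column of warning strings).
#' @export
best_match_per_query <- function(evaluated, rsl, threshold) {
  if (nrow(evaluated) == 0L) return(empty_best_matches())
  ord <- order(match(evaluated$qseqid, unique(evaluated$qseqid)),
               -evaluated$pident, -evaluated$bitscore,
               -evaluated$aln_len, evaluated$sseqid)
  best <- evaluated[ord, ][!duplicated(evaluated$qseqid[ord]), ]
  lineage <- rsl$lineage[match(best$sseqid, rsl$seq_id)]
  unresolved <- is.na(lineage)
  lineage[unresolved] <- best$sseqid[unresolved]
  out <- tibble::tibble(
    qseqid = best$qseqid,
    sseqid = best$sseqid,
    lineage = lineage,
    pident = best$pident,
    qcov = best$qcov,
    qlen = best$qlen,
    slen = best$slen,
    aln_len = best$aln_len,
    evalue = best$evalue,
    bitscore = best$bitscore,
    check_identity = best$pident < threshold,
    check_coverage = best$qcov < 75,
    notes = purrr::map(unresolved, function(u) {
      if (u) "subject identifier not found in RSL" else character(0)
    })
  )
  out
}

empty_best_matches <- function() {
  tibble::tibble(
    qseqid = character(0), sseqid = character(0), lineage = character(0),
    pident = numeric(0), qcov = numeric(0), qlen = integer(0),
    slen = integer(0), aln_len = integer(0), evalue = numeric(0),
    bitscore = numeric(0), check_identity = logical(0),
    check_coverage = logical(0), notes = list()
  )
}

#' Load taxon-specific check tags from CSV
#'
#' The optional warning file pairs a pattern (a fragment of a subject
#' identifier, e.g. a genus name or a collection acronym) with a message to
#' attach to matching best matches — typically taxa whose marker lacks
#' species-level resolution. A two-column CSV; a `pattern,message` header
#' row is auto-detected. A missing file is not an error: the feature is
#' optional and yields an empty tag set.
#'
#' @param path Path to the CSV, or `NULL`.
#' @return A tibble with columns `pattern` and `message`.
#' @export
read_check_tags <- function(path = NULL) {
  empty <- tibble::tibble(pattern = character(0), message = character(0))
  if (is.null(path) || !file.exists(path)) return(empty)
  raw <- readr::read_csv(path, col_names = FALSE, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (nrow(raw) == 0L) return(empty)
  if (ncol(raw) != 2L) {
    rlang::abort(sprintf("Check-tags file '%s' must have exactly 2 columns, found %d.",
                         path, ncol(raw)),
                 class = "barcodeid_bad_tags")
  }
  names(raw) <- c("pattern", "message")
  if (tolower(trimws(raw$pattern[1L])) == "pattern" &&
      tolower(trimws(raw$message[1L])) == "message") {
    raw <- raw[-1L, ]
  }
  raw$message[is.na(raw$message)] <- ""
  bad <- which(is.na(raw$pattern) | !nzchar(trimws(raw$pattern)))
  if (length(bad) > 0L) {
    rlang::abort(sprintf("Check-tags file '%s': empty pattern in data row %d.",
                         path, bad[1L]),
                 class = "barcodeid_bad_tags")
  }
  tibble::as_tibble(raw)
}

#' Attach check-tag warnings to best matches
#'
#' Every tag whose pattern occurs as a substring of a match's subject
#' identifier (or lineage, with `field = "lineage"`) appends its message to
#' that match's `notes`; matches gaining a note join the further-checking
#' set. Matching is case-sensitive by default, since patterns are
#' identifier fragments.
#'
#' @param matches Best matches from [best_match_per_query()].
#' @param tags Tag tibble from [read_check_tags()].
#' @param case_sensitive Logical; compare patterns case-sensitively.
#' @param field Which field patterns are matched against.
#' @return `matches` with `notes` extended.
#' @export
apply_check_tags <- function(matches, tags, case_sensitive = TRUE,
                             field = c("sseqid", "lineage")) {
  field <- rlang::arg_match(field)
  if (nrow(tags) == 0L || nrow(matches) == 0L) return(matches)
  target <- matches[[field]]
  extra <- purrr::map(target, function(x) {
    hit <- stringr::str_detect(
      x, stringr::fixed(tags$pattern, ignore_case = !case_sensitive))
    tags$message[hit]
  })
  matches$notes <- purrr::map2(matches$notes, extra, c)
  matches
}

is_flagged <- function(matches) {
  matches$check_identity | matches$check_coverage | lengths(matches$notes) > 0L
}

#' Roll up matches by RSL lineage and pool unmatched queries
#'
#' Produces the full list of RSL lineages with the query identifiers
#' assigned to each (possibly none), plus the pool of queries with no
#' retained hit at or above the identity cutoff — the "outgroups".
#'
#' @param matches Best matches from [best_match_per_query()].
#' @param rsl RSL tibble.
#' @param all_query_ids Identifiers of every input query; queries absent
#'   from `matches` are pooled below the cutoff.
#' @return A list with `rollup` (tibble `lineage`, `query_ids` list-column,
#'   `n_queries`) and `below_cutoff` (character vector of query ids).
#' @export
aggregate_by_lineage <- function(matches, rsl, all_query_ids) {
  lineages <- unique(rsl$lineage)
  by_lineage <- split(matches$qseqid, factor(matches$lineage, levels = lineages))
  rollup <- tibble::tibble(
    lineage = lineages,
    query_ids = unname(purrr::map(by_lineage, as.character)),
    n_queries = unname(lengths(by_lineage))
  )
  list(
    rollup = rollup,
    below_cutoff = setdiff(all_query_ids, matches$qseqid)
  )
}

# percentages print as integers when whole, else to one decimal
round_pct <- function(x) round(x, 1)

#' Summary statistics of an identification run
#'
#' Aggregate counts reported on the final sheet: the number of lineages in
#' the RSL, the taxonomic coverage (percent of RSL taxa found among the
#' input sequences), taxa without a sample, input sequence counts, the
#' percentage of sequences processed (100 on a correct run: every query
#' lands either in the best-match set or in the below-cutoff pool), and the
#' number of queries below the cutoff.
#'
#' @param rsl RSL tibble.
#' @param matches Best matches.
#' @param below_cutoff Character vector of pooled query ids.
#' @param total_queries Total number of input sequences.
#' @return A one-row tibble: `total_lineages`, `lineages_matched`,
#'   `taxonomic_coverage`, `taxa_without_sample`, `total_queries`,
#'   `n_best_matches`, `n_below_cutoff`, `percent_processed`.
#' @export
compute_summary <- function(rsl, matches, below_cutoff, total_queries) {
  n_match <- nrow(matches)
  n_below <- length(below_cutoff)
  if (n_match + n_below > total_queries) {
    rlang::abort(
      "Internal inconsistency: matched + pooled queries exceed the input count.",
      class = "barcodeid_internal_error"
    )
  }
  total_lineages <- length(unique(rsl$lineage))
  matched_lineages <- length(unique(matches$lineage[matches$lineage %in% rsl$lineage]))
  tibble::tibble(
    total_lineages = total_lineages,
    lineages_matched = matched_lineages,
    taxonomic_coverage = round_pct(100 * matched_lineages / total_lineages),
    taxa_without_sample = total_lineages - matched_lineages,
    total_queries = total_queries,
    n_best_matches = n_match,
    n_below_cutoff = n_below,
    percent_processed = if (total_queries == 0L) 100
                        else round_pct(100 * (n_match + n_below) / total_queries)
  )
}
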