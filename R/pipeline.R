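#' Run the five-step identification pipeline
#'
#' Orchestrates the whole workflow: load the RSL, obtain hits (either by
#' running local blastn on a query FASTA, or from a pre-computed extended
#' tabular hit file — the aligner-free mode), enforce the identity cutoff,
#' compute query coverage and apply the coverage and alignment-length
#' filters, retrieve the best match per query, flag matches below the
#' similarity threshold `100 - intersp_div`, attach taxon-specific check
#' tags, roll results up by lineage, and assemble the four-sheet report.
#'
#' Exactly one of `queries` (aligner mode) or `hits` (pre-computed mode)
#' must drive the search. In pre-computed mode the full query-id universe
#' is taken from `query_ids` (or a query FASTA passed alongside); without
#' it, only ids present in the hit table are known, so queries with zero
#' hits cannot be counted.
#'
#' @param rsl RSL tibble from [read_rsl()]/[sim_rsl()], or a FASTA path.
#' @param queries Path to the query multi-FASTA (aligner mode), or a
#'   tibble with `seq_id`/`sequence` columns.
#' @param hits Pre-computed hit tibble or path to an extended tabular hit
#'   file (bypasses the aligner).
#' @param cutoff_pident Percent-identity floor; hits below it are
#'   discarded at search time and re-checked on read (default 90).
#' @param intersp_div Interspecific divergence percent (default 3, i.e.
#'   similarity threshold 97).
#' @param tags Optional path to the check-tags CSV, or a tag tibble.
#' @param query_ids Optional character vector of all input query ids
#'   (pre-computed mode).
#' @param case_sensitive Case sensitivity of tag matching.
#' @param tag_field Field tag patterns are matched against.
#' @param task,extra_args Passed to [run_blastn()] in aligner mode.
#' @param db_dir Directory for the temporary search database.
#' @param verbose Log one summary line per step to `message()`.
#' @return An object of class `barcode_id`: a list with `report`
#'   (the [build_report()] bundle), `best_matches`, `retained_hits`,
#'   `below_cutoff`, `summary` and `params`.
#' @examples
#' rsl <- sim_rsl(seed = 1)
#' qs <- sim_queries(rsl, seed = 2)
#' hits <- sim_hit_table(qs$truth, rsl)
#' res <- run_identification(rsl, hits = hits, query_ids = qs$queries$seq_id)
#' glance(res)
#' @export
run_identification <- function(rsl, queries = NULL, hits = NULL,
                               cutoff_pident = 90, intersp_div = 3,
                               tags = NULL, query_ids = NULL,
                               case_sensitive = TRUE,
                               tag_field = "sseqid",
                               task = "megablast", extra_args = character(),
                               db_dir = tempfile("blastdb"),
                               verbose = FALSE) {
  if (!is.numeric(cutoff_pident) || cutoff_pident < 0 || cutoff_pident > 100) {
    rlang::abort("`cutoff_pident` must be in [0, 100].",
                 class = "barcodeid_bad_parameter")
  }
  threshold <- similarity_threshold(intersp_div)
  say <- function(...) if (verbose) message(sprintf(...))
  say("config: cutoff_pident=%g, intersp_div=%g, similarity threshold=%g",
      cutoff_pident, intersp_div, threshold)

  # step 1: reference library (and database, in aligner mode)
  rsl_path <- NULL
  if (is.character(rsl)) {
    rsl_path <- rsl
    rsl <- read_rsl(rsl_path)
  }
  say("step 1: RSL with %d records, %d lineages",
      nrow(rsl), length(unique(rsl$lineage)))

  # step 2: local search, or a pre-computed hit table
  if (is.null(hits) == is.null(queries) && is.null(hits)) {
    rlang::abort("Provide `queries` (aligner mode) or `hits` (pre-computed mode).",
                 class = "barcodeid_bad_parameter")
  }
  query_fasta <- NULL
  if (!is.null(queries)) {
    if (is.character(queries)) {
      query_fasta <- queries
      qset <- Biostrings::readBStringSet(query_fasta)
      all_ids <- stringr::str_split_i(names(qset), "\\s+", 1L)
    } else {
      all_ids <- queries$seq_id
      query_fasta <- tempfile(fileext = ".fasta")
      write_queries(queries, query_fasta)
    }
  }
  if (is.null(hits)) {
    if (is.null(rsl_path)) {
      rsl_path <- tempfile(fileext = ".fasta")
      write_rsl(rsl, rsl_path)
    }
    dir.create(db_dir, showWarnings = FALSE, recursive = TRUE)
    db <- build_blast_db(rsl_path, file.path(db_dir, "rsl"))
    out <- tempfile(fileext = ".tsv")
    run_blastn(query_fasta, db, cutoff_pident, out,
               task = task, extra_args = extra_args)
    hits <- read_hit_table(out)
  } else {
    if (is.character(hits)) hits <- read_hit_table(hits)
    validate_hits(hits)
    if (is.null(query_ids) && !is.null(queries)) query_ids <- all_ids
    all_ids <- query_ids %||% unique(hits$qseqid)
  }
  n_raw <- nrow(hits)
  hits <- dplyr::filter(hits, .data$pident >= cutoff_pident)
  say("step 2: %d hits (%d below cutoff_pident removed) for %d queries",
      nrow(hits), n_raw - nrow(hits), length(all_ids))

  # step 3: coverage computation, filtering, best match per query
  retained <- filter_hits(hits)
  matches <- best_match_per_query(retained, rsl, threshold)
  say("step 3: %d hits retained by filters; %d best matches",
      nrow(retained), nrow(matches))

  # step 4: threshold flags and taxa-specific warnings
  if (is.character(tags) || is.null(tags)) tags <- read_check_tags(tags)
  matches <- apply_check_tags(matches, tags,
                              case_sensitive = case_sensitive,
                              field = tag_field)
  say("step 4: %d matches tagged for further checking", sum(is_flagged(matches)))

  # step 5: roll-up, summary, report
  agg <- aggregate_by_lineage(matches, rsl, all_ids)
  stats <- compute_summary(rsl, matches, agg$below_cutoff, length(all_ids))
  bundle <- build_report(matches, retained, agg, stats)
  say("step 5: %d/%d lineages matched, %d below cutoff, %g%% processed",
      stats$lineages_matched, stats$total_lineages,
      stats$n_below_cutoff, stats$percent_processed)

  structure(
    list(report = bundle, best_matches = matches, retained_hits = retained,
         below_cutoff = agg$below_cutoff, summary = stats,
         params = list(cutoff_pident = cutoff_pident,
                       intersp_div = intersp_div,
                       similarity_threshold = threshold)),
    class = "barcode_id"
  )
}

#' @export
print.barcode_id <- function(x, ...) {
  s <- x$summary
  cat("Molecular species identification\n")
  cat(sprintf("  cutoff_pident %g%%, intersp_div %g%% (similarity threshold %g%%)\n",
              x$params$cutoff_pident, x$params$intersp_div,
              x$params$similarity_threshold))
  cat(sprintf("  %d input sequences: %d best matches (%d tagged for checking), %d below cutoff\n",
              s$total_queries, s$n_best_matches,
              sum(is_flagged(x$best_matches)), s$n_below_cutoff))
  cat(sprintf("  taxonomic coverage %g%% (%d of %d lineages), %d taxa without a sample\n",
              s$taxonomic_coverage, s$lineages_matched, s$total_lineages,
              s$taxa_without_sample))
  invisible(x)
}

#' Tidy the best matches of an identification run
#'
#' @param x A `barcode_id` object.
#' @param ... Unused.
#' @return The best-match tibble, one row per identified query, with
#'   `notes` collapsed to a single string and a `flag` label.
#' @method tidy barcode_id
#' @export
tidy.barcode_id <- function(x, ...) {
  x$report$best_matches
}

#' One-row summary of an identification run
#'
#' @param x A `barcode_id` object.
#' @param ... Unused.
#' @return The one-row summary-statistics tibble.
#' @method glance barcode_id
#' @export
glance.barcode_id <- function(x, ...) {
  x$summary
}

#' Identity/coverage overview plot of an identification run
#'
#' Scatter of percent identity against computed query coverage for every
#' best match, coloured by flag status, with the similarity threshold and
#' the 75% coverage floor drawn as dashed lines.
#'
#' @param object A `barcode_id` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot barcode_id
#' @export
autoplot.barcode_id <- function(object, ...) {
  df <- object$report$best_matches
  df$status <- ifelse(df$flag == "", "clean", df$flag)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$qcov, y = .data$pident,
                                   colour = .data$status)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = object$params$similarity_threshold,
                        linetype = "dashed") +
    ggplot2::geom_vline(xintercept = 75, linetype = "dashed") +
    ggplot2::labs(x = "query coverage (%)", y = "percent identity",
                  colour = "flag",
                  title = "Best matches vs. similarity threshold") +
    ggplot2::theme_minimal()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
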