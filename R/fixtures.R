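with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

random_dna <- function(n, length) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = "")
  }, character(1))
}

#' Simulate a Reference Sequences Library
#'
#' Generates a synthetic RSL of `n_lineages` random DNA sequences, one per
#' lineage, with binomial-style identifiers `Genus{i}_species{i}_V{i}`
#' (genus/species tokens plus a voucher-like suffix). Deterministic under
#' `seed`.
#'
#' @param n_lineages Number of reference lineages (default 25, one
#'   sequence each).
#' @param ref_length Reference sequence length in bp (default 600, a
#'   typical single-marker barcode fragment).
#' @param seed Optional RNG seed; the caller's RNG state is restored.
#' @return An RSL tibble (`seq_id`, `lineage`, `sequence`) as from
#'   [read_rsl()].
#' @export
sim_rsl <- function(n_lineages = 25, ref_length = 600, seed = NULL) {
  with_seed(seed, {
    i <- seq_len(n_lineages)
    tibble::tibble(
      seq_id = sprintf("Genus%d_species%d_V%d", i, i, i),
      lineage = sprintf("Genus%d_species%d", i, i),
      sequence = random_dna(n_lineages, ref_length)
    )
  })
}

mutate_sequence <- function(sequence, n_subs, margin) {
  bases <- strsplit(sequence, "", fixed = TRUE)[[1]]
  L <- length(bases)
  eligible <- seq.int(margin + 1L, L - margin)
  if (n_subs > length(eligible)) {
    rlang::abort(
      sprintf("Cannot place %d substitutions in %d eligible positions.",
              n_subs, length(eligible)),
      class = "barcodeid_bad_parameter"
    )
  }
  pos <- sample(eligible, n_subs)
  for (p in pos) {
    bases[p] <- sample(setdiff(c("A", "C", "G", "T"), bases[p]), 1L)
  }
  paste(bases, collapse = "")
}

#' Simulate query sequences of known divergence
#'
#' For each entry of `divergence` (percent), one query is derived from an
#' RSL reference by exactly `round(d * L / 100)` random point substitutions
#' — no indels, so the percent identity to its source is the closed form
#' `100 * (1 - subs/L)`. Substitutions are kept `margin` bp away from both
#' ends so a local aligner recovers the full-length alignment. Outgroup
#' queries are fresh random sequences unrelated to any reference. The
#' defaults emulate a typical small identification batch: nine in-group
#' queries drawn from seven lineages, of which three diverge more than a
#' 3% species threshold, plus one outgroup.
#'
#' @param rsl RSL tibble ([sim_rsl()] or [read_rsl()]); queries derive
#'   from its first `n_matched_lineages` records.
#' @param divergence Percent substitution rate per matched query, in
#'   `[0, 100)`.
#' @param n_matched_lineages Number of distinct RSL lineages the matched
#'   queries are drawn from; queries cycle through them, so several
#'   queries may share a source lineage.
#' @param n_outgroups Number of unrelated random queries.
#' @param margin Substitution-free margin at each sequence end, bp.
#' @param seed Optional RNG seed.
#' @return A list with `queries` (tibble `seq_id`, `sequence`) and `truth`
#'   (tibble `query_id`, `source_seq_id`, `lineage`, `qlen`, `n_subs`,
#'   `expected_pident`; outgroups have `NA` source and lineage).
#' @export
sim_queries <- function(rsl, divergence = c(0, 0, 0.5, 1, 1.5, 2, 4, 5, 6),
                        n_matched_lineages = min(7, length(divergence)),
                        n_outgroups = 1, margin = 25, seed = NULL) {
  stopifnot(n_matched_lineages <= nrow(rsl),
            n_matched_lineages <= length(divergence) || length(divergence) == 0,
            all(divergence >= 0 & divergence < 100))
  with_seed(seed, {
    src <- rsl[rep(seq_len(n_matched_lineages), length.out = length(divergence)), ]
    L <- nchar(src$sequence)
    n_subs <- as.integer(round(divergence * L / 100))
    qseq <- purrr::pmap_chr(list(src$sequence, n_subs),
                            function(s, k) mutate_sequence(s, k, margin))
    queries <- tibble::tibble(
      seq_id = sprintf("Q%02d_%s", seq_along(divergence), src$lineage),
      sequence = qseq
    )
    truth <- tibble::tibble(
      query_id = queries$seq_id,
      source_seq_id = src$seq_id,
      lineage = src$lineage,
      qlen = L,
      n_subs = n_subs,
      expected_pident = 100 * (1 - n_subs / L)
    )
    if (n_outgroups > 0) {
      out_len <- if (nrow(rsl) > 0) nchar(rsl$sequence[1]) else 600L
      og <- tibble::tibble(
        seq_id = sprintf("OUT%02d", seq_len(n_outgroups)),
        sequence = random_dna(n_outgroups, out_len)
      )
      queries <- dplyr::bind_rows(queries, og)
      truth <- dplyr::bind_rows(truth, tibble::tibble(
        query_id = og$seq_id, source_seq_id = NA_character_,
        lineage = NA_character_, qlen = out_len,
        n_subs = NA_integer_, expected_pident = NA_real_
      ))
    }
    list(queries = queries, truth = truth)
  })
}

#' Write query sequences to FASTA
#'
#' @param queries Tibble with `seq_id` and `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_queries <- function(queries, path) {
  set <- Biostrings::DNAStringSet(rlang::set_names(queries$sequence, queries$seq_id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Simulate an extended tabular hit table from a truth table
#'
#' Stands in for the aligner so the filtering and reporting stages are
#' testable offline: each matched query gets one full-length hit against
#' its source reference (`qstart = 1`, `qend = qlen`, identity from the
#' truth table), outgroups get none. Optionally adds full-length
#' "secondary" hits against other references at strictly lower identity
#' (competition for best-match selection) and low-coverage/short "decoy"
#' rows that the coverage and length filters must remove.
#'
#' @param truth Truth tibble from [sim_queries()].
#' @param rsl The RSL the queries derive from.
#' @param n_secondary Secondary full-length hits per matched query.
#' @param n_decoys Decoy rows per matched query; each spans 50% of the
#'   query (coverage 50 < 75) so [filter_hits()] removes it.
#' @param seed Optional RNG seed.
#' @return A 16-column hit tibble (see [read_hit_table()]).
#' @export
sim_hit_table <- function(truth, rsl, n_secondary = 0, n_decoys = 0,
                          seed = NULL) {
  matched <- truth[!is.na(truth$source_seq_id), ]
  if (nrow(matched) == 0L) return(empty_hit_table())
  with_seed(seed, {
    slen <- nchar(rsl$sequence[match(matched$source_seq_id, rsl$seq_id)])
    main <- tibble::tibble(
      qseqid = matched$query_id,
      sseqid = matched$source_seq_id,
      pident = round(matched$expected_pident, 3),
      aln_len = matched$qlen,
      mismatch = matched$n_subs,
      gapopen = 0L,
      qstart = 1L, qend = matched$qlen,
      sstart = 1L, send = slen,
      evalue = 1e-50,
      bitscore = round(2 * matched$qlen * matched$expected_pident / 100, 1),
      qlen = matched$qlen,
      slen = slen,
      gaps = 0L,
      qcovs = 100
    )
    rows <- list(main)
    if (n_secondary > 0 && nrow(rsl) > 1) {
      sec <- purrr::map(seq_len(nrow(matched)), function(i) {
        others <- setdiff(rsl$seq_id, matched$source_seq_id[i])
        k <- min(n_secondary, length(others))
        sub <- main[rep(i, k), ]
        sub$sseqid <- sample(others, k)
        sub$pident <- round(pmax(0, main$pident[i] -
                                   stats::runif(k, 1, 8)), 3)
        sub$mismatch <- as.integer(round((100 - sub$pident) / 100 * sub$aln_len))
        sub$bitscore <- round(2 * sub$qlen * sub$pident / 100, 1)
        sub
      })
      rows <- c(rows, sec)
    }
    if (n_decoys > 0) {
      dec <- purrr::map(seq_len(nrow(matched)), function(i) {
        sub <- main[rep(i, n_decoys), ]
        span <- as.integer(floor(sub$qlen / 2))
        sub$qstart <- 1L
        sub$qend <- span
        sub$aln_len <- span
        sub$send <- span
        sub$pident <- 100
        sub$mismatch <- 0L
        sub$qcovs <- round(span / sub$qlen * 100)
        sub$bitscore <- round(2 * span, 1)
        sub
      })
      rows <- c(rows, dec)
    }
    dplyr::bind_rows(rows)
  })
}
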