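#' Parse lineage names from reference sequence identifiers
#'
#' A Reference Sequences Library (RSL) carries one uniquely identified
#' sequence per described or candidate species; the species-level taxon name
#' ("lineage") is encoded in the FASTA identifier. Three conventions are
#' supported:
#'
#' * `"binomial"` (default): the first two underscore-separated tokens,
#'   joined by an underscore — `"Mantella_aurantiaca_MRSN1234"` becomes
#'   `"Mantella_aurantiaca"`. Matches binomial-nomenclature headers.
#' * `"full"`: the whole identifier is the lineage (one record per lineage).
#' * `"regex"`: the first capture group of `pattern` applied to the
#'   identifier, for headers that do not follow the binomial layout
#'   (e.g. candidate-species names).
#'
#' @param seq_id Character vector of sequence identifiers.
#' @param convention One of `"binomial"`, `"full"`, `"regex"`.
#' @param pattern Regular expression with one capture group; required when
#'   `convention = "regex"`.
#' @return Character vector of lineage names, same length as `seq_id`.
#' @examples
#' parse_lineage("Mantella_aurantiaca_MRSN1234")
#' parse_lineage("Boophis sp. Ca5|ACZC0123", convention = "regex",
#'               pattern = "^([^|]+)\\|")
#' @export
parse_lineage <- function(seq_id,
                          convention = c("binomial", "full", "regex"),
                          pattern = NULL) {
  convention <- rlang::arg_match(convention)
  if (length(seq_id) == 0L) return(character(0))
  if (any(!nzchar(seq_id) | is.na(seq_id))) {
    rlang::abort("`seq_id` must be non-empty.", class = "barcodeid_bad_seq_id")
  }
  lineage <- switch(convention,
    full = seq_id,
    binomial = {
      tokens <- stringr::str_split(seq_id, stringr::fixed("_"))
      purrr::map_chr(tokens, function(tk) {
        tk <- tk[nzchar(tk)]
        paste(utils::head(tk, 2L), collapse = "_")
      })
    },
    regex = {
      if (is.null(pattern)) {
        rlang::abort("`pattern` is required for the regex convention.",
                     class = "barcodeid_bad_convention")
      }
      stringr::str_match(seq_id, pattern)[, 2L]
    }
  )
  bad <- is.na(lineage) | !nzchar(lineage)
  if (any(bad)) {
    rlang::abort(
      sprintf("Identifier(s) yield an empty lineage under the '%s' convention: %s",
              convention, paste(utils::head(seq_id[bad], 5L), collapse = ", ")),
      class = "barcodeid_empty_lineage"
    )
  }
  lineage
}

#' Load a Reference Sequences Library from FASTA
#'
#' Reads a multi-FASTA of single-marker reference sequences, one per
#' described or candidate species, and derives the lineage name of each
#' record from its identifier (see [parse_lineage()]). Sequences are
#' upper-cased and `U` is mapped to `T`; characters outside the IUPAC
#' nucleotide alphabet (ambiguity codes permitted) are rejected, as are
#' duplicated identifiers.
#'
#' @param path Path to a multi-FASTA file.
#' @inheritParams parse_lineage
#' @return A tibble with columns `seq_id`, `lineage`, `sequence`, one row
#'   per reference record, in file order.
#' @seealso [write_rsl()], [build_blast_db()]
#' @export
read_rsl <- function(path, convention = "binomial", pattern = NULL) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("RSL file not found: %s", path),
                 class = "barcodeid_missing_file")
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      rlang::abort(sprintf("Cannot parse FASTA '%s': %s", path, conditionMessage(e)),
                   class = "barcodeid_bad_fasta", parent = e)
    }
  )
  if (length(set) == 0L) {
    rlang::abort(sprintf("RSL file '%s' contains no sequences.", path),
                 class = "barcodeid_empty_rsl")
  }
  seq_id <- stringr::str_split_i(names(set), "\\s+", 1L)
  dup <- unique(seq_id[duplicated(seq_id)])
  if (length(dup) > 0L) {
    rlang::abort(
      sprintf("Duplicate identifier(s) in RSL: %s",
              paste(utils::head(dup, 5L), collapse = ", ")),
      class = "barcodeid_duplicate_id"
    )
  }
  sequence <- chartr("u", "t", toupper(as.character(set)))
  sequence <- chartr("U", "T", sequence)
  if (any(!nzchar(sequence))) {
    rlang::abort("RSL contains empty sequence(s).", class = "barcodeid_empty_sequence")
  }
  ok <- grepl("^[ACGTRYSWKMBDHVN-]+$", sequence)
  if (!all(ok)) {
    rlang::abort(
      sprintf("Non-IUPAC nucleotide characters in record(s): %s",
              paste(utils::head(seq_id[!ok], 5L), collapse = ", ")),
      class = "barcodeid_bad_alphabet"
    )
  }
  # DNAStringSet re-validates against the IUPAC alphabet
  Biostrings::DNAStringSet(sequence)
  tibble::tibble(
    seq_id = unname(seq_id),
    lineage = parse_lineage(seq_id, convention = convention, pattern = pattern),
    sequence = unname(sequence)
  )
}

#' Write a Reference Sequences Library to FASTA
#'
#' @param rsl Tibble as returned by [read_rsl()] (columns `seq_id`,
#'   `sequence`; `lineage` is ignored on write, it is re-derived on load).
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_rsl <- function(rsl, path) {
  set <- Biostrings::DNAStringSet(rlang::set_names(rsl$sequence, rsl$seq_id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Build the local nucleotide search database for an RSL
#'
#' Thin adapter around NCBI BLAST+ `makeblastdb`. Run once per RSL; the
#' operation is idempotent (rebuilding over an existing prefix replaces it).
#'
#' @param rsl_fasta Path to the RSL FASTA.
#' @param out_prefix Filesystem prefix for the database index files.
#' @param makeblastdb Path to the `makeblastdb` executable.
#' @return Invisibly, a list with `prefix` and the index `files` created.
#' @export
build_blast_db <- function(rsl_fasta, out_prefix,
                           makeblastdb = Sys.which("makeblastdb")) {
  if (!file.exists(rsl_fasta)) {
    rlang::abort(sprintf("RSL file not found: %s", rsl_fasta),
                 class = "barcodeid_missing_file")
  }
  if (!nzchar(makeblastdb)) {
    rlang::abort(
      "The external tool 'makeblastdb' (NCBI BLAST+) was not found on PATH; install BLAST+ or pass its location via `makeblastdb`.",
      class = "barcodeid_missing_tool"
    )
  }
  out <- suppressWarnings(system2(
    makeblastdb,
    c("-in", shQuote(rsl_fasta), "-dbtype", "nucl", "-out", shQuote(out_prefix)),
    stdout = TRUE, stderr = TRUE
  ))
  status <- attr(out, "status") %||% 0L
  if (status != 0L) {
    # do not leave partial index files behind
    unlink(Sys.glob(paste0(out_prefix, ".n*")))
    rlang::abort(
      sprintf("makeblastdb failed (exit %d):\n%s", status, paste(out, collapse = "\n")),
      class = "barcodeid_tool_error"
    )
  }
  files <- Sys.glob(paste0(out_prefix, ".n*"))
  invisible(list(prefix = out_prefix, files = files))
}
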