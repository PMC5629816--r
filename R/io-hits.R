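#' Read a tab-separated alignment-hit table (BLAST outfmt-6 column order)
#'
#' Consumes the tabular output convention of BLASTN (`qseqid sseqid pident
#' length mismatch gapopen qstart qend sstart send ...`). Printed subject
#' coordinates are 1-based inclusive and are retained exactly as printed;
#' minus-orientation hits (printed start > end) additionally get normalized
#' `subject_min`/`subject_max`.
#'
#' @param path Path to the tab-separated hits file (no header). May be empty.
#' @param query_lengths Optional named integer vector mapping query id to the
#'   full query (e.g. primer) length, typically from the companion query
#'   FASTA. Absent ids yield `NA` `query_length`.
#' @return Tibble with columns `query_id`, `subject_id`, `aln_length`,
#'   `mismatches`, `subject_start`, `subject_end`, `orientation`
#'   (`"plus"`/`"minus"`), `subject_min`, `subject_max`, `query_length`.
#' @export
read_hits_table <- function(path, query_lengths = NULL) {
  if (!file.exists(path)) abort(paste0("hits file does not exist: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble::tibble(
      query_id = character(), subject_id = character(),
      aln_length = integer(), mismatches = integer(),
      subject_start = integer(), subject_end = integer(),
      orientation = character(), subject_min = integer(),
      subject_max = integer(), query_length = integer()
    ))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 10)
  if (length(bad) > 0) {
    abort(paste0("malformed hits row (fewer than 10 columns) at line ", bad[1]))
  }
  to_int <- function(col, what) {
    raw <- purrr::map_chr(fields, col)
    # tolerate thousands separators as printed in report tables
    raw <- gsub(",", "", raw, fixed = TRUE)
    ok <- grepl("^-?[0-9]+$", raw)
    if (!all(ok)) {
      abort(paste0("non-integer ", what, " field at line ", which(!ok)[1]))
    }
    as.integer(raw)
  }
  out <- tibble::tibble(
    query_id = purrr::map_chr(fields, 1),
    subject_id = purrr::map_chr(fields, 2),
    aln_length = to_int(4, "alignment-length"),
    mismatches = to_int(5, "mismatch"),
    subject_start = to_int(9, "subject-start"),
    subject_end = to_int(10, "subject-end")
  )
  if (any(out$aln_length < 1)) abort("alignment length must be >= 1")
  if (any(out$mismatches < 0)) abort("mismatch count must be >= 0")
  out <- dplyr::mutate(
    out,
    orientation = ifelse(.data$subject_start > .data$subject_end, "minus", "plus"),
    subject_min = pmin(.data$subject_start, .data$subject_end),
    subject_max = pmax(.data$subject_start, .data$subject_end),
    query_length = if (is.null(query_lengths)) {
      NA_integer_
    } else {
      as.integer(unname(query_lengths[.data$query_id]))
    }
  )
  out
}

#' Read a BED-like gene-model table
#'
#' Minimal tab-separated gene-model format: columns `gene_id`, `scaffold`,
#' `strand` (`+`/`-`), `start_phase` (0/1/2) and `exons`, the last being
#' comma-separated `start-end` 1-based inclusive intervals in transcription
#' order. This deliberately avoids general GFF3 parsing; only the structure
#' needed by the inactivation screen is modelled.
#'
#' @param path Path to the tab-separated table (with header line).
#' @return Tibble with one row per gene: `gene_id`, `scaffold`, `strand`,
#'   `start_phase` and a list-column `exons` of two-column integer matrices
#'   (`start`, `end`).
#' @export
read_gene_models <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  needed <- c("gene_id", "scaffold", "strand", "start_phase", "exons")
  if (!all(needed %in% names(raw))) {
    abort(paste0("gene-model table must have columns: ", paste(needed, collapse = ", ")))
  }
  parse_exons <- function(txt, gene) {
    parts <- strsplit(txt, ",", fixed = TRUE)[[1]]
    m <- regmatches(parts, regexec("^([0-9]+)-([0-9]+)$", parts))
    if (any(lengths(m) != 3)) {
      abort(paste0("malformed exon interval for gene ", gene))
    }
    ex <- do.call(rbind, lapply(m, function(x) as.integer(x[2:3])))
    colnames(ex) <- c("start", "end")
    validate_exons(ex, gene)
    ex
  }
  tibble::tibble(
    gene_id = raw$gene_id,
    scaffold = raw$scaffold,
    strand = raw$strand,
    start_phase = as.integer(raw$start_phase),
    exons = purrr::map2(raw$exons, raw$gene_id, parse_exons)
  )
}

validate_exons <- function(ex, gene_id = "?") {
  if (any(ex[, "end"] < ex[, "start"])) {
    abort(paste0("exon end < start for gene ", gene_id))
  }
  if (nrow(ex) > 1) {
    if (any(diff(ex[, "start"]) <= 0) || any(ex[-1, "start"] <= ex[-nrow(ex), "end"])) {
      abort(paste0("exons must be sorted and non-overlapping for gene ", gene_id))
    }
  }
  invisible(ex)
}

#' Build a single-row gene-model tibble in code
#'
#' Convenience constructor used throughout the tests and simulators.
#'
#' @param gene_id Gene identifier.
#' @param exons Two-column matrix (or list of `c(start, end)`) of 1-based
#'   inclusive exon intervals in transcription order.
#' @param scaffold Scaffold name the model lives on.
#' @param strand `"+"` or `"-"`.
#' @param start_phase Codon phase of the first exon base (0, 1 or 2).
#' @return One-row gene-model tibble as produced by [read_gene_models()].
#' @export
gene_model <- function(gene_id, exons, scaffold = "ref", strand = "+", start_phase = 0L) {
  if (is.list(exons)) exons <- do.call(rbind, exons)
  exons <- matrix(as.integer(exons), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  validate_exons(exons, gene_id)
  if (!strand %in% c("+", "-")) abort("strand must be '+' or '-'")
  if (!start_phase %in% 0:2) abort("start_phase must be 0, 1 or 2")
  tibble::tibble(
    gene_id = gene_id, scaffold = scaffold, strand = strand,
    start_phase = as.integer(start_phase), exons = list(exons)
  )
}
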