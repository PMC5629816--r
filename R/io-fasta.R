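#' Read a multi-record FASTA file into a tibble
#'
#' Parses a (possibly line-wrapped) FASTA file into one row per record.
#' Soft-masked lowercase bases are preserved as written; composition
#' statistics elsewhere in the package case-fold before counting.
#'
#' @param path Path to an existing FASTA file.
#' @return A tibble with columns `id` (character, unique), `seq` (character,
#'   no whitespace) and `length` (integer, `nchar(seq)`). Record order is
#'   file order. An empty file yields a zero-row tibble.
#' @export
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">s1", "ACGTNN", ">s2", "acgt"), f)
#' read_fasta(f)
read_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("FASTA file does not exist: ", path))
  }
  if (file.size(path) == 0) {
    return(tibble::tibble(id = character(), seq = character(), length = integer()))
  }
  # BStringSet (not DNAStringSet) so soft-mask case survives a round trip
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    abort(paste0("duplicate FASTA id(s): ", paste(dup, collapse = ", ")))
  }
  seqs <- as.character(set)
  empty <- ids[nchar(seqs) == 0]
  if (length(empty) > 0) {
    abort(paste0("empty sequence under header(s): ", paste(empty, collapse = ", ")))
  }
  tibble::tibble(id = unname(ids), seq = unname(seqs),
                 length = unname(nchar(seqs)))
}

#' Write a sequence tibble to FASTA
#'
#' Inverse of [read_fasta()]: `read_fasta(write_fasta(x, p))` is the identity
#' on `(id, seq)`. Case is preserved.
#'
#' @param records Tibble with columns `id` and `seq`.
#' @param path Output path.
#' @param wrap Line width for sequence lines; `0` writes each sequence on a
#'   single line. Default 60.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, wrap = 60) {
  stopifnot(is.data.frame(records), all(c("id", "seq") %in% names(records)))
  if (wrap < 0) abort("`wrap` must be >= 0")
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    writeLines(paste0(">", records$id[[i]]), con)
    s <- records$seq[[i]]
    if (wrap == 0 || nchar(s) <= wrap) {
      writeLines(s, con)
    } else {
      starts <- seq(1, nchar(s), by = wrap)
      writeLines(substring(s, starts, pmin(starts + wrap - 1, nchar(s))), con)
    }
  }
  invisible(path)
}
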