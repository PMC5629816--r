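#' Read a two-sample VCF into a variant tibble
#'
#' Parses a plain-text VCF 4.x with exactly two sample columns carrying
#' `GT`, `GQ` and `DP`. One row is returned per data line whose genotypes
#' are both called; lines with a missing genotype (`./.`) in either
#' individual are counted and dropped, since they cannot contribute to
#' pairwise-difference sums. Multiallelic lines are retained with their
#' full allele list (no splitting).
#'
#' The first sample column is individual A (by convention the individual
#' matching the reference assembly), the second individual B.
#'
#' @param path Path to an uncompressed VCF file.
#' @return A tibble with columns `scaffold`, `pos`, `ref_allele`,
#'   `alt_alleles` (comma-joined), `a1`, `a2`, `b1`, `b2` (integer allele
#'   indices, 0 = REF), `gq_a`, `gq_b`, `dp_a`, `dp_b`, and `is_indel`
#'   (TRUE iff any ALT allele length differs from the REF length).
#'   Attributes `n_data_lines` and `n_missing_genotype` carry the parse
#'   tallies; `n_data_lines - n_missing_genotype == nrow(result)`.
#' @export
read_vcf_two_sample <- function(path) {
  if (!file.exists(path)) abort(paste0("VCF file does not exist: ", path))
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(body)]
  empty <- tibble::tibble(
    scaffold = character(), pos = integer(), ref_allele = character(),
    alt_alleles = character(), a1 = integer(), a2 = integer(),
    b1 = integer(), b2 = integer(), gq_a = integer(), gq_b = integer(),
    dp_a = integer(), dp_b = integer(), is_indel = logical()
  )
  header <- lines[startsWith(lines, "#CHROM")]
  if (length(header) == 1) {
    n_samples <- length(strsplit(header, "\t", fixed = TRUE)[[1]]) - 9L
    if (n_samples != 2) {
      abort(paste0("expected exactly 2 sample columns, found ", n_samples))
    }
  }
  if (length(body) == 0) {
    attr(empty, "n_data_lines") <- 0L
    attr(empty, "n_missing_genotype") <- 0L
    return(empty)
  }

  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  if (ncol(vcf@gt) - 1L != 2L) {
    abort(paste0("expected exactly 2 sample columns, found ", ncol(vcf@gt) - 1L))
  }
  fix <- tibble::as_tibble(as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gq <- suppressWarnings(vcfR::extract.gt(vcf, element = "GQ", as.numeric = TRUE))
  dp <- suppressWarnings(vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE))

  parse_gt <- function(g, line_no) {
    # returns c(allele1, allele2) or c(NA, NA) for missing
    if (is.na(g) || g %in% c("./.", ".|.", ".")) return(c(NA_integer_, NA_integer_))
    m <- regmatches(g, regexec("^([0-9]+)[/|]([0-9]+)$", g))[[1]]
    if (length(m) != 3) {
      abort(paste0("malformed GT '", g, "' at data line ", line_no))
    }
    as.integer(m[2:3])
  }

  n <- nrow(fix)
  a1 <- a2 <- b1 <- b2 <- integer(n)
  for (i in seq_len(n)) {
    ga <- parse_gt(gt[i, 1], i)
    gb <- parse_gt(gt[i, 2], i)
    a1[i] <- ga[1]; a2[i] <- ga[2]; b1[i] <- gb[1]; b2[i] <- gb[2]
  }

  alt <- fix$ALT
  alt[is.na(alt)] <- ""
  alt_list <- strsplit(alt, ",", fixed = TRUE)
  n_alt <- lengths(alt_list)
  max_idx <- pmax(a1, a2, b1, b2, na.rm = FALSE)
  bad <- which(!is.na(max_idx) & max_idx > n_alt)
  if (length(bad) > 0) {
    abort(paste0("GT allele index out of range at data line ", bad[1]))
  }
  is_indel <- purrr::map2_lgl(alt_list, fix$REF, function(alts, ref) {
    any(nchar(alts) != nchar(ref) & nzchar(alts))
  })

  out <- tibble::tibble(
    scaffold = fix$CHROM,
    pos = as.integer(fix$POS),
    ref_allele = fix$REF,
    alt_alleles = alt,
    a1 = a1, a2 = a2, b1 = b1, b2 = b2,
    gq_a = as.integer(gq[, 1]), gq_b = as.integer(gq[, 2]),
    dp_a = as.integer(dp[, 1]), dp_b = as.integer(dp[, 2]),
    is_indel = is_indel
  )
  missing <- is.na(out$a1) | is.na(out$b1)
  res <- out[!missing, , drop = FALSE]
  attr(res, "n_data_lines") <- n
  attr(res, "n_missing_genotype") <- sum(missing)
  res
}

#' Write a two-sample variant tibble as a minimal VCF
#'
#' Serialises the column layout produced by [read_vcf_two_sample()] (and by
#' [simulate_variant_sites()]) as a valid two-sample VCF 4.2 file with a
#' `GT:GQ:DP` FORMAT. Used to exercise the reader and to make simulated
#' variant sets portable.
#'
#' @param sites Variant tibble (columns as in [read_vcf_two_sample()]).
#' @param path Output path.
#' @param sample_names Length-2 character vector of sample column names.
#' @return `path`, invisibly.
#' @export
write_vcf_two_sample <- function(sites, path,
                                 sample_names = c("individual_A", "individual_B")) {
  stopifnot(length(sample_names) == 2)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype Quality\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read Depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_names), collapse = "\t")
  ), con)
  if (nrow(sites) > 0) {
    fmt_gt <- function(x1, x2) {
      ifelse(is.na(x1) | is.na(x2), "./.", paste0(x1, "/", x2))
    }
    writeLines(paste(
      sites$scaffold, sites$pos, ".", sites$ref_allele, sites$alt_alleles,
      ".", ".", ".", "GT:GQ:DP",
      paste0(fmt_gt(sites$a1, sites$a2), ":", sites$gq_a, ":", sites$dp_a),
      paste0(fmt_gt(sites$b1, sites$b2), ":", sites$gq_b, ":", sites$dp_b),
      sep = "\t"
    ), con)
  }
  invisible(path)
}
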