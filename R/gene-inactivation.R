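#' Global pairwise alignment with affine gap costs
#'
#' Thin wrapper over a Needleman-Wunsch global alignment used to line up a
#' candidate gene locus against its functional reference ortholog before
#' mutation screening. Scores follow the convention that a gap of length L
#' costs `gap_open + (L - 1) * gap_extend`.
#'
#' @param ref,query Nucleotide strings (or one-row sequence tibbles).
#' @param match,mismatch Match/mismatch scores (mismatch < 0).
#' @param gap_open,gap_extend Gap costs (< 0, `|gap_open| >= |gap_extend|`).
#' @return List with `ref_aligned`, `query_aligned` (equal-length strings
#'   with `-` gaps) and `score`.
#' @export
align_pair <- function(ref, query, match = 1, mismatch = -2,
                       gap_open = -5, gap_extend = -1) {
  ref <- as_seq_string(ref)
  query <- as_seq_string(query)
  if (nchar(ref) == 0 || nchar(query) == 0) {
    abort("cannot align an empty sequence")
  }
  if (abs(gap_open) < abs(gap_extend)) {
    abort("|gap_open| must be >= |gap_extend|")
  }
  submat <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = FALSE, type = "DNA"
  )
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(toupper(ref)),
    subject = Biostrings::DNAString(toupper(query)),
    type = "global",
    substitutionMatrix = submat,
    # internal convention: gap of length L costs opening + L * extension
    gapOpening = abs(gap_open) - abs(gap_extend),
    gapExtension = abs(gap_extend)
  )
  list(
    ref_aligned = as.character(Biostrings::alignedPattern(aln)),
    query_aligned = as.character(Biostrings::alignedSubject(aln)),
    score = Biostrings::score(aln)
  )
}

as_seq_string <- function(x) {
  if (is.data.frame(x)) {
    if (nrow(x) != 1 || !"seq" %in% names(x)) {
      abort("sequence tibble input must have one row and a `seq` column")
    }
    return(x$seq[[1]])
  }
  stopifnot(is.character(x), length(x) == 1)
  x
}

#' Build a coding alignment from an aligned locus pair and a gene model
#'
#' Projects the reference gene model (exon intervals on the ungapped
#' reference locus) through a reference/query alignment, yielding one row
#' per alignment column annotated with the reference coordinate, the
#' feature it falls in (exon i / intron i / flank) and, for exonic
#' reference positions, the CDS coordinate. All downstream detectors work
#' on this columnar form.
#'
#' @param ref_aligned,query_aligned Equal-length aligned strings (`-` gaps).
#' @param model One-row gene-model tibble ([gene_model()]); exon intervals
#'   refer to the ungapped reference locus.
#' @return Object of class `coding_alignment`: list with `gene_id`, `cols`
#'   (column tibble), `model`, `start_phase`, `n_exons`, `cds_length`.
#' @export
coding_alignment <- function(ref_aligned, query_aligned, model) {
  if (nchar(ref_aligned) != nchar(query_aligned)) {
    abort("aligned strings must have equal length")
  }
  rc <- strsplit(ref_aligned, "", fixed = TRUE)[[1]]
  qc <- strsplit(query_aligned, "", fixed = TRUE)[[1]]
  ref_pos <- cumsum(rc != "-")
  ref_pos[rc == "-"] <- NA_integer_
  ref_len <- sum(rc != "-")

  exons <- model$exons[[1]]
  n_exons <- nrow(exons)
  if (max(exons) > ref_len) {
    abort("gene model exceeds the reference locus length")
  }
  # per-reference-position feature lookup
  region <- rep("flank", ref_len)
  feat <- rep(0L, ref_len)
  for (i in seq_len(n_exons)) {
    region[exons[i, "start"]:exons[i, "end"]] <- "exon"
    feat[exons[i, "start"]:exons[i, "end"]] <- i
    if (i < n_exons) {
      ib <- (exons[i, "end"] + 1L):(exons[i + 1L, "start"] - 1L)
      region[ib] <- "intron"
      feat[ib] <- i
    }
  }
  cds_pos <- rep(NA_integer_, ref_len)
  cds_pos[region == "exon"] <- seq_len(sum(region == "exon"))

  col_region <- rep(NA_character_, length(rc))
  col_feat <- rep(NA_integer_, length(rc))
  col_cds <- rep(NA_integer_, length(rc))
  has_ref <- !is.na(ref_pos)
  col_region[has_ref] <- region[ref_pos[has_ref]]
  col_feat[has_ref] <- feat[ref_pos[has_ref]]
  col_cds[has_ref] <- cds_pos[ref_pos[has_ref]]
  # insertions inherit the feature of the last preceding reference column
  if (any(!has_ref)) {
    last_region <- col_region
    last_feat <- col_feat
    for (j in seq_along(rc)) {
      if (is.na(last_region[j]) && j > 1) {
        last_region[j] <- last_region[j - 1]
        last_feat[j] <- last_feat[j - 1]
      }
    }
    col_region[!has_ref] <- last_region[!has_ref]
    col_feat[!has_ref] <- last_feat[!has_ref]
    col_region[is.na(col_region)] <- "flank"
    col_feat[is.na(col_feat)] <- 0L
  }

  structure(list(
    gene_id = model$gene_id[[1]],
    cols = tibble::tibble(
      col = seq_along(rc), ref_char = rc, query_char = qc,
      ref_pos = ref_pos, region = col_region, feat = col_feat,
      cds_pos = col_cds
    ),
    model = model,
    start_phase = model$start_phase[[1]],
    n_exons = n_exons,
    cds_length = sum(region == "exon")
  ), class = "coding_alignment")
}

empty_calls <- function() {
  tibble::tibble(
    gene_id = character(), category = character(),
    exon_or_intron_index = integer(), length = integer(),
    codon_index = integer(), position = numeric(), note = character()
  )
}

one_call <- function(aln, category, index, length = 0L, codon_index = 0L,
                     position, note = "") {
  tibble::tibble(
    gene_id = aln$gene_id, category = category,
    exon_or_intron_index = as.integer(index), length = as.integer(length),
    codon_index = as.integer(codon_index), position = as.numeric(position),
    note = note
  )
}

#' Detect loss of the ATG start codon
#'
#' Emits one `start_codon_loss` call iff the query's first codon (sense
#' strand, reference-projected) is not ATG. No alternative-start whitelist
#' is applied: any non-ATG first codon is called, matching the convention
#' of treating e.g. ACA as a start-codon mutation. A gap inside the first
#' codon yields a call noted as unalignable.
#'
#' @param aln A [coding_alignment()] with `start_phase == 0`.
#' @return Mutation-call tibble (zero or one row).
#' @export
detect_start_loss <- function(aln) {
  if (aln$start_phase != 0) {
    abort("start-codon assessment requires start_phase == 0")
  }
  cols <- dplyr::filter(aln$cols, !is.na(.data$cds_pos), .data$cds_pos <= 3)
  if (nrow(cols) < 3) return(empty_calls())
  codon <- toupper(paste(cols$query_char, collapse = ""))
  pos <- min(cols$ref_pos)
  if (grepl("-", codon, fixed = TRUE)) {
    return(one_call(aln, "start_codon_loss", 1L, codon_index = 1L,
                    position = pos, note = "start region unalignable"))
  }
  if (codon != "ATG") {
    return(one_call(aln, "start_codon_loss", 1L, codon_index = 1L,
                    position = pos, note = paste0("first codon ", codon)))
  }
  empty_calls()
}

#' Detect premature stop codons in the reference-projected frame
#'
#' Codon boundaries are taken from the reference CDS coordinates (so stops
#' downstream of a query frameshift are still reported independently). One
#' `premature_stop` call is emitted per internal TAA/TAG/TGA whose three
#' reference-projected query bases are ungapped; the terminal reference
#' codon is excluded.
#'
#' @param aln A [coding_alignment()].
#' @return Mutation-call tibble with `codon_index` (1-based over the CDS)
#'   and the exon containing the codon start.
#' @export
detect_premature_stops <- function(aln) {
  cds <- dplyr::filter(aln$cols, !is.na(.data$cds_pos))
  cds <- dplyr::arrange(cds, .data$cds_pos)
  L <- aln$cds_length
  offset <- (3L - aln$start_phase) %% 3L  # bases completing an upstream codon
  first_full <- offset + 1L
  n_codons <- (L - offset) %/% 3L
  if (n_codons < 1) return(empty_calls())
  q <- toupper(cds$query_char)
  calls <- list()
  for (k in seq_len(n_codons)) {
    s <- first_full + 3L * (k - 1L)
    idx <- s:(s + 2L)
    if (max(idx) > nrow(cds)) break
    codon <- paste(q[idx], collapse = "")
    if (s + 2L == L) next  # terminal codon of the CDS
    if (codon %in% c("TAA", "TAG", "TGA")) {
      calls[[length(calls) + 1L]] <- one_call(
        aln, "premature_stop", cds$feat[s], codon_index = k,
        position = cds$ref_pos[s], note = codon
      )
    }
  }
  dplyr::bind_rows(calls) %||% empty_calls()
}

# maximal gap runs in the alignment, annotated with the features they touch
indel_runs <- function(aln) {
  cols <- aln$cols
  state <- dplyr::case_when(
    cols$query_char == "-" & cols$ref_char != "-" ~ "del",
    cols$ref_char == "-" ~ "ins",
    TRUE ~ "match"
  )
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- tibble::tibble(kind = r$values, from = starts, to = ends)
  runs <- dplyr::filter(runs, .data$kind != "match")
  if (nrow(runs) == 0) {
    return(tibble::tibble(
      kind = character(), from = integer(), to = integer(), len = integer(),
      touches_exon = logical(), touches_intron = logical(),
      touches_flank = logical(), exon_idx = integer(), intron_idx = integer(),
      same_feature = logical(), position = numeric()
    ))
  }
  info <- purrr::pmap_dfr(runs, function(kind, from, to) {
    span <- cols[from:to, ]
    if (kind == "del") {
      regions <- span$region
      feats <- span$feat
      pos <- min(span$ref_pos, na.rm = TRUE)
    } else {
      # insertion: classify by the reference columns on either side
      prev <- if (from > 1) cols[from - 1L, ] else NULL
      nxt <- if (to < nrow(cols)) cols[to + 1L, ] else NULL
      regions <- c(if (!is.null(prev)) prev$region, if (!is.null(nxt)) nxt$region)
      feats <- c(if (!is.null(prev)) prev$feat, if (!is.null(nxt)) nxt$feat)
      pos <- if (!is.null(prev) && !is.na(prev$ref_pos)) prev$ref_pos + 0.5 else 0.5
    }
    tibble::tibble(
      len = to - from + 1L,
      touches_exon = any(regions == "exon"),
      touches_intron = any(regions == "intron"),
      touches_flank = any(regions == "flank"),
      exon_idx = if (any(regions == "exon")) feats[regions == "exon"][1] else NA_integer_,
      intron_idx = if (any(regions == "intron")) feats[regions == "intron"][1] else NA_integer_,
      same_feature = length(unique(paste(regions, feats))) == 1L,
      position = pos
    )
  })
  dplyr::bind_cols(runs, info)
}

#' Detect coding insertions and deletions
#'
#' Each maximal gap run lying fully inside one coding exon yields a
#' `frameshift_indel` call when its length is not a multiple of 3, and an
#' `inframe_indel` otherwise. Adjacent insertion and deletion runs are
#' reported separately, never netted. Runs spanning an exon-intron boundary
#' are left to [detect_splice_mutations()]; purely intronic or flanking
#' runs are ignored.
#'
#' @param aln A [coding_alignment()].
#' @return Mutation-call tibble with indel `length` and the exon index.
#' @export
detect_frameshifts <- function(aln) {
  runs <- indel_runs(aln)
  if (nrow(runs) == 0) return(empty_calls())
  coding <- dplyr::filter(runs, .data$touches_exon, !.data$touches_intron,
                          !.data$touches_flank, .data$same_feature)
  if (nrow(coding) == 0) return(empty_calls())
  purrr::pmap_dfr(coding, function(kind, len, exon_idx, position, ...) {
    category <- if (len %% 3L != 0L) "frameshift_indel" else "inframe_indel"
    one_call(aln, category, exon_idx, length = len, position = position,
             note = paste0(len, " nt ", ifelse(kind == "del", "deletion", "insertion")))
  })
}

#' Detect canonical splice-site disruptions
#'
#' For each intron, the reference-projected query dinucleotides at the
#' intron's first two (donor) and last two (acceptor) positions are checked
#' against the canonical GT / AG. A gap run spanning an exon-intron
#' boundary is reported as a single `splice_boundary_indel` (regardless of
#' its length mod 3) and suppresses the corresponding donor/acceptor call.
#' Non-canonical but functional sites (e.g. GC donors) are over-called by
#' design; see the package vignette.
#'
#' @param aln A [coding_alignment()].
#' @return Mutation-call tibble with the 1-based intron index.
#' @export
detect_splice_mutations <- function(aln) {
  if (aln$n_exons < 2) return(empty_calls())
  exons <- aln$model$exons[[1]]
  runs <- indel_runs(aln)
  boundary <- dplyr::filter(runs, .data$kind == "del", .data$touches_exon,
                            .data$touches_intron)
  calls <- list()
  if (nrow(boundary) > 0) {
    calls <- purrr::pmap(boundary, function(len, intron_idx, position, ...) {
      one_call(aln, "splice_boundary_indel", intron_idx, length = len,
               position = position, note = paste0(len, " nt boundary deletion"))
    })
  }
  cols <- aln$cols
  q_at <- function(p) {
    ch <- cols$query_char[!is.na(cols$ref_pos) & cols$ref_pos == p]
    if (length(ch) == 0) "-" else toupper(ch[1])
  }
  covered_by_boundary <- function(p) {
    if (nrow(boundary) == 0) return(FALSE)
    any(purrr::map_lgl(seq_len(nrow(boundary)), function(i) {
      span <- cols[boundary$from[i]:boundary$to[i], ]
      p %in% span$ref_pos
    }))
  }
  for (i in seq_len(aln$n_exons - 1L)) {
    istart <- exons[i, "end"] + 1L
    iend <- exons[i + 1L, "start"] - 1L
    if (iend < istart + 3L) next  # intron too short to hold both sites
    donor <- paste0(q_at(istart), q_at(istart + 1L))
    acceptor <- paste0(q_at(iend - 1L), q_at(iend))
    if (donor != "GT" &&
        !(covered_by_boundary(istart) || covered_by_boundary(istart + 1L))) {
      calls[[length(calls) + 1L]] <- one_call(
        aln, "splice_donor", i, position = istart,
        note = paste0("GT to ", donor)
      )
    }
    if (acceptor != "AG" &&
        !(covered_by_boundary(iend - 1L) || covered_by_boundary(iend))) {
      calls[[length(calls) + 1L]] <- one_call(
        aln, "splice_acceptor", i, position = iend - 1L,
        note = paste0("AG to ", acceptor)
      )
    }
  }
  dplyr::bind_rows(calls) %||% empty_calls()
}

INACTIVATING_CATEGORIES <- c(
  "start_codon_loss", "premature_stop", "frameshift_indel",
  "splice_donor", "splice_acceptor", "splice_boundary_indel"
)

#' Screen a candidate gene locus for inactivating mutations
#'
#' Aligns a query locus to its functional reference ortholog (or consumes a
#' precomputed alignment), projects the reference gene model through the
#' alignment and runs all mutation detectors: start-codon loss, premature
#' stops in the reference-projected frame, coding frameshift/in-frame
#' indels, and canonical splice-site disruptions. Calls are returned in 5'
#' to 3' order.
#'
#' @param model One-row gene-model tibble ([gene_model()]).
#' @param ref Reference locus sequence (string or one-row sequence tibble).
#' @param query Query locus sequence. An empty/absent query is an error:
#'   route such genes to [infer_gene_deletion()] instead.
#' @param alignment Optional precomputed alignment, a list with
#'   `ref_aligned` and `query_aligned`; when NULL, [align_pair()] runs with
#'   the `...` scoring arguments.
#' @param ... Passed to [align_pair()].
#' @return Object of class `inactivation_report`: `gene_id`, `calls`
#'   (mutation-call tibble), `n_inactivating` (excludes `inframe_indel`),
#'   `cds_gc_percent` (GC% of the query's aligned coding bases), `synteny`
#'   (NULL; see [infer_gene_deletion()]).
#' @export
screen_gene <- function(model, ref, query, alignment = NULL, ...) {
  ref <- as_seq_string(ref)
  q <- tryCatch(as_seq_string(query), error = function(e) "")
  if (is.null(query) || nchar(q) == 0) {
    abort(paste0(
      "query locus for ", model$gene_id[[1]],
      " is empty; use infer_gene_deletion() to assess whole-gene loss"
    ))
  }
  if (is.null(alignment)) {
    alignment <- align_pair(ref, q, ...)
  }
  aln <- coding_alignment(alignment$ref_aligned, alignment$query_aligned, model)
  calls <- dplyr::bind_rows(
    if (aln$start_phase == 0) detect_start_loss(aln) else empty_calls(),
    detect_premature_stops(aln),
    detect_frameshifts(aln),
    detect_splice_mutations(aln)
  )
  calls <- dplyr::arrange(calls, .data$position, .data$category)

  exon_q <- dplyr::filter(aln$cols, .data$region == "exon",
                          .data$query_char != "-")
  qb <- toupper(exon_q$query_char)
  gc <- 100 * sum(qb %in% c("G", "C")) / max(length(qb), 1L)

  structure(list(
    gene_id = model$gene_id[[1]],
    calls = calls,
    n_inactivating = sum(calls$category %in% INACTIVATING_CATEGORIES),
    cds_gc_percent = gc,
    synteny = NULL,
    alignment = aln
  ), class = "inactivation_report")
}

#' @export
print.inactivation_report <- function(x, ...) {
  cat("Inactivation screen:", x$gene_id, "\n")
  cat(sprintf("  calls: %d (%d inactivating)  CDS GC%%: %.1f\n",
              nrow(x$calls), x$n_inactivating, x$cds_gc_percent))
  if (nrow(x$calls) > 0) {
    print(dplyr::select(x$calls, -"gene_id"), n = Inf)
  }
  if (!is.null(x$synteny)) {
    cat("  synteny verdict:", x$synteny$verdict, "\n")
  }
  invisible(x)
}

#' @rdname screen_gene
#' @param x An `inactivation_report`.
#' @export
tidy.inactivation_report <- function(x, ...) x$calls

#' @rdname screen_gene
#' @export
glance.inactivation_report <- function(x, ...) {
  tibble::tibble(
    gene_id = x$gene_id, n_calls = nrow(x$calls),
    n_inactivating = x$n_inactivating,
    cds_gc_percent = x$cds_gc_percent,
    verdict = if (is.null(x$synteny)) NA_character_ else x$synteny$verdict
  )
}

#' @rdname screen_gene
#' @param object An `inactivation_report`.
#' @export
autoplot.inactivation_report <- function(object, ...) {
  exons <- object$alignment$model$exons[[1]]
  ex <- tibble::tibble(start = exons[, "start"], end = exons[, "end"],
                       exon = seq_len(nrow(exons)))
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = tibble::tibble(x = min(ex$start), xend = max(ex$end)),
      ggplot2::aes(x = .data$x, xend = .data$xend, y = 0, yend = 0),
      linewidth = 0.3, colour = "grey50"
    ) +
    ggplot2::geom_rect(
      data = ex,
      ggplot2::aes(xmin = .data$start, xmax = .data$end, ymin = -0.2, ymax = 0.2),
      fill = "grey80", colour = "grey30"
    ) +
    ggplot2::labs(x = "reference locus position (nt)", y = NULL,
                  title = paste0(object$gene_id, ": inactivating-mutation calls"),
                  colour = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
  if (nrow(object$calls) > 0) {
    p <- p + ggplot2::geom_point(
      data = object$calls,
      ggplot2::aes(x = .data$position, y = 0.4, colour = .data$category),
      shape = 17, size = 3
    )
  }
  p
}

#' Infer whole-gene deletion from flanking-gene synteny
#'
#' When a gene has no probe hit at all, its loss can still be supported by
#' synteny: if the two genes flanking it in related genomes both map to one
#' scaffold and the intergenic sequence is real sequence rather than an
#' N-gap, the gene was deleted rather than simply unassembled. Flanks on
#' different scaffolds, or an N-dominated intergap, leave the case
#' indeterminate.
#'
#' @param left_flank_hits,right_flank_hits Hit tibbles
#'   ([read_hits_table()]) for the two flanking genes (may be empty).
#' @param probe_hits Hit tibble for the gene's own probe.
#' @param assembly Sequence tibble holding the scaffolds (for the N-fraction
#'   check).
#' @param gene_id Gene identifier for the report.
#' @param max_n_fraction Maximum intergenic N fraction compatible with a
#'   `deletion_supported` verdict (default 0.2).
#' @return One-row tibble: `gene_id`, `left_scaffold`, `left_min`,
#'   `left_max`, `right_scaffold`, `right_min`, `right_max`,
#'   `probe_hit_present`, `intergenic_n_fraction`, `verdict` (one of
#'   `gene_present`, `deletion_supported`, `indeterminate_split`,
#'   `indeterminate_gap`, `no_evidence`).
#' @export
infer_gene_deletion <- function(left_flank_hits, right_flank_hits, probe_hits,
                                assembly, gene_id = "gene",
                                max_n_fraction = 0.2) {
  best_hit <- function(h) {
    if (is.null(h) || nrow(h) == 0) return(NULL)
    h <- dplyr::arrange(h, dplyr::desc(.data$aln_length), .data$mismatches,
                        .data$subject_id)
    h[1, ]
  }
  out <- tibble::tibble(
    gene_id = gene_id,
    left_scaffold = NA_character_, left_min = NA_integer_, left_max = NA_integer_,
    right_scaffold = NA_character_, right_min = NA_integer_, right_max = NA_integer_,
    probe_hit_present = !is.null(probe_hits) && nrow(probe_hits) > 0,
    intergenic_n_fraction = NA_real_, verdict = NA_character_
  )
  if (out$probe_hit_present) {
    out$verdict <- "gene_present"
    return(out)
  }
  left <- best_hit(left_flank_hits)
  right <- best_hit(right_flank_hits)
  if (is.null(left) || is.null(right)) {
    out$verdict <- "no_evidence"
    return(out)
  }
  out$left_scaffold <- left$subject_id
  out$left_min <- left$subject_min
  out$left_max <- left$subject_max
  out$right_scaffold <- right$subject_id
  out$right_min <- right$subject_min
  out$right_max <- right$subject_max
  if (left$subject_id != right$subject_id) {
    out$verdict <- "indeterminate_split"
    return(out)
  }
  lo <- min(left$subject_max, right$subject_max) + 1L
  hi <- max(left$subject_min, right$subject_min) - 1L
  n_frac <- 0
  if (hi >= lo) {
    scaf <- assembly$seq[assembly$id == left$subject_id]
    if (length(scaf) != 1) {
      abort(paste0("scaffold ", left$subject_id, " not found in assembly"))
    }
    inter <- toupper(substring(scaf[[1]], lo, hi))
    n_frac <- stringr::str_count(inter, "N") / nchar(inter)
  }
  out$intergenic_n_fraction <- n_frac
  out$verdict <- if (n_frac <= max_n_fraction) "deletion_supported" else "indeterminate_gap"
  out
}

#' Clean a multi-species codon alignment for downstream selection analyses
#'
#' Removes, for every taxon, any codon column in which any sequence carries
#' a stop codon (TAA/TAG/TGA), and optionally any codon column containing a
#' gap in any sequence (the operational stand-in for "questionable
#' homology"). Writes sequential relaxed PHYLIP and/or aligned FASTA.
#'
#' @param aln Named character vector, or tibble with `id` and `seq`, of
#'   equal-length aligned sequences whose length is divisible by 3.
#' @param drop_gap_columns Drop codon columns containing any gap
#'   (default TRUE).
#' @param fasta_path,phylip_path Optional output paths.
#' @return Tibble `id`, `seq` of the cleaned alignment (possibly zero-width
#'   sequences if everything was removed).
#' @export
export_codon_alignment <- function(aln, drop_gap_columns = TRUE,
                                   fasta_path = NULL, phylip_path = NULL) {
  if (is.data.frame(aln)) {
    ids <- aln$id
    seqs <- aln$seq
  } else {
    ids <- names(aln)
    seqs <- unname(aln)
  }
  if (length(seqs) < 2) abort("a codon alignment needs at least 2 sequences")
  widths <- unique(nchar(seqs))
  if (length(widths) != 1) abort("aligned sequences must have equal length")
  if (widths %% 3 != 0) abort("alignment length must be divisible by 3")
  n_codons <- widths / 3
  mat <- do.call(rbind, strsplit(toupper(seqs), "", fixed = TRUE))
  keep <- rep(TRUE, n_codons)
  for (k in seq_len(n_codons)) {
    cols <- (3 * k - 2):(3 * k)
    codons <- apply(mat[, cols, drop = FALSE], 1, paste, collapse = "")
    if (any(codons %in% c("TAA", "TAG", "TGA"))) keep[k] <- FALSE
    if (drop_gap_columns && any(grepl("-", codons, fixed = TRUE))) keep[k] <- FALSE
  }
  keep_cols <- as.vector(vapply(which(keep), function(k) (3 * k - 2):(3 * k),
                                integer(3)))
  orig <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  cleaned <- apply(orig[, keep_cols, drop = FALSE], 1, paste, collapse = "")
  if (length(keep_cols) == 0) cleaned <- rep("", length(seqs))
  out <- tibble::tibble(id = ids, seq = cleaned)
  if (!is.null(fasta_path)) write_fasta(out, fasta_path, wrap = 60)
  if (!is.null(phylip_path)) {
    con <- file(phylip_path, "wt")
    writeLines(paste(length(ids), nchar(cleaned[1])), con)
    writeLines(paste(ids, cleaned, sep = "  "), con)
    close(con)
  }
  out
}
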