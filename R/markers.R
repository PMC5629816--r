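#' Pair forward/reverse primer hits into microsatellite loci
#'
#' For each locus, the best hit of its forward and reverse primer (highest
#' alignment length, ties broken by fewest mismatches then lowest scaffold
#' id) are paired when they land on one scaffold within `max_span`. Loci
#' with a missing primer hit, or with best hits on different scaffolds or
#' too far apart, are reported unpaired with NA coordinates.
#'
#' @param hits Hit tibble from [read_hits_table()] with `query_length`
#'   populated (full primer lengths).
#' @param pairs Tibble mapping `locus_id` to `forward_id` and `reverse_id`
#'   (the primer query ids).
#' @param max_span Maximum start-to-start span for a valid pairing
#'   (default 10000 nt).
#' @return Tibble with one row per locus: `locus_id`, `paired`, `scaffold`,
#'   forward and reverse primer columns (`f_start`, `f_end`, `f_length`,
#'   `f_aln_length`, and `r_*` alike) and `product_length` (NA when
#'   unpaired).
#' @export
pair_primer_hits <- function(hits, pairs, max_span = 10000) {
  if (max_span <= 0) abort("`max_span` must be > 0")
  best_for <- function(qid) {
    h <- dplyr::filter(hits, .data$query_id == qid)
    if (nrow(h) == 0) return(NULL)
    h <- dplyr::arrange(h, dplyr::desc(.data$aln_length), .data$mismatches,
                        .data$subject_id)
    h[1, ]
  }
  purrr::pmap_dfr(pairs, function(locus_id, forward_id, reverse_id, ...) {
    f <- best_for(forward_id)
    r <- best_for(reverse_id)
    row <- tibble::tibble(
      locus_id = locus_id, paired = FALSE, scaffold = NA_character_,
      f_start = NA_integer_, f_end = NA_integer_,
      f_length = NA_integer_, f_aln_length = NA_integer_,
      r_start = NA_integer_, r_end = NA_integer_,
      r_length = NA_integer_, r_aln_length = NA_integer_,
      product_length = NA_integer_
    )
    if (!is.null(f)) {
      row$f_start <- f$subject_start; row$f_end <- f$subject_end
      row$f_length <- f$query_length; row$f_aln_length <- f$aln_length
    }
    if (!is.null(r)) {
      row$r_start <- r$subject_start; row$r_end <- r$subject_end
      row$r_length <- r$query_length; row$r_aln_length <- r$aln_length
    }
    if (is.null(f) || is.null(r)) return(row)
    if (f$subject_id != r$subject_id) return(row)
    if (abs(f$subject_start - r$subject_start) + 1 > max_span) return(row)
    row$paired <- TRUE
    row$scaffold <- f$subject_id
    row$product_length <- product_length(row)
    row
  })
}

#' Inferred PCR product length of a paired marker locus
#'
#' The product spans the outermost mapped coordinates of the primer pair.
#' When a primer aligned only partially, its outer (5'-distal) end is
#' extended outward by the unaligned remainder (`primer_length -
#' aln_length`), recovering the full-primer product a PCR would yield. The
#' product is then `max - min + 1` over the four post-extension
#' coordinates.
#'
#' @param locus One-row locus tibble as produced by [pair_primer_hits()]
#'   (columns `f_start`, `f_end`, `f_length`, `f_aln_length` and `r_*`).
#' @return Integer product length in nt.
#' @export
product_length <- function(locus) {
  stopifnot(nrow(locus) == 1)
  coords <- c(locus$f_start, locus$f_end, locus$r_start, locus$r_end)
  if (anyNA(coords)) abort("product_length requires a fully paired locus")
  lo <- min(coords)
  hi <- max(coords)
  extend <- function(start, end, trim) {
    # the outer end of this primer is whichever of its coordinates is the
    # locus-wide extreme; unaligned primer bases extend it outward
    if (trim <= 0) return(c(start, end))
    if (max(start, end) == hi) {
      return(c(min(start, end), max(start, end) + trim))
    }
    if (min(start, end) == lo) {
      return(c(min(start, end) - trim, max(start, end)))
    }
    c(start, end)
  }
  f <- extend(locus$f_start, locus$f_end, locus$f_length - locus$f_aln_length)
  r <- extend(locus$r_start, locus$r_end, locus$r_length - locus$r_aln_length)
  all_coords <- c(f, r)
  as.integer(max(all_coords) - min(all_coords) + 1)
}

#' Inclusive distance between two mapped primers
#'
#' Distances are measured between the printed 5' mapping coordinates
#' ("Genome Start", the first aligned base of each primer), inclusive:
#' `|a - b| + 1`. Identical coordinates give distance 1.
#'
#' @param a_start,b_start Printed start coordinates of the two primers.
#' @param a_scaffold,b_scaffold Optional scaffold names; if both given they
#'   must match.
#' @return Integer distance in nt.
#' @export
#' @examples
#' marker_distance(780562, 768391) # 12172
marker_distance <- function(a_start, b_start,
                            a_scaffold = NULL, b_scaffold = NULL) {
  if (!is.null(a_scaffold) && !is.null(b_scaffold) &&
      !identical(a_scaffold, b_scaffold)) {
    abort("marker distance is only defined on a single scaffold")
  }
  as.integer(abs(a_start - b_start) + 1)
}

#' Group mapped loci by scaffold and annotate linkage
#'
#' Partitions paired loci by scaffold: loci alone on their scaffold are
#' unlinked; scaffolds carrying several loci form linkage groups whose
#' pairwise forward-primer distances are reported.
#'
#' @param loci Locus tibble from [pair_primer_hits()] (unpaired rows are
#'   ignored).
#' @return List with `groups` (tibble `locus_id`, `scaffold`, `group_size`,
#'   `linked`) and `distances` (tibble `scaffold`, `locus_a`, `locus_b`,
#'   `distance` for multi-locus scaffolds).
#' @export
linkage_report <- function(loci) {
  paired <- dplyr::filter(loci, .data$paired)
  groups <- paired |>
    dplyr::add_count(.data$scaffold, name = "group_size") |>
    dplyr::mutate(linked = .data$group_size > 1) |>
    dplyr::select("locus_id", "scaffold", "group_size", "linked")
  dists <- paired |>
    dplyr::group_by(.data$scaffold) |>
    dplyr::group_map(function(g, key) {
      if (nrow(g) < 2) return(NULL)
      combos <- utils::combn(nrow(g), 2)
      purrr::map_dfr(seq_len(ncol(combos)), function(j) {
        i1 <- combos[1, j]; i2 <- combos[2, j]
        tibble::tibble(
          scaffold = key$scaffold,
          locus_a = g$locus_id[i1], locus_b = g$locus_id[i2],
          distance = marker_distance(g$f_start[i1], g$f_start[i2])
        )
      })
    }) |>
    dplyr::bind_rows()
  if (nrow(dists) == 0) {
    dists <- tibble::tibble(scaffold = character(), locus_a = character(),
                            locus_b = character(), distance = integer())
  }
  list(groups = groups, distances = dists)
}

#' Plot mapped marker loci along their scaffolds
#'
#' @param loci Locus tibble from [pair_primer_hits()].
#' @return A ggplot showing each paired locus at its scaffold position,
#'   sized by product length.
#' @export
plot_marker_map <- function(loci) {
  paired <- dplyr::filter(loci, .data$paired)
  ggplot2::ggplot(paired, ggplot2::aes(x = pmin(.data$f_start, .data$r_start),
                                       y = .data$scaffold)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$product_length),
                        colour = "grey30", alpha = 0.8) +
    ggplot2::geom_text(ggplot2::aes(label = .data$locus_id),
                       vjust = -1, size = 3) +
    ggplot2::labs(x = "scaffold position (nt)", y = NULL,
                  size = "product (nt)",
                  title = "In-silico microsatellite map") +
    ggplot2::theme_minimal()
}
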