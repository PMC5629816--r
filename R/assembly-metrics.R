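#' Drop sequences shorter than a minimum length
#'
#' Mirrors the final-assembly convention of removing all contigs and
#' scaffolds under 1,000 nt before computing statistics: strictly shorter
#' records are removed, order is preserved, and the operation is idempotent.
#'
#' @param assembly Sequence tibble from [read_fasta()].
#' @param min_length Minimum retained length (nt); 0 keeps everything.
#' @return Filtered sequence tibble.
#' @export
filter_min_length <- function(assembly, min_length) {
  if (min_length < 0) abort("`min_length` must be >= 0")
  dplyr::filter(assembly, .data$length >= min_length)
}

#' Split scaffolds into contigs at runs of N
#'
#' A run of `n_run_min` or more consecutive `N`/`n` characters is treated as
#' an unsequenced gap and splits the scaffold into contigs. `n_run_min = 1`
#' reproduces the conservative every-N convention used for draft-assembly
#' comparison; `n_run_min = 25` reproduces the final-report convention
#' (25+ N gaps only). Leading/trailing N runs produce no empty contigs, and
#' concatenating each scaffold's contigs with its removed N runs (in order)
#' reconstructs the scaffold exactly.
#'
#' @param assembly Sequence tibble from [read_fasta()].
#' @param n_run_min Minimum N-run length that splits (>= 1).
#' @return List with `contigs` (sequence tibble; ids are
#'   `<scaffold>.<ordinal>`, plus `scaffold` and `ordinal` columns) and
#'   `gaps` (tibble `scaffold`, `start` (1-based), `length`), internal gaps
#'   only.
#' @export
split_scaffolds <- function(assembly, n_run_min = 25) {
  if (n_run_min < 1) abort("`n_run_min` must be >= 1")
  contigs <- vector("list", nrow(assembly))
  gaps <- vector("list", nrow(assembly))
  pattern <- paste0("[Nn]{", n_run_min, ",}")
  for (i in seq_len(nrow(assembly))) {
    s <- assembly$seq[[i]]
    scaf_id <- assembly$id[[i]]
    m <- gregexpr(pattern, s, perl = TRUE)[[1]]
    if (m[1] == -1) {
      contigs[[i]] <- tibble::tibble(
        id = paste0(scaf_id, ".1"), seq = s, length = nchar(s),
        scaffold = scaf_id, ordinal = 1L
      )
      next
    }
    run_start <- as.integer(m)
    run_len <- attr(m, "match.length")
    run_end <- run_start + run_len - 1L
    # contig spans are the complement of the runs
    piece_start <- c(1L, run_end + 1L)
    piece_end <- c(run_start - 1L, nchar(s))
    keep <- piece_end >= piece_start
    piece_start <- piece_start[keep]
    piece_end <- piece_end[keep]
    pieces <- substring(s, piece_start, piece_end)
    contigs[[i]] <- tibble::tibble(
      id = paste0(scaf_id, ".", seq_along(pieces)),
      seq = pieces, length = nchar(pieces),
      scaffold = scaf_id, ordinal = seq_along(pieces)
    )
    internal <- run_start > 1L & run_end < nchar(s)
    if (any(internal)) {
      gaps[[i]] <- tibble::tibble(
        scaffold = scaf_id,
        start = run_start[internal],
        length = run_len[internal]
      )
    }
  }
  gaps_tbl <- dplyr::bind_rows(gaps)
  if (ncol(gaps_tbl) == 0) {
    gaps_tbl <- tibble::tibble(scaffold = character(), start = integer(),
                               length = integer())
  }
  contigs_tbl <- dplyr::bind_rows(contigs)
  if (ncol(contigs_tbl) == 0) {
    contigs_tbl <- tibble::tibble(id = character(), seq = character(),
                                  length = integer(), scaffold = character(),
                                  ordinal = integer())
  }
  list(contigs = contigs_tbl, gaps = gaps_tbl)
}

#' Nx / Lx continuity statistics
#'
#' For each level x, sequences are sorted by descending length; Nx is the
#' length of the sequence at which the cumulative length first reaches x% of
#' the total, and Lx is the number of sequences up to and including it.
#'
#' @param lengths Vector of sequence lengths (all >= 1, nonempty).
#' @param levels Percent levels in (0, 100]; default `c(50, 60, 70, 80, 90)`.
#' @return Tibble with columns `level`, `nx`, `lx`.
#' @export
#' @examples
#' nx_stats(c(500, 400, 300, 200, 100), levels = 50) # N50 = 400, L50 = 2
nx_stats <- function(lengths, levels = c(50, 60, 70, 80, 90)) {
  if (length(lengths) == 0) abort("`lengths` must be nonempty")
  if (any(lengths < 1)) abort("all lengths must be >= 1")
  if (any(levels <= 0 | levels > 100)) abort("levels must lie in (0, 100]")
  sorted <- sort(lengths, decreasing = TRUE)
  csum <- cumsum(as.numeric(sorted))
  total <- csum[length(csum)]
  purrr::map_dfr(levels, function(x) {
    idx <- which(csum >= total * x / 100)[1]
    tibble::tibble(level = x, nx = sorted[idx], lx = idx)
  })
}

#' Assembly metrics configuration
#'
#' @param n_run_min N-run length that splits scaffolds into contigs
#'   (default 25, the final-report convention; 1 gives the conservative
#'   every-N convention).
#' @param min_length Drop sequences shorter than this before computing
#'   statistics (default 0 = keep all).
#' @param nx_levels Nx/Lx percent levels (strictly increasing in (0, 100]).
#' @param class_thresholds Length-class thresholds for the strict
#'   "number of sequences > T" counts.
#' @return A list of class `metrics_config`.
#' @export
metrics_config <- function(n_run_min = 25, min_length = 0,
                           nx_levels = c(50, 60, 70, 80, 90),
                           class_thresholds = c(1e3, 1e4, 1e5, 1e6, 1e7)) {
  if (n_run_min < 1) abort("`n_run_min` must be >= 1")
  if (min_length < 0) abort("`min_length` must be >= 0")
  if (any(diff(nx_levels) <= 0) || any(nx_levels <= 0 | nx_levels > 100)) {
    abort("`nx_levels` must be strictly increasing within (0, 100]")
  }
  if (any(diff(class_thresholds) <= 0)) {
    abort("`class_thresholds` must be strictly increasing")
  }
  structure(
    list(n_run_min = n_run_min, min_length = min_length,
         nx_levels = nx_levels, class_thresholds = class_thresholds),
    class = "metrics_config"
  )
}

count_bases <- function(seqs) {
  # case-folded single-pass composition count over all sequences
  up <- toupper(paste(seqs, collapse = ""))
  tab <- table(strsplit(up, "", fixed = TRUE)[[1]])
  get <- function(b) if (b %in% names(tab)) as.numeric(tab[[b]]) else 0
  list(
    total = sum(tab),
    gc = get("G") + get("C"),
    n = get("N"),
    acgt = get("A") + get("C") + get("G") + get("T")
  )
}

#' Summarise an assembly's continuity and composition
#'
#' Computes the full continuity/composition summary for a scaffolded
#' assembly: counts, length distribution, strict length-class counts
#' ("number of scaffolds > T nt"), Nx/Lx at the configured levels, %GC over
#' non-N bases, %N over all bases, contig statistics under the configured
#' N-run splitting convention, and internal-gap statistics.
#'
#' A scaffold with no internal gap at `n_run_min` is a single unscaffolded
#' contig; scaffolds with two or more contigs contribute their contig mass
#' to the "assembly in scaffolded contigs" percentage (denominator: total
#' assembly length including Ns).
#'
#' @param assembly Sequence tibble from [read_fasta()].
#' @param config A [metrics_config()].
#' @return An object of class `assembly_metrics` (a list), with
#'   [tidy()][generics::tidy], [glance()][generics::glance] and
#'   [autoplot()][ggplot2::autoplot] methods.
#' @export
summarize_assembly <- function(assembly, config = metrics_config()) {
  assembly <- filter_min_length(assembly, config$min_length)
  if (nrow(assembly) == 0) abort("assembly is empty after min-length filtering")
  lens <- assembly$length
  comp <- count_bases(assembly$seq)

  split <- split_scaffolds(assembly, config$n_run_min)
  contigs <- split$contigs
  gaps <- split$gaps
  per_scaffold <- dplyr::count(contigs, .data$scaffold, name = "n_contigs")
  scaffolded <- per_scaffold$scaffold[per_scaffold$n_contigs > 1]
  scaffolded_mass <- sum(contigs$length[contigs$scaffold %in% scaffolded])

  classes <- purrr::map_dfr(config$class_thresholds, function(thr) {
    n <- sum(lens > thr)
    tibble::tibble(threshold = thr, count = n, fraction = 100 * n / length(lens))
  })

  structure(list(
    n_sequences = length(lens),
    total_length = sum(lens),
    longest = max(lens),
    shortest = min(lens),
    mean_length = mean(lens),
    median_length = median(lens),
    counts_over_thresholds = classes,
    nx_table = nx_stats(lens, config$nx_levels),
    pct_gc = 100 * comp$gc / (comp$total - comp$n),
    pct_n = 100 * comp$n / comp$total,
    n_contigs = nrow(contigs),
    n_contigs_in_scaffolds = sum(contigs$scaffold %in% scaffolded),
    n_contigs_unscaffolded = sum(!contigs$scaffold %in% scaffolded),
    pct_assembly_in_scaffolded_contigs = 100 * scaffolded_mass / sum(lens),
    gap_count = nrow(gaps),
    gap_mean_length = if (nrow(gaps) > 0) mean(gaps$length) else NA_real_,
    contig_nx_table = nx_stats(contigs$length, config$nx_levels),
    config = config
  ), class = "assembly_metrics")
}

#' @export
print.assembly_metrics <- function(x, ...) {
  cat("Assembly metrics (N-run split threshold:", x$config$n_run_min, "nt)\n")
  cat(sprintf("  scaffolds: %d  total: %d nt  longest: %d  shortest: %d\n",
              x$n_sequences, x$total_length, x$longest, x$shortest))
  n50 <- dplyr::filter(x$nx_table, .data$level == 50)
  if (nrow(n50) == 1) {
    cat(sprintf("  scaffold N50: %d nt (L50 %d)\n", n50$nx, n50$lx))
  }
  cat(sprintf("  %%GC (non-N): %.2f  %%N: %.2f\n", x$pct_gc, x$pct_n))
  cat(sprintf("  contigs: %d (%d in scaffolds, %d unscaffolded)\n",
              x$n_contigs, x$n_contigs_in_scaffolds, x$n_contigs_unscaffolded))
  cat(sprintf("  internal gaps: %d (mean length %s nt)\n", x$gap_count,
              ifelse(is.na(x$gap_mean_length), "-", format(round(x$gap_mean_length, 1)))))
  invisible(x)
}

#' @rdname summarize_assembly
#' @param x An `assembly_metrics` object.
#' @param ... Unused.
#' @export
tidy.assembly_metrics <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::transmute(x$nx_table, statistic = paste0("scaffold_N", .data$level),
                     value = as.numeric(.data$nx)),
    dplyr::transmute(x$nx_table, statistic = paste0("scaffold_L", .data$level),
                     value = as.numeric(.data$lx)),
    dplyr::transmute(x$contig_nx_table, statistic = paste0("contig_N", .data$level),
                     value = as.numeric(.data$nx)),
    dplyr::transmute(x$counts_over_thresholds,
                     statistic = paste0("n_over_", format(.data$threshold, scientific = FALSE, trim = TRUE)),
                     value = as.numeric(.data$count)),
    tibble::tibble(
      statistic = c("n_sequences", "total_length", "longest", "shortest",
                    "mean_length", "median_length", "pct_gc", "pct_n",
                    "n_contigs", "n_contigs_in_scaffolds", "n_contigs_unscaffolded",
                    "pct_assembly_in_scaffolded_contigs", "gap_count", "gap_mean_length"),
      value = c(x$n_sequences, x$total_length, x$longest, x$shortest,
                x$mean_length, x$median_length, x$pct_gc, x$pct_n,
                x$n_contigs, x$n_contigs_in_scaffolds, x$n_contigs_unscaffolded,
                x$pct_assembly_in_scaffolded_contigs, x$gap_count, x$gap_mean_length)
    )
  )
}

#' @rdname summarize_assembly
#' @export
glance.assembly_metrics <- function(x, ...) {
  n50 <- dplyr::filter(x$nx_table, .data$level == 50)
  c50 <- dplyr::filter(x$contig_nx_table, .data$level == 50)
  tibble::tibble(
    n_sequences = x$n_sequences, total_length = x$total_length,
    scaffold_n50 = if (nrow(n50)) n50$nx else NA_integer_,
    scaffold_l50 = if (nrow(n50)) n50$lx else NA_integer_,
    contig_n50 = if (nrow(c50)) c50$nx else NA_integer_,
    pct_gc = x$pct_gc, pct_n = x$pct_n,
    n_contigs = x$n_contigs, gap_count = x$gap_count
  )
}

#' @rdname summarize_assembly
#' @param object An `assembly_metrics` object.
#' @export
autoplot.assembly_metrics <- function(object, ...) {
  dat <- dplyr::bind_rows(
    dplyr::mutate(object$nx_table, unit = "scaffolds"),
    dplyr::mutate(object$contig_nx_table, unit = "contigs")
  )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$level, y = .data$nx,
                                    colour = .data$unit)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "x (% of assembly)", y = "Nx length (nt)",
                  colour = NULL, title = "Assembly continuity (Nx curve)") +
    ggplot2::theme_minimal()
}
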