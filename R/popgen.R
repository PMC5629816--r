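#' High-coverage exclusion threshold
#'
#' The coverage filter excludes sites whose depth exceeds the mean depth
#' plus `k` standard deviations (sample SD, n-1 denominator), computed over
#' all pre-filter sites and frozen before any site is removed.
#'
#' @param depths Nonempty vector of per-site depths.
#' @param k Number of standard deviations above the mean (default 5).
#' @return The threshold `mean(depths) + k * sd(depths)` (for a single
#'   depth, SD is taken as 0).
#' @export
coverage_threshold <- function(depths, k = 5) {
  if (length(depths) == 0) abort("`depths` must be nonempty")
  if (k < 0) abort("`k` must be >= 0")
  s <- if (length(depths) > 1) stats::sd(depths) else 0
  mean(depths) + k * s
}

#' Site-filter configuration for the divergence estimator
#'
#' @param gq_min Minimum genotype quality for both individuals (default 20;
#'   the study excluded "sites of low genotyping quality" without printing a
#'   cutoff, so this is an explicit, documented parameter).
#' @param coverage_k Coverage rule multiplier: exclude sites with combined
#'   depth above mean + `coverage_k` * SD (default 5).
#' @param exclude_indels Drop indel sites (default TRUE).
#' @param exclude_ref_homalt Drop sites where the reference individual is
#'   homozygous for a non-reference allele (default TRUE).
#' @param reference_individual Which individual matches the reference
#'   assembly, `"a"` (first sample) or `"b"` (default `"a"`).
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(gq_min = 20, coverage_k = 5, exclude_indels = TRUE,
                          exclude_ref_homalt = TRUE, reference_individual = "a") {
  if (gq_min < 0) abort("`gq_min` must be >= 0")
  if (coverage_k < 0) abort("`coverage_k` must be >= 0")
  if (!reference_individual %in% c("a", "b")) {
    abort("`reference_individual` must be 'a' or 'b'")
  }
  structure(
    list(gq_min = gq_min, coverage_k = coverage_k,
         exclude_indels = exclude_indels,
         exclude_ref_homalt = exclude_ref_homalt,
         reference_individual = reference_individual),
    class = "filter_config"
  )
}

#' Apply the divergence-study site filters
#'
#' Removes, in order: indel sites; sites where either individual's GQ falls
#' below `gq_min`; sites where the reference individual carries a homozygous
#' non-reference genotype; and sites whose combined depth (sum over both
#' individuals) exceeds [coverage_threshold()] computed over the combined
#' depths of *all* input sites (frozen before filtering, so the filter is
#' idempotent on its own output given that threshold).
#'
#' @param sites Variant tibble from [read_vcf_two_sample()] (missing
#'   genotypes already excluded by the reader).
#' @param config A [filter_config()].
#' @param threshold Optional pre-frozen coverage cutoff. By default the
#'   cutoff is [coverage_threshold()] over this call's input (or, when
#'   re-filtering previous output, the threshold frozen on it); supplying it
#'   lets a caller freeze the cutoff on the full pre-filter site set.
#' @return Subset of `sites`, with attributes `coverage_threshold` and
#'   `removal_counts` (named integer vector: indel, low_gq, ref_homalt,
#'   high_coverage).
#' @export
filter_sites <- function(sites, config = filter_config(), threshold = NULL) {
  if (nrow(sites) == 0) {
    attr(sites, "coverage_threshold") <- NA_real_
    attr(sites, "removal_counts") <- c(indel = 0L, low_gq = 0L,
                                       ref_homalt = 0L, high_coverage = 0L)
    return(sites)
  }
  combined_dp <- sites$dp_a + sites$dp_b
  thr <- threshold %||% attr(sites, "coverage_threshold") %||%
    coverage_threshold(combined_dp, config$coverage_k)

  keep <- rep(TRUE, nrow(sites))
  removed <- c(indel = 0L, low_gq = 0L, ref_homalt = 0L, high_coverage = 0L)

  if (config$exclude_indels) {
    drop <- keep & sites$is_indel
    removed[["indel"]] <- sum(drop)
    keep <- keep & !drop
  }
  drop <- keep & (sites$gq_a < config$gq_min | sites$gq_b < config$gq_min)
  removed[["low_gq"]] <- sum(drop)
  keep <- keep & !drop
  if (config$exclude_ref_homalt) {
    if (config$reference_individual == "a") {
      homalt <- sites$a1 == sites$a2 & sites$a1 > 0
    } else {
      homalt <- sites$b1 == sites$b2 & sites$b1 > 0
    }
    drop <- keep & homalt
    removed[["ref_homalt"]] <- sum(drop)
    keep <- keep & !drop
  }
  drop <- keep & (combined_dp > thr)
  removed[["high_coverage"]] <- sum(drop)
  keep <- keep & !drop

  out <- sites[keep, , drop = FALSE]
  attr(out, "coverage_threshold") <- thr
  attr(out, "removal_counts") <- removed
  out
}

#' Per-site difference decomposition
#'
#' For each site, the within-individual component is 1 iff that individual
#' is heterozygous, and the between component is the fraction of unequal
#' allele pairs among the 2 x 2 cross-individual comparisons (so a fixed
#' difference scores 1, a het against a homozygote scores 0.5). Allele
#' comparisons are categorical over the full allele list, so multiallelic
#' sites need no special casing.
#'
#' @param sites Variant tibble (allele-index columns `a1`,`a2`,`b1`,`b2`).
#' @return `sites` with numeric columns `w_a`, `w_b` (0/1) and `b` (in
#'   \[0, 1\]) appended.
#' @export
site_diffs <- function(sites) {
  if (nrow(sites) > 0 &&
      (anyNA(sites$a1) || anyNA(sites$a2) || anyNA(sites$b1) || anyNA(sites$b2))) {
    abort("missing genotype encountered; such sites must be excluded upstream")
  }
  dplyr::mutate(
    sites,
    w_a = as.numeric(.data$a1 != .data$a2),
    w_b = as.numeric(.data$b1 != .data$b2),
    b = ((.data$a1 != .data$b1) + (.data$a1 != .data$b2) +
         (.data$a2 != .data$b1) + (.data$a2 != .data$b2)) / 4
  )
}

#' Within- and between-species diversity from filtered sites
#'
#' Sums the per-site decomposition over all sites and scales by the callable
#' length L (positions at which genotypes could have been called; a
#' variant-only VCF does not carry this, so it is supplied — e.g. the non-N
#' length of the reference assembly).
#'
#' @param sites Filtered variant tibble.
#' @param callable_length Denominator L in nt (> 0).
#' @return Object of class `divergence_estimate` with fields `hw_a`, `hw_b`,
#'   `hb` (per-nt), `callable_length`, `n_sites_used` and `fst` (NA until
#'   [hudson_fst()] is applied).
#' @export
diversity <- function(sites, callable_length) {
  if (length(callable_length) != 1 || is.na(callable_length) || callable_length <= 0) {
    abort("`callable_length` must be a single positive number")
  }
  d <- site_diffs(sites)
  est <- structure(list(
    hw_a = sum(d$w_a) / callable_length,
    hw_b = sum(d$w_b) / callable_length,
    hb = sum(d$b) / callable_length,
    callable_length = callable_length,
    n_sites_used = nrow(d),
    fst = NA_real_
  ), class = "divergence_estimate")
  est
}

#' Hudson's fixation index from diversity components
#'
#' `F_ST = 1 - mean(hw_a, hw_b) / hb`: one minus the ratio of the unweighted
#' mean within-species per-nt diversity to the between-species diversity.
#'
#' @param x Either a `divergence_estimate` from [diversity()] or the numeric
#'   `hw_a` value.
#' @param hw_b,hb Numeric components when `x` is numeric.
#' @return For a `divergence_estimate`, the same object with `fst` filled
#'   in; for numeric input, the F_ST value.
#' @export
#' @examples
#' hudson_fst(2.008e-4, 2.352e-3, 7.042e-3) # ~0.819
hudson_fst <- function(x, hw_b = NULL, hb = NULL) {
  if (inherits(x, "divergence_estimate")) {
    x$fst <- hudson_fst(x$hw_a, x$hw_b, x$hb)
    return(x)
  }
  if (is.null(hw_b) || is.null(hb)) abort("supply `hw_b` and `hb`")
  if (hb <= 0) abort("F_ST is undefined when between-species diversity is 0")
  1 - mean(c(x, hw_b)) / hb
}

#' @export
print.divergence_estimate <- function(x, ...) {
  cat("Two-genome divergence estimate\n")
  cat(sprintf("  Hw (species A): %.4g per nt\n", x$hw_a))
  cat(sprintf("  Hw (species B): %.4g per nt\n", x$hw_b))
  cat(sprintf("  Hb (between):   %.4g per nt\n", x$hb))
  cat(sprintf("  callable length: %d nt; sites used: %d\n",
              as.integer(x$callable_length), x$n_sites_used))
  if (!is.na(x$fst)) cat(sprintf("  Hudson F_ST: %.3f\n", x$fst))
  invisible(x)
}

#' @rdname diversity
#' @param x A `divergence_estimate`.
#' @param ... Unused.
#' @export
tidy.divergence_estimate <- function(x, ...) {
  tibble::tibble(
    component = c("hw_a", "hw_b", "hb", "fst"),
    estimate = c(x$hw_a, x$hw_b, x$hb, x$fst)
  )
}

#' @rdname diversity
#' @export
glance.divergence_estimate <- function(x, ...) {
  tibble::tibble(
    hw_a = x$hw_a, hw_b = x$hw_b, hb = x$hb, fst = x$fst,
    callable_length = x$callable_length, n_sites_used = x$n_sites_used
  )
}

#' @rdname diversity
#' @param object A `divergence_estimate`.
#' @export
autoplot.divergence_estimate <- function(object, ...) {
  dat <- tibble::tibble(
    component = factor(c("Hw (A)", "Hw (B)", "Hb"),
                       levels = c("Hw (A)", "Hw (B)", "Hb")),
    value = c(object$hw_a, object$hw_b, object$hb)
  )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$component, y = .data$value)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = NULL, y = "per-nt diversity",
                  title = if (is.na(object$fst)) "Diversity components"
                          else sprintf("Diversity components (F_ST = %.3f)", object$fst)) +
    ggplot2::theme_minimal()
}

#' End-to-end divergence pipeline
#'
#' Convenience wrapper chaining [filter_sites()], [diversity()] and
#' [hudson_fst()] on a two-sample variant tibble.
#'
#' @param sites Variant tibble from [read_vcf_two_sample()].
#' @param callable_length Denominator L in nt.
#' @param config A [filter_config()].
#' @return A completed `divergence_estimate` (with `fst`), carrying
#'   attributes `coverage_threshold` and `removal_counts` from the filter.
#' @export
estimate_divergence <- function(sites, callable_length, config = filter_config()) {
  kept <- filter_sites(sites, config)
  est <- hudson_fst(diversity(kept, callable_length))
  attr(est, "coverage_threshold") <- attr(kept, "coverage_threshold")
  attr(est, "removal_counts") <- attr(kept, "removal_counts")
  est
}
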