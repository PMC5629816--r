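#' Configuration for the assembly simulator
#'
#' Describes a synthetic scaffolded assembly: scaffold lengths, planted
#' internal N runs (the unsequenced gaps), and a GC target for the
#' sequenced bases.
#'
#' @param scaffold_lengths Integer vector of scaffold lengths (nt).
#' @param gaps Tibble with columns `scaffold` (1-based index into
#'   `scaffold_lengths`), `start` (1-based) and `length`; every run must be
#'   internal to its scaffold and runs may not touch each other.
#' @param gc Target GC fraction of non-N bases (default 0.42, a typical
#'   avian genome value).
#' @param n_run_min N-run convention the ground truth is computed under
#'   (default 25).
#' @param seed Default seed used by [simulate_assembly()].
#' @return List of class `assembly_sim_config`.
#' @export
assembly_sim_config <- function(scaffold_lengths, gaps = NULL, gc = 0.42,
                                n_run_min = 25, seed = 1) {
  if (is.null(gaps)) {
    gaps <- tibble::tibble(scaffold = integer(), start = integer(),
                           length = integer())
  }
  if (nrow(gaps) > 0) {
    if (any(gaps$scaffold < 1 | gaps$scaffold > length(scaffold_lengths))) {
      abort("gap refers to a scaffold index out of range")
    }
    bad <- gaps$start < 2 |
      (gaps$start + gaps$length - 1) > (scaffold_lengths[gaps$scaffold] - 1)
    if (any(bad)) abort("infeasible N-run placement: runs must be internal")
    by_scaf <- split(gaps[order(gaps$start), ], gaps$scaffold[order(gaps$start)])
    for (g in by_scaf) {
      if (nrow(g) > 1) {
        ends <- g$start + g$length - 1
        if (any(g$start[-1] <= ends[-nrow(g)] + 1)) {
          abort("infeasible N-run placement: runs overlap or touch")
        }
      }
    }
  }
  structure(list(scaffold_lengths = as.integer(scaffold_lengths),
                 gaps = gaps, gc = gc, n_run_min = n_run_min, seed = seed),
            class = "assembly_sim_config")
}

sample_bases <- function(n, gc) {
  sample(c("G", "C", "A", "T"), n, replace = TRUE,
         prob = c(gc / 2, gc / 2, (1 - gc) / 2, (1 - gc) / 2))
}

# independent Nx bookkeeping used for generator ground truth (accumulation
# loop, deliberately not the implementation in nx_stats)
truth_nx <- function(lengths, levels = c(50, 60, 70, 80, 90)) {
  ls <- sort(lengths, decreasing = TRUE)
  total <- sum(as.numeric(ls))
  purrr::map_dfr(levels, function(x) {
    acc <- 0
    i <- 0L
    while (acc < total * x / 100) {
      i <- i + 1L
      acc <- acc + ls[i]
    }
    tibble::tibble(level = x, nx = ls[i], lx = i)
  })
}

#' Simulate a scaffolded assembly with known ground truth
#'
#' Generates the FASTA-ready sequence tibble and, from the generating
#' parameters alone (never by re-measuring the sequences with the analysis
#' code), the exact continuity/composition metrics the assembly must show
#' under the configured N-run convention. Deterministic for a fixed seed.
#'
#' @param config An [assembly_sim_config()].
#' @param seed Random seed (default from the config).
#' @return List with `assembly` (sequence tibble) and `truth` (named list
#'   mirroring the fields of [summarize_assembly()]).
#' @export
simulate_assembly <- function(config, seed = config$seed) {
  set.seed(seed)
  lens <- config$scaffold_lengths
  gaps <- config$gaps
  seqs <- character(length(lens))
  gc_count <- 0
  base_count <- 0
  contig_lengths <- list()
  for (i in seq_along(lens)) {
    g <- gaps[gaps$scaffold == i, , drop = FALSE]
    g <- g[order(g$start), , drop = FALSE]
    seg_start <- c(1L, g$start + g$length)
    seg_end <- c(g$start - 1L, lens[i])
    pieces <- character(0)
    seg_lens <- integer(0)
    for (s in seq_along(seg_start)) {
      n <- seg_end[s] - seg_start[s] + 1L
      bases <- sample_bases(n, config$gc)
      gc_count <- gc_count + sum(bases %in% c("G", "C"))
      base_count <- base_count + n
      pieces <- c(pieces, paste(bases, collapse = ""))
      seg_lens <- c(seg_lens, n)
    }
    joined <- pieces[1]
    for (s in seq_len(nrow(g))) {
      joined <- paste0(joined, strrep("N", g$length[s]), pieces[s + 1])
    }
    seqs[i] <- joined
    # contig decomposition under the truth convention
    splitting <- g$length >= config$n_run_min
    if (any(!splitting)) {
      # short runs stay inside contigs: merge segments across them
      merged <- integer(0)
      cur <- seg_lens[1]
      for (s in seq_len(nrow(g))) {
        if (splitting[s]) {
          merged <- c(merged, cur)
          cur <- seg_lens[s + 1]
        } else {
          cur <- cur + g$length[s] + seg_lens[s + 1]
        }
      }
      contig_lengths[[i]] <- c(merged, cur)
    } else {
      contig_lengths[[i]] <- seg_lens
    }
  }
  assembly <- tibble::tibble(id = paste0("scaffold-", seq_along(lens)),
                             seq = seqs, length = nchar(seqs))
  stopifnot(all(assembly$length == lens))

  split_gaps <- gaps[gaps$length >= config$n_run_min, , drop = FALSE]
  n_contigs_per <- lengths(contig_lengths)
  scaffolded <- n_contigs_per > 1
  all_contigs <- unlist(contig_lengths)
  total <- sum(lens)
  thresholds <- c(1e3, 1e4, 1e5, 1e6, 1e7)
  truth <- list(
    n_sequences = length(lens),
    total_length = total,
    longest = max(lens),
    shortest = min(lens),
    mean_length = mean(lens),
    median_length = median(lens),
    counts_over_thresholds = purrr::map_dfr(thresholds, function(thr) {
      tibble::tibble(threshold = thr, count = sum(lens > thr),
                     fraction = 100 * sum(lens > thr) / length(lens))
    }),
    nx_table = truth_nx(lens),
    pct_gc = 100 * gc_count / base_count,
    pct_n = 100 * sum(gaps$length) / total,
    n_contigs = length(all_contigs),
    n_contigs_in_scaffolds = sum(n_contigs_per[scaffolded]),
    n_contigs_unscaffolded = sum(n_contigs_per[!scaffolded]),
    pct_assembly_in_scaffolded_contigs =
      100 * sum(unlist(contig_lengths[scaffolded])) / total,
    gap_count = nrow(split_gaps),
    gap_mean_length = if (nrow(split_gaps) > 0) mean(split_gaps$length) else NA_real_,
    contig_nx_table = truth_nx(all_contigs)
  )
  list(assembly = assembly, truth = truth)
}

#' Configuration for the two-species variant simulator
#'
#' Per-site, independent categories: a site is heterozygous in individual A
#' with probability `het_a`, heterozygous in B with `het_b`, a fixed
#' difference with `div`, or one of four filter-violating decoy classes;
#' otherwise it is invariant and emits no VCF row.
#'
#' @param L Callable length in nt (number of sites simulated).
#' @param het_a,het_b Per-nt heterozygosity rates of individuals A and B.
#' @param div Per-nt fixed-difference rate (A hom-ref, B hom-alt).
#' @param p_indel,p_lowgq,p_refhomalt,p_highdp Decoy rates for sites that
#'   must be removed by, respectively, the indel, genotype-quality,
#'   reference-hom-alt and coverage filters.
#' @param mean_dp,sd_dp Per-individual depth distribution of ordinary sites.
#' @param gq Genotype quality of ordinary sites.
#' @param gq_low GQ planted at low-quality decoy sites.
#' @param seed Default seed used by [simulate_variant_sites()].
#' @return List of class `variant_sim_config`.
#' @export
variant_sim_config <- function(L, het_a, het_b, div, p_indel = 0,
                               p_lowgq = 0, p_refhomalt = 0, p_highdp = 0,
                               mean_dp = 30, sd_dp = 5, gq = 99, gq_low = 5,
                               seed = 1) {
  rates <- c(het_a, het_b, div, p_indel, p_lowgq, p_refhomalt, p_highdp)
  if (any(rates < 0 | rates > 1)) abort("all rates must lie in [0, 1]")
  if (sum(rates) > 1) abort("per-site category rates must not sum above 1")
  if (L < 1) abort("`L` must be >= 1")
  structure(list(L = as.integer(L), het_a = het_a, het_b = het_b, div = div,
                 p_indel = p_indel, p_lowgq = p_lowgq,
                 p_refhomalt = p_refhomalt, p_highdp = p_highdp,
                 mean_dp = mean_dp, sd_dp = sd_dp, gq = gq, gq_low = gq_low,
                 seed = seed),
            class = "variant_sim_config")
}

#' Component rates that hit a target diversity regime
#'
#' Heterozygous sites contribute 0.5 to the between-species per-site
#' difference (one of the two cross-individual allele pairs differs in two
#' of four comparisons), so the fixed-difference rate that yields an
#' expected between-species diversity `hb` is
#' `div = hb - (het_a + het_b) / 2`.
#'
#' @param hw_a,hw_b Target within-species per-nt diversities.
#' @param hb Target between-species per-nt diversity.
#' @return List with `het_a`, `het_b`, `div`.
#' @export
calibrate_divergence_rates <- function(hw_a, hw_b, hb) {
  div <- hb - (hw_a + hw_b) / 2
  if (div < 0) abort("`hb` too small for the requested within-diversities")
  list(het_a = hw_a, het_b = hw_b, div = div)
}

#' Simulate a two-species variant table with known ground truth
#'
#' Draws one category per site (multinomial over the configured rates),
#' assigns genotypes, qualities and depths accordingly, and records the
#' exact planted counts. High-depth decoys get a combined depth far above
#' the mean + 5 SD threshold; low-GQ decoys a GQ below any sensible cutoff.
#' Deterministic for a fixed seed.
#'
#' @param config A [variant_sim_config()].
#' @param seed Random seed (default from the config).
#' @return List with `sites` (variant tibble in the [read_vcf_two_sample()]
#'   layout, position-sorted on scaffold `"sim-1"`) and `truth` (list:
#'   planted per-category counts plus the implied `hw_a`, `hw_b`, `hb` over
#'   `L`).
#' @export
simulate_variant_sites <- function(config, seed = config$seed) {
  set.seed(seed)
  probs <- c(het_a = config$het_a, het_b = config$het_b, div = config$div,
             indel = config$p_indel, lowgq = config$p_lowgq,
             refhomalt = config$p_refhomalt, highdp = config$p_highdp)
  counts <- as.vector(stats::rmultinom(1, config$L, c(probs, none = 1 - sum(probs))))
  names(counts) <- c(names(probs), "none")
  n_var <- sum(counts[names(counts) != "none"])

  cat_vec <- rep(names(probs), counts[names(probs)])
  pos <- sort(sample.int(config$L, n_var))
  draw_dp <- function(n) {
    pmax(1L, as.integer(round(rnorm(n, config$mean_dp, config$sd_dp))))
  }
  base_pair <- function(n) {
    ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    alt <- purrr::map_chr(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1))
    list(ref = ref, alt = alt)
  }
  n <- length(cat_vec)
  bp <- base_pair(n)
  sites <- tibble::tibble(
    scaffold = rep("sim-1", n), pos = pos,
    ref_allele = bp$ref, alt_alleles = bp$alt,
    a1 = 0L, a2 = 0L, b1 = 0L, b2 = 0L,
    gq_a = as.integer(config$gq), gq_b = as.integer(config$gq),
    dp_a = draw_dp(n), dp_b = draw_dp(n),
    is_indel = FALSE, category = cat_vec
  )
  sites$a2[cat_vec == "het_a"] <- 1L
  sites$b2[cat_vec == "het_b"] <- 1L
  fixed_like <- cat_vec %in% c("div", "indel", "highdp")
  sites$b1[fixed_like] <- 1L
  sites$b2[fixed_like] <- 1L
  # decoys
  sites$alt_alleles[cat_vec == "indel"] <-
    paste0(sites$ref_allele[cat_vec == "indel"],
           sites$alt_alleles[cat_vec == "indel"])
  sites$is_indel[cat_vec == "indel"] <- TRUE
  sites$b2[cat_vec == "lowgq"] <- 1L
  sites$gq_b[cat_vec == "lowgq"] <- as.integer(config$gq_low)
  sites$a1[cat_vec == "refhomalt"] <- 1L
  sites$a2[cat_vec == "refhomalt"] <- 1L
  high_dp <- as.integer(50 * config$mean_dp)
  sites$dp_a[cat_vec == "highdp"] <- high_dp
  sites$dp_b[cat_vec == "highdp"] <- high_dp

  truth <- list(
    L = config$L,
    n_het_a = unname(counts[["het_a"]]),
    n_het_b = unname(counts[["het_b"]]),
    n_div = unname(counts[["div"]]),
    n_decoy = unname(sum(counts[c("indel", "lowgq", "refhomalt", "highdp")])),
    counts = counts,
    hw_a = counts[["het_a"]] / config$L,
    hw_b = counts[["het_b"]] / config$L,
    hb = (counts[["div"]] + 0.5 * (counts[["het_a"]] + counts[["het_b"]])) / config$L
  )
  list(sites = sites, truth = truth)
}

#' Serialise a hits tibble in BLAST outfmt-6 column order
#'
#' Companion writer for [read_hits_table()]; fills the percent-identity,
#' gap, query-coordinate, e-value and bit-score columns with consistent
#' placeholder values.
#'
#' @param hits Tibble with `query_id`, `subject_id`, `aln_length`,
#'   `mismatches`, `subject_start`, `subject_end`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits_table <- function(hits, path) {
  lines <- paste(
    hits$query_id, hits$subject_id,
    sprintf("%.2f", 100 * (hits$aln_length - hits$mismatches) / hits$aln_length),
    hits$aln_length, hits$mismatches, 0L,
    1L, hits$aln_length, hits$subject_start, hits$subject_end,
    "1e-5", "40.1",
    sep = "\t"
  )
  writeLines(lines, path)
  invisible(path)
}

NON_STOP_CODONS <- local({
  bases <- c("A", "C", "G", "T")
  all3 <- apply(expand.grid(bases, bases, bases), 1, paste, collapse = "")
  setdiff(all3, c("TAA", "TAG", "TGA"))
})

#' Shipped mutation-plan identifiers
#'
#' The shipped plans encode, exon by exon, the inactivating-mutation
#' catalogs reported for the rod-like cone opsin (Rh2), pinopsin (OpnP),
#' mammal-like melanopsin (Opn4m) and carotenoid ketolase (CYP2J19)
#' orthologs of the two owl species, restricted to mutations explicitly
#' enumerated (qualitative statements such as missense counts are not
#' planted).
#'
#' @return Character vector of plan ids accepted by [mutation_plan()].
#' @export
shipped_mutation_plans <- function() {
  c("rh2_tyto", "opnp_tyto", "opn4m_strix", "opn4m_tyto",
    "cyp2j19_strix", "cyp2j19_tyto")
}

#' Retrieve a mutation plan
#'
#' A plan is a gene template (exon/intron counts and lengths) plus an
#' ordered, non-overlapping set of planted events. Events use 0-based nt
#' offsets from their exon start (`offset`), codon ordinals within the exon
#' for planted stops (`codon`), and intron indices for splice events.
#'
#' @param plan_id One of [shipped_mutation_plans()], or a custom plan list.
#' @return List of class `mutation_plan` with `plan_id`, `n_exons`,
#'   `exon_len`, `intron_len`, `flank_len` and `events` (tibble `category`,
#'   `index`, `length`, `codon`, `offset`).
#' @export
mutation_plan <- function(plan_id) {
  ev <- function(category, index, length = 0L, codon = 0L, offset = 0L) {
    tibble::tibble(category = category, index = as.integer(index),
                   length = as.integer(length), codon = as.integer(codon),
                   offset = as.integer(offset))
  }
  plans <- list(
    # 29 nt deletion exon 1; premature stops exons 2 and 3; 2 nt deletion exon 4
    rh2_tyto = list(n_exons = 5, events = dplyr::bind_rows(
      ev("del", 1, length = 29, offset = 20),
      ev("stop", 2, codon = 10),
      ev("stop", 3, codon = 10),
      ev("del", 4, length = 2, offset = 40)
    )),
    # start ACA; exon1 13 del + 2 ins + 1 del; exon2 1 del; intron3-exon4
    # 21 nt boundary deletion; exon4 7 del + 2 del; exon5 1 del
    opnp_tyto = list(n_exons = 5, events = dplyr::bind_rows(
      ev("start_loss", 1),
      ev("del", 1, length = 13, offset = 10),
      ev("ins", 1, length = 2, offset = 40),
      ev("del", 1, length = 1, offset = 60),
      ev("del", 2, length = 1, offset = 50),
      ev("boundary_del", 3, length = 21),
      ev("del", 4, length = 7, offset = 30),
      ev("del", 4, length = 2, offset = 60),
      ev("del", 5, length = 1, offset = 50)
    )),
    # shared 4 nt deletion exon 8 plus a species-specific premature stop
    opn4m_strix = list(n_exons = 13, events = dplyr::bind_rows(
      ev("del", 8, length = 4, offset = 30),
      ev("stop", 8, codon = 20)
    )),
    # shared 4 nt deletion exon 8 plus an intron-11 GT-to-AT donor mutation
    opn4m_tyto = list(n_exons = 13, events = dplyr::bind_rows(
      ev("del", 8, length = 4, offset = 30),
      ev("splice_donor", 11)
    )),
    # 1 nt insertion and 2 nt deletion in exon 9
    cyp2j19_strix = list(n_exons = 9, events = dplyr::bind_rows(
      ev("ins", 9, length = 1, offset = 30),
      ev("del", 9, length = 2, offset = 60)
    )),
    # premature stops exons 1, 5 and 6; 5 nt deletion exon 3
    cyp2j19_tyto = list(n_exons = 9, events = dplyr::bind_rows(
      ev("stop", 1, codon = 20),
      ev("del", 3, length = 5, offset = 40),
      ev("stop", 5, codon = 10),
      ev("stop", 6, codon = 10)
    ))
  )
  if (is.list(plan_id) && !is.null(plan_id$events)) {
    plan <- plan_id
  } else {
    if (!plan_id %in% names(plans)) {
      abort(paste0("unknown mutation plan: ", plan_id))
    }
    plan <- plans[[plan_id]]
    plan$plan_id <- plan_id
  }
  plan$exon_len <- rep_len(plan$exon_len %||% 120L, plan$n_exons)
  plan$intron_len <- if (plan$n_exons > 1) {
    rep_len(plan$intron_len %||% 90L, plan$n_exons - 1L)
  } else {
    integer(0)
  }
  plan$flank_len <- plan$flank_len %||% 30L
  structure(plan, class = "mutation_plan")
}

expected_calls_from_plan <- function(plan) {
  exon_codons <- plan$exon_len %/% 3L
  cum_codons <- cumsum(c(0L, exon_codons))
  purrr::pmap_dfr(plan$events, function(category, index, length, codon, offset) {
    switch(category,
      start_loss = tibble::tibble(category = "start_codon_loss",
                                  exon_or_intron_index = 1L, length = 0L,
                                  codon_index = 1L),
      stop = tibble::tibble(category = "premature_stop",
                            exon_or_intron_index = index, length = 0L,
                            codon_index = cum_codons[index] + codon),
      del = ,
      ins = tibble::tibble(
        category = ifelse(length %% 3L != 0L, "frameshift_indel", "inframe_indel"),
        exon_or_intron_index = index, length = length, codon_index = 0L),
      boundary_del = tibble::tibble(category = "splice_boundary_indel",
                                    exon_or_intron_index = index,
                                    length = length, codon_index = 0L),
      splice_donor = tibble::tibble(category = "splice_donor",
                                    exon_or_intron_index = index, length = 0L,
                                    codon_index = 0L),
      abort(paste0("unknown event category: ", category))
    )
  })
}

#' Build a reference/query gene-locus fixture from a mutation plan
#'
#' The reference is a clean multi-exon gene: ATG start, stop-free internal
#' codons, a terminal stop codon, canonical GT...AG introns and random
#' flanks. The query carries exactly the planted events; the true
#' event-level alignment and the expected mutation calls come out with the
#' sequences, so detector output can be compared against construction-time
#' truth.
#'
#' @param plan A [mutation_plan()] (or a plan id string).
#' @param seed Random seed.
#' @return List with `ref` and `query` (sequence tibbles), `model`
#'   (gene-model tibble on the reference locus), `alignment` (the true
#'   `ref_aligned`/`query_aligned` pair) and `expected` (tibble of planted
#'   calls: `category`, `exon_or_intron_index`, `length`, `codon_index`).
#' @export
make_locus_fixture <- function(plan, seed = 1) {
  if (is.character(plan)) plan <- mutation_plan(plan)
  set.seed(seed)
  n_ex <- plan$n_exons
  if (any(plan$exon_len %% 3L != 0L)) {
    abort("template exon lengths must be codon-aligned (multiples of 3)")
  }
  # reference CDS: ATG, non-stop internal codons, terminal TGA
  n_codons <- sum(plan$exon_len) %/% 3L
  codons <- c("ATG",
              sample(NON_STOP_CODONS, n_codons - 2L, replace = TRUE),
              "TGA")
  cds <- paste(codons, collapse = "")
  exon_seq <- character(n_ex)
  at <- 1L
  for (i in seq_len(n_ex)) {
    exon_seq[i] <- substr(cds, at, at + plan$exon_len[i] - 1L)
    at <- at + plan$exon_len[i]
  }
  intron_seq <- purrr::map_chr(plan$intron_len, function(L) {
    paste0("GT", paste(sample(c("A", "C", "G", "T"), L - 4L, replace = TRUE),
                       collapse = ""), "AG")
  })
  flank5 <- paste(sample(c("A", "C", "G", "T"), plan$flank_len, replace = TRUE),
                  collapse = "")
  flank3 <- paste(sample(c("A", "C", "G", "T"), plan$flank_len, replace = TRUE),
                  collapse = "")
  parts <- character(0)
  exon_start <- integer(n_ex)
  pos <- nchar(flank5)
  for (i in seq_len(n_ex)) {
    exon_start[i] <- pos + 1L
    parts <- c(parts, exon_seq[i])
    pos <- pos + plan$exon_len[i]
    if (i < n_ex) {
      parts <- c(parts, intron_seq[i])
      pos <- pos + plan$intron_len[i]
    }
  }
  ref_locus <- paste0(flank5, paste(parts, collapse = ""), flank3)
  exons <- cbind(start = exon_start, end = exon_start + plan$exon_len - 1L)
  model <- gene_model(plan$plan_id %||% "synthetic_gene", exons)

  # per-reference-position edit state: substitutions, deletions, insertions
  ref_chars <- strsplit(ref_locus, "", fixed = TRUE)[[1]]
  query_chars <- ref_chars
  deleted <- rep(FALSE, length(ref_chars))
  insert_after <- rep("", length(ref_chars))
  intron_start <- exon_start[-n_ex] + plan$exon_len[-n_ex]

  mark_del <- function(from, to) {
    if (any(deleted[from:to]) || any(nzchar(insert_after[from:to]))) {
      abort("mutation plan events overlap")
    }
    deleted[from:to] <<- TRUE
  }
  for (j in seq_len(nrow(plan$events))) {
    e <- plan$events[j, ]
    switch(e$category,
      start_loss = {
        s <- exon_start[1]
        query_chars[s:(s + 2L)] <- c("A", "C", "A")
      },
      stop = {
        s <- exon_start[e$index] + 3L * (e$codon - 1L)
        query_chars[s:(s + 2L)] <- c("T", "G", "A")
      },
      del = {
        s <- exon_start[e$index] + e$offset
        mark_del(s, s + e$length - 1L)
      },
      ins = {
        s <- exon_start[e$index] + e$offset
        insert_after[s] <- paste(sample(c("A", "C", "G", "T"), e$length,
                                        replace = TRUE), collapse = "")
      },
      boundary_del = {
        k <- as.integer(ceiling(e$length / 2))
        iend <- exon_start[e$index + 1L] - 1L  # last intron base (acceptor G)
        mark_del(iend - k + 1L, iend + (e$length - k))
      },
      splice_donor = {
        s <- intron_start[e$index]
        query_chars[s] <- "A"  # GT -> AT
      },
      abort(paste0("unknown event category: ", e$category))
    )
  }

  ref_aln <- character(0)
  query_aln <- character(0)
  for (p in seq_along(ref_chars)) {
    ref_aln <- c(ref_aln, ref_chars[p])
    query_aln <- c(query_aln, if (deleted[p]) "-" else query_chars[p])
    if (nzchar(insert_after[p])) {
      ins <- strsplit(insert_after[p], "", fixed = TRUE)[[1]]
      ref_aln <- c(ref_aln, rep("-", length(ins)))
      query_aln <- c(query_aln, ins)
    }
  }
  query_locus <- paste(query_aln[query_aln != "-"], collapse = "")

  list(
    ref = tibble::tibble(id = "ref_locus", seq = ref_locus,
                         length = nchar(ref_locus)),
    query = tibble::tibble(id = "query_locus", seq = query_locus,
                           length = nchar(query_locus)),
    model = model,
    alignment = list(ref_aligned = paste(ref_aln, collapse = ""),
                     query_aligned = paste(query_aln, collapse = "")),
    expected = expected_calls_from_plan(plan),
    plan = plan
  )
}

#' Synteny fixtures for whole-gene deletion inference
#'
#' Two shipped scenarios: `"opnp_deletion_synteny"` plants both flanking
#' genes on one scaffold with clean intergenic sequence and no probe hit
#' (deletion supported), and `"sws1_synteny_split"` puts the flanks on
#' different scaffolds (indeterminate).
#'
#' @param plan_id Scenario id.
#' @param seed Random seed.
#' @return List with `assembly`, `left_flank_hits`, `right_flank_hits`,
#'   `probe_hits` (empty tibble) and `expected_verdict`.
#' @export
make_synteny_fixture <- function(plan_id = c("opnp_deletion_synteny",
                                             "sws1_synteny_split"),
                                 seed = 1) {
  plan_id <- match.arg(plan_id)
  set.seed(seed)
  rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")
  hit <- function(q, s, from, to, len) {
    tibble::tibble(query_id = q, subject_id = s, aln_length = len,
                   mismatches = 0L, subject_start = from, subject_end = to,
                   orientation = "plus", subject_min = pmin(from, to),
                   subject_max = pmax(from, to), query_length = len)
  }
  probe_hits <- hit("probe", "none", 1L, 1L, 1L)[0, ]
  if (plan_id == "opnp_deletion_synteny") {
    assembly <- tibble::tibble(id = "scaffold-syn1", seq = rand_seq(5000),
                               length = 5000L)
    list(
      assembly = assembly,
      left_flank_hits = hit("left_flank", "scaffold-syn1", 101L, 1100L, 1000L),
      right_flank_hits = hit("right_flank", "scaffold-syn1", 3901L, 4900L, 1000L),
      probe_hits = probe_hits,
      expected_verdict = "deletion_supported"
    )
  } else {
    assembly <- tibble::tibble(
      id = c("scaffold-synA", "scaffold-synB"),
      seq = c(rand_seq(2000), rand_seq(2000)), length = c(2000L, 2000L)
    )
    list(
      assembly = assembly,
      left_flank_hits = hit("left_flank", "scaffold-synA", 101L, 1100L, 1000L),
      right_flank_hits = hit("right_flank", "scaffold-synB", 201L, 1200L, 1000L),
      probe_hits = probe_hits,
      expected_verdict = "indeterminate_split"
    )
  }
}

#' Simulate a scaffold with planted microsatellite primer sites
#'
#' Plants each primer pair at a known position with a known outer-to-outer
#' product span and optional partial-alignment trims at the outer primer
#' ends, and emits the corresponding BLAST-style hits table plus the
#' expected locus table computed from the generator's own arithmetic.
#'
#' @param pairs Tibble with columns `locus_id`, `f_len`, `r_len`,
#'   `product` (outer-to-outer span, full primers), `position` (scaffold
#'   start of the product) and optional `f_trim`, `r_trim` (unaligned outer
#'   bases; default 0).
#' @param seed Random seed.
#' @param scaffold_id Scaffold name.
#' @return List with `scaffold` (sequence tibble), `hits` (hit tibble),
#'   `pairs` (locus to primer-id map for [pair_primer_hits()]),
#'   `query_lengths` (named primer lengths) and `expected` (tibble
#'   `locus_id`, `product_length`).
#' @export
simulate_marker_scaffold <- function(pairs, seed = 1, scaffold_id = "sim-scaffold") {
  set.seed(seed)
  if (nrow(pairs) == 0) {
    empty_hits <- tibble::tibble(
      query_id = character(), subject_id = character(),
      aln_length = integer(), mismatches = integer(),
      subject_start = integer(), subject_end = integer(),
      orientation = character(), subject_min = integer(),
      subject_max = integer(), query_length = integer()
    )
    return(list(
      scaffold = tibble::tibble(id = scaffold_id, seq = "", length = 0L)[0, ],
      hits = empty_hits,
      pairs = tibble::tibble(locus_id = character(), forward_id = character(),
                             reverse_id = character()),
      query_lengths = integer(),
      expected = tibble::tibble(locus_id = character(),
                                product_length = integer())
    ))
  }
  if (!"f_trim" %in% names(pairs)) pairs$f_trim <- 0L
  if (!"r_trim" %in% names(pairs)) pairs$r_trim <- 0L
  if (any(pairs$product < pairs$f_len + pairs$r_len)) {
    abort("product span must fit both primers")
  }
  iv <- cbind(pairs$position, pairs$position + pairs$product - 1L)
  if (nrow(iv) > 1) {
    o <- order(iv[, 1])
    if (any(iv[o, 1][-1] <= iv[o, 2][-nrow(iv)])) {
      abort("planted primer-pair sites overlap")
    }
  }
  scaffold_len <- max(iv[, 2]) + 100L
  scaffold <- tibble::tibble(
    id = scaffold_id,
    seq = paste(sample(c("A", "C", "G", "T"), scaffold_len, replace = TRUE),
                collapse = ""),
    length = scaffold_len
  )
  rows <- purrr::pmap(pairs, function(locus_id, f_len, r_len, product,
                                      position, f_trim, r_trim, ...) {
    # forward primer maps plus-strand at the left end; its 5' (outer) end is
    # the low coordinate, and unaligned outer bases shift the printed start
    f_start <- position + f_trim
    f_end <- position + f_len - 1L
    # reverse primer maps minus-strand at the right end; printed start is
    # its 5' (outer, high) coordinate
    r_start <- position + product - 1L - r_trim
    r_end <- position + product - r_len
    list(
      hits = dplyr::bind_rows(
        tibble::tibble(query_id = paste0(locus_id, "_F"),
                       subject_id = scaffold_id,
                       aln_length = f_len - f_trim, mismatches = 0L,
                       subject_start = f_start, subject_end = f_end),
        tibble::tibble(query_id = paste0(locus_id, "_R"),
                       subject_id = scaffold_id,
                       aln_length = r_len - r_trim, mismatches = 0L,
                       subject_start = r_start, subject_end = r_end)
      ),
      lengths = setNames(c(f_len, r_len),
                         paste0(locus_id, c("_F", "_R"))),
      expected = tibble::tibble(
        locus_id = locus_id,
        # generator arithmetic: trims extend back to the planted outer ends
        product_length = (max(r_start + r_trim, f_end) -
                          min(f_start - f_trim, r_end) + 1L)
      )
    )
  })
  hits <- dplyr::bind_rows(purrr::map(rows, "hits"))
  query_lengths <- unlist(purrr::map(rows, "lengths"))
  hits$orientation <- ifelse(hits$subject_start > hits$subject_end, "minus", "plus")
  hits$subject_min <- pmin(hits$subject_start, hits$subject_end)
  hits$subject_max <- pmax(hits$subject_start, hits$subject_end)
  hits$query_length <- as.integer(query_lengths[hits$query_id])
  list(
    scaffold = scaffold,
    hits = hits,
    pairs = tibble::tibble(locus_id = pairs$locus_id,
                           forward_id = paste0(pairs$locus_id, "_F"),
                           reverse_id = paste0(pairs$locus_id, "_R")),
    query_lengths = query_lengths,
    expected = dplyr::bind_rows(purrr::map(rows, "expected"))
  )
}
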