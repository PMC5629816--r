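# Independent oracles and frozen published inputs used across the suite.

random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Brute-force assembly recomputation: character vectors and run-length
# encoding, deliberately sharing no code with the package implementation.
brute_assembly_metrics <- function(assembly, n_run_min = 25) {
  chars <- strsplit(toupper(assembly$seq), "", fixed = TRUE)
  all_chars <- unlist(chars)
  lens <- assembly$length
  contig_lens_per <- lapply(chars, function(cv) {
    r <- rle(cv == "N")
    is_gap <- r$values & r$lengths >= n_run_min
    # walk runs, accumulating contig length between splitting gaps
    out <- integer(0)
    cur <- 0L
    for (j in seq_along(r$lengths)) {
      if (is_gap[j]) {
        if (cur > 0) out <- c(out, cur)
        cur <- 0L
      } else {
        cur <- cur + r$lengths[j]
      }
    }
    if (cur > 0) out <- c(out, cur)
    out
  })
  gap_lens <- unlist(lapply(chars, function(cv) {
    r <- rle(cv == "N")
    idx <- which(r$values & r$lengths >= n_run_min)
    # internal only
    idx <- idx[idx > 1 & idx < length(r$lengths)]
    r$lengths[idx]
  }))
  n_per <- lengths(contig_lens_per)
  scaffolded <- n_per > 1
  list(
    n_sequences = nrow(assembly),
    total_length = sum(lens),
    longest = max(lens),
    shortest = min(lens),
    mean_length = mean(lens),
    median_length = median(lens),
    pct_gc = 100 * sum(all_chars %in% c("G", "C")) / sum(all_chars != "N"),
    pct_n = 100 * sum(all_chars == "N") / length(all_chars),
    n_contigs = sum(n_per),
    n_contigs_in_scaffolds = sum(n_per[scaffolded]),
    n_contigs_unscaffolded = sum(n_per[!scaffolded]),
    pct_assembly_in_scaffolded_contigs =
      100 * sum(unlist(contig_lens_per[scaffolded])) / sum(lens),
    gap_count = length(gap_lens),
    gap_mean_length = if (length(gap_lens) > 0) mean(gap_lens) else NA_real_,
    contig_lengths = sort(unlist(contig_lens_per))
  )
}

# Brute-force diversity: explicit loop over sites and over all four
# cross-individual allele pairs.
brute_diversity <- function(sites, L) {
  hw_a <- 0
  hw_b <- 0
  hb <- 0
  for (i in seq_len(nrow(sites))) {
    A <- c(sites$a1[i], sites$a2[i])
    B <- c(sites$b1[i], sites$b2[i])
    hw_a <- hw_a + as.integer(A[1] != A[2])
    hw_b <- hw_b + as.integer(B[1] != B[2])
    d <- 0
    for (x in A) for (y in B) d <- d + as.integer(x != y)
    hb <- hb + d / 4
  }
  fst <- if (hb > 0) 1 - ((hw_a + hw_b) / 2) / hb else NA_real_
  list(hw_a = hw_a / L, hw_b = hw_b / L, hb = hb / L, fst = fst)
}

random_variant_table <- function(n_sites, seed) {
  set.seed(seed)
  gts <- matrix(sample(0:1, 4 * n_sites, replace = TRUE), ncol = 4)
  tibble::tibble(
    scaffold = "t", pos = seq_len(n_sites),
    ref_allele = "A", alt_alleles = "T",
    a1 = gts[, 1], a2 = gts[, 2], b1 = gts[, 3], b2 = gts[, 4],
    gq_a = 99L, gq_b = 99L, dp_a = 30L, dp_b = 30L, is_indel = FALSE
  )
}

# Published microsatellite mapping table: primer lengths, alignment
# lengths, mismatches, printed coordinates and the printed product length
# for the 15 loci that mapped.
table8_loci <- function() {
  tibble::tribble(
    ~locus_id, ~scaffold,
    ~f_length, ~f_aln_length, ~f_mm, ~f_start, ~f_end,
    ~r_length, ~r_aln_length, ~r_mm, ~r_start, ~r_end, ~printed_product,
    "13D8",   "scaffold88",  22L, 22L, 0L, 4241040L, 4241019L, 21L, 21L, 0L, 4240854L, 4240874L, 187L,
    "15A6",   "scaffold233", 21L, 21L, 0L, 2208703L, 2208723L, 19L, 16L, 0L, 2208847L, 2208832L, 148L,
    "1C6",    "scaffold178", 20L, 20L, 0L, 2550734L, 2550753L, 20L, 20L, 0L, 2550843L, 2550824L, 110L,
    "4E10",   "scaffold11",  22L, 22L, 0L,  768391L,  768371L, 22L, 22L, 0L,  768162L,  768183L, 230L,
    "4E10.2", "scaffold11",  18L, 18L, 0L,  780562L,  780579L, 18L, 18L, 0L,  780787L,  780770L, 226L,
    "6H8",    "scaffold103", 21L, 21L, 0L, 3773885L, 3773865L, 16L, 16L, 0L, 3773793L, 3773808L,  93L,
    "Bb126",  "scaffold219", 20L, 20L, 0L, 2548147L, 2548166L, 24L, 24L, 0L, 2548331L, 2548308L, 185L,
    "BOOW18", "scaffold244", 19L, 19L, 1L,  648444L,  648426L, 20L, 20L, 1L,  648240L,  648259L, 205L,
    "FEPO5",  "scaffold138", 22L, 22L, 0L,  720315L,  720336L, 25L, 25L, 2L,  720584L,  720560L, 270L,
    "Oe045",  "scaffold173", 23L, 23L, 2L, 3777655L, 3777677L, 19L, 19L, 0L, 3777781L, 3777763L, 127L,
    "Oe053",  "scaffold136", 23L, 23L, 1L,  299240L,  299262L, 22L, 22L, 1L,  299457L,  299436L, 218L,
    "Oe128",  "scaffold72",  27L, 27L, 0L,  802232L,  802206L, 24L, 24L, 0L,  801914L,  801937L, 319L,
    "Oe129",  "scaffold529", 24L, 21L, 2L, 3066759L, 3066739L, 24L, 24L, 1L, 3066497L, 3066520L, 266L,
    "Oe149",  "scaffold11",  21L, 21L, 1L,   51010L,   50990L, 20L, 20L, 0L,   50753L,   50772L, 258L,
    "Oe3-7",  "scaffold35",  20L, 19L, 1L,  572329L,  572347L, 23L, 23L, 0L,  572456L,  572434L, 129L
  )
}

# Brute-force product-length oracle: enumerate the four coordinates after
# extending each primer's locus-outermost coordinate by its unaligned
# remainder, then take max - min + 1.
brute_product_length <- function(row) {
  coords <- c(f1 = row$f_start, f2 = row$f_end, r1 = row$r_start, r2 = row$r_end)
  trims <- c(f = row$f_length - row$f_aln_length,
             r = row$r_length - row$r_aln_length)
  lo_is_f <- min(coords[c("f1", "f2")]) < min(coords[c("r1", "r2")])
  left <- if (lo_is_f) "f" else "r"
  right <- if (lo_is_f) "r" else "f"
  lo <- min(coords) - trims[[left]]
  hi <- max(coords) + trims[[right]]
  hi - lo + 1
}

# A mutation-free custom plan for property testing (random gene shapes).
clean_plan <- function(n_exons, exon_len, intron_len) {
  mutation_plan(list(
    plan_id = "clean", n_exons = n_exons,
    exon_len = exon_len, intron_len = intron_len,
    events = tibble::tibble(category = character(), index = integer(),
                            length = integer(), codon = integer(),
                            offset = integer())
  ))
}
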