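test_that("global alignment recovers exact matches and single indels", {
  idt <- align_pair("ACGTACGT", "ACGTACGT")
  expect_equal(idt$ref_aligned, "ACGTACGT")
  expect_equal(idt$query_aligned, "ACGTACGT")

  # hand-computed dynamic-programming optimum: delete the C, score 3 - 2 = 1
  aln <- align_pair("ACGT", "AGT", match = 1, mismatch = -1,
                    gap_open = -2, gap_extend = -1)
  expect_equal(aln$score, 1)
  expect_equal(aln$ref_aligned, "ACGT")
  expect_equal(aln$query_aligned, "A-GT")

  expect_error(align_pair("", "ACGT"), "empty")
})

test_that("start-codon loss is called for any non-ATG first codon", {
  fx <- make_locus_fixture(clean_plan(2, c(30L, 30L), 80L), seed = 1)
  aln_of <- function(query_chars_sub) {
    q <- fx$ref$seq
    substr(q, fx$model$exons[[1]][1, "start"],
           fx$model$exons[[1]][1, "start"] + 2) <- query_chars_sub
    coding_alignment(fx$ref$seq, q, fx$model)
  }
  expect_equal(detect_start_loss(aln_of("ACA"))$category, "start_codon_loss")
  expect_equal(detect_start_loss(aln_of("GTG"))$category, "start_codon_loss")
  expect_equal(nrow(detect_start_loss(aln_of("ATG"))), 0)
})

test_that("premature stops are indexed in the reference-projected frame", {
  # 60-codon single-exon gene; plant TGA at codon 5
  fx <- make_locus_fixture(clean_plan(1, 180L, integer(0)), seed = 2)
  q <- fx$ref$seq
  s <- fx$model$exons[[1]][1, "start"] + 3 * 4
  substr(q, s, s + 2) <- "TGA"
  calls <- detect_premature_stops(coding_alignment(fx$ref$seq, q, fx$model))
  expect_equal(nrow(calls), 1)
  expect_equal(calls$codon_index, 5L)
  expect_equal(calls$exon_or_intron_index, 1L)

  # unmutated: silent, including over the terminal reference stop codon
  none <- detect_premature_stops(coding_alignment(fx$ref$seq, fx$ref$seq,
                                                  fx$model))
  expect_equal(nrow(none), 0)
})

test_that("indel runs classify by length mod 3 and stay within exons", {
  fx <- make_locus_fixture(clean_plan(2, c(120L, 120L), 90L), seed = 3)
  del_aln <- function(len, offset) {
    s <- fx$model$exons[[1]][1, "start"] + offset
    q <- paste0(substr(fx$ref$seq, 1, s - 1), strrep("-", len),
                substr(fx$ref$seq, s + len, nchar(fx$ref$seq)))
    coding_alignment(fx$ref$seq, q, fx$model)
  }
  fs <- detect_frameshifts(del_aln(29, 20))
  expect_equal(fs$category, "frameshift_indel")  # 29 mod 3 == 2
  expect_equal(fs$length, 29L)
  inf <- detect_frameshifts(del_aln(3, 20))
  expect_equal(inf$category, "inframe_indel")
  expect_equal(nrow(detect_frameshifts(
    coding_alignment(fx$ref$seq, fx$ref$seq, fx$model))), 0)
})

test_that("splice-site checks call non-canonical dinucleotides and boundary indels", {
  fx <- make_locus_fixture(clean_plan(3, c(90L, 90L, 90L), 90L), seed = 4)
  exons <- fx$model$exons[[1]]
  donor1 <- exons[1, "end"] + 1

  q <- fx$ref$seq
  substr(q, donor1, donor1) <- "A"  # GT -> AT
  calls <- detect_splice_mutations(coding_alignment(fx$ref$seq, q, fx$model))
  expect_equal(calls$category, "splice_donor")
  expect_equal(calls$exon_or_intron_index, 1L)
  expect_match(calls$note, "GT to AT")

  expect_equal(nrow(detect_splice_mutations(
    coding_alignment(fx$ref$seq, fx$ref$seq, fx$model))), 0)

  # 21-nt deletion across the intron 2 / exon 3 boundary: one boundary
  # call, no frameshift (21 mod 3 == 0), no separate acceptor call
  iend <- exons[3, "start"] - 1
  from <- iend - 10
  qa <- paste0(substr(fx$ref$seq, 1, from - 1), strrep("-", 21),
               substr(fx$ref$seq, from + 21, nchar(fx$ref$seq)))
  aln <- coding_alignment(fx$ref$seq, qa, fx$model)
  sp <- detect_splice_mutations(aln)
  expect_equal(sp$category, "splice_boundary_indel")
  expect_equal(sp$exon_or_intron_index, 2L)
  expect_equal(sp$length, 21L)
  expect_equal(nrow(detect_frameshifts(aln)), 0)
})

test_that("screen_gene reproduces every shipped mutation catalog exactly", {
  call_key <- function(calls) {
    calls <- calls[order(calls$category, calls$exon_or_intron_index,
                         calls$length), ]
    paste(calls$category, calls$exon_or_intron_index, calls$length,
          collapse = " | ")
  }
  for (plan_id in shipped_mutation_plans()) {
    fx <- make_locus_fixture(plan_id, seed = 42)
    for (rep in list(
      screen_gene(fx$model, fx$ref, fx$query, alignment = fx$alignment),
      screen_gene(fx$model, fx$ref, fx$query)  # de-novo alignment path
    )) {
      expect_equal(call_key(rep$calls), call_key(fx$expected), info = plan_id)
      expect_equal(rep$n_inactivating, nrow(fx$expected), info = plan_id)
    }
  }
})

test_that("planted stop codons carry the correct global codon index", {
  fx <- make_locus_fixture("opn4m_strix", seed = 42)
  rep <- screen_gene(fx$model, fx$ref, fx$query)
  stop_call <- rep$calls[rep$calls$category == "premature_stop", ]
  # exons 1..7 of 120 nt hold 7 * 40 codons; planted at codon 20 of exon 8
  expect_equal(stop_call$codon_index, 7L * 40L + 20L)
  expect_equal(stop_call$exon_or_intron_index, 8L)
})

test_that("unmutated loci and empty queries are handled", {
  fx <- make_locus_fixture(clean_plan(4, rep(90L, 4), rep(80L, 3)), seed = 5)
  rep <- screen_gene(fx$model, fx$ref, fx$ref)
  expect_equal(nrow(rep$calls), 0)
  expect_equal(rep$n_inactivating, 0L)
  expect_error(screen_gene(fx$model, fx$ref, ""), "infer_gene_deletion")
})

test_that("mutation-free loci of random shape produce no calls", {
  set.seed(66)
  n_loci <- 400
  for (i in seq_len(n_loci)) {
    k <- sample(1:6, 1)
    plan <- clean_plan(k, sample(c(60L, 90L, 120L), k, replace = TRUE),
                       if (k > 1) sample(70L:120L, k - 1, replace = TRUE)
                       else integer(0))
    fx <- make_locus_fixture(plan, seed = i)
    rep <- screen_gene(fx$model, fx$ref, fx$query, alignment = fx$alignment)
    expect_equal(nrow(rep$calls), 0)
  }
  # a smaller subset through the de-novo alignment path
  for (i in 1:15) {
    k <- sample(2:4, 1)
    plan <- clean_plan(k, sample(c(90L, 120L), k, replace = TRUE),
                       sample(80L:110L, k - 1, replace = TRUE))
    fx <- make_locus_fixture(plan, seed = 1000 + i)
    expect_equal(nrow(screen_gene(fx$model, fx$ref, fx$query)$calls), 0)
  }
})

test_that("net frame offset equals the planted indel balance mod 3", {
  for (plan_id in shipped_mutation_plans()) {
    fx <- make_locus_fixture(plan_id, seed = 7)
    rep <- screen_gene(fx$model, fx$ref, fx$query, alignment = fx$alignment)
    indels <- rep$calls[rep$calls$category %in%
                          c("frameshift_indel", "inframe_indel"), ]
    signs <- ifelse(grepl("insertion", indels$note), 1L, -1L)
    ev <- fx$plan$events
    ev_ind <- ev[ev$category %in% c("del", "ins"), ]
    planted <- sum(ifelse(ev_ind$category == "ins", 1L, -1L) * ev_ind$length)
    expect_equal(sum(signs * indels$length) %% 3L, planted %% 3L,
                 info = plan_id)
  }
})

test_that("synteny verdicts follow flank placement, probe hits and N content", {
  del <- make_synteny_fixture("opnp_deletion_synteny", seed = 3)
  ev <- infer_gene_deletion(del$left_flank_hits, del$right_flank_hits,
                            del$probe_hits, del$assembly, gene_id = "opnp")
  expect_equal(ev$verdict, "deletion_supported")
  expect_lte(ev$intergenic_n_fraction, 0.2)

  split <- make_synteny_fixture("sws1_synteny_split", seed = 3)
  ev2 <- infer_gene_deletion(split$left_flank_hits, split$right_flank_hits,
                             split$probe_hits, split$assembly, gene_id = "sws1")
  expect_equal(ev2$verdict, "indeterminate_split")

  # probe present dominates everything
  ev3 <- infer_gene_deletion(del$left_flank_hits, del$right_flank_hits,
                             del$left_flank_hits, del$assembly)
  expect_equal(ev3$verdict, "gene_present")

  # no flank evidence at all
  ev4 <- infer_gene_deletion(del$left_flank_hits[0, ], del$right_flank_hits,
                             del$probe_hits, del$assembly)
  expect_equal(ev4$verdict, "no_evidence")

  # N-dominated intergap
  gap_asm <- del$assembly
  gap_asm$seq <- paste0(substr(gap_asm$seq, 1, 1100), strrep("N", 2800),
                        substr(gap_asm$seq, 3901, 5000))
  gap_asm$length <- nchar(gap_asm$seq)
  ev5 <- infer_gene_deletion(del$left_flank_hits, del$right_flank_hits,
                             del$probe_hits, gap_asm)
  expect_equal(ev5$verdict, "indeterminate_gap")
  expect_gt(ev5$intergenic_n_fraction, 0.2)
})

test_that("codon-alignment cleaning removes stop and gap columns alignment-wide", {
  aln <- c(
    sp1 = "ATGAAATAACCCGGG",
    sp2 = "ATGAAAAAAC--GGG",
    sp3 = "ATGAAACCCCCCGGG"
  )
  # codon 3 holds a stop in sp1; codon 4 holds a gap in sp2
  out <- export_codon_alignment(aln, drop_gap_columns = TRUE)
  expect_equal(nchar(out$seq), rep(9L, 3))
  expect_equal(out$seq[[1]], "ATGAAAGGG")

  out2 <- export_codon_alignment(aln, drop_gap_columns = FALSE)
  expect_equal(nchar(out2$seq), rep(12L, 3))

  no_stops <- c(a = "ATGAAA", b = "ATGCCC")
  expect_equal(export_codon_alignment(no_stops, drop_gap_columns = FALSE)$seq,
               unname(no_stops))
  expect_error(export_codon_alignment(c(a = "ATGA", b = "ATGA")), "divisible")

  fa <- withr::local_tempfile(fileext = ".fa")
  phy <- withr::local_tempfile(fileext = ".phy")
  export_codon_alignment(aln, fasta_path = fa, phylip_path = phy)
  expect_equal(read_fasta(fa)$seq, out$seq)
  expect_equal(readLines(phy)[1], "3 9")
})

test_that("cleaned codon alignments never retain a stop codon", {
  set.seed(88)
  codons <- c("ATG", "AAA", "TAA", "TAG", "TGA", "CCC", "GG-", "---", "CGT")
  for (rep in 1:10) {
    n_taxa <- sample(2:5, 1)
    n_cod <- sample(4:12, 1)
    aln <- vapply(seq_len(n_taxa), function(i) {
      paste(sample(codons, n_cod, replace = TRUE), collapse = "")
    }, character(1))
    names(aln) <- paste0("t", seq_len(n_taxa))
    out <- export_codon_alignment(aln, drop_gap_columns = FALSE)
    expect_equal(unique(nchar(out$seq)) %% 3, 0)
    for (s in out$seq) {
      if (nchar(s) == 0) next
      cods <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
      expect_false(any(toupper(cods) %in% c("TAA", "TAG", "TGA")))
    }
  }
})

test_that("screen reports expose broom-style accessors and a gene diagram", {
  fx <- make_locus_fixture("rh2_tyto", seed = 42)
  rep <- screen_gene(fx$model, fx$ref, fx$query, alignment = fx$alignment)
  expect_equal(tidy(rep), rep$calls)
  g <- glance(rep)
  expect_equal(g$n_inactivating, 4L)
  expect_true(g$cds_gc_percent > 0 && g$cds_gc_percent < 100)
  expect_s3_class(autoplot(rep), "ggplot")
})
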