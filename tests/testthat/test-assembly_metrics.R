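toy_assembly <- function(...) {
  seqs <- c(...)
  tibble::tibble(id = paste0("s", seq_along(seqs)), seq = seqs,
                 length = nchar(seqs))
}

test_that("minimum-length filtering removes strictly shorter records and is idempotent", {
  asm <- toy_assembly(random_seq(999), random_seq(1000))
  kept <- filter_min_length(asm, 1000)
  expect_equal(kept$id, "s2")
  expect_equal(filter_min_length(asm, 0), asm)
  expect_equal(filter_min_length(kept, 1000), kept)
  expect_equal(nrow(filter_min_length(asm[0, ], 10)), 0)
})

test_that("scaffolds split into contigs at N runs under both conventions", {
  r <- split_scaffolds(toy_assembly("AANAA"), n_run_min = 1)
  expect_equal(r$contigs$seq, c("AA", "AA"))
  expect_equal(r$contigs$id, c("s1.1", "s1.2"))
  expect_equal(r$gaps$length, 1L)
  expect_equal(r$gaps$start, 3L)

  # a 30-N run splits at the 25+ convention, a 10-N run does not
  scaf <- paste0(random_seq(100), strrep("N", 30), random_seq(50),
                 strrep("N", 10), random_seq(40))
  r2 <- split_scaffolds(toy_assembly(scaf), n_run_min = 25)
  expect_equal(nrow(r2$contigs), 2)
  expect_equal(r2$contigs$length, c(100L, 100L))
  expect_equal(r2$gaps$length, 30L)

  r3 <- split_scaffolds(toy_assembly(random_seq(80)), n_run_min = 25)
  expect_equal(nrow(r3$contigs), 1)
  expect_equal(nrow(r3$gaps), 0)

  # leading/trailing runs yield no empty contigs and no internal-gap records
  r4 <- split_scaffolds(toy_assembly("NNNACGTNNN"), n_run_min = 2)
  expect_equal(r4$contigs$seq, "ACGT")
  expect_equal(nrow(r4$gaps), 0)
})

test_that("contigs plus recorded gaps reconstruct each scaffold exactly", {
  set.seed(31)
  for (rep in 1:20) {
    n_run_min <- sample(c(1, 5, 25), 1)
    scafs <- vapply(1:4, function(i) {
      pieces <- replicate(sample(1:4, 1), random_seq(sample(20:80, 1)))
      gaps <- replicate(length(pieces) - 1,
                        strrep("N", sample(c(1, 3, 25, 40), 1)))
      paste0(paste0(pieces, c(gaps, ""), collapse = ""))
    }, character(1))
    asm <- toy_assembly(scafs)
    sp <- split_scaffolds(asm, n_run_min)
    for (i in seq_len(nrow(asm))) {
      ctg <- sp$contigs[sp$contigs$scaffold == asm$id[i], ]
      gap <- sp$gaps[sp$gaps$scaffold == asm$id[i], ]
      gap <- gap[order(gap$start), ]
      rebuilt <- ctg$seq[1]
      for (j in seq_len(nrow(gap))) {
        rebuilt <- paste0(rebuilt, strrep("N", gap$length[j]), ctg$seq[j + 1])
      }
      expect_equal(rebuilt, asm$seq[i])
    }
  }
})

test_that("Nx/Lx follow the cumulative-length definition", {
  nx <- nx_stats(c(500, 400, 300, 200, 100), levels = c(50, 90))
  expect_equal(nx$nx, c(400, 200))  # cumulative 900 >= 750; 1400 >= 1350
  expect_equal(nx$lx, c(2L, 4L))
  one <- nx_stats(7777, levels = c(10, 50, 100))
  expect_true(all(one$nx == 7777) && all(one$lx == 1L))
  expect_error(nx_stats(integer(0)), "nonempty")
})

test_that("Nx is non-increasing in x for arbitrary length sets", {
  set.seed(41)
  for (rep in 1:25) {
    lens <- sample.int(1e5, sample(1:40, 1), replace = TRUE)
    nx <- nx_stats(lens, levels = sort(sample(5:100, 8)))
    expect_true(all(diff(nx$nx) <= 0))
    expect_true(all(diff(nx$lx) >= 0))
  }
})

test_that("assembly summaries match hand-derived composition values", {
  m <- summarize_assembly(toy_assembly("ACGT"))
  expect_equal(m$pct_gc, 50)
  expect_equal(m$pct_n, 0)
  expect_equal(m$n_contigs, 1)
  expect_equal(m$pct_assembly_in_scaffolded_contigs, 0)

  m2 <- summarize_assembly(toy_assembly(paste0("AC", strrep("N", 25), "GT")),
                           metrics_config(n_run_min = 25))
  expect_equal(m2$pct_n, 25 / 29 * 100)
  expect_equal(m2$pct_gc, 100 * 2 / 4)  # C and G among 4 non-N bases
  expect_equal(m2$n_contigs, 2)
  expect_equal(m2$n_contigs_in_scaffolds, 2)
  expect_equal(m2$gap_count, 1)
  expect_equal(m2$gap_mean_length, 25)
  expect_equal(m2$pct_assembly_in_scaffolded_contigs, 100 * 4 / 29)
  expect_error(summarize_assembly(toy_assembly("ACGT")[0, ]), "empty")
})

test_that("lowercase soft-masked bases are case-folded for composition", {
  m <- summarize_assembly(toy_assembly("acgtACGT"))
  expect_equal(m$pct_gc, 50)
  expect_equal(m$pct_n, 0)
})

test_that("summaries agree with an independent brute-force recomputation", {
  set.seed(51)
  asm <- toy_assembly(
    paste0(random_seq(500), strrep("N", 30), random_seq(470)),
    random_seq(600),
    paste0(random_seq(100), strrep("N", 10), random_seq(290))
  )
  m <- summarize_assembly(asm, metrics_config(n_run_min = 25))
  b <- brute_assembly_metrics(asm, n_run_min = 25)
  for (f in c("n_sequences", "total_length", "longest", "shortest",
              "mean_length", "median_length", "pct_gc", "pct_n",
              "n_contigs", "n_contigs_in_scaffolds", "n_contigs_unscaffolded",
              "pct_assembly_in_scaffolded_contigs", "gap_count",
              "gap_mean_length")) {
    expect_equal(m[[f]], b[[f]], info = f)
  }
  split <- split_scaffolds(asm, 25)
  expect_equal(sort(split$contigs$length), b$contig_lengths)
})

test_that("contig N50 is non-decreasing as the N-run threshold grows", {
  set.seed(61)
  scafs <- vapply(1:5, function(i) {
    pieces <- replicate(sample(2:5, 1), random_seq(sample(50:400, 1)))
    gaps <- replicate(length(pieces) - 1,
                      strrep("N", sample(c(1, 5, 10, 15, 20, 25, 40), 1)))
    paste0(paste0(pieces, c(gaps, ""), collapse = ""))
  }, character(1))
  asm <- toy_assembly(scafs)
  n50 <- vapply(c(1, 5, 10, 15, 20, 25), function(k) {
    ctg <- split_scaffolds(asm, k)$contigs
    nx_stats(ctg$length, 50)$nx
  }, numeric(1))
  expect_true(all(diff(n50) >= 0))
})

test_that("summaries reproduce generator ground truth exactly", {
  configs <- list(
    assembly_sim_config(c(1000L, 600L, 400L),
                        gaps = tibble::tibble(scaffold = 1L, start = 301L,
                                              length = 30L)),
    assembly_sim_config(c(5000L, 2000L, 800L, 120L),
                        gaps = tibble::tibble(scaffold = c(1L, 1L, 2L),
                                              start = c(1001L, 3001L, 500L),
                                              length = c(40L, 25L, 100L)),
                        gc = 0.5),
    assembly_sim_config(c(300L, 200L))  # gapless
  )
  for (cfg in configs) {
    sim <- simulate_assembly(cfg, seed = 7)
    m <- summarize_assembly(sim$assembly, metrics_config(n_run_min = cfg$n_run_min))
    tr <- sim$truth
    for (f in setdiff(names(tr),
                      c("counts_over_thresholds", "nx_table", "contig_nx_table"))) {
      expect_equal(m[[f]], tr[[f]], info = f)
    }
    expect_equal(as.data.frame(m$nx_table), as.data.frame(tr$nx_table))
    expect_equal(as.data.frame(m$contig_nx_table),
                 as.data.frame(tr$contig_nx_table))
    expect_equal(as.data.frame(m$counts_over_thresholds),
                 as.data.frame(tr$counts_over_thresholds))
  }
})

test_that("length-class counts use a strict greater-than cut", {
  asm <- toy_assembly(random_seq(1000), random_seq(1001))
  m <- summarize_assembly(asm)
  over1k <- m$counts_over_thresholds$count[m$counts_over_thresholds$threshold == 1e3]
  expect_equal(over1k, 1L)
})

test_that("metrics objects expose tidy, glance and autoplot views", {
  sim <- simulate_assembly(assembly_sim_config(
    c(2000L, 900L), gaps = tibble::tibble(scaffold = 1L, start = 501L,
                                          length = 30L)), seed = 2)
  m <- summarize_assembly(sim$assembly)
  td <- tidy(m)
  expect_true(all(c("statistic", "value") %in% names(td)))
  expect_equal(td$value[td$statistic == "scaffold_N50"], 2000)
  g <- glance(m)
  expect_equal(g$n_sequences, 2L)
  expect_s3_class(autoplot(m), "ggplot")
})
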