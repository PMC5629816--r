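clean_site <- function(pos, a = c(0L, 0L), b = c(0L, 0L), gq = c(99L, 99L),
                       dp = c(30L, 30L), indel = FALSE) {
  tibble::tibble(
    scaffold = "s", pos = pos, ref_allele = "A",
    alt_alleles = if (indel) "AT" else "T",
    a1 = a[1], a2 = a[2], b1 = b[1], b2 = b[2],
    gq_a = gq[1], gq_b = gq[2], dp_a = dp[1], dp_b = dp[2], is_indel = indel
  )
}

test_that("coverage threshold is mean plus k sample standard deviations", {
  expect_equal(coverage_threshold(c(10, 10, 10, 10), k = 5), 10)
  expect_equal(coverage_threshold(c(8, 12), k = 5), 10 + 5 * sqrt(8))
  expect_equal(coverage_threshold(c(3, 9, 17), k = 0), mean(c(3, 9, 17)))
  expect_error(coverage_threshold(numeric(0)), "nonempty")
})

test_that("each site filter removes exactly its target class", {
  sites <- dplyr::bind_rows(
    clean_site(1, b = c(1L, 1L), indel = TRUE),       # indel
    clean_site(2, b = c(0L, 1L), gq = c(99L, 5L)),    # low GQ
    clean_site(3, a = c(1L, 1L)),                     # reference hom-alt
    clean_site(4, b = c(1L, 1L), dp = c(900L, 900L)), # excess coverage
    clean_site(5, a = c(0L, 1L))                      # clean heterozygote
  )
  # threshold frozen externally over a (larger) pre-filter site set
  kept <- filter_sites(sites, threshold = 500)
  expect_equal(kept$pos, 5)
  expect_equal(attr(kept, "removal_counts"),
               c(indel = 1L, low_gq = 1L, ref_homalt = 1L, high_coverage = 1L))
  expect_equal(attr(kept, "coverage_threshold"), 500)

  # by default the threshold comes from this input's combined depths
  self_thr <- filter_sites(sites)
  expect_equal(attr(self_thr, "coverage_threshold"),
               coverage_threshold(sites$dp_a + sites$dp_b, 5))

  # idempotent given the frozen threshold carried on the output
  expect_equal(filter_sites(kept), kept, ignore_attr = TRUE)
  expect_equal(attr(filter_sites(kept), "coverage_threshold"), 500)

  empty <- filter_sites(sites[0, ])
  expect_equal(nrow(empty), 0)
  all_clean <- dplyr::bind_rows(clean_site(1), clean_site(2, a = c(0L, 1L)))
  expect_equal(filter_sites(all_clean), all_clean, ignore_attr = TRUE)
})

test_that("per-site decomposition enumerates the four allele pairs", {
  d <- site_diffs(dplyr::bind_rows(
    clean_site(1, a = c(0L, 1L), b = c(0L, 0L)),  # A/T vs A/A
    clean_site(2),                                # A/A vs A/A
    clean_site(3, b = c(1L, 1L))                  # A/A vs T/T
  ))
  expect_equal(d$w_a, c(1, 0, 0))
  expect_equal(d$w_b, c(0, 0, 0))
  expect_equal(d$b, c(0.5, 0, 1))
  bad <- clean_site(1)
  bad$a1 <- NA_integer_
  expect_error(site_diffs(bad), "missing genotype")
})

test_that("diversity sums scale by callable length", {
  sites <- dplyr::bind_rows(
    clean_site(1, a = c(0L, 1L)),
    clean_site(2, b = c(1L, 1L))
  )
  est <- diversity(sites, callable_length = 10)
  expect_equal(est$hw_a, 0.1)
  expect_equal(est$hw_b, 0)
  expect_equal(est$hb, 0.15)
  expect_equal(est$n_sites_used, 2L)

  est0 <- diversity(sites[0, ], callable_length = 100)
  expect_equal(c(est0$hw_a, est0$hw_b, est0$hb), c(0, 0, 0))

  est1 <- diversity(clean_site(1, b = c(1L, 1L)), callable_length = 1000)
  expect_equal(est1$hb, 0.001)
  expect_error(diversity(sites, callable_length = 0), "positive")
})

test_that("Hudson's fixation index follows 1 - mean(Hw)/Hb", {
  expect_equal(round(hudson_fst(2.008e-4, 2.352e-3, 7.042e-3), 3), 0.819)
  expect_equal(hudson_fst(0.1, 0.1, 0.1), 0)
  expect_equal(hudson_fst(0, 0, 0.5), 1)
  expect_error(hudson_fst(0.1, 0.1, 0), "undefined")
})

test_that("pipeline estimates equal a brute-force allele-pair enumerator", {
  for (seed in 1:12) {
    n <- sample(10:100, 1)
    sites <- random_variant_table(n, seed = seed)
    L <- 1000
    est <- hudson_fst(diversity(sites, L))
    b <- brute_diversity(sites, L)
    expect_equal(est$hw_a, b$hw_a)
    expect_equal(est$hw_b, b$hw_b)
    expect_equal(est$hb, b$hb)
    if (!is.na(b$fst)) expect_equal(est$fst, b$fst)
  }
})

test_that("filtering never increases any diversity numerator", {
  set.seed(77)
  for (rep in 1:10) {
    sites <- random_variant_table(60, seed = rep)
    sites$gq_b[sample.int(60, 5)] <- 3L
    sites$dp_a[sample.int(60, 2)] <- 500L
    kept <- filter_sites(sites)
    d_all <- site_diffs(sites)
    d_kept <- site_diffs(kept)
    expect_lte(sum(d_kept$w_a), sum(d_all$w_a))
    expect_lte(sum(d_kept$w_b), sum(d_all$w_b))
    expect_lte(sum(d_kept$b), sum(d_all$b))
  }
})

test_that("the fixation index is invariant under swapping species labels", {
  for (seed in 1:5) {
    sites <- random_variant_table(50, seed = 100 + seed)
    swapped <- dplyr::rename(sites, a1 = b1, a2 = b2, b1 = a1, b2 = a2,
                             gq_a = gq_b, gq_b = gq_a, dp_a = dp_b, dp_b = dp_a)
    e1 <- hudson_fst(diversity(sites, 500))
    e2 <- hudson_fst(diversity(swapped, 500))
    expect_equal(e1$fst, e2$fst)
    expect_equal(e1$hw_a, e2$hw_b)
  }
})

test_that("the full wrapper reports filter metadata alongside the estimate", {
  sim <- simulate_variant_sites(
    variant_sim_config(L = 50000, het_a = 1e-3, het_b = 2e-3, div = 5e-3,
                       p_indel = 1e-4, p_highdp = 1e-4), seed = 9
  )
  est <- estimate_divergence(dplyr::select(sim$sites, -category), 50000)
  expect_s3_class(est, "divergence_estimate")
  expect_false(is.na(est$fst))
  expect_equal(est$hw_a, sim$truth$hw_a)
  expect_equal(est$hw_b, sim$truth$hw_b)
  expect_equal(est$hb, sim$truth$hb)
  rc <- attr(est, "removal_counts")
  expect_equal(unname(rc[["indel"]]), unname(sim$truth$counts[["indel"]]))
  td <- tidy(est)
  expect_equal(td$component, c("hw_a", "hw_b", "hb", "fst"))
  expect_equal(glance(est)$callable_length, 50000)
  expect_s3_class(autoplot(est), "ggplot")
})
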