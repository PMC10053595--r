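design10 <- group_design(paste0("s", 1:10), rep(c("EP", "ML"), each = 5))
samples10 <- paste0("s", 1:10)

counts_site <- function(alt_by_sample, depth = 20L) {
  make_sites(100, ref_counts = matrix(depth - alt_by_sample, 1),
             alt_counts = matrix(alt_by_sample, 1), samples = samples10)
}

test_that("AAF arithmetic: per-sample, pooled group and delta", {
  expect_error(group_design("s1", "EP"), "two groups")
  aaf <- compute_aaf(counts_site(rep(8L, 10)), design10)
  expect_equal(unname(aaf$aaf_per_sample[1, 1]), 0.4)
  expect_equal(unname(aaf$delta_aaf), 0)             # identical groups
  # pooled 30/100 vs 70/100
  alt <- c(rep(6L, 5), rep(14L, 5))
  aaf2 <- compute_aaf(counts_site(alt), design10)
  expect_equal(unname(aaf2$group_aaf[1, ]), c(aaf_g1 = 0.3, aaf_g2 = 0.7),
               ignore_attr = TRUE)
  expect_equal(unname(aaf2$delta_aaf), -0.4)
})

test_that("zero-depth groups are flagged untestable", {
  s <- make_sites(100, ref_counts = matrix(c(rep(0L, 5), rep(10L, 5)), 1),
                  alt_counts = matrix(0L, 1, 10), samples = samples10)
  aaf <- compute_aaf(s, design10)
  expect_false(aaf$testable)
  expect_true(is.na(test_delta_aaf(s, design10)))
})

test_that("the likelihood-ratio test collapses under H0 and separates extremes", {
  same <- counts_site(rep(8L, 10))
  expect_equal(test_delta_aaf(same, design10), 1)
  extreme <- make_sites(100,
                        ref_counts = matrix(c(rep(0L, 5), rep(20L, 5)), 1),
                        alt_counts = matrix(c(rep(20L, 5), rep(0L, 5)), 1),
                        samples = samples10)
  expect_lt(test_delta_aaf(extreme, design10), 1e-10)
})

test_that("the test is label-symmetric", {
  set.seed(31)
  for (rep_i in 1:20) {
    alt <- as.integer(rbinom(10, 30, runif(1, 0.2, 0.8)))
    s <- make_sites(100, ref_counts = matrix(30L - alt, 1),
                    alt_counts = matrix(alt, 1), samples = samples10)
    # same partition with group roles exchanged: group1 is now s6..s10
    flipped <- group_design(paste0("s", c(6:10, 1:5)),
                            rep(c("ML", "EP"), each = 5))
    expect_equal(test_delta_aaf(s, design10), test_delta_aaf(s, flipped))
    expect_equal(compute_aaf(s, design10)$delta_aaf,
                 -compute_aaf(s, flipped)$delta_aaf)
  }
})

test_that("empirical type-I error of the test is nominal at depth 50, n = 5 + 5", {
  set.seed(77)
  n_sim <- 2000
  p <- numeric(n_sim)
  for (i in seq_len(n_sim)) {
    depth <- rpois(10, 50)
    alt <- rbinom(10, depth, 0.5)
    s <- make_sites(100, ref_counts = matrix(depth - alt, 1),
                    alt_counts = matrix(alt, 1), samples = samples10)
    p[i] <- test_delta_aaf(s, design10)
  }
  rate <- mean(p < 0.05)
  expect_gte(rate, 0.035)
  expect_lte(rate, 0.065)
})

test_that("BH adjustment matches the hand-derived step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(19)
  for (rep_i in 1:100) {
    p <- runif(sample(1:50, 1))
    expect_equal(bh_adjust(p), bh_oracle(p))
  }
  # NA p-values stay NA and do not enter the family
  p <- c(0.01, NA, 0.04)
  q <- bh_adjust(p)
  expect_true(is.na(q[2]))
  expect_equal(q[c(1, 3)], bh_oracle(p[c(1, 3)]))
})

test_that("allelic balance categories follow the 1:1 goodness-of-fit test", {
  bal50 <- balance_category(counts_site(rep(10L, 10)))   # pooled 100/100
  expect_equal(bal50$balance_p, 1)
  expect_equal(bal50$category, "true_heterozygote")
  # pooled 90 ref / 10 alt: chi2 = 64
  s_ref <- make_sites(100, ref_counts = matrix(9L, 1, 10),
                      alt_counts = matrix(1L, 1, 10), samples = samples10)
  bal <- balance_category(s_ref)
  expect_equal(bal$balance_p, pchisq(64, 1, lower.tail = FALSE))
  expect_equal(bal$category, "HeteroRef")
  s_alt <- make_sites(100, ref_counts = matrix(1L, 1, 10),
                      alt_counts = matrix(9L, 1, 10), samples = samples10)
  bal2 <- balance_category(s_alt)
  expect_equal(bal2$balance_p, bal$balance_p)            # symmetric statistic
  expect_equal(bal2$category, "HeteroAlt")
  # closed form agrees with the textbook test
  expect_equal(bal$balance_p,
               suppressWarnings(chisq.test(c(90, 10), p = c(0.5, 0.5),
                                           correct = FALSE)$p.value))
})

test_that("chi-square direction agrees with the exact binomial test", {
  set.seed(23)
  for (rep_i in 1:50) {
    ref_t <- sample(0:60, 1); alt_t <- sample(0:60, 1)
    if (ref_t + alt_t == 0) next
    s <- make_sites(100, ref_counts = matrix(ref_t, 1, 1),
                    alt_counts = matrix(alt_t, 1, 1), samples = "s1")
    bal <- balance_category(s)
    if (bal$category == "HeteroRef") expect_gt(ref_t, alt_t)
    if (bal$category == "HeteroAlt") expect_gt(alt_t, ref_t)
    if (bal$category != "true_heterozygote") {
      bt <- binom.test(alt_t, ref_t + alt_t, 0.5)
      dir_bt <- sign(bt$estimate - 0.5)
      expect_equal(unname(dir_bt), if (bal$category == "HeteroAlt") 1 else -1)
    }
  }
})

test_that("the ASE flag is the conjunction of effect size, FDR and balance", {
  res <- data.frame(delta_aaf = c(0.05, 0.5, 0.5, 0.5),
                    q_value = c(1e-6, 5e-4, 0.01, 5e-4),
                    balance_p = c(0.001, 0.001, 0.001, 0.5))
  out <- classify_ase(res)
  expect_equal(out$ase_flag, c(FALSE, TRUE, FALSE, FALSE))
})

test_that("null cohorts are flagged at far below the nominal FDR ceiling", {
  cfg <- sim_config(seed = 6, n_chroms = 1, chrom_length = 80000,
                    genes_per_chrom = 6, n_sites = 400, ase_fraction = 0,
                    editing_fraction = 0, context_violation_fraction = 0,
                    quality_fail_fraction = 0, proximity_fail_fraction = 0,
                    sparse_fraction = 0, n_editing_decoys = 0)
  ref <- simulate_reference(cfg)
  v <- simulate_variants(cfg, ref)
  res <- classify_ase(ase_table(v$sites, v$design))
  expect_lte(mean(res$ase_flag), 0.005)
})
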