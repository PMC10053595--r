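test_that("Pearson r and p behave at the exact extremes", {
  x <- as.numeric(1:10)
  aff <- pearson_with_p(x, 2 * x + 1)
  expect_equal(aff$r, 1)
  expect_equal(aff$p, 0)
  # constructed zero-covariance pair
  y <- c(1, -1, 1, -1, 1, -1, 1, -1, 1, -1)
  z <- c(1, 1, -1, -1, 1, 1, -1, -1, 1, 1)
  orth <- pearson_with_p(y, z)
  expect_equal(orth$r, 0, tolerance = 1e-12)
  expect_equal(orth$p, 1)
  expect_warning(flat <- pearson_with_p(rep(1, 5), 1:5), "constant")
  expect_true(is.na(flat$r))
})

test_that("(r, p) match the reference statistical test to 1e-10", {
  set.seed(71)
  for (rep_i in 1:100) {
    n <- sample(4:30, 1)
    x <- rnorm(n)
    y <- 0.5 * x + rnorm(n)
    got <- pearson_with_p(x, y)
    want <- cor.test(x, y)
    expect_equal(got$r, unname(want$estimate), tolerance = 1e-10)
    expect_equal(got$p, want$p.value, tolerance = 1e-10)
  }
})

test_that("pair order does not change |r| or p", {
  set.seed(73)
  x <- rnorm(10); y <- rnorm(10)
  a <- pearson_with_p(x, y)
  b <- pearson_with_p(y, x)
  expect_equal(abs(a$r), abs(b$r))
  expect_equal(a$p, b$p)
})

pair_row <- function(r, p, ndg = NA, prob = NA) {
  data.frame(del_id = "L", deg_id = "G", r = r, p_corr = p, ndg = ndg,
             binding_prob = prob)
}

test_that("trans triage needs correlation and at least one binding line", {
  keep <- trans_triage(pair_row(0.95, 0.001, ndg = -0.5))
  expect_equal(nrow(keep), 1)
  expect_equal(keep$direction, "positive")
  # correlated but no binding evidence
  expect_equal(nrow(trans_triage(pair_row(0.95, 0.001, ndg = -0.05, prob = 0.5))), 0)
  # binding but weak correlation
  expect_equal(nrow(trans_triage(pair_row(0.85, 0.001, ndg = -0.5))), 0)
  neg <- trans_triage(pair_row(-0.95, 0.001, prob = 0.95))
  expect_equal(neg$direction, "negative")
  # thresholds are strict
  expect_equal(nrow(trans_triage(pair_row(0.9, 0.001, ndg = -0.5))), 0)
  expect_equal(nrow(trans_triage(pair_row(0.95, 0.05, ndg = -0.5))), 0)
  expect_equal(nrow(trans_triage(pair_row(0.95, 0.001, ndg = -0.1))), 0)
  expect_equal(nrow(trans_triage(pair_row(0.95, 0.001, prob = 0.9))), 0)
})

test_that("loosening any trans threshold only grows the retained set", {
  set.seed(81)
  pairs <- data.frame(del_id = paste0("L", 1:200), deg_id = paste0("G", 1:200),
                      r = runif(200, -1, 1), p_corr = runif(200),
                      ndg = ifelse(runif(200) < 0.5, runif(200, -1, 0.2), NA),
                      binding_prob = ifelse(runif(200) < 0.5, runif(200), NA))
  tight <- trans_triage(pairs)
  loose <- trans_triage(pairs, r_min = 0.5, p_max = 0.2, ndg_max = 0,
                        prob_min = 0.5)
  expect_true(all(paste(tight$del_id, tight$deg_id) %in%
                    paste(loose$del_id, loose$deg_id)))
})

test_that("cis pairing uses the edge-to-edge 10 kb gap with overlap as zero", {
  del <- GenomicRanges::GRanges("c1", IRanges::IRanges(1001, 2000))
  del$id <- "L1"
  genes <- GenomicRanges::GRanges(c("c1", "c1", "c2"),
                                  IRanges::IRanges(c(12000, 12002, 12000),
                                                   c(13000, 13000, 13000)))
  genes$id <- c("G_in", "G_out", "G_chr2")
  out <- cis_pairs(del, genes)
  # gap 9,999 is cis; 10,001 and the other chromosome are not
  expect_equal(out$deg_id, "G_in")
  expect_equal(out$gap, 9999L)
  over <- cis_pairs(del, GenomicRanges::GRanges("c1", IRanges::IRanges(1500, 2500),
                                                id = "Gov"))
  expect_equal(over$gap, 0L)
  # boundary: gap exactly 10,000 is retained
  edge <- cis_pairs(del, GenomicRanges::GRanges("c1", IRanges::IRanges(12001, 13000),
                                                id = "Gedge"))
  expect_equal(edge$gap, 10000L)
})

test_that("cis pairs equal the all-vs-all oracle on random loci", {
  set.seed(83)
  for (rep_i in 1:30) {
    nd <- sample(1:12, 1); ng <- sample(1:12, 1)
    del <- data.frame(id = paste0("L", seq_len(nd)),
                      chrom = sample(c("c1", "c2"), nd, TRUE),
                      start = sample(1e5, nd))
    del$end <- del$start + sample(100:5000, nd, TRUE)
    gene <- data.frame(id = paste0("G", seq_len(ng)),
                       chrom = sample(c("c1", "c2"), ng, TRUE),
                       start = sample(1e5, ng))
    gene$end <- gene$start + sample(100:5000, ng, TRUE)
    dgr <- GenomicRanges::GRanges(del$chrom, IRanges::IRanges(del$start, del$end))
    dgr$id <- del$id
    ggr <- GenomicRanges::GRanges(gene$chrom, IRanges::IRanges(gene$start, gene$end))
    ggr$id <- gene$id
    got <- cis_pairs(dgr, ggr)
    want <- cis_oracle(del, gene)
    key <- function(d) sort(paste(d$del_id, d$deg_id, d$gap))
    expect_equal(key(got), key(want))
  }
})

test_that("all-pairs correlation matches the per-pair computation", {
  set.seed(85)
  expr <- matrix(rlnorm(8 * 10), 8, 10,
                 dimnames = list(paste0("f", 1:8), paste0("s", 1:10)))
  pairs <- correlate_pairs(expr, c("f1", "f2"), c("f3", "f4", "f5"))
  expect_equal(nrow(pairs), 6)
  for (i in seq_len(nrow(pairs))) {
    single <- pearson_with_p(expr[pairs$del_id[i], ], expr[pairs$deg_id[i], ])
    expect_equal(pairs$r[i], single$r)
    expect_equal(pairs$p_corr[i], single$p, tolerance = 1e-12)
  }
  # constant feature is skipped with a warning
  expr2 <- rbind(expr, flat = rep(2, 10))
  expect_warning(out <- correlate_pairs(expr2, c("f1", "flat"), "f3"),
                 "constant")
  expect_equal(out$del_id, "f1")
})

test_that("planted interactions and only they survive the triage", {
  cfg <- sim_config(seed = 16)
  ref <- simulate_reference(cfg)
  ex <- simulate_expression_and_scores(cfg, ref)
  pairs <- correlate_pairs(ex$expr, ex$del_ids, ex$deg_ids)
  key <- function(d) paste(d$del_id, d$deg_id)
  pairs$ndg <- ex$ndg$ndg[match(key(pairs), key(ex$ndg))]
  pairs$binding_prob <- ex$prob$prob[match(key(pairs), key(ex$prob))]
  got <- trans_triage(pairs)
  expect_setequal(key(got), key(ex$truth$trans))
  m <- merge(got, ex$truth$trans, by = c("del_id", "deg_id"))
  expect_equal(m$direction.x, m$direction.y)
  cis <- cis_pairs(ex$del_loci, ex$deg_loci)
  expect_setequal(paste(cis$del_id, cis$deg_id, cis$gap),
                  paste(ex$truth$cis$del_id, ex$truth$cis$deg_id,
                        ex$truth$cis$gap))
})
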