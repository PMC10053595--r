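th <- filter_thresholds()

test_that("quality filter applies strict inequalities and tolerates absent values", {
  sites <- make_sites(c(100, 200, 300, 400, 500, 600),
                      MQ = c(35, 60, 40, NA, 60, 60),
                      DP = c(100, 100, 100, 100, 10, 100),
                      QD = c(5, 5, 5, 5, 5, NA),
                      ReadPosRankSum = c(0, 0, 0, 0, 0, -8.5),
                      MQRankSum = 0)
  out <- quality_filter(sites, th)
  # 35 and exactly-40 fail MQ (> 40 strict); exactly-10 fails DP; -8.5 fails
  # the read-position rank sum; absent values pass
  expect_equal(out$sites$pos, c(200, 400))
  expect_equal(out$removed$pos, c(100, 300, 500, 600))
  strict <- quality_filter(sites, filter_thresholds(strict_quality = TRUE))
  expect_equal(strict$sites$pos, 200)
})

test_that("junction windows span both exonic and intronic sides of a boundary", {
  ann <- make_annotation(rbind(
    ex_row("c1", 101, 200, "+", "G1", "T1"),
    ex_row("c1", 301, 400, "+", "G1", "T1")
  ))
  # boundary coordinate 200: bases within 5 bp on either side are excluded;
  # base 204 (distance 3 on the intronic side) falls, base 207 survives
  sites <- make_sites(c(204, 196, 195, 207, 350))
  out <- context_filter(sites, ann, thresholds = th)
  expect_equal(sort(out$removed$pos), c(196, 204))
  expect_equal(out$sites$pos, c(195, 207, 350))
  expect_true(all(out$reasons$junction[sites$pos %in% c(196, 204)]))
})

test_that("paralog flanks use exact boundary arithmetic", {
  ann <- make_annotation(ex_row("c2", 50000, 50100, "+", "GX", "TX"))
  paralog <- GenomicRanges::GRanges("c1", IRanges::IRanges(1001, 1100))
  # flanked mask covers bases 951..1150
  sites <- make_sites(c(950, 951, 1150, 1151, 1050))
  out <- context_filter(sites, ann, paralog_bed = paralog, thresholds = th)
  expect_equal(sort(out$removed$pos), c(951, 1050, 1150))
  expect_equal(out$sites$pos, c(950, 1151))
  expect_true(all(out$reasons$paralog[sites$pos %in% c(951, 1050, 1150)]))
})

test_that("bidirectional regions are the opposite-strand gene-body overlap", {
  ann <- make_annotation(rbind(
    ex_row("c1", 1000, 2000, "+", "GA", "TA"),
    ex_row("c1", 1500, 2500, "-", "GB", "TB")
  ))
  bid <- bidirectional_regions(ann)
  expect_equal(GenomicRanges::start(bid), 1500)
  expect_equal(GenomicRanges::end(bid), 2000)
  sites <- make_sites(c(1499, 1500, 2000, 2001))
  out <- context_filter(sites, ann, thresholds = th)
  expect_equal(sort(out$removed$pos), c(1500, 2000))
})

test_that("proximity rules remove every participant of a close pair or triplet", {
  both <- proximity_filter(make_sites(c(100, 140)), th)
  expect_equal(nrow(both$sites), 0)              # distance 40 <= 45
  apart <- proximity_filter(make_sites(c(100, 150)), th)
  expect_equal(nrow(apart$sites), 2)             # distance 50 > 45
  # same positions on different chromosomes never pair
  cross <- proximity_filter(make_sites(c(100, 140), chrom = c("c1", "c2")), th)
  expect_equal(nrow(cross$sites), 2)
})

test_that("proximity filter equals the exhaustive oracle on random layouts", {
  set.seed(21)
  for (rep_i in 1:400) {
    n <- sample(2:18, 1)
    pos <- sort(sample(1000, n))
    thr <- filter_thresholds(pair_window = sample(c(10, 45, 80), 1),
                             triplet_window = sample(c(35, 120), 1))
    sites <- make_sites(pos)
    got <- proximity_filter(sites, thr)
    want_rm <- prox_oracle(pos, thr$pair_window, thr$triplet_window)
    expect_equal(got$removed$pos, pos[want_rm])
  }
})

test_that("prevalence requires alt support in at least half of the samples", {
  mk10 <- function(alt_in) {
    altc <- matrix(0L, 1, 10)
    altc[1, seq_len(alt_in)] <- 5L
    make_sites(100, ref_counts = matrix(10L, 1, 10), alt_counts = altc,
               samples = paste0("s", 1:10))
  }
  expect_equal(nrow(prevalence_filter(mk10(5))$sites), 1)   # 5 of 10 passes
  expect_equal(nrow(prevalence_filter(mk10(4))$sites), 0)
})

test_that("the cascade chains its report and is idempotent", {
  empty <- make_sites(integer(0))
  ann <- make_annotation(ex_row("c9", 10, 20, "+", "G", "T"))
  out <- run_cascade(empty, ann)
  expect_equal(out$report$n_in, rep(0L, 4))
  expect_equal(out$report$stage, c("quality", "context", "proximity", "prevalence"))

  cfg <- sim_config(seed = 8, n_chroms = 1, chrom_length = 80000,
                    genes_per_chrom = 6, n_sites = 300)
  ref <- simulate_reference(cfg)
  v <- simulate_variants(cfg, ref)
  mask <- ssr_mask(as.character(ref$genome))
  once <- run_cascade(v$sites, ref$annotation, ref$paralog, mask)
  expect_equal(once$report$n_out, once$report$n_in - once$report$n_removed)
  expect_equal(once$report$n_in[-1], once$report$n_out[-4])
  twice <- run_cascade(once$sites, ref$annotation, ref$paralog, mask)
  expect_equal(sum(twice$report$n_removed), 0)
  expect_equal(twice$sites$pos, once$sites$pos)
})

test_that("loosening thresholds never shrinks the surviving set", {
  cfg <- sim_config(seed = 12, n_chroms = 1, chrom_length = 80000,
                    genes_per_chrom = 6, n_sites = 300)
  ref <- simulate_reference(cfg)
  v <- simulate_variants(cfg, ref)
  mask <- ssr_mask(as.character(ref$genome))
  tight <- run_cascade(v$sites, ref$annotation, ref$paralog, mask,
                       filter_thresholds())
  loose <- run_cascade(v$sites, ref$annotation, ref$paralog, mask,
                       filter_thresholds(mq_min = 20, junction_flank = 2,
                                         paralog_flank = 10, pair_window = 20,
                                         triplet_window = 10,
                                         prevalence_fraction = 0.2))
  key <- function(d) paste(d$chrom, d$pos)
  expect_true(all(key(tight$sites) %in% key(loose$sites)))
})

test_that("context sub-rules commute", {
  cfg <- sim_config(seed = 14, n_chroms = 1, chrom_length = 80000,
                    genes_per_chrom = 6, n_sites = 300)
  ref <- simulate_reference(cfg)
  v <- simulate_variants(cfg, ref)
  mask <- ssr_mask(as.character(ref$genome))
  full <- context_filter(v$sites, ref$annotation, ref$paralog, mask, th)
  # applying single-reason filters in any order gives the same survivors
  s1 <- context_filter(v$sites, ref$annotation, paralog_bed = ref$paralog,
                       thresholds = th)$sites
  s2 <- context_filter(s1, ref$annotation, ssr = mask, thresholds = th)$sites
  expect_equal(sort(s2$pos), sort(full$sites$pos))
})

test_that("cascade survivors of the synthetic cohort audit clean against every rule", {
  cfg <- sim_config(seed = 2, n_chroms = 1, chrom_length = 120000,
                    genes_per_chrom = 8, n_sites = 600)
  ref <- simulate_reference(cfg)
  v <- simulate_variants(cfg, ref)
  mask <- ssr_mask(as.character(ref$genome))
  out <- run_cascade(v$sites, ref$annotation, ref$paralog, mask)
  key <- function(d) paste(d$chrom, d$pos)
  truth <- v$truth[match(key(out$sites), key(v$truth)), ]
  # survivors are exactly the classes that pass every stage
  expect_true(all(truth$class %in% c("null", "ase", "editing", "editing_decoy")))
  # and per-stage removal counts equal the ledger's class counts
  cls <- table(v$truth$class)
  get <- function(x) if (x %in% names(cls)) unname(cls[x]) else 0L
  expect_equal(out$report$n_removed[1], get("quality_fail"))
  expect_equal(out$report$n_removed[2],
               sum(vapply(c("context_junction", "context_paralog",
                            "context_ssr", "context_bidirectional"),
                          get, integer(1))))
  expect_equal(out$report$n_removed[3], get("proximity_fail"))
  expect_equal(out$report$n_removed[4], get("sparse"))
})
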