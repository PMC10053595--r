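gene_plus <- ex_row("c1", 1000, 2000, "+", "GP", "TP")
gene_minus <- ex_row("c1", 3000, 4000, "-", "GM", "TM")
ann2 <- make_annotation(rbind(gene_plus, gene_minus))

test_that("canonical substitutions resolve through the gene strand", {
  s <- make_sites(c(1500, 3500, 1600, 3600, 5000, 5100),
                  ref = c("A", "T", "G", "C", "A", "C"),
                  alt = c("G", "C", "A", "T", "G", "T"))
  r <- resolve_canonical(s, ann2)
  # A>G on + gene; T>C on - gene reads A>G on the gene strand
  expect_equal(r$editing_type[1:2], c("A_to_I", "A_to_I"))
  expect_equal(r$resolved_strand[1:2], c("+", "-"))
  # G>A on a + gene is not canonical; C>T on a - gene is not canonical
  expect_true(is.na(r$editing_type[3]))
  expect_true(is.na(r$editing_type[4]))
  # intergenic: the unique canonical reading implies the strand
  expect_equal(r$editing_type[5], "A_to_I")
  expect_equal(r$resolved_strand[5], "+")
  expect_equal(r$editing_type[6], "C_to_U")
  expect_equal(r$resolved_strand[6], "+")
  # intergenic G>A reads C>T on the minus strand
  s2 <- make_sites(5200, ref = "G", alt = "A")
  r2 <- resolve_canonical(s2, ann2)
  expect_equal(r2$editing_type, "C_to_U")
  expect_equal(r2$resolved_strand, "-")
})

test_that("strand resolution is involution-consistent", {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  combos <- expand.grid(ref = names(comp), alt = names(comp),
                        stringsAsFactors = FALSE)
  combos <- combos[combos$ref != combos$alt, ]
  for (i in seq_len(nrow(combos))) {
    s_plus <- make_sites(1500, ref = combos$ref[i], alt = combos$alt[i])
    s_minus <- make_sites(3500, ref = comp[[combos$ref[i]]],
                          alt = comp[[combos$alt[i]]])
    tp <- resolve_canonical(s_plus, ann2)$editing_type
    tm <- resolve_canonical(s_minus, ann2)$editing_type
    expect_equal(tp, tm)
  }
})

edit_fixture <- function(id = NA_character_, pos = 1500, max_aaf = 0.5,
                         q = 1e-4, delta = 0.3) {
  samples <- paste0("s", 1:10)
  depth <- 20L
  alt <- as.integer(round(depth * max_aaf))
  altc <- matrix(2L, 1, 10)
  altc[1, 1] <- alt
  s <- make_sites(pos, ref = "A", alt = "G", id = id,
                  ref_counts = matrix(depth, 1, 10) - altc, alt_counts = altc,
                  samples = samples)
  ase <- data.frame(q_value = q, delta_aaf = delta)
  list(sites = s, ase = ase)
}
sine_track <- GenomicRanges::GRanges("c1", IRanges::IRanges(1400, 1700))

test_that("the editing filter enforces all four rules with a per-rule audit", {
  ok <- edit_fixture()
  out <- editing_filter(ok$sites, ok$ase, ann2, sine_track)
  expect_equal(nrow(out$candidates), 1)
  expect_equal(out$candidates$editing_type, "A_to_I")

  ceiling_fail <- edit_fixture(max_aaf = 0.75)
  out2 <- editing_filter(ceiling_fail$sites, ceiling_fail$ase, ann2, sine_track)
  expect_equal(nrow(out2$candidates), 0)
  expect_false(out2$audit$pass_ceiling)
  expect_true(all(out2$audit[, c("pass_no_id", "pass_sine", "pass_significance")] == TRUE))

  # exactly at the ceiling passes (strict > fails only above)
  at_ceiling <- edit_fixture(max_aaf = 0.7)
  expect_equal(nrow(editing_filter(at_ceiling$sites, at_ceiling$ase, ann2,
                                   sine_track)$candidates), 1)

  known <- edit_fixture(id = "rs999")
  out3 <- editing_filter(known$sites, known$ase, ann2, sine_track)
  expect_equal(nrow(out3$candidates), 0)
  expect_false(out3$audit$pass_no_id)

  outside <- edit_fixture(pos = 1900)
  out4 <- editing_filter(outside$sites, outside$ase, ann2, sine_track)
  expect_false(out4$audit$pass_sine)

  weak <- edit_fixture(q = 0.2)
  out5 <- editing_filter(weak$sites, weak$ase, ann2, sine_track)
  expect_false(out5$audit$pass_significance)
  small <- edit_fixture(delta = 0.05)
  expect_false(editing_filter(small$sites, small$ase, ann2,
                              sine_track)$audit$pass_significance)
})

test_that("known-site intersection matches a nested-loop join", {
  set.seed(41)
  for (rep_i in 1:25) {
    n <- sample(1:30, 1)
    cand <- data.frame(chrom = sample(c("c1", "c2"), n, TRUE),
                       pos = sample(500, n, TRUE),
                       editing_type = sample(c("A_to_I", "C_to_U"), n, TRUE),
                       stringsAsFactors = FALSE)
    m <- sample(0:30, 1)
    known <- data.frame(chrom = sample(c("c1", "c2"), m, TRUE),
                        pos = sample(500, m, TRUE),
                        type = sample(c("A_to_I", "C_to_U"), m, TRUE),
                        tissue = sample(letters, m, TRUE),
                        stringsAsFactors = FALSE)
    known <- known[!duplicated(known[, c("chrom", "pos", "type")]), ]
    got <- intersect_known(cand, known)
    want <- logical(n)
    for (i in seq_len(n)) {
      for (j in seq_len(nrow(known))) {
        if (cand$chrom[i] == known$chrom[j] && cand$pos[i] == known$pos[j] &&
            cand$editing_type[i] == known$type[j]) want[i] <- TRUE
      }
    }
    expect_equal(!is.na(got$known_site_match), want)
  }
  # empty known table gives zero matches
  none <- intersect_known(data.frame(chrom = "c1", pos = 1,
                                     editing_type = "A_to_I"),
                          data.frame(chrom = character(), pos = integer(),
                                     type = character()))
  expect_true(is.na(none$known_site_match))
})

test_that("surviving synthetic editing candidates re-audit clean and stay within the cascade output", {
  cfg <- sim_config(seed = 4, n_chroms = 1, chrom_length = 120000,
                    genes_per_chrom = 8, n_sites = 600)
  ref <- simulate_reference(cfg)
  v <- simulate_variants(cfg, ref)
  mask <- ssr_mask(as.character(ref$genome))
  casc <- run_cascade(v$sites, ref$annotation, ref$paralog, mask)
  ase <- classify_ase(ase_table(casc$sites, v$design))
  out <- editing_filter(casc$sites, ase, ref$annotation, ref$sine)
  key <- function(d) paste(d$chrom, d$pos)
  # containment: candidates are a subset of the cascade survivors
  expect_true(all(key(out$candidates) %in% key(casc$sites)))
  # every survivor passes all four rules in the audit
  aud <- out$audit[out$audit$retained, ]
  expect_true(all(aud$pass_ceiling & aud$pass_no_id & aud$pass_sine &
                    aud$pass_significance))
  # candidates equal the planted editing truth
  planted <- v$truth[v$truth$editing_class == "planted", ]
  expect_setequal(key(out$candidates), key(planted))
  # and the resolved types match the generator's strand bookkeeping
  m <- match(key(out$candidates), key(planted))
  expect_equal(out$candidates$editing_type, planted$editing_type_truth[m])
  expect_equal(out$candidates$resolved_strand, planted$editing_strand_truth[m])
})
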