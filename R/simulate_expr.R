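#' Simulate transcript tables, coding-potential scores, expression and
#' interaction evidence with planted truth
#'
#' Emits (i) a candidate-transcript table mixing the reference gene models
#' with novel assembled transcripts whose structural properties and
#' five-tool coding-potential verdicts are planted to exercise every rule of
#' the lncRNA cascade (including the exact boundary scores), (ii) domain
#' evidence, (iii) an expression matrix over the cohort samples in which
#' designated lncRNA-gene pairs carry strong planted correlations (|r| >=
#' 0.95, both signs) plus binding evidence while decoys get independent
#' noise or correlation without binding, and (iv) lncRNA loci placed at
#' known gaps from genes for the cis rule. All intended outcomes are
#' recorded at construction in the truth ledgers.
#'
#' @param config a [sim_config()]
#' @param reference output of [simulate_reference()]
#' @return list with `transcripts`, `scores`, `evidence`, `expr` (matrix),
#'   `del_ids`, `deg_ids`, `ndg`, `prob`, `del_loci`, `deg_loci`, and
#'   `truth` (`lncrna`, `trans`, `cis` ledgers)
#' @export
simulate_expression_and_scores <- function(config, reference) {
  stopifnot(config$genes_per_chrom >= 15, config$chrom_length >= 360000)
  ann <- reference$annotation
  floor_expr <- config$lnc_expression_floor

  nc <- "noncoding"; cd <- "coding"
  good <- list(cpat = 0.40, cpc2 = -1.2, feelnc = 0.20, cnci = nc, plek = nc)
  # each case: structural fields, five verdicts, domain evidence, intended
  # outcome decided here, before any score is emitted
  cases <- list(
    list(id = "MSTRG.1.1", len = 1200L, ex = 3L, expr = 10, bt = "novel",
         sc = list(cpat = 0.40, cpc2 = -1.2, feelnc = 0.20, cnci = cd, plek = cd),
         pfam = NA, rfam = FALSE, lnc = TRUE),
    list(id = "MSTRG.2.1", len = 2400L, ex = 5L, expr = 30, bt = "novel",
         sc = good, pfam = NA, rfam = FALSE, lnc = TRUE),
    list(id = "MSTRG.3.1", len = 900L, ex = 2L, expr = 8, bt = "novel",
         sc = list(cpat = 0.40, cpc2 = -1.2, feelnc = 0.90, cnci = cd, plek = cd),
         pfam = NA, rfam = FALSE, lnc = FALSE),          # only 2 noncoding votes
    list(id = "MSTRG.4.1", len = 800L, ex = 2L, expr = 5, bt = "novel",
         sc = list(cpat = 0.78, cpc2 = -1.0, feelnc = 0.30, cnci = cd, plek = cd),
         pfam = NA, rfam = FALSE, lnc = FALSE),          # CPAT boundary: coding
    list(id = "MSTRG.5.1", len = 800L, ex = 2L, expr = 5, bt = "novel",
         sc = list(cpat = 0.7799, cpc2 = -0.5, feelnc = 0.50, cnci = cd, plek = cd),
         pfam = NA, rfam = FALSE, lnc = TRUE),
    list(id = "MSTRG.6.1", len = 700L, ex = 2L, expr = 5, bt = "novel",
         sc = list(cpat = 0.40, cpc2 = -1.0, feelnc = 0.558, cnci = cd, plek = cd),
         pfam = NA, rfam = FALSE, lnc = FALSE),          # FEELnc boundary
    list(id = "MSTRG.7.1", len = 700L, ex = 2L, expr = 5, bt = "novel",
         sc = list(cpat = 0.40, cpc2 = 0, feelnc = 0.90, cnci = nc, plek = cd),
         pfam = NA, rfam = FALSE, lnc = FALSE),          # CPC2 boundary
    list(id = "MSTRG.8.1", len = 199L, ex = 3L, expr = 5, bt = "novel",
         sc = good, pfam = NA, rfam = FALSE, lnc = FALSE),
    list(id = "MSTRG.9.1", len = 200L, ex = 2L, expr = 5, bt = "novel",
         sc = good, pfam = NA, rfam = FALSE, lnc = TRUE),
    list(id = "MSTRG.10.1", len = 1500L, ex = 1L, expr = 5, bt = "novel",
         sc = good, pfam = NA, rfam = FALSE, lnc = FALSE),
    list(id = "MSTRG.11.1", len = 1500L, ex = 3L, expr = 5, bt = "protein_coding",
         sc = good, pfam = NA, rfam = FALSE, lnc = FALSE),
    list(id = "MSTRG.12.1", len = 1500L, ex = 3L, expr = 0.5, bt = "novel",
         sc = good, pfam = NA, rfam = FALSE, lnc = FALSE),  # below floor
    list(id = "MSTRG.13.1", len = 1000L, ex = 2L, expr = 5, bt = "novel",
         sc = list(cpat = 0.40, cpc2 = -1.0, feelnc = NA, cnci = NA, plek = NA),
         pfam = NA, rfam = FALSE, lnc = FALSE),          # insufficient evidence
    list(id = "MSTRG.14.1", len = 1000L, ex = 2L, expr = 5, bt = "novel",
         sc = list(cpat = 0.40, cpc2 = -1.0, feelnc = NA, cnci = nc, plek = NA),
         pfam = NA, rfam = FALSE, lnc = TRUE),           # 3 of 3 available
    list(id = "MSTRG.15.1", len = 1000L, ex = 2L, expr = 5, bt = "novel",
         sc = list(cpat = 0.40, cpc2 = 1.0, feelnc = NA, cnci = nc, plek = NA),
         pfam = NA, rfam = FALSE, lnc = FALSE),          # 2 of 3 available
    list(id = "MSTRG.16.1", len = 1100L, ex = 3L, expr = 5, bt = "novel",
         sc = good, pfam = 1e-5, rfam = FALSE, lnc = FALSE),
    list(id = "MSTRG.17.1", len = 1100L, ex = 3L, expr = 5, bt = "novel",
         sc = good, pfam = 1e-3, rfam = FALSE, lnc = FALSE),  # e-value boundary
    list(id = "MSTRG.18.1", len = 1100L, ex = 3L, expr = 5, bt = "novel",
         sc = good, pfam = 0.01, rfam = FALSE, lnc = TRUE),
    list(id = "MSTRG.19.1", len = 1100L, ex = 3L, expr = 5, bt = "novel",
         sc = good, pfam = NA, rfam = TRUE, lnc = FALSE),
    list(id = "MSTRG.20.1", len = 950L, ex = 2L, expr = 6, bt = "lncRNA",
         sc = list(cpat = 0.95, cpc2 = 2.0, feelnc = 0.9, cnci = cd, plek = cd),
         pfam = NA, rfam = FALSE, lnc = TRUE)            # known biotype bypass
  )
  extra <- with_stream(config$seed, "lnc_extra", {
    lapply(1:20, function(i) {
      k_nc <- sample(0:5, 1)
      verdicts <- sample(c(rep(TRUE, k_nc), rep(FALSE, 5 - k_nc)))
      expr_i <- round(stats::rlnorm(1, 1.5, 0.7), 3)
      list(id = sprintf("MSTRG.%d.1", 100 + i),
           len = sample(300:3000, 1), ex = sample(2:6, 1),
           expr = expr_i, bt = "novel",
           sc = list(cpat = if (verdicts[1]) round(stats::runif(1, 0, 0.77), 3)
                            else round(stats::runif(1, 0.79, 1), 3),
                     cpc2 = if (verdicts[2]) round(stats::runif(1, -3, -0.01), 3)
                            else round(stats::runif(1, 0.01, 3), 3),
                     feelnc = if (verdicts[3]) round(stats::runif(1, 0, 0.55), 3)
                              else round(stats::runif(1, 0.56, 1), 3),
                     cnci = if (verdicts[4]) nc else cd,
                     plek = if (verdicts[5]) nc else cd),
           pfam = NA, rfam = FALSE, lnc = k_nc >= 3 && expr_i >= floor_expr)
    })
  })
  cases <- c(cases, extra)

  novel <- do.call(rbind, lapply(cases, function(x) {
    data.frame(transcript_id = x$id, gene_id = sub("\\.1$", "", x$id),
               biotype = x$bt, length_nt = x$len, exon_count = x$ex,
               mean_expression = x$expr, stringsAsFactors = FALSE)
  }))
  ref_tx <- reference$annotation$transcripts
  ref_records <- data.frame(transcript_id = ref_tx$transcript_id,
                            gene_id = ref_tx$gene_id, biotype = ref_tx$biotype,
                            length_nt = ref_tx$length,
                            exon_count = ref_tx$n_exons,
                            mean_expression = 5, stringsAsFactors = FALSE)
  transcripts <- rbind(novel, ref_records)

  scores <- do.call(rbind, lapply(cases, function(x) {
    data.frame(transcript_id = x$id, cpat = x$sc$cpat, cpc2 = x$sc$cpc2,
               feelnc = x$sc$feelnc,
               cnci_label = if (is.na(x$sc$cnci[1])) NA_character_ else x$sc$cnci,
               plek_label = if (is.na(x$sc$plek[1])) NA_character_ else x$sc$plek,
               stringsAsFactors = FALSE)
  }))
  evidence <- do.call(rbind, lapply(cases, function(x) {
    data.frame(transcript_id = x$id, best_pfam_evalue = as.numeric(x$pfam),
               has_rfam_hit = x$rfam, stringsAsFactors = FALSE)
  }))
  # intended outcome per planted case; known lncRNA-biotype reference
  # transcripts (structural pass) join the expected set
  expected_novel <- vapply(cases, function(x) {
    x$lnc && !(x$bt %in% .LNC_BIOTYPES)
  }, logical(1))
  known_ok <- transcripts$biotype %in% .LNC_BIOTYPES &
    transcripts$length_nt >= 200 & transcripts$exon_count >= 2 &
    transcripts$mean_expression >= floor_expr
  lnc_truth <- data.frame(
    transcript_id = transcripts$transcript_id,
    expected = c(vapply(cases, `[[`, logical(1), "lnc"),
                 logical(nrow(ref_records))) | known_ok,
    stringsAsFactors = FALSE)

  ## ---- expression and interaction evidence ---------------------------------
  lnc_pool <- vapply(cases, `[[`, character(1), "id")[expected_novel]
  del_ids <- lnc_pool[seq_len(8L)]
  genes <- ann$genes
  deg_slot <- function(c_idx, k) sprintf("G%d_%02d", c_idx, k)
  deg_ids <- c(vapply(10:14, function(k) deg_slot(1, k), character(1)),
               vapply(10:14, function(k) deg_slot(2, k), character(1)))
  noise_ids <- sprintf("NOISE%02d", 1:12)
  samples <- .sample_names(config)
  ns <- length(samples)

  planted <- data.frame(del = del_ids[1:6], deg = deg_ids[1:6],
                        sign = c(1, 1, 1, -1, -1, 1))
  expr <- matrix(NA_real_, nrow = 0, ncol = ns)
  rows <- list()
  with_stream(config$seed, "expression", {
    mk_pair <- function(sign) {
      x <- round(exp(stats::rnorm(ns, 2.5, 0.6)), 4)
      z <- as.numeric(scale(x))
      eps <- stats::rnorm(ns, 0, 2)
      repeat {
        y <- 100 + 12 * sign * z + eps
        if (abs(stats::cor(x, y)) >= 0.952) break
        eps <- eps * 0.6
      }
      list(x = x, y = round(y, 4))
    }
    for (i in seq_len(nrow(planted))) {
      p <- mk_pair(planted$sign[i])
      rows[[planted$del[i]]] <- p$x
      rows[[planted$deg[i]]] <- p$y
    }
    # correlation without binding evidence: must be excluded by the triage
    p7 <- mk_pair(1)
    rows[[del_ids[7]]] <- p7$x
    rows[[deg_ids[7]]] <- p7$y
    for (id in c(del_ids[8], deg_ids[8:10], noise_ids)) {
      rows[[id]] <- round(exp(stats::rnorm(ns, 2.2, 0.7)), 4)
    }
  })
  expr <- do.call(rbind, rows)
  colnames(expr) <- samples

  ndg <- rbind(
    data.frame(del_id = planted$del[c(1, 3, 5)], deg_id = planted$deg[c(1, 3, 5)],
               ndg = c(-0.50, -0.35, -0.20), stringsAsFactors = FALSE),
    data.frame(del_id = c(del_ids[7], del_ids[8]),
               deg_id = c(deg_ids[7], deg_ids[8]),
               ndg = c(-0.05, -0.02), stringsAsFactors = FALSE))
  prob <- rbind(
    data.frame(del_id = planted$del[c(2, 4, 6)], deg_id = planted$deg[c(2, 4, 6)],
               prob = c(0.95, 0.99, 0.93), stringsAsFactors = FALSE),
    data.frame(del_id = del_ids[7], deg_id = deg_ids[7], prob = 0.50,
               stringsAsFactors = FALSE))
  trans_truth <- data.frame(
    del_id = planted$del, deg_id = planted$deg,
    direction = ifelse(planted$sign > 0, "positive", "negative"),
    stringsAsFactors = FALSE)

  ## ---- cis layout: lncRNA loci at controlled gaps from DEG genes -----------
  gene_row <- function(id) genes[genes$gene_id == id, ]
  g1 <- gene_row(deg_ids[1]); g2 <- gene_row(deg_ids[2])
  g3 <- gene_row(deg_ids[3]); g4 <- gene_row(deg_ids[4])
  del_loci_df <- data.frame(
    id = del_ids,
    chrom = c(g1$chrom, g2$chrom, g3$chrom, g4$chrom, "chr1", "chr2", "chr2", "chr2"),
    start = c(g1$start + 100L,              # overlap: gap 0
              g2$end + 10000L,              # gap 9999
              g3$end + 10001L,              # gap exactly 10000
              g4$end + 10002L,              # gap 10001: not cis
              300000L, 310000L, 330000L, 350000L),
    stringsAsFactors = FALSE)
  del_loci_df$end <- del_loci_df$start + 499L
  # analytic cis truth by plain interval arithmetic over all DEL x DEG pairs
  cis_truth <- list()
  for (i in seq_len(nrow(del_loci_df))) {
    for (gid in deg_ids) {
      g <- gene_row(gid)
      if (g$chrom != del_loci_df$chrom[i]) next
      gap <- max(g$start - del_loci_df$end[i] - 1L,
                 del_loci_df$start[i] - g$end - 1L, 0L)
      if (gap <= 10000L) {
        cis_truth[[length(cis_truth) + 1L]] <- data.frame(
          del_id = del_loci_df$id[i], deg_id = gid, gap = gap,
          stringsAsFactors = FALSE)
      }
    }
  }
  cis_truth <- if (length(cis_truth)) do.call(rbind, cis_truth) else
    data.frame(del_id = character(), deg_id = character(), gap = integer())
  del_loci <- GenomicRanges::GRanges(del_loci_df$chrom,
                                     IRanges::IRanges(del_loci_df$start,
                                                      del_loci_df$end))
  del_loci$id <- del_loci_df$id
  deg_rows <- genes[match(deg_ids, genes$gene_id), ]
  deg_loci <- GenomicRanges::GRanges(deg_rows$chrom,
                                     IRanges::IRanges(deg_rows$start, deg_rows$end))
  deg_loci$id <- deg_rows$gene_id

  list(transcripts = transcripts, scores = scores, evidence = evidence,
       expr = expr, del_ids = del_ids, deg_ids = deg_ids, ndg = ndg,
       prob = prob, del_loci = del_loci, deg_loci = deg_loci,
       truth = list(lncrna = lnc_truth, trans = trans_truth, cis = cis_truth))
}

#' Run the complete synthetic-data generator
#'
#' Reference, variant cohort and expression/score tables in one call,
#' optionally written to disk in the standard formats.
#'
#' @param config a [sim_config()]
#' @param outdir optional directory; when given, FASTA/GTF/BED/VCF/TSV
#'   artifacts and the truth ledgers are written there
#' @return list with `reference`, `variants`, `expression`, `config`
#' @export
simulate_all <- function(config = sim_config(), outdir = NULL) {
  reference <- simulate_reference(config)
  variants <- simulate_variants(config, reference)
  expression <- simulate_expression_and_scores(config, reference)
  # synthetic stand-in for a known-editing-site database: a subset of the
  # planted sites plus unrelated records
  known_editing <- with_stream(config$seed, "known_sites", {
    planted <- variants$truth[variants$truth$editing_class == "planted", ]
    take <- planted[stats::runif(nrow(planted)) < 0.4, , drop = FALSE]
    extra <- data.frame(
      chrom = sample(.chrom_names(config), 20, replace = TRUE),
      pos = sample(config$chrom_length, 20),
      type = sample(c("A_to_I", "C_to_U"), 20, replace = TRUE),
      tissue = "other", stringsAsFactors = FALSE)
    rbind(data.frame(chrom = take$chrom, pos = take$pos,
                     type = take$editing_type_truth, tissue = "AP",
                     stringsAsFactors = FALSE), extra)
  })
  out <- list(reference = reference, variants = variants,
              expression = expression, known_editing = known_editing,
              config = config)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    fp <- function(x) file.path(outdir, x)
    write_fasta(reference$genome, fp("genome.fa"))
    write_gtf(reference$annotation, fp("annotation.gtf"))
    write_bed(reference$sine, fp("sine.bed"))
    write_bed(reference$paralog, fp("paralog.bed"))
    write_bed(reference$ssr_truth, fp("ssr_planted.bed"))
    write_variants_vcf(variants$sites, fp("variants.vcf"))
    write_variants_tsv(variants$sites, fp("variants.tsv"))
    d <- variants$design
    write_result_tsv(data.frame(sample = d$samples, group = d$groups),
                     fp("design.tsv"))
    write_result_tsv(variants$truth, fp("truth_sites.tsv"))
    write_result_tsv(expression$transcripts, fp("transcripts.tsv"))
    write_result_tsv(expression$scores, fp("scores.tsv"))
    write_result_tsv(expression$evidence, fp("domain_evidence.tsv"))
    write_result_tsv(expression$truth$lncrna, fp("lnc_truth.tsv"))
    em <- data.frame(feature_id = rownames(expression$expr), expression$expr,
                     check.names = FALSE)
    write_result_tsv(em, fp("expression.tsv"))
    writeLines(expression$del_ids, fp("del_ids.txt"))
    writeLines(expression$deg_ids, fp("deg_ids.txt"))
    write_result_tsv(expression$ndg, fp("ndg.tsv"))
    write_result_tsv(expression$prob, fp("prob.tsv"))
    dl <- expression$del_loci
    dl$name <- dl$id
    write_bed(dl, fp("del_loci.bed"))
    write_result_tsv(known_editing, fp("known_editing_synthetic.tsv"))
  }
  out
}
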