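#' Run the full variant post-processing pipeline from files
#'
#' Orchestrates the cascade end to end: reads genome, annotation, masks,
#' design and variants; computes the SSR mask natively from the genome;
#' applies the filter cascade; tests and classifies allele-specific
#' expression; annotates consequences of flagged sites; runs the
#' RNA-editing branch; and, when lncRNA/interaction inputs are supplied,
#' the lncRNA cascade and cis/trans triage. All result tables are written
#' to `out_dir` and a machine-readable run report (stage counts, summary
#' counts and the exact thresholds used) is returned and saved as JSON.
#' The run is deterministic: rerunning on identical inputs reproduces the
#' tables byte for byte, and inputs are never mutated.
#'
#' @param paths named list of input paths: required `variants`, `gtf`,
#'   `fasta`, `design` (TSV with sample/group); optional `paralog_bed`,
#'   `sine_bed`, `known_editing` (TSV chrom/pos/type/tissue),
#'   `transcripts`, `scores`, `evidence`, `expression`, `del_ids`,
#'   `deg_ids`, `ndg`, `prob`, `del_loci_bed`
#' @param out_dir output directory (created if needed)
#' @param thresholds a [filter_thresholds()] list
#' @param ase_delta_min,ase_fdr_max,balance_alpha ASE operating point
#' @param editing_fdr_max,editing_aaf_ceiling editing operating point
#' @param consequence_flank bp for upstream/downstream classification
#' @param lnc_min_expression expression floor of the lncRNA cascade
#' @return the run report, invisibly (also written as `run_report.json`)
#' @export
run_all <- function(paths, out_dir, thresholds = filter_thresholds(),
                    ase_delta_min = 0.1, ase_fdr_max = 0.001,
                    balance_alpha = 0.05, editing_fdr_max = 0.05,
                    editing_aaf_ceiling = 0.7, consequence_flank = 1000L,
                    lnc_min_expression = 0) {
  required <- c("variants", "gtf", "fasta", "design")
  for (k in required) {
    if (is.null(paths[[k]])) stop("missing required input path: ", k)
  }
  for (k in names(paths)) {
    if (!file.exists(paths[[k]])) stop("input file does not exist: ", k,
                                       " = ", paths[[k]])
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(x) file.path(out_dir, x)

  design_df <- read_result_tsv(paths$design)
  design <- group_design(design_df$sample, design_df$group)
  genome <- read_fasta(paths$fasta)
  annotation <- read_gtf(paths$gtf)
  paralog <- if (!is.null(paths$paralog_bed)) read_bed(paths$paralog_bed)
             else GenomicRanges::GRanges()
  sine <- if (!is.null(paths$sine_bed)) read_bed(paths$sine_bed)
          else GenomicRanges::GRanges()
  sites <- read_variants(paths$variants, design$samples)
  ssr <- ssr_mask(genome)

  casc <- run_cascade(sites, annotation, paralog, ssr, thresholds)
  write_result_tsv(casc$report, fp("filter_report.tsv"))
  write_variants_tsv(casc$sites, fp("sites_filtered.tsv"))

  ase <- ase_table(casc$sites, design)
  ase <- classify_ase(ase, ase_delta_min, ase_fdr_max, balance_alpha)
  ase$consequence <- NA_character_
  flagged <- which(ase$ase_flag)
  if (length(flagged)) {
    ase$consequence[flagged] <- annotate_consequence(
      .subset_sites(casc$sites, flagged), annotation, genome,
      flank = consequence_flank)
  }
  write_result_tsv(ase, fp("ase_results.tsv"))

  ed <- editing_filter(casc$sites, ase, annotation, sine,
                       aaf_ceiling = editing_aaf_ceiling,
                       delta_min = ase_delta_min, fdr_max = editing_fdr_max)
  candidates <- ed$candidates
  if (!is.null(paths$known_editing)) {
    known <- read_result_tsv(paths$known_editing)
    candidates <- intersect_known(candidates, known)
  }
  write_result_tsv(candidates, fp("editing_candidates.tsv"))
  write_result_tsv(ed$audit, fp("editing_audit.tsv"))

  report <- list(
    thresholds = unclass(thresholds),
    ase = list(delta_min = ase_delta_min, fdr_max = ase_fdr_max,
               balance_alpha = balance_alpha),
    editing = list(fdr_max = editing_fdr_max, aaf_ceiling = editing_aaf_ceiling),
    stages = casc$report,
    n_input_sites = nrow(sites),
    n_surviving_sites = nrow(casc$sites),
    n_ase_flagged = sum(ase$ase_flag),
    n_editing_candidates = nrow(candidates)
  )

  has_lnc <- !is.null(paths$transcripts)
  if (has_lnc) {
    transcripts <- read_result_tsv(paths$transcripts)
    scores <- read_result_tsv(paths$scores)
    evidence <- read_result_tsv(paths$evidence)
    evidence$has_rfam_hit <- as.logical(evidence$has_rfam_hit)
    lnc <- identify_lncrna(transcripts, scores, evidence,
                           min_expression = lnc_min_expression)
    write_result_tsv(lnc, fp("lncrna.tsv"))
    report$n_lncrna <- nrow(lnc)
  }
  has_int <- !is.null(paths$expression)
  if (has_int) {
    em <- read_result_tsv(paths$expression)
    expr <- as.matrix(em[, -1, drop = FALSE])
    rownames(expr) <- em$feature_id
    del_ids <- readLines(paths$del_ids)
    deg_ids <- readLines(paths$deg_ids)
    pairs <- correlate_pairs(expr, del_ids, deg_ids)
    ndg <- read_result_tsv(paths$ndg)
    prob <- read_result_tsv(paths$prob)
    key <- function(d) paste(d$del_id, d$deg_id)
    pairs$ndg <- ndg$ndg[match(key(pairs), key(ndg))]
    pairs$binding_prob <- prob$prob[match(key(pairs), key(prob))]
    trans <- trans_triage(pairs)
    del_loci <- read_bed(paths$del_loci_bed)
    del_loci$id <- del_loci$name
    genes <- annotation$genes
    deg_rows <- genes[match(deg_ids, genes$gene_id), ]
    deg_loci <- GenomicRanges::GRanges(deg_rows$chrom,
                                       IRanges::IRanges(deg_rows$start,
                                                        deg_rows$end))
    deg_loci$id <- deg_rows$gene_id
    cis <- cis_pairs(del_loci, deg_loci)
    interactions <- rbind(
      trans[, c("del_id", "deg_id", "mode", "direction")],
      cbind(cis[, c("del_id", "deg_id", "mode")], direction = NA_character_))
    write_result_tsv(trans, fp("trans_interactions.tsv"))
    write_result_tsv(cis, fp("cis_interactions.tsv"))
    write_result_tsv(interactions, fp("interactions.tsv"))
    report$n_trans_interactions <- nrow(trans)
    report$n_cis_pairs <- nrow(cis)
  }
  jsonlite::write_json(report, fp("run_report.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows", pretty = TRUE)
  invisible(report)
}
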