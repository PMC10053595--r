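#' Filter-cascade thresholds
#'
#' Defaults follow the published operating point of the variant
#' post-processing cascade: strict GATK-style quality cut-offs (RMS mapping
#' quality > 40, total depth > 10, quality-by-depth > 2, read-position rank
#' sum > -8, mapping-quality rank sum > -12.5), a 5 bp exon-intron junction
#' flank, a 50 bp paralog flank, close-proximity windows of 2 SNVs within
#' 45 bp or 3 within 35 bp, and an alternative-allele prevalence of at least
#' half the samples.
#'
#' @param mq_min,dp_min,qd_min,readpos_ranksum_min,mq_ranksum_min quality
#'   cut-offs (strict `>` comparisons)
#' @param junction_flank bp around each splice-junction boundary
#' @param paralog_flank bp added up- and downstream of paralog intervals
#' @param pair_window bp window for the 2-SNV proximity rule
#' @param triplet_window bp span for the 3-SNV proximity rule
#' @param prevalence_fraction minimum fraction of samples with alt support
#' @param strict_quality if TRUE, absent quality annotations fail the
#'   quality filter instead of passing it
#' @return a `filter_thresholds` list
#' @export
filter_thresholds <- function(mq_min = 40, dp_min = 10, qd_min = 2,
                              readpos_ranksum_min = -8, mq_ranksum_min = -12.5,
                              junction_flank = 5L, paralog_flank = 50L,
                              pair_window = 45L, triplet_window = 35L,
                              prevalence_fraction = 0.5,
                              strict_quality = FALSE) {
  stopifnot(junction_flank >= 0, paralog_flank >= 0, pair_window >= 0,
            triplet_window >= 0, prevalence_fraction > 0,
            prevalence_fraction <= 1)
  structure(list(mq_min = mq_min, dp_min = dp_min, qd_min = qd_min,
                 readpos_ranksum_min = readpos_ranksum_min,
                 mq_ranksum_min = mq_ranksum_min,
                 junction_flank = as.integer(junction_flank),
                 paralog_flank = as.integer(paralog_flank),
                 pair_window = as.integer(pair_window),
                 triplet_window = as.integer(triplet_window),
                 prevalence_fraction = prevalence_fraction,
                 strict_quality = strict_quality),
            class = "filter_thresholds")
}

.subset_sites <- function(sites, keep) {
  .new_variant_table(sites[keep, , drop = FALSE], variant_samples(sites))
}

#' Quality filter
#'
#' A site survives iff every *present* quality annotation satisfies its
#' strict inequality; absent annotations do not fail the site (GATK emits
#' the rank-sum statistics only where they are computable) unless
#' `strict_quality` is set.
#'
#' @param sites a variant table
#' @param thresholds a [filter_thresholds()] list
#' @return list with `sites` (survivors) and `removed`
#' @export
quality_filter <- function(sites, thresholds = filter_thresholds()) {
  chk <- function(x, min) {
    if (thresholds$strict_quality) !is.na(x) & x > min else is.na(x) | x > min
  }
  keep <- chk(sites$MQ, thresholds$mq_min) &
    chk(sites$DP, thresholds$dp_min) &
    chk(sites$QD, thresholds$qd_min) &
    chk(sites$ReadPosRankSum, thresholds$readpos_ranksum_min) &
    chk(sites$MQRankSum, thresholds$mq_ranksum_min)
  list(sites = .subset_sites(sites, keep), removed = .subset_sites(sites, !keep))
}

#' Splice-junction exclusion windows of an annotation
#'
#' Each exon-intron boundary (the coordinate between the last exonic and the
#' first intronic base, and vice versa) excludes variants within `flank` bp
#' on either side, exonic and intronic alike.
#'
#' @param ann a `genome_annotation`
#' @param flank bp
#' @return `GRanges` of exclusion windows
#' @export
junction_windows <- function(ann, flank = 5L) {
  j <- ann$junctions
  if (!nrow(j)) return(GenomicRanges::GRanges())
  # boundary b sits between base b and b+1; bases within `flank` of the
  # boundary coordinate span [b - flank + 1, b + flank + 1]
  GenomicRanges::reduce(GenomicRanges::GRanges(
    j$chrom, IRanges::IRanges(pmax(1L, j$boundary - flank + 1L),
                              j$boundary + flank + 1L)))
}

#' Regions covered by gene bodies on both strands
#' @param ann a `genome_annotation`
#' @return `GRanges` of bidirectional-overlap regions
#' @export
bidirectional_regions <- function(ann) {
  g <- gene_ranges(ann)
  plus <- GenomicRanges::reduce(g[GenomicRanges::strand(g) == "+"], ignore.strand = TRUE)
  minus <- GenomicRanges::reduce(g[GenomicRanges::strand(g) == "-"], ignore.strand = TRUE)
  GenomicRanges::intersect(plus, minus, ignore.strand = TRUE)
}

#' Genomic-context filter
#'
#' Removes sites near splice junctions, within flanked paralog regions,
#' inside SSR intervals, or inside bidirectional-gene regions (bases covered
#' by gene bodies on both strands). A site may be removed for several
#' reasons; all are recorded.
#'
#' @param sites a variant table
#' @param annotation a `genome_annotation`
#' @param paralog_bed `GRanges` of paralog regions (may be empty)
#' @param ssr `GRanges` SSR mask (may be empty)
#' @param thresholds a [filter_thresholds()] list
#' @return list with `sites`, `removed`, and `reasons` (logical data.frame
#'   over all input sites with columns junction/paralog/ssr/bidirectional)
#' @export
context_filter <- function(sites, annotation, paralog_bed = GenomicRanges::GRanges(),
                           ssr = GenomicRanges::GRanges(),
                           thresholds = filter_thresholds()) {
  pos <- variant_granges(sites)
  jw <- junction_windows(annotation, thresholds$junction_flank)
  par <- if (length(paralog_bed)) {
    GenomicRanges::GRanges(
      as.character(GenomicRanges::seqnames(paralog_bed)),
      IRanges::IRanges(pmax(1L, GenomicRanges::start(paralog_bed) - thresholds$paralog_flank),
                       GenomicRanges::end(paralog_bed) + thresholds$paralog_flank))
  } else {
    GenomicRanges::GRanges()
  }
  bid <- bidirectional_regions(annotation)
  hit <- function(mask) {
    if (!length(mask)) rep(FALSE, nrow(sites))
    else IRanges::overlapsAny(pos, mask, ignore.strand = TRUE)
  }
  reasons <- data.frame(junction = hit(jw), paralog = hit(par), ssr = hit(ssr),
                        bidirectional = hit(bid))
  remove <- Reduce(`|`, reasons)
  list(sites = .subset_sites(sites, !remove),
       removed = .subset_sites(sites, remove),
       reasons = reasons)
}

#' Close-proximity filter
#'
#' Removes every site participating in a pair at distance `<= pair_window`
#' bp or in a triplet spanning `<= triplet_window` bp (distances are
#' `|pos_i - pos_j|` on the same chromosome). Both rules are applied
#' independently so non-default windows behave as documented.
#'
#' @param sites a variant table (sorted by chrom, pos)
#' @param thresholds a [filter_thresholds()] list
#' @return list with `sites` and `removed`
#' @export
proximity_filter <- function(sites, thresholds = filter_thresholds()) {
  n <- nrow(sites)
  remove <- logical(n)
  if (n) {
    ord <- order(sites$chrom, sites$pos)
    for (idx in split(ord, sites$chrom[ord])) {
      p <- sites$pos[idx]
      m <- length(idx)
      if (m >= 2) {
        close_pair <- (p[-1] - p[-m]) <= thresholds$pair_window
        rm_here <- c(FALSE, close_pair) | c(close_pair, FALSE)
        remove[idx] <- remove[idx] | rm_here
      }
      if (m >= 3) {
        span3 <- (p[-(1:2)] - p[seq_len(m - 2)]) <= thresholds$triplet_window
        for (k in which(span3)) remove[idx[k:(k + 2)]] <- TRUE
      }
    }
  }
  list(sites = .subset_sites(sites, !remove), removed = .subset_sites(sites, remove))
}

#' Alt-allele prevalence filter
#'
#' A site survives iff the number of samples with alternative-allele support
#' (`alt_count > 0` and non-zero depth) is at least
#' `ceiling(fraction * n_samples)` — "AAF > 0 within at least half of the
#' samples" at the default fraction.
#'
#' @param sites a variant table
#' @param fraction minimum fraction of samples
#' @return list with `sites` and `removed`
#' @export
prevalence_filter <- function(sites, fraction = 0.5) {
  altm <- alt_count_matrix(sites)
  refm <- ref_count_matrix(sites)
  n_samples <- ncol(altm)
  supported <- rowSums(altm > 0 & (altm + refm) > 0)
  keep <- supported >= ceiling(fraction * n_samples)
  if (!nrow(sites)) keep <- logical(0)
  list(sites = .subset_sites(sites, keep), removed = .subset_sites(sites, !keep))
}

#' Run the full SNV filter cascade
#'
#' Applies, in fixed order: quality, genomic context, close proximity,
#' prevalence. Returns survivors plus a chained per-stage report.
#'
#' @param sites a variant table
#' @param annotation a `genome_annotation`
#' @param paralog_bed `GRanges` of paralog regions
#' @param ssr `GRanges` SSR mask
#' @param thresholds a [filter_thresholds()] list
#' @return list with `sites` (survivors), `report` (data.frame stage/n_in/
#'   n_removed/n_out), and `context_reasons`
#' @export
run_cascade <- function(sites, annotation, paralog_bed = GenomicRanges::GRanges(),
                        ssr = GenomicRanges::GRanges(),
                        thresholds = filter_thresholds()) {
  report <- data.frame(stage = character(), n_in = integer(),
                       n_removed = integer(), n_out = integer(),
                       stringsAsFactors = FALSE)
  log_stage <- function(name, n_in, n_out) {
    report <<- rbind(report, data.frame(stage = name, n_in = n_in,
                                        n_removed = n_in - n_out, n_out = n_out))
  }
  n0 <- nrow(sites)
  q <- quality_filter(sites, thresholds)
  log_stage("quality", n0, nrow(q$sites))
  ctx <- context_filter(q$sites, annotation, paralog_bed, ssr, thresholds)
  log_stage("context", nrow(q$sites), nrow(ctx$sites))
  prox <- proximity_filter(ctx$sites, thresholds)
  log_stage("proximity", nrow(ctx$sites), nrow(prox$sites))
  prev <- prevalence_filter(prox$sites, thresholds$prevalence_fraction)
  log_stage("prevalence", nrow(prox$sites), nrow(prev$sites))
  list(sites = prev$sites, report = report, context_reasons = ctx$reasons)
}
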