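#' Pearson correlation with its two-sided p-value
#'
#' Sample Pearson r with the t transform `r * sqrt((n-2) / (1-r^2))` on
#' `n - 2` df. Constant vectors give an absent result with a warning.
#'
#' @param x,y numeric vectors of equal length, n >= 3
#' @return list with `r` and `p` (both NA for constant input)
#' @export
pearson_with_p <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant expression vector; correlation undefined, pair skipped")
    return(list(r = NA_real_, p = NA_real_))
  }
  n <- length(x)
  r <- stats::cor(x, y)
  p <- .cor_pvalue(r, n)
  list(r = r, p = p)
}

.cor_pvalue <- function(r, n) {
  r2 <- pmin(r^2, 1)
  t <- abs(r) * sqrt((n - 2) / pmax(1 - r2, .Machine$double.eps))
  p <- 2 * stats::pt(t, df = n - 2, lower.tail = FALSE)
  p[r2 >= 1] <- 0
  pmin(p, 1)
}

#' All DEL x DEG expression correlations
#'
#' Row-wise Pearson correlation of every (lncRNA, gene) pair across the
#' pooled samples of both groups.
#'
#' @param expr numeric matrix, features x samples
#' @param del_ids,deg_ids feature ids (rows of `expr`)
#' @return data.frame `del_id`, `deg_id`, `r`, `p_corr`; constant features
#'   are skipped with a warning
#' @export
correlate_pairs <- function(expr, del_ids, deg_ids) {
  miss <- setdiff(c(del_ids, deg_ids), rownames(expr))
  if (length(miss)) stop("features absent from expression matrix: ",
                         paste(miss, collapse = ", "))
  n <- ncol(expr)
  sds <- apply(expr, 1, stats::sd)
  drop_del <- del_ids[sds[del_ids] == 0]
  drop_deg <- deg_ids[sds[deg_ids] == 0]
  if (length(drop_del) || length(drop_deg)) {
    warning("constant expression vector(s) skipped: ",
            paste(c(drop_del, drop_deg), collapse = ", "))
    del_ids <- setdiff(del_ids, drop_del)
    deg_ids <- setdiff(deg_ids, drop_deg)
  }
  if (!length(del_ids) || !length(deg_ids)) {
    return(data.frame(del_id = character(), deg_id = character(),
                      r = numeric(), p_corr = numeric()))
  }
  rmat <- stats::cor(t(expr[del_ids, , drop = FALSE]),
                     t(expr[deg_ids, , drop = FALSE]))
  out <- expand.grid(del_id = del_ids, deg_id = deg_ids,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$r <- rmat[cbind(match(out$del_id, del_ids), match(out$deg_id, deg_ids))]
  out$p_corr <- .cor_pvalue(out$r, n)
  out
}

#' Trans-interaction triage
#'
#' Retains a DEL-DEG pair iff `|r| > r_min` and `p < p_max` and at least one
#' line of binding evidence holds: `ndg < ndg_max` (more negative = stronger
#' predicted duplex) or `binding_prob > prob_min`. The correlation sign is
#' recorded as the interaction direction.
#'
#' @param pairs data.frame with `del_id`, `deg_id`, `r`, `p_corr`, `ndg`
#'   (NA when absent), `binding_prob` (NA when absent)
#' @param r_min,p_max correlation thresholds
#' @param ndg_max,prob_min binding-evidence thresholds
#' @return retained pairs with an added `direction`
#'   (`"positive"`/`"negative"`) and `mode = "trans"`
#' @export
trans_triage <- function(pairs, r_min = 0.9, p_max = 0.05, ndg_max = -0.1,
                         prob_min = 0.9) {
  binding <- (!is.na(pairs$ndg) & pairs$ndg < ndg_max) |
    (!is.na(pairs$binding_prob) & pairs$binding_prob > prob_min)
  keep <- !is.na(pairs$r) & abs(pairs$r) > r_min &
    !is.na(pairs$p_corr) & pairs$p_corr < p_max & binding
  out <- pairs[keep, , drop = FALSE]
  out$direction <- ifelse(out$r >= 0, "positive", "negative")
  out$mode <- rep("trans", nrow(out))
  rownames(out) <- NULL
  out
}

#' Cis DEL-DEG pairs by genomic proximity
#'
#' Reports a pair when the two loci lie on the same chromosome with an
#' edge-to-edge gap of at most `window` bp (overlap counts as gap 0).
#'
#' @param del_loci `GRanges` with an `id` metadata column
#' @param gene_loci `GRanges` with an `id` metadata column
#' @param window maximum gap in bp
#' @return data.frame `del_id`, `deg_id`, `gap`, `mode = "cis"`
#' @export
cis_pairs <- function(del_loci, gene_loci, window = 10000L) {
  if (!length(del_loci) || !length(gene_loci)) {
    return(data.frame(del_id = character(), deg_id = character(),
                      gap = integer(), mode = character()))
  }
  common <- union(GenomeInfoDb::seqlevels(del_loci),
                  GenomeInfoDb::seqlevels(gene_loci))
  GenomeInfoDb::seqlevels(del_loci) <- common
  GenomeInfoDb::seqlevels(gene_loci) <- common
  hits <- GenomicRanges::findOverlaps(del_loci, gene_loci, maxgap = window,
                                      ignore.strand = TRUE)
  gap <- GenomicRanges::distance(del_loci[S4Vectors::queryHits(hits)],
                                 gene_loci[S4Vectors::subjectHits(hits)],
                                 ignore.strand = TRUE)
  out <- data.frame(del_id = del_loci$id[S4Vectors::queryHits(hits)],
                    deg_id = gene_loci$id[S4Vectors::subjectHits(hits)],
                    gap = as.integer(gap), stringsAsFactors = FALSE)
  out <- out[!is.na(out$gap) & out$gap <= window, , drop = FALSE]
  out$mode <- rep("cis", nrow(out))
  rownames(out) <- NULL
  out
}
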