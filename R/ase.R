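#' Two-group sample design
#'
#' @param sample_ids character vector of all samples
#' @param groups character vector of group labels, parallel to `sample_ids`;
#'   exactly two distinct labels, both non-empty
#' @return a `group_design` list with `samples`, `groups`, `group1`,
#'   `group2` (sample id vectors; group order follows first appearance)
#' @export
group_design <- function(sample_ids, groups) {
  stopifnot(length(sample_ids) == length(groups), !anyNA(groups))
  lev <- unique(groups)
  if (length(lev) != 2) stop("design must have exactly two groups, got: ",
                             paste(lev, collapse = ", "))
  structure(list(samples = sample_ids, groups = groups,
                 group_labels = lev,
                 group1 = sample_ids[groups == lev[1]],
                 group2 = sample_ids[groups == lev[2]]),
            class = "group_design")
}

.group_totals <- function(sites, design) {
  refm <- ref_count_matrix(sites)
  altm <- alt_count_matrix(sites)
  s <- variant_samples(sites)
  i1 <- match(design$group1, s)
  i2 <- match(design$group2, s)
  if (anyNA(c(i1, i2))) stop("design samples not present in variant table")
  list(alt1 = rowSums(altm[, i1, drop = FALSE]),
       n1 = rowSums(altm[, i1, drop = FALSE] + refm[, i1, drop = FALSE]),
       alt2 = rowSums(altm[, i2, drop = FALSE]),
       n2 = rowSums(altm[, i2, drop = FALSE] + refm[, i2, drop = FALSE]))
}

#' Per-sample and group alternative-allele fractions
#'
#' Per-sample AAF is `alt / (ref + alt)` (NA at zero depth); group AAF pools
#' counts (`sum(alt) / sum(ref + alt)`), weighting samples by coverage;
#' `delta_aaf` is group1 minus group2. Sites with zero total depth in a
#' whole group are flagged untestable.
#'
#' @param sites a variant table
#' @param design a [group_design()]
#' @return list with `aaf_per_sample` (matrix), `group_aaf` (2-column
#'   matrix), `delta_aaf`, `testable`
#' @export
compute_aaf <- function(sites, design) {
  refm <- ref_count_matrix(sites)
  altm <- alt_count_matrix(sites)
  tot <- refm + altm
  aaf <- altm / ifelse(tot == 0, NA_real_, tot)
  colnames(aaf) <- variant_samples(sites)
  g <- .group_totals(sites, design)
  g1 <- g$alt1 / ifelse(g$n1 == 0, NA_real_, g$n1)
  g2 <- g$alt2 / ifelse(g$n2 == 0, NA_real_, g$n2)
  list(aaf_per_sample = aaf,
       group_aaf = cbind(aaf_g1 = g1, aaf_g2 = g2),
       delta_aaf = g1 - g2,
       testable = g$n1 > 0 & g$n2 > 0)
}

.binll <- function(alt, n, p) {
  # binomial log-likelihood kernel; 0*log(0) := 0
  term <- function(k, q) ifelse(k == 0, 0, k * log(q))
  term(alt, p) + term(n - alt, 1 - p)
}

#' Likelihood-ratio test for a group difference in allele fraction
#'
#' Binomial likelihood per sample with group-level AAF parameters: under H0
#' one shared AAF, under H1 one AAF per group (maximised by the pooled group
#' fractions). The statistic `2 * (l1 - l0)` is referred to chi-square with
#' 1 df. Sites with zero depth in a whole group get `NA`.
#'
#' @param sites a variant table
#' @param design a [group_design()]
#' @return numeric vector of p-values
#' @export
test_delta_aaf <- function(sites, design) {
  g <- .group_totals(sites, design)
  p1 <- g$alt1 / g$n1
  p2 <- g$alt2 / g$n2
  p0 <- (g$alt1 + g$alt2) / (g$n1 + g$n2)
  ll1 <- .binll(g$alt1, g$n1, p1) + .binll(g$alt2, g$n2, p2)
  ll0 <- .binll(g$alt1, g$n1, p0) + .binll(g$alt2, g$n2, p0)
  stat <- pmax(0, 2 * (ll1 - ll0))
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  p[!(g$n1 > 0 & g$n2 > 0)] <- NA_real_
  p
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment (via [stats::p.adjust()]) with input order
#' preserved; `NA` p-values stay `NA` and do not enter the family.
#'
#' @param p_values numeric vector in `[0, 1]`
#' @return q-values, same order as the input
#' @export
bh_adjust <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  q <- rep(NA_real_, length(p_values))
  q[ok] <- stats::p.adjust(p_values[ok], method = "BH")
  q
}

#' Allelic-balance classification
#'
#' Chi-square goodness-of-fit of the pooled (ref, alt) totals against 1:1
#' (1 df, no continuity correction): `chi2 = (ref - alt)^2 / (ref + alt)`.
#' Sites not rejecting at `alpha` are `true_heterozygote`; rejected sites
#' are `HeteroRef` (ref excess) or `HeteroAlt` (alt excess).
#'
#' @param sites a variant table
#' @param alpha rejection level for the 1:1 test
#' @return data.frame with `ref_total`, `alt_total`, `balance_p`, `category`
#' @export
balance_category <- function(sites, alpha = 0.05) {
  ref_total <- rowSums(ref_count_matrix(sites))
  alt_total <- rowSums(alt_count_matrix(sites))
  tot <- ref_total + alt_total
  if (any(tot == 0)) stop("balance test requires pooled coverage > 0 at every site")
  stat <- (ref_total - alt_total)^2 / tot
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  category <- ifelse(p >= alpha, "true_heterozygote",
                     ifelse(ref_total > alt_total, "HeteroRef", "HeteroAlt"))
  # equal totals give chi2 = 0, p = 1; guard regardless
  category[p < alpha & ref_total == alt_total] <- "true_heterozygote"
  data.frame(ref_total = ref_total, alt_total = alt_total, balance_p = p,
             category = category, stringsAsFactors = FALSE)
}

#' Full per-site ASE result table
#'
#' Computes group AAFs, the likelihood-ratio p-value, BH q-value over all
#' testable sites, and the allelic-balance category for every site.
#'
#' @param sites a variant table (normally the cascade survivors)
#' @param design a [group_design()]
#' @return data.frame: `chrom`, `pos`, `ref`, `alt`, `id`, `aaf_g1`,
#'   `aaf_g2`, `delta_aaf`, `p_value`, `q_value`, `balance_p`, `category`
#' @export
ase_table <- function(sites, design) {
  aaf <- compute_aaf(sites, design)
  p <- test_delta_aaf(sites, design)
  q <- bh_adjust(p)
  bal <- balance_category(sites)
  data.frame(chrom = sites$chrom, pos = sites$pos, ref = sites$ref,
             alt = sites$alt, id = sites$id,
             aaf_g1 = aaf$group_aaf[, "aaf_g1"],
             aaf_g2 = aaf$group_aaf[, "aaf_g2"],
             delta_aaf = aaf$delta_aaf, p_value = p, q_value = q,
             balance_p = bal$balance_p, category = bal$category,
             stringsAsFactors = FALSE)
}

#' Flag allele-specific expression events
#'
#' A site is flagged ASE iff `|delta_aaf| > delta_min`, `q < fdr_max`, and
#' the chi-square allelic-balance confirmation rejects 1:1 at
#' `balance_alpha` (the published operating point: |dAAF| > 0.1,
#' FDR < 0.001, balance p < 0.05).
#'
#' @param results an [ase_table()] data.frame
#' @param delta_min minimum |delta AAF|
#' @param fdr_max maximum BH q-value
#' @param balance_alpha level of the 1:1 confirmation test
#' @return `results` with an added logical `ase_flag` column
#' @export
classify_ase <- function(results, delta_min = 0.1, fdr_max = 0.001,
                         balance_alpha = 0.05) {
  flag <- !is.na(results$delta_aaf) & abs(results$delta_aaf) > delta_min &
    !is.na(results$q_value) & results$q_value < fdr_max &
    results$balance_p < balance_alpha
  results$ase_flag <- flag
  results
}
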