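.canonical_reading <- function(ref, alt) {
  # editing type implied by a substitution read on its own strand
  if (ref == "A" && alt == "G") "A_to_I"
  else if (ref == "C" && alt == "T") "C_to_U"
  else NA_character_
}

#' Resolve canonical editing substitutions against gene strand
#'
#' A substitution is canonical when it reads A>G (A-to-I) or C>T (C-to-U)
#' on the strand of the overlapping gene. Sites overlapping genes on both
#' strands with conflicting canonical readings are flagged ambiguous and
#' excluded. For intergenic sites both strand readings are evaluated; if
#' exactly one is canonical it is used, with the implied strand recorded.
#'
#' @param sites a variant table
#' @param annotation a `genome_annotation`
#' @return data.frame with `editing_type` (`A_to_I` / `C_to_U` / NA),
#'   `resolved_strand` (`+` / `-` / NA) and logical `ambiguous`
#' @export
resolve_canonical <- function(sites, annotation) {
  pos <- variant_granges(sites)
  genes <- gene_ranges(annotation)
  hits <- GenomicRanges::findOverlaps(pos, genes, ignore.strand = TRUE)
  strands_by_site <- split(as.character(GenomicRanges::strand(genes))[S4Vectors::subjectHits(hits)],
                           S4Vectors::queryHits(hits))
  n <- nrow(sites)
  type <- rep(NA_character_, n)
  strand <- rep(NA_character_, n)
  ambiguous <- logical(n)
  comp <- .COMPLEMENT
  for (i in seq_len(n)) {
    ref <- sites$ref[i]
    alt <- sites$alt[i]
    plus_type <- .canonical_reading(ref, alt)
    minus_type <- .canonical_reading(comp[[ref]], comp[[alt]])
    ss <- unique(strands_by_site[[as.character(i)]])
    if (is.null(ss)) {
      # intergenic: at most one strand reading can be canonical for an SNV
      if (!is.na(plus_type) && is.na(minus_type)) {
        type[i] <- plus_type; strand[i] <- "+"
      } else if (!is.na(minus_type) && is.na(plus_type)) {
        type[i] <- minus_type; strand[i] <- "-"
      }
    } else if (all(c("+", "-") %in% ss)) {
      if (!is.na(plus_type) && !is.na(minus_type) && plus_type != minus_type) {
        ambiguous[i] <- TRUE
      } else if (!is.na(plus_type)) {
        type[i] <- plus_type; strand[i] <- "+"
      } else if (!is.na(minus_type)) {
        type[i] <- minus_type; strand[i] <- "-"
      }
    } else {
      gstrand <- ss[1]
      t <- if (gstrand == "-") minus_type else plus_type
      if (!is.na(t)) {
        type[i] <- t; strand[i] <- gstrand
      }
    }
  }
  data.frame(editing_type = type, resolved_strand = strand,
             ambiguous = ambiguous, stringsAsFactors = FALSE)
}

#' Build and filter RNA-editing candidates
#'
#' From ASE-tested sites, keeps candidates that are strand-resolved
#' canonical substitutions and satisfy all four editing rules:
#' (a) no sample has AAF above the editing-efficiency ceiling (strictly
#' `> aaf_ceiling` fails; exactly at the ceiling passes), (b) no known-SNP
#' identifier, (c) the position overlaps a SINE interval, and (d)
#' `q < fdr_max` and `|delta_aaf| > delta_min`. The returned audit table
#' records every rule verdict for every canonical candidate.
#'
#' @param sites a variant table (cascade survivors)
#' @param ase an [ase_table()] data.frame aligned row-wise with `sites`
#' @param annotation a `genome_annotation`
#' @param sine_bed `GRanges` of SINE repeat intervals
#' @param aaf_ceiling maximum tolerated per-sample AAF
#' @param delta_min minimum |delta AAF|
#' @param fdr_max maximum BH q-value
#' @param sine_flank bp of slack around SINE intervals (0 = literal overlap)
#' @return list with `candidates` (surviving editing candidates, with
#'   `editing_type`, `resolved_strand`, `delta_aaf`, `q_value`) and `audit`
#'   (all canonical candidates with per-rule logical columns `pass_ceiling`,
#'   `pass_no_id`, `pass_sine`, `pass_significance`, `retained`)
#' @export
editing_filter <- function(sites, ase, annotation, sine_bed,
                           aaf_ceiling = 0.7, delta_min = 0.1, fdr_max = 0.05,
                           sine_flank = 0L) {
  stopifnot(nrow(sites) == nrow(ase))
  res <- resolve_canonical(sites, annotation)
  canonical <- !is.na(res$editing_type) & !res$ambiguous
  refm <- ref_count_matrix(sites)
  altm <- alt_count_matrix(sites)
  tot <- refm + altm
  aaf <- altm / ifelse(tot == 0, NA_real_, tot)
  max_aaf <- apply(aaf, 1, function(x) if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE))
  sine <- if (length(sine_bed) && sine_flank > 0) {
    GenomicRanges::GRanges(
      as.character(GenomicRanges::seqnames(sine_bed)),
      IRanges::IRanges(pmax(1L, GenomicRanges::start(sine_bed) - sine_flank),
                       GenomicRanges::end(sine_bed) + sine_flank))
  } else {
    sine_bed
  }
  in_sine <- if (length(sine)) {
    IRanges::overlapsAny(variant_granges(sites), sine, ignore.strand = TRUE)
  } else {
    rep(FALSE, nrow(sites))
  }
  pass_ceiling <- !is.na(max_aaf) & max_aaf <= aaf_ceiling
  pass_no_id <- is.na(sites$id)
  pass_sig <- !is.na(ase$q_value) & ase$q_value < fdr_max &
    !is.na(ase$delta_aaf) & abs(ase$delta_aaf) > delta_min
  audit <- data.frame(chrom = sites$chrom, pos = sites$pos, ref = sites$ref,
                      alt = sites$alt, editing_type = res$editing_type,
                      resolved_strand = res$resolved_strand,
                      delta_aaf = ase$delta_aaf, q_value = ase$q_value,
                      max_sample_aaf = max_aaf,
                      pass_ceiling = pass_ceiling, pass_no_id = pass_no_id,
                      pass_sine = in_sine, pass_significance = pass_sig,
                      stringsAsFactors = FALSE)[canonical, , drop = FALSE]
  audit$retained <- audit$pass_ceiling & audit$pass_no_id & audit$pass_sine &
    audit$pass_significance
  rownames(audit) <- NULL
  list(candidates = audit[audit$retained, , drop = FALSE], audit = audit)
}

#' Intersect editing candidates with a known-editing-site table
#'
#' Matches on (chrom, pos, editing_type); non-matching candidates keep an
#' absent match.
#'
#' @param candidates data.frame with `chrom`, `pos`, `editing_type`
#' @param known data.frame with `chrom`, `pos`, `type` (and optionally
#'   `tissue`)
#' @return `candidates` with an added `known_site_match` column (the known
#'   row's tissue tag, or `"known"` when no tag; NA when unmatched)
#' @export
intersect_known <- function(candidates, known) {
  key <- paste(candidates$chrom, candidates$pos, candidates$editing_type)
  kkey <- paste(known$chrom, known$pos, known$type)
  idx <- match(key, kkey)
  tag <- if (!is.null(known$tissue)) known$tissue else rep("known", nrow(known))
  candidates$known_site_match <- ifelse(is.na(idx), NA_character_, tag[idx])
  candidates
}
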