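.LNC_BIOTYPES <- c("lncRNA", "lincRNA", "antisense", "sense_intronic",
                   "sense_overlapping")

#' Structural pre-filter of the lncRNA identification cascade
#'
#' Retains transcripts that are at least `min_length` nt, have at least
#' `min_exons` exons, are not annotated protein-coding, and reach the
#' expression floor. Transcripts already carrying a known lncRNA biotype
#' are flagged (`is_known_lncrna`) and bypass the downstream coding-potential
#' vote and domain exclusion.
#'
#' @param transcripts data.frame with `transcript_id`, `gene_id`, `biotype`,
#'   `length_nt`, `exon_count`, `mean_expression`
#' @param min_length minimum transcript length (nt); strict `length >= 200`
#'   boundary (199 fails, 200 passes)
#' @param min_exons minimum exon count
#' @param min_expression expression floor (abundance units of the input)
#' @return `transcripts` restricted to survivors, with `is_known_lncrna`
#' @export
structural_filter <- function(transcripts, min_length = 200L, min_exons = 2L,
                              min_expression = 0) {
  keep <- transcripts$length_nt >= min_length &
    transcripts$exon_count >= min_exons &
    transcripts$biotype != "protein_coding" &
    transcripts$mean_expression >= min_expression
  out <- transcripts[keep, , drop = FALSE]
  out$is_known_lncrna <- out$biotype %in% .LNC_BIOTYPES
  rownames(out) <- NULL
  out
}

#' Consensus coding-potential vote
#'
#' Per-tool noncoding verdicts: CPAT score < 0.78, CPC2 score < 0, FEELnc
#' score < 0.558 (all strict), CNCI label "noncoding", PLEK label
#' "noncoding". A transcript is called noncoding iff at least 3 of the
#' available verdicts are noncoding; with fewer than 3 verdicts available
#' it is excluded for insufficient evidence.
#'
#' @param scores data.frame with `transcript_id` and columns `cpat`, `cpc2`,
#'   `feelnc` (numeric, NA when missing), `cnci_label`, `plek_label`
#'   (`"coding"`/`"noncoding"`/NA)
#' @param cpat_max,cpc2_max,feelnc_max score cut-offs (strict `<`)
#' @return data.frame with `transcript_id`, `votes_noncoding`,
#'   `votes_available`, `noncoding` (logical; NA = insufficient evidence)
#' @export
coding_potential_vote <- function(scores, cpat_max = 0.78, cpc2_max = 0,
                                  feelnc_max = 0.558) {
  lab_ok <- function(x) {
    bad <- !is.na(x) & !x %in% c("coding", "noncoding")
    if (any(bad)) stop("tool label must be 'coding' or 'noncoding', got: ",
                       x[bad][1])
    x
  }
  verdicts <- cbind(cpat = scores$cpat < cpat_max,
                    cpc2 = scores$cpc2 < cpc2_max,
                    feelnc = scores$feelnc < feelnc_max,
                    cnci = lab_ok(scores$cnci_label) == "noncoding",
                    plek = lab_ok(scores$plek_label) == "noncoding")
  available <- rowSums(!is.na(verdicts))
  noncoding_votes <- rowSums(verdicts, na.rm = TRUE)
  data.frame(transcript_id = scores$transcript_id,
             votes_noncoding = noncoding_votes,
             votes_available = available,
             noncoding = ifelse(available >= 3, noncoding_votes >= 3, NA),
             stringsAsFactors = FALSE)
}

#' Protein-domain and structured-RNA exclusion
#'
#' Retains candidates with no meaningful Pfam similarity (best e-value
#' absent or strictly greater than `pfam_evalue_max`) and no Rfam hit.
#' Candidates absent from the evidence table are treated as having no hit.
#'
#' @param candidates data.frame with `transcript_id`
#' @param evidence data.frame with `transcript_id`, `best_pfam_evalue`
#'   (NA = no hit), `has_rfam_hit` (logical)
#' @param pfam_evalue_max Pfam e-value threshold
#' @return `candidates` restricted to survivors
#' @export
domain_exclusion <- function(candidates, evidence, pfam_evalue_max = 1e-3) {
  idx <- match(candidates$transcript_id, evidence$transcript_id)
  ev <- evidence$best_pfam_evalue[idx]
  rf <- evidence$has_rfam_hit[idx]
  rf[is.na(rf)] <- FALSE
  keep <- (is.na(ev) | ev > pfam_evalue_max) & !rf
  out <- candidates[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the full lncRNA identification cascade
#'
#' Structural filter, then the 3-of-5 consensus coding-potential vote, then
#' Pfam/Rfam exclusion; transcripts with a known lncRNA biotype that pass
#' the structural filter join the final pool directly.
#'
#' @inheritParams structural_filter
#' @inheritParams coding_potential_vote
#' @inheritParams domain_exclusion
#' @param scores coding-potential score table (see
#'   [coding_potential_vote()])
#' @param evidence domain-evidence table (see [domain_exclusion()])
#' @return data.frame of identified lncRNAs with `is_known_lncrna`,
#'   `votes_noncoding`, `votes_available`
#' @export
identify_lncrna <- function(transcripts, scores, evidence,
                            min_length = 200L, min_exons = 2L,
                            min_expression = 0, cpat_max = 0.78,
                            cpc2_max = 0, feelnc_max = 0.558,
                            pfam_evalue_max = 1e-3) {
  surv <- structural_filter(transcripts, min_length, min_exons, min_expression)
  known <- surv[surv$is_known_lncrna, , drop = FALSE]
  novel <- surv[!surv$is_known_lncrna, , drop = FALSE]
  vote <- coding_potential_vote(scores, cpat_max, cpc2_max, feelnc_max)
  v <- vote[match(novel$transcript_id, vote$transcript_id), , drop = FALSE]
  noncoding <- !is.na(v$noncoding) & v$noncoding
  novel <- cbind(novel[noncoding, , drop = FALSE],
                 v[noncoding, c("votes_noncoding", "votes_available"), drop = FALSE])
  novel <- domain_exclusion(novel, evidence, pfam_evalue_max)
  if (nrow(known)) {
    known$votes_noncoding <- NA_integer_
    known$votes_available <- NA_integer_
  }
  out <- rbind(novel, known)
  out <- out[order(out$transcript_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
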