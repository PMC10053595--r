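.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

.genome_base <- function(genome, chrom, pos) {
  vapply(seq_along(chrom), function(i) {
    as.character(Biostrings::subseq(genome[[chrom[i]]], pos[i], pos[i]))
  }, character(1))
}

# coding-strand sequence of a transcript's CDS (segments sorted by start)
.coding_sequence <- function(genome, cds_segments, strand) {
  parts <- vapply(seq_along(cds_segments), function(j) {
    as.character(Biostrings::subseq(
      genome[[as.character(GenomicRanges::seqnames(cds_segments))[j]]],
      GenomicRanges::start(cds_segments)[j], GenomicRanges::end(cds_segments)[j]))
  }, character(1))
  s <- paste(parts, collapse = "")
  if (strand == "-") {
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }
  s
}

.classify_cds_site <- function(genome, cds_segments, strand, pos, ref, alt,
                               transcript_id) {
  starts <- GenomicRanges::start(cds_segments)
  ends <- GenomicRanges::end(cds_segments)
  widths <- ends - starts + 1L
  seg <- which(pos >= starts & pos <= ends)[1]
  off_plus <- sum(widths[seq_len(seg - 1L)]) + (pos - starts[seg])  # 0-based
  total <- sum(widths)
  i0 <- if (strand == "-") total - 1L - off_plus else off_plus
  coding <- .coding_sequence(genome, cds_segments, strand)
  codon_start <- (i0 %/% 3L) * 3L + 1L
  if (codon_start + 2L > total) {
    stop("variant falls in an incomplete terminal codon of transcript ",
         transcript_id)
  }
  ref_cod <- substr(coding, codon_start, codon_start + 2L)
  alt_base <- if (strand == "-") .COMPLEMENT[[alt]] else alt
  within <- i0 %% 3L
  alt_cod <- ref_cod
  substr(alt_cod, within + 1L, within + 1L) <- alt_base
  aa_ref <- Biostrings::GENETIC_CODE[[ref_cod]]
  aa_alt <- Biostrings::GENETIC_CODE[[alt_cod]]
  if (identical(aa_ref, aa_alt)) "cds_synonymous" else "cds_missense"
}

#' Annotate variant sites with their transcript consequence class
#'
#' Assigns each site exactly one class by severity precedence
#' CDS > UTR > noncoding exon > intron > upstream/downstream > intergenic.
#' For CDS sites the codon containing the site is read on the coding strand
#' (strand-aware complementation for minus-strand transcripts), ref and alt
#' codons are translated with the standard genetic code, and identical amino
#' acids give `cds_synonymous`, otherwise `cds_missense`. Ties between
#' overlapping transcripts of equal severity are broken by the
#' lexicographically smallest transcript id (gene id for the flank classes).
#'
#' @param sites a variant table
#' @param annotation a `genome_annotation`
#' @param genome named `DNAStringSet`; the reference base at every site must
#'   agree with `ref` (a mismatch is a data-consistency error)
#' @param flank bp defining the upstream/downstream windows around gene
#'   bodies
#' @return character vector of consequence classes, one per site, from
#'   {upstream, five_prime_utr, cds_synonymous, cds_missense, intron,
#'   three_prime_utr, downstream, noncoding_exon, intergenic}
#' @export
annotate_consequence <- function(sites, annotation, genome, flank = 1000L) {
  n <- nrow(sites)
  if (!n) return(character(0))
  gb <- .genome_base(genome, sites$chrom, sites$pos)
  bad <- which(gb != sites$ref)
  if (length(bad)) {
    stop("reference base mismatch with genome at ", sites$chrom[bad[1]], ":",
         sites$pos[bad[1]], " (genome ", gb[bad[1]], ", ref ",
         sites$ref[bad[1]], ")")
  }
  pos <- variant_granges(sites)
  tx <- annotation$transcripts
  txspan <- GenomicRanges::GRanges(tx$chrom, IRanges::IRanges(tx$start, tx$end))
  coding_tx <- unique(annotation$cds$transcript_id)

  cds_hits <- GenomicRanges::findOverlaps(pos, annotation$cds, ignore.strand = TRUE)
  exon_hits <- GenomicRanges::findOverlaps(pos, annotation$exons, ignore.strand = TRUE)
  tx_hits <- GenomicRanges::findOverlaps(pos, txspan, ignore.strand = TRUE)

  g <- annotation$genes
  up <- GenomicRanges::GRanges(g$chrom, IRanges::IRanges(
    ifelse(g$strand == "+", pmax(1L, g$start - flank), g$end + 1L),
    ifelse(g$strand == "+", pmax(1L, g$start - 1L), g$end + flank)))
  down <- GenomicRanges::GRanges(g$chrom, IRanges::IRanges(
    ifelse(g$strand == "+", g$end + 1L, pmax(1L, g$start - flank)),
    ifelse(g$strand == "+", g$end + flank, pmax(1L, g$start - 1L))))
  # a zero-width flank (gene at the chromosome start) collapses away
  up_ok <- GenomicRanges::start(up) <= GenomicRanges::end(up) &
    !(g$strand == "+" & g$start == 1L)
  up_hits <- GenomicRanges::findOverlaps(pos, up[up_ok], ignore.strand = TRUE)
  down_hits <- GenomicRanges::findOverlaps(pos, down, ignore.strand = TRUE)
  up_gene <- g$gene_id[up_ok]

  out <- rep("intergenic", n)
  cds_by_site <- split(S4Vectors::subjectHits(cds_hits), S4Vectors::queryHits(cds_hits))
  exon_by_site <- split(S4Vectors::subjectHits(exon_hits), S4Vectors::queryHits(exon_hits))
  tx_by_site <- split(S4Vectors::subjectHits(tx_hits), S4Vectors::queryHits(tx_hits))
  up_by_site <- split(S4Vectors::subjectHits(up_hits), S4Vectors::queryHits(up_hits))
  down_by_site <- split(S4Vectors::subjectHits(down_hits), S4Vectors::queryHits(down_hits))

  for (i in seq_len(n)) {
    key <- as.character(i)
    ch <- cds_by_site[[key]]
    if (!is.null(ch)) {
      tid <- min(annotation$cds$transcript_id[ch])
      segs <- annotation$cds[annotation$cds$transcript_id == tid]
      segs <- segs[order(GenomicRanges::start(segs))]
      strand <- tx$strand[tx$transcript_id == tid][1]
      out[i] <- .classify_cds_site(genome, segs, strand, sites$pos[i],
                                   sites$ref[i], sites$alt[i], tid)
      next
    }
    eh <- exon_by_site[[key]]
    if (!is.null(eh)) {
      tids <- annotation$exons$transcript_id[eh]
      cod <- sort(intersect(tids, coding_tx))
      if (length(cod)) {
        tid <- cod[1]
        segs <- annotation$cds[annotation$cds$transcript_id == tid]
        strand <- tx$strand[tx$transcript_id == tid][1]
        cds_lo <- min(GenomicRanges::start(segs))
        cds_hi <- max(GenomicRanges::end(segs))
        before <- sites$pos[i] < cds_lo
        out[i] <- if ((strand == "+" && before) || (strand == "-" && !before &&
                                                    sites$pos[i] > cds_hi)) {
          "five_prime_utr"
        } else {
          "three_prime_utr"
        }
        next
      }
      out[i] <- "noncoding_exon"
      next
    }
    th <- tx_by_site[[key]]
    if (!is.null(th)) {
      out[i] <- "intron"
      next
    }
    uh <- up_by_site[[key]]
    dh <- down_by_site[[key]]
    cand <- rbind(
      if (!is.null(uh)) data.frame(gene = up_gene[uh], class = "upstream"),
      if (!is.null(dh)) data.frame(gene = g$gene_id[dh], class = "downstream")
    )
    if (!is.null(cand) && nrow(cand)) {
      cand <- cand[order(cand$gene, cand$class, decreasing = c(FALSE, TRUE),
                         method = "radix"), , drop = FALSE]
      out[i] <- cand$class[1]
    }
  }
  out
}
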