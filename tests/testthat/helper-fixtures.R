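# --- fixture builders -------------------------------------------------------

# compact variant-table constructor; counts default to 10/10 per sample
make_sites <- function(pos, chrom = "c1", ref = "A", alt = "G",
                       id = NA_character_, MQ = 50, DP = 100, QD = 10,
                       ReadPosRankSum = 0, MQRankSum = 0,
                       ref_counts = NULL, alt_counts = NULL,
                       samples = c("s1", "s2")) {
  n <- length(pos)
  rec <- function(x) rep_len(x, n)
  if (is.null(ref_counts)) ref_counts <- matrix(10L, n, length(samples))
  if (is.null(alt_counts)) alt_counts <- matrix(10L, n, length(samples))
  df <- data.frame(chrom = rec(chrom), pos = as.integer(pos), ref = rec(ref),
                   alt = rec(alt), id = rec(id), MQ = rec(MQ), DP = rec(DP),
                   QD = rec(QD), ReadPosRankSum = rec(ReadPosRankSum),
                   MQRankSum = rec(MQRankSum), ad_missing = rec(FALSE),
                   stringsAsFactors = FALSE)
  cnt <- cbind(as.data.frame(ref_counts), as.data.frame(alt_counts))
  names(cnt) <- c(paste0("ref_", samples), paste0("alt_", samples))
  df <- cbind(df, cnt)
  attr(df, "samples") <- samples
  df
}

# write a GTF from an exon table (and optional CDS table) and parse it back
make_annotation <- function(exons, cds = NULL) {
  fmt <- function(d, feature) {
    sprintf('%s\tsim\t%s\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s"; gene_biotype "%s";',
            d$chrom, feature, d$start, d$end, d$strand, d$gene_id,
            d$transcript_id,
            if (is.null(d$biotype)) rep("protein_coding", nrow(d)) else d$biotype)
  }
  lines <- fmt(exons, "exon")
  if (!is.null(cds)) lines <- c(lines, fmt(cds, "CDS"))
  path <- tempfile(fileext = ".gtf")
  writeLines(lines, path)
  read_gtf(path)
}

ex_row <- function(chrom, start, end, strand, gene, tx, biotype = "protein_coding") {
  data.frame(chrom = chrom, start = start, end = end, strand = strand,
             gene_id = gene, transcript_id = tx, biotype = biotype,
             stringsAsFactors = FALSE)
}

# random DNA string
rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

# --- independent oracles ----------------------------------------------------

# PCRE backreference scan: maximal leftmost perfect tandem repeats, complete
# repeats only, reported once under a primitive motif
ssr_oracle <- function(s, min_repeats = ssr_min_repeats()) {
  out <- list()
  for (p in 1:6) {
    minr <- min_repeats[[as.character(p)]]
    pat <- sprintf("([ACGT]{%d})\\1{%d,}", p, minr - 1L)
    m <- gregexpr(pat, s, perl = TRUE)[[1]]
    if (m[1] == -1) next
    len <- attr(m, "match.length")
    for (k in seq_along(m)) {
      start <- as.integer(m[k])
      motif <- substr(s, start, start + p - 1L)
      primitive <- TRUE
      for (q in seq_len(p - 1L)) {
        if (p %% q == 0L && motif == strrep(substr(motif, 1, q), p %/% q)) {
          primitive <- FALSE
          break
        }
      }
      if (!primitive) next
      out[[length(out) + 1L]] <- data.frame(start = start, period = p,
                                            count = len[k] %/% p)
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(), period = integer(), count = integer()))
  }
  res <- do.call(rbind, out)
  res[order(res$start, res$period), , drop = FALSE]
}

# exhaustive pair/triplet proximity scan on one chromosome
prox_oracle <- function(pos, pair = 45, trip = 35) {
  n <- length(pos)
  rm <- logical(n)
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (abs(pos[i] - pos[j]) <= pair) rm[c(i, j)] <- TRUE
      }
    }
  }
  if (n >= 3) {
    cmb <- utils::combn(n, 3)
    for (k in seq_len(ncol(cmb))) {
      idx <- cmb[, k]
      if (max(pos[idx]) - min(pos[idx]) <= trip) rm[idx] <- TRUE
    }
  }
  rm
}

# hand-written Benjamini-Hochberg step-up
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}

# all-vs-all cis scan with plain interval arithmetic
cis_oracle <- function(del, gene, window = 10000) {
  hits <- list()
  for (i in seq_len(nrow(del))) {
    for (j in seq_len(nrow(gene))) {
      if (del$chrom[i] != gene$chrom[j]) next
      gap <- max(gene$start[j] - del$end[i] - 1L,
                 del$start[i] - gene$end[j] - 1L, 0L)
      if (gap <= window) {
        hits[[length(hits) + 1L]] <- data.frame(del_id = del$id[i],
                                                deg_id = gene$id[j], gap = gap)
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(del_id = character(), deg_id = character(),
                      gap = integer()))
  }
  do.call(rbind, hits)
}
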