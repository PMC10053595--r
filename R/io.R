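#' @import methods
#' @importFrom GenomicRanges GRanges seqnames start end strand width reduce
#'   findOverlaps countOverlaps resize mcols distance
#' @importFrom IRanges IRanges subsetByOverlaps overlapsAny
#' @importFrom S4Vectors queryHits subjectHits DataFrame
#' @importFrom GenomeInfoDb seqlevels seqlengths
NULL

.BASES <- c("A", "C", "G", "T")

## ---------------------------------------------------------------------------
## FASTA

#' Read a genome FASTA into a named sequence set
#'
#' Sequences are uppercased and keyed by the header token before the first
#' whitespace. Duplicate headers are an error.
#'
#' @param path FASTA file
#' @return a [Biostrings::DNAStringSet] keyed by chromosome name
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs)) {
    names(seqs) <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1L)
    if (anyDuplicated(names(seqs))) {
      stop("duplicate FASTA header: ", names(seqs)[duplicated(names(seqs))][1])
    }
    seqs <- Biostrings::DNAStringSet(toupper(seqs))
  }
  seqs
}

#' Write a sequence set to FASTA
#' @param seqs named [Biostrings::DNAStringSet] or named character vector
#' @param path output path
#' @return `path`, invisibly
#' @export
write_fasta <- function(seqs, path) {
  if (!methods::is(seqs, "DNAStringSet")) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

## ---------------------------------------------------------------------------
## BED

#' Read a BED3/BED6 file of genomic intervals
#'
#' Returns intervals as `GRanges` (1-based closed, the package-wide internal
#' convention); BED's 0-based half-open columns are converted on ingest.
#' Strand is taken from column 6 when present, `*` otherwise.
#'
#' @param path BED file
#' @return a [GenomicRanges::GRanges]
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") & !startsWith(lines, "track")]
  if (!length(lines)) return(GenomicRanges::GRanges())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) stop("BED line with fewer than 3 fields at line ", which(nf < 3)[1])
  s0 <- as.integer(vapply(fields, `[`, character(1), 2L))
  e0 <- as.integer(vapply(fields, `[`, character(1), 3L))
  bad <- which(s0 >= e0)
  if (length(bad)) stop("BED interval with start >= end at line ", bad[1])
  gr <- GenomicRanges::GRanges(
    seqnames = vapply(fields, `[`, character(1), 1L),
    ranges = IRanges::IRanges(start = s0 + 1L, end = e0),
    strand = ifelse(nf >= 6, vapply(fields, function(f) if (length(f) >= 6 && f[6] %in% c("+", "-")) f[6] else "*", character(1)), "*")
  )
  if (any(nf >= 4)) {
    gr$name <- vapply(fields, function(f) if (length(f) >= 4) f[4] else ".", character(1))
  }
  gr
}

#' Write genomic intervals to BED
#'
#' Canonical BED3 is emitted when the intervals carry neither strand nor a
#' `name` column, so that `write_bed(read_bed(f))` is byte-identical for
#' canonical BED3 input; otherwise BED6.
#'
#' @param gr a [GenomicRanges::GRanges]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_bed <- function(gr, path) {
  chrom <- as.character(GenomicRanges::seqnames(gr))
  s0 <- GenomicRanges::start(gr) - 1L
  e0 <- GenomicRanges::end(gr)
  str <- as.character(GenomicRanges::strand(gr))
  has_name <- !is.null(gr$name)
  if (!has_name && all(str == "*")) {
    lines <- paste(chrom, s0, e0, sep = "\t")
  } else {
    nm <- if (has_name) gr$name else rep(".", length(gr))
    lines <- paste(chrom, s0, e0, nm, 0L, ifelse(str == "*", ".", str), sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}

## ---------------------------------------------------------------------------
## GTF

#' Read gene models from a GTF file
#'
#' Parses an Ensembl-dialect GTF (via `rtracklayer`) into a
#' `genome_annotation` object: per-gene/per-transcript tables, exon and CDS
#' `GRanges`, and the splice-junction boundary table that drives the context
#' filter. Exons are sorted by start within each transcript.
#'
#' @param path GTF file
#' @return an object of class `genome_annotation` with elements `genes`,
#'   `transcripts`, `exons`, `cds`, `junctions`
#' @export
read_gtf <- function(path) {
  lines <- readLines(path)
  data_idx <- which(nzchar(lines) & !startsWith(lines, "#"))
  if (length(data_idx)) {
    nf <- lengths(strsplit(lines[data_idx], "\t", fixed = TRUE))
    if (any(nf != 9)) {
      stop("malformed GTF line (expected 9 tab-separated fields) at line ",
           data_idx[nf != 9][1])
    }
  }
  if (!length(data_idx)) {
    return(.new_annotation(
      genes = data.frame(gene_id = character(), chrom = character(),
                         strand = character(), start = integer(), end = integer()),
      transcripts = data.frame(transcript_id = character(), gene_id = character(),
                               chrom = character(), strand = character(),
                               biotype = character(), n_exons = integer(),
                               start = integer(), end = integer(), length = integer()),
      exons = GenomicRanges::GRanges(), cds = GenomicRanges::GRanges(),
      junctions = data.frame(chrom = character(), boundary = integer(),
                             transcript_id = character())
    ))
  }
  rec <- rtracklayer::import(path, format = "gtf")
  exons <- rec[rec$type == "exon"]
  cds <- rec[rec$type == "CDS"]
  if (length(exons) && (is.null(exons$transcript_id) || anyNA(exons$transcript_id))) {
    stop("GTF exon record without transcript_id")
  }
  biotype_of <- function(gr) {
    if (!is.null(gr$transcript_biotype)) gr$transcript_biotype
    else if (!is.null(gr$gene_biotype)) gr$gene_biotype
    else rep(NA_character_, length(gr))
  }
  ex_df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(exons)),
    start = GenomicRanges::start(exons), end = GenomicRanges::end(exons),
    strand = as.character(GenomicRanges::strand(exons)),
    transcript_id = exons$transcript_id, gene_id = exons$gene_id,
    biotype = biotype_of(exons), stringsAsFactors = FALSE
  )
  ex_df <- ex_df[order(ex_df$transcript_id, ex_df$start), , drop = FALSE]
  .annotation_from_tables(ex_df, cds)
}

.annotation_from_tables <- function(ex_df, cds_gr) {
  sp <- split(ex_df, ex_df$transcript_id)
  tx <- do.call(rbind, lapply(sp, function(d) {
    data.frame(transcript_id = d$transcript_id[1], gene_id = d$gene_id[1],
               chrom = d$chrom[1], strand = d$strand[1],
               biotype = ifelse(is.na(d$biotype[1]), ".", d$biotype[1]),
               n_exons = nrow(d), start = min(d$start), end = max(d$end),
               length = sum(d$end - d$start + 1L), stringsAsFactors = FALSE)
  }))
  rownames(tx) <- NULL
  tx <- tx[order(tx$transcript_id), , drop = FALSE]
  gsp <- split(tx, tx$gene_id)
  genes <- do.call(rbind, lapply(gsp, function(d) {
    data.frame(gene_id = d$gene_id[1], chrom = d$chrom[1], strand = d$strand[1],
               start = min(d$start), end = max(d$end), stringsAsFactors = FALSE)
  }))
  rownames(genes) <- NULL
  junc <- do.call(rbind, lapply(sp, function(d) {
    if (nrow(d) < 2) return(NULL)
    # boundary coordinate = 1-based index of the last base left of the
    # exon/intron junction: exon end (donor side) and intron end (acceptor)
    data.frame(chrom = d$chrom[1],
               boundary = c(d$end[-nrow(d)], d$start[-1] - 1L),
               transcript_id = d$transcript_id[1], stringsAsFactors = FALSE)
  }))
  if (is.null(junc)) {
    junc <- data.frame(chrom = character(), boundary = integer(),
                       transcript_id = character())
  }
  rownames(junc) <- NULL
  exons <- GenomicRanges::GRanges(ex_df$chrom,
                                  IRanges::IRanges(ex_df$start, ex_df$end),
                                  strand = ex_df$strand)
  exons$transcript_id <- ex_df$transcript_id
  exons$gene_id <- ex_df$gene_id
  cds <- if (length(cds_gr)) {
    g <- GenomicRanges::GRanges(as.character(GenomicRanges::seqnames(cds_gr)),
                                IRanges::IRanges(GenomicRanges::start(cds_gr),
                                                 GenomicRanges::end(cds_gr)),
                                strand = as.character(GenomicRanges::strand(cds_gr)))
    g$transcript_id <- cds_gr$transcript_id
    g$gene_id <- cds_gr$gene_id
    g[order(g$transcript_id, GenomicRanges::start(g))]
  } else {
    GenomicRanges::GRanges()
  }
  .new_annotation(genes = genes, transcripts = tx, exons = exons, cds = cds,
                  junctions = junc)
}

.new_annotation <- function(genes, transcripts, exons, cds, junctions) {
  structure(list(genes = genes, transcripts = transcripts, exons = exons,
                 cds = cds, junctions = junctions),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("genome_annotation:", nrow(x$genes), "genes,", nrow(x$transcripts),
      "transcripts,", length(x$exons), "exons,", length(x$cds), "CDS segments,",
      nrow(x$junctions), "junction boundaries\n")
  invisible(x)
}

#' Gene body ranges of an annotation
#' @param ann a `genome_annotation`
#' @return `GRanges` of gene spans with `gene_id` metadata
#' @export
gene_ranges <- function(ann) {
  g <- ann$genes
  gr <- GenomicRanges::GRanges(g$chrom, IRanges::IRanges(g$start, g$end),
                               strand = g$strand)
  gr$gene_id <- g$gene_id
  gr
}

#' Write a `genome_annotation` back to GTF
#' @param ann a `genome_annotation`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_gtf <- function(ann, path) {
  lines <- character(0)
  ex <- ann$exons
  cds <- ann$cds
  tx <- ann$transcripts
  fmt <- function(chrom, feature, start, end, strand, attrs) {
    sprintf("%s\tsim\t%s\t%d\t%d\t.\t%s\t.\t%s", chrom, feature, start, end, strand, attrs)
  }
  for (i in seq_len(nrow(tx))) {
    t <- tx[i, ]
    attrs <- sprintf('gene_id "%s"; transcript_id "%s"; gene_biotype "%s";',
                     t$gene_id, t$transcript_id, t$biotype)
    lines <- c(lines, fmt(t$chrom, "transcript", t$start, t$end, t$strand, attrs))
    exi <- ex[ex$transcript_id == t$transcript_id]
    for (j in seq_along(exi)) {
      lines <- c(lines, fmt(as.character(GenomicRanges::seqnames(exi))[j], "exon",
                            GenomicRanges::start(exi)[j], GenomicRanges::end(exi)[j],
                            t$strand, attrs))
    }
    if (length(cds)) {
      ci <- cds[cds$transcript_id == t$transcript_id]
      for (j in seq_along(ci)) {
        lines <- c(lines, fmt(as.character(GenomicRanges::seqnames(ci))[j], "CDS",
                              GenomicRanges::start(ci)[j], GenomicRanges::end(ci)[j],
                              t$strand, attrs))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

## ---------------------------------------------------------------------------
## Variant tables

.QUALITY_KEYS <- c("MQ", "DP", "QD", "ReadPosRankSum", "MQRankSum")

#' Sample identifiers of a variant table
#' @param sites a variant table (see [read_variants()])
#' @return character vector of sample ids
#' @export
variant_samples <- function(sites) attr(sites, "samples")

#' Per-sample count matrices of a variant table
#' @param sites a variant table
#' @return integer matrix, sites x samples
#' @export
ref_count_matrix <- function(sites) {
  s <- variant_samples(sites)
  as.matrix(sites[, paste0("ref_", s), drop = FALSE])
}

#' @rdname ref_count_matrix
#' @export
alt_count_matrix <- function(sites) {
  s <- variant_samples(sites)
  as.matrix(sites[, paste0("alt_", s), drop = FALSE])
}

.new_variant_table <- function(df, samples) {
  rownames(df) <- NULL
  attr(df, "samples") <- samples
  df
}

#' Single-base `GRanges` of variant positions
#' @param sites a variant table
#' @return `GRanges` of width-1 positions
#' @export
variant_granges <- function(sites) {
  GenomicRanges::GRanges(sites$chrom, IRanges::IRanges(sites$pos, width = 1L))
}

#' Read called variants with per-sample allele depths
#'
#' Accepts either a VCF 4.x file with a per-sample `AD` FORMAT field (parsed
#' with `VariantAnnotation`) or the package's TSV dialect (columns `chrom`,
#' `pos`, `ref`, `alt`, `id`, the five quality keys, then `ref_<sample>` /
#' `alt_<sample>` pairs). Only biallelic SNVs are kept: indel records are
#' skipped with a warning count and multiallelic records are split into
#' biallelic sites by default (or dropped).
#'
#' @param path VCF (`.vcf`) or TSV file
#' @param sample_ids character vector of samples that must be present
#' @param multiallelic `"split"` (default) or `"drop"`
#' @return a variant table: data.frame sorted by (chrom, pos) with columns
#'   `chrom`, `pos` (1-based), `ref`, `alt`, `id` (NA when absent), `MQ`,
#'   `DP`, `QD`, `ReadPosRankSum`, `MQRankSum`, `ad_missing`, and per-sample
#'   `ref_<s>`/`alt_<s>` counts; sample ids attached as the `samples`
#'   attribute
#' @export
read_variants <- function(path, sample_ids, multiallelic = c("split", "drop")) {
  multiallelic <- match.arg(multiallelic)
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
    .read_variants_vcf(path, sample_ids, multiallelic)
  } else {
    .read_variants_tsv(path, sample_ids)
  }
}

.read_variants_tsv <- function(path, sample_ids) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE, na.strings = .NA_TOKEN,
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("chrom", "pos", "ref", "alt", "id", .QUALITY_KEYS,
            paste0("ref_", sample_ids), paste0("alt_", sample_ids))
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("variant TSV is missing columns: ", paste(miss, collapse = ", "))
  keep <- df$ref %in% .BASES & df$alt %in% .BASES
  if (any(!keep)) warning(sum(!keep), " non-SNV record(s) skipped")
  df <- df[keep, , drop = FALSE]
  df$ad_missing <- FALSE
  df <- df[order(df$chrom, df$pos), c("chrom", "pos", "ref", "alt", "id",
                                      .QUALITY_KEYS, "ad_missing",
                                      paste0("ref_", sample_ids),
                                      paste0("alt_", sample_ids)), drop = FALSE]
  .new_variant_table(df, sample_ids)
}

.read_variants_vcf <- function(path, sample_ids, multiallelic) {
  vcf <- VariantAnnotation::readVcf(path)
  hdr_samples <- colnames(vcf)
  miss <- setdiff(sample_ids, hdr_samples)
  if (length(miss)) stop("VCF is missing sample(s): ", paste(miss, collapse = ", "))
  # IDs straight from the file; "." means absent
  dl <- readLines(path)
  dl <- dl[nzchar(dl) & !startsWith(dl, "#")]
  fields <- strsplit(dl, "\t", fixed = TRUE)
  raw_id <- vapply(fields, `[`, character(1), 3L)
  raw_alt <- vapply(fields, `[`, character(1), 5L)
  n_alt <- lengths(strsplit(raw_alt, ",", fixed = TRUE))
  is_multi <- n_alt > 1
  if (multiallelic == "drop" && any(is_multi)) {
    vcf <- vcf[!is_multi]
    raw_id <- raw_id[!is_multi]
    n_alt <- n_alt[!is_multi]
  }
  vcf <- VariantAnnotation::expand(vcf)
  id <- if (multiallelic == "split") rep(raw_id, n_alt) else raw_id
  id[id == "."] <- NA_character_
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(rr$REF)
  alt <- as.character(rr$ALT)
  snv <- ref %in% .BASES & alt %in% .BASES
  if (any(!snv)) warning(sum(!snv), " non-SNV record(s) skipped")
  info <- VariantAnnotation::info(vcf)
  getq <- function(key) {
    if (key %in% names(info)) as.numeric(info[[key]]) else rep(NA_real_, length(vcf))
  }
  AD <- VariantAnnotation::geno(vcf)$AD
  n <- length(vcf)
  refc <- matrix(0L, n, length(sample_ids), dimnames = list(NULL, sample_ids))
  altc <- refc
  ad_missing <- logical(n)
  if (length(dim(AD)) == 3L) {
    # biallelic records expand to an n x samples x 2 array
    for (j in seq_along(sample_ids)) {
      r <- AD[, sample_ids[j], 1L]
      a <- AD[, sample_ids[j], 2L]
      miss <- is.na(r) | is.na(a)
      ad_missing <- ad_missing | miss
      refc[!miss, j] <- as.integer(r[!miss])
      altc[!miss, j] <- as.integer(a[!miss])
    }
  } else {
    for (j in seq_along(sample_ids)) {
      col <- AD[, sample_ids[j]]
      for (i in seq_len(n)) {
        v <- col[[i]]
        if (is.null(v) || length(v) < 2 || anyNA(v[1:2])) {
          ad_missing[i] <- TRUE
        } else {
          refc[i, j] <- as.integer(v[1])
          altc[i, j] <- as.integer(v[2])
        }
      }
    }
  }
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(rr)),
                   pos = GenomicRanges::start(rr), ref = ref, alt = alt,
                   id = id, MQ = getq("MQ"), DP = getq("DP"), QD = getq("QD"),
                   ReadPosRankSum = getq("ReadPosRankSum"),
                   MQRankSum = getq("MQRankSum"), ad_missing = ad_missing,
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(refc), as.data.frame(altc))
  names(df)[(ncol(df) - 2 * length(sample_ids) + 1):ncol(df)] <-
    c(paste0("ref_", sample_ids), paste0("alt_", sample_ids))
  df <- df[snv, , drop = FALSE]
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  .new_variant_table(df, sample_ids)
}

#' Write a variant table in the TSV dialect
#' @param sites a variant table
#' @param path output path
#' @return `path`, invisibly
#' @export
write_variants_tsv <- function(sites, path) {
  s <- variant_samples(sites)
  cols <- c("chrom", "pos", "ref", "alt", "id", .QUALITY_KEYS,
            paste0("ref_", s), paste0("alt_", s))
  write_result_tsv(sites[, cols, drop = FALSE], path)
}

#' Write a variant table as minimal VCF 4.2 with FORMAT/AD
#' @param sites a variant table
#' @param path output path
#' @return `path`, invisibly
#' @export
write_variants_vcf <- function(sites, path) {
  s <- variant_samples(sites)
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total depth\">",
           "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
           "##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description=\"Read position rank sum\">",
           "##INFO=<ID=MQRankSum,Number=1,Type=Float,Description=\"Mapping quality rank sum\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
                   "FORMAT", s), collapse = "\t"))
  fmt_info <- function(i) {
    keys <- .QUALITY_KEYS
    vals <- unlist(sites[i, keys])
    ok <- !is.na(vals)
    if (!any(ok)) return(".")
    paste(paste0(keys[ok], "=", vapply(vals[ok], format, character(1), digits = 10)),
          collapse = ";")
  }
  refm <- ref_count_matrix(sites)
  altm <- alt_count_matrix(sites)
  body <- vapply(seq_len(nrow(sites)), function(i) {
    ad <- paste0(refm[i, ], ",", altm[i, ])
    paste(c(sites$chrom[i], sites$pos[i],
            ifelse(is.na(sites$id[i]), ".", sites$id[i]),
            sites$ref[i], sites$alt[i], ".", "PASS", fmt_info(i), "AD", ad),
          collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}
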