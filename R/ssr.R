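#' Default minimum repeat counts per motif length
#'
#' Conservative genome-wide microsatellite-scanner conventions: mono 12,
#' di 7, tri 5, tetra/penta/hexa 4.
#'
#' @return named integer vector indexed by motif length "1".."6"
#' @export
ssr_min_repeats <- function() {
  c(`1` = 12L, `2` = 7L, `3` = 5L, `4` = 4L, `5` = 4L, `6` = 4L)
}

.check_min_repeats <- function(min_repeats) {
  len <- as.integer(names(min_repeats))
  if (anyNA(len) || any(len < 1L | len > 6L)) {
    stop("min_repeats must be named by motif lengths 1..6")
  }
  if (any(min_repeats < 2L)) stop("min_repeats values must be >= 2")
  min_repeats
}

.canonical_rotation <- function(motif) {
  p <- nchar(motif)
  if (p == 1L) return(motif)
  rots <- vapply(seq_len(p), function(k) {
    paste0(substr(motif, k, p), substr(motif, 1, k - 1))
  }, character(1))
  min(rots)
}

.is_primitive <- function(motif) {
  p <- nchar(motif)
  if (p == 1L) return(TRUE)
  for (q in seq_len(p - 1L)) {
    if (p %% q == 0L && motif == strrep(substr(motif, 1, q), p %/% q)) return(FALSE)
  }
  TRUE
}

#' Scan a sequence for perfect microsatellites (SSRs)
#'
#' Reports every maximal, non-extendable perfect tandem run with motif length
#' 1-6 nt whose complete-repeat count reaches the per-motif-length minimum.
#' A run is reported once, under its shortest period (so `ATATAT` is a
#' period-2 run, never period-6), at its leftmost phase. Runs containing a
#' base outside A/C/G/T are excluded. The reported interval covers complete
#' repeats only (`length = period * repeat_count`); `run_start`/`run_end`
#' give the full maximal periodic region including any trailing partial
#' repeat.
#'
#' @param sequence a character string or `DNAString` over A/C/G/T/N
#' @param chrom chromosome name attached to the loci
#' @param min_repeats named integer vector, motif length ("1".."6") to
#'   minimum repeat count; see [ssr_min_repeats()]
#' @return data.frame with columns `chrom`, `start`, `end` (1-based closed),
#'   `motif` (canonical rotation), `period`, `repeat_count`, `run_start`,
#'   `run_end`
#' @export
find_ssrs <- function(sequence, chrom = "seq", min_repeats = ssr_min_repeats()) {
  min_repeats <- .check_min_repeats(min_repeats)
  s <- toupper(as.character(sequence))
  n <- nchar(s)
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      motif = character(), period = integer(),
                      repeat_count = integer(), run_start = integer(),
                      run_end = integer(), stringsAsFactors = FALSE)
  if (n == 0L) return(empty)
  x <- utf8ToInt(s)
  valid <- x %in% utf8ToInt("ACGT")
  out <- list()
  for (p in sort(as.integer(names(min_repeats)))) {
    minr <- min_repeats[[as.character(p)]]
    if (n < p * minr) next
    eq <- x[seq_len(n - p)] == x[(p + 1L):n] &
      valid[seq_len(n - p)] & valid[(p + 1L):n]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    hit <- which(r$values & r$lengths >= p * (minr - 1L))
    for (k in hit) {
      a <- starts[k]                    # first position of the periodic run
      L <- r$lengths[k]                 # matched lag-p positions
      region_len <- L + p
      count <- region_len %/% p
      if (count < minr) next
      motif <- substr(s, a, a + p - 1L)
      if (!.is_primitive(motif)) next   # shortest-period reporting
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom, start = a, end = a + p * count - 1L,
        motif = .canonical_rotation(motif), period = p, repeat_count = count,
        run_start = a, run_end = a + region_len - 1L, stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res[order(res$start, res$period), , drop = FALSE]
}

#' SSR loci as genomic ranges
#' @param loci output of [find_ssrs()]
#' @return `GRanges` with `motif`, `period`, `repeat_count` metadata
#' @export
ssr_granges <- function(loci) {
  gr <- GenomicRanges::GRanges(loci$chrom, IRanges::IRanges(loci$start, loci$end))
  gr$motif <- loci$motif
  gr$period <- loci$period
  gr$repeat_count <- loci$repeat_count
  gr
}

#' Genome-wide SSR mask
#'
#' Runs [find_ssrs()] per chromosome and merges overlapping loci into a
#' single interval mask, the form consumed by the variant context filter.
#'
#' @param genome named `DNAStringSet` (or named character vector)
#' @param min_repeats see [find_ssrs()]
#' @return merged `GRanges` mask
#' @export
ssr_mask <- function(genome, min_repeats = ssr_min_repeats()) {
  loci <- lapply(names(genome), function(chrom) {
    find_ssrs(genome[[chrom]], chrom = chrom, min_repeats = min_repeats)
  })
  loci <- do.call(rbind, loci)
  if (is.null(loci) || !nrow(loci)) return(GenomicRanges::GRanges())
  GenomicRanges::reduce(ssr_granges(loci))
}

#' Write SSR loci as BED6 (motif x count in the name column)
#' @param loci output of [find_ssrs()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_ssr_bed <- function(loci, path) {
  lines <- sprintf("%s\t%d\t%d\t%sx%d\t%d\t+", loci$chrom, loci$start - 1L,
                   loci$end, loci$motif, loci$repeat_count, loci$repeat_count)
  writeLines(lines, path)
  invisible(path)
}
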