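#' Synthetic-study configuration
#'
#' The defaults emulate the study design the pipeline targets: two groups of
#' five replicate RNA-Seq samples, per-site allele counts that are binomial
#' draws at Poisson(50) depth, a planted group difference in allele fraction
#' of 0.3 at ASE sites, editing-type substitutions confined to SINE
#' intervals, and small planted fractions of sites violating exactly one
#' cascade rule each.
#'
#' @param seed master seed; every artifact draws from its own stream keyed
#'   by (seed, purpose)
#' @param n_chroms,chrom_length,genes_per_chrom genome layout
#' @param n_samples_per_group replicates per group (two groups)
#' @param n_sites total variant sites emitted
#' @param depth_mean mean per-sample sequencing depth (Poisson)
#' @param ase_fraction fraction of sites with a planted ASE effect
#' @param editing_fraction fraction of sites planted as editing events
#' @param context_violation_fraction fraction violating one context rule
#'   (split across junction / paralog / SSR / bidirectional)
#' @param quality_fail_fraction fraction failing exactly one quality rule
#' @param proximity_fail_fraction fraction planted in close pairs/triplets
#' @param sparse_fraction fraction with alt support in under half the samples
#' @param delta_aaf_planted planted group AAF difference at ASE sites
#' @param n_editing_decoys editing decoys, one rule violated each (multiple
#'   of 4: no-SINE / known-id / AAF-ceiling / non-significant)
#' @param overdispersion_rho beta-binomial overdispersion (0 = binomial)
#' @param lnc_expression_floor expression floor used for the planted lncRNA
#'   truth
#' @return a `sim_config` list
#' @export
sim_config <- function(seed = 1L, n_chroms = 2L, chrom_length = 400000L,
                       genes_per_chrom = 20L, n_samples_per_group = 5L,
                       n_sites = 10000L, depth_mean = 50,
                       ase_fraction = 0.05, editing_fraction = 0.008,
                       context_violation_fraction = 0.02,
                       quality_fail_fraction = 0.02,
                       proximity_fail_fraction = 0.02,
                       sparse_fraction = 0.02,
                       delta_aaf_planted = 0.3,
                       n_editing_decoys = 12L,
                       overdispersion_rho = 0,
                       lnc_expression_floor = 1) {
  fr <- c(ase_fraction, editing_fraction, context_violation_fraction,
          quality_fail_fraction, proximity_fail_fraction, sparse_fraction)
  stopifnot(all(fr >= 0), all(fr <= 1), sum(fr) <= 1,
            n_samples_per_group >= 1, n_editing_decoys %% 4 == 0)
  structure(as.list(environment()), class = "sim_config")
}

.SLOT <- 8000L     # per-gene layout slot
.SLOT0 <- 1000L    # offset of the first slot on each chromosome

.chrom_names <- function(config) paste0("chr", seq_len(config$n_chroms))

.sample_names <- function(config) {
  n <- config$n_samples_per_group
  c(paste0("EP", seq_len(n)), paste0("ML", seq_len(n)))
}

#' Two-group design matching the synthetic cohort
#' @param config a [sim_config()]
#' @return a [group_design()]
#' @export
sim_design <- function(config) {
  s <- .sample_names(config)
  group_design(s, rep(c("EP", "ML"), each = config$n_samples_per_group))
}

# deterministic genome layout: genes, masks, planted-SSR spec
.sim_layout <- function(config) {
  ssr_spec <- list(c("A", 14L), c("AG", 9L), c("AAT", 6L), c("ACGT", 5L),
                   c("AACGT", 4L), c("AACGTC", 4L))
  genes <- list(); sine <- list(); paralog <- list(); ssr <- list()
  for (c_idx in seq_len(config$n_chroms)) {
    chrom <- paste0("chr", c_idx)
    for (k in seq_len(config$genes_per_chrom) - 1L) {
      b <- .SLOT0 + k * .SLOT + 1L      # 1-based gene start
      strand <- if (k %% 2L == 0L) "+" else "-"
      genes[[length(genes) + 1L]] <- list(
        chrom = chrom, slot = k, base = b, strand = strand,
        gene_id = sprintf("G%d_%02d", c_idx, k),
        transcript_id = sprintf("T%d_%02d", c_idx, k),
        exons = cbind(start = b + c(0L, 800L, 1700L),
                      end = b + c(299L, 1199L, 1999L)),
        cds = cbind(start = b + c(150L, 800L, 1700L),
                    end = b + c(299L, 1199L, 1848L)),
        biotype = "protein_coding"
      )
      if (k == 0L) {
        # opposite-strand overlapping partner (bidirectional pair)
        genes[[length(genes) + 1L]] <- list(
          chrom = chrom, slot = k, base = b, strand = "-",
          gene_id = sprintf("G%d_B", c_idx),
          transcript_id = sprintf("T%d_B", c_idx),
          exons = cbind(start = b + c(1000L, 2600L),
                        end = b + c(1399L, 2999L)),
          cds = NULL, biotype = "lncRNA"
        )
      }
      # intronic SINE in even slots >= 2 (inside intron 1, clear of junctions)
      if (k >= 2L && k %% 2L == 0L) {
        sine[[length(sine) + 1L]] <- list(chrom = chrom, start = b + 400L,
                                          end = b + 699L, context = "intronic",
                                          gene_strand = strand)
      }
      sine[[length(sine) + 1L]] <- list(chrom = chrom, start = b + 3500L,
                                        end = b + 3799L, context = "intergenic",
                                        gene_strand = NA_character_)
      if (k %% 2L == 1L) {
        paralog[[length(paralog) + 1L]] <- list(chrom = chrom,
                                                start = b + 4500L,
                                                end = b + 4899L)
      }
      for (which_ssr in 1:2) {
        spec <- ssr_spec[[(2L * k + which_ssr - 1L) %% length(ssr_spec) + 1L]]
        st <- b + 5500L + (which_ssr - 1L) * 100L
        len <- nchar(spec[1]) * as.integer(spec[2])
        ssr[[length(ssr) + 1L]] <- list(chrom = chrom, start = st,
                                        end = st + len - 1L, motif = spec[1],
                                        count = as.integer(spec[2]))
      }
    }
  }
  list(genes = genes, sine = sine, paralog = paralog, ssr = ssr)
}

.layout_granges <- function(items) {
  if (!length(items)) return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(vapply(items, `[[`, character(1), "chrom"),
                         IRanges::IRanges(vapply(items, `[[`, integer(1), "start"),
                                          vapply(items, `[[`, integer(1), "end")))
}

.layout_annotation <- function(layout) {
  if (!length(layout$genes)) {
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
  ex <- list(); cds_rows <- list()
  for (g in layout$genes) {
    ne <- nrow(g$exons)
    ex[[length(ex) + 1L]] <- data.frame(
      chrom = g$chrom, start = g$exons[, "start"], end = g$exons[, "end"],
      strand = g$strand, transcript_id = g$transcript_id, gene_id = g$gene_id,
      biotype = g$biotype, stringsAsFactors = FALSE)
    if (!is.null(g$cds)) {
      cds_rows[[length(cds_rows) + 1L]] <- data.frame(
        chrom = g$chrom, start = g$cds[, "start"], end = g$cds[, "end"],
        strand = g$strand, transcript_id = g$transcript_id,
        gene_id = g$gene_id, stringsAsFactors = FALSE)
    }
  }
  ex_df <- do.call(rbind, ex)
  ex_df <- ex_df[order(ex_df$transcript_id, ex_df$start), , drop = FALSE]
  cds_df <- do.call(rbind, cds_rows)
  cds_gr <- GenomicRanges::GRanges(cds_df$chrom,
                                   IRanges::IRanges(cds_df$start, cds_df$end),
                                   strand = cds_df$strand)
  cds_gr$transcript_id <- cds_df$transcript_id
  cds_gr$gene_id <- cds_df$gene_id
  .annotation_from_tables(ex_df, cds_gr)
}

.MUTATE_NEXT <- c(A = "C", C = "G", G = "T", T = "A")

# remove incidental SSRs from a random genome so the mask holds exactly the
# planted loci; planted intervals are left untouched
.scrub_ssrs <- function(seqs, planted, min_repeats) {
  for (chrom in names(seqs)) {
    keep <- planted[as.character(GenomicRanges::seqnames(planted)) == chrom]
    for (pass in 1:12) {
      loci <- find_ssrs(seqs[[chrom]], chrom = chrom, min_repeats = min_repeats)
      if (!nrow(loci)) break
      gr <- ssr_granges(loci)
      incidental <- !IRanges::overlapsAny(gr, keep, ignore.strand = TRUE)
      if (!any(incidental)) break
      for (i in which(incidental)) {
        mid <- (loci$start[i] + loci$end[i]) %/% 2L
        cur <- substr(seqs[[chrom]], mid, mid)
        substr(seqs[[chrom]], mid, mid) <- .MUTATE_NEXT[[cur]]
      }
    }
  }
  seqs
}

.REVCOMP <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Simulate the synthetic reference: genome, gene models and masks
#'
#' Generates a random genome with planted gene models (multi-exon, CDS and
#' UTRs, both strands, one opposite-strand overlapping gene pair per
#' chromosome), SINE and paralog interval tracks, literal SSR runs, and the
#' codon exemplars used by the consequence-annotation checks. Incidental
#' SSRs arising by chance in the random sequence are scrubbed so the SSR
#' mask contains exactly the planted loci.
#'
#' @param config a [sim_config()]
#' @return list with `genome` (`DNAStringSet`), `annotation`
#'   (`genome_annotation`), `sine`, `paralog`, `ssr_truth` (`GRanges`),
#'   `layout`, `config`
#' @export
simulate_reference <- function(config) {
  if (config$chrom_length < .SLOT0 + config$genes_per_chrom * .SLOT + 2000L) {
    stop("infeasible config: genes do not fit on chrom_length ",
         config$chrom_length)
  }
  layout <- .sim_layout(config)
  seqs <- with_stream(config$seed, "genome", {
    out <- lapply(seq_len(config$n_chroms), function(i) {
      paste(sample(.BASES, config$chrom_length, replace = TRUE), collapse = "")
    })
    names(out) <- .chrom_names(config)
    out
  })
  # plant SSR runs; pin the flanking bases so the run cannot extend into the
  # random backbone and shift its phase
  for (s in layout$ssr) {
    run <- strrep(s$motif, s$count)
    substr(seqs[[s$chrom]], s$start, s$end) <- run
    p <- nchar(s$motif)
    block <- function(avoid) setdiff(.BASES, avoid)[1]
    left_periodic <- substr(seqs[[s$chrom]], s$start + p - 1L, s$start + p - 1L)
    substr(seqs[[s$chrom]], s$start - 1L, s$start - 1L) <- block(left_periodic)
    right_periodic <- substr(seqs[[s$chrom]], s$end + 1L - p, s$end + 1L - p)
    substr(seqs[[s$chrom]], s$end + 1L, s$end + 1L) <- block(right_periodic)
  }
  ssr_truth <- .layout_granges(layout$ssr)
  seqs <- .scrub_ssrs(seqs, ssr_truth, ssr_min_repeats())
  # codon exemplars in the slot-2 (+) and slot-3 (-) genes of each chromosome
  for (g in layout$genes) {
    if (!g$slot %in% c(2L, 3L) || is.null(g$cds)) next
    b <- g$base
    syn <- if (g$strand == "+") "GCT" else .REVCOMP("GCT")
    mis <- if (g$strand == "+") "GAT" else .REVCOMP("GAT")
    substr(seqs[[g$chrom]], b + 899L, b + 901L) <- syn
    substr(seqs[[g$chrom]], b + 959L, b + 961L) <- mis
  }
  genome <- Biostrings::DNAStringSet(unlist(seqs))
  names(genome) <- names(seqs)
  list(genome = genome, annotation = .layout_annotation(layout),
       sine = .layout_granges(layout$sine),
       paralog = .layout_granges(layout$paralog),
       ssr_truth = ssr_truth, layout = layout, config = config)
}

## ---------------------------------------------------------------------------
## variant cohort

.rdepth <- function(n, mean, min_depth = 0L) {
  min_depth + stats::rpois(n, max(mean - min_depth, 1))
}

.ralt <- function(depth, aaf, rho = 0) {
  if (rho > 0) {
    nu <- 1 / rho - 1
    p <- stats::rbeta(length(depth), pmax(aaf * nu, 1e-6),
                      pmax((1 - aaf) * nu, 1e-6))
    stats::rbinom(length(depth), depth, p)
  } else {
    stats::rbinom(length(depth), depth, aaf)
  }
}

# binomial draw kept within a band around the target fraction (bounded
# rejection; deterministic fallback), for planted sites whose downstream
# verdict must be certain by construction
.ralt_banded <- function(depth, target, band) {
  out <- integer(length(depth))
  for (i in seq_along(depth)) {
    ok <- FALSE
    for (try in 1:50) {
      a <- stats::rbinom(1L, depth[i], target)
      if (abs(a / depth[i] - target) <= band) { out[i] <- a; ok <- TRUE; break }
    }
    if (!ok) out[i] <- round(depth[i] * target)
  }
  out
}

.base_at <- function(seqs_chr, pos) substr(seqs_chr, pos, pos)

.find_base_positions <- function(seq_chr, start, end, base) {
  region <- substr(seq_chr, start, end)
  which(strsplit(region, "")[[1]] == base) + start - 1L
}

#' Simulate the variant cohort with a complete planted-truth ledger
#'
#' Emits one variant table over the synthetic cohort (two groups of
#' replicates). Per site and sample, total depth is Poisson and the alt
#' count binomial at the site's group-level allele fraction. Null sites
#' share one AAF across groups; planted ASE sites shift one group's AAF by
#' `delta_aaf_planted`; planted editing sites are canonical substitutions
#' inside SINE intervals with a guaranteed group difference and per-sample
#' AAF at most 0.65; planted failure classes violate exactly one cascade
#' rule each; editing decoys violate exactly one editing rule each.
#'
#' @param config a [sim_config()]
#' @param reference output of [simulate_reference()]
#' @return list with `sites` (a variant table) and `truth` (per-site ledger:
#'   `class`, `editing_class`, `differential`, true group AAFs, consequence
#'   and editing-type truth)
#' @export
simulate_variants <- function(config, reference) {
  layout <- reference$layout
  seqs <- as.character(reference$genome)
  n_sites <- config$n_sites
  n_grp <- config$n_samples_per_group
  n_smp <- 2L * n_grp

  n_ase <- round(config$ase_fraction * n_sites)
  n_edit <- round(config$editing_fraction * n_sites)
  n_qual <- round(config$quality_fail_fraction * n_sites)
  n_ctx <- round(config$context_violation_fraction * n_sites)
  n_prox <- round(config$proximity_fail_fraction * n_sites)
  n_sparse <- round(config$sparse_fraction * n_sites)
  n_decoy <- config$n_editing_decoys

  ## ---- positions -----------------------------------------------------------
  # clean grid: intergenic stretches, 50 bp spacing, clear of every mask
  grid <- list()
  slots_end <- .SLOT0 + config$genes_per_chrom * .SLOT
  for (c_idx in seq_len(config$n_chroms)) {
    chrom <- paste0("chr", c_idx)
    for (k in seq_len(config$genes_per_chrom) - 1L) {
      b <- .SLOT0 + k * .SLOT + 1L
      grid[[length(grid) + 1L]] <- data.frame(
        chrom = chrom, pos = seq(b + 6000L, b + 6900L, by = 50L))
    }
    tail_start <- slots_end + 2000L
    tail_end <- config$chrom_length - 1000L
    grid[[length(grid) + 1L]] <- data.frame(
      chrom = chrom, pos = seq(tail_start, tail_end, by = 50L))
  }
  grid <- do.call(rbind, grid)

  mk <- function(chrom, pos, class, editing_class = "none", aaf1 = NA_real_,
                 aaf2 = NA_real_, consequence = NA_character_,
                 ref = NA_character_, alt = NA_character_,
                 etype = NA_character_, estrand = NA_character_,
                 differential = FALSE) {
    data.frame(chrom = chrom, pos = as.integer(pos), class = class,
               editing_class = editing_class, true_aaf_g1 = aaf1,
               true_aaf_g2 = aaf2, consequence_truth = consequence,
               ref_forced = ref, alt_forced = alt,
               editing_type_truth = etype, editing_strand_truth = estrand,
               differential = differential, stringsAsFactors = FALSE)
  }
  plan <- list()
  add <- function(row) plan[[length(plan) + 1L]] <<- row

  # consequence exemplars (slot-2 "+" and slot-3 "-" genes; slot-0 partner)
  for (g in layout$genes) {
    b <- g$base
    if (g$gene_id == sprintf("G%s_B", sub("chr", "", g$chrom))) {
      add(mk(g$chrom, b + 2700L, "null", consequence = "noncoding_exon"))
      next
    }
    if (!g$slot %in% c(2L, 3L)) next
    plus <- g$strand == "+"
    syn_pos <- if (plus) b + 901L else b + 899L
    syn_alt <- if (plus) "C" else "G"
    mis_pos <- b + 960L
    mis_alt <- if (plus) "T" else "A"
    add(mk(g$chrom, syn_pos, "null", consequence = "cds_synonymous", alt = syn_alt))
    add(mk(g$chrom, mis_pos, "null", consequence = "cds_missense", alt = mis_alt))
    add(mk(g$chrom, b + 100L, "null",
           consequence = if (plus) "five_prime_utr" else "three_prime_utr"))
    add(mk(g$chrom, b + 1900L, "null",
           consequence = if (plus) "three_prime_utr" else "five_prime_utr"))
    add(mk(g$chrom, b + 330L, "null", consequence = "intron"))
    add(mk(g$chrom, b - 500L, "null",
           consequence = if (plus) "upstream" else "downstream"))
    add(mk(g$chrom, b + 2499L, "null",
           consequence = if (plus) "downstream" else "upstream"))
  }

  # context violations, one rule each
  ctx_each <- n_ctx %/% 4L
  ctx_counts <- c(junction = n_ctx - 3L * ctx_each, paralog = ctx_each,
                  ssr = ctx_each, bidirectional = ctx_each)
  jpos <- list()
  for (g in layout$genes) {
    if (g$slot == 0L || is.null(g$cds)) next
    for (bd in c(g$exons[1, "end"], g$exons[2, "start"] - 1L,
                 g$exons[2, "end"], g$exons[3, "start"] - 1L)) {
      jpos[[length(jpos) + 1L]] <- data.frame(chrom = g$chrom, pos = bd + 2L)
    }
  }
  jpos <- do.call(rbind, jpos)
  if (nrow(jpos) < ctx_counts[["junction"]]) stop("infeasible: junction sites")
  for (i in seq_len(ctx_counts[["junction"]])) {
    add(mk(jpos$chrom[i], jpos$pos[i], "context_junction"))
  }
  ppos <- list()
  for (p in layout$paralog) {
    for (off in seq(50L, 330L, by = 70L)) {
      ppos[[length(ppos) + 1L]] <- data.frame(chrom = p$chrom, pos = p$start + off)
    }
  }
  ppos <- do.call(rbind, ppos)
  if (nrow(ppos) < ctx_counts[["paralog"]]) stop("infeasible: paralog sites")
  for (i in seq_len(ctx_counts[["paralog"]])) {
    add(mk(ppos$chrom[i], ppos$pos[i], "context_paralog"))
  }
  spos <- do.call(rbind, lapply(layout$ssr, function(s) {
    data.frame(chrom = s$chrom, pos = s$start + 3L)
  }))
  if (nrow(spos) < ctx_counts[["ssr"]]) stop("infeasible: SSR sites")
  for (i in seq_len(ctx_counts[["ssr"]])) {
    add(mk(spos$chrom[i], spos$pos[i], "context_ssr"))
  }
  bpos <- list()
  for (c_idx in seq_len(config$n_chroms)) {
    b <- .SLOT0 + 1L
    cand <- b + seq(1010L, 1980L, by = 33L)
    excl <- b + c(1195:1205, 1395:1405, 1695:1705)
    cand <- setdiff(cand, excl)
    bpos[[c_idx]] <- data.frame(chrom = paste0("chr", c_idx), pos = cand)
  }
  bpos <- do.call(rbind, bpos)
  if (nrow(bpos) < ctx_counts[["bidirectional"]]) stop("infeasible: bidirectional sites")
  for (i in seq_len(ctx_counts[["bidirectional"]])) {
    add(mk(bpos$chrom[i], bpos$pos[i], "context_bidirectional"))
  }

  # editing sites and in-SINE decoys from the SINE tracks
  sine_list <- layout$sine
  n_in_sine_decoy <- 3L * (n_decoy %/% 4L)
  canon_for <- function(sine) {
    if (sine$context == "intronic") {
      if (sine$gene_strand == "+") list(c("A", "G", "A_to_I", "+"),
                                        c("C", "T", "C_to_U", "+"))
      else list(c("T", "C", "A_to_I", "-"), c("G", "A", "C_to_U", "-"))
    } else {
      list(c("A", "G", "A_to_I", "+"), c("C", "T", "C_to_U", "+"),
           c("T", "C", "A_to_I", "-"), c("G", "A", "C_to_U", "-"))
    }
  }
  sine_sites <- list()
  for (i in seq_along(sine_list)) {
    s <- sine_list[[i]]
    pats <- canon_for(s)
    taken <- integer(0)
    for (j in seq_along(pats)) {
      if (length(taken) >= 2L) break
      pat <- pats[[(i + j) %% length(pats) + 1L]]
      cand <- .find_base_positions(seqs[[s$chrom]], s$start + 20L, s$end - 20L,
                                   pat[1])
      cand <- cand[vapply(cand, function(p) all(abs(p - taken) >= 60L), logical(1))]
      if (!length(cand)) next
      taken <- c(taken, cand[1])
      sine_sites[[length(sine_sites) + 1L]] <- data.frame(
        chrom = s$chrom, pos = cand[1], ref = pat[1], alt = pat[2],
        etype = pat[3], estrand = pat[4], stringsAsFactors = FALSE)
    }
  }
  sine_sites <- do.call(rbind, sine_sites)
  if (nrow(sine_sites) < n_edit + n_in_sine_decoy) {
    stop("infeasible: not enough canonical positions inside SINE intervals")
  }
  for (i in seq_len(n_edit)) {
    r <- sine_sites[i, ]
    add(mk(r$chrom, r$pos, "editing", "planted", aaf1 = 0.45, aaf2 = 0.05,
           ref = r$ref, alt = r$alt, etype = r$etype, estrand = r$estrand,
           differential = TRUE))
  }
  decoy_rows <- sine_sites[n_edit + seq_len(n_in_sine_decoy), , drop = FALSE]
  decoy_kinds <- rep(c("decoy_rsid", "decoy_ceiling", "decoy_nonsig"),
                     each = n_decoy %/% 4L)
  for (i in seq_len(n_in_sine_decoy)) {
    r <- decoy_rows[i, ]
    kind <- decoy_kinds[i]
    add(mk(r$chrom, r$pos, "editing_decoy", kind,
           aaf1 = if (kind == "decoy_nonsig") 0.30 else 0.45,
           aaf2 = if (kind == "decoy_nonsig") 0.30 else 0.05,
           ref = r$ref, alt = r$alt, etype = r$etype, estrand = r$estrand,
           differential = kind != "decoy_nonsig"))
  }

  ## clean-grid assignment (streamed)
  used <- do.call(rbind, plan)
  plan_sites <- with_stream(config$seed, "positions", {
    # proximity groups first: consecutive grid points so members stay clear
    # of every other site
    n_pairs <- round(n_prox * 0.5) %/% 2L
    n_trip <- (n_prox - 2L * n_pairs) %/% 3L
    n_prox_actual <- 2L * n_pairs + 3L * n_trip
    gi <- 1L
    take_group <- function(sz) {
      # consume two adjacent grid points on one chromosome
      repeat {
        if (gi + 1L > nrow(grid)) stop("infeasible: grid exhausted (proximity)")
        a <- grid[gi, ]; b2 <- grid[gi + 1L, ]
        gi <<- gi + 2L
        if (a$chrom == b2$chrom && b2$pos - a$pos == 50L) {
          return(if (sz == 2L) data.frame(chrom = a$chrom, pos = a$pos + c(0L, 30L))
                 else data.frame(chrom = a$chrom, pos = a$pos + c(0L, 15L, 30L)))
        }
      }
    }
    for (i in seq_len(n_pairs)) {
      g <- take_group(2L)
      for (j in 1:2) add(mk(g$chrom[j], g$pos[j], "proximity_fail"))
    }
    for (i in seq_len(n_trip)) {
      g <- take_group(3L)
      for (j in 1:3) add(mk(g$chrom[j], g$pos[j], "proximity_fail"))
    }
    rest <- grid[gi:nrow(grid), , drop = FALSE]
    rest <- rest[sample.int(nrow(rest)), , drop = FALSE]
    # sine-rule editing decoys need a canonical-capable base (A -> G works
    # anywhere outside genes: unique implied strand)
    n_out_decoy <- n_decoy %/% 4L
    is_A <- vapply(seq_len(nrow(rest)), function(i) {
      .base_at(seqs[[rest$chrom[i]]], rest$pos[i]) == "A"
    }, logical(1))
    a_idx <- which(is_A)[seq_len(n_out_decoy)]
    for (i in a_idx) {
      add(mk(rest$chrom[i], rest$pos[i], "editing_decoy", "decoy_sine",
             aaf1 = 0.45, aaf2 = 0.05, ref = "A", alt = "G",
             etype = "A_to_I", estrand = "+", differential = TRUE))
    }
    if (length(a_idx)) rest <- rest[-a_idx, , drop = FALSE]
    # `used` already holds exemplars, context fails, editing and in-SINE decoys
    n_planned <- nrow(used) + n_prox_actual + n_out_decoy
    n_null <- n_sites - n_planned - n_ase - n_qual - n_sparse
    if (n_null < 0) stop("infeasible: fractions exceed n_sites")
    need <- n_ase + n_qual + n_sparse + n_null
    if (nrow(rest) < need) stop("infeasible: clean grid too small (need ",
                                need, ", have ", nrow(rest), ")")
    cls <- c(rep("ase", n_ase), rep("quality_fail", n_qual),
             rep("sparse", n_sparse), rep("null", n_null))
    ase_sign <- sample(c(-1, 1), n_ase, replace = TRUE)
    null_aaf <- sample(seq(0.10, 0.90, by = 0.05), n_qual + n_sparse + n_null,
                       replace = TRUE)
    kq <- 0L
    for (i in seq_along(cls)) {
      if (cls[i] == "ase") {
        a1 <- 0.5 + ase_sign[i] * config$delta_aaf_planted
        add(mk(rest$chrom[i], rest$pos[i], "ase", aaf1 = a1, aaf2 = 0.5,
               differential = TRUE))
      } else {
        kq <- kq + 1L
        add(mk(rest$chrom[i], rest$pos[i], cls[i], aaf1 = null_aaf[kq],
               aaf2 = null_aaf[kq]))
      }
    }
    do.call(rbind, plan)
  })
  truth <- plan_sites
  # shared-AAF defaults for classes planted before the stream (exemplars,
  # context fails, decoys already carry targets)
  fill <- is.na(truth$true_aaf_g1)
  truth$true_aaf_g1[fill] <- 0.5
  truth$true_aaf_g2[fill] <- 0.5
  ord <- order(truth$chrom, truth$pos)
  truth <- truth[ord, , drop = FALSE]
  rownames(truth) <- NULL
  if (anyDuplicated(paste(truth$chrom, truth$pos))) {
    stop("internal: duplicate planted positions")
  }

  ## ---- counts, quality annotations, ids ------------------------------------
  n <- nrow(truth)
  samples <- .sample_names(config)
  design <- sim_design(config)
  refm <- matrix(0L, n, n_smp); altm <- matrix(0L, n, n_smp)
  with_stream(config$seed, "counts", {
    rho <- config$overdispersion_rho
    g1_cols <- seq_len(n_grp); g2_cols <- n_grp + seq_len(n_grp)
    for (i in seq_len(n)) {
      cls <- truth$class[i]; ecl <- truth$editing_class[i]
      banded <- ecl %in% c("planted", "decoy_sine", "decoy_rsid",
                           "decoy_ceiling", "decoy_nonsig")
      min_d <- if (banded) 20L else 0L
      depth <- .rdepth(n_smp, config$depth_mean, min_d)
      a1 <- truth$true_aaf_g1[i]; a2 <- truth$true_aaf_g2[i]
      if (cls == "sparse") {
        alt <- integer(n_smp)
        supp <- sample.int(n_smp, 3L)
        alt[supp] <- pmax(1L, .ralt(depth[supp], 0.4, rho))
      } else if (banded) {
        band <- if (ecl == "decoy_nonsig") 0.04 else 0.10
        alt <- c(.ralt_banded(depth[g1_cols], a1, band),
                 .ralt_banded(depth[g2_cols], a2, band))
        if (ecl == "decoy_ceiling") {
          alt[1L] <- as.integer(ceiling(depth[1L] * 0.75))
        }
      } else {
        for (try in 1:25) {
          alt <- c(.ralt(depth[g1_cols], a1, rho), .ralt(depth[g2_cols], a2, rho))
          supported <- sum(alt > 0L & depth > 0L)
          if (supported >= ceiling(0.5 * n_smp)) break
        }
      }
      altm[i, ] <- alt
      refm[i, ] <- depth - alt
    }
  })
  qual <- with_stream(config$seed, "quality", {
    q <- data.frame(MQ = round(stats::runif(n, 45, 60), 2),
                    DP = as.integer(rowSums(refm + altm)),
                    QD = round(stats::runif(n, 5, 25), 2),
                    ReadPosRankSum = round(stats::runif(n, -2, 2), 3),
                    MQRankSum = round(stats::runif(n, -2, 2), 3))
    fail_keys <- c("MQ", "DP", "QD", "ReadPosRankSum", "MQRankSum")
    fail_vals <- list(MQ = 35, DP = 8L, QD = 1.5, ReadPosRankSum = -9,
                      MQRankSum = -13)
    qi <- which(truth$class == "quality_fail")
    for (j in seq_along(qi)) {
      key <- fail_keys[(j - 1L) %% 5L + 1L]
      q[[key]][qi[j]] <- fail_vals[[key]]
    }
    q
  })
  ids <- with_stream(config$seed, "ids", {
    id <- rep(NA_character_, n)
    eligible <- truth$editing_class == "none" & truth$class %in% c("null", "ase")
    pick <- which(eligible & stats::runif(n) < 0.08)
    id[pick] <- paste0("rs", sample(1e6, length(pick)))
    id[truth$editing_class == "decoy_rsid"] <-
      paste0("rs9", sample(1e5, sum(truth$editing_class == "decoy_rsid")))
    id
  })
  ref <- vapply(seq_len(n), function(i) .base_at(seqs[[truth$chrom[i]]],
                                                 truth$pos[i]), character(1))
  forced <- !is.na(truth$ref_forced)
  if (any(forced & ref != truth$ref_forced)) {
    stop("internal: planted base mismatch")
  }
  alt <- with_stream(config$seed, "alt_alleles", {
    vapply(seq_len(n), function(i) {
      if (!is.na(truth$alt_forced[i])) truth$alt_forced[i]
      else sample(setdiff(.BASES, ref[i]), 1L)
    }, character(1))
  })
  sites <- data.frame(chrom = truth$chrom, pos = truth$pos, ref = ref,
                      alt = alt, id = ids, MQ = qual$MQ, DP = qual$DP,
                      QD = qual$QD, ReadPosRankSum = qual$ReadPosRankSum,
                      MQRankSum = qual$MQRankSum, ad_missing = FALSE,
                      stringsAsFactors = FALSE)
  cnt <- cbind(as.data.frame(refm), as.data.frame(altm))
  names(cnt) <- c(paste0("ref_", samples), paste0("alt_", samples))
  sites <- cbind(sites, cnt)
  list(sites = .new_variant_table(sites, samples), truth = truth,
       design = design)
}
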