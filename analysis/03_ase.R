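#!/usr/bin/env Rscript

# Step 3 — differential allelic expression. Computes group allele fractions,
# the binomial likelihood-ratio p-value with BH correction, the chi-square
# allelic-balance category, flags ASE events at the operating point
# (|dAAF| > 0.1, FDR < 0.001, balance p < 0.05), and annotates flagged sites
# with their codon-aware consequence class.

suppressPackageStartupMessages(library(aseditr))

p <- function(x) file.path("results/sim", x)
design_df <- read_result_tsv(p("design.tsv"))
design <- group_design(design_df$sample, design_df$group)
genome <- read_fasta(p("genome.fa"))
ann <- read_gtf(p("annotation.gtf"))
sites <- read_variants("results/sites_filtered.tsv", design$samples)

res <- classify_ase(ase_table(sites, design))
res$consequence <- NA_character_
flagged <- which(res$ase_flag)
if (length(flagged)) {
  sub <- sites[flagged, , drop = FALSE]
  attr(sub, "samples") <- variant_samples(sites)
  res$consequence[flagged] <- annotate_consequence(sub, ann, genome)
}
write_result_tsv(res, "results/ase_results.tsv")

cat(sprintf("%d of %d tested sites flagged as ASE\n", sum(res$ase_flag),
            sum(!is.na(res$p_value))))
cat("Allelic-balance categories of flagged sites:\n")
print(table(res$category[res$ase_flag]))
cat("Consequence classes of flagged sites:\n")
print(table(res$consequence[res$ase_flag]))
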