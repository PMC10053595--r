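#!/usr/bin/env Rscript

# Step 4 — RNA-editing candidates. From the cascade survivors, keeps
# strand-resolved canonical A-to-I / C-to-U substitutions that pass the
# editing-efficiency ceiling (no sample AAF > 0.7), carry no known-SNP id,
# overlap the SINE track, and meet FDR < 0.05 with |dAAF| > 0.1; then
# intersects them with the (synthetic) known-editing-site table.

suppressPackageStartupMessages(library(aseditr))

p <- function(x) file.path("results/sim", x)
design_df <- read_result_tsv(p("design.tsv"))
design <- group_design(design_df$sample, design_df$group)
ann <- read_gtf(p("annotation.gtf"))
sites <- read_variants("results/sites_filtered.tsv", design$samples)
ase <- read_result_tsv("results/ase_results.tsv")
stopifnot(identical(paste(sites$chrom, sites$pos), paste(ase$chrom, ase$pos)))

ed <- editing_filter(sites, ase, ann, read_bed(p("sine.bed")))
known <- read_result_tsv(p("known_editing_synthetic.tsv"))
cand <- intersect_known(ed$candidates, known)

write_result_tsv(cand, "results/editing_candidates.tsv")
write_result_tsv(ed$audit, "results/editing_audit.tsv")

cat(sprintf("%d canonical candidates audited; %d survive all four rules\n",
            nrow(ed$audit), nrow(cand)))
print(table(type = cand$editing_type, strand = cand$resolved_strand))
cat(sprintf("%d candidates match known editing records\n",
            sum(!is.na(cand$known_site_match))))
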