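#!/usr/bin/env Rscript

# Step 5 — consensus lncRNA identification. Structural filter (>= 200 nt,
# multi-exonic, non-protein-coding, above the expression floor), the 3-of-5
# coding-potential vote (CPAT < 0.78, CPC2 < 0, FEELnc < 0.558, CNCI/PLEK
# noncoding), and Pfam/Rfam exclusion; known lncRNA-biotype transcripts join
# the pool directly.

suppressPackageStartupMessages(library(aseditr))

p <- function(x) file.path("results/sim", x)
transcripts <- read_result_tsv(p("transcripts.tsv"))
scores <- read_result_tsv(p("scores.tsv"))
evidence <- read_result_tsv(p("domain_evidence.tsv"))
evidence$has_rfam_hit <- as.logical(evidence$has_rfam_hit)

lnc <- identify_lncrna(transcripts, scores, evidence, min_expression = 1)
write_result_tsv(lnc, "results/lncrna.tsv")

cat(sprintf("%d of %d candidate transcripts identified as lncRNAs\n",
            nrow(lnc), nrow(transcripts)))
cat(sprintf("  known biotype: %d; novel by consensus vote: %d\n",
            sum(lnc$is_known_lncrna), sum(!lnc$is_known_lncrna)))
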