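#!/usr/bin/env Rscript

# Step 1 — generate the synthetic study: a two-chromosome genome with planted
# gene models, SINE/paralog/SSR tracks, a 10,000-site variant cohort over two
# groups of five replicates, and expression/score tables with planted
# lncRNA-gene interactions. All downstream steps read the files written here.

suppressPackageStartupMessages(library(aseditr))

cfg <- sim_config(seed = 1)
sim <- simulate_all(cfg, outdir = "results/sim")

cat("Simulated study written to results/sim/\n")
cat(sprintf("  genome: %d chromosomes x %d bp\n", cfg$n_chroms, cfg$chrom_length))
cat(sprintf("  gene models: %d genes / %d transcripts\n",
            nrow(sim$reference$annotation$genes),
            nrow(sim$reference$annotation$transcripts)))
cat(sprintf("  variant sites: %d over %d samples\n",
            nrow(sim$variants$sites), length(variant_samples(sim$variants$sites))))
cat("  planted site classes:\n")
print(table(sim$variants$truth$class))
cat(sprintf("  lncRNA candidates: %d transcripts (%d expected lncRNAs)\n",
            nrow(sim$expression$transcripts),
            sum(sim$expression$truth$lncrna$expected)))
cat(sprintf("  planted trans interactions: %d; cis pairs by construction: %d\n",
            nrow(sim$expression$truth$trans), nrow(sim$expression$truth$cis)))
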