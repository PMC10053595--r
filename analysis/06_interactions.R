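#!/usr/bin/env Rscript

# Step 6 — lncRNA-gene interaction triage. Cis pairs by genomic proximity
# (edge-to-edge gap <= 10 kb); trans pairs by cross-sample co-expression
# (|r| > 0.9, p < 0.05) backed by binding evidence (ndG < -0.1 or binding
# probability > 0.9).

suppressPackageStartupMessages(library(aseditr))

p <- function(x) file.path("results/sim", x)
em <- read_result_tsv(p("expression.tsv"))
expr <- as.matrix(em[, -1, drop = FALSE])
rownames(expr) <- em$feature_id
del_ids <- readLines(p("del_ids.txt"))
deg_ids <- readLines(p("deg_ids.txt"))

pairs <- correlate_pairs(expr, del_ids, deg_ids)
key <- function(d) paste(d$del_id, d$deg_id)
ndg <- read_result_tsv(p("ndg.tsv"))
prob <- read_result_tsv(p("prob.tsv"))
pairs$ndg <- ndg$ndg[match(key(pairs), key(ndg))]
pairs$binding_prob <- prob$prob[match(key(pairs), key(prob))]
trans <- trans_triage(pairs)

ann <- read_gtf(p("annotation.gtf"))
del_loci <- read_bed(p("del_loci.bed"))
del_loci$id <- del_loci$name
genes <- ann$genes[match(deg_ids, ann$genes$gene_id), ]
deg_loci <- GenomicRanges::GRanges(genes$chrom,
                                   IRanges::IRanges(genes$start, genes$end))
deg_loci$id <- genes$gene_id
cis <- cis_pairs(del_loci, deg_loci)

write_result_tsv(trans, "results/trans_interactions.tsv")
write_result_tsv(cis, "results/cis_interactions.tsv")

cat(sprintf("%d of %d DEL-DEG pairs retained as trans interactions:\n",
            nrow(trans), nrow(pairs)))
print(trans[, c("del_id", "deg_id", "r", "direction")])
cat(sprintf("%d cis pairs within 10 kb\n", nrow(cis)))
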