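#!/usr/bin/env Rscript
# Stage 5: expression quantification and differential expression.
#
# FPKM from union-exon lengths, then the NB Wald test with
# median-of-ratios normalisation; genes are called at the fold-change
# rule (FC > 2 or FC < 0.5) with raw p < 0.05.

suppressPackageStartupMessages(library(popsweep))

ct <- read_counts("results/data/counts.tsv", "results/data/groups.tsv",
                  "results/data/mapped_reads.tsv")
genes <- read_gff("results/data/genes.gff3")
truth <- jsonlite::read_json("results/data/truth.json", simplifyVector = TRUE)

fp <- fpkm(ct, genes)
write.table(data.frame(gene_id = rownames(fp), round(fp, 4),
                       check.names = FALSE),
            "results/fpkm.tsv", sep = "\t", quote = FALSE, row.names = FALSE)

degs <- call_degs(deg_test(ct))
write.table(degs, "results/degs.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
ud <- deg_lists(degs)

called <- c(ud$up, ud$down)
sens <- mean(truth$de_genes %in% called)
fdp <- if (length(called)) mean(!called %in% truth$de_genes) else 0
cat(sprintf("genes tested: %d; up-regulated: %d, down-regulated: %d\n",
            nrow(degs), length(ud$up), length(ud$down)))
cat(sprintf("planted-DE sensitivity: %.1f%%, false discovery proportion: %.1f%%\n",
            100 * sens, 100 * fdp))
cat(sprintf("median FPKM across genes: %.2f\n", median(fp)))
cat("wrote results/fpkm.tsv, results/degs.tsv\n")
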