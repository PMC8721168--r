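#!/usr/bin/env Rscript
# Stage 3: windowed selection scan and joint outlier calling.
#
# For each selected-vs-control comparison: per-window theta-pi for both
# populations and Weir-Cockerham FST (40-kb windows, 20-kb steps), the
# log2 diversity ratio (control/selected), and the joint top-5% rule.
# Outlier windows are merged and mapped to overlapping genes; the two
# forward comparisons are intersected, mirroring the shared-signal Venn.

suppressPackageStartupMessages(library(popsweep))

gm <- read_vcf("results/filtered.vcf", "results/data/samples.tsv")
cohort <- yaml::read_yaml("results/data/cohort.yaml")
genes <- read_gff("results/data/genes.gff3")
truth <- jsonlite::read_json("results/data/truth.json", simplifyVector = TRUE)
windows <- make_windows(unlist(cohort$chrom_lengths))
key <- function(d) paste(d$chrom, d$start, d$end)

gene_sets <- list()
for (cmp in cohort$comparisons) {
  lbl <- sprintf("%s_vs_%s", cmp$selected, cmp$control)
  sw <- scan_windows(gm, cmp$selected, cmp$control, windows = windows)
  call <- joint_outliers(sw)
  gene_sets[[lbl]] <- windows_to_genes(call, genes)
  write.table(call$windows, sprintf("results/scan_%s.tsv", lbl),
              sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(gene_sets[[lbl]], sprintf("results/sweep_genes_%s.txt", lbl))
  tw <- truth$sweep_windows[truth$sweep_windows$selected_pop == cmp$selected, ]
  recall <- if (nrow(tw))
    mean(key(tw) %in% key(call$windows[call$windows$outlier, ])) else NA
  cat(sprintf(
    "%s: %d/%d outlier windows (FST >= %.3f, log2 ratio >= %.3f), %d genes%s\n",
    lbl, call$n_outliers, call$n_rankable, call$fst_threshold,
    call$ratio_threshold, length(gene_sets[[lbl]]),
    if (!is.na(recall)) sprintf(", truth-window recall %.0f%%", 100 * recall)
    else ""))
}

venn <- overlap_sets(gene_sets[c("A_vs_C", "B_vs_C")])
jsonlite::write_json(list(counts = as.list(venn$counts),
                          shared = venn$members$`A_vs_C&B_vs_C`),
                     "results/sweep_venn.json", auto_unbox = TRUE,
                     digits = NA, pretty = TRUE)
cat(sprintf("shared selected genes, A_vs_C and B_vs_C: %d\n",
            venn$counts[["A_vs_C&B_vs_C"]]))
cat("wrote results/scan_*.tsv, results/sweep_genes_*.txt, results/sweep_venn.json\n")
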