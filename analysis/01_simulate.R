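#!/usr/bin/env Rscript
# Stage 1: simulate the study cohort.
#
# Three diverged populations (A and B: two "selected" breeds, C: the
# control breed; 8 + 8 + 7 diploid individuals, matching a 23-animal
# resequencing panel) genotyped at 50k SNPs over two 5-Mb chromosomes at
# ~7x depth, with one 400-kb sweep region planted per chromosome
# (diversity reduced to 20% in the selected population, differentiation
# boosted by 0.3), a 1,000-gene annotation, and a 4-vs-4 RNA-seq count
# matrix with 200 planted DE genes, 10 of them inside sweep regions.

suppressPackageStartupMessages(library(popsweep))

dir.create("results/data", recursive = TRUE, showWarnings = FALSE)
seed <- 20260401L

cfg <- sim_config(seed = seed,
                  rnaseq = list(n_genes = 1000L, n_de = 100L,
                                n_de_in_sweep = 10L))

sim <- simulate_genotypes(cfg)
genes <- simulate_annotation(cfg)
cnt <- simulate_counts(cfg, gene_models = genes)

write_vcf(sim$gm, "results/data/cohort.vcf", cfg$chrom_lengths)
write.table(data.frame(sample = names(sim$gm$pop_labels),
                       population = unname(sim$gm$pop_labels)),
            "results/data/samples.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write_gff(genes, "results/data/genes.gff3")
write_counts(cnt$ct, "results/data/counts.tsv", "results/data/groups.tsv",
             "results/data/mapped_reads.tsv")
jsonlite::write_json(
  list(seed = seed,
       sweep_regions = sim$truth$sweep_regions,
       sweep_windows = sim$truth$sweep_windows,
       de_genes = cnt$truth$de_genes,
       de_sign = as.list(cnt$truth$de_sign),
       size_factors = as.list(cnt$truth$size_factors)),
  "results/data/truth.json", auto_unbox = TRUE, digits = NA, pretty = TRUE)
yaml::write_yaml(list(seed = seed,
                      chrom_lengths = as.list(cfg$chrom_lengths),
                      comparisons = list(
                        list(selected = "A", control = "C"),
                        list(selected = "B", control = "C"),
                        list(selected = "C", control = "A"),
                        list(selected = "C", control = "B"))),
                 "results/data/cohort.yaml")

print(sim$gm)
cat(sprintf("planted sweep windows: %d (truth for the scan stage)\n",
            nrow(sim$truth$sweep_windows)))
cat(sprintf("planted DE genes: %d (%d inside sweep regions)\n",
            length(cnt$truth$de_genes),
            sum(cnt$truth$de_genes %in%
                  genes$gene_id[(genes$chrom == "chr1" &
                                   genes$start >= 2e6 & genes$end <= 2.4e6) |
                                  (genes$chrom == "chr2" &
                                     genes$start >= 2e6 & genes$end <= 2.4e6)])))
cat("wrote results/data/{cohort.vcf,samples.tsv,genes.gff3,counts.tsv,truth.json}\n")
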