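#!/usr/bin/env Rscript
# Stage 4: population structure.
#
# Allele-sharing distances between all individuals, a neighbor-joining
# tree with SNP-bootstrap support (200 replicates at this desk scale; the
# package default is 1,000), and Patterson-scaled PCA.

suppressPackageStartupMessages(library(popsweep))

gm <- read_vcf("results/filtered.vcf", "results/data/samples.tsv")
cohort <- yaml::read_yaml("results/data/cohort.yaml")

tree <- bootstrap_support(gm, n_boot = 200, seed = cohort$seed + 1L)
ape::write.tree(tree, "results/nj_tree.nwk")

pca <- pca_genotypes(gm, k = 6)
scores <- data.frame(sample = rownames(pca$scores),
                     population = unname(gm$pop_labels[rownames(pca$scores)]),
                     pca$scores)
write.table(scores, "results/pca_scores.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

# support of each population's bipartition
pp <- ape::prop.part(tree)
for (pop in unique(gm$pop_labels)) {
  tips <- which(tree$tip.label %in% names(gm$pop_labels)[gm$pop_labels == pop])
  node <- which(vapply(pp, function(cl)
    setequal(cl, tips) || setequal(cl, setdiff(seq_along(tree$tip.label), tips)),
    logical(1)))
  cat(sprintf("population %s monophyletic: %s (bootstrap %s)\n", pop,
              length(node) > 0,
              if (length(node)) max(tree$node.label[node]) else "-"))
}
cat(sprintf("PC1/PC2 variance explained: %.1f%% / %.1f%%\n",
            100 * pca$varexp[1], 100 * pca$varexp[2]))
agg <- aggregate(scores$PC1, list(pop = scores$population), range)
print(agg)
cat("wrote results/nj_tree.nwk, results/pca_scores.tsv\n")
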