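#!/usr/bin/env Rscript
# Stage 2: SNP quality control.
#
# Applies the three site filters -- Phred quality >= 20, minimum 5-bp
# spacing with both members of a close pair removed, and site depth
# within [1/3, 5] times the genome-wide average -- all evaluated on the
# pre-filter site set, then removes the union of flags.

suppressPackageStartupMessages(library(popsweep))

gm <- read_vcf("results/data/cohort.vcf", "results/data/samples.tsv")
cohort <- yaml::read_yaml("results/data/cohort.yaml")

res <- apply_filters(gm)
rep <- res$report
write_vcf(res$gm, "results/filtered.vcf",
          unlist(cohort$chrom_lengths))
jsonlite::write_json(rep, "results/filter_report.json", auto_unbox = TRUE,
                     digits = NA, pretty = TRUE)

cat(sprintf("input SNPs:          %d\n", rep$n_input))
cat(sprintf("fail quality (<Q20): %d (%.2f%%)\n", rep$n_fail_qual,
            100 * rep$n_fail_qual / rep$n_input))
cat(sprintf("fail 5-bp spacing:   %d (%.2f%%)\n", rep$n_fail_spacing,
            100 * rep$n_fail_spacing / rep$n_input))
cat(sprintf("fail depth bounds:   %d (%.2f%%), mean depth %.1f\n",
            rep$n_fail_depth, 100 * rep$n_fail_depth / rep$n_input,
            rep$mean_depth_used))
cat(sprintf("passing SNPs:        %d (%.2f%%)\n", rep$n_pass,
            100 * rep$n_pass / rep$n_input))
cat("wrote results/filtered.vcf, results/filter_report.json\n")
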