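# popsweep

Selective-sweep scanning with transcriptome integration for small
resequencing cohorts of diverged populations (livestock breeds, local
varieties), built as a tested R package plus a numbered analysis
workflow.

The scientific question it serves: *which genes differentiate a
selected population from a control population at both the genome and
the transcriptome level?* The workflow answers it in five steps:

1. **SNP quality control** — remove sites with Phred quality < 20,
   SNP pairs closer than 5 bp (both members), and sites whose depth
   falls outside [1/3, 5] × the genome-wide average.
2. **Windowed selection scan** — in 40-kb windows sliding by 20 kb,
   compute per-population nucleotide diversity θπ (per-bp, span
   normalised) and Weir–Cockerham FST as a ratio of summed variance
   components, `Σa / Σ(a+b+c)`. A window is a sweep candidate iff it is
   simultaneously in the top 5% of FST *and* of
   `log2(θπ_control / θπ_selected)`; merged outlier windows are mapped
   to overlapping genes.
3. **Population structure** — allele-sharing distances, a
   neighbor-joining tree with SNP-bootstrap support, and
   EIGENSOFT-style PCA (per-site scaling by `sqrt(p(1−p))`).
4. **Differential expression** — FPKM
   (`count / (mapped_reads/10⁶ × exon_kb)`, union-exon lengths) and a
   shrinkage-free NB Wald test with median-of-ratios normalisation;
   genes called at FC > 2 or FC < 0.5 with p < 0.05.
5. **Integration** — candidate genes are the exact intersection of
   sweep genes with the called DEGs, with hypergeometric
   over-representation against a user-supplied term map.

Because workflows like this are published without their raw data, the
package ships a synthetic-data generator with exactly known truth:
Balding–Nichols population frequencies at a configurable background
FST, deterministic sweep transformations (diversity reduced to a set
fraction, differentiation boosted) in declared regions, a matching
gene annotation, and NB count matrices with planted fold changes —
optionally planted *inside* sweep regions so the headline intersection
has known positives.

## Worked example

The `analysis/` scripts run the whole study on the default synthetic
cohort (23 animals in three populations A, B, C; 50k SNPs on two 5-Mb
chromosomes; one 400-kb sweep per chromosome — selected in A on chr1,
in C on chr2; 4-vs-4 RNA-seq with 100 planted DE genes, 10 inside
sweep regions):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_filter_snps.R
Rscript analysis/03_sweep_scan.R
Rscript analysis/04_population_structure.R
Rscript analysis/05_expression.R
Rscript analysis/06_integration.R
```

Output of the QC stage:

```
input SNPs:          50000
fail quality (<Q20): 2490 (4.98%)
fail 5-bp spacing:   1938 (3.88%)
fail depth bounds:   3462 (6.92%), mean depth 168.5
passing SNPs:        42500 (85.00%)
```

The planted 5% sub-Q20 fraction comes back as 4.98%; the depth rule
works on summed depth across the 23 samples (~7.3× each, hence mean
168.5).

The scan stage, per comparison (selected vs control):

```
A_vs_C: 18/500 outlier windows (FST >= 0.305, log2 ratio >= 0.137), 41 genes, truth-window recall 89%
B_vs_C: 0/500 outlier windows  (FST >= 0.083, log2 ratio >= 0.104), 0 genes
C_vs_A: 7/500 outlier windows  (FST >= 0.305, log2 ratio >= 0.125), 22 genes, truth-window recall 37%
C_vs_B: 21/500 outlier windows (FST >= 0.083, log2 ratio >= 0.157), 44 genes, truth-window recall 95%
```

A's planted sweep is recovered at 89% window recall; B, which carries
no sweep, yields zero joint outliers. The reciprocal C_vs_A comparison
shows an instructive interference: the chr1 sweep in A inflates FST on
chr1 as well, consuming top-5% budget and halving recall of the chr2
sweep — the reason the workflow runs each direction separately and
intersects gene sets afterwards.

Integration (sweep genes ∩ DEGs):

```
candidate_report [A_vs_C]: 41 sweep genes x 101 shared DEGs -> 12 candidates
planted sweep-DE genes recovered: 12/12
```

All planted sweep-DE genes return as candidates; the positional-block
enrichment table flags the block containing the sweep at
padj ≈ 2×10⁻¹⁵.

As a library, each step is one call: `read_vcf()`, `apply_filters()`,
`scan_windows()`, `joint_outliers()`, `windows_to_genes()`,
`bootstrap_support()`, `pca_genotypes()`, `fpkm()`, `deg_test()`,
`call_degs()`, `integrate_candidates()`, `hypergeom_enrich()` — or
`run_pipeline(cfg)` for the whole chain from one (YAML-able)
configuration, which writes a deterministic, timestamp-free output
tree.

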