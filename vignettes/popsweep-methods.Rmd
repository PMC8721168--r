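---
title: "Methods: selective-sweep scanning with transcriptome integration"
author: "popsweep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: selective-sweep scanning with transcriptome integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

popsweep re-implements, as tested and reusable functions, a comparative
genome + transcriptome workflow for small panels of diverged livestock
populations: SNP quality control, a windowed FST / nucleotide-diversity
selection scan with joint top-5% outlier calling, population-structure
summaries, negative-binomial differential-expression calling, and the
intersection of sweep genes with differentially expressed genes into
candidate genes. This vignette documents the statistical model behind
each stage, the tunable parameters and their defaults, what the
synthetic-data generator does and does not emulate, and the numerical
and design choices that were genuinely open.

## SNP quality control

Three site-level rules, all evaluated on the *pre-filter* site set
before the union of flags is removed:

1. **Site quality.** A site is removed when its Phred-scaled quality is
   below 20 (error probability above 1%). Quality exactly 20 is kept:
   the rule is read as "at least Q20". (`min_qual = 20`.)
2. **Spacing.** Two SNPs closer than 5 bp on the same chromosome are
   considered likely artifacts and *both* are removed; removal walks
   along runs, so every member of a cluster of mutually close SNPs
   goes. A distance of exactly 5 bp is allowed. Spacing is evaluated
   per chromosome on the original positions; removing a site cannot
   create a closer pair, so a single pass is exact.
   (`min_spacing_bp = 5`.)
3. **Depth.** Site depth (summed across samples) must lie within
   [1/3, 5] times the genome-wide average depth, bounds inclusive. The
   average is anchored to the pre-filter site set: no iteration scheme
   is applied, which is the simplest single-pass reading of the rule.
   (`low_mult = 1/3`, `high_mult = 5`.)

The "site depth" a depth filter should use is ambiguous in practice
(total over samples vs. per-sample mean). `read_vcf()` takes the INFO
`DP` field when present, else the sum of per-sample `DP`, and records
which source was used; since the bounds are multiplicative in the mean
depth, the choice only matters if sources are mixed, which the reader
refuses to do silently.

## Windowed selection scan

**Windows.** 40-kb windows advancing in 20-kb increments, starting at
0 on each chromosome, truncated at the chromosome end. Windows with at
least one usable SNP enter the ranking (`min_snps = 1`; exposed because
sparser genomes may warrant a higher floor).

**Nucleotide diversity.** Per site, theta-pi is the mean pairwise
difference among sampled alleles, `2 n_ref n_alt / (n (n-1))`, with
missing genotypes dropped site-wise. Window theta-pi sums per-site
values over the window and divides by the *full window span* in bp,
not by the number of variant sites: invariant sites contribute zero
diversity, and span normalisation is what makes swept windows *low*
rather than average. A per-variant-site normalisation is a documented
alternative a user can compute from the emitted columns.

**FST.** The Weir & Cockerham (1984) two-population ANOVA estimator:
per site, the among-population (a), among-individual (b) and
within-individual (c) variance components are computed from allele
frequencies, sample sizes and observed heterozygote frequencies; the
windowed estimate is the ratio of sums `sum(a) / sum(a+b+c)` over the
window's usable sites, which is the standard, low-diversity-stable
combination (a mean of per-site ratios is not). Slightly negative
estimates arise when differentiation is absent and are deliberately
retained in the ranking: clipping at zero would distort the lower tail
against which the top 5% is defined. A Hudson-type estimator
(Bhatia et al. 2013 form) is available as `estimator = "hudson"` for
sensitivity analysis. The estimator identity behind the original
study's scan is not recoverable from its text; Weir-Cockerham is this
package's explicit choice as the field default.

**Joint outliers.** Per window, the log2 diversity ratio
`log2(pi_control / pi_selected)` is large and positive where the
selected population has lost diversity. A window is a sweep candidate
iff it lies simultaneously at or above the empirical 95th percentile of
windowed FST *and* of the log2 ratio (`top_fraction = 0.05`).
Quantiles use the linear-interpolation definition (R type 7) and ties
at the threshold pass — a deterministic, conservative-transparent rule;
the source text does not define tie handling. A window whose selected
population is completely swept (`pi_selected = 0`, control polymorphic)
gets a `+Inf` ratio: it is the strongest possible signal, always passes
the ratio arm, and the reported ratio threshold is computed over the
finite values. Windows with zero diversity in both populations carry no
ranking information and are excluded.

**Window-to-gene mapping.** Outlier windows are merged into maximal
intervals, then a gene is selected iff its interval overlaps a merged
interval by at least 1 bp (coordinates 0-based half-open internally;
GFF's 1-based closed intervals are converted on read). "Any overlap" is
the least-assumption rule; `rule = "contained"` is available where a
stricter call is wanted. Cross-comparison overlaps are exact 2- or
3-set Venn partitions.

## Population structure

**Distance.** Allele-sharing distance between individuals: the mean of
`|dosage_i - dosage_j| / 2` over co-called sites (0 identical, 1
opposite homozygotes throughout). The original study's tree was built
from a distance whose exact model is not documented; allele-sharing is
this package's declared substitute and is computed exactly with
indicator-matrix cross products.

**Tree.** Neighbor-joining (Saitou-Nei, via ape) on the individual
level; NJ's occasionally negative branch lengths are clamped to zero
with the clamped total recorded. Bootstrap support resamples SNP
*columns* with replacement (standard phylogenetic bootstrap
semantics, not sample resampling), rebuilds distance and tree, and
scores each internal bipartition of the full-data tree by its
replicate frequency. The study default is 1,000 replicates
(`n_boot = 1000`); the bundled analysis scripts use 200 at desk scale,
where support for true splits saturates far earlier.

**PCA.** Genotypes are centred by twice the sample allele frequency
and scaled by `sqrt(p(1-p))` (the EIGENSOFT-style binomial scaling);
missing entries are mean-imputed after centring, monomorphic sites
dropped. Because panels here are tens of individuals, the
decomposition is the exact eigendecomposition of the sample covariance
(normalised by the number of sites) rather than an iterative solver,
and signs follow a deterministic largest-score-positive convention so
runs are reproducible to the byte.

## Expression and differential expression

**FPKM.** `count / (mapped_reads/1e6 * exon_kb)` with union-exon
lengths (overlap-merged exon intervals per gene).

**DEG test.** Counts are normalised by median-of-ratios size factors
(geometric-mean reference over all-positive genes, factors rescaled to
geometric mean 1; library-size fallback with a warning when no gene
qualifies). Per gene, the log2 fold change is
`log2((mean2 + 0.5) / (mean1 + 0.5))` of normalised counts — the 0.5
pseudocount defines fold changes for zero-count groups, which the bare
fold-change rule leaves undefined. The NB dispersion is a per-gene
method-of-moments estimate from the pooled within-group variance,
floored at 1e-8; the Wald statistic divides the log2 fold change by a
delta-method standard error from the NB variance `mu + alpha mu^2`,
with two-sided normal p-values and Benjamini-Hochberg adjustment.
Genes are called up when FC > 2 (strictly) and down when FC < 0.5
(strictly) with raw p < 0.05; the raw-p gate is the literal stated
rule, and `use_adjusted = TRUE` switches to the BH-adjusted p, which is
also always emitted.

This is a deliberately transparent, shrinkage-free re-implementation
of NB Wald testing: no dispersion sharing across genes, no fold-change
moderation, no independent filtering. **Known limitation:** with 4
samples per group the per-gene dispersion estimate carries only 6
residual degrees of freedom, so the Wald z behaves like a t(6) variate
under the null and the raw p < 0.05 rate is ~0.09 rather than 0.05
(the suite measures ~0.088 across 10 simulated null datasets of 2,000
genes). Calibrating it to nominal would require exactly the
cross-gene shrinkage this implementation intentionally omits (or a t
reference distribution). In this workflow the fold-change arm of the
DEG rule and the downstream intersection with sweep genes dominate
specificity, and power for 4-fold changes at dispersion 0.05 is
~95-99%; users needing calibrated raw p-values at this sample size
should treat the emitted p-values as anti-conservative.

## Integration and enrichment

Candidate genes are the exact intersection of a comparison's sweep
genes with the called DEG set; when several DEG contrasts are given,
the shared DEG set defaults to their intersection (mirroring a
two-contrasts-versus-common-control design) and is switchable to the
union. Over-representation uses the plain upper-tail hypergeometric
test with BH adjustment, term sets intersected with the background
first. The background defaults to the annotated genes present in the
counts table. No gene-length bias correction is applied (the weighting
function such corrections estimate requires data this workflow does
not assume); and note that *padding the background with genes that
belong to no term can only strengthen apparent enrichment* — the
choice of universe is the analyst's responsibility. Term maps are
user-supplied tables; no GO/KEGG content ships with the package.

## The synthetic cohort

The generator produces the statistical *signature* of sweeps, not
genealogies. Per site, an ancestral allele frequency is drawn from a
Beta(0.7, 0.7) rescaled to (0.05, 0.95) (a U-shaped folded spectrum
without near-fixed sites); each population's frequency is a
Balding-Nichols draw, `Beta(p(1-F)/F, (1-p)(1-F)/F)`, so the target
differentiation F is controlled analytically. Inside a sweep region
the selected population's frequency is transformed deterministically —
pushed toward the nearer boundary so its expected heterozygosity is
multiplied by `diversity_reduction`, then displaced a further
`differentiation_boost` fraction of the remaining distance — which
makes the truth windows exactly known, the property parameter-recovery
tests need. Genotypes are binomial(2, p) per individual; site QUAL has
a configurable sub-Q20 fraction (default 5%) and summed site depth is
negative-binomial around 7.3x per sample (overdispersion 0.3), so both
QC filters have realistic work to do. RNA-seq counts are NB with
log-normal baselines (log-mean 4, log-sd 1.5, dispersion 0.1 — typical
bulk values), true log-normal library-size factors (sd 0.15), and
`n_de` genes given a 2^`lfc_de` fold change in group 2, half up, half
down; optionally a chosen number of DE genes is planted inside sweep
regions so the end-to-end intersection has known positives.

Defaults mirror a 23-animal, three-breed panel (8 + 8 + 7) at 50k SNPs
over two 5-Mb chromosomes with one 400-kb sweep per chromosome, and a
4-vs-4 transcriptome. What the generator does *not* emulate: linkage
disequilibrium beyond what Balding-Nichols sampling induces,
recombination-rate variation, the gradual flanks of real sweeps
(regions here have sharp edges), genotype-calling error correlated
with depth, and gene-length-dependent count bias. Passing tests
therefore demonstrate correctness of the estimators and of the
decision rules under controlled truth, not robustness to every
property of real resequencing data.

All randomness flows from one master seed through named substreams
(genotypes / counts / bootstrap), so stages are reproducible in
isolation and in sequence; two pipeline runs with the same
configuration produce byte-identical output trees (no timestamps are
written).

## Problem sizes used by the test suite

Oracle-equivalence checks run 1,000 random small sites against
enumeration and a scalar transcription of the Weir-Cockerham
equations; null-calibration scans use 50k SNPs (8+8 samples, F = 0);
sweep recovery uses 100k SNPs over 10 Mb with one 400-kb region
(reduction 0.2, boost 0.3) — sized so the truth windows (19) fit
inside the top-5% budget (25 of 500 windows); structure recovery uses
F = 0.2 with 200 bootstrap replicates; DEG calibration uses ten
2,000-gene null datasets. End-to-end runs use a reduced cohort (6k
SNPs, 2x2 Mb, 300 genes) chosen as the smallest size at which every
stage still has unambiguous signal.
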