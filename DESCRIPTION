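Package: popsweep
Title: Selective-Sweep Scanning with Transcriptome Integration for Small Resequencing Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of a comparative genome plus
    transcriptome workflow for diverged livestock populations: SNP
    quality-control filtering (site quality, inter-SNP spacing, depth
    bounds), windowed nucleotide diversity (theta-pi) and Weir-Cockerham
    FST with joint top-5% outlier calling of selective-sweep windows,
    population-structure summaries (allele-sharing distances,
    neighbor-joining tree with bootstrap support, Patterson-scaled PCA),
    FPKM quantification and negative-binomial Wald differential-expression
    calling, and intersection of sweep genes with differentially expressed
    genes into candidate-gene reports with hypergeometric
    over-representation tests. Includes a Balding-Nichols synthetic-data
    generator with planted sweeps and planted differentially expressed
    genes so every stage is testable against known truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
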