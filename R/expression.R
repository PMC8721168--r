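#' FPKM from gene-level counts
#'
#' Fragments per kilobase of exon model per million mapped reads:
#' FPKM\[g, s\] = counts\[g, s\] / (mapped_reads\[s\] / 1e6 *
#' exon_union_kb\[g\]), using each gene's union-exon length.
#'
#' @param ct a [counts_table()].
#' @param genes gene table from [read_gff()] / [simulate_annotation()]
#'   covering every counted gene.
#' @return numeric matrix, genes x samples.
#' @export
fpkm <- function(ct, genes) {
  missing_genes <- setdiff(rownames(ct$counts), genes$gene_id)
  if (length(missing_genes))
    stop("genes missing from the annotation: ",
         paste(utils::head(missing_genes, 5), collapse = ", "),
         if (length(missing_genes) > 5) sprintf(" (and %d more)", length(missing_genes) - 5))
  if (any(ct$mapped_reads <= 0)) stop("zero mapped reads for some samples")
  len_kb <- genes$exon_union_kb[match(rownames(ct$counts), genes$gene_id)]
  ct$counts / outer(len_kb, ct$mapped_reads / 1e6)
}

#' Median-of-ratios size factors
#'
#' For each sample, the median over genes of the ratio of its count to
#' the gene's geometric mean across samples, restricted to genes with
#' all-positive counts; factors are rescaled to geometric mean 1. If no
#' gene is all-positive the factors fall back to relative library sizes,
#' with a warning.
#'
#' @param ct a [counts_table()] or a counts matrix (genes x samples).
#' @return named numeric vector of per-sample size factors.
#' @export
size_factors <- function(ct) {
  counts <- if (inherits(ct, "counts_table")) ct$counts else as.matrix(ct)
  pos <- rowSums(counts == 0) == 0
  if (!any(pos)) {
    warning("no gene has positive counts in every sample; ",
            "falling back to library-size scaling")
    sf <- colSums(counts)
    return(sf / exp(mean(log(sf))))
  }
  lc <- log(counts[pos, , drop = FALSE])
  log_gm <- rowMeans(lc)
  sf <- exp(apply(lc - log_gm, 2, stats::median))
  sf / exp(mean(log(sf)))
}

#' Negative-binomial Wald test for two-group differential expression
#'
#' Counts are normalised by median-of-ratios size factors; per gene, the
#' log2 fold change is log2((mean2 + 0.5) / (mean1 + 0.5)) of normalised
#' counts (pseudocount 0.5 guards zeros), the NB dispersion is a
#' method-of-moments estimate from the pooled within-group variance
#' (floored at 1e-8), and the Wald statistic is log2fc / SE(log2fc) with
#' the standard error from the NB variance mu + alpha * mu^2 through the
#' delta method. Two-sided normal p-values, Benjamini-Hochberg adjusted.
#' All-zero genes get p = 1.
#'
#' This is a deliberately transparent re-implementation of the core of
#' shrinkage-free NB Wald testing: no dispersion sharing across genes,
#' no fold-change moderation, no independent filtering.
#'
#' @param ct a [counts_table()] with exactly two groups, each of at
#'   least 2 samples.
#' @param group_order optional length-2 character vector fixing which
#'   group is the fold-change denominator (group 1) and numerator
#'   (group 2); defaults to the order of first appearance.
#' @return data.frame (one row per gene): `gene_id`, `base_mean`,
#'   `log2fc`, `se`, `stat`, `p`, `padj`.
#' @export
deg_test <- function(ct, group_order = NULL) {
  groups <- ct$group_labels
  lev <- if (is.null(group_order)) unique(groups) else group_order
  if (length(lev) != 2) stop("deg_test needs exactly two groups")
  i1 <- which(groups == lev[1])
  i2 <- which(groups == lev[2])
  if (length(i1) < 2 || length(i2) < 2)
    stop("each group needs at least 2 samples")
  sf <- size_factors(ct)
  norm <- sweep(ct$counts, 2, sf, `/`)
  m1 <- rowMeans(norm[, i1, drop = FALSE])
  m2 <- rowMeans(norm[, i2, drop = FALSE])
  v1 <- apply(norm[, i1, drop = FALSE], 1, stats::var)
  v2 <- apply(norm[, i2, drop = FALSE], 1, stats::var)
  n1 <- length(i1); n2 <- length(i2)
  v_pool <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  base_mean <- (n1 * m1 + n2 * m2) / (n1 + n2)
  alpha <- pmax((v_pool - base_mean) / base_mean^2, 1e-8)
  alpha[base_mean == 0] <- 1e-8

  log2fc <- log2((m2 + 0.5) / (m1 + 0.5))
  # Var(log2 mean_k) ~ (1/mean_k + alpha) / (n_k * ln(2)^2), delta method
  se <- sqrt((1 / (m1 + 0.5) + alpha) / n1 +
             (1 / (m2 + 0.5) + alpha) / n2) / log(2)
  stat <- log2fc / se
  p <- 2 * stats::pnorm(-abs(stat))
  zero <- m1 == 0 & m2 == 0
  p[zero] <- 1
  stat[zero] <- 0
  log2fc[zero] <- 0
  data.frame(gene_id = rownames(ct$counts),
             base_mean = base_mean, log2fc = log2fc, se = se, stat = stat,
             p = p, padj = stats::p.adjust(p, method = "BH"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Call differentially expressed genes at the fold-change + p rule
#'
#' A gene is up-regulated iff its fold change exceeds `fc_hi` (strictly)
#' and the p-criterion holds; down-regulated iff the fold change is
#' below `fc_lo` (strictly) with the p-criterion; otherwise not
#' significant. The default p-criterion is the raw p-value below
#' `alpha`, matching the rule "fold-change > 2 or fold-change < 0.5 and
#' p < 0.05"; set `use_adjusted = TRUE` to threshold the BH-adjusted p
#' instead.
#'
#' @param tab output of [deg_test()].
#' @param fc_hi,fc_lo fold-change bounds (on the linear scale).
#' @param alpha p threshold.
#' @param use_adjusted threshold `padj` instead of `p`.
#' @return `tab` with an added `call` column ("up" / "down" / "ns").
#' @export
call_degs <- function(tab, fc_hi = 2, fc_lo = 0.5, alpha = 0.05,
                      use_adjusted = FALSE) {
  fc <- 2^tab$log2fc
  pcrit <- if (use_adjusted) tab$padj < alpha else tab$p < alpha
  tab$call <- ifelse(pcrit & fc > fc_hi, "up",
              ifelse(pcrit & fc < fc_lo, "down", "ns"))
  tab
}

#' Up/down gene id lists from a called DEG table
#' @param tab output of [call_degs()].
#' @return list with `up` and `down` character vectors.
#' @export
deg_lists <- function(tab) {
  list(up = tab$gene_id[tab$call == "up"],
       down = tab$gene_id[tab$call == "down"])
}
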