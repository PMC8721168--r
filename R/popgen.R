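#' Build a sliding-window grid over the genome
#'
#' Windows start at 0, step, 2*step, ... while the start is inside the
#' chromosome; the final windows are truncated at the chromosome end.
#' Defaults are 40-kb windows advancing in 20-kb increments, the grid of
#' the selection scan.
#'
#' @param chrom_lengths named vector of chromosome lengths in bp.
#' @param size window span (bp).
#' @param step increment between window starts (bp).
#' @return data.frame: `chrom`, `start`, `end` (0-based half-open).
#' @export
make_windows <- function(chrom_lengths, size = 40000, step = 20000) {
  if (step <= 0 || size < step) stop("need size >= step > 0")
  if (any(chrom_lengths <= 0)) stop("non-positive chromosome length")
  out <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    starts <- seq(0, len - 1, by = step)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + size, len), stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Per-population allele and heterozygote counts at every site
#'
#' Missing genotypes are excluded site-wise (pairwise deletion): a sample
#' contributes its two alleles only where it has a call.
#'
#' @param gm a [genotype_matrix()].
#' @param pop population name.
#' @return list of vectors over sites: `n_ref`, `n_alt` (allele counts),
#'   `n_ind` (called diploid individuals), `n_het` (observed
#'   heterozygotes).
#' @export
allele_counts <- function(gm, pop) {
  d <- gm$dosage[pop_index(gm, pop), , drop = FALSE]
  called <- !is.na(d)
  n_ind <- colSums(called)
  n_alt <- colSums(d, na.rm = TRUE)
  list(n_ref = 2 * n_ind - n_alt, n_alt = n_alt,
       n_ind = n_ind, n_het = colSums(d == 1L, na.rm = TRUE))
}

#' Per-site nucleotide diversity
#'
#' The mean pairwise difference among the sampled alleles at one site:
#' pi = 2 * n_ref * n_alt / (n * (n - 1)) with n = n_ref + n_alt. Sites
#' with fewer than two called alleles are returned as `NA` (skipped).
#'
#' @param n_ref,n_alt allele counts (vectors).
#' @return numeric vector of per-site pi.
#' @export
site_pi <- function(n_ref, n_alt) {
  n <- n_ref + n_alt
  ifelse(n >= 2, 2 * n_ref * n_alt / (n * (n - 1)), NA_real_)
}

#' Windowed nucleotide diversity per population
#'
#' Window theta-pi is the sum of per-site pi over SNPs in \[start, end)
#' divided by the full window span in bp (a per-bp diversity; invariant
#' sites contribute zero, so normalising by span rather than by SNP count
#' is what makes swept windows *low*).
#'
#' @param gm a [genotype_matrix()].
#' @param pop population name.
#' @param windows window grid from [make_windows()].
#' @return data.frame: windows plus `n_snps` (SNP records in window),
#'   `n_used` (sites with >= 2 called alleles), `pi` (per-bp diversity;
#'   0 for empty windows, which are flagged by `n_used == 0`).
#' @export
window_pi <- function(gm, pop, windows) {
  ac <- allele_counts(gm, pop)
  sp <- site_pi(ac$n_ref, ac$n_alt)
  agg <- window_aggregate(gm$sites, windows, cbind(pi_sum = sp))
  out <- windows
  out$n_snps <- agg$n_snps
  out$n_used <- agg$n_used[, "pi_sum"]
  out$pi <- agg$sums[, "pi_sum"] / (windows$end - windows$start)
  out
}

#' Weir-Cockerham (1984) variance components at biallelic sites
#'
#' The two-population ANOVA decomposition of allelic variance into
#' among-population (a), among-individual-within-population (b) and
#' within-individual (c) components, computed from allele frequencies,
#' sample sizes and observed heterozygote frequencies. Per-site FST is
#' a / (a + b + c); it can be slightly negative when there is no
#' differentiation, and negative values are deliberately retained.
#' Sites where either population has fewer than two called allele copies
#' (or with only one individual overall) are `NA`.
#'
#' @param gm a [genotype_matrix()].
#' @param popA,popB population names.
#' @return data.frame over sites: `a`, `b`, `c`.
#' @export
site_fst_components <- function(gm, popA, popB) {
  acA <- allele_counts(gm, popA)
  acB <- allele_counts(gm, popB)
  wc_components(acA$n_ind, acA$n_alt, acA$n_het,
                acB$n_ind, acB$n_alt, acB$n_het)
}

# n1, n2: called diploid individuals; x1, x2: alt allele counts;
# h1c, h2c: heterozygote counts. Vectorised over sites.
wc_components <- function(n1, x1, h1c, n2, x2, h2c) {
  ok <- n1 >= 1 & n2 >= 1 & (n1 + n2) > 2
  p1 <- ifelse(n1 > 0, x1 / (2 * n1), NA_real_)
  p2 <- ifelse(n2 > 0, x2 / (2 * n2), NA_real_)
  h1 <- ifelse(n1 > 0, h1c / n1, NA_real_)
  h2 <- ifelse(n2 > 0, h2c / n2, NA_real_)
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- nbar / nc *
    (s2 - 1 / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  data.frame(a = ifelse(ok, a, NA_real_),
             b = ifelse(ok, b, NA_real_),
             c = ifelse(ok, cc, NA_real_))
}

# Hudson-estimator per-site numerator/denominator (Bhatia et al. 2013
# form), offered as a sensitivity alternative to the Weir-Cockerham
# default. n here counts allele copies.
hudson_components <- function(gm, popA, popB) {
  acA <- allele_counts(gm, popA)
  acB <- allele_counts(gm, popB)
  nA <- acA$n_ref + acA$n_alt
  nB <- acB$n_ref + acB$n_alt
  ok <- nA >= 2 & nB >= 2
  p1 <- acA$n_alt / nA
  p2 <- acB$n_alt / nB
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (nA - 1) - p2 * (1 - p2) / (nB - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  data.frame(num = ifelse(ok, num, NA_real_),
             den = ifelse(ok, den, NA_real_))
}

#' Windowed FST as a ratio of sums
#'
#' Per-window FST = sum(a) / sum(a + b + c) over the usable sites in the
#' window (ratio of sums, not mean of per-site ratios, which is unstable
#' in low-diversity windows). Windows with a zero or undefined
#' denominator are returned as `NA` and excluded from outlier ranking.
#'
#' @param gm a [genotype_matrix()].
#' @param popA,popB population names.
#' @param windows window grid from [make_windows()].
#' @param estimator "wc" (Weir-Cockerham ANOVA, default) or "hudson".
#' @return data.frame: windows plus `n_snps`, `n_used`, `fst`.
#' @export
window_fst <- function(gm, popA, popB, windows, estimator = c("wc", "hudson")) {
  estimator <- match.arg(estimator)
  if (estimator == "wc") {
    comp <- site_fst_components(gm, popA, popB)
    vals <- cbind(num = comp$a, den = comp$a + comp$b + comp$c)
  } else {
    comp <- hudson_components(gm, popA, popB)
    vals <- cbind(num = comp$num, den = comp$den)
  }
  agg <- window_aggregate(gm$sites, windows, vals)
  out <- windows
  out$n_snps <- agg$n_snps
  out$n_used <- agg$n_used[, "num"]
  den <- agg$sums[, "den"]
  out$fst <- ifelse(agg$n_used[, "num"] > 0 & den != 0,
                    agg$sums[, "num"] / den, NA_real_)
  out
}

# Shared window aggregation: per-site value columns summed over the sites
# falling in each (possibly overlapping) window, via cumulative sums over
# position-sorted sites. NA site values count as unusable and add zero.
window_aggregate <- function(sites, windows, values) {
  values <- as.matrix(values)
  n_snps <- integer(nrow(windows))
  sums <- matrix(0, nrow(windows), ncol(values),
                 dimnames = list(NULL, colnames(values)))
  n_used <- matrix(0L, nrow(windows), ncol(values),
                   dimnames = list(NULL, colnames(values)))
  pos0 <- sites$pos - 1  # windows are 0-based half-open
  for (ch in unique(windows$chrom)) {
    sidx <- which(sites$chrom == ch)
    widx <- which(windows$chrom == ch)
    if (!length(sidx)) next
    p <- pos0[sidx]
    v <- values[sidx, , drop = FALSE]
    used <- !is.na(v)
    v[!used] <- 0
    cs <- apply(v, 2, cumsum)
    cu <- apply(used, 2, cumsum)
    if (!is.matrix(cs)) { cs <- matrix(cs, nrow = 1); cu <- matrix(cu, nrow = 1) }
    lo <- findInterval(windows$start[widx] - 0.5, p)      # sites before window
    hi <- findInterval(windows$end[widx] - 0.5, p)        # sites up to end-1
    n_snps[widx] <- hi - lo
    take <- function(m, i) ifelse(i > 0, m[pmax(i, 1), , drop = FALSE], 0)
    for (j in seq_len(ncol(values))) {
      cs_j <- c(0, cs[, j]); cu_j <- c(0, cu[, j])
      sums[widx, j] <- cs_j[hi + 1L] - cs_j[lo + 1L]
      n_used[widx, j] <- cu_j[hi + 1L] - cu_j[lo + 1L]
    }
  }
  list(n_snps = n_snps, sums = sums, n_used = n_used)
}

#' Windowed scan table for one selected-vs-control comparison
#'
#' Convenience wrapper assembling, per window: SNP counts, theta-pi for
#' both populations, windowed FST, and the log2 diversity ratio
#' (control over selected).
#'
#' @param gm a [genotype_matrix()].
#' @param selected_pop,control_pop population names.
#' @param windows window grid; built from `chrom_lengths` if `NULL`.
#' @param chrom_lengths used when `windows` is `NULL`.
#' @param size,step window geometry for [make_windows()].
#' @param estimator FST estimator, see [window_fst()].
#' @return data.frame: `chrom`, `start`, `end`, `n_snps`, `pi_selected`,
#'   `pi_control`, `fst`, `log2_ratio`.
#' @export
scan_windows <- function(gm, selected_pop, control_pop, windows = NULL,
                         chrom_lengths = NULL, size = 40000, step = 20000,
                         estimator = "wc") {
  if (is.null(windows)) {
    if (is.null(chrom_lengths))
      chrom_lengths <- tapply(gm$sites$pos, gm$sites$chrom, max)
    windows <- make_windows(chrom_lengths, size, step)
  }
  ps <- window_pi(gm, selected_pop, windows)
  pc <- window_pi(gm, control_pop, windows)
  wf <- window_fst(gm, selected_pop, control_pop, windows, estimator = estimator)
  out <- windows
  out$n_snps <- wf$n_snps
  out$pi_selected <- ps$pi
  out$pi_control <- pc$pi
  out$fst <- wf$fst
  out$log2_ratio <- log2_pi_ratio(out$pi_control, out$pi_selected)
  out
}
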