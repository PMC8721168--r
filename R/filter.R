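#' SNP quality-control filters
#'
#' Three site-level rules applied to a raw SNP set, each evaluated on the
#' ORIGINAL (pre-filter) site set before the union of flags is removed:
#'
#' 1. site quality: remove sites with Phred QUAL below 20 (quality
#'    exactly 20 is kept);
#' 2. spacing: any two SNPs closer than 5 bp on the same chromosome are
#'    both removed (a distance of exactly 5 bp is allowed); removal walks
#'    along runs, so every member of a cluster of close SNPs goes;
#' 3. depth: site depth must lie within \[1/3, 5\] times the genome-wide
#'    average depth, bounds inclusive, with the average anchored to the
#'    pre-filter site set.
#'
#' @name variant_filters
#' @param gm a [genotype_matrix()].
#' @param min_qual Phred threshold; sites with `qual < min_qual` are
#'   flagged.
#' @param min_spacing_bp minimum allowed distance between adjacent SNPs.
#' @param low_mult,high_mult multipliers on the mean depth defining the
#'   closed acceptance interval.
#' @return for the individual rules, a logical vector over sites (`TRUE`
#'   = flagged for removal).
NULL

#' @rdname variant_filters
#' @export
filter_qual <- function(gm, min_qual = 20) {
  q <- gm$sites$qual
  if (anyNA(q)) stop("missing QUAL at ", sum(is.na(q)), " sites")
  q < min_qual
}

#' @rdname variant_filters
#' @export
filter_spacing <- function(gm, min_spacing_bp = 5) {
  s <- gm$sites
  flag <- logical(nrow(s))
  for (ch in unique(s$chrom)) {
    idx <- which(s$chrom == ch)
    p <- s$pos[idx]
    if (is.unsorted(p, strictly = TRUE))
      stop("positions not sorted within chromosome ", ch)
    close_pair <- diff(p) < min_spacing_bp
    # both members of every too-close pair go; runs flag transitively
    f <- logical(length(p))
    f[which(close_pair)] <- TRUE
    f[which(close_pair) + 1L] <- TRUE
    flag[idx] <- f
  }
  flag
}

#' @rdname variant_filters
#' @export
filter_depth <- function(gm, low_mult = 1/3, high_mult = 5) {
  d <- gm$sites$site_depth
  if (anyNA(d)) stop("missing site depth at ", sum(is.na(d)), " sites")
  mean_depth <- mean(d)
  if (mean_depth == 0) stop("all site depths are zero; depth filter undefined")
  flag <- d < low_mult * mean_depth | d > high_mult * mean_depth
  attr(flag, "mean_depth") <- mean_depth
  flag
}

#' Apply all three QC rules and report per-rule attrition
#'
#' All rules are evaluated on the input site set (mean depth and spacing
#' are computed before any removal), then the union of flagged sites is
#' removed in one pass. Removal cannot create new too-close pairs, so no
#' second spacing pass is needed.
#'
#' @inheritParams variant_filters
#' @return list: `gm` (filtered [genotype_matrix()]) and `report` (list
#'   with `n_input`, `n_fail_qual`, `n_fail_spacing`, `n_fail_depth`,
#'   `n_pass`, `mean_depth_used`).
#' @export
apply_filters <- function(gm, min_qual = 20, min_spacing_bp = 5,
                          low_mult = 1/3, high_mult = 5) {
  fq <- filter_qual(gm, min_qual)
  fs <- filter_spacing(gm, min_spacing_bp)
  fd <- filter_depth(gm, low_mult, high_mult)
  fail <- fq | fs | fd
  report <- list(n_input = n_sites(gm),
                 n_fail_qual = sum(fq),
                 n_fail_spacing = sum(fs),
                 n_fail_depth = sum(fd),
                 n_pass = sum(!fail),
                 mean_depth_used = attr(fd, "mean_depth"))
  if (report$n_pass == 0)
    warning("no SNPs survive filtering")
  list(gm = subset_sites(gm, !fail), report = report)
}
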