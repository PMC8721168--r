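#' Log2 diversity ratio of control over selected population
#'
#' Large positive values mean the selected population has lost diversity
#' relative to the control -- the sweep signature. A window whose
#' selected-population diversity is exactly zero while the control is
#' polymorphic gets `+Inf` (the strongest possible signal; it ranks
#' above every finite value). Windows with zero diversity in both
#' populations get `NA` and are excluded from ranking.
#'
#' @param pi_control,pi_selected per-window theta-pi vectors.
#' @return numeric vector of log2 ratios.
#' @export
log2_pi_ratio <- function(pi_control, pi_selected) {
  if (any(pi_control < 0, na.rm = TRUE) || any(pi_selected < 0, na.rm = TRUE))
    stop("negative diversity values")
  out <- ifelse(pi_control == 0 & pi_selected == 0, NA_real_,
         ifelse(pi_selected == 0, Inf, log2(pi_control / pi_selected)))
  out
}

#' Joint top-fraction outlier windows (sweep candidates)
#'
#' A window is a sweep candidate iff it lies simultaneously in the upper
#' `top_fraction` tail of windowed FST *and* of the log2 diversity
#' ratio. Thresholds are the empirical (1 - top_fraction) quantiles
#' (linear-interpolation definition) of the rankable windows; ties at a
#' threshold pass ("at or above" rule). `+Inf` ratio windows always pass
#' the ratio arm; the reported ratio threshold is computed over the
#' finite values.
#'
#' A window is rankable when it has at least `min_snps` SNPs, a defined
#' FST and a defined (finite or `+Inf`) ratio.
#'
#' @param windows scan table from [scan_windows()] (needs `fst` and
#'   `log2_ratio` columns).
#' @param top_fraction upper tail size (default 0.05, the top 5%).
#' @param min_snps minimum SNPs per window to enter the ranking.
#' @return list of class `sweep_call`: `windows` (input plus `rankable`,
#'   `fst_pass`, `ratio_pass`, `outlier`), `fst_threshold`,
#'   `ratio_threshold`, `n_rankable`, `n_outliers`.
#' @export
joint_outliers <- function(windows, top_fraction = 0.05, min_snps = 1L) {
  if (top_fraction <= 0 || top_fraction > 1)
    stop("top_fraction must lie in (0, 1]")
  rankable <- windows$n_snps >= min_snps & !is.na(windows$fst) &
    !is.na(windows$log2_ratio)
  n_rank <- sum(rankable)
  if (n_rank < 20)
    stop("only ", n_rank, " rankable windows; need at least 20 for a ",
         "meaningful empirical quantile")
  fst_thr <- stats::quantile(windows$fst[rankable], 1 - top_fraction,
                             names = FALSE, type = 7)
  # the reported ratio threshold is the quantile of the finite ratios;
  # +Inf sentinel windows are force-passed below
  ratio_fin <- windows$log2_ratio[rankable & is.finite(windows$log2_ratio)]
  ratio_thr <- if (length(ratio_fin)) {
    stats::quantile(ratio_fin, 1 - top_fraction, names = FALSE, type = 7)
  } else Inf
  fst_pass <- rankable & windows$fst >= fst_thr
  ratio_pass <- rankable &
    (is.infinite(windows$log2_ratio) | windows$log2_ratio >= ratio_thr)
  out <- windows
  out$rankable <- rankable
  out$fst_pass <- fst_pass
  out$ratio_pass <- ratio_pass
  out$outlier <- fst_pass & ratio_pass
  structure(list(windows = out,
                 fst_threshold = fst_thr,
                 ratio_threshold = ratio_thr,
                 n_rankable = n_rank,
                 n_outliers = sum(out$outlier)),
            class = "sweep_call")
}

#' @export
print.sweep_call <- function(x, ...) {
  cat(sprintf(paste0("sweep_call: %d / %d rankable windows are joint outliers\n",
                     "thresholds: FST >= %.4f, log2 ratio >= %s\n"),
              x$n_outliers, x$n_rankable, x$fst_threshold,
              format(x$ratio_threshold, digits = 4)))
  invisible(x)
}

#' Map outlier windows to the genes they overlap
#'
#' Overlapping outlier windows are merged into maximal sweep intervals
#' first, then a gene is selected iff its \[start, end) interval overlaps
#' a merged interval by at least 1 bp (`rule = "overlap"`) or lies fully
#' inside one (`rule = "contained"`). Each gene is reported once.
#'
#' @param sweep a `sweep_call` from [joint_outliers()], or a data.frame
#'   of outlier windows (`chrom`, `start`, `end`).
#' @param genes gene table from [read_gff()] / [simulate_annotation()].
#' @param rule "overlap" (any overlap, default) or "contained".
#' @return character vector of selected gene ids (sorted).
#' @export
windows_to_genes <- function(sweep, genes, rule = c("overlap", "contained")) {
  rule <- match.arg(rule)
  win <- if (inherits(sweep, "sweep_call")) {
    sweep$windows[sweep$windows$outlier, c("chrom", "start", "end"), drop = FALSE]
  } else {
    sweep[, c("chrom", "start", "end"), drop = FALSE]
  }
  if (!nrow(genes)) {
    warning("empty annotation; no genes can be assigned")
    return(character(0))
  }
  if (!nrow(win)) return(character(0))
  # 0-based half-open -> IRanges 1-based closed
  wgr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    win$chrom, IRanges::IRanges(win$start + 1L, win$end)))
  ggr <- GenomicRanges::GRanges(genes$chrom,
                                IRanges::IRanges(genes$start + 1L, genes$end))
  hits <- if (rule == "overlap") {
    GenomicRanges::findOverlaps(ggr, wgr)
  } else {
    GenomicRanges::findOverlaps(ggr, wgr, type = "within")
  }
  sort(unique(genes$gene_id[S4Vectors::queryHits(hits)]))
}

#' Venn partition of two or three gene sets
#'
#' Exact region cardinalities and memberships of the 2- or 3-set Venn
#' partition, used for the cross-comparison overlaps of selected-gene and
#' DEG lists.
#'
#' @param sets named list of 2 or 3 character vectors.
#' @return list: `counts` (named integer vector over the 3 or 7 disjoint
#'   regions, names like "A", "A&B", "A&B&C"), `members` (the
#'   corresponding id vectors), `union_size`.
#' @export
overlap_sets <- function(sets) {
  k <- length(sets)
  if (!k %in% 2:3) stop("overlap_sets needs 2 or 3 sets")
  if (is.null(names(sets)) || any(names(sets) == ""))
    names(sets) <- LETTERS[seq_len(k)]
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (!is.matrix(member)) member <- matrix(member, nrow = length(universe))
  key <- apply(member, 1, function(row)
    paste(names(sets)[row], collapse = "&"))
  regions <- unlist(lapply(seq_len(k), function(i)
    utils::combn(names(sets), i, paste, collapse = "&", simplify = FALSE)))
  members <- stats::setNames(lapply(regions, function(r)
    sort(universe[key == r])), regions)
  counts <- vapply(members, length, integer(1))
  list(counts = counts, members = members, union_size = length(universe))
}
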