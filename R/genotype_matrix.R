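#' Construct a genotype matrix
#'
#' The central container for all population-genetic computations: a
#' samples-by-sites grid of alternate-allele dosages for diploid biallelic
#' SNPs, together with per-site metadata (chromosome, 1-based position,
#' alleles, Phred site quality, summed site depth) and a population label
#' per sample.
#'
#' Dosage is coded 0 (homozygous reference), 1 (heterozygous),
#' 2 (homozygous alternate) or `NA` (missing call). Missing is never
#' conflated with 0. Sites must be sorted by position, strictly
#' increasing within each chromosome.
#'
#' @param dosage integer matrix, samples in rows (rownames = sample ids),
#'   sites in columns; values in \{0, 1, 2, NA\}.
#' @param sites data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `qual`, `site_depth`; one row per dosage column.
#' @param pop_labels named character vector mapping every sample id to a
#'   population name.
#' @param depth_source how `site_depth` was obtained ("info_dp",
#'   "sum_format_dp" or "simulated").
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, sites, pop_labels, depth_source = "info_dp") {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  stopifnot(is.data.frame(sites),
            all(c("chrom", "pos", "ref", "alt", "qual", "site_depth") %in% names(sites)),
            nrow(sites) == ncol(dosage))
  if (is.null(rownames(dosage)))
    stop("dosage must carry sample ids as rownames")
  bad <- dosage[!is.na(dosage)]
  if (length(bad) && !all(bad %in% 0:2))
    stop("dosage values must be 0, 1, 2 or NA")
  if (any(sites$pos < 1)) stop("positions must be >= 1 (1-based, as in VCF)")
  for (ch in unique(sites$chrom)) {
    p <- sites$pos[sites$chrom == ch]
    if (is.unsorted(p, strictly = TRUE))
      stop("sites must be strictly increasing in position within chromosome ", ch)
  }
  missing_lab <- setdiff(rownames(dosage), names(pop_labels))
  if (length(missing_lab))
    stop("samples without a population label: ", paste(missing_lab, collapse = ", "))
  structure(list(
    dosage       = dosage,
    sites        = sites,
    pop_labels   = pop_labels[rownames(dosage)],
    depth_source = depth_source
  ), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d biallelic SNPs\n",
              nrow(x$dosage), ncol(x$dosage)))
  tab <- table(x$pop_labels)
  cat("populations:", paste(sprintf("%s (n=%d)", names(tab), tab), collapse = ", "), "\n")
  cat("chromosomes:", paste(unique(x$sites$chrom), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Number of samples / sites in a genotype matrix
#' @param gm a `genotype_matrix`.
#' @return integer count.
#' @export
n_samples <- function(gm) nrow(gm$dosage)

#' @rdname n_samples
#' @export
n_sites <- function(gm) ncol(gm$dosage)

#' Subset a genotype matrix by site index
#'
#' Keeps the selected site columns (in their original order) and the
#' matching site metadata.
#'
#' @param gm a `genotype_matrix`.
#' @param keep integer or logical index over sites.
#' @return a `genotype_matrix`.
#' @export
subset_sites <- function(gm, keep) {
  if (is.logical(keep)) keep <- which(keep)
  genotype_matrix(gm$dosage[, keep, drop = FALSE],
                  gm$sites[keep, , drop = FALSE],
                  gm$pop_labels,
                  depth_source = gm$depth_source)
}

#' Samples belonging to one population
#' @param gm a `genotype_matrix`.
#' @param pop population name.
#' @return integer row indices into the dosage matrix.
#' @export
pop_index <- function(gm, pop) {
  idx <- which(gm$pop_labels == pop)
  if (!length(idx)) stop("no samples in population '", pop, "'")
  idx
}

# Derive a 32-bit substream seed from a master seed and a stage name, so
# each pipeline stage is reproducible in isolation and in sequence.
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647L)
}
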