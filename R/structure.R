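#' Pairwise allele-sharing distance between individuals
#'
#' d_ij is the mean, over sites where both individuals are called, of
#' |dosage_i - dosage_j| / 2: 0 for identical genotypes everywhere, 1 for
#' opposite homozygotes everywhere. Computed with indicator-matrix cross
#' products, so it scales to tens of thousands of sites; missing
#' genotypes are dropped pairwise.
#'
#' @param gm a [genotype_matrix()].
#' @return list of class `dist_matrix`: `d` (symmetric matrix, zero
#'   diagonal), `n_sites_used` (per-pair co-called site counts).
#' @export
allele_sharing_distance <- function(gm) {
  X <- gm$dosage
  if (nrow(X) < 2) stop("need at least 2 samples")
  called <- !is.na(X)
  A <- lapply(0:2, function(v) {
    m <- matrix(0, nrow(X), ncol(X))
    m[which(X == v)] <- 1
    m
  })
  N <- lapply(A, function(ai) lapply(A, function(aj) tcrossprod(ai, aj)))
  # sum over co-called sites of |d_i - d_j|
  S <- N[[1]][[2]] + N[[2]][[1]] + N[[2]][[3]] + N[[3]][[2]] +
    2 * (N[[1]][[3]] + N[[3]][[1]])
  C <- tcrossprod(called * 1)
  off <- C[upper.tri(C)]
  if (any(off == 0)) {
    idx <- which(C == 0 & upper.tri(C), arr.ind = TRUE)[1, ]
    stop("samples ", rownames(X)[idx[1]], " and ", rownames(X)[idx[2]],
         " share no co-called sites")
  }
  d <- S / (2 * C)
  diag(d) <- 0
  dimnames(d) <- list(rownames(X), rownames(X))
  structure(list(d = d, n_sites_used = C), class = "dist_matrix")
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration (via \pkg{ape}); negative branch
#' lengths, which the NJ length equations can produce, are clamped to
#' zero with the total clamped deficit recorded in the `clamped_deficit`
#' attribute.
#'
#' @param D a `dist_matrix` from [allele_sharing_distance()] or a
#'   symmetric numeric matrix with sample ids as dimnames.
#' @return an unrooted `phylo` tree.
#' @export
nj_tree <- function(D) {
  d <- if (inherits(D, "dist_matrix")) D$d else as.matrix(D)
  if (!isSymmetric(unname(d), tol = 1e-8)) stop("distance matrix must be symmetric")
  if (nrow(d) < 3) stop("need at least 3 samples for a tree")
  tr <- ape::nj(d)
  deficit <- -sum(tr$edge.length[tr$edge.length < 0])
  tr$edge.length[tr$edge.length < 0] <- 0
  attr(tr, "clamped_deficit") <- deficit
  tr
}

#' Bootstrap support for the NJ tree
#'
#' SNP columns are resampled with replacement (same count), the distance
#' matrix and NJ tree rebuilt per replicate, and each internal
#' bipartition of the full-data tree scored by the percentage of
#' replicates containing it. Supports are stored as internal node labels
#' of the returned tree. Deterministic given the seed.
#'
#' @param gm a [genotype_matrix()].
#' @param n_boot number of replicates (the study design uses 1,000).
#' @param seed RNG seed.
#' @return the full-data NJ tree with `node.label` set to supports in
#'   \[0, 100\].
#' @export
bootstrap_support <- function(gm, n_boot = 1000, seed = 1L) {
  if (n_boot < 1) stop("n_boot must be at least 1")
  set.seed(seed)
  full <- nj_tree(allele_sharing_distance(gm))
  m <- n_sites(gm)
  reps <- vector("list", n_boot)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(m, m, replace = TRUE)
    gmb <- gm
    gmb$dosage <- gm$dosage[, idx, drop = FALSE]
    reps[[b]] <- nj_tree(structure(
      list(d = allele_sharing_distance_raw(gmb$dosage)), class = "dist_matrix"))
  }
  counts <- ape::prop.clades(full, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0
  full$node.label <- round(100 * counts / n_boot, 1)
  full
}

# distance kernel without the validation/bookkeeping, for the bootstrap
# inner loop
allele_sharing_distance_raw <- function(X) {
  called <- !is.na(X)
  A <- lapply(0:2, function(v) {
    m <- matrix(0, nrow(X), ncol(X)); m[which(X == v)] <- 1; m
  })
  S <- tcrossprod(A[[1]], A[[2]]) + tcrossprod(A[[2]], A[[1]]) +
    tcrossprod(A[[2]], A[[3]]) + tcrossprod(A[[3]], A[[2]]) +
    2 * (tcrossprod(A[[1]], A[[3]]) + tcrossprod(A[[3]], A[[1]]))
  C <- tcrossprod(called * 1)
  d <- S / (2 * C)
  diag(d) <- 0
  dimnames(d) <- list(rownames(X), rownames(X))
  d
}

#' Principal component analysis of genotypes (Patterson scaling)
#'
#' Each site is centred by twice its sample alternate-allele frequency
#' and scaled by sqrt(p(1-p)) -- the binomial standard deviation used by
#' EIGENSOFT-style genotype PCA. Missing entries are mean-imputed (zero
#' after centring) and monomorphic sites dropped. The decomposition is
#' the exact eigendecomposition of the sample-by-sample covariance
#' (normalised by the number of sites); signs follow a deterministic
#' convention (the largest-magnitude score of each component is
#' positive).
#'
#' @param gm a [genotype_matrix()].
#' @param k number of components to return.
#' @return list of class `pca_result`: `eigenvalues` (all, descending),
#'   `scores` (samples x k, eigenvectors scaled by sqrt(eigenvalue)),
#'   `varexp` (variance-explained fractions for the k components),
#'   `n_sites_used`.
#' @export
pca_genotypes <- function(gm, k = 10) {
  X <- gm$dosage
  if (nrow(X) < 2) stop("need at least 2 samples")
  p_hat <- colMeans(X, na.rm = TRUE) / 2
  informative <- !is.na(p_hat) & p_hat > 0 & p_hat < 1
  if (!any(informative)) stop("all sites are monomorphic; PCA undefined")
  X <- X[, informative, drop = FALSE]
  p_hat <- p_hat[informative]
  M <- sweep(X, 2, 2 * p_hat, `-`)
  M <- sweep(M, 2, sqrt(p_hat * (1 - p_hat)), `/`)
  M[is.na(M)] <- 0
  m <- ncol(M)
  C <- tcrossprod(M) / m
  eig <- eigen(C, symmetric = TRUE)
  k <- min(k, nrow(X) - 1)
  vals <- eig$values
  vecs <- eig$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    if (vecs[which.max(abs(vecs[, j])), j] < 0) vecs[, j] <- -vecs[, j]
  }
  scores <- sweep(vecs, 2, sqrt(pmax(vals[seq_len(k)], 0)), `*`)
  rownames(scores) <- rownames(X)
  colnames(scores) <- paste0("PC", seq_len(k))
  structure(list(eigenvalues = vals,
                 scores = scores,
                 varexp = pmax(vals[seq_len(k)], 0) / sum(pmax(vals, 0)),
                 n_sites_used = m),
            class = "pca_result")
}
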