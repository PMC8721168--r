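# Independent oracles and tiny fixture builders shared across the suite.
# Each oracle is a deliberately naive re-derivation (enumeration, scalar
# transcription, all-pairs loops) kept separate from the vectorised code
# paths it checks.

# --- fixture builder -------------------------------------------------------

# toy genotype matrix from a dosage grid; positions default to 100, 200, ...
make_gm <- function(dosage, pos = NULL, chrom = NULL, qual = NULL,
                    depth = NULL, pops = NULL) {
  dosage <- as.matrix(dosage)
  m <- ncol(dosage)
  if (is.null(rownames(dosage)))
    rownames(dosage) <- sprintf("s%02d", seq_len(nrow(dosage)))
  if (is.null(pos)) pos <- seq_len(m) * 100L
  if (is.null(chrom)) chrom <- rep("chr1", m)
  if (is.null(qual)) qual <- rep(50, m)
  if (is.null(depth)) depth <- rep(100, m)
  if (is.null(pops))
    pops <- stats::setNames(rep(c("A", "B"), length.out = nrow(dosage)),
                            rownames(dosage))
  genotype_matrix(dosage,
                  data.frame(chrom = chrom, pos = as.integer(pos),
                             ref = rep("A", m), alt = rep("G", m),
                             qual = qual, site_depth = depth,
                             stringsAsFactors = FALSE),
                  pops)
}

# random two-population genotype fixture with missingness
random_gm <- function(n_per_pop = 8, m = 50, miss = 0.05) {
  d <- matrix(sample(0:2, 2 * n_per_pop * m, replace = TRUE), ncol = m)
  d[stats::runif(length(d)) < miss] <- NA
  rownames(d) <- sprintf("s%02d", seq_len(2 * n_per_pop))
  make_gm(d, pops = stats::setNames(rep(c("A", "B"), each = n_per_pop),
                                    rownames(d)))
}

# --- popgen oracles --------------------------------------------------------

# per-site pi by explicit enumeration of all allele pairs
site_pi_oracle <- function(n_ref, n_alt) {
  alleles <- c(rep(0L, n_ref), rep(1L, n_alt))
  n <- length(alleles)
  if (n < 2) return(NA_real_)
  diffs <- 0L; pairs <- 0L
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    diffs <- diffs + (alleles[i] != alleles[j])
    pairs <- pairs + 1L
  }
  diffs / pairs
}

# Weir & Cockerham (1984) two-population variance components, transcribed
# scalar-by-scalar from the published equations; g1/g2 are dosage vectors
wc84_oracle <- function(g1, g2) {
  g1 <- g1[!is.na(g1)]; g2 <- g2[!is.na(g2)]
  n <- c(length(g1), length(g2))
  if (any(n < 1) || sum(n) <= 2) return(c(a = NA, b = NA, c = NA))
  p <- c(sum(g1) / (2 * n[1]), sum(g2) / (2 * n[2]))
  h <- c(mean(g1 == 1L), mean(g2 == 1L))
  r <- 2
  nbar <- sum(n) / r
  nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
  pbar <- sum(n * p) / sum(n)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / sum(n)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) * s2 / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) * s2 / r - (2 * nbar - 1) * hbar / (4 * nbar))
  c(a = a, b = b, c = hbar / 2)
}

# allele-sharing distance by an all-pairs, all-sites double loop
dist_oracle <- function(X) {
  n <- nrow(X)
  d <- matrix(0, n, n, dimnames = list(rownames(X), rownames(X)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    ok <- !is.na(X[i, ]) & !is.na(X[j, ])
    d[i, j] <- mean(abs(X[i, ok] - X[j, ok])) / 2
  }
  d
}

# per-base occupancy count of merged intervals (1-based closed input)
union_length_oracle <- function(starts, ends, max_pos = max(ends)) {
  covered <- logical(max_pos)
  for (k in seq_along(starts)) covered[starts[k]:ends[k]] <- TRUE
  sum(covered)
}

# brute-force window membership count over sites
window_count_oracle <- function(sites, windows) {
  vapply(seq_len(nrow(windows)), function(w) {
    sum(sites$chrom == windows$chrom[w] &
          sites$pos - 1 >= windows$start[w] &
          sites$pos - 1 < windows$end[w])
  }, numeric(1))
}

# inclusion-exclusion region sizes for 3 sets
venn3_oracle <- function(A, B, C) {
  u <- union(union(A, B), C)
  inA <- u %in% A; inB <- u %in% B; inC <- u %in% C
  c(`A` = sum(inA & !inB & !inC), `B` = sum(!inA & inB & !inC),
    `C` = sum(!inA & !inB & inC), `A&B` = sum(inA & inB & !inC),
    `A&C` = sum(inA & !inB & inC), `B&C` = sum(!inA & inB & inC),
    `A&B&C` = sum(inA & inB & inC))
}

window_key <- function(d) paste(d$chrom, d$start, d$end)
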