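test_that("window grid matches the declared geometry", {
  w <- make_windows(c(chr1 = 100000))
  expect_equal(w$start, c(0, 20000, 40000, 60000, 80000))
  expect_equal(w$end[5], 100000)
  w2 <- make_windows(c(chr1 = 40000))
  expect_equal(nrow(w2), 2L)
  expect_equal(w2$start, c(0, 20000))
  expect_equal(w2$end, c(40000, 40000))
  # every position falls in at most ceiling(size/step) windows
  w3 <- make_windows(c(chr1 = 130000, chr2 = 57000, chr3 = 20001))
  cover <- vapply(c(1, 19999, 20000, 56999, 110000), function(p)
    sum(w3$chrom == "chr1" & w3$start <= p & w3$end > p), numeric(1))
  expect_true(all(cover <= 2))
  # independent enumeration of the total window count
  n_oracle <- 0
  for (len in c(130000, 57000, 20001)) {
    s <- 0
    while (s < len) { n_oracle <- n_oracle + 1; s <- s + 20000 }
  }
  expect_equal(nrow(w3), n_oracle)
  expect_error(make_windows(c(chr1 = 0)), "length")
  expect_error(make_windows(c(chr1 = 100), size = 10, step = 20), "step")
})

test_that("per-site pi equals the pairwise-difference enumeration", {
  expect_equal(site_pi(2, 2), 2 / 3)          # 4 of 6 pairs differ
  expect_equal(site_pi(5, 0), 0)              # monomorphic
  expect_equal(site_pi(1, 1), 1)              # the single pair differs
  expect_true(is.na(site_pi(1, 0)))           # n < 2 skipped
  set.seed(101)
  for (i in 1:200) {
    nr <- sample(0:12, 1); na <- sample(0:12, 1)
    if (nr + na < 2) next
    expect_equal(site_pi(nr, na), site_pi_oracle(nr, na), tolerance = 1e-12)
  }
})

test_that("WC84 components match an independent scalar transcription", {
  set.seed(202)
  for (i in 1:300) {
    n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
    g1 <- sample(0:2, n1, replace = TRUE)
    g2 <- sample(0:2, n2, replace = TRUE)
    gm <- make_gm(matrix(c(g1, g2), ncol = 1),
                  pops = stats::setNames(rep(c("A", "B"), c(n1, n2)),
                                         sprintf("s%02d", seq_len(n1 + n2))))
    comp <- site_fst_components(gm, "A", "B")
    oracle <- wc84_oracle(g1, g2)
    expect_equal(c(comp$a, comp$b, comp$c), unname(oracle), tolerance = 1e-12)
  }
})

test_that("WC84 endpoints: fixed difference gives 1, identical pops give <= 0", {
  g_fix <- make_gm(matrix(c(rep(0L, 8), rep(2L, 8)), ncol = 1),
                   pops = stats::setNames(rep(c("A", "B"), each = 8),
                                          sprintf("s%02d", 1:16)))
  comp <- site_fst_components(g_fix, "A", "B")
  expect_equal(comp$a / (comp$a + comp$b + comp$c), 1)
  g_id <- matrix(rep(c(0L, 1L, 2L, 1L, 0L, 1L, 2L, 0L), 2), ncol = 1)
  gm_id <- make_gm(g_id, pops = stats::setNames(rep(c("A", "B"), each = 8),
                                                sprintf("s%02d", 1:16)))
  comp2 <- site_fst_components(gm_id, "A", "B")
  expect_lte(comp2$a, 0)
  expect_lte(comp2$a / (comp2$a + comp2$b + comp2$c), 0)
})

test_that("missing genotypes are dropped pairwise in allele counts", {
  d <- matrix(c(0L, NA, 2L, 1L,
                1L, 1L, NA, NA), nrow = 4)
  gm <- make_gm(d, pops = stats::setNames(rep("A", 4), sprintf("s%02d", 1:4)))
  ac <- allele_counts(gm, "A")
  expect_equal(ac$n_ind, c(3, 2))
  expect_equal(ac$n_alt, c(3, 2))
  expect_equal(ac$n_ref, c(3, 2))
  expect_equal(ac$n_het, c(1, 2))
})

test_that("windowed statistics equal site-wise oracles applied window-wise", {
  set.seed(303)
  gm <- random_gm(6, 120, miss = 0.08)
  gm$sites$pos <- sort(sample.int(90000, 120))
  windows <- make_windows(c(chr1 = 90000))
  wp <- window_pi(gm, "A", windows)
  wf <- window_fst(gm, "A", "B", windows)
  iA <- which(gm$pop_labels == "A"); iB <- which(gm$pop_labels == "B")
  for (w in seq_len(nrow(windows))) {
    in_w <- gm$sites$pos - 1 >= windows$start[w] &
      gm$sites$pos - 1 < windows$end[w]
    # pi: sum of enumerated per-site values over the window span
    pis <- vapply(which(in_w), function(s) {
      g <- gm$dosage[iA, s]; g <- g[!is.na(g)]
      if (length(g) < 1 || 2 * length(g) < 2) return(NA_real_)
      site_pi_oracle(2 * length(g) - sum(g), sum(g))
    }, numeric(1))
    expect_equal(wp$pi[w],
                 sum(pis, na.rm = TRUE) / (windows$end[w] - windows$start[w]),
                 tolerance = 1e-12)
    # FST: ratio of summed oracle components
    comps <- vapply(which(in_w), function(s)
      wc84_oracle(gm$dosage[iA, s], gm$dosage[iB, s]), numeric(3))
    if (length(comps) && any(!is.na(comps[1, ]))) {
      num <- sum(comps[1, ], na.rm = TRUE)
      den <- sum(colSums(comps), na.rm = TRUE)
      if (den != 0)
        expect_equal(wf$fst[w], num / den, tolerance = 1e-12)
    }
  }
  expect_equal(wp$n_snps, window_count_oracle(gm$sites, windows))
})

test_that("pi is invariant to swapping ref/alt labels at every site", {
  gm <- random_gm(6, 80, miss = 0.05)
  wp1 <- window_pi(gm, "A", make_windows(c(chr1 = 10000), 5000, 5000))
  gm2 <- gm
  gm2$dosage <- 2L - gm$dosage
  wp2 <- window_pi(gm2, "A", make_windows(c(chr1 = 10000), 5000, 5000))
  expect_equal(wp1$pi, wp2$pi)
})

test_that("windowed FST recovers simulated differentiation monotonically", {
  mean_fst <- vapply(c(0.02, 0.1, 0.3), function(F) {
    cfg <- sim_config(seed = 77, n_snps = 10000, fst_background = F,
                      chrom_lengths = c(chr1 = 2e6),
                      pop_sizes = c(A = 8L, B = 8L), sweep_regions = NULL)
    gm <- simulate_genotypes(cfg)$gm
    wf <- window_fst(gm, "A", "B", make_windows(c(chr1 = 2e6)))
    mean(wf$fst, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(mean_fst) > 0))
})

test_that("window pi is stable when the sample size doubles", {
  pis <- vapply(c(8L, 16L), function(n) {
    cfg <- sim_config(seed = 88, n_snps = 20000, fst_background = 0.05,
                      chrom_lengths = c(chr1 = 4e6),
                      pop_sizes = stats::setNames(c(n, 8L), c("A", "B")),
                      sweep_regions = NULL)
    gm <- simulate_genotypes(cfg)$gm
    mean(window_pi(gm, "A", make_windows(c(chr1 = 4e6)))$pi)
  }, numeric(1))
  expect_lt(abs(pis[2] - pis[1]) / pis[1], 0.05)
})

test_that("degenerate windows are marked rather than ranked", {
  # window of fixed differences -> FST 1; empty window -> NA
  d <- matrix(c(rep(0L, 4), rep(2L, 4)), nrow = 8, ncol = 3)
  rownames(d) <- sprintf("s%02d", 1:8)
  gm <- make_gm(d, pos = c(100, 200, 300),
                pops = stats::setNames(rep(c("A", "B"), each = 4), rownames(d)))
  w <- data.frame(chrom = "chr1", start = c(0, 1000), end = c(1000, 2000))
  wf <- window_fst(gm, "A", "B", w)
  expect_equal(wf$fst[1], 1)
  expect_true(is.na(wf$fst[2]))
  expect_equal(wf$n_snps, c(3L, 0L))
  # monomorphic-in-both windows are undefined
  gm0 <- make_gm(matrix(0L, 8, 2), pos = c(100, 200),
                 pops = stats::setNames(rep(c("A", "B"), each = 4),
                                        sprintf("s%02d", 1:8)))
  wf0 <- window_fst(gm0, "A", "B", data.frame(chrom = "chr1", start = 0, end = 1000))
  expect_true(is.na(wf0$fst))
})

test_that("the Hudson alternative agrees with WC in direction on strong signal", {
  cfg <- sim_config(seed = 99, n_snps = 5000, fst_background = 0.2,
                    chrom_lengths = c(chr1 = 1e6),
                    pop_sizes = c(A = 8L, B = 8L), sweep_regions = NULL)
  gm <- simulate_genotypes(cfg)$gm
  w <- make_windows(c(chr1 = 1e6))
  f_wc <- window_fst(gm, "A", "B", w)$fst
  f_hu <- window_fst(gm, "A", "B", w, estimator = "hudson")$fst
  expect_gt(stats::cor(f_wc, f_hu, use = "complete.obs"), 0.9)
})
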