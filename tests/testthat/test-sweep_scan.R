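test_that("log2 ratio follows the declared conventions", {
  expect_equal(log2_pi_ratio(0.002, 0.001), 1)
  expect_equal(log2_pi_ratio(0.003, 0.003), 0)
  expect_equal(log2_pi_ratio(0.001, 0), Inf)
  expect_true(is.na(log2_pi_ratio(0, 0)))
  expect_error(log2_pi_ratio(-1, 1), "negative")
  # swapping selected/control negates every finite ratio exactly
  set.seed(11)
  pc <- stats::runif(50, 1e-5, 1e-2); ps <- stats::runif(50, 1e-5, 1e-2)
  expect_equal(log2_pi_ratio(pc, ps), -log2_pi_ratio(ps, pc))
})

make_scan_table <- function(fst, ratio, n_snps = 10L) {
  n <- length(fst)
  data.frame(chrom = "chr1", start = (seq_len(n) - 1) * 20000,
             end = (seq_len(n) - 1) * 20000 + 40000,
             n_snps = n_snps, pi_selected = 1e-3, pi_control = 1e-3,
             fst = fst, log2_ratio = ratio)
}

test_that("perfectly concordant ranks give exactly the top windows", {
  tab <- make_scan_table(fst = seq(0.01, 1, length.out = 100),
                         ratio = seq(-1, 4, length.out = 100))
  call <- joint_outliers(tab, top_fraction = 0.05)
  expect_equal(call$n_outliers, 5L)
  expect_equal(which(call$windows$outlier), 96:100)
  # thresholds reported are the quantiles actually applied
  expect_equal(call$fst_threshold,
               stats::quantile(tab$fst, 0.95, names = FALSE))
})

test_that("anti-correlated ranks give zero joint outliers", {
  tab <- make_scan_table(fst = seq_len(100) / 100,
                         ratio = rev(seq_len(100)) / 25)
  call <- joint_outliers(tab)
  expect_equal(call$n_outliers, 0L)
})

test_that("sentinel ratio windows are force-passed and undefined windows excluded", {
  fst <- seq(0.01, 1, length.out = 100)
  ratio <- seq(-1, 4, length.out = 100)
  ratio[100] <- Inf                       # swept to zero diversity
  fst[1] <- NA                            # undefined window
  tab <- make_scan_table(fst, ratio)
  call <- joint_outliers(tab)
  expect_equal(call$n_rankable, 99L)
  expect_true(call$windows$outlier[100])
  expect_false(call$windows$rankable[1])
  # min_snps gate removes windows from the ranking
  tab$n_snps[50] <- 0L
  call2 <- joint_outliers(tab, min_snps = 1L)
  expect_false(call2$windows$rankable[50])
  expect_error(joint_outliers(tab[1:10, ]), "rankable")
})

test_that("top_fraction = 1 marks every rankable window an outlier", {
  set.seed(5)
  tab <- make_scan_table(fst = stats::runif(60), ratio = stats::rnorm(60))
  call <- joint_outliers(tab, top_fraction = 1)
  expect_equal(call$n_outliers, call$n_rankable)
  # and the outlier count never exceeds tie-free expectation by much
  call2 <- joint_outliers(tab, top_fraction = 0.05)
  expect_lte(call2$n_outliers, ceiling(0.05 * 60) + 1)
})

test_that("window-to-gene assignment honours the half-open boundary and merges windows", {
  genes <- data.frame(gene_id = c("gA", "gB", "gC"), chrom = "chr1",
                      start = c(50000, 39000, 85000),
                      end = c(60000, 40000, 95000), strand = "+",
                      exon_union_bp = 1000, exon_union_kb = 1)
  win <- data.frame(chrom = "chr1", start = c(40000, 60000),
                    end = c(80000, 90000))
  got <- windows_to_genes(win, genes)
  expect_setequal(got, c("gA", "gC"))      # gB ends exactly at window start
  # contained rule is stricter
  expect_setequal(windows_to_genes(win, genes, rule = "contained"), "gA")
  expect_warning(got0 <- windows_to_genes(win, genes[0, ]), "empty")
  expect_length(got0, 0)
})

test_that("gene assignment equals a brute-force all-pairs interval check", {
  set.seed(17)
  genes <- data.frame(gene_id = sprintf("g%02d", 1:50), chrom = "chr1",
                      start = sample.int(1e6, 50))
  genes$end <- genes$start + sample(500:20000, 50, replace = TRUE)
  win_start <- sort(sample(seq(0, 9.6e5, by = 20000), 10))
  win <- data.frame(chrom = "chr1", start = win_start, end = win_start + 40000)
  got <- windows_to_genes(win, genes)
  oracle <- character(0)
  for (g in seq_len(nrow(genes))) for (w in seq_len(nrow(win))) {
    if (genes$start[g] < win$end[w] && genes$end[g] > win$start[w])
      oracle <- c(oracle, genes$gene_id[g])
  }
  expect_setequal(got, unique(oracle))
})

test_that("Venn partitions are exact set algebra", {
  v <- overlap_sets(list(X = c("a", "b", "c"), Y = c("b", "c", "d")))
  expect_equal(unname(v$counts[c("X", "Y", "X&Y")]), c(1L, 1L, 2L))
  expect_equal(v$members$`X&Y`, c("b", "c"))
  v_id <- overlap_sets(list(S = letters[1:4], T = letters[1:4]))
  expect_equal(unname(v_id$counts), c(0L, 0L, 4L))
  set.seed(29)
  for (i in 1:20) {
    A <- sample(letters, sample(5:15, 1))
    B <- sample(letters, sample(5:15, 1))
    C <- sample(letters, sample(5:15, 1))
    v3 <- overlap_sets(list(A = A, B = B, C = C))
    expect_equal(v3$counts[names(venn3_oracle(A, B, C))], venn3_oracle(A, B, C))
    expect_equal(sum(v3$counts), v3$union_size)
  }
})

test_that("no-sweep joint outlier rate stays at or below the nominal tail", {
  cfg <- sim_config(seed = 55, n_snps = 30000, fst_background = 0.05,
                    chrom_lengths = c(chr1 = 4e6, chr2 = 4e6),
                    pop_sizes = c(A = 8L, B = 8L), sweep_regions = NULL)
  gm <- simulate_genotypes(cfg)$gm
  sw <- scan_windows(gm, "A", "B", chrom_lengths = cfg$chrom_lengths)
  call <- joint_outliers(sw)
  expect_lte(call$n_outliers / call$n_rankable, 0.05 + 0.01)
})

test_that("sweep recall rises as the planted diversity reduction deepens", {
  recall <- vapply(c(0.8, 0.5, 0.2), function(d) {
    cfg <- sim_config(seed = 65, n_snps = 40000,
                      chrom_lengths = c(chr1 = 8e6),
                      pop_sizes = c(A = 8L, B = 8L),
                      sweep_regions = data.frame(chrom = "chr1", start = 3e6,
                                                 end = 3.4e6, selected_pop = "A",
                                                 diversity_reduction = d,
                                                 differentiation_boost = 0.3))
    sim <- simulate_genotypes(cfg)
    sw <- scan_windows(sim$gm, "A", "B", chrom_lengths = cfg$chrom_lengths)
    call <- joint_outliers(sw)
    ow <- call$windows[call$windows$outlier, ]
    mean(window_key(sim$truth$sweep_windows) %in% window_key(ow))
  }, numeric(1))
  expect_true(all(diff(recall) >= 0))
})
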