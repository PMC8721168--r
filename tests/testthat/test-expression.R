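test_that("FPKM reproduces the defining identity and its algebra", {
  genes <- data.frame(gene_id = "g1", chrom = "chr1", start = 0, end = 1000,
                      strand = "+", exon_union_bp = 1000, exon_union_kb = 1)
  ct <- counts_table(matrix(10L, 1, 2, dimnames = list("g1", c("s1", "s2"))),
                     c(s1 = "x", s2 = "y"),
                     mapped_reads = c(s1 = 1e6, s2 = 1e6))
  expect_equal(unname(fpkm(ct, genes)["g1", "s1"]), 10)
  # zero counts give zero FPKM
  ct0 <- counts_table(matrix(0L, 1, 2, dimnames = list("g1", c("s1", "s2"))),
                      c(s1 = "x", s2 = "y"),
                      mapped_reads = c(s1 = 1e6, s2 = 2e6))
  expect_equal(unname(fpkm(ct0, genes)[1, ]), c(0, 0))
})

test_that("FPKM is linear in counts and inversely linear in length", {
  set.seed(3)
  n_g <- 50
  genes <- data.frame(gene_id = sprintf("g%02d", 1:n_g), chrom = "chr1",
                      start = 0, end = 10, strand = "+",
                      exon_union_bp = sample(200:5000, n_g))
  genes$exon_union_kb <- genes$exon_union_bp / 1000
  counts <- matrix(rpois(n_g * 4, 50), n_g, 4,
                   dimnames = list(genes$gene_id, paste0("s", 1:4)))
  mr <- stats::setNames(c(2e6, 3e6, 1e6, 5e6), paste0("s", 1:4))
  grp <- stats::setNames(rep(c("x", "y"), 2), paste0("s", 1:4))
  ct <- counts_table(counts, grp, mr)
  f <- fpkm(ct, genes)
  # element-wise loop oracle
  for (g in sample(n_g, 10)) for (s in 1:4) {
    expect_equal(f[g, s],
                 counts[g, s] / ((mr[s] / 1e6) * genes$exon_union_kb[g]),
                 ignore_attr = TRUE)
  }
  # doubling counts doubles FPKM; doubling length halves it
  ct2 <- counts_table(counts * 2L, grp, mr * 2)
  f2 <- fpkm(ct2, genes)
  expect_equal(f2, f)                   # counts x2, mapped x2 cancel
  genes2 <- genes; genes2$exon_union_kb <- genes$exon_union_kb * 2
  expect_equal(fpkm(ct, genes2), f / 2)
  # missing annotation and zero mapped reads are hard errors
  expect_error(fpkm(ct, genes[-1, ]), "missing")
  bad_mr <- mr; bad_mr[1] <- 0
  expect_error(fpkm(counts_table(counts, grp, bad_mr), genes), "mapped_reads|mapped reads")
})

test_that("size factors recover scaling structure", {
  counts <- matrix(rpois(400, 100), 100, 4,
                   dimnames = list(sprintf("g%03d", 1:100), paste0("s", 1:4)))
  grp <- stats::setNames(rep(c("x", "y"), 2), paste0("s", 1:4))
  sf <- size_factors(counts_table(counts, grp))
  expect_equal(unname(sf), rep(1, 4), tolerance = 0.1)
  # one column doubled gets a factor ~2 relative to the others
  counts2 <- counts; counts2[, 2] <- counts[, 2] * 2L
  sf2 <- size_factors(counts_table(counts2, grp))
  expect_equal(unname(sf2[2] / sf2[1]), 2, tolerance = 0.1)
  # identical columns give exactly 1
  cts <- matrix(rep(rpois(50, 30), 4), 50, 4,
                dimnames = list(sprintf("g%03d", 1:50), paste0("s", 1:4)))
  expect_equal(unname(size_factors(counts_table(cts, grp))), rep(1, 4))
  # NB fixture: factors within 5% of the true simulated depth multipliers
  cfg <- sim_config(seed = 7, rnaseq = list(n_genes = 3000L, n_de = 0L))
  cnt <- simulate_counts(cfg)
  est <- size_factors(cnt$ct)
  expect_equal(unname(est), unname(cnt$truth$size_factors), tolerance = 0.05)
})

test_that("deg_test is symmetric under group swap and flags planted signal", {
  cfg <- sim_config(seed = 9, rnaseq = list(n_genes = 400L, n_de = 40L,
                                            lfc_de = 2, dispersion = 0.05))
  cnt <- simulate_counts(cfg)
  tab12 <- deg_test(cnt$ct, group_order = c("meat", "ornamental"))
  tab21 <- deg_test(cnt$ct, group_order = c("ornamental", "meat"))
  expect_equal(tab12$log2fc, -tab21$log2fc, tolerance = 1e-12)
  expect_equal(tab12$p, tab21$p, tolerance = 1e-12)
  # BH never inverts the p ordering
  ord <- order(tab12$p)
  expect_true(all(diff(tab12$padj[ord]) >= -1e-15))
  expect_true(all(tab12$padj >= tab12$p - 1e-15))
  # planted up-genes trend up, down-genes trend down
  sgn <- cnt$truth$de_sign
  est <- stats::setNames(tab12$log2fc, tab12$gene_id)[names(sgn)]
  expect_gt(mean(sign(est) == sgn), 0.9)
})

test_that("degenerate genes and degenerate designs are handled", {
  counts <- rbind(g1 = c(0L, 0L, 0L, 0L), g2 = c(10L, 12L, 9L, 11L))
  colnames(counts) <- paste0("s", 1:4)
  grp <- stats::setNames(rep(c("x", "y"), each = 2), paste0("s", 1:4))
  tab <- deg_test(counts_table(counts, grp))
  expect_equal(tab$p[tab$gene_id == "g1"], 1)
  expect_equal(tab$log2fc[tab$gene_id == "g1"], 0)
  grp1 <- stats::setNames(c("x", "y", "y", "y"), paste0("s", 1:4))
  expect_error(deg_test(counts_table(counts, grp1)), "at least 2")
})

test_that("DEG calling applies the strict fold-change and p rule", {
  tab <- data.frame(gene_id = sprintf("g%d", 1:6),
                    base_mean = 100,
                    log2fc = c(1, log2(3), -2, -0.8, 1.8, 0),
                    se = 1, stat = 0,
                    p = c(0.04, 0.04, 0.01, 0.01, 0.2, 0.9),
                    padj = c(0.2, 0.2, 0.04, 0.04, 0.4, 0.9))
  out <- call_degs(tab)
  # FC exactly 2 (log2fc = 1) is NOT called; FC 3 with p < .05 is up
  expect_equal(out$call, c("ns", "up", "down", "ns", "ns", "ns"))
  lists <- deg_lists(out)
  expect_equal(lists$up, "g2")
  expect_equal(lists$down, "g3")
  # adjusted-p variant gates on padj instead
  out2 <- call_degs(tab, use_adjusted = TRUE)
  expect_equal(out2$call, c("ns", "ns", "down", "ns", "ns", "ns"))
  # row-wise enumeration oracle on random tables
  set.seed(31)
  rt <- data.frame(gene_id = sprintf("r%03d", 1:300), base_mean = 50,
                   log2fc = stats::rnorm(300, 0, 2), se = 1, stat = 0,
                   p = stats::runif(300))
  rt$padj <- stats::p.adjust(rt$p, "BH")
  called <- call_degs(rt)
  for (i in sample(300, 50)) {
    fc <- 2^rt$log2fc[i]
    expected <- if (rt$p[i] < 0.05 && fc > 2) "up"
      else if (rt$p[i] < 0.05 && fc < 0.5) "down" else "ns"
    expect_equal(called$call[i], expected)
  }
})

test_that("planted-DE recovery is stable across seeds", {
  sens <- fdp <- numeric(5)
  for (s in seq_len(5)) {
    cfg <- sim_config(seed = 100 + s,
                      rnaseq = list(n_genes = 1000L, n_de = 100L,
                                    lfc_de = 2, dispersion = 0.05))
    cnt <- simulate_counts(cfg)
    tab <- call_degs(deg_test(cnt$ct))
    called <- tab$gene_id[tab$call != "ns"]
    sens[s] <- mean(cnt$truth$de_genes %in% called)
    fdp[s] <- if (length(called)) mean(!called %in% cnt$truth$de_genes) else 0
  }
  expect_true(all(sens > 0.7))
  expect_lt(stats::sd(sens) / mean(sens), 0.2)
  expect_lt(stats::sd(fdp) / max(mean(fdp), 1e-9), 1.5)
})
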