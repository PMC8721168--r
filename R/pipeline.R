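#' Default pipeline configuration
#'
#' All analysis parameters with their study defaults: 40-kb windows with
#' 20-kb increments, top-5% joint outlier fraction, Q20 site quality,
#' 5-bp minimum SNP spacing, depth bounds of \[1/3, 5\] times the average
#' depth, 1,000 bootstrap replicates, fold-change bounds 2 and 0.5 with
#' raw p < 0.05 for DEG calling. The `sim` block configures the
#' synthetic cohort (see [sim_config()]); comparisons pair each
#' selected population with its control in both directions.
#'
#' @param seed master seed.
#' @param outdir output directory for [run_pipeline()].
#' @return nested list of class `pipeline_config`.
#' @export
default_config <- function(seed = 1L, outdir = "results/run") {
  structure(list(
    seed = as.integer(seed),
    outdir = outdir,
    sim = list(),                      # overrides for sim_config()
    params = list(
      window_size = 40000,
      window_step = 20000,
      top_fraction = 0.05,
      min_snps = 1,
      min_qual = 20,
      min_spacing_bp = 5,
      depth_low_mult = 1 / 3,
      depth_high_mult = 5,
      n_boot = 1000,
      pca_k = 10,
      fc_hi = 2,
      fc_lo = 0.5,
      alpha = 0.05,
      use_adjusted = FALSE,
      estimator = "wc",
      gene_rule = "overlap",
      shared_deg_rule = "intersection"
    ),
    comparisons = list(
      list(selected = "A", control = "C"),
      list(selected = "B", control = "C"),
      list(selected = "C", control = "A"),
      list(selected = "C", control = "B")
    )
  ), class = "pipeline_config")
}

#' Validate and normalise a pipeline configuration
#'
#' Accepts a YAML path or a (possibly partial) config list, fills every
#' missing field from [default_config()], and checks ranges and
#' population references. All problems are collected and reported
#' together, not first-fail.
#'
#' @param cfg YAML file path or list.
#' @return the normalised `pipeline_config`; errors abort with the full
#'   list of problems.
#' @export
validate_config <- function(cfg = list()) {
  if (is.character(cfg)) cfg <- yaml::read_yaml(cfg)
  base <- default_config()
  out <- utils::modifyList(unclass(base), cfg, keep.null = TRUE)
  # modifyList replaces whole lists for comparisons; keep user's if given
  if (!is.null(cfg$comparisons)) out$comparisons <- cfg$comparisons
  p <- out$params
  errs <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) errs <<- c(errs, msg)
  chk(p$top_fraction > 0 && p$top_fraction <= 1,
      "top_fraction must lie in (0, 1]")
  chk(p$window_step > 0 && p$window_size >= p$window_step,
      "need window_size >= window_step > 0")
  chk(p$min_qual >= 0, "min_qual must be non-negative")
  chk(p$min_spacing_bp >= 0, "min_spacing_bp must be non-negative")
  chk(p$depth_low_mult > 0 && p$depth_high_mult > p$depth_low_mult,
      "need depth_high_mult > depth_low_mult > 0")
  chk(p$n_boot >= 1, "n_boot must be at least 1")
  chk(p$fc_hi > 1 && p$fc_lo > 0 && p$fc_lo < 1,
      "need fc_hi > 1 and fc_lo in (0, 1)")
  chk(p$alpha > 0 && p$alpha < 1, "alpha must lie in (0, 1)")
  chk(p$estimator %in% c("wc", "hudson"), "estimator must be 'wc' or 'hudson'")
  chk(p$gene_rule %in% c("overlap", "contained"),
      "gene_rule must be 'overlap' or 'contained'")
  chk(p$shared_deg_rule %in% c("intersection", "union"),
      "shared_deg_rule must be 'intersection' or 'union'")
  sim_cfg <- try(do.call(sim_config, c(list(seed = out$seed), out$sim)),
                 silent = TRUE)
  if (inherits(sim_cfg, "try-error")) {
    errs <- c(errs, paste("sim block:", attr(sim_cfg, "condition")$message))
  } else {
    pops <- names(sim_cfg$pop_sizes)
    for (cmp in out$comparisons) {
      for (role in c("selected", "control"))
        chk(cmp[[role]] %in% pops,
            sprintf("comparison %s population '%s' not simulated",
                    role, cmp[[role]]))
    }
  }
  if (length(errs))
    stop("invalid pipeline configuration:\n  - ",
         paste(errs, collapse = "\n  - "), call. = FALSE)
  out$sim_config <- sim_cfg
  class(out) <- "pipeline_config"
  out
}

#' Run the full pipeline from one configuration
#'
#' Stages, in dependency order: simulate the cohort (VCF, sample map,
#' GFF, counts); QC-filter the SNPs; compute windowed theta-pi/FST scans
#' per comparison; call joint top-fraction outlier windows and map them
#' to genes; summarise population structure (NJ tree with bootstrap,
#' PCA); quantify FPKM and call DEGs; intersect sweep genes with DEGs
#' into candidate reports. Every stage reads its inputs from the files
#' the previous stage wrote, and all outputs are plain text with no
#' timestamps, so identical configurations give byte-identical output
#' trees.
#'
#' @param cfg a `pipeline_config`, partial list, or YAML path (passed
#'   through [validate_config()]).
#' @param outdir optional override of the configured output directory.
#' @return invisibly, a manifest list: per stage, the files written and
#'   headline counts. Also written as `manifest.json` in `outdir`.
#' @export
run_pipeline <- function(cfg = default_config(), outdir = NULL) {
  cfg <- validate_config(unclass(cfg))
  if (!is.null(outdir)) cfg$outdir <- outdir
  out <- cfg$outdir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  p <- cfg$params
  scfg <- cfg$sim_config
  manifest <- list(seed = cfg$seed, stages = list())
  path <- function(...) file.path(out, paste0(...))
  log_stage <- function(name, files, ...) {
    manifest$stages[[name]] <<- c(list(files = files), list(...))
    message(sprintf("[%s] %s", name,
                    paste(names(list(...)), unlist(list(...)),
                          sep = "=", collapse = " ")))
  }

  ## 1. simulate ------------------------------------------------------
  sim <- simulate_genotypes(scfg, window_size = p$window_size,
                            window_step = p$window_step)
  genes <- simulate_annotation(scfg)
  cnt <- simulate_counts(scfg, gene_models = genes)
  write_vcf(sim$gm, path("cohort.vcf"), chrom_lengths = scfg$chrom_lengths)
  utils::write.table(
    data.frame(sample = names(sim$gm$pop_labels),
               population = unname(sim$gm$pop_labels)),
    path("samples.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write_gff(genes, path("genes.gff3"))
  write_counts(cnt$ct, path("counts.tsv"), path("groups.tsv"),
               path("mapped_reads.tsv"))
  truth <- list(sweep_regions = sim$truth$sweep_regions,
                sweep_windows = sim$truth$sweep_windows,
                de_genes = cnt$truth$de_genes,
                de_sign = as.list(cnt$truth$de_sign),
                size_factors = as.list(cnt$truth$size_factors))
  jsonlite::write_json(truth, path("truth.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  log_stage("simulate",
            c("cohort.vcf", "samples.tsv", "genes.gff3", "counts.tsv",
              "groups.tsv", "mapped_reads.tsv", "truth.json"),
            n_snps = n_sites(sim$gm), n_samples = n_samples(sim$gm),
            n_genes = nrow(genes))

  ## 2. filter --------------------------------------------------------
  gm <- read_vcf(path("cohort.vcf"), path("samples.tsv"))
  flt <- apply_filters(gm, min_qual = p$min_qual,
                       min_spacing_bp = p$min_spacing_bp,
                       low_mult = p$depth_low_mult,
                       high_mult = p$depth_high_mult)
  write_vcf(flt$gm, path("filtered.vcf"), chrom_lengths = scfg$chrom_lengths)
  jsonlite::write_json(flt$report, path("filter_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_stage("filter", c("filtered.vcf", "filter_report.json"),
            n_input = flt$report$n_input, n_pass = flt$report$n_pass)

  ## 3 + 4. scan and sweep calls per comparison ------------------------
  windows <- make_windows(scfg$chrom_lengths, p$window_size, p$window_step)
  gmf <- flt$gm
  annotation <- read_gff(path("genes.gff3"))
  sweep_gene_sets <- list()
  scan_files <- character(0)
  for (cmp in cfg$comparisons) {
    lbl <- sprintf("%s_vs_%s", cmp$selected, cmp$control)
    sw <- scan_windows(gmf, cmp$selected, cmp$control, windows = windows,
                       estimator = p$estimator)
    call <- joint_outliers(sw, top_fraction = p$top_fraction,
                           min_snps = p$min_snps)
    gset <- windows_to_genes(call, annotation, rule = p$gene_rule)
    sweep_gene_sets[[lbl]] <- gset
    scan_f <- paste0("scan_", lbl, ".tsv")
    utils::write.table(format_num(call$windows), path(scan_f), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    ow <- call$windows[call$windows$outlier, c("chrom", "start", "end")]
    bed_f <- paste0("outliers_", lbl, ".bed")
    utils::write.table(ow, path(bed_f), sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    genes_f <- paste0("sweep_genes_", lbl, ".txt")
    writeLines(gset, path(genes_f))
    scan_files <- c(scan_files, scan_f, bed_f, genes_f)
    log_stage(paste0("sweep_", lbl), c(scan_f, bed_f, genes_f),
              n_rankable = call$n_rankable, n_outliers = call$n_outliers,
              n_genes = length(gset),
              fst_threshold = signif(call$fst_threshold, 6))
  }
  # cross-comparison overlap of the two "meat selected" gene sets, when
  # the design has at least two comparisons
  if (length(sweep_gene_sets) >= 2) {
    venn <- overlap_sets(sweep_gene_sets[1:2])
    jsonlite::write_json(list(counts = as.list(venn$counts),
                              union_size = venn$union_size),
                         path("sweep_venn.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }

  ## 5. population structure ------------------------------------------
  D <- allele_sharing_distance(gmf)
  tree <- bootstrap_support(gmf, n_boot = p$n_boot,
                            seed = substream_seed(cfg$seed, "bootstrap"))
  ape::write.tree(tree, path("nj_tree.nwk"))
  pca <- pca_genotypes(gmf, k = p$pca_k)
  sc <- data.frame(sample = rownames(pca$scores),
                   population = unname(gmf$pop_labels[rownames(pca$scores)]),
                   format_num(as.data.frame(pca$scores)),
                   stringsAsFactors = FALSE)
  utils::write.table(sc, path("pca_scores.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  log_stage("structure", c("nj_tree.nwk", "pca_scores.tsv"),
            n_boot = p$n_boot,
            pc1_varexp = signif(pca$varexp[1], 6))

  ## 6. expression ----------------------------------------------------
  ct <- read_counts(path("counts.tsv"), path("groups.tsv"),
                    path("mapped_reads.tsv"))
  fp <- fpkm(ct, annotation)
  utils::write.table(
    data.frame(gene_id = rownames(fp), format_num(as.data.frame(fp)),
               check.names = FALSE),
    path("fpkm.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  degs <- call_degs(deg_test(ct), fc_hi = p$fc_hi, fc_lo = p$fc_lo,
                    alpha = p$alpha, use_adjusted = p$use_adjusted)
  utils::write.table(format_num(degs), path("degs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ud <- deg_lists(degs)
  log_stage("express", c("fpkm.tsv", "degs.tsv"),
            n_up = length(ud$up), n_down = length(ud$down))

  ## 7. integration ---------------------------------------------------
  reports <- list()
  for (lbl in names(sweep_gene_sets)) {
    rep <- integrate_candidates(sweep_gene_sets[[lbl]], list(degs),
                                shared_deg_rule = p$shared_deg_rule,
                                comparison = lbl,
                                annotation_genes = annotation$gene_id)
    reports[[lbl]] <- rep
  }
  cand <- do.call(rbind, lapply(reports, function(r) {
    if (is.null(r$evidence) || !nrow(r$evidence)) return(NULL)
    cbind(comparison = r$comparison, r$evidence)
  }))
  if (is.null(cand))
    cand <- data.frame(comparison = character(0), contrast = character(0),
                       gene_id = character(0), log2fc = numeric(0),
                       p = numeric(0), call = character(0))
  utils::write.table(format_num(cand), path("candidates.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    lapply(reports, function(r) list(
      n_sweep_genes = length(r$sweep_genes),
      n_shared_degs = length(r$shared_degs),
      candidates = r$candidates)),
    path("integration.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_stage("integrate", c("candidates.tsv", "integration.json"),
            n_candidates = length(unique(cand$gene_id)))

  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

# stable numeric formatting for TSV output (deterministic across runs)
format_num <- function(df) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- signif(df[[j]], 10)
  }
  df
}
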