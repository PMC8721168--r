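#' Simulation configuration
#'
#' Bundles every parameter of the synthetic cohort: a small number of
#' diverged populations genotyped at tens of thousands of SNPs, with one
#' or more engineered sweep regions (locally reduced diversity in the
#' selected population plus elevated differentiation), a matching gene
#' annotation, and small-group negative-binomial RNA-seq count matrices
#' with planted differentially expressed genes.
#'
#' Population differentiation follows the Balding-Nichols model: each
#' population's allele frequency at a site is drawn from a Beta
#' distribution centred on the ancestral frequency with variance governed
#' by `fst_background` (the model's F), so the target FST is controlled
#' analytically rather than through forward simulation. Defaults mirror a
#' three-breed resequencing cohort of 23 birds at ~7x depth with
#' 4-vs-4 muscle transcriptomes.
#'
#' @param seed master seed; all stage substreams derive from it.
#' @param pop_sizes named integer vector, diploid samples per population.
#' @param chrom_lengths named integer vector of chromosome lengths (bp).
#' @param n_snps total SNPs across the genome.
#' @param fst_background Balding-Nichols F in [0, 1).
#' @param sweep_regions data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open), `selected_pop`, `diversity_reduction` in (0, 1]
#'   (multiplier on expected heterozygosity inside the sweep; 1 = no
#'   reduction), `differentiation_boost` in [0, 1) (fraction of the
#'   remaining distance to the nearer allele-frequency boundary the
#'   selected population is pushed). `NULL` for no sweeps.
#' @param rnaseq list: `n_genes`, `n_per_group`, `mean_log_expression`,
#'   `sd_log_expression`, `dispersion`, `n_de`, `lfc_de`, `n_de_in_sweep`.
#' @param depth_model list: `mean_depth` (per sample), `overdispersion`
#'   (negative-binomial alpha for the summed site depth).
#' @param qual_model list: `low_frac`, the fraction of sites drawn with
#'   Phred quality below 20 to exercise the Q20 filter.
#' @param annotation list: `n_genes`, `gene_length`, `n_exons`.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       pop_sizes = c(A = 8L, B = 8L, C = 7L),
                       chrom_lengths = c(chr1 = 5e6, chr2 = 5e6),
                       n_snps = 50000L,
                       fst_background = 0.05,
                       sweep_regions = data.frame(
                         chrom = c("chr1", "chr2"),
                         start = c(2e6, 2e6),
                         end   = c(2.4e6, 2.4e6),
                         selected_pop = c("A", "C"),
                         diversity_reduction = 0.2,
                         differentiation_boost = 0.3,
                         stringsAsFactors = FALSE),
                       rnaseq = list(),
                       depth_model = list(mean_depth = 7.3, overdispersion = 0.3),
                       qual_model = list(low_frac = 0.05),
                       annotation = list(n_genes = 1000L, gene_length = 4000L,
                                         n_exons = 3L)) {
  rnaseq_defaults <- list(n_genes = 2000L, n_per_group = 4L,
                          mean_log_expression = 4, sd_log_expression = 1.5,
                          dispersion = 0.1, n_de = 200L, lfc_de = 2,
                          n_de_in_sweep = 10L)
  rnaseq <- utils::modifyList(rnaseq_defaults, rnaseq)
  cfg <- list(seed = as.integer(seed), pop_sizes = pop_sizes,
              chrom_lengths = chrom_lengths, n_snps = as.integer(n_snps),
              fst_background = fst_background, sweep_regions = sweep_regions,
              rnaseq = rnaseq, depth_model = depth_model,
              qual_model = qual_model, annotation = annotation)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$fst_background < 0 || cfg$fst_background >= 1)
    stop("fst_background must lie in [0, 1)")
  if (cfg$qual_model$low_frac < 0 || cfg$qual_model$low_frac > 1)
    stop("qual_model$low_frac must lie in [0, 1]")
  sr <- cfg$sweep_regions
  if (!is.null(sr) && nrow(sr)) {
    if (!all(sr$chrom %in% names(cfg$chrom_lengths)))
      stop("sweep region on unknown chromosome")
    lens <- cfg$chrom_lengths[sr$chrom]
    if (any(sr$start < 0) || any(sr$end > lens) || any(sr$start >= sr$end))
      stop("sweep region outside chromosome bounds")
    if (!all(sr$selected_pop %in% names(cfg$pop_sizes)))
      stop("sweep selected_pop not a simulated population")
    if (any(sr$diversity_reduction <= 0) || any(sr$diversity_reduction > 1))
      stop("diversity_reduction must lie in (0, 1]")
    if (any(sr$differentiation_boost < 0) || any(sr$differentiation_boost >= 1))
      stop("differentiation_boost must lie in [0, 1)")
  }
  rn <- cfg$rnaseq
  if (rn$n_de > rn$n_genes) stop("n_de cannot exceed n_genes")
  if (rn$n_per_group < 2) stop("n_per_group must be at least 2")
  invisible(cfg)
}

# Deterministic heterozygosity reduction: move p toward the nearer boundary
# so that 2p'(1-p') = d * 2p(1-p), staying on the same side of 1/2.
reduce_het <- function(p, d) {
  h <- 2 * p * (1 - p)
  lo <- (1 - sqrt(pmax(0, 1 - 2 * d * h))) / 2
  ifelse(p <= 0.5, lo, 1 - lo)
}

# Push a fraction b of the remaining distance to the nearer boundary.
boost_displacement <- function(p, b) {
  ifelse(p <= 0.5, p * (1 - b), p + b * (1 - p))
}

#' Simulate genotypes for a multi-population cohort with planted sweeps
#'
#' Ancestral allele frequencies are Beta-distributed on (0.05, 0.95);
#' per-population frequencies are Balding-Nichols draws with the
#' configured F. Inside each sweep region the selected population's
#' frequency is first transformed deterministically so its expected
#' heterozygosity is multiplied by `diversity_reduction`, then pushed a
#' further `differentiation_boost` fraction toward the nearer boundary.
#' Diploid genotypes are binomial draws from the population frequency;
#' site QUAL and summed depth are generated from the quality and depth
#' models so the downstream QC filters have something to remove.
#'
#' @param cfg a [sim_config()].
#' @param window_size,window_step window grid used to derive the truth
#'   set of windows fully inside sweep regions.
#' @return list with elements `gm` (a [genotype_matrix()]) and `truth`
#'   (list: `sweep_regions`, `sweep_windows`, `pop_freqs`).
#' @export
simulate_genotypes <- function(cfg, window_size = 40000, window_step = 20000) {
  set.seed(substream_seed(cfg$seed, "genotypes"))
  pops <- names(cfg$pop_sizes)
  sample_ids <- unlist(lapply(pops, function(p)
    sprintf("%s%02d", p, seq_len(cfg$pop_sizes[[p]]))))
  pop_labels <- stats::setNames(rep(pops, cfg$pop_sizes), sample_ids)

  # apportion SNPs to chromosomes by length, positions uniform without ties
  lens <- cfg$chrom_lengths
  n_per_chrom <- round(cfg$n_snps * lens / sum(lens))
  n_per_chrom[length(n_per_chrom)] <- cfg$n_snps - sum(n_per_chrom[-length(n_per_chrom)])
  chrom <- rep(names(lens), n_per_chrom)
  pos <- unlist(lapply(seq_along(lens), function(i)
    sort(sample.int(lens[[i]], n_per_chrom[[i]]))))
  m <- cfg$n_snps

  p0 <- 0.05 + 0.9 * stats::rbeta(m, 0.7, 0.7)
  F <- cfg$fst_background
  pop_freqs <- matrix(NA_real_, nrow = length(pops), ncol = m,
                      dimnames = list(pops, NULL))
  for (p in pops) {
    pop_freqs[p, ] <- if (F > 0) {
      stats::rbeta(m, p0 * (1 - F) / F, (1 - p0) * (1 - F) / F)
    } else p0
  }

  sr <- cfg$sweep_regions
  if (!is.null(sr) && nrow(sr)) {
    for (i in seq_len(nrow(sr))) {
      # positions are 1-based; regions 0-based half-open
      in_region <- chrom == sr$chrom[i] &
        pos > sr$start[i] & pos <= sr$end[i]
      sel <- sr$selected_pop[i]
      p_sel <- pop_freqs[sel, in_region]
      p_sel <- reduce_het(p_sel, sr$diversity_reduction[i])
      p_sel <- boost_displacement(p_sel, sr$differentiation_boost[i])
      pop_freqs[sel, in_region] <- p_sel
    }
  }

  dosage <- matrix(NA_integer_, nrow = length(sample_ids), ncol = m,
                   dimnames = list(sample_ids, NULL))
  for (p in pops) {
    idx <- which(pop_labels == p)
    n_i <- length(idx)
    dosage[idx, ] <- matrix(
      stats::rbinom(n_i * m, 2L, rep(pop_freqs[p, ], each = n_i)),
      nrow = n_i)
  }

  low <- stats::runif(m) < cfg$qual_model$low_frac
  qual <- ifelse(low, stats::runif(m, 5, 19.5), stats::runif(m, 30, 60))
  depth_mu <- cfg$depth_model$mean_depth * length(sample_ids)
  alpha <- cfg$depth_model$overdispersion
  site_depth <- if (alpha > 0) {
    stats::rnbinom(m, mu = depth_mu, size = 1 / alpha)
  } else {
    stats::rpois(m, depth_mu)
  }

  ref_alt <- sample_ref_alt(m)
  sites <- data.frame(chrom = chrom, pos = as.integer(pos),
                      ref = ref_alt$ref, alt = ref_alt$alt,
                      qual = qual, site_depth = as.numeric(site_depth),
                      stringsAsFactors = FALSE)
  gm <- genotype_matrix(dosage, sites, pop_labels, depth_source = "simulated")

  truth <- list(sweep_regions = sr,
                sweep_windows = truth_sweep_windows(cfg, window_size, window_step),
                pop_freqs = pop_freqs)
  list(gm = gm, truth = truth)
}

sample_ref_alt <- function(m) {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, m, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
  list(ref = ref, alt = unname(alt))
}

# Windows of the scan grid that lie fully inside a sweep region: the
# ground truth against which outlier recall is measured.
truth_sweep_windows <- function(cfg, window_size, window_step) {
  sr <- cfg$sweep_regions
  if (is.null(sr) || !nrow(sr))
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), selected_pop = character(0)))
  win <- make_windows(cfg$chrom_lengths, size = window_size, step = window_step)
  out <- lapply(seq_len(nrow(sr)), function(i) {
    inside <- win$chrom == sr$chrom[i] &
      win$start >= sr$start[i] & win$end <= sr$end[i]
    if (!any(inside)) return(NULL)
    cbind(win[inside, c("chrom", "start", "end")],
          selected_pop = sr$selected_pop[i])
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Simulate a gene annotation matched to the genome and its sweep regions
#'
#' Genes are tiled non-overlapping along each chromosome with regularly
#' spaced multi-exon structures. The tiling is then adjusted so that every
#' sweep region contains at least one gene strictly inside it and one gene
#' spanning its left boundary, so window-to-gene assignment can be tested
#' on both containment and partial overlap.
#'
#' @param cfg a [sim_config()].
#' @return data.frame of gene models in the same format as [read_gff()],
#'   plus an `exons` attribute (data.frame of exon intervals, 0-based
#'   half-open) used by [write_gff()].
#' @export
simulate_annotation <- function(cfg) {
  an <- cfg$annotation
  lens <- cfg$chrom_lengths
  n_per_chrom <- round(an$n_genes * lens / sum(lens))
  n_per_chrom[length(n_per_chrom)] <- an$n_genes - sum(n_per_chrom[-length(n_per_chrom)])
  glen <- an$gene_length
  genes <- do.call(rbind, lapply(seq_along(lens), function(ci) {
    n_g <- n_per_chrom[[ci]]
    spacing <- lens[[ci]] / n_g
    if (spacing < glen + 2) stop("genes cannot fit on chromosome ", names(lens)[ci])
    start <- round((seq_len(n_g) - 0.5) * spacing - glen / 2)
    data.frame(chrom = names(lens)[ci], start = start, end = start + glen,
               stringsAsFactors = FALSE)
  }))

  sr <- cfg$sweep_regions
  if (!is.null(sr) && nrow(sr)) {
    for (i in seq_len(nrow(sr))) {
      on_chr <- which(genes$chrom == sr$chrom[i])
      inside <- on_chr[genes$start[on_chr] >= sr$start[i] &
                       genes$end[on_chr] <= sr$end[i]]
      if (!length(inside)) {
        # recentre the nearest gene into the region
        mid <- (sr$start[i] + sr$end[i]) / 2
        j <- on_chr[which.min(abs((genes$start[on_chr] + genes$end[on_chr]) / 2 - mid))]
        genes$start[j] <- round(mid - glen / 2)
        genes$end[j] <- genes$start[j] + glen
      }
      # one gene straddling the left boundary
      straddle <- on_chr[genes$start[on_chr] < sr$start[i] &
                         genes$end[on_chr] > sr$start[i]]
      if (!length(straddle)) {
        d <- abs((genes$start[on_chr] + genes$end[on_chr]) / 2 - sr$start[i])
        cand <- on_chr[order(d)]
        # don't steal the only interior gene
        inside_now <- on_chr[genes$start[on_chr] >= sr$start[i] &
                             genes$end[on_chr] <= sr$end[i]]
        j <- setdiff(cand, if (length(inside_now) == 1L) inside_now else integer(0))[1]
        genes$start[j] <- round(sr$start[i] - glen / 2)
        genes$end[j] <- genes$start[j] + glen
      }
    }
    genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
    if (any(diff(genes$start) <= 0 & diff(as.integer(factor(genes$chrom))) == 0) ||
        any(genes$start[-1] < genes$end[-nrow(genes)] &
            genes$chrom[-1] == genes$chrom[-nrow(genes)]))
      stop("gene adjustment produced overlapping genes; reduce n_genes or gene_length")
  }
  genes$gene_id <- sprintf("gene%04d", seq_len(nrow(genes)))
  genes$strand <- rep(c("+", "-"), length.out = nrow(genes))

  # alternating equal-size exons/introns: n_exons exons, n_exons-1 introns
  k <- an$n_exons
  piece <- glen / (2 * k - 1)
  exons <- do.call(rbind, lapply(seq_len(nrow(genes)), function(g) {
    es <- genes$start[g] + round((seq_len(k) - 1) * 2 * piece)
    ee <- pmin(es + round(piece), genes$end[g])
    data.frame(gene_id = genes$gene_id[g], chrom = genes$chrom[g],
               start = es, end = ee, stringsAsFactors = FALSE)
  }))
  exon_bp <- tapply(exons$end - exons$start, exons$gene_id, sum)
  genes$exon_union_bp <- as.numeric(exon_bp[genes$gene_id])
  genes$exon_union_kb <- genes$exon_union_bp / 1000
  rownames(genes) <- NULL
  genes <- genes[, c("gene_id", "chrom", "start", "end", "strand",
                     "exon_union_bp", "exon_union_kb")]
  attr(genes, "exons") <- exons
  genes
}

#' Write simulated gene models as GFF3
#'
#' @param genes output of [simulate_annotation()] (needs its `exons`
#'   attribute).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff <- function(genes, path) {
  exons <- attr(genes, "exons")
  if (is.null(exons)) stop("gene table lacks exon structures")
  lines <- c("##gff-version 3")
  for (g in seq_len(nrow(genes))) {
    gid <- genes$gene_id[g]
    st <- genes$strand[g]
    # 0-based half-open -> 1-based closed
    lines <- c(lines,
      sprintf("%s\tpopsweep\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              genes$chrom[g], genes$start[g] + 1L, genes$end[g], st, gid),
      sprintf("%s\tpopsweep\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.t1;Parent=%s",
              genes$chrom[g], genes$start[g] + 1L, genes$end[g], st, gid, gid))
    ex <- exons[exons$gene_id == gid, , drop = FALSE]
    lines <- c(lines,
      sprintf("%s\tpopsweep\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s.t1",
              ex$chrom, ex$start + 1L, ex$end, st, gid, seq_len(nrow(ex)), gid))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Simulate a two-group RNA-seq count matrix with planted DE genes
#'
#' Gene baseline means are log-normal; counts are negative-binomial with
#' the configured dispersion around mean x true size factor; `n_de` genes
#' receive a multiplicative fold change of `2^lfc_de` in group 2 (half up,
#' half down). When gene models are supplied the counted genes are exactly
#' the annotated genes and `n_de_in_sweep` of the planted DE genes are
#' drawn from genes lying fully inside sweep regions, so the end-to-end
#' sweep-by-expression intersection has known positives.
#'
#' @param cfg a [sim_config()].
#' @param gene_models optional gene table from [simulate_annotation()].
#' @param group_names names for the two conditions.
#' @return list: `ct` (a [counts_table()]) and `truth` (list: `de_genes`,
#'   `de_sign`, `size_factors`, `mu`).
#' @export
simulate_counts <- function(cfg, gene_models = NULL,
                            group_names = c("meat", "ornamental")) {
  set.seed(substream_seed(cfg$seed, "counts"))
  rn <- cfg$rnaseq
  if (is.null(gene_models)) {
    gene_ids <- sprintf("gene%04d", seq_len(rn$n_genes))
  } else {
    gene_ids <- gene_models$gene_id
  }
  n_genes <- length(gene_ids)
  n <- rn$n_per_group
  sample_ids <- c(sprintf("%s%d", group_names[1], seq_len(n)),
                  sprintf("%s%d", group_names[2], seq_len(n)))
  groups <- stats::setNames(rep(group_names, each = n), sample_ids)

  mu <- exp(stats::rnorm(n_genes, rn$mean_log_expression, rn$sd_log_expression))
  sf <- exp(stats::rnorm(2 * n, 0, 0.15))
  sf <- sf / exp(mean(log(sf)))

  n_de <- min(rn$n_de, n_genes)
  de_idx <- integer(0)
  if (n_de > 0) {
    forced <- integer(0)
    if (!is.null(gene_models) && rn$n_de_in_sweep > 0 &&
        !is.null(cfg$sweep_regions) && nrow(cfg$sweep_regions)) {
      sw <- genes_inside_regions(gene_models, cfg$sweep_regions)
      forced <- utils::head(match(sw, gene_ids), min(rn$n_de_in_sweep, n_de))
    }
    rest <- sample(setdiff(seq_len(n_genes), forced), n_de - length(forced))
    de_idx <- c(forced, rest)
  }
  lfc <- numeric(n_genes)
  if (length(de_idx)) {
    half <- ceiling(length(de_idx) / 2)
    lfc[de_idx[seq_len(half)]] <- rn$lfc_de
    lfc[de_idx[-seq_len(half)]] <- -rn$lfc_de
  }

  mean_mat <- outer(mu, sf) *
    2^(outer(lfc, as.numeric(groups == group_names[2])))
  counts <- if (rn$dispersion > 0) {
    matrix(stats::rnbinom(length(mean_mat), mu = mean_mat,
                          size = 1 / rn$dispersion),
           nrow = n_genes)
  } else {
    matrix(stats::rpois(length(mean_mat), mean_mat), nrow = n_genes)
  }
  dimnames(counts) <- list(gene_ids, sample_ids)
  mapped <- ceiling(colSums(counts) * 1.05)
  ct <- counts_table(counts, groups, mapped)
  truth <- list(de_genes = gene_ids[de_idx],
                de_sign = stats::setNames(sign(lfc[de_idx]), gene_ids[de_idx]),
                size_factors = stats::setNames(sf, sample_ids),
                mu = stats::setNames(mu, gene_ids))
  list(ct = ct, truth = truth)
}

# gene ids whose [start, end) lies fully inside any sweep region
genes_inside_regions <- function(genes, regions) {
  hit <- rep(FALSE, nrow(genes))
  for (i in seq_len(nrow(regions))) {
    hit <- hit | (genes$chrom == regions$chrom[i] &
                  genes$start >= regions$start[i] &
                  genes$end <= regions$end[i])
  }
  genes$gene_id[hit]
}
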