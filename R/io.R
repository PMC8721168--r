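#' Read a multi-sample VCF into a genotype matrix
#'
#' Ingests a VCF 4.x file, keeping only biallelic SNP records (single-base
#' REF and ALT, exactly one ALT allele). Indels, multi-allelic records and
#' records without a called ALT are skipped and counted, never split:
#' splitting multi-allelics would silently change site counts downstream.
#'
#' Site depth is taken from the INFO `DP` field when present, otherwise as
#' the sum of per-sample FORMAT `DP` values; the source used is recorded in
#' the returned object (`depth_source`).
#'
#' @param path path to a VCF file (plain or bgzipped).
#' @param sample_map path to a two-column TSV (`sample<TAB>population`,
#'   with a header line) or a named character vector mapping sample id to
#'   population.
#' @return a [genotype_matrix()] with attribute `n_skipped`, the number of
#'   non-SNP / multi-allelic records dropped.
#' @export
read_vcf <- function(path, sample_map) {
  pop_labels <- if (is.character(sample_map) && length(sample_map) == 1L &&
                    file.exists(sample_map)) {
    read_sample_map(sample_map)
  } else {
    sample_map
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  snp <- !is.na(alt) & nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_skipped <- sum(!snp)
  if (!any(snp)) stop("no biallelic SNP records in ", path)

  gt <- vcfR::extract.gt(v, element = "GT")[snp, , drop = FALSE]
  samples <- colnames(gt)
  missing_samples <- setdiff(samples, names(pop_labels))
  if (length(missing_samples))
    stop("samples absent from the sample map: ",
         paste(missing_samples, collapse = ", "))

  # GT strings -> alt-allele dosage; "." anywhere means a missing call
  dos <- gt_to_dosage(gt)              # sites x samples
  qual <- suppressWarnings(as.numeric(fix[snp, "QUAL"]))

  info_dp <- suppressWarnings(
    as.numeric(vcfR::extract.info(v, element = "DP"))[snp])
  if (all(is.na(info_dp))) {
    fmt_dp <- suppressWarnings(
      vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))[snp, , drop = FALSE]
    site_depth <- rowSums(fmt_dp, na.rm = TRUE)
    depth_source <- "sum_format_dp"
  } else {
    site_depth <- info_dp
    depth_source <- "info_dp"
  }

  sites <- data.frame(chrom = fix[snp, "CHROM"],
                      pos = as.integer(fix[snp, "POS"]),
                      ref = ref[snp], alt = alt[snp],
                      qual = qual, site_depth = site_depth,
                      stringsAsFactors = FALSE)
  for (ch in unique(sites$chrom)) {
    if (is.unsorted(sites$pos[sites$chrom == ch], strictly = TRUE))
      stop("VCF not sorted by position within chromosome ", ch)
  }
  gm <- genotype_matrix(t(dos), sites, pop_labels, depth_source = depth_source)
  attr(gm, "n_skipped") <- n_skipped
  gm
}

gt_to_dosage <- function(gt) {
  u <- unique(as.vector(gt))
  map <- vapply(u, function(g) {
    if (is.na(g)) return(NA_integer_)
    al <- strsplit(gsub("\\|", "/", g), "/", fixed = TRUE)[[1]]
    if (any(al == ".") || !length(al)) return(NA_integer_)
    sum(al == "1")
  }, integer(1))
  out <- map[match(as.vector(gt), u)]
  matrix(out, nrow = nrow(gt), dimnames = dimnames(gt))
}

#' Write a genotype matrix as a plain-text VCF
#'
#' Emits a minimal, deterministic VCF 4.2 file: fixed header (no
#' timestamps, so identical inputs give byte-identical files), INFO `DP`
#' carrying site depth, and unphased GT genotypes. The inverse of
#' [read_vcf()] on the dosage grid.
#'
#' @param gm a [genotype_matrix()].
#' @param path output path.
#' @param chrom_lengths optional named vector of chromosome lengths for
#'   `##contig` header lines.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path, chrom_lengths = NULL) {
  s <- gm$sites
  hdr <- c("##fileformat=VCFv4.2",
           "##source=popsweep",
           if (!is.null(chrom_lengths))
             sprintf("##contig=<ID=%s,length=%d>",
                     names(chrom_lengths), as.integer(chrom_lengths)),
           '##INFO=<ID=DP,Number=1,Type=Integer,Description="Total site depth">',
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", rownames(gm$dosage)), collapse = "\t"))
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  dos <- gm$dosage
  gt <- matrix("./.", nrow = nrow(dos), ncol = ncol(dos))
  ok <- !is.na(dos)
  gt[ok] <- gt_code[as.character(dos[ok])]
  body <- paste(s$chrom, s$pos, ".", s$ref, s$alt,
                sprintf("%.2f", s$qual), "PASS",
                sprintf("DP=%d", as.integer(round(s$site_depth))), "GT",
                apply(gt, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a sample-to-population map
#' @param path TSV with header and columns `sample`, `population`.
#' @return named character vector (sample id -> population).
#' @export
read_sample_map <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(ncol(m) >= 2)
  stats::setNames(as.character(m[[2]]), as.character(m[[1]]))
}

#' Read gene models from a GFF3/GTF file
#'
#' Parses gene and exon features and returns one gene model per gene with
#' its interval converted to 0-based half-open coordinates and the union
#' (overlap-merged) exonic length in kilobases -- the `exon_length (kB)`
#' term of the FPKM formula. Exons are matched to genes through their
#' `Parent`/`gene_id` attribute chain.
#'
#' @param path GFF3 or GTF file.
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open), `strand`, `exon_union_bp`, `exon_union_kb`.
#' @export
read_gff <- function(path) {
  gr <- rtracklayer::import(path)
  type <- as.character(gr$type)
  genes <- gr[type == "gene"]
  exons <- gr[type == "exon"]
  if (!length(genes)) stop("no gene features in ", path)
  gene_ids <- gene_id_of(genes)
  if (anyNA(gene_ids)) stop("gene feature without an identifier in ", path)

  exon_gene <- exon_parent_gene(exons, genes)
  if (anyNA(exon_gene)) stop("exon without a resolvable parent gene in ", path)

  # union-exon length: merge overlapping exons within each gene
  exon_bp <- numeric(length(genes))
  names(exon_bp) <- gene_ids
  if (length(exons)) {
    spl <- split(IRanges::ranges(exons), exon_gene)
    merged <- vapply(spl, function(r) sum(IRanges::width(IRanges::reduce(r))),
                     numeric(1))
    exon_bp[names(merged)] <- merged
  }
  out <- data.frame(
    gene_id = gene_ids,
    chrom   = as.character(GenomicRanges::seqnames(genes)),
    start   = GenomicRanges::start(genes) - 1L,   # 1-based closed -> 0-based half-open
    end     = GenomicRanges::end(genes),
    strand  = as.character(GenomicRanges::strand(genes)),
    exon_union_bp = as.numeric(exon_bp),
    stringsAsFactors = FALSE)
  out$exon_union_kb <- out$exon_union_bp / 1000
  if (any(out$exon_union_bp <= 0))
    stop("genes with zero exonic length: ",
         paste(out$gene_id[out$exon_union_bp <= 0], collapse = ", "))
  out[order(out$chrom, out$start), , drop = FALSE]
}

gene_id_of <- function(gr) {
  for (field in c("gene_id", "ID", "Name")) {
    if (field %in% names(S4Vectors::mcols(gr))) {
      v <- S4Vectors::mcols(gr)[[field]]
      v <- vapply(v, function(x) if (length(x)) as.character(x)[1] else NA_character_,
                  character(1))
      if (!all(is.na(v))) return(v)
    }
  }
  rep(NA_character_, length(gr))
}

exon_parent_gene <- function(exons, genes) {
  if (!length(exons)) return(character(0))
  gene_ids <- gene_id_of(genes)
  mc <- S4Vectors::mcols(exons)
  parent <- if ("Parent" %in% names(mc)) {
    vapply(mc$Parent, function(x) if (length(x)) as.character(x)[1] else NA_character_,
           character(1))
  } else if ("gene_id" %in% names(mc)) {
    as.character(mc$gene_id)
  } else {
    rep(NA_character_, length(exons))
  }
  # Parent may point at an mRNA id of the form <gene>.t1, or at the gene id
  parent_gene <- ifelse(parent %in% gene_ids, parent, sub("\\.t\\d+$", "", parent))
  ifelse(parent_gene %in% gene_ids, parent_gene, NA_character_)
}

#' Read a gene-level count matrix with sample groups and library sizes
#'
#' @param path counts TSV: first column gene ids, remaining columns one
#'   per sample, header row of sample ids.
#' @param group_map TSV (`sample<TAB>group`, header) or named vector.
#' @param mapped_reads TSV (`sample<TAB>mapped_reads`, header), named
#'   numeric vector, or `NULL` to use column sums.
#' @return a list of class `counts_table`: integer matrix `counts`
#'   (genes x samples), `group_labels`, `mapped_reads`.
#' @export
read_counts <- function(path, group_map, mapped_reads = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  counts <- as.matrix(tab[, -1, drop = FALSE])
  rownames(counts) <- as.character(tab[[1]])
  groups <- if (is.character(group_map) && length(group_map) == 1L &&
                file.exists(group_map)) read_sample_map(group_map) else group_map
  mr <- if (is.null(mapped_reads)) {
    colSums(counts)
  } else if (is.character(mapped_reads) && length(mapped_reads) == 1L &&
             file.exists(mapped_reads)) {
    m <- utils::read.delim(mapped_reads, stringsAsFactors = FALSE)
    stats::setNames(as.numeric(m[[2]]), as.character(m[[1]]))
  } else {
    mapped_reads
  }
  counts_table(counts, groups, mr)
}

#' Construct a validated counts table
#' @param counts genes x samples numeric matrix of non-negative integers.
#' @param group_labels named character vector (sample -> condition).
#' @param mapped_reads named numeric vector of per-sample mapped fragments;
#'   defaults to column sums.
#' @return object of class `counts_table`.
#' @export
counts_table <- function(counts, group_labels, mapped_reads = colSums(counts)) {
  counts <- as.matrix(counts)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  storage.mode(counts) <- "integer"
  missing_grp <- setdiff(colnames(counts), names(group_labels))
  if (length(missing_grp))
    stop("samples without a group label: ", paste(missing_grp, collapse = ", "))
  mr <- mapped_reads[colnames(counts)]
  if (anyNA(mr)) stop("mapped_reads missing for some samples")
  if (any(mr < colSums(counts)))
    stop("mapped_reads smaller than the column sum for some samples")
  structure(list(counts = counts,
                 group_labels = group_labels[colnames(counts)],
                 mapped_reads = mr),
            class = "counts_table")
}

#' Write a counts table and its companion maps as TSV files
#' @param ct a [counts_table()].
#' @param counts_path,group_path,mapped_path output TSV paths.
#' @return invisibly, the three paths.
#' @export
write_counts <- function(ct, counts_path, group_path, mapped_path) {
  df <- data.frame(gene_id = rownames(ct$counts), ct$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample = names(ct$group_labels), group = unname(ct$group_labels)),
    group_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample = names(ct$mapped_reads),
               mapped_reads = unname(ct$mapped_reads)),
    mapped_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(counts_path, group_path, mapped_path))
}
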