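#' Intersect sweep genes with differentially expressed genes
#'
#' The headline integration: genes under a selective sweep in a
#' comparison that are also differentially expressed in the matching
#' transcriptome contrast(s) become candidate genes. When two DEG tables
#' are supplied the shared DEG set is, by default, the intersection of
#' the two called DEG lists (mirroring a two-contrasts-versus-one-control
#' design); `shared_deg_rule = "union"` uses their union instead.
#'
#' @param sweep_genes character vector of selected-gene ids (from
#'   [windows_to_genes()]).
#' @param deg_tables a single called DEG table ([call_degs()]) or a list
#'   of them.
#' @param shared_deg_rule "intersection" (default) or "union" of the DEG
#'   lists when more than one table is given.
#' @param comparison label stored in the report.
#' @param annotation_genes optional character vector of all annotated
#'   gene ids; when given, zero id overlap between the annotation and the
#'   counted genes is treated as a hard error (disjoint namespaces).
#' @return list of class `candidate_report`: `comparison`,
#'   `sweep_genes`, `shared_degs`, `candidates` (data.frame with gene id,
#'   log2fc, p, call per source table), `venn` (from [overlap_sets()]).
#' @export
integrate_candidates <- function(sweep_genes, deg_tables,
                                 shared_deg_rule = c("intersection", "union"),
                                 comparison = "selected_vs_control",
                                 annotation_genes = NULL) {
  shared_deg_rule <- match.arg(shared_deg_rule)
  if (is.data.frame(deg_tables)) deg_tables <- list(deg_tables)
  if (is.null(names(deg_tables)))
    names(deg_tables) <- paste0("contrast", seq_along(deg_tables))
  deg_sets <- lapply(deg_tables, function(t) t$gene_id[t$call != "ns"])
  all_count_genes <- unique(unlist(lapply(deg_tables, `[[`, "gene_id")))
  if (!is.null(annotation_genes) &&
      !length(intersect(annotation_genes, all_count_genes)))
    stop("annotation and counts share no gene identifiers; ",
         "cannot integrate across disjoint namespaces")
  shared <- Reduce(if (shared_deg_rule == "intersection") intersect else union,
                   deg_sets)
  candidates <- sort(intersect(sweep_genes, shared))
  evidence <- do.call(rbind, lapply(names(deg_tables), function(nm) {
    t <- deg_tables[[nm]]
    rows <- t[t$gene_id %in% candidates, c("gene_id", "log2fc", "p", "call")]
    if (nrow(rows)) cbind(contrast = nm, rows) else NULL
  }))
  venn_sets <- c(list(sweep = sweep_genes), deg_sets)
  venn <- if (length(venn_sets) %in% 2:3) overlap_sets(venn_sets) else NULL
  structure(list(comparison = comparison,
                 sweep_genes = sort(unique(sweep_genes)),
                 shared_degs = sort(shared),
                 candidates = candidates,
                 evidence = evidence,
                 venn = venn),
            class = "candidate_report")
}

#' @export
print.candidate_report <- function(x, ...) {
  cat(sprintf("candidate_report [%s]: %d sweep genes x %d shared DEGs -> %d candidates\n",
              x$comparison, length(x$sweep_genes), length(x$shared_degs),
              length(x$candidates)))
  if (length(x$candidates))
    cat("candidates:", paste(utils::head(x$candidates, 20), collapse = ", "),
        if (length(x$candidates) > 20) "..." else "", "\n")
  invisible(x)
}

#' Hypergeometric over-representation test across annotation terms
#'
#' For each term, the upper-tail probability of observing at least the
#' seen overlap between the study set and the term's genes when drawing
#' |study| genes from the background without replacement; BH-adjusted
#' across terms. Term gene sets are intersected with the background
#' before testing. This is a plain over-representation test: no
#' gene-length bias weighting is applied.
#'
#' @param study character vector of study gene ids (must be a subset of
#'   `background`).
#' @param background character vector, the gene universe.
#' @param term_map data.frame with columns `term_id`, `gene_id` and
#'   optionally `term_name`, or a named list of gene id vectors.
#' @return data.frame sorted by `padj`: `term_id`, `term_name`,
#'   `term_size`, `overlap_size`, `fold_enrichment`, `p`, `padj`.
#' @export
hypergeom_enrich <- function(study, background, term_map) {
  study <- unique(study)
  background <- unique(background)
  if (length(setdiff(study, background)))
    stop("study genes outside the background: ",
         paste(utils::head(setdiff(study, background), 5), collapse = ", "))
  if (is.data.frame(term_map)) {
    names_map <- if ("term_name" %in% names(term_map)) {
      tm <- unique(term_map[, c("term_id", "term_name")])
      stats::setNames(tm$term_name, tm$term_id)
    } else NULL
    term_map <- split(term_map$gene_id, term_map$term_id)
  } else names_map <- NULL
  term_map <- lapply(term_map, function(g) intersect(unique(g), background))
  term_map <- term_map[vapply(term_map, length, integer(1)) > 0]
  N <- length(background)
  n <- length(study)
  rows <- lapply(names(term_map), function(tid) {
    K <- length(term_map[[tid]])
    x <- length(intersect(study, term_map[[tid]]))
    p <- stats::phyper(x - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = tid,
               term_name = if (!is.null(names_map)) unname(names_map[tid]) else tid,
               term_size = K, overlap_size = x,
               fold_enrichment = if (n > 0 && K > 0) (x / n) / (K / N) else NA_real_,
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$padj <- stats::p.adjust(out$p, method = "BH")
  out[order(out$padj, out$p, out$term_id), , drop = FALSE]
}
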