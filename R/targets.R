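# Gene-level target calling and target-set comparison.
#
# A gene is a target when it is expressed (fpkm >= 5 by default) and owns
# at least one significantly edited site with differential edit frequency
# >= 0.1. Cell-type comparisons use exact set algebra on target gene sets,
# and "gene-expression independent" subsets remove genes whose differential
# binding could be an expression artefact.

#' Call gene-level targets from per-site test results
#'
#' @param site_results Data frame from [test_editing()] (columns `gene`,
#'   `fdr`, `diff_frequency`).
#' @param expression Data frame with columns `gene` and `fpkm`.
#' @param fpkm_min Minimum expression; boundary inclusive (`>=`).
#' @param difffreq_min Minimum differential edit frequency of at least one
#'   significant site; boundary inclusive (`>=`).
#' @param fdr_threshold Site-significance threshold (strict `<`), a number
#'   or a preset name understood by [fdr_preset()].
#' @return Data frame, one row per target gene: `gene`, `n_sites`
#'   (significant sites passing `difffreq_min`... see Details), `n_sig_sites`,
#'   `max_diff_frequency` (over the gene's significant sites), `fpkm`.
#'   Genes with significant sites but no expression record are excluded
#'   with a warning, since the expression rule cannot be evaluated.
#' @details `n_sites` counts the gene's significant sites regardless of
#'   `difffreq_min`; `max_diff_frequency` is the maximum over those sites.
#' @export
call_targets <- function(site_results, expression, fpkm_min = 5,
                         difffreq_min = 0.1, fdr_threshold = 0.05) {
  thr <- fdr_preset(fdr_threshold)
  stopifnot(is.data.frame(site_results), is.data.frame(expression),
            all(c("gene", "fdr", "diff_frequency") %in% names(site_results)),
            all(c("gene", "fpkm") %in% names(expression)))
  if (fpkm_min < 0 || difffreq_min < -1 || difffreq_min > 1) {
    stop("thresholds out of range")
  }
  sig <- site_results[site_results$fdr < thr &
                        !is.na(site_results$diff_frequency), , drop = FALSE]
  if (nrow(sig) == 0) {
    return(data.frame(gene = character(), n_sig_sites = integer(),
                      max_diff_frequency = numeric(), fpkm = numeric()))
  }
  by_gene <- split(sig$diff_frequency, sig$gene)
  genes <- names(by_gene)
  maxdf <- vapply(by_gene, max, numeric(1))
  nsig <- lengths(by_gene)
  fpkm <- expression$fpkm[match(genes, expression$gene)]
  missing_expr <- is.na(fpkm)
  if (any(missing_expr)) {
    warning(sprintf(
      "%d gene(s) with significant sites lack an expression record and were excluded",
      sum(missing_expr)))
  }
  keep <- !missing_expr & fpkm >= fpkm_min & maxdf >= difffreq_min
  out <- data.frame(gene = genes[keep], n_sig_sites = nsig[keep],
                    max_diff_frequency = maxdf[keep], fpkm = fpkm[keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$gene), , drop = FALSE]
}

#' Compare target gene sets across conditions or cell types
#'
#' @param target_sets Named list (>= 2 entries) of character vectors of
#'   gene ids; each must be duplicate-free.
#' @return List with `shared` (genes in every set), `unique` (named list:
#'   genes found in exactly that one set), and `counts` (named sizes,
#'   including each input set).
#' @export
compare_target_sets <- function(target_sets) {
  stopifnot(is.list(target_sets), length(target_sets) >= 2,
            !is.null(names(target_sets)), all(nzchar(names(target_sets))))
  for (nm in names(target_sets)) {
    if (anyDuplicated(target_sets[[nm]])) {
      stop(sprintf("target set '%s' contains duplicate gene ids", nm))
    }
  }
  shared <- Reduce(intersect, target_sets)
  uniq <- lapply(seq_along(target_sets), function(i) {
    setdiff(target_sets[[i]], unique(unlist(target_sets[-i])))
  })
  names(uniq) <- names(target_sets)
  counts <- c(vapply(target_sets, length, integer(1)),
              shared = length(shared),
              stats::setNames(lengths(uniq), paste0(names(uniq), "_unique")))
  list(shared = sort(shared), unique = lapply(uniq, sort), counts = counts)
}

#' Gene-expression-independent target filter
#'
#' Keeps targets whose differential binding cannot be explained by a
#' differential-expression difference: a gene passes when its expression
#' change is not significant (`fdr >= fdr_cut`), or is significant but
#' small in the stated direction (`log2fc <= log2fc_max` after applying
#' `direction`). Use `direction = -1` for the reciprocal comparison (the
#' rule `log2fc >= -log2fc_max`).
#'
#' @param genes Character vector of target gene ids.
#' @param de_table Data frame with columns `gene`, `log2fc`, `fdr` from an
#'   external differential-expression analysis.
#' @param direction `+1` or `-1`, multiplying `log2fc` before the
#'   comparison.
#' @param log2fc_max Fold-change ceiling, default 0.26 (fold change 1.2).
#' @param fdr_cut Differential-expression significance cut, default 0.05.
#' @return Subset of `genes`; genes absent from `de_table` are excluded
#'   with a warning.
#' @export
ge_independent_filter <- function(genes, de_table, direction = 1,
                                  log2fc_max = 0.26, fdr_cut = 0.05) {
  stopifnot(is.character(genes) || length(genes) == 0,
            is.data.frame(de_table),
            all(c("gene", "log2fc", "fdr") %in% names(de_table)),
            direction %in% c(1, -1))
  i <- match(genes, de_table$gene)
  absent <- is.na(i)
  if (any(absent)) {
    warning(sprintf("%d gene(s) absent from the DE table were excluded",
                    sum(absent)))
  }
  lfc <- direction * de_table$log2fc[i]
  fdr <- de_table$fdr[i]
  keep <- !absent & (fdr >= fdr_cut | lfc <= log2fc_max)
  genes[keep]
}

#' Candidate cell-type-specific targets
#'
#' A gene is a candidate for one cell type when it is a significantly
#' edited target there (maximum differential edit frequency >= `difffreq_min`
#' and significant fusion-versus-control editing) but not significantly
#' edited in any other cell type. Candidates then go through
#' [test_celltype()]; final specificity requires its adjusted p < 0.1.
#'
#' @param gene_calls Data frame with one row per (gene, cell type):
#'   columns `gene`, `celltype`, `significant` (logical: the gene has at
#'   least one significant fusion-vs-control site in that cell type), and
#'   `max_diff_frequency`.
#' @param difffreq_min Minimum maximum diff.frequency, default 0.1.
#' @return Data frame `gene`, `celltype` of candidates.
#' @export
celltype_specific_candidates <- function(gene_calls, difffreq_min = 0.1) {
  req <- c("gene", "celltype", "significant", "max_diff_frequency")
  stopifnot(is.data.frame(gene_calls), all(req %in% names(gene_calls)))
  if (anyDuplicated(paste(gene_calls$gene, gene_calls$celltype))) {
    stop("one row per (gene, celltype) required")
  }
  sig_count <- tapply(gene_calls$significant, gene_calls$gene, sum)
  cand <- gene_calls$significant &
    gene_calls$max_diff_frequency >= difffreq_min &
    sig_count[gene_calls$gene] == 1L
  out <- gene_calls[cand, c("gene", "celltype"), drop = FALSE]
  rownames(out) <- NULL
  out[order(out$celltype, out$gene), , drop = FALSE]
}

#' Gene-by-cell-type matrix of maximum differential edit frequencies
#'
#' @param genes Character vector of genes (matrix rows, in this order).
#' @param results_by_celltype Named list of [test_editing()]-style data
#'   frames (columns `gene`, `diff_frequency`), one per cell type.
#' @return List with `matrix` (entry = max diff.frequency of that gene's
#'   sites in that cell type; 0 where the gene was not tested) and `tested`
#'   (logical mask distinguishing untested pairs from tested ones).
#' @export
build_difffreq_matrix <- function(genes, results_by_celltype) {
  stopifnot(is.list(results_by_celltype),
            !is.null(names(results_by_celltype)))
  cts <- names(results_by_celltype)
  m <- matrix(0, length(genes), length(cts), dimnames = list(genes, cts))
  tested <- matrix(FALSE, length(genes), length(cts),
                   dimnames = list(genes, cts))
  for (ct in cts) {
    res <- results_by_celltype[[ct]]
    stopifnot(all(c("gene", "diff_frequency") %in% names(res)))
    res <- res[res$gene %in% genes & !is.na(res$diff_frequency), ,
               drop = FALSE]
    if (nrow(res) == 0) next
    mx <- tapply(res$diff_frequency, res$gene, max)
    m[names(mx), ct] <- as.numeric(mx)
    tested[names(mx), ct] <- TRUE
  }
  if (all(!tested)) stop("none of the requested genes appear in any result")
  list(matrix = m, tested = tested)
}

#' Order rows of a per-cell-type matrix for stacked display
#'
#' Sorts genes within each cell type's block from lowest to highest value,
#' where a gene belongs to the cell type of its column-wise maximum.
#'
#' @param m Numeric matrix (genes x cell types).
#' @return Row-name ordering (character vector).
#' @export
stacked_row_order <- function(m) {
  stopifnot(is.matrix(m), !is.null(rownames(m)))
  block <- max.col(m, ties.method = "first")
  ord <- order(block, m[cbind(seq_len(nrow(m)), block)])
  rownames(m)[ord]
}

#' Z-scored expression matrix from stabilised counts
#'
#' Averages replicate libraries within each condition, then z-transforms
#' each gene across conditions using the population (n-denominator)
#' standard deviation. Constant rows become all zeros with a warning.
#'
#' @param vst Numeric matrix (genes x libraries) of variance-stabilised
#'   expression values (e.g. DESeq2 VST), computed externally.
#' @param replicate_groups Named character vector, library -> condition.
#' @return Gene-by-condition matrix of z-scores.
#' @export
zscore_expression_matrix <- function(vst, replicate_groups) {
  stopifnot(is.matrix(vst), !is.null(colnames(vst)),
            all(colnames(vst) %in% names(replicate_groups)))
  grp <- replicate_groups[colnames(vst)]
  conds <- unique(grp)
  if (length(conds) < 2) stop("z-scores need at least two conditions")
  means <- vapply(conds, function(g) {
    rowMeans(vst[, grp == g, drop = FALSE])
  }, numeric(nrow(vst)))
  colnames(means) <- conds
  mu <- rowMeans(means)
  sd_pop <- sqrt(rowMeans((means - mu)^2))
  const <- sd_pop == 0
  if (any(const)) {
    warning(sprintf("%d constant row(s) set to zero z-scores", sum(const)))
    sd_pop[const] <- 1
  }
  (means - mu) / sd_pop
}

#' WPGMA (McQuitty) leaf order of matrix rows
#'
#' Hierarchical agglomerative clustering of rows by Euclidean distance
#' with McQuitty (WPGMA) linkage; the leaf order of the dendrogram is the
#' heatmap row order.
#'
#' @param m Numeric matrix with >= 2 rows and no missing values.
#' @return Integer vector: row indices in dendrogram leaf order.
#' @export
wpgma_row_order <- function(m) {
  stopifnot(is.matrix(m))
  if (nrow(m) < 2) stop("need at least two rows to cluster")
  if (any(!is.finite(m))) stop("matrix contains missing or infinite values")
  stats::hclust(stats::dist(m), method = "mcquitty")$order
}
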