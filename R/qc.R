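#' Cell-level quality-control thresholds
#'
#' Three negative indicators of cell quality are evaluated: low total
#' counts, a low number of detected genes (\eqn{\le} 1,000 by default) and a
#' high mitochondrial fraction (\eqn{\ge} 0.2 by default). A cell is flagged
#' low-quality when more than one indicator fires. "Low total counts" has no
#' published numeric threshold and defaults to the 5th percentile of the
#' cell's sample. The ribosomal fraction is computed and reported by the
#' generator but is not a negative indicator.
#'
#' @param min_genes gene-count indicator threshold (indicator fires when
#'   `n_genes <= min_genes`).
#' @param max_mito mitochondrial-fraction indicator threshold (fires when
#'   `mito_fraction >= max_mito`).
#' @param low_counts_quantile per-sample quantile below which the total-count
#'   indicator fires.
#' @param min_indicators_to_flag number of indicators needed to flag a cell.
#' @return object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_genes = 1000, max_mito = 0.2,
                          low_counts_quantile = 0.05,
                          min_indicators_to_flag = 2) {
  if (min_genes <= 0 || max_mito <= 0 || low_counts_quantile <= 0)
    stopf("thresholds must be positive")
  if (min_indicators_to_flag < 1)
    stopf("min_indicators_to_flag must be >= 1")
  structure(list(min_genes = min_genes, max_mito = max_mito,
                 low_counts_quantile = low_counts_quantile,
                 min_indicators_to_flag = min_indicators_to_flag),
            class = "qc_thresholds")
}

#' Flag low-quality cells
#'
#' Evaluates the three negative indicators per cell and flags cells with at
#' least `min_indicators_to_flag` (default 2, i.e. "more than one") firing.
#'
#' @param mat an `expression_matrix`, or a data.frame with columns
#'   `total_counts`, `n_genes`, `mito_fraction` (and optionally `sample`).
#' @param thresholds a [qc_thresholds()].
#' @return data.frame with the three indicator columns, `n_indicators` and
#'   the `low_quality` flag, one row per cell.
#' @export
qc_flag_cells <- function(mat, thresholds = qc_thresholds()) {
  meta <- if (inherits(mat, "expression_matrix")) mat$cell_meta else mat
  need <- c("total_counts", "n_genes", "mito_fraction")
  if (!all(need %in% names(meta)))
    stopf("cell metadata must contain: %s", paste(need, collapse = ", "))
  sample_id <- if ("sample" %in% names(meta)) meta$sample else
    rep("all", nrow(meta))
  cut_low <- stats::ave(meta$total_counts, sample_id, FUN = function(x)
    quantile(x, thresholds$low_counts_quantile, names = FALSE))
  ind_counts <- meta$total_counts < cut_low
  ind_genes <- meta$n_genes <= thresholds$min_genes
  ind_mito <- meta$mito_fraction >= thresholds$max_mito
  n_ind <- ind_counts + ind_genes + ind_mito
  data.frame(barcode = if ("barcode" %in% names(meta)) meta$barcode else
               seq_len(nrow(meta)),
             ind_low_counts = ind_counts,
             ind_low_genes = ind_genes,
             ind_high_mito = ind_mito,
             n_indicators = n_ind,
             low_quality = n_ind >= thresholds$min_indicators_to_flag)
}

#' Cluster-level exclusion of low-quality and contaminated clusters
#'
#' Quality is assessed at the cluster level rather than per cell: a cluster
#' is dropped when more than `majority_fraction` of its cells are flagged
#' low-quality, or when more than `contaminant_fraction` of its cells
#' express any contaminant gene (count > 0). Clustering itself is external;
#' cluster ids are taken from the metadata.
#'
#' @param mat an `expression_matrix` with a `cluster` metadata column.
#' @param flags data.frame from [qc_flag_cells()].
#' @param contaminant_genes character vector of contaminant marker genes
#'   (e.g. `Ptprc` for hematopoietic cells, `Gcm2` for parathyroid). Unknown
#'   names raise a warning and are ignored.
#' @param majority_fraction,contaminant_fraction drop thresholds.
#' @return data.frame per cluster with `n_cells`, `frac_flagged`,
#'   `frac_contaminant` and `drop`; the percentage of retained cells is in
#'   attribute `"retained_pct"`.
#' @export
exclude_low_quality_clusters <- function(mat, flags,
                                         contaminant_genes = c("Ptprc", "Gcm2"),
                                         majority_fraction = 0.5,
                                         contaminant_fraction = 0.5) {
  stopifnot(inherits(mat, "expression_matrix"))
  if (!"cluster" %in% names(mat$cell_meta))
    stopf("cell metadata has no 'cluster' column")
  known <- intersect(contaminant_genes, colnames(mat$counts))
  unknown <- setdiff(contaminant_genes, known)
  if (length(unknown))
    warnf("unknown contaminant gene(s) ignored: %s",
          paste(unknown, collapse = ", "))
  has_contam <- if (length(known))
    Matrix::rowSums(mat$counts[, known, drop = FALSE] > 0) > 0
  else rep(FALSE, nrow(mat$counts))

  cl <- mat$cell_meta$cluster
  res <- data.frame(cluster = sort(unique(cl)))
  res$n_cells <- vapply(res$cluster, function(k) sum(cl == k), 0L)
  res$frac_flagged <- vapply(res$cluster, function(k)
    mean(flags$low_quality[cl == k]), 0)
  res$frac_contaminant <- vapply(res$cluster, function(k)
    mean(has_contam[cl == k]), 0)
  res$drop <- res$frac_flagged > majority_fraction |
    res$frac_contaminant > contaminant_fraction
  kept <- sum(res$n_cells[!res$drop])
  attr(res, "retained_pct") <- 100 * kept / sum(res$n_cells)
  res
}

#' Library-size normalization with log transform
#'
#' Scales each cell to a total library size of 10,000 counts and applies a
#' natural-log transform with a pseudo-count of 1:
#' `value = log(1 + 10000 * count / total_counts)`. Zeros map to zeros, so
#' sparsity is preserved, and for every cell
#' `sum(exp(value) - 1) == 10000` exactly (up to floating point).
#'
#' @param mat an `expression_matrix`, or a cells-by-genes matrix of counts.
#' @param target scaled library size (default 10,000).
#' @return sparse cells-by-genes matrix of normalized values.
#' @export
normalize_log1p <- function(mat, target = 1e4) {
  counts <- if (inherits(mat, "expression_matrix")) mat$counts else
    Matrix::Matrix(mat, sparse = TRUE)
  totals <- Matrix::rowSums(counts)
  if (any(totals <= 0))
    stopf("cells with zero total counts: %s",
          paste(head(rownames(counts)[totals <= 0], 10), collapse = ", "))
  scaled <- Matrix::Diagonal(x = target / totals) %*% counts
  out <- methods::as(scaled, "CsparseMatrix")
  out@x <- log1p(out@x)
  dimnames(out) <- dimnames(counts)
  out
}
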