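#' Specification of a synthetic single-cell count matrix
#'
#' Describes a negative-binomial cells-by-genes count matrix with
#' subset-specific marker genes, lognormal library-size variation,
#' beta-distributed mitochondrial fractions, an optional low-quality cell
#' population, doublet-like mixtures, an optional contaminant-expressing
#' cluster, and two age conditions that differ in subset frequencies
#' (aaTEC-like subsets present only in the aged condition).
#'
#' @param n_cells number of single cells to draw (before doublets).
#' @param n_genes total gene count, including mitochondrial and ribosomal
#'   genes.
#' @param n_mito_genes,n_ribo_genes counts of `mt-`/`Rps|Rpl`-named genes.
#' @param subsets subset names; defaults follow thymic epithelial biology
#'   with two age-associated subsets.
#' @param markers_per_subset exclusive marker genes per subset.
#' @param marker_log_fold_change natural-log fold change applied to a
#'   subset's markers in its own cells; 0 yields a null dataset.
#' @param nb_dispersion negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`).
#' @param library_size_lognormal_params `c(meanlog, sdlog)` of per-cell
#'   library size.
#' @param mito_beta_params `c(shape1, shape2)` of the per-cell target
#'   mitochondrial fraction.
#' @param frequencies named list of per-condition subset frequency vectors,
#'   each summing to 1.
#' @param condition_fractions proportion of cells per condition.
#' @param lowq_cell_fraction fraction of low-quality cells.
#' @param lowq_library_factor,lowq_mito_target library-size shrinkage and
#'   mitochondrial target applied to low-quality cells.
#' @param doublet_fraction fraction of additional doublet-like cells formed
#'   by summing two random singles.
#' @param n_contam_cells cells in a planted contaminant cluster.
#' @param contaminant_gene gene expressed by the contaminant cluster.
#' @param contam_expr_fraction fraction of contaminant-cluster cells with
#'   nonzero contaminant-gene counts.
#' @param seed integer seed.
#' @return object of class `expr_sim_spec`.
#' @export
expr_sim_spec <- function(n_cells = 2000,
                          n_genes = 1000,
                          n_mito_genes = 13,
                          n_ribo_genes = 20,
                          subsets = c("cTEC", "mTEC1", "mTEC2",
                                      "aaTEC1", "aaTEC2"),
                          markers_per_subset = 25,
                          marker_log_fold_change = 2,
                          nb_dispersion = 0.5,
                          library_size_lognormal_params = c(log(5000), 0.3),
                          mito_beta_params = c(2, 38),
                          frequencies = list(
                            young = c(cTEC = 0.25, mTEC1 = 0.35, mTEC2 = 0.40,
                                      aaTEC1 = 0, aaTEC2 = 0),
                            aged = c(cTEC = 0.15, mTEC1 = 0.25, mTEC2 = 0.30,
                                     aaTEC1 = 0.15, aaTEC2 = 0.15)),
                          condition_fractions = c(young = 0.5, aged = 0.5),
                          lowq_cell_fraction = 0.05,
                          lowq_library_factor = 0.15,
                          lowq_mito_target = 0.35,
                          doublet_fraction = 0.02,
                          n_contam_cells = 0,
                          contaminant_gene = "Ptprc",
                          contam_expr_fraction = 0.6,
                          seed = 1L) {
  for (f in frequencies) {
    if (abs(sum(f) - 1) > 1e-8) stopf("frequency vectors must sum to 1")
    if (!setequal(names(f), subsets))
      stopf("frequency vectors must be named by the subsets")
  }
  n_special <- n_mito_genes + n_ribo_genes + 1L  # +1 contaminant gene
  if (markers_per_subset * length(subsets) > n_genes - n_special)
    stopf("markers_per_subset x n_subsets (%d) exceeds available genes (%d)",
          markers_per_subset * length(subsets), n_genes - n_special)
  structure(list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
                 n_mito_genes = as.integer(n_mito_genes),
                 n_ribo_genes = as.integer(n_ribo_genes),
                 subsets = subsets, markers_per_subset = markers_per_subset,
                 marker_log_fold_change = marker_log_fold_change,
                 nb_dispersion = nb_dispersion,
                 library_size_lognormal_params = library_size_lognormal_params,
                 mito_beta_params = mito_beta_params,
                 frequencies = frequencies,
                 condition_fractions = condition_fractions,
                 lowq_cell_fraction = lowq_cell_fraction,
                 lowq_library_factor = lowq_library_factor,
                 lowq_mito_target = lowq_mito_target,
                 doublet_fraction = doublet_fraction,
                 n_contam_cells = as.integer(n_contam_cells),
                 contaminant_gene = contaminant_gene,
                 contam_expr_fraction = contam_expr_fraction,
                 seed = as.integer(seed)),
            class = "expr_sim_spec")
}

#' Generate a synthetic single-cell count matrix with truth labels
#'
#' Draws negative-binomial counts per cell from a fixed gene-weight profile
#' modulated by subset markers, then computes all per-cell metadata (total
#' counts, detected genes, mitochondrial and ribosomal fractions) from the
#' generated counts. Truth columns record the subset, low-quality status and
#' doublet status of every cell; cluster ids equal the truth subset (plus
#' `contam`/`doublet`), standing in for an external clustering.
#'
#' @param spec an [expr_sim_spec()].
#' @return object of class `expression_matrix`: list with sparse `counts`
#'   (cells x genes, `dgCMatrix`), `cell_meta` and `gene_meta` data.frames.
#' @export
make_expression <- function(spec) {
  stopifnot(inherits(spec, "expr_sim_spec"))
  with_seed(spec$seed, {
    n_mt <- spec$n_mito_genes
    n_rb <- spec$n_ribo_genes
    genes <- c(sprintf("mt-g%02d", seq_len(n_mt)),
               sprintf("Rps%02d", seq_len(n_rb)),
               spec$contaminant_gene,
               sprintf("gene%04d",
                       seq_len(spec$n_genes - n_mt - n_rb - 1L)))
    is_mito <- grepl("^mt-", genes)
    is_ribo <- grepl("^Rp[sl]", genes)
    ordinary <- which(!is_mito & !is_ribo & genes != spec$contaminant_gene)

    n_sub <- length(spec$subsets)
    markers <- split(ordinary[seq_len(n_sub * spec$markers_per_subset)],
                     rep(seq_len(n_sub), each = spec$markers_per_subset))
    names(markers) <- spec$subsets

    base_w <- rlnorm(spec$n_genes, meanlog = 0, sdlog = 1)
    base_w[is_mito] <- 0                      # mito mass set per cell
    base_w[genes == spec$contaminant_gene] <- 0

    conds <- sample(names(spec$condition_fractions), spec$n_cells,
                    replace = TRUE, prob = spec$condition_fractions)
    subset_of <- vapply(conds, function(cd)
      sample(spec$subsets, 1, prob = spec$frequencies[[cd]]), "")
    lowq <- runif(spec$n_cells) < spec$lowq_cell_fraction
    lib <- rlnorm(spec$n_cells,
                  spec$library_size_lognormal_params[1],
                  spec$library_size_lognormal_params[2])
    lib[lowq] <- lib[lowq] * spec$lowq_library_factor
    mito_target <- rbeta(spec$n_cells, spec$mito_beta_params[1],
                         spec$mito_beta_params[2])
    mito_target[lowq] <- spec$lowq_mito_target

    size <- 1 / spec$nb_dispersion
    lfc <- spec$marker_log_fold_change
    mito_split <- rlnorm(n_mt, 0, 0.5)
    mito_split <- mito_split / sum(mito_split)

    draw_cell <- function(subset, L, m) {
      w <- base_w
      if (lfc != 0 && subset %in% names(markers))
        w[markers[[subset]]] <- w[markers[[subset]]] * exp(lfc)
      w[is_mito] <- sum(w) * m / (1 - m) * mito_split
      mu <- L * w / sum(w)
      rnbinom(spec$n_genes, mu = mu, size = size)
    }

    counts <- matrix(0L, nrow = spec$n_cells, ncol = spec$n_genes)
    for (i in seq_len(spec$n_cells))
      counts[i, ] <- draw_cell(subset_of[i], lib[i], mito_target[i])

    cluster <- subset_of
    doubl <- rep(FALSE, spec$n_cells)
    cond_all <- conds
    lowq_all <- lowq

    # contaminant cluster (e.g. residual CD45+ cells)
    if (spec$n_contam_cells > 0) {
      cm <- matrix(0L, spec$n_contam_cells, spec$n_genes)
      cg <- which(genes == spec$contaminant_gene)
      # plant the contaminant in an exact fraction of the cluster
      expr_in <- sample(spec$n_contam_cells,
                        round(spec$contam_expr_fraction * spec$n_contam_cells))
      for (i in seq_len(spec$n_contam_cells)) {
        cm[i, ] <- draw_cell(spec$subsets[1], mean(lib), 0.05)
        if (i %in% expr_in) cm[i, cg] <- rpois(1, 5) + 1L
      }
      counts <- rbind(counts, cm)
      cluster <- c(cluster, rep("contam", spec$n_contam_cells))
      subset_of <- c(subset_of, rep("contam", spec$n_contam_cells))
      cond_all <- c(cond_all, rep(cond_all[1], spec$n_contam_cells))
      lowq_all <- c(lowq_all, rep(FALSE, spec$n_contam_cells))
      doubl <- c(doubl, rep(FALSE, spec$n_contam_cells))
    }

    # doublet-like mixtures of two random single cells
    n_db <- round(spec$doublet_fraction * spec$n_cells)
    if (n_db > 0) {
      pa <- sample(spec$n_cells, n_db, replace = TRUE)
      pb <- sample(spec$n_cells, n_db, replace = TRUE)
      counts <- rbind(counts, counts[pa, , drop = FALSE] +
                        counts[pb, , drop = FALSE])
      cluster <- c(cluster, cluster[pa])
      subset_of <- c(subset_of, rep("doublet", n_db))
      cond_all <- c(cond_all, cond_all[pa])
      lowq_all <- c(lowq_all, rep(FALSE, n_db))
      doubl <- c(doubl, rep(TRUE, n_db))
    }

    n_all <- nrow(counts)
    barcodes <- sprintf("cell%05d", seq_len(n_all))
    total <- rowSums(counts)
    cell_meta <- data.frame(
      barcode = barcodes,
      total_counts = total,
      n_genes = rowSums(counts > 0),
      mito_fraction = rowSums(counts[, is_mito, drop = FALSE]) / pmax(total, 1),
      ribo_fraction = rowSums(counts[, is_ribo, drop = FALSE]) / pmax(total, 1),
      cluster = cluster,
      sample = paste0(cond_all, "_s", 1 + seq_len(n_all) %% 2),
      condition = cond_all,
      subset = subset_of,
      doublet = doubl,
      lowq_truth = lowq_all)
    gene_meta <- data.frame(name = genes, mito = is_mito, ribo = is_ribo)
    marker_names <- lapply(markers, function(ix) genes[ix])

    counts <- Matrix::Matrix(counts, sparse = TRUE)
    dimnames(counts) <- list(barcodes, genes)
    structure(list(counts = counts, cell_meta = cell_meta,
                   gene_meta = gene_meta, markers = marker_names,
                   spec = spec),
              class = "expression_matrix")
  })
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d cells x %d genes\n",
              nrow(x$counts), ncol(x$counts)))
  print(table(x$cell_meta$subset, x$cell_meta$condition))
  invisible(x)
}

#' Write / read an expression matrix as an MTX triplet plus metadata CSV
#'
#' Writes `matrix.mtx` (genes x cells, MatrixMarket), `features.tsv`,
#' `barcodes.tsv` and `cell_metadata.csv` into `dir`.
#'
#' @param mat an `expression_matrix` (see [make_expression()]).
#' @param dir output directory.
#' @return `write_expression_mtx` returns `dir` invisibly;
#'   `read_expression_mtx` returns an `expression_matrix`.
#' @export
write_expression_mtx <- function(mat, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Matrix::writeMM(Matrix::t(mat$counts), file.path(dir, "matrix.mtx"))
  writeLines(colnames(mat$counts), file.path(dir, "features.tsv"))
  writeLines(rownames(mat$counts), file.path(dir, "barcodes.tsv"))
  write.csv(mat$cell_meta, file.path(dir, "cell_metadata.csv"),
            row.names = FALSE)
  invisible(dir)
}

#' @rdname write_expression_mtx
#' @export
read_expression_mtx <- function(dir) {
  counts <- Matrix::t(Matrix::readMM(file.path(dir, "matrix.mtx")))
  counts <- methods::as(counts, "CsparseMatrix")
  genes <- readLines(file.path(dir, "features.tsv"))
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  dimnames(counts) <- list(barcodes, genes)
  cell_meta <- read.csv(file.path(dir, "cell_metadata.csv"))
  gene_meta <- data.frame(name = genes, mito = grepl("^mt-", genes),
                          ribo = grepl("^Rp[sl]", genes))
  structure(list(counts = counts, cell_meta = cell_meta,
                 gene_meta = gene_meta),
            class = "expression_matrix")
}
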