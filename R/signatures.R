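#' Reference-subtracted signature score
#'
#' Scores each cell as the mean normalized expression of the signature genes
#' minus the mean of an expression-matched random reference set: genes are
#' binned into `n_bins` groups of equal size by average expression across
#' cells, and for each signature gene `ctrl_per_gene` control genes are
#' sampled (without replacement, excluding signature genes) from the same
#' bin; the reference is the union of sampled controls. With all genes
#' identically expressed the score is exactly zero.
#'
#' @param normalized cells-by-genes matrix of normalized expression.
#' @param signature character vector of gene names; genes absent from the
#'   matrix are dropped with a warning.
#' @param n_bins number of expression bins.
#' @param ctrl_per_gene control genes sampled per signature gene.
#' @param seed integer seed making the reference sample reproducible.
#' @return numeric per-cell score vector; the sampled reference genes are in
#'   attribute `"control_genes"`.
#' @export
score_signature <- function(normalized, signature, n_bins = 25,
                            ctrl_per_gene = 50, seed = 0L) {
  genes <- colnames(normalized)
  if (is.null(genes)) stopf("'normalized' must have gene column names")
  missing_genes <- setdiff(signature, genes)
  if (length(missing_genes))
    warnf("dropping %d signature gene(s) absent from the matrix: %s",
          length(missing_genes),
          paste(head(missing_genes, 5), collapse = ", "))
  sig <- intersect(signature, genes)
  if (!length(sig)) stopf("signature is empty after filtering")

  avg <- Matrix::colMeans(normalized)
  # rank bins with min-ties so identically expressed genes share a bin
  bin <- ceiling(rank(avg, ties.method = "min") /
                   ceiling(length(avg) / n_bins))
  names(bin) <- genes

  ctrl <- with_seed(seed, {
    picked <- character(0)
    for (g in sort(sig)) {       # sorted: reference independent of gene order
      pool <- genes[bin == bin[g]]
      pool <- setdiff(pool, sig)
      if (!length(pool)) next
      picked <- c(picked, sample(pool, min(ctrl_per_gene, length(pool))))
    }
    unique(picked)
  })
  sig_mean <- Matrix::rowMeans(normalized[, sig, drop = FALSE])
  ctrl_mean <- if (length(ctrl))
    Matrix::rowMeans(normalized[, ctrl, drop = FALSE])
  else rep(0, nrow(normalized))
  score <- as.numeric(sig_mean - ctrl_mean)
  names(score) <- rownames(normalized)
  attr(score, "control_genes") <- ctrl
  score
}

#' Score a set of signatures
#'
#' @param normalized cells-by-genes normalized matrix.
#' @param sigs a `signature_set` (named list subset -> genes).
#' @param ... passed to [score_signature()].
#' @param seed base seed; each signature uses a seed derived from it and the
#'   signature name.
#' @return cells-by-signatures numeric matrix of scores.
#' @export
score_signature_set <- function(normalized, sigs, seed = 0L, ...) {
  keep <- vapply(sigs, length, 1L) > 0
  scores <- vapply(names(sigs)[keep], function(s)
    score_signature(normalized, sigs[[s]], seed = derive_seed(seed, s), ...),
    numeric(nrow(normalized)))
  rownames(scores) <- rownames(normalized)
  scores
}

#' Assign cells or spots to the best-scoring subset
#'
#' Each row of the score matrix is assigned to the signature with the
#' largest score; exact ties are left unassigned (`NA`). The margin (top
#' score minus runner-up) is reported.
#'
#' @param scores cells/spots-by-signatures numeric matrix.
#' @return data.frame with `cell`, `assigned`, `margin` and `best_score`.
#' @export
map_subsets <- function(scores) {
  scores <- as.matrix(scores)
  if (ncol(scores) < 1) stopf("at least one signature score is required")
  assigned <- character(nrow(scores))
  margin <- numeric(nrow(scores))
  best <- numeric(nrow(scores))
  for (i in seq_len(nrow(scores))) {
    s <- scores[i, ]
    top <- max(s)
    winners <- which(s == top)
    best[i] <- top
    if (ncol(scores) == 1) {
      assigned[i] <- colnames(scores)[1]
      margin[i] <- Inf
    } else {
      second <- max(s[-winners[1]])
      margin[i] <- top - second
      assigned[i] <- if (length(winners) > 1) NA_character_ else
        colnames(scores)[winners]
    }
  }
  data.frame(cell = rownames(scores) %||% seq_len(nrow(scores)),
             assigned = assigned, margin = margin, best_score = best)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Scaled change in subset frequency between conditions
#'
#' Per-subset difference in within-compartment frequency between two
#' conditions, scaled by the maximum absolute change so values lie in
#' `[-1, 1]`; the subset absorbing the largest shift scores +/-1. This
#' normalization is a reconstruction of the published display and is
#' labelled as such in the output attribute `"scaling"`.
#'
#' @param freq data.frame with columns `subset`, `condition`, `frequency`;
#'   frequencies must sum to 1 within each condition.
#' @param condition_ref,condition_alt condition names; the change is
#'   `alt - ref` (aged minus young by default).
#' @return data.frame with `subset`, `change`, `scaled_change`.
#' @export
scaled_frequency_change <- function(freq, condition_ref = "young",
                                    condition_alt = "aged") {
  for (cd in c(condition_ref, condition_alt)) {
    f <- freq$frequency[freq$condition == cd]
    if (!length(f)) stopf("condition '%s' not found", cd)
    if (abs(sum(f) - 1) > 1e-6)
      stopf("frequencies for condition '%s' must sum to 1", cd)
  }
  subsets <- unique(freq$subset)
  f_ref <- setNames(freq$frequency[freq$condition == condition_ref],
                    freq$subset[freq$condition == condition_ref])
  f_alt <- setNames(freq$frequency[freq$condition == condition_alt],
                    freq$subset[freq$condition == condition_alt])
  change <- f_alt[subsets] - f_ref[subsets]
  m <- max(abs(change))
  scaled <- if (m > 0) change / m else change * 0
  out <- data.frame(subset = subsets, change = unname(change),
                    scaled_change = unname(scaled))
  attr(out, "scaling") <- "max-absolute-change reconstruction"
  out
}
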