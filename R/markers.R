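#' One-vs-rest Wilcoxon rank-sum marker ranking
#'
#' For each subset, every gene is tested one-vs-rest with the Wilcoxon
#' rank-sum statistic using the tie-corrected normal approximation (no
#' continuity correction, matching the exact permutation mean and variance
#' of the rank sum under ties). P values are adjusted by Benjamini-Hochberg
#' within each one-vs-rest comparison; no fold-change filter is applied.
#'
#' @param normalized cells-by-genes matrix of normalized expression.
#' @param labels per-cell subset labels (length `nrow(normalized)`).
#' @param alpha FDR level recorded for downstream signature construction.
#' @return data.frame of class `marker_table` with one row per (subset,
#'   gene): `subset`, `gene`, `z` (rank-sum z score, positive when the gene
#'   is higher in the subset), `p`, `q` (BH-adjusted within the comparison)
#'   and `direction`.
#' @export
rank_markers <- function(normalized, labels, alpha = 0.05) {
  labels <- as.character(labels)
  if (nrow(normalized) != length(labels))
    stopf("labels must match the number of cells")
  groups <- sort(unique(labels))
  if (length(groups) < 2)
    stopf("at least two distinct labels are required")
  small <- groups[vapply(groups, function(g) sum(labels == g) < 2, TRUE)]
  if (length(small))
    stopf("groups with fewer than 2 cells: %s", paste(small, collapse = ", "))

  X <- as.matrix(normalized)
  N <- nrow(X)
  ranks <- apply(X, 2, rank)                  # average ranks, ties included
  tie_term <- apply(X, 2, function(x) {
    t <- table(x)
    sum(t^3 - t)
  })
  out <- vector("list", length(groups))
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    in_g <- labels == g
    n1 <- sum(in_g)
    n2 <- N - n1
    r1 <- colSums(ranks[in_g, , drop = FALSE])
    u <- r1 - n1 * (n1 + 1) / 2
    mu <- n1 * n2 / 2
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
    z <- ifelse(sigma2 > 0, (u - mu) / sqrt(sigma2), 0)
    p <- 2 * pnorm(-abs(z))
    out[[gi]] <- data.frame(subset = g, gene = colnames(X),
                            z = z, p = p, q = p.adjust(p, "BH"),
                            direction = ifelse(z >= 0, "up", "down"),
                            row.names = NULL)
  }
  res <- do.call(rbind, out)
  attr(res, "alpha") <- alpha
  class(res) <- c("marker_table", "data.frame")
  res
}

#' Build subset gene signatures from ranked markers
#'
#' Per subset, keeps FDR-passing genes (`q <= alpha`), sorts them by
#' descending rank-sum z score (ties broken lexicographically by gene name)
#' and truncates at `n` genes. A subset with no passing genes yields an
#' empty signature with a warning.
#'
#' @param markers a [rank_markers()] table.
#' @param n signature length (20 by default; 30 and 10 are used for other
#'   mappings).
#' @param alpha FDR cutoff; defaults to the level recorded in `markers`.
#' @return named list of character vectors, class `signature_set`.
#' @export
build_signatures <- function(markers, n = 20, alpha = NULL) {
  if (is.null(alpha)) alpha <- attr(markers, "alpha")
  if (is.null(alpha)) alpha <- 0.05
  subsets <- unique(markers$subset)
  sigs <- lapply(subsets, function(s) {
    m <- markers[markers$subset == s & markers$q <= alpha, ]
    if (nrow(m) == 0) {
      warnf("subset '%s' has no FDR-passing genes; empty signature", s)
      return(character(0))
    }
    m <- m[order(-m$z, m$gene), ]
    head(m$gene, n)
  })
  names(sigs) <- subsets
  structure(sigs, class = "signature_set")
}

#' @export
print.signature_set <- function(x, ...) {
  for (s in names(x))
    cat(sprintf("%s (%d): %s\n", s, length(x[[s]]),
                paste(head(x[[s]], 8), collapse = ", ")))
  invisible(x)
}

#' Serialize signatures as JSON
#'
#' @param sigs a `signature_set` (named list subset -> genes).
#' @param path JSON file path.
#' @return `write_signatures` returns `path` invisibly; `read_signatures`
#'   returns a `signature_set`.
#' @export
write_signatures <- function(sigs, path) {
  jsonlite::write_json(unclass(sigs), path, pretty = TRUE)
  invisible(path)
}

#' @rdname write_signatures
#' @export
read_signatures <- function(path) {
  sigs <- jsonlite::read_json(path, simplifyVector = TRUE)
  sigs <- lapply(sigs, as.character)
  structure(sigs, class = "signature_set")
}
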