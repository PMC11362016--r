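#' E-cadherin-anchored EMT axis
#'
#' Places cells on an epithelial-mesenchymal axis: cells are ranked by
#' descending expression of the anchor gene (E-cadherin, `Cdh1`), per-cell
#' epithelial and mesenchymal scores are the mean normalized expression of
#' the two gene sets, and each cell is classed into a quadrant of the
#' anchor/vimentin plane by detection (expression > 0) of the two markers:
#' `epithelial` (Cdh1+ Vim-), `hybrid` (Cdh1+ Vim+), `pEMT` (Cdh1- Vim+) and
#' `double_negative` (Cdh1- Vim-).
#'
#' @param normalized cells-by-genes matrix of normalized expression.
#' @param anchor epithelial anchor gene; must be present.
#' @param epithelial_set,mesenchymal_set gene sets for the E and M scores;
#'   absent genes are dropped.
#' @param vim mesenchymal marker gene for the quadrant plane.
#' @return list with `ordering` (cell indices by descending anchor
#'   expression) and `table` (per-cell `anchor_expr`, `vim_expr`, `e_score`,
#'   `m_score`, `quadrant`).
#' @export
emt_axis <- function(normalized, anchor = "Cdh1",
                     epithelial_set = character(0),
                     mesenchymal_set = character(0),
                     vim = "Vim") {
  genes <- colnames(normalized)
  if (!anchor %in% genes) stopf("anchor gene '%s' not present", anchor)
  if (!vim %in% genes) stopf("gene '%s' not present", vim)
  a <- as.numeric(normalized[, anchor])
  v <- as.numeric(normalized[, vim])
  set_mean <- function(set) {
    set <- intersect(set, genes)
    if (!length(set)) return(rep(0, nrow(normalized)))
    as.numeric(Matrix::rowMeans(normalized[, set, drop = FALSE]))
  }
  e_score <- set_mean(epithelial_set)
  m_score <- set_mean(mesenchymal_set)
  quadrant <- ifelse(a > 0,
                     ifelse(v > 0, "hybrid", "epithelial"),
                     ifelse(v > 0, "pEMT", "double_negative"))
  ordering <- order(a, decreasing = TRUE)
  list(ordering = ordering,
       table = data.frame(cell = rownames(normalized) %||%
                            seq_len(nrow(normalized)),
                          anchor_expr = a, vim_expr = v,
                          e_score = e_score, m_score = m_score,
                          quadrant = quadrant))
}
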