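# Per-gene cell-type specificity from pseudobulk counts-per-million.

#' Pseudobulk counts-per-million by cell type or class
#'
#' Sums raw counts per gene over the cells of each group, then scales each
#' group's vector so its genes sum to one million.
#'
#' @param m Cells x genes raw count matrix.
#' @param labels Labels `data.frame` covering every cell of `m`.
#' @param level `"type"` (fine) or `"class"` (coarse).
#' @return Dense group x gene matrix; every row sums to 1e6.
#' @export
pseudobulk_cpm <- function(m, labels, level = c("type", "class")) {
  level <- match.arg(level)
  labels <- validate_labels(labels)
  if (!all(rownames(m) %in% labels$cell_id)) {
    stop("labels do not cover all cells in the matrix", call. = FALSE)
  }
  grp <- labels[[if (level == "type") "cell_type" else "cell_class"]][
    match(rownames(m), labels$cell_id)]
  groups <- sort(unique(grp))
  pb <- matrix(0, nrow = length(groups), ncol = ncol(m),
               dimnames = list(groups, colnames(m)))
  for (g in groups) {
    pb[g, ] <- Matrix::colSums(m[grp == g, , drop = FALSE])
  }
  totals <- rowSums(pb)
  if (any(totals == 0)) {
    stop("cell group(s) with zero total counts: ",
         paste(groups[totals == 0], collapse = ", "), call. = FALSE)
  }
  pb / totals * 1e6
}

#' Per-gene cell-type specificity scores and ranking
#'
#' The specificity of gene g in group t is its pseudobulk CPM there divided
#' by its summed CPM over all groups, so the scores of an expressed gene sum
#' to 1. Genes with zero total expression are excluded from the ranking and
#' listed in attribute `zero_genes`. Genes are ranked by descending maximum
#' specificity (rank 1 = most specific), ties broken by gene id.
#'
#' @param pb Group x gene pseudobulk CPM matrix from [pseudobulk_cpm()].
#' @return `data.frame` with `gene_id`, one specificity column per group,
#'   `max_specificity`, `rank`.
#' @export
specificity_scores <- function(pb) {
  totals <- colSums(pb)
  zero <- colnames(pb)[totals == 0]
  keep <- totals > 0
  sp <- sweep(pb[, keep, drop = FALSE], 2, totals[keep], "/")
  out <- data.frame(gene_id = colnames(sp), t(sp),
                    stringsAsFactors = FALSE, check.names = FALSE)
  out$max_specificity <- apply(sp, 2, max)
  ord <- order(-out$max_specificity, out$gene_id)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "zero_genes") <- zero
  out
}
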