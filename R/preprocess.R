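# Normalization, highly-variable-gene selection, PCA and permutation-based
# selection of significant components.

#' Log-normalize a count matrix
#'
#' Per cell: `value = ln(1 + count / total * scale_factor)`, the standard
#' library-size normalization with a global scale factor (default 10,000).
#' Cells with zero total counts map to all-zero rows with a warning.
#'
#' @param m Cells x genes count matrix.
#' @param scale_factor Positive scale factor, default `1e4`.
#' @return A `normalized_matrix`: the log-normalized cells x genes matrix
#'   with attribute `scale_factor`.
#' @examples
#' m <- matrix(c(1, 3), nrow = 1, dimnames = list("c1", c("g1", "g2")))
#' log_normalize(m)  # ln(1 + 2500), ln(1 + 7500)
#' @export
log_normalize <- function(m, scale_factor = 1e4) {
  if (!is.numeric(scale_factor) || length(scale_factor) != 1 ||
      scale_factor <= 0) {
    stop("'scale_factor' must be a positive number", call. = FALSE)
  }
  totals <- Matrix::rowSums(m)
  zero <- totals == 0
  if (any(zero)) {
    warning(sum(zero), " cell(s) with zero total counts produce all-zero ",
            "normalized rows")
    totals[zero] <- 1
  }
  sf <- scale_factor / totals
  nm <- Matrix::Diagonal(x = sf) %*% Matrix::Matrix(m, sparse = TRUE)
  nm <- methods::as(methods::as(nm, "CsparseMatrix"), "generalMatrix")
  nm@x <- log1p(nm@x)
  dimnames(nm) <- dimnames(m)
  attr(nm, "scale_factor") <- scale_factor
  nm
}

nm_values <- function(nm) {
  # accept either the normalized matrix or any cells x genes matrix
  nm
}

#' Select highly variable genes
#'
#' Genes are ranked by standardized dispersion: the per-gene variance of the
#' normalized values divided by a binned-median mean-variance trend over the
#' log mean (20 bins). Constant genes get dispersion 0 and rank last.
#'
#' @param nm Normalized cells x genes matrix from [log_normalize()].
#' @param n_top Number of genes to return (default 2000). If fewer genes are
#'   available all are returned with a warning.
#' @param n_bins Bins for the mean-variance trend.
#' @return Character vector of gene ids, most variable first.
#' @export
select_hvgs <- function(nm, n_top = 2000, n_bins = 20) {
  stopifnot(n_top >= 1)
  x <- nm_values(nm)
  mu <- Matrix::colMeans(x)
  ex2 <- Matrix::colMeans(x^2)
  v <- pmax(ex2 - mu^2, 0) * nrow(x) / max(nrow(x) - 1, 1)
  lm <- log1p(mu)
  bins <- cut(lm, breaks = max(min(n_bins, length(unique(lm))), 1),
              include.lowest = TRUE)
  trend <- stats::ave(v, bins, FUN = function(z) {
    md <- stats::median(z[z > 0])
    if (!is.finite(md) || md == 0) 1 else md
  })
  disp <- ifelse(v > 0, v / trend, 0)
  ord <- order(-disp, colnames(x))
  if (n_top >= length(ord)) {
    if (n_top > length(ord)) {
      warning("fewer genes than 'n_top'; returning all genes")
    }
    return(colnames(x)[ord])
  }
  colnames(x)[ord[seq_len(n_top)]]
}

#' Principal component analysis on selected genes
#'
#' Genes are centered and scaled to unit variance (constant genes dropped
#' with a warning) before an exact SVD.
#'
#' @param nm Normalized cells x genes matrix.
#' @param genes Genes to use; must be present in `nm`.
#' @param n_pcs Number of components; must not exceed `min(cells, genes)`.
#' @return List of class `pca_result` with `scores` (cells x n_pcs),
#'   `loadings` (genes x n_pcs) and `variance_explained` (fractions,
#'   non-increasing, summing to <= 1).
#' @export
run_pca <- function(nm, genes = colnames(nm_values(nm)), n_pcs = 10) {
  x <- nm_values(nm)
  missing <- setdiff(genes, colnames(x))
  if (length(missing)) {
    stop("genes not present in the matrix: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  x <- as.matrix(x[, genes, drop = FALSE])
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant gene(s) dropped before PCA")
    x <- x[, sds > 0, drop = FALSE]
  }
  if (n_pcs > min(dim(x))) {
    stop("'n_pcs' exceeds min(cells, genes)", call. = FALSE)
  }
  p <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  ve <- p$sdev^2 / sum(p$sdev^2)
  k <- seq_len(n_pcs)
  structure(list(scores = p$x[, k, drop = FALSE],
                 loadings = p$rotation[, k, drop = FALSE],
                 variance_explained = ve[k]),
            class = "pca_result")
}

#' Count significant principal components by a permutation (jackstraw) test
#'
#' Repeatedly permutes a small random fraction of genes across cells,
#' recomputes the PCA, and collects the absolute loadings of the permuted
#' genes per component as a null. A component is significant when the
#' observed loading magnitudes stochastically dominate the null (one-sided
#' Wilcoxon rank-sum, p < `alpha`). Returns the number of leading
#' significant components; the first non-significant one truncates the
#' count.
#'
#' @param nm Normalized cells x genes matrix.
#' @param genes Genes to use.
#' @param n_pcs_max Components to evaluate (<= `min(cells, genes)`).
#' @param n_perm Number of permutation rounds (>= 10).
#' @param perm_fraction Fraction of genes permuted per round.
#' @param alpha Per-component significance level.
#' @param seed RNG seed.
#' @return Integer count of leading significant components.
#' @export
jackstraw_significant_pcs <- function(nm, genes = colnames(nm_values(nm)),
                                      n_pcs_max = 10, n_perm = 100,
                                      perm_fraction = 0.01, alpha = 0.05,
                                      seed = 1L) {
  if (n_perm < 10) stop("'n_perm' must be >= 10 (unstable below)",
                        call. = FALSE)
  x <- as.matrix(nm_values(nm)[, genes, drop = FALSE])
  sds <- apply(x, 2, stats::sd)
  x <- x[, sds > 0, drop = FALSE]
  if (n_pcs_max > min(dim(x))) {
    stop("'n_pcs_max' exceeds min(cells, genes)", call. = FALSE)
  }
  set.seed(seed)
  obs <- abs(stats::prcomp(x, center = TRUE, scale. = TRUE)$rotation[
    , seq_len(n_pcs_max), drop = FALSE])
  n_swap <- max(1L, round(perm_fraction * ncol(x)))
  null_load <- vector("list", n_perm)
  for (b in seq_len(n_perm)) {
    xi <- x
    swap <- sample(ncol(x), n_swap)
    for (g in swap) xi[, g] <- xi[sample(nrow(x)), g]
    pb <- stats::prcomp(xi, center = TRUE, scale. = TRUE)
    null_load[[b]] <- abs(pb$rotation[swap, seq_len(n_pcs_max),
                                      drop = FALSE])
  }
  nulls <- do.call(rbind, null_load)
  n_sig <- 0L
  for (k in seq_len(n_pcs_max)) {
    p <- stats::wilcox.test(obs[, k], nulls[, k],
                            alternative = "greater", exact = FALSE)$p.value
    if (is.na(p) || p >= alpha) break
    n_sig <- n_sig + 1L
  }
  n_sig
}
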