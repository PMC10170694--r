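# Size-matched random-gene-set null distributions and empirical p-values
# for summed neighbor-voting AUROC scores.

#' Sample random gene sets of a fixed size
#'
#' @param universe Character vector of candidate gene ids.
#' @param size Genes per set (2 <= size <= length(universe)).
#' @param n Number of sets (default 10,000).
#' @param seed RNG seed.
#' @return List of `n` character vectors, each of `size` distinct genes.
#' @export
sample_random_gene_sets <- function(universe, size, n = 10000, seed = 1L) {
  universe <- unique(universe)
  if (size > length(universe)) {
    stop("'size' exceeds the universe size", call. = FALSE)
  }
  if (size < 2) stop("'size' must be >= 2", call. = FALSE)
  set.seed(seed)
  lapply(seq_len(n), function(i) sample(universe, size))
}

#' Empirical p-value of an observed summed score against a null sample
#'
#' `direction = "greater"`: the fraction of null values greater than or
#' equal to the observed value (ties in the numerator, no pseudo-count, so
#' p = 0 is attainable). `direction = "less"` mirrors it with <=. Set
#' `pseudo_count = TRUE` for the (k + 1) / (N + 1) estimator.
#'
#' @param observed_sum Observed summed AUROC.
#' @param null_sums Non-empty numeric vector of null summed AUROCs.
#' @param direction `"greater"` or `"less"`.
#' @param pseudo_count Use the add-one estimator (default FALSE).
#' @return p-value in `[0, 1]`.
#' @examples
#' empirical_pvalue(7.5, 1:10, "greater")  # 3/10
#' empirical_pvalue(7.5, 1:10, "less")     # 7/10
#' @export
empirical_pvalue <- function(observed_sum, null_sums,
                             direction = c("greater", "less"),
                             pseudo_count = FALSE) {
  direction <- match.arg(direction)
  if (length(null_sums) == 0) stop("'null_sums' is empty", call. = FALSE)
  k <- if (direction == "greater") sum(null_sums >= observed_sum)
       else sum(null_sums <= observed_sum)
  if (pseudo_count) (k + 1) / (length(null_sums) + 1)
  else k / length(null_sums)
}

#' Size-matched null test of gene-set discriminability
#'
#' Scores every annotated term, then builds — per distinct usable set size
#' and per universe — a null distribution of summed AUROCs from `N` random
#' gene sets of that size, scored with the same split seed as the observed
#' terms (a paired design that removes split-resampling variance from the
#' comparison). Each term gets empirical p-values in both directions against
#' the null of its own size, for each universe.
#'
#' @param nm Normalized cells x genes matrix.
#' @param labels Per-cell label vector.
#' @param ontology A `gene_ontology` or named list of gene sets.
#' @param universes Named list of gene-id vectors to draw random sets from.
#'   Default: `all_expressed` (genes with nonzero total) and
#'   `annotation_universe` (annotated genes present in the matrix).
#' @param N Random sets per (size, universe) null (default 10,000).
#' @param n_splits,seed Passed to the scorer; the seed also drives sampling.
#' @param min_genes Minimum usable genes per term.
#' @return List with `pvalues` (`data.frame`: term_id, universe,
#'   observed_sum, p_greater, p_less, N, set_size), `null_curves`
#'   (`data.frame` of per-size mean null AUROC per universe) and
#'   `null_sums` (list of the raw null samples, named `size<k>.<universe>`).
#' @export
run_size_matched_null <- function(nm, labels, ontology, universes = NULL,
                                  N = 10000, n_splits = 10, seed = 1L,
                                  min_genes = 2) {
  x <- nm_values(nm)
  sets <- if (inherits(ontology, "gene_ontology")) ontology$members
          else ontology
  if (is.null(universes)) {
    expressed <- colnames(x)[Matrix::colSums(x) > 0]
    annot <- intersect(unique(unlist(sets, use.names = FALSE)), colnames(x))
    universes <- list(all_expressed = expressed,
                      annotation_universe = annot)
  }
  obs <- score_gene_sets(nm, labels, sets, min_genes = min_genes,
                         n_splits = n_splits, seed = seed)
  if (nrow(obs) == 0) stop("no scorable terms", call. = FALSE)
  n_labels <- length(unique(as.character(labels)))

  null_sums <- list()
  curves <- list()
  pvals <- list()
  for (uname in names(universes)) {
    uni <- intersect(universes[[uname]], colnames(x))
    for (sz in sort(unique(obs$n_genes_used))) {
      if (sz > length(uni)) {
        warning(sprintf("size %d exceeds universe '%s'; terms skipped",
                        sz, uname))
        next
      }
      draw_seed <- (seed + sz * 131L) %% 2147483647L
      rand_sets <- sample_random_gene_sets(uni, sz, n = N, seed = draw_seed)
      sums <- numeric(N)
      mean_au <- numeric(N)
      for (i in seq_len(N)) {
        net <- build_cell_network(nm, rand_sets[[i]])
        au <- neighbor_voting_auroc(net, labels, n_splits = n_splits,
                                    seed = seed)
        sums[i] <- sum(au)
        mean_au[i] <- mean(au)
      }
      key <- sprintf("size%d.%s", sz, uname)
      null_sums[[key]] <- sums
      curves[[key]] <- data.frame(set_size = sz, universe = uname,
                                  mean_null_auroc = mean(mean_au),
                                  N = N, stringsAsFactors = FALSE)
      sel <- obs[obs$n_genes_used == sz, , drop = FALSE]
      for (r in seq_len(nrow(sel))) {
        pvals[[length(pvals) + 1L]] <- data.frame(
          term_id = sel$gene_set_id[r], universe = uname,
          observed_sum = sel$summed_auroc[r],
          p_greater = empirical_pvalue(sel$summed_auroc[r], sums,
                                       "greater"),
          p_less = empirical_pvalue(sel$summed_auroc[r], sums, "less"),
          N = N, set_size = sz, stringsAsFactors = FALSE)
      }
    }
  }
  list(pvalues = do.call(rbind, pvals),
       null_curves = do.call(rbind, unname(curves)),
       null_sums = null_sums,
       n_labels = n_labels,
       observed = obs)
}
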