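# Neighbor-voting discriminability scoring: rank-standardized Spearman cell
# networks, cross-validated neighbor voting, per-label AUROC, and pairwise
# comparison of gene-set families.

#' Build a rank-standardized cell similarity network from a gene set
#'
#' Spearman correlation between cells over the gene subset; all off-diagonal
#' entries are then replaced by their midranks scaled to `(0, 1]` and the
#' diagonal is set to 1. Cells with a constant profile over the gene subset
#' (undefined correlation) are treated as similarity 0 before ranking.
#'
#' @param nm Normalized cells x genes matrix.
#' @param genes Gene-id set; at least 2 must be present in `nm`.
#' @return Symmetric cells x cells matrix with unit diagonal.
#' @export
build_cell_network <- function(nm, genes) {
  x <- nm_values(nm)
  use <- intersect(genes, colnames(x))
  if (length(use) < 2) {
    stop("gene set has fewer than 2 usable genes",
         call. = FALSE)
  }
  sub <- as.matrix(x[, use, drop = FALSE])
  s <- suppressWarnings(stats::cor(t(sub), method = "spearman"))
  s[!is.finite(s)] <- 0
  n <- nrow(s)
  up <- upper.tri(s)
  r <- rank(s[up], ties.method = "average")
  std <- r / length(r)
  net <- diag(1, n)
  net[up] <- std
  net <- net + t(net) - diag(1, n)
  dimnames(net) <- list(rownames(sub), rownames(sub))
  net
}

#' Midrank Mann-Whitney AUROC
#'
#' Area under the ROC curve of `scores` against a logical positive
#' indicator, computed from midranks; equals the probability that a random
#' positive outranks a random negative, counting ties as 1/2.
#'
#' @param scores Numeric scores.
#' @param positive Logical vector, TRUE for positives.
#' @return AUROC in `[0, 1]`, or NA if either group is empty.
#' @export
auroc_midrank <- function(scores, positive) {
  n_pos <- sum(positive)
  n_neg <- sum(!positive)
  if (n_pos == 0 || n_neg == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# one stratified train index set; guarantees >= 1 train and >= 1 test cell
# per label (labels with >= 2 cells)
stratified_train_idx <- function(labels, train_fraction = 2 / 3) {
  idx <- integer()
  for (l in unique(labels)) {
    cells <- which(labels == l)
    n_train <- round(train_fraction * length(cells))
    n_train <- max(1L, min(length(cells) - 1L, n_train))
    idx <- c(idx, sample(cells, n_train))
  }
  sort(idx)
}

#' Neighbor-voting AUROC per label
#'
#' For each of `n_splits` label-stratified train/test partitions (default
#' 2/3 train), every test cell's vote for label L is the degree-normalized
#' sum of its network similarities to training cells carrying L. Votes are
#' scored against the true label indicator with a midrank Mann-Whitney
#' AUROC; the returned per-label AUROC is the mean over splits. 0.5 is
#' chance level.
#'
#' @param network Symmetric cell similarity matrix from
#'   [build_cell_network()].
#' @param labels Per-cell label vector (same order as network rows); at
#'   least 2 labels, each with at least 2 cells.
#' @param train_fraction Fraction of each label's cells used for training
#'   (default 2/3), clamped so both partitions keep at least one cell per
#'   label.
#' @param n_splits Number of train/test resamples.
#' @param seed RNG seed; results are deterministic given `seed` and
#'   `n_splits`.
#' @param splits Optional list of integer vectors of training-cell indices;
#'   when supplied these partitions are used verbatim (for reproducibility
#'   and verification) and `train_fraction`/`n_splits`/`seed` are ignored.
#' @return Named numeric vector of per-label AUROCs.
#' @export
neighbor_voting_auroc <- function(network, labels, train_fraction = 2 / 3,
                                  n_splits = 10, seed = 1L,
                                  splits = NULL) {
  labels <- as.character(labels)
  tab <- table(labels)
  if (length(tab) < 2) stop("need at least 2 labels", call. = FALSE)
  if (any(tab < 2)) {
    stop("every label needs at least 2 cells", call. = FALSE)
  }
  stopifnot(nrow(network) == length(labels))
  set.seed(seed)
  if (!is.null(splits)) n_splits <- length(splits)
  ulab <- sort(unique(labels))
  acc <- matrix(0, nrow = n_splits, ncol = length(ulab),
                dimnames = list(NULL, ulab))
  n <- length(labels)
  for (s in seq_len(n_splits)) {
    if (!is.null(splits)) {
      train <- splits[[s]]
      test <- setdiff(seq_len(n), train)
      if (!all(ulab %in% labels[train]) || !all(ulab %in% labels[test])) {
        stop("supplied split ", s, " is missing a label in one partition",
             call. = FALSE)
      }
    } else {
      for (attempt in seq_len(100)) {
        train <- stratified_train_idx(labels, train_fraction)
        test <- setdiff(seq_len(n), train)
        ok <- all(ulab %in% labels[train]) && all(ulab %in% labels[test])
        if (ok) break
        if (attempt == 100) stop("could not draw a split containing every ",
                                 "label in both partitions", call. = FALSE)
      }
    }
    w <- network[test, train, drop = FALSE]
    deg <- rowSums(w)
    deg[deg == 0] <- 1
    for (l in ulab) {
      votes <- as.numeric(w %*% (labels[train] == l)) / deg
      acc[s, l] <- auroc_midrank(votes, labels[test] == l)
    }
  }
  colMeans(acc)
}

#' Score every annotated gene set for label discriminability
#'
#' Applies [build_cell_network()] + [neighbor_voting_auroc()] per annotated
#' term. Terms with fewer than `min_genes` usable genes are skipped and
#' reported in attribute `skipped`.
#'
#' @param nm Normalized cells x genes matrix.
#' @param labels Per-cell label vector (class- or type-level, caller's
#'   choice).
#' @param ontology A `gene_ontology`, or a named list of gene-id vectors.
#' @param min_genes Minimum usable genes per set (default 2).
#' @inheritParams neighbor_voting_auroc
#' @return `data.frame` with one row per scored term: `gene_set_id`, one
#'   AUROC column per label, `summed_auroc`, `n_genes_used`.
#' @export
score_gene_sets <- function(nm, labels, ontology, min_genes = 2,
                            n_splits = 10, seed = 1L) {
  sets <- if (inherits(ontology, "gene_ontology")) ontology$members
          else ontology
  x <- nm_values(nm)
  rows <- list()
  skipped <- character()
  for (id in names(sets)) {
    use <- intersect(sets[[id]], colnames(x))
    if (length(use) < max(min_genes, 2)) {
      skipped <- c(skipped, id)
      next
    }
    net <- build_cell_network(nm, use)
    au <- neighbor_voting_auroc(net, labels, n_splits = n_splits,
                                seed = seed)
    rows[[id]] <- data.frame(gene_set_id = id, t(au),
                             summed_auroc = sum(au),
                             n_genes_used = length(use),
                             stringsAsFactors = FALSE, check.names = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_set_id = character(), summed_auroc = numeric(),
               n_genes_used = integer(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Compare AUROC distributions between gene-set families
#'
#' Two-sided Wilcoxon rank-sum tests on the per-label AUROC values of every
#' pair of families, with Benjamini-Hochberg adjustment across all pairs.
#' Families with fewer than 2 values are skipped with a warning.
#'
#' @param families Named list of numeric AUROC vectors, one per family.
#' @return `data.frame` with columns `family_a`, `family_b`, `p_value`,
#'   `q_value`.
#' @export
compare_gene_sets <- function(families) {
  stopifnot(is.list(families), !is.null(names(families)))
  sizes <- vapply(families, length, integer(1))
  if (any(sizes < 2)) {
    warning("families skipped (fewer than 2 values): ",
            paste(names(families)[sizes < 2], collapse = ", "))
    families <- families[sizes >= 2]
  }
  if (length(families) < 2) stop("need at least 2 comparable families",
                                 call. = FALSE)
  pairs <- utils::combn(names(families), 2)
  p <- apply(pairs, 2, function(pr) {
    suppressWarnings(stats::wilcox.test(families[[pr[1]]],
                                        families[[pr[2]]],
                                        exact = FALSE)$p.value)
  })
  data.frame(family_a = pairs[1, ], family_b = pairs[2, ],
             p_value = p, q_value = stats::p.adjust(p, method = "BH"),
             stringsAsFactors = FALSE)
}
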