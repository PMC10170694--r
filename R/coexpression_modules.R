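# Weighted gene co-expression modules: soft-threshold adjacency, topological
# overlap, average-linkage clustering with a multi-height consensus cut, and
# classification of modules into discrete / intermediate / pure gradient
# expression patterns.

wgcna_palette <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
  "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
  "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
  "orange", "darkorange", "white", "skyblue", "saddlebrown", "steelblue")

#' Soft-threshold co-expression adjacency
#'
#' Unsigned adjacency `a_ij = |cor(g_i, g_j)|^beta` with Pearson correlation
#' over cells; diagonal 1. Zero-variance genes are dropped with a warning.
#'
#' @param nm Normalized cells x genes matrix.
#' @param genes Genes to include (>= 3 after dropping constants).
#' @param beta Soft thresholding power (> 0), default 4.
#' @return Symmetric gene x gene adjacency matrix in `[0, 1]`.
#' @export
soft_adjacency <- function(nm, genes = colnames(nm_values(nm)), beta = 4) {
  if (beta <= 0) stop("'beta' must be > 0", call. = FALSE)
  x <- as.matrix(nm_values(nm)[, genes, drop = FALSE])
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " zero-variance gene(s) dropped")
    x <- x[, sds > 0, drop = FALSE]
  }
  if (ncol(x) < 3) stop("need at least 3 usable genes", call. = FALSE)
  a <- abs(stats::cor(x))^beta
  diag(a) <- 1
  a
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` over
#' `u != i, j`, with connectivity `k_i = sum_{u != i} a_iu`; diagonal 1.
#' The clustering distance is `1 - TOM`.
#'
#' @param adjacency Symmetric adjacency in `[0, 1]` with unit diagonal.
#' @return Symmetric TOM in `[0, 1]` with unit diagonal.
#' @export
topological_overlap <- function(adjacency) {
  a <- as.matrix(adjacency)
  stopifnot(nrow(a) == ncol(a))
  diag(a) <- 1
  aa <- a %*% a
  # remove the u = i and u = j terms (diag(a) = 1 makes both equal a_ij)
  shared <- aa - 2 * a
  k <- rowSums(a) - 1
  kmin <- outer(k, k, pmin)
  tom <- (shared + a) / (kmin + 1 - a)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adjacency)
  tom
}

#' Detect modules by a multi-height consensus cut
#'
#' Average-linkage hierarchical clustering on the `1 - TOM` distance. The
#' dendrogram is cut at each height in `heights`; clusters below
#' `min_module_size` are dissolved to "unassigned" at that height. Two genes
#' share a final module iff they share a (retained) cluster at every height;
#' final groups below `min_module_size` are unassigned. Modules are named by
#' decreasing size from a fixed color palette (ties broken by the
#' lexicographically smallest member id), following the naming convention of
#' co-expression network analyses.
#'
#' @param tom_distance Symmetric gene x gene distance matrix (`1 - TOM`).
#' @param heights Cut heights, default `c(0.9, 0.95, 0.98)`.
#' @param min_module_size Minimum module size, default 20.
#' @return A `module_catalog`: list with `assignments` (named character
#'   vector, `"unassigned"` for leftovers) and `modules` (named list of
#'   member gene vectors, size-descending).
#' @export
cut_modules <- function(tom_distance, heights = c(0.9, 0.95, 0.98),
                        min_module_size = 20) {
  d <- as.matrix(tom_distance)
  genes <- rownames(d)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(d)))
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  per_height <- lapply(heights, function(h) {
    cl <- stats::cutree(hc, h = h)
    sizes <- table(cl)
    small <- as.integer(names(sizes)[sizes < min_module_size])
    cl[cl %in% small] <- NA
    cl
  })
  assigned_all <- Reduce(`&`, lapply(per_height, function(cl) !is.na(cl)))
  key <- rep(NA_character_, length(genes))
  if (any(assigned_all)) {
    key[assigned_all] <- apply(
      do.call(cbind, lapply(per_height, function(cl) cl[assigned_all])),
      1, paste, collapse = "|")
  }
  groups <- split(genes[!is.na(key)], key[!is.na(key)])
  groups <- groups[vapply(groups, length, integer(1)) >= min_module_size]
  if (length(groups) == 0) {
    warning("no module reached 'min_module_size'; empty catalog")
    assignments <- stats::setNames(rep("unassigned", length(genes)), genes)
    return(structure(list(assignments = assignments, modules = list()),
                     class = "module_catalog"))
  }
  # deterministic size-descending order; palette naming
  first_member <- vapply(groups, function(g) min(sort(g)), character(1))
  ord <- order(-vapply(groups, length, integer(1)), first_member)
  groups <- lapply(groups[ord], function(g) sort(g))
  nm_pool <- c(wgcna_palette,
               paste0("module", seq_len(max(0, length(groups) -
                                              length(wgcna_palette)))))
  names(groups) <- nm_pool[seq_along(groups)]
  assignments <- stats::setNames(rep("unassigned", length(genes)), genes)
  for (mname in names(groups)) assignments[groups[[mname]]] <- mname
  structure(list(assignments = assignments, modules = groups),
            class = "module_catalog")
}

#' @export
print.module_catalog <- function(x, ...) {
  cat(sprintf("module_catalog: %d modules over %d genes (%d unassigned)\n",
              length(x$modules), length(x$assignments),
              sum(x$assignments == "unassigned")))
  if (!is.null(x$gradient_class)) {
    cat("gradient classes:",
        paste(sprintf("%s=%s", names(x$gradient_class), x$gradient_class),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Build a module catalog directly from planted or external memberships
#'
#' @param modules Named list of gene-id vectors (disjoint).
#' @param all_genes Optional full gene universe for the assignment vector.
#' @return A `module_catalog`.
#' @export
module_catalog <- function(modules, all_genes = NULL) {
  if (is.null(all_genes)) all_genes <- unique(unlist(modules))
  assignments <- stats::setNames(rep("unassigned", length(all_genes)),
                                 all_genes)
  for (m in names(modules)) assignments[modules[[m]]] <- m
  structure(list(assignments = assignments, modules = modules),
            class = "module_catalog")
}

#' Per-cell module expression profiles with background normalization
#'
#' For each module: the per-cell mean normalized expression of its member
#' genes (raw profile) and the same divided by the mean profile of
#' `n_background_draws` random gene sets of equal size (background-normalized
#' profile).
#'
#' @param nm Normalized cells x genes matrix.
#' @param catalog A `module_catalog`.
#' @param n_background_draws Random background sets per module.
#' @param seed RNG seed for the background draws.
#' @return The catalog with `profiles` (cells x modules, raw means) and
#'   `profiles_norm` (background-normalized) added.
#' @export
module_profiles <- function(nm, catalog, n_background_draws = 100,
                            seed = 1L) {
  stopifnot(inherits(catalog, "module_catalog"))
  if (length(catalog$modules) == 0) stop("empty module catalog",
                                         call. = FALSE)
  x <- nm_values(nm)
  set.seed(seed)
  all_genes <- colnames(x)
  raw <- sapply(catalog$modules, function(g) {
    Matrix::rowMeans(x[, intersect(g, all_genes), drop = FALSE])
  })
  norm <- raw
  for (m in seq_along(catalog$modules)) {
    sz <- length(intersect(catalog$modules[[m]], all_genes))
    bg <- rowMeans(sapply(seq_len(n_background_draws), function(i) {
      Matrix::rowMeans(x[, sample(all_genes, sz), drop = FALSE])
    }))
    bg[bg == 0] <- 1
    norm[, m] <- raw[, m] / bg
  }
  rownames(raw) <- rownames(norm) <- rownames(x)
  catalog$profiles <- raw
  catalog$profiles_norm <- norm
  catalog
}

#' Classify modules into discrete / intermediate / pure gradient patterns
#'
#' Builds the module x group variance matrix V (variance over the cells of
#' each group of the module's raw per-cell mean profile), removes group
#' identity by sorting every row in descending order, takes the first
#' principal component of the sorted matrix, and K-means clusters the
#' modules (k groups, 100 restarts) on their PC1 coordinate. Clusters are
#' mapped to classes by the descending mean range (max - min) of their
#' sorted variance rows: the most uneven profiles are "discrete", the
#' flattest "pure", the rest "intermediate".
#'
#' @param catalog A `module_catalog` with profiles (see
#'   [module_profiles()]).
#' @param labels Labels `data.frame` covering the profile cells.
#' @param level Grouping level for the variance matrix: `"class"` (default)
#'   or `"type"`. Class-level variance separates on/off modules (bimodal
#'   within a class) from within-group gradients.
#' @param k Number of K-means clusters (default 3, one per named class).
#' @param seed RNG seed for K-means restarts.
#' @return The catalog with `gradient_class` (named character vector),
#'   `variance_matrix` (sorted V), `pc1_coordinate` and
#'   `pc1_variance_explained` added.
#' @export
classify_gradients <- function(catalog, labels, level = c("class", "type"),
                               k = 3, seed = 1L) {
  stopifnot(inherits(catalog, "module_catalog"))
  level <- match.arg(level)
  if (is.null(catalog$profiles)) {
    stop("catalog has no profiles; run module_profiles() first",
         call. = FALSE)
  }
  if (length(catalog$modules) < k) {
    stop("fewer modules than 'k'", call. = FALSE)
  }
  labels <- validate_labels(labels)
  grp <- labels[[if (level == "type") "cell_type" else "cell_class"]][
    match(rownames(catalog$profiles), labels$cell_id)]
  groups <- sort(unique(grp))
  v <- t(sapply(colnames(catalog$profiles), function(m) {
    vapply(groups, function(g) {
      stats::var(catalog$profiles[grp == g, m])
    }, numeric(1))
  }))
  colnames(v) <- groups
  v_sorted <- t(apply(v, 1, sort, decreasing = TRUE))
  p <- stats::prcomp(v_sorted, center = TRUE, scale. = FALSE)
  pc1 <- p$x[, 1]
  ve <- p$sdev^2 / sum(p$sdev^2)
  set.seed(seed)
  k_eff <- min(k, length(unique(pc1)))
  clusters <- if (length(pc1) <= k_eff) {
    seq_along(pc1)                      # every module its own cluster
  } else {
    stats::kmeans(pc1, centers = k_eff, nstart = 100)$cluster
  }
  ranges <- apply(v_sorted, 1, function(r) max(r) - min(r))
  cl_range <- tapply(ranges, clusters, mean)
  class_names <- c("discrete", "intermediate", "pure")[seq_along(cl_range)]
  mapping <- stats::setNames(
    class_names[rank(-cl_range, ties.method = "first")],
    names(cl_range))
  catalog$gradient_class <- stats::setNames(
    mapping[as.character(clusters)], names(pc1))
  catalog$variance_matrix <- v_sorted
  catalog$pc1_coordinate <- pc1
  catalog$pc1_variance_explained <- ve[1]
  catalog
}

#' Correlation between module expression profiles
#'
#' Pearson correlation matrix of the raw per-cell mean profiles; used to
#' detect anti-regulated module pairs.
#'
#' @param catalog A `module_catalog` with profiles.
#' @return Symmetric module x module correlation matrix.
#' @export
module_correlation <- function(catalog) {
  stopifnot(inherits(catalog, "module_catalog"))
  if (is.null(catalog$profiles)) {
    stop("catalog has no profiles; run module_profiles() first",
         call. = FALSE)
  }
  if (ncol(catalog$profiles) < 2) stop("need at least 2 modules",
                                       call. = FALSE)
  stats::cor(catalog$profiles)
}
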