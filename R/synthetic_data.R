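# Synthetic single-cell count data with planted co-expression modules.
#
# The generator emulates the structure the downstream analysis assumes:
# discrete cell classes containing multiple cell types, negative-binomial
# counts, and gene modules whose expression is (i) specific to one type or
# class ("discrete"), (ii) a per-cell gradient restricted to one class
# ("intermediate"), or (iii) a pan-cellular gradient ("pure_gradient"),
# optionally with one anti-regulated module pair.

#' Define a simulation design
#'
#' Builds and validates the specification consumed by [simulate_labels()],
#' [simulate_counts()] and [simulate_ontology()]. Cell types are nested in
#' classes (`n_classes * types_per_class` types, `cells_per_type` cells
#' each); classes are split half/half into "excitatory" and "inhibitory"
#' categories. Genes not claimed by `module_plan` are background noise genes.
#'
#' @param n_classes Number of coarse cell classes (>= 1).
#' @param types_per_class Number of fine cell types per class (>= 1).
#' @param cells_per_type Cells simulated per type (>= 1).
#' @param n_genes Total genes; must be >= sum of module sizes.
#' @param module_plan `data.frame` with columns `size` (int), `kind`
#'   (`"discrete"`, `"intermediate"`, `"pure_gradient"`), `target` (a class
#'   name such as `"class1"`, a type name such as `"class1.type2"`, or
#'   `"all"`) and `effect_size` (fold change >= 1). May have zero rows.
#' @param anti_pair Optional integer pair of module-plan row indices whose
#'   per-cell gradient factors are anti-regulated: the second module's
#'   factor is `1 + effect_size - factor` of the first.
#' @param baseline_mean Mean counts per gene before module effects (> 0).
#' @param dispersion Negative-binomial dispersion (> 0); variance is
#'   `mu + dispersion * mu^2`.
#' @param library_size_cv Coefficient of variation of log-normal per-cell
#'   library-size factors (>= 0; 0 disables).
#' @param seed Master seed; all sub-streams are derived from it.
#'
#' @return An object of class `simulation_spec`.
#' @examples
#' spec <- simulation_spec(n_classes = 2, types_per_class = 3,
#'                         cells_per_type = 10, n_genes = 100)
#' @export
simulation_spec <- function(n_classes, types_per_class, cells_per_type,
                            n_genes,
                            module_plan = empty_module_plan(),
                            anti_pair = NULL,
                            baseline_mean = 20,
                            dispersion = 0.1,
                            library_size_cv = 0.3,
                            seed = 1L) {
  check_count <- function(x, name, min = 1) {
    if (length(x) != 1 || !is.numeric(x) || is.na(x) || x < min ||
        x != as.integer(x)) {
      stop(sprintf("invalid simulation spec: '%s' must be an integer >= %d",
                   name, min), call. = FALSE)
    }
    as.integer(x)
  }
  n_classes <- check_count(n_classes, "n_classes")
  types_per_class <- check_count(types_per_class, "types_per_class")
  cells_per_type <- check_count(cells_per_type, "cells_per_type")
  n_genes <- check_count(n_genes, "n_genes")

  module_plan <- as.data.frame(module_plan, stringsAsFactors = FALSE)
  needed <- c("size", "kind", "target", "effect_size")
  if (!all(needed %in% names(module_plan))) {
    stop("invalid simulation spec: 'module_plan' must have columns ",
         paste(needed, collapse = ", "), call. = FALSE)
  }
  if (nrow(module_plan) > 0) {
    if (any(module_plan$size < 2)) {
      stop("invalid simulation spec: 'module_plan$size' must be >= 2",
           call. = FALSE)
    }
    if (!all(module_plan$kind %in%
             c("discrete", "intermediate", "pure_gradient"))) {
      stop("invalid simulation spec: 'module_plan$kind' must be one of ",
           "discrete, intermediate, pure_gradient", call. = FALSE)
    }
    if (any(module_plan$effect_size < 1)) {
      stop("invalid simulation spec: 'module_plan$effect_size' must be >= 1",
           call. = FALSE)
    }
  }
  if (sum(module_plan$size) > n_genes) {
    stop("invalid simulation spec: sum of module sizes exceeds 'n_genes'",
         call. = FALSE)
  }
  if (!is.null(anti_pair)) {
    if (length(anti_pair) != 2 || any(anti_pair < 1) ||
        any(anti_pair > nrow(module_plan)) || anti_pair[1] == anti_pair[2]) {
      stop("invalid simulation spec: 'anti_pair' must index two distinct ",
           "module_plan rows", call. = FALSE)
    }
    anti_pair <- as.integer(anti_pair)
  }
  if (!is.numeric(baseline_mean) || baseline_mean <= 0) {
    stop("invalid simulation spec: 'baseline_mean' must be > 0",
         call. = FALSE)
  }
  if (!is.numeric(dispersion) || dispersion <= 0) {
    stop("invalid simulation spec: 'dispersion' must be > 0", call. = FALSE)
  }
  if (!is.numeric(library_size_cv) || library_size_cv < 0) {
    stop("invalid simulation spec: 'library_size_cv' must be >= 0",
         call. = FALSE)
  }
  structure(
    list(n_classes = n_classes, types_per_class = types_per_class,
         cells_per_type = cells_per_type, n_genes = n_genes,
         module_plan = module_plan, anti_pair = anti_pair,
         baseline_mean = baseline_mean, dispersion = dispersion,
         library_size_cv = library_size_cv, seed = as.integer(seed)),
    class = "simulation_spec")
}

#' @rdname simulation_spec
#' @export
empty_module_plan <- function() {
  data.frame(size = integer(), kind = character(), target = character(),
             effect_size = numeric(), stringsAsFactors = FALSE)
}

# deterministic sub-stream seeds per operation, kept below 2^31
sim_substream <- function(seed, offset) {
  (abs(as.integer(seed)) * 1009L + offset) %% 2147483647L
}

#' Gene identifiers and planted module membership implied by a spec
#'
#' Module `m` occupies the next `module_plan$size[m]` gene ids in order;
#' remaining genes are background.
#'
#' @param spec A `simulation_spec`.
#' @return Named list of gene-id character vectors, one per planted module
#'   (`module1`, `module2`, ...), with attribute `background` holding the
#'   unassigned gene ids.
#' @export
planted_modules <- function(spec) {
  genes <- sim_gene_ids(spec$n_genes)
  out <- list()
  at <- 1L
  if (nrow(spec$module_plan) > 0) {
    for (m in seq_len(nrow(spec$module_plan))) {
      sz <- spec$module_plan$size[m]
      out[[paste0("module", m)]] <- genes[at:(at + sz - 1L)]
      at <- at + sz
    }
  }
  attr(out, "background") <- if (at <= spec$n_genes) genes[at:spec$n_genes]
                             else character()
  out
}

sim_gene_ids <- function(n) sprintf("gene%05d", seq_len(n))

#' Simulate cell labels
#'
#' @param spec A `simulation_spec`.
#' @return A labels `data.frame` with columns `cell_id`, `cell_class`,
#'   `cell_type`, `category`; exactly
#'   `n_classes * types_per_class * cells_per_type` rows.
#' @examples
#' lab <- simulate_labels(simulation_spec(2, 3, 10, 50))
#' table(lab$cell_class)
#' @export
simulate_labels <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  classes <- paste0("class", seq_len(spec$n_classes))
  category <- ifelse(seq_len(spec$n_classes) <= ceiling(spec$n_classes / 2),
                     "excitatory", "inhibitory")
  rows <- list()
  i <- 1L
  for (k in seq_len(spec$n_classes)) {
    for (t in seq_len(spec$types_per_class)) {
      type <- paste0(classes[k], ".type", t)
      rows[[length(rows) + 1L]] <- data.frame(
        cell_class = classes[k], cell_type = type, category = category[k],
        count = spec$cells_per_type, stringsAsFactors = FALSE)
    }
  }
  plan <- do.call(rbind, rows)
  labels <- data.frame(
    cell_id = sprintf("cell%05d",
                      seq_len(sum(plan$count))),
    cell_class = rep(plan$cell_class, plan$count),
    cell_type = rep(plan$cell_type, plan$count),
    category = rep(plan$category, plan$count),
    stringsAsFactors = FALSE)
  labels
}

# per-cell multiplicative factor of one module given its plan row
module_cell_factor <- function(plan_row, labels) {
  n <- nrow(labels)
  target <- plan_row$target
  in_scope <- if (identical(target, "all")) {
    rep(TRUE, n)
  } else if (target %in% labels$cell_class) {
    labels$cell_class == target
  } else if (target %in% labels$cell_type) {
    labels$cell_type == target
  } else {
    stop(sprintf("invalid simulation spec: module target '%s' is neither a ",
                 target), "class, a type, nor \"all\"", call. = FALSE)
  }
  f <- rep(1, n)
  if (plan_row$kind == "discrete") {
    f[in_scope] <- plan_row$effect_size
  } else {
    # gradient kinds: per-cell uniform factor in [1, effect_size];
    # pure gradients span all cells, intermediate only the target class
    if (plan_row$kind == "pure_gradient") in_scope <- rep(TRUE, n)
    f[in_scope] <- stats::runif(sum(in_scope), min = 1,
                                max = plan_row$effect_size)
  }
  f
}

#' Simulate a negative-binomial count matrix with planted modules
#'
#' Counts are NB with gene-level mean `baseline_mean` multiplied by the
#' module factor of the gene's module (if any) and a log-normal per-cell
#' library-size factor with the requested coefficient of variation.
#' Discrete modules multiply the mean by `effect_size` in target cells only;
#' gradient modules draw one uniform factor in `[1, effect_size]` per cell
#' (within the target class for `intermediate`, everywhere for
#' `pure_gradient`). If `anti_pair` is set the second module's factor is
#' `1 + effect_size - factor` of the first, giving anti-correlated module
#' means. Fully reproducible from `spec$seed`.
#'
#' @param spec A `simulation_spec`.
#' @param labels Labels from [simulate_labels()] for the same spec.
#' @return A sparse cells x genes count matrix (`dgCMatrix`) with cell ids
#'   as rownames and gene ids as colnames.
#' @export
simulate_counts <- function(spec, labels) {
  stopifnot(inherits(spec, "simulation_spec"))
  expected <- spec$n_classes * spec$types_per_class * spec$cells_per_type
  if (nrow(labels) != expected) {
    stop("labels are inconsistent with the simulation spec", call. = FALSE)
  }
  n_cells <- nrow(labels)
  set.seed(sim_substream(spec$seed, 1L))

  lib <- rep(1, n_cells)
  if (spec$library_size_cv > 0) {
    sdlog <- sqrt(log1p(spec$library_size_cv^2))
    lib <- stats::rlnorm(n_cells, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }

  # per-module per-cell factors, with anti-regulation applied after the fact
  n_mod <- nrow(spec$module_plan)
  factors <- matrix(1, nrow = n_cells, ncol = max(n_mod, 1L))
  if (n_mod > 0) {
    for (m in seq_len(n_mod)) {
      factors[, m] <- module_cell_factor(spec$module_plan[m, ], labels)
    }
    if (!is.null(spec$anti_pair)) {
      i <- spec$anti_pair[1]; j <- spec$anti_pair[2]
      e <- spec$module_plan$effect_size[i]
      f2 <- 1 + e - factors[, i]
      # respect the second module's own scope: cells outside it stay at 1
      scope2 <- module_cell_factor(spec$module_plan[j, ], labels) > 1 |
        spec$module_plan$kind[j] == "pure_gradient" |
        spec$module_plan$target[j] == "all"
      factors[, j] <- ifelse(scope2, f2, 1)
    }
  }

  modules <- planted_modules(spec)
  gene_mod <- integer(spec$n_genes)       # 0 = background
  if (n_mod > 0) {
    gene_ids <- sim_gene_ids(spec$n_genes)
    for (m in seq_len(n_mod)) {
      gene_mod[match(modules[[m]], gene_ids)] <- m
    }
  }

  mu <- matrix(spec$baseline_mean, nrow = n_cells, ncol = spec$n_genes)
  for (m in seq_len(max(n_mod, 0L))) {
    idx <- which(gene_mod == m)
    if (length(idx)) mu[, idx] <- mu[, idx] * factors[, m]
  }
  mu <- mu * lib

  counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                  size = 1 / spec$dispersion),
                   nrow = n_cells, ncol = spec$n_genes,
                   dimnames = list(labels$cell_id,
                                   sim_gene_ids(spec$n_genes)))
  methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                          "CsparseMatrix"), "generalMatrix")
}

#' Simulate a hierarchical gene-set annotation table
#'
#' Creates one "true" term per planted module containing `overlap_fraction`
#' of the module's genes padded back to the module size with genes drawn
#' from outside the module, plus `n_random_terms` terms of matched sizes
#' sampled uniformly from all genes. Terms sit under a two-level hierarchy
#' (root -> domain -> term) with domains alternating between BP and CC.
#' Every term has at least 2 genes.
#'
#' @param spec A `simulation_spec` with at least one planted module.
#' @param overlap_fraction Fraction in `[0, 1]` of each module's genes
#'   included in its true term.
#' @param n_random_terms Number of additional size-matched random terms.
#' @param seed Seed for the term sampling.
#' @return A `gene_ontology` object (see [ontology_table()]); true terms are
#'   named `term_module<m>`, random terms `term_random<k>`.
#' @export
simulate_ontology <- function(spec, overlap_fraction = 1,
                              n_random_terms = 0, seed = spec$seed) {
  stopifnot(inherits(spec, "simulation_spec"))
  if (overlap_fraction < 0 || overlap_fraction > 1) {
    stop("'overlap_fraction' must be in [0, 1]", call. = FALSE)
  }
  modules <- planted_modules(spec)
  if (length(modules) == 0) {
    stop("the simulation spec has no planted modules", call. = FALSE)
  }
  set.seed(sim_substream(seed, 2L))
  all_genes <- sim_gene_ids(spec$n_genes)

  terms <- data.frame(term_id = c("root", "BP_domain", "CC_domain"),
                      term_name = c("root", "biological process",
                                    "cellular component"),
                      domain = c(NA, "BP", "CC"),
                      parent_id = c(NA, "root", "root"),
                      stringsAsFactors = FALSE)
  members <- list()
  domains <- c("BP", "CC")
  sizes <- vapply(modules, length, integer(1))

  for (m in seq_along(modules)) {
    mod_genes <- modules[[m]]
    n_in <- max(2L, round(overlap_fraction * length(mod_genes)))
    n_in <- min(n_in, length(mod_genes))
    if (overlap_fraction == 0) n_in <- 0L
    inside <- if (n_in > 0) sort(sample(mod_genes, n_in)) else character()
    n_pad <- length(mod_genes) - n_in
    outside_pool <- setdiff(all_genes, mod_genes)
    pad <- if (n_pad > 0) sample(outside_pool, n_pad) else character()
    memb <- c(inside, pad)
    if (length(memb) < 2) memb <- c(memb, sample(outside_pool, 2 - length(memb)))
    dom <- domains[(m - 1) %% 2 + 1]
    id <- paste0("term_module", m)
    terms <- rbind(terms, data.frame(
      term_id = id, term_name = paste("true term for module", m),
      domain = dom, parent_id = paste0(dom, "_domain"),
      stringsAsFactors = FALSE))
    members[[id]] <- memb
  }
  if (n_random_terms > 0) {
    for (k in seq_len(n_random_terms)) {
      sz <- max(2L, sizes[(k - 1) %% length(sizes) + 1])
      dom <- domains[(k - 1) %% 2 + 1]
      id <- paste0("term_random", k)
      terms <- rbind(terms, data.frame(
        term_id = id, term_name = paste("random term", k),
        domain = dom, parent_id = paste0(dom, "_domain"),
        stringsAsFactors = FALSE))
      members[[id]] <- sort(sample(all_genes, sz))
    }
  }
  ontology_table(terms, members)
}

#' Simulate a complete labelled dataset
#'
#' Convenience wrapper running [simulate_labels()], [simulate_counts()] and
#' (when modules are planted) [simulate_ontology()].
#'
#' @inheritParams simulate_ontology
#' @return List with elements `counts`, `labels`, `ontology` (NULL when no
#'   modules are planted) and `modules` (the planted membership).
#' @export
simulate_dataset <- function(spec, overlap_fraction = 1,
                             n_random_terms = 0) {
  labels <- simulate_labels(spec)
  counts <- simulate_counts(spec, labels)
  onto <- NULL
  if (nrow(spec$module_plan) > 0) {
    onto <- simulate_ontology(spec, overlap_fraction, n_random_terms)
  }
  list(counts = counts, labels = labels, ontology = onto,
       modules = planted_modules(spec))
}
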