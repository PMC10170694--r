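# End-to-end orchestration: filter -> normalize -> gene-set discriminability
# -> size-matched null -> specificity -> co-expression modules -> gradient
# classification -> enrichment, with a hashed output manifest.

#' Build and validate a pipeline configuration
#'
#' Accepts either a YAML file path or a named list. Required entries:
#' `counts` (a directory with `matrix.mtx`/`genes.tsv`/`cells.tsv`, or a
#' dense CSV path), `labels`, `ontology`, `out_dir`. Optional entries with
#' defaults: `keep_categories` (NULL = keep all), `scale_factor` (10000),
#' `n_splits` (10), `level` (`"class"`), `n_permutations` (10000), `beta`
#' (4), `heights` (0.9, 0.95, 0.98), `min_module_size` (20), `k` (3),
#' `classify_level` (`"class"`), `seed` (1).
#'
#' @param config YAML path or named list.
#' @return Validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- list(keep_categories = NULL, scale_factor = 1e4,
                   n_splits = 10, level = "class", n_permutations = 10000,
                   beta = 4, heights = c(0.9, 0.95, 0.98),
                   min_module_size = 20, k = 3, classify_level = "class",
                   seed = 1L)
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  for (nm in c("counts", "labels", "ontology", "out_dir")) {
    if (is.null(config[[nm]])) {
      stop("pipeline config is missing '", nm, "'", call. = FALSE)
    }
  }
  for (nm in c("labels", "ontology")) {
    if (!file.exists(config[[nm]])) {
      stop("pipeline config: file not found: ", config[[nm]],
           call. = FALSE)
    }
  }
  if (!file.exists(config$counts) && !dir.exists(config$counts)) {
    stop("pipeline config: counts input not found: ", config$counts,
         call. = FALSE)
  }
  structure(config, class = "pipeline_config")
}

pipeline_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

write_stage_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes every stage on the configured inputs and writes all outputs plus
#' a JSON manifest listing each file with its MD5 content hash. Identical
#' config and seed give identical manifest hashes.
#'
#' @param config A `pipeline_config`, or anything [pipeline_config()]
#'   accepts.
#' @return The manifest, invisibly (named list: file -> md5).
#' @export
run_pipeline <- function(config) {
  cfg <- pipeline_config(config)
  out <- cfg$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  files <- character()

  counts <- if (dir.exists(cfg$counts)) {
    read_counts(file.path(cfg$counts, "matrix.mtx"),
                file.path(cfg$counts, "genes.tsv"),
                file.path(cfg$counts, "cells.tsv"))
  } else {
    read_counts(cfg$counts)
  }
  labels <- read_labels(cfg$labels)
  onto <- read_ontology(cfg$ontology)
  pipeline_log("input", "%d cells x %d genes; %d annotated terms",
               nrow(counts), ncol(counts), length(onto$members))

  if (!is.null(cfg$keep_categories)) {
    f <- filter_cells_by_category(counts, labels, cfg$keep_categories)
    counts <- f$counts
    labels <- f$labels
    pipeline_log("filter", "%d cells retained in categories: %s",
                 nrow(counts), paste(cfg$keep_categories, collapse = ", "))
  }
  annotated <- intersect(ontology_genes(onto), colnames(counts))
  pipeline_log("filter", "%d annotated genes present in the matrix",
               length(annotated))

  nm <- log_normalize(counts, cfg$scale_factor)
  lab_vec <- labels[[if (cfg$level == "type") "cell_type" else
                       "cell_class"]][match(rownames(counts),
                                            labels$cell_id)]

  auroc <- score_gene_sets(nm, lab_vec, onto, n_splits = cfg$n_splits,
                           seed = cfg$seed)
  files["auroc"] <- write_stage_tsv(auroc, file.path(out, "auroc.tsv"))
  pipeline_log("discriminability", "%d terms scored, %d skipped",
               nrow(auroc), length(attr(auroc, "skipped")))

  null_res <- run_size_matched_null(nm, lab_vec, onto,
                                    N = cfg$n_permutations,
                                    n_splits = cfg$n_splits,
                                    seed = cfg$seed)
  files["pvalues"] <- write_stage_tsv(null_res$pvalues,
                                      file.path(out, "pvalues.tsv"))
  files["null_curves"] <- write_stage_tsv(null_res$null_curves,
                                          file.path(out,
                                                    "null_curves.tsv"))

  pb <- pseudobulk_cpm(counts, labels, level = "type")
  spec_tab <- specificity_scores(pb)
  files["specificity"] <- write_stage_tsv(spec_tab,
                                          file.path(out,
                                                    "specificity.tsv"))

  adj <- soft_adjacency(nm, annotated, beta = cfg$beta)
  tom <- topological_overlap(adj)
  catalog <- cut_modules(1 - tom, heights = cfg$heights,
                         min_module_size = cfg$min_module_size)
  pipeline_log("modules", "%d modules detected", length(catalog$modules))
  if (length(catalog$modules) >= max(2, cfg$k)) {
    catalog <- module_profiles(nm, catalog, seed = cfg$seed)
    catalog <- classify_gradients(catalog, labels,
                                  level = cfg$classify_level, k = cfg$k,
                                  seed = cfg$seed)
    files["module_correlation"] <- write_stage_tsv(
      data.frame(module_id = rownames(module_correlation(catalog)),
                 module_correlation(catalog), check.names = FALSE),
      file.path(out, "module_correlation.tsv"))
    files["gradient_classes"] <- write_stage_tsv(
      data.frame(module_id = names(catalog$gradient_class),
                 gradient_class = unname(catalog$gradient_class),
                 pc1 = unname(catalog$pc1_coordinate),
                 stringsAsFactors = FALSE),
      file.path(out, "gradient_classes.tsv"))
    enr <- hypergeom_enrich(catalog, onto, universe = annotated)
    files["enrichment"] <- write_stage_tsv(enr,
                                           file.path(out,
                                                     "enrichment.tsv"))
  }
  files["modules"] <- write_stage_tsv(
    data.frame(gene_id = names(catalog$assignments),
               module_id = unname(catalog$assignments),
               stringsAsFactors = FALSE),
    file.path(out, "modules.tsv"))

  manifest <- as.list(tools::md5sum(unname(files)))
  names(manifest) <- basename(names(manifest))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  pipeline_log("done", "%d output files; manifest written", length(files))
  invisible(manifest)
}

#' Adjusted Rand index between two labelings
#'
#' Standard permutation-model-corrected agreement between two partitions of
#' the same items; 1 = identical partitions, 0 = chance agreement.
#'
#' @param a,b Label vectors of equal length.
#' @return Numeric ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(length(a))
  expected <- sum_a * sum_b / n
  mx <- (sum_a + sum_b) / 2
  if (mx == expected) return(1)
  (sum_ij - expected) / (mx - expected)
}
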