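# Hypergeometric over-representation of modules in annotated terms.

#' Hypergeometric gene-set enrichment of modules against an ontology
#'
#' One-sided over-representation test per (module, term) pair:
#' `p = P(X >= k)` for `X ~ Hypergeom(N, K, n)` with universe size `N`,
#' term size in the universe `K`, module size `n` and overlap `k`
#' (exact tail via `phyper`). Term member sets are intersected with the
#' universe before testing; terms with `K = 0` are not tested. Bonferroni
#' correction uses the number of tests actually performed, capped at 1.
#'
#' @param catalog A `module_catalog` (or named list of gene-id vectors).
#' @param ontology A `gene_ontology` or named list of term gene sets.
#' @param universe Background gene-id set; must contain every module gene.
#' @return `data.frame` with columns `module_id`, `term_id`, `overlap`,
#'   `module_size`, `term_size`, `universe_size`, `p_value`,
#'   `p_bonferroni`.
#' @examples
#' mods <- list(m1 = c("a", "b", "c"))
#' onto <- list(t1 = c("a", "b", "d"))
#' hypergeom_enrich(mods, onto, universe = letters[1:10])
#' @export
hypergeom_enrich <- function(catalog, ontology, universe) {
  modules <- if (inherits(catalog, "module_catalog")) catalog$modules
             else catalog
  sets <- if (inherits(ontology, "gene_ontology")) ontology$members
          else ontology
  universe <- unique(universe)
  outside <- setdiff(unique(unlist(modules)), universe)
  if (length(outside)) {
    stop("module gene(s) outside the universe (misconfigured background): ",
         paste(utils::head(outside, 5), collapse = ", "), call. = FALSE)
  }
  n_univ <- length(universe)
  rows <- list()
  for (m in names(modules)) {
    mod <- intersect(modules[[m]], universe)
    for (tid in names(sets)) {
      term <- intersect(sets[[tid]], universe)
      if (length(term) == 0) next
      k <- length(intersect(mod, term))
      p <- stats::phyper(k - 1, length(term), n_univ - length(term),
                         length(mod), lower.tail = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        module_id = m, term_id = tid, overlap = k,
        module_size = length(mod), term_size = length(term),
        universe_size = n_univ, p_value = p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$p_value * nrow(out))
  rownames(out) <- NULL
  out
}
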