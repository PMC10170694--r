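# Readers/writers and validation for the matrix, label, gene-list and
# annotation-table formats used by every stage. All text outputs are UTF-8
# TSV with header rows; count matrices use Matrix Market with genes.tsv /
# cells.tsv sidecars (genes as rows on disk, transposed to cells x genes in
# memory).

#' Validate a cells x genes count matrix
#'
#' @param m Matrix-like object (base matrix or `Matrix`), cells in rows.
#' @return The matrix, invisibly, after checking ids and values.
#' @export
validate_counts <- function(m) {
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("count matrix must have cell rownames and gene colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(m))) {
    stop("duplicate cell ids in count matrix", call. = FALSE)
  }
  if (anyDuplicated(colnames(m))) {
    stop("duplicate gene ids in count matrix", call. = FALSE)
  }
  v <- if (inherits(m, "sparseMatrix")) m@x else as.numeric(m)
  if (length(v) && min(v) < 0) {
    stop("count matrix contains negative entries", call. = FALSE)
  }
  if (length(v) && any(v != floor(v))) {
    stop("count matrix contains non-integer entries", call. = FALSE)
  }
  invisible(m)
}

#' Read a count matrix
#'
#' Accepts Matrix Market plus TSV sidecars, or a single dense CSV with cells
#' in rows (first column = cell id, header = gene ids). Sparse input stays
#' sparse.
#'
#' @param path_matrix `.mtx` file (genes as rows) or `.csv` file (cells as
#'   rows).
#' @param path_genes,path_cells One-column TSVs with headers `gene_id` /
#'   `cell_id`; required for MTX input, ignored for CSV.
#' @return Validated cells x genes matrix.
#' @export
read_counts <- function(path_matrix, path_genes = NULL, path_cells = NULL) {
  if (grepl("\\.csv$", path_matrix, ignore.case = TRUE)) {
    df <- utils::read.csv(path_matrix, check.names = FALSE,
                          stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- as.character(df[[1]])
    storage.mode(m) <- "double"
    return(validate_counts(m))
  }
  if (is.null(path_genes) || is.null(path_cells)) {
    stop("MTX input requires gene and cell sidecar files", call. = FALSE)
  }
  mm <- Matrix::readMM(path_matrix)          # genes x cells on disk
  genes <- utils::read.delim(path_genes, stringsAsFactors = FALSE)$gene_id
  cells <- utils::read.delim(path_cells, stringsAsFactors = FALSE)$cell_id
  if (nrow(mm) != length(genes) || ncol(mm) != length(cells)) {
    stop(sprintf(paste0("dimension mismatch: matrix is %d x %d but sidecars ",
                        "list %d genes and %d cells"),
                 nrow(mm), ncol(mm), length(genes), length(cells)),
         call. = FALSE)
  }
  m <- Matrix::t(mm)
  m <- methods::as(methods::as(m, "CsparseMatrix"), "generalMatrix")
  dimnames(m) <- list(cells, genes)
  validate_counts(m)
}

#' Write a count matrix as Matrix Market plus sidecars
#'
#' @param m Validated cells x genes matrix.
#' @param dir Output directory (created if missing). Writes `matrix.mtx`,
#'   `genes.tsv`, `cells.tsv`.
#' @return Invisibly, the paths written.
#' @export
write_counts <- function(m, dir) {
  validate_counts(m)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pm <- file.path(dir, "matrix.mtx")
  Matrix::writeMM(methods::as(Matrix::t(Matrix::Matrix(m, sparse = TRUE)),
                              "CsparseMatrix"), pm)
  pg <- file.path(dir, "genes.tsv")
  pc <- file.path(dir, "cells.tsv")
  utils::write.table(data.frame(gene_id = colnames(m)), pg, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(cell_id = rownames(m)), pc, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(matrix = pm, genes = pg, cells = pc))
}

#' Read / write cell labels
#'
#' Labels are TSV with columns `cell_id`, `cell_class`, `cell_type`,
#' `category`. Each cell type must map to exactly one class and each class
#' to exactly one category.
#'
#' @param path TSV path.
#' @return `data.frame` of labels.
#' @export
read_labels <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_labels(df)
}

#' @rdname read_labels
#' @param labels Labels `data.frame`.
#' @export
write_labels <- function(labels, path) {
  validate_labels(labels)
  utils::write.table(labels, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

validate_labels <- function(labels) {
  needed <- c("cell_id", "cell_class", "cell_type", "category")
  if (!all(needed %in% names(labels))) {
    stop("labels must have columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(labels$cell_id)) {
    stop("duplicate cell ids in labels", call. = FALSE)
  }
  t2c <- unique(labels[, c("cell_type", "cell_class")])
  if (anyDuplicated(t2c$cell_type)) {
    stop("a cell type maps to more than one cell class", call. = FALSE)
  }
  c2g <- unique(labels[, c("cell_class", "category")])
  if (anyDuplicated(c2g$cell_class)) {
    stop("a cell class maps to more than one category", call. = FALSE)
  }
  labels
}

#' Keep only cells belonging to given categories
#'
#' Mirrors the study design of restricting the analysis to neuronal
#' categories (e.g. GABAergic and glutamatergic cells) before any other
#' processing. Cell order is preserved; genes are untouched.
#'
#' @param m Cells x genes count matrix.
#' @param labels Labels covering all cells of `m`.
#' @param keep Non-empty character vector of categories to retain.
#' @return List with the filtered `counts` and `labels`.
#' @export
filter_cells_by_category <- function(m, labels, keep) {
  if (length(keep) == 0) stop("'keep' must not be empty", call. = FALSE)
  labels <- validate_labels(labels)
  if (!all(rownames(m) %in% labels$cell_id)) {
    stop("labels do not cover all cells in the matrix", call. = FALSE)
  }
  unknown <- setdiff(keep, unique(labels$category))
  if (length(unknown)) {
    warning("unknown categories ignored: ", paste(unknown, collapse = ", "))
  }
  labels <- labels[match(rownames(m), labels$cell_id), , drop = FALSE]
  sel <- labels$category %in% keep
  list(counts = m[sel, , drop = FALSE],
       labels = labels[sel, , drop = FALSE])
}

#' Subset a count matrix to a gene set
#'
#' Retains the intersection of the matrix genes and the requested set,
#' preserving matrix gene order. The number of requested genes absent from
#' the matrix is recorded in attribute `n_missing`.
#'
#' @param m Cells x genes matrix.
#' @param genes Character vector of gene ids.
#' @return Subset matrix; errors if the intersection is empty.
#' @export
subset_genes <- function(m, genes) {
  sel <- colnames(m) %in% genes
  if (!any(sel)) stop("no requested genes are present in the matrix",
                      call. = FALSE)
  out <- m[, sel, drop = FALSE]
  attr(out, "n_missing") <- length(setdiff(genes, colnames(m)))
  out
}

#' Construct a hierarchical gene-set annotation table
#'
#' @param terms `data.frame` with columns `term_id`, `term_name`, `domain`
#'   (`"BP"`, `"CC"` or NA for internal hierarchy nodes), `parent_id`
#'   (NA for roots). Parent links must form a forest.
#' @param members Named list mapping term ids to non-empty gene-id vectors;
#'   internal hierarchy nodes carry no entry.
#' @return Object of class `gene_ontology`.
#' @export
ontology_table <- function(terms, members) {
  stopifnot(is.data.frame(terms), is.list(members))
  needed <- c("term_id", "term_name", "domain", "parent_id")
  if (!all(needed %in% names(terms))) {
    stop("ontology terms need columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(terms$term_id)) {
    stop("duplicate term ids in ontology", call. = FALSE)
  }
  bad_parent <- setdiff(stats::na.omit(terms$parent_id), terms$term_id)
  if (length(bad_parent)) {
    stop("unknown parent ids: ", paste(bad_parent, collapse = ", "),
         call. = FALSE)
  }
  unknown_terms <- setdiff(names(members), terms$term_id)
  if (length(unknown_terms)) {
    stop("membership rows reference unknown term ids: ",
         paste(unknown_terms, collapse = ", "), call. = FALSE)
  }
  if (any(vapply(members, length, integer(1)) == 0)) {
    stop("every annotated term must have a non-empty member set",
         call. = FALSE)
  }
  # cycle check: walk each term to a root, bounded by the number of terms
  parent <- stats::setNames(terms$parent_id, terms$term_id)
  for (id in terms$term_id) {
    cur <- id
    for (step in seq_len(nrow(terms) + 1L)) {
      cur <- parent[[cur]]
      if (is.na(cur)) break
      if (cur == id || step > nrow(terms)) {
        stop("cyclic parent links in ontology at term '", id, "'",
             call. = FALSE)
      }
    }
  }
  structure(list(terms = terms, members = members), class = "gene_ontology")
}

#' @export
print.gene_ontology <- function(x, ...) {
  cat(sprintf("gene_ontology: %d terms (%d annotated), %d member genes\n",
              nrow(x$terms), length(x$members),
              length(unique(unlist(x$members)))))
  invisible(x)
}

#' Genes annotated anywhere in an ontology
#' @param ontology A `gene_ontology`.
#' @return Character vector of unique gene ids.
#' @export
ontology_genes <- function(ontology) {
  sort(unique(unlist(ontology$members, use.names = FALSE)))
}

#' Read / write an annotation table
#'
#' On-disk format: TSV with columns `term_id`, `term_name`, `domain`,
#' `parent_id`, `gene_id` — one row per term-gene membership; internal
#' hierarchy nodes appear once with an empty `gene_id`.
#'
#' @param path TSV path.
#' @return A `gene_ontology`.
#' @export
read_ontology <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  terms <- unique(df[, c("term_id", "term_name", "domain", "parent_id")])
  with_gene <- df[!is.na(df$gene_id), , drop = FALSE]
  members <- split(with_gene$gene_id, with_gene$term_id)
  # keep the original term order
  terms <- terms[order(match(terms$term_id, df$term_id)), , drop = FALSE]
  rownames(terms) <- NULL
  members <- members[intersect(terms$term_id, names(members))]
  ontology_table(terms, members)
}

#' @rdname read_ontology
#' @param ontology A `gene_ontology`.
#' @export
write_ontology <- function(ontology, path) {
  stopifnot(inherits(ontology, "gene_ontology"))
  rows <- lapply(seq_len(nrow(ontology$terms)), function(i) {
    t <- ontology$terms[i, ]
    memb <- ontology$members[[t$term_id]]
    if (is.null(memb)) memb <- NA_character_
    data.frame(term_id = t$term_id, term_name = t$term_name,
               domain = t$domain, parent_id = t$parent_id, gene_id = memb,
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a plain gene list (one id per line)
#' @param path Text file path.
#' @return Character vector of unique gene ids.
#' @export
read_gene_list <- function(path) {
  x <- readLines(path, encoding = "UTF-8")
  unique(trimws(x[nzchar(trimws(x))]))
}
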