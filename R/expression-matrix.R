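#' Construct an expression matrix container
#'
#' A light wrapper around a cells x genes matrix (dense or `Matrix` sparse)
#' carrying cell and gene identifiers, a per-gene observed mask, and a flag
#' recording whether values are raw counts or log-normalized expression.
#'
#' The observed mask distinguishes "gene not measured in this dataset" from
#' "gene measured at zero": columns with `observed_mask = FALSE` hold
#' placeholder zeros in storage but are materialized as missing values when a
#' model consumes them, so the tree learner routes them through its native
#' missing-value paths instead of treating them as absence of expression.
#'
#' @param values cells x genes numeric matrix or `Matrix::Matrix`.
#' @param cell_ids character vector of unique cell identifiers (rows).
#' @param gene_ids character vector of unique gene identifiers (columns).
#' @param normalized logical; `TRUE` if values are log-normalized expression,
#'   `FALSE` if raw counts.
#' @param observed_mask logical vector, one per gene; `FALSE` marks genes
#'   absent from the source data.
#' @return an object of class `expr_matrix`.
#' @export
expression_matrix <- function(values, cell_ids = rownames(values),
                              gene_ids = colnames(values),
                              normalized = FALSE,
                              observed_mask = rep(TRUE, length(gene_ids))) {
  cell_ids <- as.character(cell_ids)
  gene_ids <- as.character(gene_ids)
  if (nrow(values) != length(cell_ids) || ncol(values) != length(gene_ids)) {
    stop("dimension mismatch: values is ", nrow(values), "x", ncol(values),
         " but there are ", length(cell_ids), " cell ids and ",
         length(gene_ids), " gene ids", call. = FALSE)
  }
  if (anyDuplicated(cell_ids)) {
    stop("duplicate cell ids: ",
         paste(unique(cell_ids[duplicated(cell_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene ids: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (length(observed_mask) != length(gene_ids)) {
    stop("observed_mask length must equal the number of genes", call. = FALSE)
  }
  vals <- if (inherits(values, "Matrix")) values else as.matrix(values)
  obs_vals <- if (all(observed_mask)) vals else vals[, observed_mask, drop = FALSE]
  if (length(obs_vals) > 0) {
    rng <- suppressWarnings(range(obs_vals, na.rm = FALSE))
    if (anyNA(rng) || !all(is.finite(rng)) || rng[1] < 0) {
      stop("observed expression values must be finite and >= 0", call. = FALSE)
    }
  }
  dimnames(vals) <- list(cell_ids, gene_ids)
  structure(
    list(values = vals, cell_ids = cell_ids, gene_ids = gene_ids,
         normalized = isTRUE(normalized),
         observed_mask = as.logical(observed_mask)),
    class = "expr_matrix"
  )
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d cells x %d genes (%s, %d genes observed)\n",
              length(x$cell_ids), length(x$gene_ids),
              if (x$normalized) "log-normalized" else "raw counts",
              sum(x$observed_mask)))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) c(length(x$cell_ids), length(x$gene_ids))

# Dense numeric matrix with unobserved genes materialized as NA.
# This is the representation handed to the gradient-boosted learner.
em_dense <- function(em) {
  m <- as.matrix(em$values)
  storage.mode(m) <- "double"
  if (!all(em$observed_mask)) m[, !em$observed_mask] <- NA_real_
  m
}

#' Subset an expression matrix by cells
#'
#' @param em an [expression_matrix()].
#' @param idx integer, logical or character (cell id) row index.
#' @return an [expression_matrix()] with the selected cells, preserving the
#'   gene set, observed mask and normalization flag.
#' @export
subset_cells <- function(em, idx) {
  stopifnot(inherits(em, "expr_matrix"))
  if (is.character(idx)) idx <- match(idx, em$cell_ids)
  expression_matrix(em$values[idx, , drop = FALSE],
                    cell_ids = em$cell_ids[idx], gene_ids = em$gene_ids,
                    normalized = em$normalized,
                    observed_mask = em$observed_mask)
}

# internal alias used throughout
em_subset_cells <- function(em, idx) subset_cells(em, idx)
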