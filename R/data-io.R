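#' Read an expression matrix from disk
#'
#' Two dialects are supported. `"csv"`: cells in rows, first column cell ids,
#' header row of gene ids. `"mtx"`: a MatrixMarket triplet file with
#' `genes.tsv` and `barcodes.tsv` sidecars in the same directory (first
#' column of each is used); both genes-as-rows and cells-as-rows orientations
#' are accepted and resolved by matching sidecar lengths against the matrix
#' dimensions.
#'
#' Whether the values are raw counts or already log-normalized cannot be
#' inferred from the file, so the caller states it via `normalized` and the
#' flag is carried on the returned object.
#'
#' @param path file path (for mtx, the `.mtx` file).
#' @param format `"csv"` or `"mtx"`.
#' @param normalized logical; `TRUE` if the file holds log-normalized values.
#' @return an [expression_matrix()].
#' @export
read_expression <- function(path, format = c("csv", "mtx"), normalized = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "csv") {
    dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
    cell_ids <- as.character(dt[[1]])
    vals <- as.matrix(dt[, -1, drop = FALSE])
    storage.mode(vals) <- "double"
    return(expression_matrix(vals, cell_ids = cell_ids,
                             gene_ids = colnames(dt)[-1],
                             normalized = normalized))
  }
  m <- Matrix::readMM(path)
  dir <- dirname(path)
  genes_f <- file.path(dir, "genes.tsv")
  cells_f <- file.path(dir, "barcodes.tsv")
  for (f in c(genes_f, cells_f)) {
    if (!file.exists(f)) stop("missing mtx sidecar file: ", f, call. = FALSE)
  }
  genes <- data.table::fread(genes_f, header = FALSE, data.table = FALSE)[[1]]
  cells <- data.table::fread(cells_f, header = FALSE, data.table = FALSE)[[1]]
  if (nrow(m) == length(genes) && ncol(m) == length(cells)) {
    m <- Matrix::t(m)  # genes-as-rows dialect
  } else if (!(nrow(m) == length(cells) && ncol(m) == length(genes))) {
    stop("mtx dimensions ", nrow(m), "x", ncol(m),
         " match neither orientation of sidecars (", length(cells),
         " barcodes, ", length(genes), " genes)", call. = FALSE)
  }
  expression_matrix(methods::as(m, "CsparseMatrix"),
                    cell_ids = as.character(cells),
                    gene_ids = as.character(genes), normalized = normalized)
}

#' Write an expression matrix
#'
#' Inverse of [read_expression()]: `"csv"` writes the dense cells x genes
#' table; `"mtx"` writes a genes-as-rows MatrixMarket triplet plus
#' `genes.tsv`/`barcodes.tsv` sidecars next to it.
#'
#' @param em an [expression_matrix()].
#' @param path output path (for mtx, the `.mtx` file).
#' @param format `"csv"` or `"mtx"`.
#' @return `path`, invisibly.
#' @export
write_expression <- function(em, path, format = c("csv", "mtx")) {
  format <- match.arg(format)
  stopifnot(inherits(em, "expr_matrix"))
  if (format == "csv") {
    df <- data.frame(cell_id = em$cell_ids, as.matrix(em$values),
                     check.names = FALSE)
    data.table::fwrite(df, path)
  } else {
    Matrix::writeMM(methods::as(Matrix::t(Matrix::Matrix(em$values, sparse = TRUE)),
                                "generalMatrix"), path)
    writeLines(em$gene_ids, file.path(dirname(path), "genes.tsv"))
    writeLines(em$cell_ids, file.path(dirname(path), "barcodes.tsv"))
  }
  invisible(path)
}

#' Log-normalize raw counts (log CP10K)
#'
#' Each gene's count is divided by the cell's total count, scaled to 10,000,
#' and natural-log transformed with a pseudocount of one:
#' `value = ln(1 + 10000 * count / total)`. Zero counts map to zero, so
#' sparsity is preserved; within-cell rank order of genes is preserved.
#'
#' @param em an [expression_matrix()] of raw counts.
#' @param scale_factor per-cell total after scaling; 10,000 is the
#'   conventional value.
#' @return an [expression_matrix()] flagged `normalized = TRUE`.
#' @export
normalize_counts <- function(em, scale_factor = 1e4) {
  stopifnot(inherits(em, "expr_matrix"))
  if (em$normalized) stop("matrix is already log-normalized", call. = FALSE)
  totals <- Matrix::rowSums(em$values)
  if (any(totals <= 0)) {
    stop("cell(s) with zero total counts: ",
         paste(head(em$cell_ids[totals <= 0], 5), collapse = ", "),
         call. = FALSE)
  }
  vals <- em$values
  if (inherits(vals, "CsparseMatrix")) {
    scaled <- Matrix::Diagonal(x = scale_factor / totals) %*% vals
    scaled <- methods::as(scaled, "CsparseMatrix")
    scaled@x <- log1p(scaled@x)
    vals <- scaled
  } else {
    vals <- log1p(as.matrix(vals) * (scale_factor / totals))
  }
  expression_matrix(vals, cell_ids = em$cell_ids, gene_ids = em$gene_ids,
                    normalized = TRUE, observed_mask = em$observed_mask)
}

#' Align query genes to a trained feature space
#'
#' Reorders the query's columns to match `feature_list` exactly. Features the
#' query does not measure are retained as columns but marked unobserved in
#' the mask (they become missing values for the model, never zeros);
#' query-only genes are dropped.
#'
#' @param query an [expression_matrix()].
#' @param feature_list ordered character vector of training gene ids.
#' @param case_insensitive match gene ids ignoring case.
#' @param warn_fraction emit a warning when the fraction of training features
#'   found in the query falls below this value.
#' @return an [expression_matrix()] whose `gene_ids` equal `feature_list`.
#' @export
align_genes <- function(query, feature_list, case_insensitive = FALSE,
                        warn_fraction = 0.5) {
  stopifnot(inherits(query, "expr_matrix"))
  feature_list <- as.character(feature_list)
  qg <- if (case_insensitive) toupper(query$gene_ids) else query$gene_ids
  fg <- if (case_insensitive) toupper(feature_list) else feature_list
  idx <- match(fg, qg)
  n_hit <- sum(!is.na(idx))
  if (n_hit == 0) {
    stop("no overlap between query genes and the ", length(feature_list),
         " training features (0 shared genes)", call. = FALSE)
  }
  frac <- n_hit / length(feature_list)
  if (frac < warn_fraction) {
    warning(sprintf("only %d/%d (%.1f%%) training features found in query",
                    n_hit, length(feature_list), 100 * frac), call. = FALSE)
  }
  n_cells <- length(query$cell_ids)
  vals <- matrix(0, n_cells, length(feature_list))
  obs <- !is.na(idx) & query$observed_mask[ifelse(is.na(idx), 1L, idx)]
  if (any(obs)) vals[, obs] <- as.matrix(query$values[, idx[obs], drop = FALSE])
  cc_msg(sprintf("align_genes: %d/%d features observed, %d query-only genes dropped",
                 sum(obs), length(feature_list), length(qg) - n_hit))
  expression_matrix(vals, cell_ids = query$cell_ids, gene_ids = feature_list,
                    normalized = query$normalized, observed_mask = obs)
}

#' Map query genes to orthologs of the training species
#'
#' Renames source genes to their targets using a user-supplied two-column
#' table (no network lookups). When several source genes map to one target,
#' the collision is resolved by `collapse_rule`; query genes without a map
#' entry are dropped and counted.
#'
#' @param query an [expression_matrix()].
#' @param map data.frame with columns `source` and `target` (or a two-column
#'   table taken in that order), or a path to a two-column TSV.
#' @param collapse_rule `"mean"`, `"max"` or `"first"` for many-to-one
#'   collisions (applied to the stored values, e.g. log-normalized expression).
#' @return an [expression_matrix()] on the target gene namespace.
#' @export
map_orthologs <- function(query, map, collapse_rule = c("mean", "max", "first")) {
  collapse_rule <- match.arg(collapse_rule)
  stopifnot(inherits(query, "expr_matrix"))
  if (is.character(map) && length(map) == 1) {
    map <- data.table::fread(map, header = FALSE, data.table = FALSE,
                             col.names = c("source", "target"))
  }
  map <- as.data.frame(map)
  if (ncol(map) < 2 || nrow(map) == 0) {
    stop("ortholog map must be a non-empty two-column table", call. = FALSE)
  }
  names(map)[1:2] <- c("source", "target")
  map <- map[map$source %in% query$gene_ids, , drop = FALSE]
  # one source gene contributes to at most one target
  map <- map[!duplicated(map$source), , drop = FALSE]
  if (nrow(map) == 0) {
    stop("ortholog map shares no source genes with the query", call. = FALSE)
  }
  n_unmapped <- length(setdiff(query$gene_ids, map$source))
  cc_msg(sprintf("map_orthologs: %d genes mapped, %d unmapped genes dropped",
                 nrow(map), n_unmapped))
  vals <- as.matrix(query$values[, map$source, drop = FALSE])
  targets <- sort(unique(map$target))
  out <- matrix(0, nrow(vals), length(targets),
                dimnames = list(query$cell_ids, targets))
  for (tg in targets) {
    cols <- which(map$target == tg)
    out[, tg] <- if (length(cols) == 1) {
      vals[, cols]
    } else {
      switch(collapse_rule,
             mean  = rowMeans(vals[, cols, drop = FALSE]),
             max   = apply(vals[, cols, drop = FALSE], 1, max),
             first = vals[, cols[1]])
    }
  }
  expression_matrix(out, cell_ids = query$cell_ids, gene_ids = targets,
                    normalized = query$normalized)
}
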