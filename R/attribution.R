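#' Per-gene Shapley attributions for one layer's classifier
#'
#' Computes exact tree-path Shapley values (TreeSHAP) for a sample of cells:
#' for each cell and class, a signed per-gene contribution to the model's
#' margin (pre-softmax) score, plus a base value. By the efficiency property
#' the contributions and base value sum to the margin exactly. Genes the
#' sample never measured (unobserved in its mask) receive zero attribution:
#' their default-path contribution is folded into the base value, so
#' unmeasured genes cannot enter marker rankings.
#'
#' For layers below the root, pass the layer's own branch cells as
#' `X_sample`: rankings summed over out-of-branch cells are dominated by the
#' evidence of *absent* sibling markers rather than the class's own markers.
#'
#' @param lo a `layer_object`.
#' @param X_sample an [expression_matrix()] aligned to `lo$feature_list`.
#' @param max_cells cap on the number of cells attributed; when the sample is
#'   larger, a seeded random subsample of this size is used (default 2000).
#' @param seed integer seed for the subsample.
#' @return an `attribution` object: `values` is a cells x classes x genes
#'   array, `base` a cells x classes matrix of base values.
#' @export
attribute_layer <- function(lo, X_sample, max_cells = 2000, seed = 1) {
  stopifnot(inherits(lo, "layer_object"), inherits(X_sample, "expr_matrix"))
  if (!identical(X_sample$gene_ids, lo$feature_list)) {
    stop("sample gene order does not match the layer's feature list; ",
         "run align_genes(query, lo$feature_list) first", call. = FALSE)
  }
  labels <- names(lo$label_codes)[order(lo$label_codes)]
  if (is_constant_layer(lo)) {
    message("layer node ", lo$node$id,
            " is a constant single-class predictor; no attributions to compute")
    return(structure(
      list(values = array(0, dim = c(0, 1, length(lo$feature_list)),
                          dimnames = list(NULL, labels, lo$feature_list)),
           base = matrix(0, 0, 1, dimnames = list(NULL, labels)),
           class_labels = labels, gene_ids = lo$feature_list,
           cell_ids = character(), layer_name = lo$node$layer_name,
           node_id = lo$node$id),
      class = "attribution"))
  }
  n <- length(X_sample$cell_ids)
  if (n > max_cells) {
    set.seed(seed)
    X_sample <- em_subset_cells(X_sample, sort(sample.int(n, max_cells)))
  }
  Xd <- em_dense(X_sample)
  contrib <- predict(lo$model,
                     xgboost::xgb.DMatrix(Xd, missing = NA, nthread = 1),
                     predcontrib = TRUE)
  # contrib: cells x classes x (features + BIAS)
  n_feat <- length(lo$feature_list)
  values <- contrib[, , seq_len(n_feat), drop = FALSE]
  base <- contrib[, , n_feat + 1L]
  if (is.null(dim(base))) base <- matrix(base, ncol = length(labels))
  # genes the query never measured carry no evidence about the cell: their
  # default-path contribution is folded into the base value so unmeasured
  # genes get zero attribution while efficiency still holds
  if (!all(X_sample$observed_mask)) {
    miss <- which(!X_sample$observed_mask)
    base <- base + apply(values[, , miss, drop = FALSE], c(1, 2), sum)
    values[, , miss] <- 0
  }
  dimnames(values) <- list(X_sample$cell_ids, labels, lo$feature_list)
  dimnames(base) <- list(X_sample$cell_ids, labels)
  structure(
    list(values = values, base = base, class_labels = labels,
         gene_ids = lo$feature_list, cell_ids = X_sample$cell_ids,
         layer_name = lo$node$layer_name, node_id = lo$node$id),
    class = "attribution")
}

#' @export
print.attribution <- function(x, ...) {
  cat(sprintf("<attribution> %s: %d cells x %d classes x %d genes\n",
              x$node_id, length(x$cell_ids), length(x$class_labels),
              length(x$gene_ids)))
  invisible(x)
}

#' Rank positive and negative predictor genes per class
#'
#' Scores each gene for each class by the sum of its Shapley attributions
#' over the sampled cells (`score = "mean"` divides by the cell count), then
#' reports the `n_top` genes with the largest positive scores and the `n_top`
#' with the most negative scores per class.
#'
#' @param att an `attribution` from [attribute_layer()].
#' @param n_top number of genes per direction per class (default 10).
#' @param score `"sum"` (default) or `"mean"` over sampled cells.
#' @return a `feature_ranking` data.frame with columns `layer_name`, `class`,
#'   `direction` (`"positive"`/`"negative"`), `rank`, `gene`, `score`.
#' @export
rank_features <- function(att, n_top = 10, score = c("sum", "mean")) {
  score <- match.arg(score)
  stopifnot(inherits(att, "attribution"))
  if (n_top < 0) stop("n_top must be >= 0", call. = FALSE)
  rows <- list()
  for (cl in att$class_labels) {
    g_scores <- if (length(att$cell_ids) == 0) {
      setNames(numeric(length(att$gene_ids)), att$gene_ids)
    } else {
      s <- colSums(matrix(att$values[, cl, ], ncol = length(att$gene_ids),
                          dimnames = list(NULL, att$gene_ids)))
      if (score == "mean") s / length(att$cell_ids) else s
    }
    pos <- sort(g_scores[g_scores > 0], decreasing = TRUE)
    neg <- sort(g_scores[g_scores < 0], decreasing = FALSE)
    pos <- head(pos, n_top)
    neg <- head(neg, n_top)
    if (length(pos) > 0) {
      rows[[length(rows) + 1L]] <- data.frame(
        layer_name = att$layer_name, class = cl, direction = "positive",
        rank = seq_along(pos), gene = names(pos), score = unname(pos),
        stringsAsFactors = FALSE)
    }
    if (length(neg) > 0) {
      rows[[length(rows) + 1L]] <- data.frame(
        layer_name = att$layer_name, class = cl, direction = "negative",
        rank = seq_along(neg), gene = names(neg), score = unname(neg),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows) == 0) {
    data.frame(layer_name = character(), class = character(),
               direction = character(), rank = integer(),
               gene = character(), score = numeric(),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, rows)
  }
  class(out) <- c("feature_ranking", class(out))
  out
}

#' Write per-layer feature rankings to CSV
#'
#' @param fr a `feature_ranking` from [rank_features()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_ranking <- function(fr, path) {
  data.table::fwrite(as.data.frame(fr), path)
  invisible(path)
}
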