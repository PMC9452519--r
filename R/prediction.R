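new_prediction_result <- function(cell_ids, layer_names, threshold) {
  n <- length(cell_ids)
  layers <- setNames(lapply(layer_names, function(l) {
    list(label = rep(NA_character_, n),
         max_prob = rep(NA_real_, n),
         node_id = rep(NA_character_, n),
         timepoint_used = rep(NA_character_, n))
  }), layer_names)
  structure(list(cell_ids = cell_ids, layers = layers, probs = list(),
                 threshold = threshold),
            class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf("<prediction_result> %d cells, %d layer(s), threshold %s\n",
              length(x$cell_ids), length(x$layers),
              paste(format(x$threshold), collapse = "/")))
  for (ln in names(x$layers)) {
    lab <- x$layers[[ln]]$label
    cat(sprintf("  %s: %d assigned, %d unclassified, %d not evaluated\n",
                ln, sum(!is.na(lab) & lab != UNCLASSIFIED),
                sum(!is.na(lab) & lab == UNCLASSIFIED), sum(is.na(lab))))
  }
  invisible(x)
}

#' Flatten a prediction result to a wide data.frame
#'
#' One row per cell; per layer, a `<layer>_label` column (`"Unclassified"`
#' for rejected cells, `NA` for cells the cascade never routed there) and a
#' `<layer>_prob` column with the maximum class probability.
#'
#' @param x a `prediction_result`.
#' @param ... unused.
#' @return a data.frame.
#' @export
as.data.frame.prediction_result <- function(x, ...) {
  out <- data.frame(cell_id = x$cell_ids, stringsAsFactors = FALSE)
  for (ln in names(x$layers)) {
    out[[paste0(ln, "_label")]] <- x$layers[[ln]]$label
    out[[paste0(ln, "_prob")]] <- x$layers[[ln]]$max_prob
  }
  out
}

# Probability matrix for one layer object on aligned data, columns in
# lexicographic label order (the label-code order).
layer_prob_matrix <- function(lo, X_aligned) {
  labels <- names(lo$label_codes)[order(lo$label_codes)]
  if (is_constant_layer(lo)) {
    probs <- matrix(1, length(X_aligned$cell_ids), 1)
  } else {
    probs <- booster_probs(lo$model, em_dense(X_aligned))
  }
  dimnames(probs) <- list(X_aligned$cell_ids, labels)
  probs
}

#' Predict a single hierarchy layer with the rejection option
#'
#' Scores every supplied cell with one layer object. The argmax class is
#' assigned when its probability reaches `threshold`, otherwise the cell is
#' reported `"Unclassified"`; ties at the maximum break lexicographically.
#' The query must already be aligned to the layer's feature list (see
#' [align_genes()]); a mismatched gene order is an error, never silently
#' reordered.
#'
#' @param lo a `layer_object`.
#' @param X_aligned an [expression_matrix()] with `gene_ids` identical to
#'   `lo$feature_list`.
#' @param threshold rejection threshold in `[0, 1]` (default 0.5); a cell is
#'   `"Unclassified"` iff its maximum class probability is strictly below it.
#' @return a `prediction_result` covering this one layer.
#' @export
predict_layer <- function(lo, X_aligned, threshold = 0.5) {
  stopifnot(inherits(lo, "layer_object"), inherits(X_aligned, "expr_matrix"))
  if (!identical(X_aligned$gene_ids, lo$feature_list)) {
    stop("query gene order does not match the layer's feature list; ",
         "run align_genes(query, lo$feature_list) first", call. = FALSE)
  }
  probs <- layer_prob_matrix(lo, X_aligned)
  top <- max.col(probs, ties.method = "first")
  max_prob <- probs[cbind(seq_len(nrow(probs)), top)]
  label <- colnames(probs)[top]
  label[max_prob < threshold] <- UNCLASSIFIED
  res <- new_prediction_result(X_aligned$cell_ids, lo$node$layer_name, threshold)
  res$layers[[lo$node$layer_name]] <- list(
    label = label, max_prob = max_prob,
    node_id = rep(lo$node$id, length(label)),
    timepoint_used = rep(lo$node$timepoint_context, length(label)))
  res$probs[[lo$node$id]] <- probs
  res
}

find_parent_node_id <- function(h, node) {
  if (nrow(node$parent_path) == 0) return(NULL)
  k <- nrow(node$parent_path)
  want_layer <- node$parent_path$layer[k]
  want_labels <- node$parent_path$label[-k]
  cand <- Filter(function(n) {
    n$layer_name == want_layer &&
      identical(n$parent_path$label, want_labels) &&
      (is.na(n$timepoint_context) ||
         identical(n$timepoint_context, node$timepoint_context))
  }, h$nodes)
  if (length(cand) == 0) return(NULL)
  # prefer the parent sharing the timepoint context over an unpartitioned one
  tps <- vapply(cand, `[[`, "", "timepoint_context")
  hit <- which(!is.na(tps) & tps == node$timepoint_context)
  if (length(hit) > 0) cand[[hit[1]]]$id else cand[[1]]$id
}

#' Cascade query cells down the annotation hierarchy
#'
#' The root layer scores every cell; each deeper layer object scores only the
#' cells whose parent-layer assignment equals its parent class and — for
#' timepoint-partitioned layers — whose timepoint matches its context. Cells
#' rejected at a layer are `"Unclassified"` there and are not routed deeper
#' (they stay `NA`, "not evaluated", below). Timepoint routing uses
#' `query_timepoints` when supplied; without it, partitioned branches are
#' skipped with a warning.
#'
#' @param bundle a `model_bundle`.
#' @param X an [expression_matrix()] of log-normalized query values (any gene
#'   set; genes are aligned to each layer's feature list internally).
#' @param query_timepoints optional character vector of per-cell timepoints,
#'   same order as `X`'s cells.
#' @param threshold rejection threshold; either a single value for all layers
#'   or a named vector of per-layer overrides (names = layer names) with an
#'   optional unnamed/`"default"` entry. Defaults to the bundle's stored
#'   value.
#' @return a `prediction_result` spanning all reached layers.
#' @export
predict_cascade <- function(bundle, X, query_timepoints = NULL,
                            threshold = NULL) {
  stopifnot(inherits(bundle, "model_bundle"), inherits(X, "expr_matrix"))
  h <- bundle$hierarchy
  threshold <- threshold %||% bundle$rejection_threshold_default
  thr_for <- function(layer_name) {
    if (is.null(names(threshold))) return(threshold[1])
    if (layer_name %in% names(threshold)) return(threshold[[layer_name]])
    if ("default" %in% names(threshold)) return(threshold[["default"]])
    stop("no threshold given for layer ", layer_name, call. = FALSE)
  }
  n <- length(X$cell_ids)
  if (!is.null(query_timepoints)) {
    query_timepoints <- as.character(query_timepoints)
    stopifnot(length(query_timepoints) == n)
    known <- hierarchy_timepoints(h)
    unknown <- setdiff(unique(query_timepoints), known)
    if (h$has_timepoints && length(unknown) > 0) {
      warning("query timepoint(s) absent from the hierarchy, affected branch ",
              "predictions skipped: ", paste(unknown, collapse = ", "),
              call. = FALSE)
    }
  }
  nodes <- layers_in_training_order(h)
  res <- new_prediction_result(X$cell_ids, h$layer_names, threshold)
  # cache one gene alignment per distinct feature list (usually all layers
  # share one list, since training uses the full gene set)
  aligned_cache <- list()
  aligned_for <- function(feature_list) {
    for (entry in aligned_cache) {
      if (identical(entry$features, feature_list)) return(entry$aligned)
    }
    aligned <- align_genes(X, feature_list)
    aligned_cache[[length(aligned_cache) + 1L]] <<-
      list(features = feature_list, aligned = aligned)
    aligned
  }
  node_assign <- list()
  evaluated_any <- FALSE
  for (node in nodes) {
    lo <- bundle$layer_objects[[node$id]]
    if (is.null(lo)) next
    if (nrow(node$parent_path) == 0) {
      idx <- seq_len(n)
    } else {
      pid <- find_parent_node_id(h, node)
      pa <- if (is.null(pid)) NULL else node_assign[[pid]]
      if (is.null(pa)) next  # parent branch was skipped
      last_lab <- node$parent_path$label[nrow(node$parent_path)]
      idx <- pa$idx[pa$label == last_lab]
      parent_node <- h$nodes[[pid]]
      introduces_tp <- node$is_timepoint_partition &&
        is.na(parent_node$timepoint_context)
      if (introduces_tp) {
        if (is.null(query_timepoints)) {
          warning("no query timepoints supplied; skipping timepoint-",
                  "partitioned layer node ", node$id, call. = FALSE)
          next
        }
        idx <- idx[query_timepoints[idx] == node$timepoint_context]
      }
    }
    if (length(idx) == 0) {
      node_assign[[node$id]] <- list(idx = integer(), label = character())
      next
    }
    Xa <- em_subset_cells(aligned_for(lo$feature_list), idx)
    one <- predict_layer(lo, Xa, thr_for(node$layer_name))
    lr <- one$layers[[node$layer_name]]
    res$layers[[node$layer_name]]$label[idx] <- lr$label
    res$layers[[node$layer_name]]$max_prob[idx] <- lr$max_prob
    res$layers[[node$layer_name]]$node_id[idx] <- node$id
    if (node$is_timepoint_partition) {
      res$layers[[node$layer_name]]$timepoint_used[idx] <- node$timepoint_context
    }
    res$probs[[node$id]] <- one$probs[[node$id]]
    node_assign[[node$id]] <- list(idx = idx, label = lr$label)
    evaluated_any <- TRUE
    cc_msg(sprintf("%s: %d cells, %d assigned, %d unclassified", node$id,
                   length(idx), sum(lr$label != UNCLASSIFIED),
                   sum(lr$label == UNCLASSIFIED)))
  }
  if (!evaluated_any) stop("no layers reachable for this query", call. = FALSE)
  res
}

#' Write a prediction result to CSV
#'
#' One row per cell: cell id, then per layer its assigned label
#' (`"Unclassified"` for rejected cells, empty for layers the cell never
#' reached) and the maximum class probability. Full per-class probability
#' vectors go to an optional long-format sidecar CSV.
#'
#' @param r a `prediction_result`.
#' @param path output CSV path.
#' @param probs_path optional sidecar CSV path for full probability vectors.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(r, path, probs_path = NULL) {
  stopifnot(inherits(r, "prediction_result"))
  df <- as.data.frame(r)
  data.table::fwrite(df, path, na = "")
  if (!is.null(probs_path)) {
    long <- do.call(rbind, lapply(names(r$probs), function(nid) {
      p <- r$probs[[nid]]
      data.frame(node_id = nid,
                 cell_id = rep(rownames(p), ncol(p)),
                 class = rep(colnames(p), each = nrow(p)),
                 prob = as.vector(p), stringsAsFactors = FALSE)
    }))
    data.table::fwrite(long, probs_path)
  }
  invisible(path)
}
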