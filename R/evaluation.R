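#' Stratified hold-out split
#'
#' Splits cells into a training partition and a held-out partition by
#' per-class random sampling: each class contributes `round(fraction * n)`
#' cells to the hold-out (never all of its cells), so the held-out fraction
#' per class is within one cell of the target. The default mirrors the
#' conventional 90/10 design.
#'
#' @param labels character vector of per-cell class labels.
#' @param fraction held-out fraction (default 0.10).
#' @param seed integer seed; identical seeds give identical splits.
#' @return list with integer index vectors `train_idx` and `holdout_idx`.
#' @export
holdout_split <- function(labels, fraction = 0.10, seed = 1) {
  labels <- as.character(labels)
  stopifnot(length(labels) > 0, fraction > 0, fraction < 1)
  tab <- table(labels)
  if (any(tab < 2)) {
    stop("class(es) with a single cell cannot be split: ",
         paste(names(tab)[tab < 2], collapse = ", "), call. = FALSE)
  }
  holdout_idx <- stratified_holdout_idx(labels, fraction, seed, min_keep = 0L)
  list(train_idx = setdiff(seq_along(labels), holdout_idx),
       holdout_idx = holdout_idx)
}

#' Classification metrics with rejection-aware accounting
#'
#' Accuracy is matches over evaluated cells, where a cell counts as evaluated
#' when its prediction is an actual class label — `"Unclassified"` cells are
#' excluded from accuracy/precision/recall/F1 denominators and reported as a
#' separate rate, and `NA` predictions (cells a cascade never routed to this
#' layer) are dropped. Headline precision/recall/F1 are macro averages over
#' true classes; micro (pooled) values are also reported.
#'
#' @param true character vector of true labels.
#' @param pred character vector of predicted labels (may contain
#'   `"Unclassified"` and `NA`).
#' @return a `metrics_report`: overall fractions, a `per_class` table with
#'   precision/recall/F1/support, and unclassified accounting.
#' @export
compute_metrics <- function(true, pred) {
  true <- as.character(true); pred <- as.character(pred)
  if (length(true) == 0) stop("empty label vectors", call. = FALSE)
  if (length(true) != length(pred)) {
    stop("label vectors differ in length", call. = FALSE)
  }
  routed <- !is.na(pred)
  n_unclassified <- sum(pred[routed] == UNCLASSIFIED)
  evaluated <- routed & pred != UNCLASSIFIED
  n_eval <- sum(evaluated)
  if (n_eval == 0) stop("no evaluated (classified) cells to score", call. = FALSE)
  t_ev <- true[evaluated]; p_ev <- pred[evaluated]
  classes <- sort(unique(t_ev))
  per_class <- do.call(rbind, lapply(classes, function(cl) {
    tp <- sum(t_ev == cl & p_ev == cl)
    n_pred <- sum(p_ev == cl)
    support <- sum(t_ev == cl)
    precision <- if (n_pred > 0) tp / n_pred else 0
    recall <- tp / support
    f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
    data.frame(class = cl, precision = precision, recall = recall, f1 = f1,
               support = support, stringsAsFactors = FALSE)
  }))
  structure(
    list(accuracy = mean(t_ev == p_ev),
         precision_macro = mean(per_class$precision),
         recall_macro = mean(per_class$recall),
         f1_macro = mean(per_class$f1),
         precision_micro = mean(t_ev == p_ev),
         per_class = per_class,
         n_evaluated = n_eval,
         n_unclassified = n_unclassified,
         unclassified_rate = n_unclassified / sum(routed)),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(paste0("<metrics_report> accuracy %.4f | macro P %.4f R %.4f ",
                     "F1 %.4f | %d evaluated, %.1f%% unclassified\n"),
              x$accuracy, x$precision_macro, x$recall_macro, x$f1_macro,
              x$n_evaluated, 100 * x$unclassified_rate))
  invisible(x)
}

#' Confusion matrix with row-normalized percentages
#'
#' Rows are true classes, columns predicted classes; `row_percent` normalizes
#' each row to 100 so the diagonal is the per-class prediction accuracy. With
#' `include_unclassified = TRUE`, rejected cells occupy an extra
#' `"Unclassified"` column (every routed cell then appears in exactly one
#' cell of the matrix); otherwise they are dropped before counting.
#'
#' @param true,pred label vectors as in [compute_metrics()].
#' @param include_unclassified keep rejected cells as their own column.
#' @return a `confusion_matrix`: integer `counts` and numeric `row_percent`
#'   matrices.
#' @export
confusion_matrix <- function(true, pred, include_unclassified = FALSE) {
  true <- as.character(true); pred <- as.character(pred)
  if (length(true) != length(pred)) {
    stop("label vectors differ in length", call. = FALSE)
  }
  keep <- !is.na(pred)
  if (!include_unclassified) keep <- keep & pred != UNCLASSIFIED
  t_k <- true[keep]; p_k <- pred[keep]
  if (length(t_k) == 0) stop("no cells to tabulate", call. = FALSE)
  classes <- sort(unique(t_k))
  pred_classes <- sort(unique(c(classes, setdiff(p_k, UNCLASSIFIED))))
  if (include_unclassified && any(p_k == UNCLASSIFIED)) {
    pred_classes <- c(pred_classes, UNCLASSIFIED)
  }
  counts <- matrix(0L, length(classes), length(pred_classes),
                   dimnames = list(classes, pred_classes))
  tb <- table(t_k, p_k)
  counts[rownames(tb), colnames(tb)] <- tb
  rs <- rowSums(counts)
  row_percent <- sweep(counts, 1, ifelse(rs > 0, rs, NA_real_), "/") * 100
  structure(list(classes = classes, pred_classes = pred_classes,
                 counts = counts, row_percent = row_percent),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix> row-normalized percentages:\n")
  print(round(x$row_percent, 1))
  invisible(x)
}

# Pool per-layer (true label, predicted label) pairs by scoring each layer
# node's true-branch cells with its own layer object; timepoint-partitioned
# nodes of one layer are pooled. Used for hold-out and fold evaluation.
layer_truth_predictions <- function(bundle, X, md, threshold = 0.5) {
  h <- bundle$hierarchy
  aligned <- NULL
  out <- list()
  for (node in layers_in_training_order(h)) {
    lo <- bundle$layer_objects[[node$id]]
    if (is.null(lo)) next
    sel <- layer_training_cells(node, md)
    if (length(sel$idx) == 0) next
    if (is.null(aligned) || !identical(aligned$gene_ids, lo$feature_list)) {
      aligned <- align_genes(X, lo$feature_list)
    }
    res <- predict_layer(lo, em_subset_cells(aligned, sel$idx), threshold)
    ln <- node$layer_name
    if (is.null(out[[ln]])) {
      out[[ln]] <- data.frame(cell_id = character(), true = character(),
                              pred = character(), max_prob = numeric(),
                              stringsAsFactors = FALSE)
    }
    out[[ln]] <- rbind(out[[ln]], data.frame(
      cell_id = X$cell_ids[sel$idx], true = sel$labels,
      pred = res$layers[[ln]]$label, max_prob = res$layers[[ln]]$max_prob,
      stringsAsFactors = FALSE))
  }
  out
}

#' Per-layer hold-out evaluation of a trained bundle
#'
#' Scores each layer node on the cells that truly belong to its branch
#' (per the supplied metadata), pooling timepoint-partitioned nodes of one
#' layer, and returns metrics and a confusion matrix per layer.
#'
#' @param bundle a `model_bundle`.
#' @param X an [expression_matrix()] of log-normalized values for the
#'   evaluation cells.
#' @param md metadata data.frame for the same cells (true labels).
#' @param threshold rejection threshold used while scoring (default 0.5).
#' @return named list per layer with elements `metrics` (a `metrics_report`),
#'   `confusion` (a `confusion_matrix`) and `predictions` (the pooled table).
#' @export
evaluate_layers <- function(bundle, X, md, threshold = 0.5) {
  preds <- layer_truth_predictions(bundle, X, md, threshold)
  lapply(preds, function(df) {
    list(metrics = compute_metrics(df$true, df$pred),
         confusion = confusion_matrix(df$true, df$pred,
                                      include_unclassified = TRUE),
         predictions = df)
  })
}

#' Repeated-reshuffle cross-validation
#'
#' Runs `n_folds` independent reshuffles of the supplied partition: each fold
#' re-splits it 90/10 with per-class stratification (on the cells' full label
#' paths), retrains the whole hierarchy on the 90% segment and scores every
#' layer on the 10% segment. Hyperparameters are tuned once at the topmost
#' layer before the folds (or supplied via `hp`) and reused, so folds differ
#' only in their reshuffle. Aggregates are reported as mean plus/minus the
#' half-width of a normal-approximation 95% confidence interval over folds.
#'
#' @param X an [expression_matrix()] of log-normalized values (typically the
#'   90% cross-validation partition of a prior [holdout_split()]).
#' @param md matching metadata data.frame.
#' @param h an `annotation_hierarchy`.
#' @param n_folds number of independent reshuffles (default 10).
#' @param seed integer master seed.
#' @param test_fraction per-fold test fraction (default 0.10).
#' @param hp optional pre-tuned `hyperparam_config`.
#' @param n_trials tuning budget when `hp` is not supplied.
#' @param threshold rejection threshold during fold scoring.
#' @return a `cv_report`: `folds` (long data.frame of per-fold per-layer
#'   metrics) and `summary` (per-layer mean and `ci95_half` per metric).
#' @export
cross_validate <- function(X, md, h, n_folds = 10, seed = 1,
                           test_fraction = 0.10, hp = NULL, n_trials = 50,
                           threshold = 0.5) {
  stopifnot(inherits(X, "expr_matrix"), inherits(h, "annotation_hierarchy"),
            n_folds >= 1)
  blank <- function(x) is.na(x) | !nzchar(trimws(as.character(x)))
  path_lab <- apply(md[, h$layer_names, drop = FALSE], 1, function(r) {
    r <- as.character(r); paste(r[!blank(r)], collapse = ">")
  })
  if (is.null(hp)) {
    root <- layers_in_training_order(h)[[1]]
    sel <- layer_training_cells(root, md)
    hp <- tune_hyperparameters(em_subset_cells(X, sel$idx), sel$labels,
                               n_trials = n_trials,
                               seed = derive_seed(seed, 1000L))
  }
  fold_rows <- list()
  for (f in seq_len(n_folds)) {
    split <- holdout_split(path_lab, fraction = test_fraction,
                           seed = derive_seed(seed, 3000L + f))
    bundle <- tryCatch(
      train_all(h, em_subset_cells(X, split$train_idx),
                md[split$train_idx, , drop = FALSE],
                seed = derive_seed(seed, 4000L + f), hp = hp),
      error = function(e) stop("fold ", f, ": ", conditionMessage(e),
                               call. = FALSE))
    evals <- evaluate_layers(bundle, em_subset_cells(X, split$holdout_idx),
                             md[split$holdout_idx, , drop = FALSE], threshold)
    for (ln in names(evals)) {
      m <- evals[[ln]]$metrics
      fold_rows[[length(fold_rows) + 1L]] <- data.frame(
        fold = f, layer = ln, accuracy = m$accuracy,
        precision_macro = m$precision_macro, recall_macro = m$recall_macro,
        f1_macro = m$f1_macro, unclassified_rate = m$unclassified_rate,
        n_evaluated = m$n_evaluated, stringsAsFactors = FALSE)
    }
    cc_msg(sprintf("fold %d/%d done", f, n_folds))
  }
  folds <- do.call(rbind, fold_rows)
  metrics <- c("accuracy", "precision_macro", "recall_macro", "f1_macro",
               "unclassified_rate")
  summary <- do.call(rbind, lapply(split(folds, folds$layer), function(d) {
    row <- data.frame(layer = d$layer[1], n_folds = nrow(d),
                      stringsAsFactors = FALSE)
    for (mt in metrics) {
      v <- d[[mt]]
      row[[paste0(mt, "_mean")]] <- mean(v)
      row[[paste0(mt, "_ci95_half")]] <-
        if (length(v) > 1) 1.96 * sd(v) / sqrt(length(v)) else 0
    }
    row
  }))
  rownames(summary) <- NULL
  structure(list(folds = folds, summary = summary, hp = hp),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d folds\n", max(x$folds$fold)))
  print(x$summary[, c("layer", "accuracy_mean", "accuracy_ci95_half",
                      "f1_macro_mean")], row.names = FALSE)
  invisible(x)
}
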