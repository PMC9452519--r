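#' Default randomized-search ranges for the tree booster
#'
#' Learning rate is sampled log-uniformly, maximum tree depth uniformly over
#' the integer range, and the per-tree row (observation) and feature
#' subsampling ratios uniformly. The number of boosting rounds is fixed with
#' early stopping on the validation split (patience `early_stopping_rounds`).
#'
#' @return a list of search-range settings, suitable for the `ranges`
#'   argument of [tune_hyperparameters()].
#' @export
default_search_ranges <- function() {
  list(learning_rate = c(0.01, 0.3),       # log-uniform
       max_depth = c(3L, 10L),             # uniform integer
       row_subsample_ratio = c(0.5, 1.0),  # uniform
       feature_subsample_ratio = c(0.3, 1.0),
       n_rounds = 200L,
       early_stopping_rounds = 20L)
}

sample_hyperparams <- function(n_trials, seed, ranges = default_search_ranges()) {
  set.seed(seed)
  lr <- exp(runif(n_trials, log(ranges$learning_rate[1]),
                  log(ranges$learning_rate[2])))
  depth <- sample(seq(ranges$max_depth[1], ranges$max_depth[2]),
                  n_trials, replace = TRUE)
  rows <- runif(n_trials, ranges$row_subsample_ratio[1],
                ranges$row_subsample_ratio[2])
  feats <- runif(n_trials, ranges$feature_subsample_ratio[1],
                 ranges$feature_subsample_ratio[2])
  lapply(seq_len(n_trials), function(i) {
    structure(list(learning_rate = lr[i], max_depth = depth[i],
                   row_subsample_ratio = rows[i],
                   feature_subsample_ratio = feats[i],
                   n_rounds = as.integer(ranges$n_rounds),
                   early_stopping_rounds = as.integer(ranges$early_stopping_rounds),
                   seed = derive_seed(seed, i)),
              class = "hyperparam_config")
  })
}

xgb_param_list <- function(hp, num_class) {
  list(objective = "multi:softprob",
       num_class = num_class,
       eta = hp$learning_rate,
       max_depth = hp$max_depth,
       subsample = hp$row_subsample_ratio,
       colsample_bytree = hp$feature_subsample_ratio,
       tree_method = "hist",
       nthread = 1,
       seed = hp$seed)
}

# Stratified per-class sample of indices for the held-out part.
# Held-out size per class is round(fraction * n), clamped to [min_keep, n-1].
stratified_holdout_idx <- function(labels, fraction, seed, min_keep = 1L) {
  set.seed(seed)
  out <- integer()
  for (cl in sort(unique(labels))) {
    idx <- which(labels == cl)
    n_out <- min(max(round(fraction * length(idx)), min_keep), length(idx) - 1L)
    if (n_out >= 1) out <- c(out, sample(idx, n_out))
  }
  sort(out)
}

# Train one multiclass booster; labels are integer codes 0..k-1.
# When a validation set is supplied, uses early stopping (misclassification).
fit_booster <- function(X, y_codes, hp, num_class,
                        X_val = NULL, y_val = NULL) {
  dtrain <- xgboost::xgb.DMatrix(X, label = y_codes, missing = NA, nthread = 1)
  params <- xgb_param_list(hp, num_class)
  if (!is.null(X_val)) {
    dval <- xgboost::xgb.DMatrix(X_val, label = y_val, missing = NA, nthread = 1)
    # a continuous stopping metric: merror ties at 0 on separable layers,
    # which would freeze boosting at the first round and leave probabilities
    # uninformatively close to uniform
    params$eval_metric <- "mlogloss"
    xgboost::xgb.train(params = params, data = dtrain,
                       nrounds = hp$n_rounds,
                       evals = list(val = dval),
                       early_stopping_rounds = hp$early_stopping_rounds,
                       verbose = 0)
  } else {
    xgboost::xgb.train(params = params, data = dtrain,
                       nrounds = hp$n_rounds, verbose = 0)
  }
}

booster_probs <- function(model, X) {
  predict(model, xgboost::xgb.DMatrix(X, missing = NA, nthread = 1))
}

#' Tune booster hyperparameters by randomized search
#'
#' Samples `n_trials` configurations uniformly from `ranges`, trains each on
#' a stratified 80/20 split of the supplied cells with early stopping, and
#' returns the configuration minimizing the tuning loss on the validation
#' part. The default loss is the validation misclassification rate;
#' `loss = "mae"` instead minimizes the mean absolute error between encoded
#' (lexicographically ordered) integer class codes, a literal reading of
#' "minimum mean absolute error" model selection.
#'
#' @param X an [expression_matrix()] of log-normalized values.
#' @param y character vector of class labels, one per cell.
#' @param n_trials number of random configurations (default 50).
#' @param seed integer seed; the search is deterministic given it.
#' @param loss `"misclassification"` or `"mae"`.
#' @param ranges search ranges, see [default_search_ranges()].
#' @return the winning `hyperparam_config`, with the per-trial validation
#'   losses attached as attribute `"trial_losses"`.
#' @export
tune_hyperparameters <- function(X, y, n_trials = 50, seed = 1,
                                 loss = c("misclassification", "mae"),
                                 ranges = default_search_ranges()) {
  loss <- match.arg(loss)
  stopifnot(inherits(X, "expr_matrix"), n_trials >= 1)
  y <- as.character(y)
  classes <- sort(unique(y))
  if (length(classes) < 2) {
    stop("hyperparameter tuning needs >= 2 classes; a single-class layer ",
         "is trained as a constant predictor instead", call. = FALSE)
  }
  codes <- setNames(seq_along(classes) - 1L, classes)
  y_code <- codes[y]
  val_idx <- stratified_holdout_idx(y, 0.2, derive_seed(seed, 0L))
  Xd <- em_dense(X)
  X_tr <- Xd[-val_idx, , drop = FALSE]; y_tr <- y_code[-val_idx]
  X_va <- Xd[val_idx, , drop = FALSE];  y_va <- y_code[val_idx]
  configs <- sample_hyperparams(n_trials, seed, ranges)
  losses <- vapply(seq_along(configs), function(i) {
    model <- fit_booster(X_tr, y_tr, configs[[i]], length(classes),
                         X_val = X_va, y_val = y_va)
    probs <- booster_probs(model, X_va)
    pred_code <- max.col(probs, ties.method = "first") - 1L
    l <- if (loss == "misclassification") {
      mean(pred_code != y_va)
    } else {
      mean(abs(pred_code - y_va))
    }
    cc_msg(sprintf("tuning trial %d/%d: %s = %.4f", i, length(configs), loss, l))
    l
  }, 0)
  best <- which.min(losses)
  hp <- configs[[best]]
  attr(hp, "trial_losses") <- losses
  attr(hp, "tuning_loss") <- loss
  cc_msg(sprintf("selected trial %d (%s = %.4f)", best, loss, losses[best]))
  hp
}

# Cells belonging to a node's training branch: parent labels along the path
# match, the timepoint matches when the node is partitioned, and the cell
# carries a non-blank label in the node's own layer column.
layer_training_cells <- function(node, md) {
  keep <- rep(TRUE, nrow(md))
  if (nrow(node$parent_path) > 0) {
    for (j in seq_len(nrow(node$parent_path))) {
      col <- as.character(md[[node$parent_path$layer[j]]])
      keep <- keep & !is.na(col) & col == node$parent_path$label[j]
    }
  }
  if (node$is_timepoint_partition) {
    tp <- as.character(md$Timepoint)
    keep <- keep & !is.na(tp) & tp == node$timepoint_context
  }
  lab <- as.character(md[[node$layer_name]])
  keep <- keep & !is.na(lab) & nzchar(trimws(lab))
  list(idx = which(keep), labels = lab[keep])
}

#' Train the classifier of a single hierarchy layer node
#'
#' Selects the training subset (cells whose metadata matches the node's
#' parent-label path and timepoint context and that carry a non-blank label
#' in this layer), then fits a multiclass gradient-boosted tree ensemble on
#' the full gene list — no prior feature selection. Hierarchy classes with no
#' surviving cells are dropped from the label coding with a warning; a node
#' left with a single class becomes a constant predictor emitting
#' probability 1.
#'
#' @param node a `layer_node` from the hierarchy.
#' @param X an [expression_matrix()] of log-normalized values covering all
#'   cells in `md` (same order).
#' @param md metadata data.frame (see [validate_metadata()]).
#' @param hp a `hyperparam_config`, e.g. from [tune_hyperparameters()].
#' @param seed integer seed for the internal validation split and booster.
#' @return a `layer_object`.
#' @export
train_layer <- function(node, X, md, hp, seed = hp$seed) {
  stopifnot(inherits(X, "expr_matrix"))
  if (!identical(X$cell_ids, as.character(md$cell_id))) {
    stop("expression matrix and metadata refer to different cells or orders",
         call. = FALSE)
  }
  sel <- layer_training_cells(node, md)
  if (length(sel$idx) == 0) {
    stop("no training cells for layer node ", node$id, call. = FALSE)
  }
  if (any(sel$labels == UNCLASSIFIED)) {
    stop("reserved label \"", UNCLASSIFIED, "\" found in training labels of ",
         node$id, call. = FALSE)
  }
  present <- sort(unique(sel$labels))
  dropped <- setdiff(node$class_labels, present)
  if (length(dropped) > 0) {
    warning("layer node ", node$id, ": class(es) with no training cells ",
            "dropped from the label coding: ", paste(dropped, collapse = ", "),
            call. = FALSE)
  }
  extra <- setdiff(present, node$class_labels)
  if (length(extra) > 0) {
    stop("layer node ", node$id, ": training labels not in the hierarchy: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  cc_msg(sprintf("training %s: %d cells, %d classes", node$id,
                 length(sel$idx), length(present)))
  if (length(present) == 1) {
    return(new_layer_object(node, feature_list = X$gene_ids,
                            label_codes = setNames(0L, present),
                            model = NULL, hyperparams = unclass(hp),
                            n_training_cells = length(sel$idx),
                            constant_label = present))
  }
  codes <- setNames(seq_along(present) - 1L, present)
  Xd <- em_dense(em_subset_cells(X, sel$idx))
  y <- codes[sel$labels]
  hp_local <- hp
  hp_local$seed <- seed
  # early stopping needs a validation slice; only carve one when every class
  # can spare cells for it
  use_es <- all(table(sel$labels) >= 10)
  if (use_es) {
    val_idx <- stratified_holdout_idx(sel$labels, 0.1, derive_seed(seed, 1L))
    model <- fit_booster(Xd[-val_idx, , drop = FALSE], y[-val_idx],
                         hp_local, length(present),
                         X_val = Xd[val_idx, , drop = FALSE],
                         y_val = y[val_idx])
  } else {
    model <- fit_booster(Xd, y, hp_local, length(present))
  }
  new_layer_object(node, feature_list = X$gene_ids, label_codes = codes,
                   model = model, hyperparams = unclass(hp_local),
                   n_training_cells = length(sel$idx))
}

#' Train the full hierarchical annotation model
#'
#' Iterates the hierarchy in training order and fits one layer object per
#' node, each on its own branch subset. Under the default
#' `tune_policy = "root_only"` the booster hyperparameters are tuned once by
#' randomized search at the topmost layer and reused for every layer;
#' `"per_layer"` re-tunes at each multi-class node.
#'
#' @param h an `annotation_hierarchy`.
#' @param X an [expression_matrix()] of log-normalized values.
#' @param md metadata data.frame; must pass [validate_metadata()] cleanly.
#' @param seed integer master seed for tuning, splits and boosters.
#' @param tune_policy `"root_only"` (default) or `"per_layer"`.
#' @param n_trials randomized-search budget (default 50).
#' @param hp optional pre-chosen `hyperparam_config`; skips tuning entirely.
#' @param rejection_threshold default rejection threshold stored in the
#'   bundle (default 0.5).
#' @param loss tuning loss, see [tune_hyperparameters()].
#' @return a `model_bundle`.
#' @export
train_all <- function(h, X, md, seed = 1,
                      tune_policy = c("root_only", "per_layer"),
                      n_trials = 50, hp = NULL, rejection_threshold = 0.5,
                      loss = c("misclassification", "mae")) {
  tune_policy <- match.arg(tune_policy)
  loss <- match.arg(loss)
  stopifnot(inherits(h, "annotation_hierarchy"), inherits(X, "expr_matrix"))
  report <- validate_metadata(h, md)
  if (nrow(report) > 0) {
    stop("metadata is inconsistent with the hierarchy (",
         nrow(report), " problem(s)); first: cell ", report$cell_id[1], ", ",
         report$layer[1], ": ", report$problem[1], call. = FALSE)
  }
  nodes <- layers_in_training_order(h)
  if (is.null(hp)) {
    root <- nodes[[1]]
    sel <- layer_training_cells(root, md)
    if (length(unique(sel$labels)) >= 2) {
      cc_msg("tuning hyperparameters at the topmost layer (", n_trials, " trials)")
      hp <- tune_hyperparameters(em_subset_cells(X, sel$idx), sel$labels,
                                 n_trials = n_trials,
                                 seed = derive_seed(seed, 1000L), loss = loss)
    } else {
      hp <- sample_hyperparams(1, derive_seed(seed, 1000L))[[1]]
    }
  }
  layer_objects <- list()
  for (i in seq_along(nodes)) {
    node <- nodes[[i]]
    hp_node <- hp
    if (tune_policy == "per_layer" && i > 1) {
      sel <- layer_training_cells(node, md)
      if (length(unique(sel$labels)) >= 2) {
        hp_node <- tune_hyperparameters(em_subset_cells(X, sel$idx), sel$labels,
                                        n_trials = n_trials,
                                        seed = derive_seed(seed, 1000L + i),
                                        loss = loss)
      }
    }
    lo <- tryCatch(
      train_layer(node, X, md, hp_node, seed = derive_seed(seed, 2000L + i)),
      error = function(e) stop("while training layer node ", node$id, ": ",
                               conditionMessage(e), call. = FALSE))
    layer_objects[[node$id]] <- lo
  }
  new_model_bundle(h, layer_objects, training_seed = seed,
                   rejection_threshold_default = rejection_threshold)
}
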