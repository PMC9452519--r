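# Shared synthetic fixtures. Trained bundles are cached in the helper
# environment so several test files can reuse one training run.

.fixture_cache <- new.env(parent = emptyenv())

tiny_paths <- function() {
  list(c("GroupA", "A1"), c("GroupA", "A2"),
       c("GroupB", "B1"), c("GroupB", "B2"))
}

# Two-layer, 2 -> 4 class fixture: small enough to train in seconds, with
# planted markers strong enough to be cleanly separable.
tiny_spec <- function(...) {
  args <- list(hierarchy = hierarchy_from_paths(tiny_paths()),
               cells_per_terminal_class = 50, n_genes = 200,
               markers_per_class = 10, marker_log_fold = 1.5, seed = 101)
  do.call(synthetic_spec, utils::modifyList(args, list(...)))
}

fixed_hp <- function(seed = 5L, learning_rate = 0.1) {
  structure(list(learning_rate = learning_rate, max_depth = 6,
                 row_subsample_ratio = 0.8, feature_subsample_ratio = 0.8,
                 n_rounds = 150L, early_stopping_rounds = 20L,
                 seed = as.integer(seed)),
            class = "hyperparam_config")
}

cached_tiny <- function() {
  if (is.null(.fixture_cache$tiny)) {
    spec <- tiny_spec()
    ds <- generate_dataset(spec)
    X <- normalize_counts(ds$expression)
    bundle <- train_all(spec$hierarchy, X, ds$metadata, seed = 11,
                        hp = fixed_hp())
    .fixture_cache$tiny <- list(spec = spec, ds = ds, X = X, bundle = bundle)
  }
  .fixture_cache$tiny
}

# Timepoint-partitioned fixture: cardiomyocyte subtypes exist only at their
# stage; endothelial cells have no sublayer.
tp_paths <- function() {
  list(c("CM", "T:E1", "V1"), c("CM", "T:E1", "A1"),
       c("CM", "T:E2", "V2"), c("CM", "T:E2", "A2"),
       "EC")
}

tp_spec <- function(...) {
  args <- list(hierarchy = hierarchy_from_paths(tp_paths()),
               cells_per_terminal_class = 40, n_genes = 200,
               markers_per_class = 10, marker_log_fold = 1.5,
               timepoint_assignment = c(EC = "E1"), seed = 303)
  do.call(synthetic_spec, utils::modifyList(args, list(...)))
}

cached_tp <- function() {
  if (is.null(.fixture_cache$tp)) {
    spec <- tp_spec()
    ds <- generate_dataset(spec)
    X <- normalize_counts(ds$expression)
    bundle <- train_all(spec$hierarchy, X, ds$metadata, seed = 21,
                        hp = fixed_hp())
    .fixture_cache$tp <- list(spec = spec, ds = ds, X = X, bundle = bundle)
  }
  .fixture_cache$tp
}

# Default-condition fixture (2 -> 4 -> 8, 200 cells/terminal class), with a
# stratified 90/10 hold-out and a bundle trained on the 90% side under the
# full 50-trial randomized search. Built once; the acceptance tests share it.
cached_default <- function() {
  if (is.null(.fixture_cache$default)) {
    spec <- default_synthetic_spec(seed = 424242)
    ds <- generate_dataset(spec)
    X <- normalize_counts(ds$expression)
    split <- holdout_split(ds$truth$terminal_class, fraction = 0.10, seed = 7)
    md_tr <- ds$metadata[split$train_idx, , drop = FALSE]
    bundle <- train_all(spec$hierarchy,
                        cellcascade:::em_subset_cells(X, split$train_idx),
                        md_tr, seed = 2024, n_trials = 50)
    .fixture_cache$default <- list(
      spec = spec, ds = ds, X = X, split = split, bundle = bundle,
      X_holdout = cellcascade:::em_subset_cells(X, split$holdout_idx),
      md_holdout = ds$metadata[split$holdout_idx, , drop = FALSE])
  }
  .fixture_cache$default
}

write_tiny_hierarchy_csv <- function(lines, file = tempfile(fileext = ".csv")) {
  writeLines(lines, file)
  file
}
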