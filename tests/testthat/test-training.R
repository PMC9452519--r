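# Separable two-class toy: disjoint marker blocks, no noise overlap.
separable_toy <- function(n_per_class = 40, seed = 900) {
  spec <- synthetic_spec(hierarchy_from_paths(list("K1", "K2")),
                         cells_per_terminal_class = n_per_class,
                         n_genes = 100, markers_per_class = 10,
                         marker_log_fold = 3, seed = seed)
  ds <- generate_dataset(spec)
  list(spec = spec, ds = ds, X = normalize_counts(ds$expression))
}

test_that("randomized search samples within ranges and is seed-deterministic", {
  toy <- separable_toy()
  y <- toy$ds$metadata$Layer1
  hp1 <- tune_hyperparameters(toy$X, y, n_trials = 1, seed = 3)
  rng <- default_search_ranges()
  expect_gte(hp1$learning_rate, rng$learning_rate[1])
  expect_lte(hp1$learning_rate, rng$learning_rate[2])
  expect_true(hp1$max_depth %in% seq(rng$max_depth[1], rng$max_depth[2]))
  expect_gte(hp1$row_subsample_ratio, 0.5)
  expect_lte(hp1$feature_subsample_ratio, 1.0)
  expect_equal(hp1$n_rounds, 200L)
  expect_length(attr(hp1, "trial_losses"), 1L)

  hp2 <- tune_hyperparameters(toy$X, y, n_trials = 1, seed = 3)
  expect_equal(unclass(hp1), unclass(hp2))

  # linearly separable toy: the winning trial reaches zero validation error
  hp3 <- tune_hyperparameters(toy$X, y, n_trials = 3, seed = 5)
  expect_equal(min(attr(hp3, "trial_losses")), 0)

  expect_error(tune_hyperparameters(toy$X, rep("K1", length(y))), ">= 2 classes")
})

test_that("mae tuning loss scores encoded labels and selects a config", {
  toy <- separable_toy(n_per_class = 30)
  hp <- tune_hyperparameters(toy$X, toy$ds$metadata$Layer1, n_trials = 2,
                             seed = 4, loss = "mae")
  expect_s3_class(hp, "hyperparam_config")
  expect_equal(attr(hp, "tuning_loss"), "mae")
})

test_that("branch subsetting never admits out-of-branch or off-stage cells", {
  fx <- cached_tp()
  h <- fx$spec$hierarchy
  md <- fx$ds$metadata
  for (node in layers_in_training_order(h)) {
    sel <- cellcascade:::layer_training_cells(node, md)
    if (nrow(node$parent_path) > 0) {
      for (j in seq_len(nrow(node$parent_path))) {
        expect_true(all(md[[node$parent_path$layer[j]]][sel$idx] ==
                          node$parent_path$label[j]),
                    label = paste("branch purity at", node$id))
      }
    }
    if (node$is_timepoint_partition) {
      expect_true(all(md$Timepoint[sel$idx] == node$timepoint_context),
                  label = paste("stage purity at", node$id))
    }
    expect_true(all(nzchar(sel$labels)))
  }
})

test_that("a single-class node trains to a constant unit-probability predictor", {
  h <- hierarchy_from_paths(list(c("A", "A1"), "B"))
  md <- data.frame(cell_id = paste0("c", 1:6),
                   Layer1 = c("A", "A", "A", "B", "B", "B"),
                   Layer2 = c("A1", "A1", "A1", "", "", ""),
                   stringsAsFactors = FALSE)
  set.seed(1)
  X <- expression_matrix(matrix(rpois(6 * 20, 5), 6, 20,
                                dimnames = list(md$cell_id, paste0("g", 1:20))))
  X <- normalize_counts(X)
  node <- Filter(function(n) n$layer_name == "Layer2",
                 h$nodes)[[1]]
  lo <- train_layer(node, X, md, fixed_hp())
  expect_true(cellcascade:::is_constant_layer(lo))
  res <- predict_layer(lo, align_genes(X, lo$feature_list))
  expect_true(all(res$layers$Layer2$max_prob == 1))
  expect_true(all(res$layers$Layer2$label == "A1"))
})

test_that("a separable two-class layer reaches perfect hold-out accuracy", {
  toy <- separable_toy(n_per_class = 60)
  split <- holdout_split(toy$ds$metadata$Layer1, 0.2, seed = 8)
  root <- layers_in_training_order(toy$spec$hierarchy)[[1]]
  lo <- train_layer(root, cellcascade:::em_subset_cells(toy$X, split$train_idx),
                    toy$ds$metadata[split$train_idx, ], fixed_hp())
  res <- predict_layer(lo, cellcascade:::em_subset_cells(
    align_genes(toy$X, lo$feature_list), split$holdout_idx), threshold = 0)
  expect_equal(res$layers$Layer1$label,
               toy$ds$metadata$Layer1[split$holdout_idx])
})

test_that("train_all produces one layer object per node and is reproducible", {
  fx <- cached_tiny()
  h <- fx$spec$hierarchy
  expect_setequal(names(fx$bundle$layer_objects), names(h$nodes))

  # depth-1 hierarchy: exactly one layer object
  toy <- separable_toy(n_per_class = 20)
  b1 <- train_all(toy$spec$hierarchy, toy$X, toy$ds$metadata, seed = 5,
                  hp = fixed_hp())
  expect_length(b1$layer_objects, 1L)

  # identical seeds give bit-identical predictions
  b2 <- train_all(toy$spec$hierarchy, toy$X, toy$ds$metadata, seed = 5,
                  hp = fixed_hp())
  expect_identical(predict_cascade(b1, toy$X)$probs,
                   predict_cascade(b2, toy$X)$probs)
})

test_that("removing a class's cells removes it from the output space", {
  toy <- separable_toy(n_per_class = 25, seed = 911)
  md <- toy$ds$metadata
  # relabel K2 cells away (blank root is invalid, so route via train_layer)
  root <- layers_in_training_order(toy$spec$hierarchy)[[1]]
  md_k1 <- md[md$Layer1 == "K1", , drop = FALSE]
  X_k1 <- cellcascade:::em_subset_cells(toy$X, which(md$Layer1 == "K1"))
  expect_warning(lo <- train_layer(root, X_k1, md_k1, fixed_hp()),
                 "dropped from the label coding: K2")
  expect_equal(names(lo$label_codes), "K1")
  res <- predict_layer(lo, align_genes(toy$X, lo$feature_list))
  expect_true(all(res$layers$Layer1$label == "K1"))
})

test_that("training-set pathologies raise named errors", {
  toy <- separable_toy(n_per_class = 10)
  md <- toy$ds$metadata
  root <- layers_in_training_order(toy$spec$hierarchy)[[1]]
  md_empty <- md; md_empty$Layer1 <- ""
  expect_error(train_layer(root, toy$X, md_empty, fixed_hp()),
               "no training cells")
  md_res <- md; md_res$Layer1[1] <- "Unclassified"
  expect_error(train_layer(root, toy$X, md_res, fixed_hp()), "reserved")
  expect_error(train_all(toy$spec$hierarchy, toy$X, md_res, hp = fixed_hp()),
               "inconsistent")
})
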