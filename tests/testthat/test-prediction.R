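test_that("the rejection threshold gates assignment exactly", {
  fx <- cached_tiny()
  lo <- fx$bundle$layer_objects[["Layer1"]]
  Xa <- align_genes(fx$X, lo$feature_list)

  all_in <- predict_layer(lo, Xa, threshold = 0)
  expect_true(all(all_in$layers$Layer1$label != "Unclassified"))

  # assigned iff max_prob >= threshold, at any threshold
  for (thr in c(0.25, 0.5, 0.9)) {
    r <- predict_layer(lo, Xa, threshold = thr)
    lr <- r$layers$Layer1
    expect_identical(lr$label == "Unclassified", lr$max_prob < thr)
  }

  # probability vectors are proper distributions
  expect_true(all(abs(rowSums(all_in$probs$Layer1) - 1) < 1e-6))

  # feature-order mismatch is a contract error, never a silent reorder
  shuffled <- expression_matrix(as.matrix(fx$X$values)[, rev(fx$X$gene_ids)],
                                cell_ids = fx$X$cell_ids,
                                gene_ids = rev(fx$X$gene_ids),
                                normalized = TRUE)
  expect_error(predict_layer(lo, shuffled), "gene order")
})

test_that("unclassified count is non-decreasing in the threshold", {
  fx <- cached_tiny()
  # mix in ambiguous midpoints so intermediate confidences exist
  mid <- make_ambiguous_cells(fx$spec, "A1", "B1", 30)
  lo <- fx$bundle$layer_objects[["Layer1"]]
  Xa <- align_genes(mid, lo$feature_list)
  counts <- vapply(seq(0, 1, by = 0.1), function(thr) {
    sum(predict_layer(lo, Xa, thr)$layers$Layer1$label == "Unclassified")
  }, 0L)
  expect_true(all(diff(counts) >= 0))
})

test_that("cascade equals the manual per-layer composition exactly", {
  fx <- cached_tiny()
  res <- predict_cascade(fx$bundle, fx$X, threshold = 0.5)
  # manual composition: root standalone, then children on matching subsets
  h <- fx$spec$hierarchy
  lo_root <- fx$bundle$layer_objects[["Layer1"]]
  Xa <- align_genes(fx$X, lo_root$feature_list)
  manual_root <- predict_layer(lo_root, Xa, 0.5)$layers$Layer1
  expect_identical(res$layers$Layer1$label, manual_root$label)
  expect_identical(res$layers$Layer1$max_prob, manual_root$max_prob)
  for (node in layers_in_training_order(h)) {
    if (nrow(node$parent_path) == 0) next
    lo <- fx$bundle$layer_objects[[node$id]]
    idx <- which(manual_root$label == node$parent_path$label[1])
    manual <- predict_layer(lo, cellcascade:::em_subset_cells(Xa, idx),
                            0.5)$layers[[node$layer_name]]
    expect_identical(res$layers$Layer2$label[idx], manual$label)
    expect_identical(res$layers$Layer2$max_prob[idx], manual$max_prob)
  }
})

test_that("cells rejected at a layer are not evaluated deeper", {
  fx <- cached_tiny()
  mid <- make_ambiguous_cells(fx$spec, "A1", "B1", 20)
  res <- predict_cascade(fx$bundle, mid, threshold = 0.999)
  l1 <- res$layers$Layer1
  rejected <- which(l1$label == "Unclassified")
  if (length(rejected) > 0) {
    expect_true(all(is.na(res$layers$Layer2$label[rejected])))
  }
  # and routing soundness for the assigned ones
  assigned <- which(!is.na(res$layers$Layer2$label) &
                      res$layers$Layer2$label != "Unclassified")
  for (i in assigned) {
    node <- fx$spec$hierarchy$nodes[[res$layers$Layer2$node_id[i]]]
    expect_equal(node$parent_path$label[1], res$layers$Layer1$label[i])
  }
})

test_that("timepoint routing only scores cells at their own stage", {
  fx <- cached_tp()
  md <- fx$ds$metadata
  res <- predict_cascade(fx$bundle, fx$X, query_timepoints = md$Timepoint)
  l2 <- res$layers$Layer2
  evaluated <- which(!is.na(l2$label))
  expect_gt(length(evaluated), 0)
  expect_true(all(l2$timepoint_used[evaluated] == md$Timepoint[evaluated]))
  # no stage-foreign label ever assigned
  e1_labels <- c("V1", "A1"); e2_labels <- c("V2", "A2")
  expect_false(any(l2$label[md$Timepoint == "E2"] %in% e1_labels))
  expect_false(any(l2$label[md$Timepoint == "E1"] %in% e2_labels))

  # unknown stage: warning, branch skipped for those cells
  tps <- md$Timepoint; tps[1:5] <- "E99"
  expect_warning(res2 <- predict_cascade(fx$bundle, fx$X, query_timepoints = tps),
                 "absent from the hierarchy")
  cm_skipped <- intersect(1:5, which(md$Layer1 == "CM"))
  expect_true(all(is.na(res2$layers$Layer2$label[cm_skipped])))

  # without query timepoints every partitioned node is skipped with a warning
  w <- capture_warnings(res3 <- predict_cascade(fx$bundle, fx$X))
  expect_true(all(grepl("timepoint", w)))
  expect_length(w, 2L)
  expect_true(all(is.na(res3$layers$Layer2$label)))
})

test_that("prediction CSV output round-trips labels and distinguishes states", {
  fx <- cached_tp()
  mid <- make_ambiguous_cells(fx$spec, "V1", "EC", 10)
  X_all <- expression_matrix(rbind(cellcascade:::em_dense(fx$X),
                                   cellcascade:::em_dense(mid)),
                             cell_ids = c(fx$X$cell_ids, mid$cell_ids),
                             gene_ids = fx$X$gene_ids, normalized = TRUE)
  tps <- c(fx$ds$metadata$Timepoint, rep("E1", 10))
  res <- predict_cascade(fx$bundle, X_all, query_timepoints = tps,
                         threshold = 0.95)
  f <- tempfile(fileext = ".csv")
  pf <- tempfile(fileext = ".csv")
  write_predictions(res, f, probs_path = pf)
  back <- data.table::fread(f, data.table = FALSE, colClasses = "character",
                            na.strings = NULL)
  # header: cell id + (label, prob) per layer
  expect_equal(ncol(back), 1 + 2 * length(res$layers))
  df <- as.data.frame(res)
  expect_identical(back$Layer1_label,
                   ifelse(is.na(df$Layer1_label), "", df$Layer1_label))
  expect_identical(back$Layer2_label,
                   ifelse(is.na(df$Layer2_label), "", df$Layer2_label))
  # unclassified-at-layer-1 cells have empty (not-evaluated) deeper columns
  uncl <- back$Layer1_label == "Unclassified"
  if (any(uncl)) expect_true(all(back$Layer2_label[uncl] == ""))
  probs <- data.table::fread(pf, data.table = FALSE)
  expect_true(all(c("node_id", "cell_id", "class", "prob") %in% names(probs)))
})
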