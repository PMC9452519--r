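test_that("CSV expression round-trips with ids intact", {
  m <- matrix(c(0, 1, 2, 3, 4, 5), 2, 3,
              dimnames = list(c("c1", "c2"), c("gA", "gB", "gC")))
  em <- expression_matrix(m)
  f <- tempfile(fileext = ".csv")
  write_expression(em, f, "csv")
  back <- read_expression(f, "csv")
  expect_equal(back$cell_ids, c("c1", "c2"))
  expect_equal(back$gene_ids, c("gA", "gB", "gC"))
  expect_equal(as.matrix(back$values), m)
  expect_false(back$normalized)
})

test_that("MTX triplets load in either orientation with implicit zeros", {
  dir <- tempfile(); dir.create(dir)
  # genes-as-rows dialect: 4 genes x 5 cells, 7 nonzeros
  m <- Matrix::sparseMatrix(i = c(1, 2, 3, 4, 1, 2, 3),
                            j = c(1, 2, 3, 4, 5, 5, 5),
                            x = c(1, 2, 3, 4, 5, 6, 7), dims = c(4, 5))
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(paste0("g", 1:4), file.path(dir, "genes.tsv"))
  writeLines(paste0("c", 1:5), file.path(dir, "barcodes.tsv"))
  em <- read_expression(file.path(dir, "matrix.mtx"), "mtx")
  expect_equal(dim(em), c(5L, 4L))
  expect_equal(Matrix::nnzero(em$values), 7L)
  expect_equal(as.numeric(em$values["c5", ]), c(5, 6, 7, 0))

  # cells-as-rows dialect is auto-detected from the sidecar lengths
  dir2 <- tempfile(); dir.create(dir2)
  Matrix::writeMM(Matrix::t(m), file.path(dir2, "matrix.mtx"))
  writeLines(paste0("g", 1:4), file.path(dir2, "genes.tsv"))
  writeLines(paste0("c", 1:5), file.path(dir2, "barcodes.tsv"))
  em2 <- read_expression(file.path(dir2, "matrix.mtx"), "mtx")
  expect_equal(as.matrix(em2$values), as.matrix(em$values))

  # mismatched sidecars
  writeLines(paste0("g", 1:3), file.path(dir2, "genes.tsv"))
  expect_error(read_expression(file.path(dir2, "matrix.mtx"), "mtx"),
               "neither orientation")
})

test_that("duplicate gene ids are rejected and named", {
  m <- matrix(1:4, 2, 2)
  expect_error(expression_matrix(m, cell_ids = c("c1", "c2"),
                                 gene_ids = c("Actb", "Actb")),
               "duplicate gene ids: Actb")
})

test_that("log CP10K normalization matches hand arithmetic", {
  m <- matrix(c(5, 5), 1, 2, dimnames = list("c1", c("g1", "g2")))
  norm <- normalize_counts(expression_matrix(m))
  expect_equal(as.numeric(norm$values), rep(log(1 + 5 * 1e4 / 10), 2),
               tolerance = 1e-12)
  expect_true(norm$normalized)

  # zero counts map exactly to zero; zero-total cells are named
  m2 <- matrix(c(3, 0, 1, 0), 2, 2,
               dimnames = list(c("ok", "empty"), c("g1", "g2")))
  expect_error(normalize_counts(expression_matrix(m2)), "empty")
  m3 <- matrix(c(0, 3), 1, 2, dimnames = list("c1", c("g1", "g2")))
  expect_equal(as.numeric(normalize_counts(expression_matrix(m3))$values[1, 1]), 0)

  expect_error(normalize_counts(norm), "already")
})

test_that("normalization preserves within-cell rank order, dense and sparse", {
  set.seed(4)
  counts <- matrix(rpois(20 * 30, 3), 20, 30,
                   dimnames = list(paste0("c", 1:20), paste0("g", 1:30)))
  counts[1, ] <- pmax(counts[1, ], 1)
  dense <- normalize_counts(expression_matrix(counts))
  sparse <- normalize_counts(
    expression_matrix(Matrix::Matrix(counts, sparse = TRUE)))
  expect_equal(as.matrix(sparse$values), as.matrix(dense$values),
               tolerance = 1e-12, ignore_attr = TRUE)
  for (i in seq_len(nrow(counts))) {
    expect_equal(order(counts[i, ], as.numeric(dense$values[i, ])),
                 order(as.numeric(dense$values[i, ]), counts[i, ]))
  }
})

test_that("align_genes reorders, masks missing features, drops extras", {
  m <- matrix(1:6, 2, 3, dimnames = list(c("c1", "c2"), c("g1", "g3", "g4")))
  em <- expression_matrix(m, normalized = TRUE)
  out <- align_genes(em, c("g1", "g2", "g3"))
  expect_equal(out$gene_ids, c("g1", "g2", "g3"))
  expect_equal(out$observed_mask, c(TRUE, FALSE, TRUE))
  expect_equal(as.numeric(out$values[, "g1"]), c(1, 2))
  expect_equal(as.numeric(out$values[, "g3"]), c(3, 4))
  # the masked gene is missing downstream, not zero
  expect_true(all(is.na(cellcascade:::em_dense(out)[, "g2"])))

  # shuffled identical gene set: pure reorder, everything observed
  out2 <- align_genes(em, c("g4", "g1", "g3"))
  expect_true(all(out2$observed_mask))
  expect_equal(as.numeric(out2$values[, "g4"]), c(5, 6))

  expect_error(align_genes(em, c("x1", "x2")), "no overlap")
  expect_warning(align_genes(em, c("g1", "x1", "x2", "x3")),
                 "training features found")

  # idempotence under a fixed feature list
  once <- suppressWarnings(align_genes(em, c("g1", "g2", "g3")))
  twice <- suppressWarnings(align_genes(once, c("g1", "g2", "g3")))
  expect_equal(twice$values, once$values, ignore_attr = TRUE)
  expect_equal(twice$observed_mask, once$observed_mask)
})

test_that("ortholog mapping renames, collapses collisions, drops unmapped", {
  m <- matrix(c(2, 4, 1), 1, 3, dimnames = list("c1", c("H1", "H2", "H3")))
  em <- expression_matrix(m, normalized = TRUE)
  idmap <- data.frame(source = c("H1", "H2", "H3"),
                      target = c("H1", "H2", "H3"))
  same <- map_orthologs(em, idmap)
  expect_equal(as.matrix(same$values)[, em$gene_ids], as.matrix(em$values)[1, ])

  collide <- data.frame(source = c("H1", "H2"), target = c("m1", "m1"))
  expect_equal(as.numeric(map_orthologs(em, collide, "mean")$values), 3.0)
  expect_equal(as.numeric(map_orthologs(em, collide, "max")$values), 4.0)
  expect_equal(as.numeric(map_orthologs(em, collide, "first")$values), 2.0)
  # H3 had no map entry: absent from output
  expect_equal(map_orthologs(em, collide)$gene_ids, "m1")

  expect_error(map_orthologs(em, data.frame()), "two-column")
  # file-driven map (TSV)
  f <- tempfile(fileext = ".tsv")
  writeLines(c("H1\tmA", "H2\tmB"), f)
  expect_equal(sort(map_orthologs(em, f)$gene_ids), c("mA", "mB"))
})

test_that("bundle save/load round-trips to bit-identical predictions", {
  fx <- cached_tiny()
  dir <- tempfile()
  save_bundle(fx$bundle, dir)
  b2 <- load_bundle(dir)
  r1 <- predict_cascade(fx$bundle, fx$X)
  r2 <- predict_cascade(b2, fx$X)
  expect_identical(r1$probs, r2$probs)
  expect_identical(as.data.frame(r1), as.data.frame(r2))

  # a standalone layer object reproduces its layer alone
  id <- names(fx$bundle$layer_objects)[2]
  lo <- load_layer_object(dir, id)
  Xa <- align_genes(fx$X, lo$feature_list)
  solo <- predict_layer(lo, Xa)
  orig <- predict_layer(fx$bundle$layer_objects[[id]], Xa)
  expect_identical(solo$probs, orig$probs)

  expect_error(load_layer_object(dir, "no_such_layer"), "no layer object")
})

test_that("corrupt or incompatible bundles fail loudly, never partially", {
  fx <- cached_tiny()
  dir <- tempfile()
  save_bundle(fx$bundle, dir)
  manifest <- file.path(dir, "manifest.json")
  txt <- readLines(manifest)
  writeLines(substr(paste(txt, collapse = ""), 1, 50), manifest)
  expect_error(load_bundle(dir), "corrupted")

  dir2 <- tempfile()
  save_bundle(fx$bundle, dir2)
  m <- jsonlite::read_json(file.path(dir2, "manifest.json"))
  m$format_version <- "99.0"
  jsonlite::write_json(m, file.path(dir2, "manifest.json"), auto_unbox = TRUE)
  expect_error(load_bundle(dir2), "unsupported bundle format")

  expect_error(load_bundle(tempfile()), "no manifest")
})
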