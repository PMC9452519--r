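#' Specify a synthetic hierarchically structured scRNA-seq dataset
#'
#' The generator emulates the inputs the annotation pipeline consumes:
#' negative-binomial counts with per-cell library-size variation, and a known
#' rooted annotation hierarchy in which every class of every layer node owns
#' a disjoint block of marker genes whose expected expression is elevated by
#' `exp(marker_log_fold)`. A cell of a terminal class carries the elevated
#' markers of *every* node class along its root-to-leaf path, producing the
#' nested signal that hierarchical classification exploits.
#'
#' @param hierarchy an `annotation_hierarchy` (timepoint partitions allowed;
#'   each leaf's timepoint is taken from its path).
#' @param cells_per_terminal_class cells simulated per leaf class.
#' @param n_genes total gene count; must cover all planted markers.
#' @param markers_per_class marker genes planted per class per layer node.
#' @param marker_log_fold natural-log fold elevation of marker means.
#' @param baseline_mean relative mean of non-marker genes.
#' @param dispersion negative-binomial size parameter (smaller = noisier).
#' @param library_size_range integer `(min, max)` of per-cell total counts.
#' @param timepoint_assignment optional named character vector mapping
#'   terminal classes to timepoints, for hierarchies without timepoint
#'   partitions that still want a `Timepoint` metadata column.
#' @param seed integer seed; generation is deterministic given it.
#' @return a `synthetic_spec` object.
#' @export
synthetic_spec <- function(hierarchy, cells_per_terminal_class = 200,
                           n_genes = 500, markers_per_class = 20,
                           marker_log_fold = 1.5, baseline_mean = 1,
                           dispersion = 2,
                           library_size_range = c(2000L, 5000L),
                           timepoint_assignment = NULL, seed = 1) {
  stopifnot(inherits(hierarchy, "annotation_hierarchy"),
            cells_per_terminal_class >= 0, n_genes > 0,
            markers_per_class > 0, marker_log_fold > 0, baseline_mean > 0,
            dispersion > 0, length(library_size_range) == 2,
            library_size_range[1] >= 1,
            library_size_range[2] >= library_size_range[1])
  n_marker_sets <- sum(vapply(hierarchy$nodes, function(n)
    length(n$class_labels), 0L))
  if (n_marker_sets * markers_per_class > n_genes) {
    stop("marker budget (", n_marker_sets, " classes x ", markers_per_class,
         " markers = ", n_marker_sets * markers_per_class,
         ") exceeds n_genes = ", n_genes, call. = FALSE)
  }
  structure(
    list(hierarchy = hierarchy,
         cells_per_terminal_class = as.integer(cells_per_terminal_class),
         n_genes = as.integer(n_genes),
         markers_per_class = as.integer(markers_per_class),
         marker_log_fold = marker_log_fold, baseline_mean = baseline_mean,
         dispersion = dispersion,
         library_size_range = as.integer(library_size_range),
         timepoint_assignment = timepoint_assignment,
         seed = as.integer(seed)),
    class = "synthetic_spec")
}

#' The default three-layer synthetic fixture specification
#'
#' A 2 -> 4 -> 8 class hierarchy (two root groups, two subtypes each, two
#' sub-subtypes each) with 200 cells per terminal class, 500 genes, 20
#' markers per class and a natural-log fold change of 1.5 — separable enough
#' for near-perfect held-out annotation while keeping negative-binomial noise
#' and library-size variation realistic for droplet-style data.
#'
#' @param ... overrides passed on to [synthetic_spec()].
#' @return a `synthetic_spec`.
#' @export
default_synthetic_spec <- function(...) {
  paths <- list()
  for (g in c("A", "B")) {
    for (s in 1:2) {
      for (t in c("a", "b")) {
        paths[[length(paths) + 1L]] <-
          c(paste0("Group", g), paste0(g, s), paste0(g, s, t))
      }
    }
  }
  synthetic_spec(hierarchy_from_paths(paths), ...)
}

# Marker gene ids per (node, class), assigned as disjoint consecutive blocks
# in deterministic node order.
planted_markers <- function(spec) {
  gene_ids <- sprintf("g%04d", seq_len(spec$n_genes))
  markers <- list()
  offset <- 0L
  for (node in layers_in_training_order(spec$hierarchy)) {
    for (cl in node$class_labels) {
      markers[[paste(node$id, cl, sep = "||")]] <-
        gene_ids[offset + seq_len(spec$markers_per_class)]
      offset <- offset + spec$markers_per_class
    }
  }
  markers
}

# Leaf descriptors: label path (layers only), timepoint, and the marker keys
# active along the path.
leaf_table <- function(spec) {
  h <- spec$hierarchy
  lapply(h$paths, function(p) {
    is_tp <- startsWith(p, "T:")
    labels <- p[!is_tp]
    tp <- if (any(is_tp)) sub("^T:", "", p[is_tp][1]) else NA_character_
    terminal <- labels[length(labels)]
    if (is.na(tp) && !is.null(spec$timepoint_assignment) &&
        terminal %in% names(spec$timepoint_assignment)) {
      tp <- spec$timepoint_assignment[[terminal]]
    }
    # locate the node classifying each level of this path
    keys <- character(length(labels))
    node <- root_node(h)
    for (d in seq_along(labels)) {
      keys[d] <- paste(node$id, labels[d], sep = "||")
      kids <- child_nodes(h, node, labels[d])
      if (length(kids) > 0) {
        tps <- vapply(kids, `[[`, "", "timepoint_context")
        node <- if (all(is.na(tps))) kids[[1]] else {
          hit <- which(tps == tp)
          if (length(hit) > 0) kids[[hit[1]]] else kids[[1]]
        }
      }
    }
    list(labels = labels, timepoint = tp, terminal = terminal,
         marker_keys = keys)
  })
}

# Relative (pre-library-size) mean expression profile of one leaf.
leaf_rel_means <- function(spec, leaf, markers) {
  r <- rep(spec$baseline_mean, spec$n_genes)
  names(r) <- sprintf("g%04d", seq_len(spec$n_genes))
  for (k in leaf$marker_keys) {
    r[markers[[k]]] <- r[markers[[k]]] * exp(spec$marker_log_fold)
  }
  r
}

#' Generate a synthetic dataset with known ground truth
#'
#' Draws raw negative-binomial counts from a [synthetic_spec()]: each cell's
#' library size is uniform over `library_size_range`, gene means are the
#' cell's leaf-class relative profile scaled to that library size, and
#' markers of every node class along the leaf's path are elevated. Output is
#' deterministic given `spec$seed`.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `expression` (raw-count [expression_matrix()]),
#'   `metadata` (data.frame with `cell_id`, one column per layer, and
#'   `Timepoint` when applicable) and `truth` (planted markers per node class
#'   and the per-cell label paths).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  h <- spec$hierarchy
  markers <- planted_markers(spec)
  leaves <- leaf_table(spec)
  gene_ids <- sprintf("g%04d", seq_len(spec$n_genes))
  n_cells <- spec$cells_per_terminal_class * length(leaves)
  has_tp <- h$has_timepoints || !is.null(spec$timepoint_assignment)

  md <- data.frame(cell_id = if (n_cells > 0) sprintf("cell_%05d", seq_len(n_cells))
                   else character(), stringsAsFactors = FALSE)
  for (ln in h$layer_names) md[[ln]] <- rep("", n_cells)
  if (has_tp) md$Timepoint <- rep("", n_cells)

  counts <- matrix(0, n_cells, spec$n_genes,
                   dimnames = list(md$cell_id, gene_ids))
  set.seed(spec$seed)
  row <- 0L
  for (leaf in leaves) {
    if (spec$cells_per_terminal_class == 0) break
    r <- leaf_rel_means(spec, leaf, markers)
    p <- r / sum(r)
    lib <- sample(seq(spec$library_size_range[1], spec$library_size_range[2]),
                  spec$cells_per_terminal_class, replace = TRUE)
    for (j in seq_len(spec$cells_per_terminal_class)) {
      row <- row + 1L
      counts[row, ] <- rnbinom(spec$n_genes, mu = lib[j] * p,
                               size = spec$dispersion)
      for (d in seq_along(leaf$labels)) {
        md[[h$layer_names[d]]][row] <- leaf$labels[d]
      }
      if (has_tp && !is.na(leaf$timepoint)) md$Timepoint[row] <- leaf$timepoint
    }
  }
  # guard against the (vanishingly rare) all-zero draw, which normalization
  # rejects by design
  if (n_cells > 0) {
    zero <- rowSums(counts) == 0
    if (any(zero)) counts[zero, 1] <- 1
  }
  truth <- structure(
    list(markers = markers,
         cell_paths = md,
         terminal_class = if (n_cells > 0)
           rep(vapply(leaves, `[[`, "", "terminal"),
               each = spec$cells_per_terminal_class) else character(),
         spec = spec),
    class = "planted_truth")
  list(expression = expression_matrix(counts, cell_ids = md$cell_id,
                                      gene_ids = gene_ids, normalized = FALSE),
       metadata = md, truth = truth)
}

#' Deterministic centroid and midpoint cells for rejection-option tests
#'
#' Builds noise-free cells on the log-normalized scale whose expression is
#' the coordinatewise mean of two classes' generative mean profiles — by
#' construction equidistant from both class centroids. With
#' `class_a == class_b` the result is that class's pure centroid, the natural
#' comparator for confidence contrasts.
#'
#' @param spec a [synthetic_spec()].
#' @param class_a,class_b terminal class labels from the hierarchy.
#' @param n number of (identical) cells to emit.
#' @return a log-normalized [expression_matrix()] with `n` rows.
#' @export
make_ambiguous_cells <- function(spec, class_a, class_b, n) {
  stopifnot(inherits(spec, "synthetic_spec"), n >= 0)
  markers <- planted_markers(spec)
  leaves <- leaf_table(spec)
  terminals <- vapply(leaves, `[[`, "", "terminal")
  pick <- function(cl) {
    hit <- which(terminals == cl)
    if (length(hit) == 0) {
      stop("terminal class not in hierarchy: ", cl, call. = FALSE)
    }
    leaves[[hit[1]]]
  }
  r_mid <- (leaf_rel_means(spec, pick(class_a), markers) +
              leaf_rel_means(spec, pick(class_b), markers)) / 2
  vals <- log1p(1e4 * r_mid / sum(r_mid))
  m <- matrix(rep(vals, each = n), nrow = n, ncol = length(vals),
              dimnames = list(NULL, names(vals)))
  expression_matrix(m,
                    cell_ids = if (n > 0)
                      sprintf("mid_%s_%s_%03d", sanitize_id(class_a),
                              sanitize_id(class_b), seq_len(n)) else character(),
                    gene_ids = names(vals), normalized = TRUE)
}
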