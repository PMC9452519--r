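#' Annotation hierarchies
#'
#' An annotation hierarchy is a rooted tree of annotation *layers*. Each row
#' of the hierarchy file is one root-to-leaf label path, one column per
#' level; trailing empty cells are allowed, lines starting with `#` are
#' comments and there is no header row. A level value prefixed `T:` denotes a
#' developmental-timepoint partition: the layer immediately below it is
#' trained and predicted separately for each listed timepoint, so
#' stage-restricted subtypes are only ever assigned within their stage.
#'
#' Classification layers are named `Layer1`, `Layer2`, ... by their depth
#' among non-timepoint levels; per-cell metadata must carry one column per
#' layer (blank = the cell is not in that branch) and a `Timepoint` column
#' when any partition is present.
#'
#' @param path path to a hierarchy CSV file.
#' @return an `annotation_hierarchy` object.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("Cardiomyocytes,T:E10.5,VentricularCM",
#'              "Cardiomyocytes,T:E10.5,AtrialCM",
#'              "Endothelial"), f)
#' h <- parse_hierarchy(f)
#' h
#' @export
parse_hierarchy <- function(path) {
  if (!file.exists(path)) stop("hierarchy file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) stop("hierarchy file is empty: ", path, call. = FALSE)
  paths <- lapply(strsplit(lines, ",", fixed = TRUE), function(p) {
    p <- trimws(p)
    # trailing blanks pad short rows; internal blanks are malformed
    while (length(p) > 0 && !nzchar(p[length(p)])) p <- p[-length(p)]
    if (any(!nzchar(p))) {
      stop("hierarchy row has an internal blank level: ",
           paste(p, collapse = ","), call. = FALSE)
    }
    p
  })
  paths <- paths[lengths(paths) > 0]
  if (length(paths) == 0) stop("hierarchy file is empty: ", path, call. = FALSE)
  hierarchy_from_paths(paths)
}

#' Build an annotation hierarchy from label paths
#'
#' Programmatic equivalent of [parse_hierarchy()]: each element of `paths` is
#' one root-to-leaf character vector of labels, with timepoint partition
#' values prefixed `"T:"`.
#'
#' @param paths list of character vectors of labels, root first.
#' @return an `annotation_hierarchy` object.
#' @export
hierarchy_from_paths <- function(paths) {
  paths <- lapply(paths, as.character)
  keys <- vapply(paths, paste, "", collapse = "\r")
  if (anyDuplicated(keys)) {
    stop("duplicate identical paths in hierarchy: ",
         paste(unique(keys[duplicated(keys)]), collapse = "; "), call. = FALSE)
  }
  for (p in paths) {
    is_tp <- startsWith(p, "T:")
    if (sum(is_tp) > 1) {
      stop("at most one timepoint level is allowed per path: ",
           paste(p, collapse = ","), call. = FALSE)
    }
    if (length(p) > 0 && is_tp[1]) {
      stop("the root level cannot be a timepoint partition: ",
           paste(p, collapse = ","), call. = FALSE)
    }
    if (length(p) > 0 && is_tp[length(p)]) {
      stop("a timepoint level must be followed by at least one label level: ",
           paste(p, collapse = ","), call. = FALSE)
    }
    if (any(p[!is_tp] == UNCLASSIFIED)) {
      stop("the label \"", UNCLASSIFIED,
           "\" is reserved for the rejection output and cannot appear in a hierarchy",
           call. = FALSE)
    }
  }
  # canonical order makes parse -> serialize -> parse idempotent
  paths <- paths[order(keys)]

  nodes <- list()
  build <- function(suffixes, parent_path, depth, timepoint) {
    firsts <- vapply(suffixes, `[`, "", 1L)
    is_tp <- startsWith(firsts, "T:")
    if (any(is_tp) && !all(is_tp)) {
      stop("timepoint and plain labels mixed at one level under parent [",
           paste(parent_path$label, collapse = " > "), "]", call. = FALSE)
    }
    if (all(is_tp)) {
      for (tp in sort(unique(sub("^T:", "", firsts)))) {
        sel <- sub("^T:", "", firsts) == tp
        build(lapply(suffixes[sel], `[`, -1L), parent_path, depth, tp)
      }
      return(invisible(NULL))
    }
    layer_name <- paste0("Layer", depth)
    labels <- sort(unique(firsts))
    id <- sanitize_id(paste(
      c(layer_name, parent_path$label, if (!is.na(timepoint)) timepoint),
      collapse = "_"))
    node <- structure(
      list(id = id, layer_name = layer_name,
           parent_path = parent_path, class_labels = labels,
           timepoint_context = timepoint,
           is_timepoint_partition = !is.na(timepoint),
           depth = depth),
      class = "layer_node")
    nodes[[id]] <<- node
    for (lab in labels) {
      deeper <- suffixes[firsts == lab & lengths(suffixes) > 1L]
      if (length(deeper) > 0) {
        build(lapply(deeper, `[`, -1L),
              rbind(parent_path,
                    data.frame(layer = layer_name, label = lab,
                               stringsAsFactors = FALSE)),
              depth + 1L, timepoint)
      }
    }
    invisible(NULL)
  }
  build(paths, data.frame(layer = character(), label = character(),
                          stringsAsFactors = FALSE), 1L, NA_character_)

  # ambiguity: within one layer + timepoint context a label may appear under
  # only one parent path, otherwise metadata columns cannot be routed
  ctx <- vapply(nodes, function(n)
    paste(n$layer_name, n$timepoint_context, sep = "\r"), "")
  for (cx in unique(ctx)) {
    grp <- nodes[ctx == cx]
    seen <- list()
    for (n in grp) {
      pkey <- paste(n$parent_path$label, collapse = " > ")
      for (lab in n$class_labels) {
        if (!is.null(seen[[lab]]) && !identical(seen[[lab]], pkey)) {
          stop("ambiguous hierarchy: label \"", lab, "\" in ", n$layer_name,
               " appears under both parents [", seen[[lab]], "] and [",
               pkey, "]", call. = FALSE)
        }
        seen[[lab]] <- pkey
      }
    }
  }

  depths <- vapply(nodes, `[[`, 1L, "depth")
  structure(
    list(root_layer_name = "Layer1",
         nodes = nodes,
         paths = paths,
         max_depth = max(depths),
         layer_names = paste0("Layer", seq_len(max(depths))),
         has_timepoints = any(vapply(nodes, `[[`, TRUE, "is_timepoint_partition"))),
    class = "annotation_hierarchy")
}

#' @export
print.annotation_hierarchy <- function(x, ...) {
  cat(sprintf("<annotation_hierarchy> %d layers, %d layer nodes, %d leaf paths%s\n",
              x$max_depth, length(x$nodes), length(x$paths),
              if (x$has_timepoints) ", timepoint-partitioned" else ""))
  for (n in layers_in_training_order(x)) {
    cat(sprintf("  %s%s [%s]%s\n",
                strrep("  ", n$depth - 1L), n$id,
                paste(n$class_labels, collapse = ", "),
                if (n$is_timepoint_partition)
                  paste0(" @", n$timepoint_context) else ""))
  }
  invisible(x)
}

#' Serialize an annotation hierarchy back to its CSV form
#'
#' Writes one root-to-leaf path per row with `T:` timepoint markers
#' reinstated; `parse_hierarchy(write_hierarchy(h, f))` reproduces `h`.
#'
#' @param h an `annotation_hierarchy`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_hierarchy <- function(h, path) {
  stopifnot(inherits(h, "annotation_hierarchy"))
  width <- max(lengths(h$paths))
  rows <- vapply(h$paths, function(p)
    paste(c(p, rep("", width - length(p))), collapse = ","), "")
  writeLines(rows, path)
  invisible(path)
}

#' Layer nodes in training order
#'
#' Breadth-first over the hierarchy: parents always precede children, ties
#' broken lexicographically (layer name, then parent path, then timepoint),
#' so the order is deterministic across runs.
#'
#' @param h an `annotation_hierarchy`.
#' @return list of `layer_node` objects.
#' @export
layers_in_training_order <- function(h) {
  stopifnot(inherits(h, "annotation_hierarchy"))
  nodes <- h$nodes
  key <- vapply(nodes, function(n)
    paste(sprintf("%04d", n$depth), n$layer_name,
          paste(n$parent_path$label, collapse = "\r"),
          n$timepoint_context, sep = "\r"), "")
  nodes[order(key)]
}

# Child nodes of `node` routed through class label `label`.
child_nodes <- function(h, node, label) {
  want <- c(node$parent_path$label, label)
  Filter(function(n) {
    identical(n$parent_path$label, want) &&
      (is.na(node$timepoint_context) ||
         identical(n$timepoint_context, node$timepoint_context))
  }, h$nodes)
}

root_node <- function(h) {
  h$nodes[[which(vapply(h$nodes, function(n) nrow(n$parent_path) == 0L, TRUE))[1]]]
}

# All timepoint values referenced anywhere in the hierarchy.
hierarchy_timepoints <- function(h) {
  sort(unique(stats::na.omit(vapply(h$nodes, `[[`, "", "timepoint_context"))))
}

#' Validate per-cell metadata against a hierarchy
#'
#' Checks that every cell's labels trace a prefix of exactly one root-to-leaf
#' path: the root label must exist in the hierarchy, each deeper label must
#' be a class of the layer node its parent label (and timepoint, for
#' partitioned layers) routes to, and a blank simply means the cell is not in
#' that branch. Labels in layers the cell's branch never reaches are flagged.
#'
#' @param h an `annotation_hierarchy`.
#' @param md data.frame of cell metadata with a `cell_id` column, one column
#'   per hierarchy layer, and a `Timepoint` column when the hierarchy is
#'   timepoint-partitioned.
#' @return data.frame with columns `cell_id`, `layer`, `label`, `problem`;
#'   zero rows iff the metadata is fully consistent.
#' @export
validate_metadata <- function(h, md) {
  stopifnot(inherits(h, "annotation_hierarchy"), is.data.frame(md))
  need <- c("cell_id", h$layer_names, if (h$has_timepoints) "Timepoint")
  missing_cols <- setdiff(need, names(md))
  if (length(missing_cols) > 0) {
    stop("metadata is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  blank <- function(x) is.na(x) | !nzchar(trimws(as.character(x)))
  bad <- list()
  note <- function(cell, layer, label, problem) {
    bad[[length(bad) + 1L]] <<- data.frame(
      cell_id = cell, layer = layer, label = label, problem = problem,
      stringsAsFactors = FALSE)
  }
  root <- root_node(h)
  for (i in seq_len(nrow(md))) {
    cell <- md$cell_id[i]
    tp <- if (h$has_timepoints) as.character(md$Timepoint[i]) else NA_character_
    consumed <- character()
    node <- root
    repeat {
      lab <- as.character(md[[node$layer_name]][i])
      if (blank(lab)) {
        if (node$layer_name == h$root_layer_name) {
          note(cell, node$layer_name, "", "blank label at the root layer")
        }
        break
      }
      consumed <- c(consumed, node$layer_name)
      if (identical(lab, UNCLASSIFIED)) {
        note(cell, node$layer_name, lab, "reserved label used as annotation")
        break
      }
      if (!(lab %in% node$class_labels)) {
        note(cell, node$layer_name, lab,
             paste0("label not found under parent [",
                    paste(node$parent_path$label, collapse = " > "), "]"))
        break
      }
      kids <- child_nodes(h, node, lab)
      if (length(kids) == 0) break
      tps <- vapply(kids, `[[`, "", "timepoint_context")
      if (all(is.na(tps))) {
        node <- kids[[1]]
      } else {
        hit <- which(tps == tp)
        if (length(hit) == 0) break  # branch has no sublayer at this timepoint
        node <- kids[[hit[1]]]
      }
    }
    stray <- setdiff(h$layer_names[!blank(unlist(md[i, h$layer_names]))], consumed)
    for (ly in stray) {
      note(cell, ly, as.character(md[[ly]][i]),
           "label present in a layer outside the cell's branch")
    }
  }
  if (length(bad) == 0) {
    data.frame(cell_id = character(), layer = character(),
               label = character(), problem = character(),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, bad)
  }
}
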