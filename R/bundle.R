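BUNDLE_FORMAT_VERSION <- "1.0"

new_layer_object <- function(node, feature_list, label_codes, model,
                             hyperparams, n_training_cells,
                             constant_label = NULL) {
  structure(
    list(node = node, feature_list = feature_list, label_codes = label_codes,
         model = model, hyperparams = hyperparams,
         n_training_cells = n_training_cells,
         constant_label = constant_label),
    class = "layer_object")
}

is_constant_layer <- function(lo) !is.null(lo$constant_label)

#' @export
print.layer_object <- function(x, ...) {
  cat(sprintf("<layer_object> %s: %d classes [%s], %d features, %d training cells%s\n",
              x$node$id, length(x$label_codes),
              paste(names(x$label_codes), collapse = ", "),
              length(x$feature_list), x$n_training_cells,
              if (is_constant_layer(x)) " (constant)" else ""))
  invisible(x)
}

new_model_bundle <- function(hierarchy, layer_objects, training_seed,
                             rejection_threshold_default = 0.5) {
  structure(
    list(hierarchy = hierarchy, layer_objects = layer_objects,
         format_version = BUNDLE_FORMAT_VERSION,
         training_seed = as.integer(training_seed),
         rejection_threshold_default = rejection_threshold_default),
    class = "model_bundle")
}

#' @export
print.model_bundle <- function(x, ...) {
  cat(sprintf("<model_bundle> format %s, %d layer objects, seed %d, threshold %.2f\n",
              x$format_version, length(x$layer_objects), x$training_seed,
              x$rejection_threshold_default))
  invisible(x)
}

node_to_list <- function(node) {
  list(id = node$id, layer_name = node$layer_name,
       parent_layers = as.list(node$parent_path$layer),
       parent_labels = as.list(node$parent_path$label),
       class_labels = as.list(node$class_labels),
       timepoint_context = if (is.na(node$timepoint_context)) NULL else node$timepoint_context,
       depth = node$depth)
}

node_from_list <- function(x) {
  structure(
    list(id = x$id, layer_name = x$layer_name,
         parent_path = data.frame(layer = unlist(x$parent_layers) %||% character(),
                                  label = unlist(x$parent_labels) %||% character(),
                                  stringsAsFactors = FALSE),
         class_labels = unlist(x$class_labels),
         timepoint_context = x$timepoint_context %||% NA_character_,
         is_timepoint_partition = !is.null(x$timepoint_context),
         depth = as.integer(x$depth)),
    class = "layer_node")
}

#' Save a trained model bundle to a directory
#'
#' Writes a JSON manifest (hierarchy, per-layer feature lists, label codes,
#' hyperparameters, seed, default rejection threshold) plus one model
#' artifact per layer object. Individual layer objects can later be loaded
#' standalone by name with [load_layer_object()].
#'
#' @param bundle a `model_bundle` from [train_all()].
#' @param dir output directory (created if absent).
#' @return the manifest path, invisibly.
#' @export
save_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "model_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  layers <- lapply(bundle$layer_objects, function(lo) {
    entry <- list(
      node = node_to_list(lo$node),
      feature_list = as.list(lo$feature_list),
      label_codes = as.list(setNames(as.integer(lo$label_codes),
                                     names(lo$label_codes))),
      hyperparams = lo$hyperparams,
      n_training_cells = lo$n_training_cells,
      constant_label = lo$constant_label)
    if (!is_constant_layer(lo)) {
      fname <- paste0(lo$node$id, ".model.ubj")
      xgboost::xgb.save(lo$model, file.path(dir, fname))
      entry$model_file <- fname
    }
    entry
  })
  manifest <- list(
    format_version = bundle$format_version,
    training_seed = bundle$training_seed,
    rejection_threshold_default = bundle$rejection_threshold_default,
    hierarchy_paths = bundle$hierarchy$paths,
    layers = layers)
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(manifest_path)
}

read_manifest <- function(dir) {
  manifest_path <- file.path(dir, "manifest.json")
  if (!file.exists(manifest_path)) {
    stop("no manifest.json in bundle directory: ", dir, call. = FALSE)
  }
  manifest <- tryCatch(
    jsonlite::read_json(manifest_path),
    error = function(e) stop("corrupted bundle manifest: ", conditionMessage(e),
                             call. = FALSE))
  if (!identical(manifest$format_version, BUNDLE_FORMAT_VERSION)) {
    stop("unsupported bundle format version \"", manifest$format_version,
         "\" (this build reads version ", BUNDLE_FORMAT_VERSION, ")",
         call. = FALSE)
  }
  manifest
}

layer_from_entry <- function(entry, dir) {
  model <- NULL
  if (!is.null(entry$model_file)) {
    mf <- file.path(dir, entry$model_file)
    if (!file.exists(mf)) stop("missing model artifact: ", mf, call. = FALSE)
    model <- xgboost::xgb.load(mf)
  }
  codes <- unlist(entry$label_codes)
  new_layer_object(
    node = node_from_list(entry$node),
    feature_list = unlist(entry$feature_list),
    label_codes = setNames(as.integer(codes), names(codes)),
    model = model,
    hyperparams = entry$hyperparams,
    n_training_cells = as.integer(entry$n_training_cells),
    constant_label = entry$constant_label)
}

#' Load a trained model bundle
#'
#' @param dir directory written by [save_bundle()].
#' @return a `model_bundle`.
#' @export
load_bundle <- function(dir) {
  manifest <- read_manifest(dir)
  hierarchy <- hierarchy_from_paths(
    lapply(manifest$hierarchy_paths, function(p) unlist(p)))
  layer_objects <- lapply(manifest$layers, layer_from_entry, dir = dir)
  names(layer_objects) <- vapply(layer_objects, function(lo) lo$node$id, "")
  bundle <- new_model_bundle(hierarchy, layer_objects,
                             manifest$training_seed,
                             manifest$rejection_threshold_default)
  bundle$format_version <- manifest$format_version
  bundle
}

#' Load a single layer object standalone
#'
#' Layer objects are portable: one layer's classifier can be loaded without
#' the rest of the bundle and used with [predict_layer()].
#'
#' @param dir bundle directory.
#' @param name the layer object id (e.g. `"Layer2_Cardiomyocytes_E10.5"`).
#' @return a `layer_object`.
#' @export
load_layer_object <- function(dir, name) {
  manifest <- read_manifest(dir)
  ids <- vapply(manifest$layers, function(e) e$node$id, "")
  hit <- which(ids == name)
  if (length(hit) == 0) {
    stop("no layer object named \"", name, "\" in bundle (available: ",
         paste(ids, collapse = ", "), ")", call. = FALSE)
  }
  layer_from_entry(manifest$layers[[hit[1]]], dir)
}
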