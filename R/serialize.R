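## Lossless model serialization as self-describing JSON: schema, control,
## and recursive node records. Used both for single trees and for the
## aggregated global model (per-label tree documents plus the label order).

node_to_list <- function(node) {
  out <- list(class_counts = node$class_counts,
              prune_counts = node$prune_counts,
              predicted = node$predicted, depth = node$depth)
  if (!is.null(node$split)) {
    out$split <- node$split[!vapply(node$split, is.null, NA)]
    out$heaviest <- node$heaviest
    out$children <- lapply(node$children, node_to_list)
  }
  out
}

node_from_list <- function(x) {
  node <- list(split = NULL, children = list(),
               class_counts = as.numeric(x$class_counts),
               prune_counts = as.numeric(x$prune_counts),
               predicted = as.integer(x$predicted),
               depth = as.integer(x$depth))
  if (!is.null(x$split)) {
    node$split <- list(feature = x$split$feature, type = x$split$type,
                       threshold = x$split$threshold,
                       categories = if (!is.null(x$split$categories))
                         as.character(x$split$categories) else NULL)
    node$heaviest <- as.integer(x$heaviest)
    node$children <- lapply(x$children, node_from_list)
  }
  node
}

feature_to_list <- function(f) {
  list(name = f$name, kind = f$kind, categories = f$categories, role = f$role)
}

feature_from_list <- function(x) {
  feature_spec(x$name, kind = x$kind,
               categories = as.character(x$categories %||% character()),
               role = x$role)
}

label_to_list <- function(l) {
  list(name = l$name, classes = l$classes, positive = l$positive)
}

label_from_list <- function(x) {
  label_spec(x$name, as.character(x$classes), positive = x$positive)
}

reptree_to_list <- function(model) {
  list(format = "fmll-reptree", version = 1L,
       target = label_to_list(model$target), mode = model$mode,
       classes = model$classes,
       control = unclass(model$control),
       features = lapply(model$features, feature_to_list),
       n_train = model$n_train,
       root = node_to_list(model$root))
}

reptree_from_list <- function(x) {
  ctl <- x$control
  control <- reptree_control(max_depth = ctl$max_depth, min_num = ctl$min_num,
                             min_variance_prop = ctl$min_variance_prop,
                             no_pruning = ctl$no_pruning,
                             num_folds = ctl$num_folds, seed = ctl$seed,
                             initial_count = ctl$initial_count,
                             spread_initial_count = ctl$spread_initial_count,
                             num_decimal_places = ctl$num_decimal_places,
                             ordinal_as_nominal = isTRUE(ctl$ordinal_as_nominal))
  structure(list(root = node_from_list(x$root), control = control,
                 classes = as.character(x$classes),
                 target = label_from_list(x$target), mode = x$mode,
                 features = lapply(x$features, feature_from_list),
                 n_train = as.integer(x$n_train)),
            class = "reptree")
}

#' Write / read a fitted model as JSON
#'
#' Both single [reptree()] models and aggregated [fmll()] global models are
#' written as self-describing JSON documents with a lossless round trip
#' (values at full double precision).
#'
#' @param model A `reptree` or `fmll` object.
#' @param path Output path.
#' @return `write_fmll_model()` returns `path` invisibly; `read_fmll_model()`
#'   returns the reconstructed model object.
#' @export
write_fmll_model <- function(model, path) {
  doc <- if (inherits(model, "reptree")) reptree_to_list(model)
         else if (inherits(model, "fmll")) fmll_to_list(model)
         else stop_fmll("unsupported model class")
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_fmll_model
#' @export
read_fmll_model <- function(path) {
  if (!file.exists(path)) stop_fmll("model file not found: %s", path)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  switch(doc$format %||% "",
         "fmll-reptree" = reptree_from_list(doc),
         "fmll-global" = fmll_from_list(doc),
         stop_fmll("not a recognised model document: %s", path))
}
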