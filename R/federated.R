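## Simulated client/server federation. Binary Relevance assigns one client
## per label: client j stores only its own single-target dataset D_yj and
## trains a local REPTree M_j. The server receives the q local models (never
## raw rows) and aggregates them by pure union into the global model
## G = U_j M_j, keyed and ordered by the dataset's label order. Prediction
## concatenates the per-label outputs.

#' Prepare one client node per label
#'
#' Runs the Binary Relevance decomposition and hands client j the j-th
#' single-target dataset. Clients are isolated: no client holds another
#' client's data or model.
#'
#' @param dataset A [multilabel_dataset()].
#' @param mode Decomposition mode, as in [br_decompose()].
#' @return A list of `q` `client_node` objects in label order, each with
#'   fields `index`, `label`, `local_data`, and `local_model` (`NULL` until
#'   trained).
#' @export
client_prepare <- function(dataset, mode = c("strict_binary", "per_label")) {
  mode <- match.arg(mode)
  parts <- br_decompose(dataset, mode)
  clients <- lapply(seq_along(parts), function(j) {
    structure(list(index = j, label = parts[[j]]$source_label,
                   local_data = parts[[j]], local_model = NULL),
              class = "client_node")
  })
  names(clients) <- names(parts)
  clients
}

#' Train one client's local model
#'
#' @param client A `client_node` from [client_prepare()].
#' @param control A [reptree_control()]. Clients share no mutable state, so
#'   they are trainable in any order (or concurrently) with identical
#'   results.
#' @return The client with `local_model` set to the fitted [reptree()].
#' @export
client_train <- function(client, control = reptree_control()) {
  stopifnot(inherits(client, "client_node"))
  client$local_model <- reptree(client$local_data, control)
  client
}

#' @export
print.client_node <- function(x, ...) {
  cat(sprintf("Client %d for label '%s': %d local rows, model %s\n",
              x$index, x$label$name, nrow(x$local_data$data),
              if (is.null(x$local_model)) "not trained" else "trained"))
  invisible(x)
}

#' Aggregate local models into the global model
#'
#' The aggregation is a pure union: the received models are stored unchanged,
#' keyed and ordered by `label_order` regardless of arrival order.
#'
#' @param models A list of fitted [reptree()] models, one per label, in any
#'   order.
#' @param label_order List of [label_spec()] objects (or character names)
#'   fixing the label order of the global model.
#' @return An `fmll_global` object: `$models` (label-keyed list) and
#'   `$label_order`.
#' @export
server_aggregate <- function(models, label_order) {
  lab_names <- if (is.character(label_order)) label_order
               else vapply(label_order, `[[`, "", "name")
  got <- vapply(models, function(m) m$target$name, "")
  if (anyDuplicated(got))
    stop_fmll("duplicate model(s) for label(s): %s",
              paste(unique(got[duplicated(got)]), collapse = ", "))
  absent <- setdiff(lab_names, got)
  if (length(absent))
    stop_fmll("missing model(s) for label(s): %s", paste(absent, collapse = ", "))
  extra <- setdiff(got, lab_names)
  if (length(extra))
    stop_fmll("model(s) for undeclared label(s): %s", paste(extra, collapse = ", "))
  ordered <- models[match(lab_names, got)]
  names(ordered) <- lab_names
  labels <- if (is.character(label_order)) lapply(ordered, `[[`, "target")
            else label_order
  structure(list(models = ordered, label_order = labels),
            class = "fmll_global")
}

#' Fit a federated multi-label model
#'
#' End-to-end Binary Relevance federation: one client per label is prepared
#' ([client_prepare()]), each trains a local REPTree ([client_train()]), and
#' the server aggregates the local models into the global model
#' ([server_aggregate()]).
#'
#' @param dataset A [multilabel_dataset()].
#' @param mode `"auto"` (the default) uses `"strict_binary"` when every label
#'   is binary and `"per_label"` otherwise.
#' @param control A [reptree_control()].
#' @return An `fmll` object with print, summary and predict methods.
#' @seealso [predict.fmll()], [cv_fmll()]
#' @export
fmll <- function(dataset, mode = c("auto", "strict_binary", "per_label"),
                 control = reptree_control()) {
  stopifnot(inherits(dataset, "multilabel_dataset"))
  mode <- match.arg(mode)
  if (mode == "auto") {
    all_binary <- all(vapply(dataset$labels, `[[`, NA, "is_binary"))
    mode <- if (all_binary) "strict_binary" else "per_label"
  }
  clients <- client_prepare(dataset, mode)
  clients <- lapply(clients, client_train, control = control)
  global <- server_aggregate(lapply(clients, `[[`, "local_model"),
                             dataset$labels)
  structure(list(global = global, mode = mode, labels = dataset$labels,
                 features = dataset$features, control = control,
                 dataset_name = dataset$name, n_train = nrow(dataset$data),
                 call = match.call()),
            class = "fmll")
}

#' Predict label sets from a federated multi-label model
#'
#' Each label's local model predicts independently and the outputs are
#' concatenated in label order. For a strict-binary model, a label belongs to
#' the predicted label set iff its client outputs the positive class.
#'
#' @param object An [fmll()] model.
#' @param newdata A data.frame or [multilabel_dataset()] with the training
#'   feature columns.
#' @param type `"class"` (default): a data.frame with one predicted class
#'   column per label. `"labelset"`: a list of character vectors, each the
#'   predicted label set Y-hat of one row (only for strict-binary models).
#'   `"prob"`: a list of per-label probability matrices.
#' @param ... Unused.
#' @export
predict.fmll <- function(object, newdata,
                         type = c("class", "labelset", "prob"), ...) {
  type <- match.arg(type)
  df <- if (inherits(newdata, "multilabel_dataset")) newdata$data
        else as.data.frame(newdata)
  models <- object$global$models
  if (type == "prob")
    return(lapply(models, predict, newdata = df, type = "prob"))
  cls <- lapply(models, predict, newdata = df, type = "class")
  if (type == "class") {
    out <- as.data.frame(cls, check.names = FALSE, optional = TRUE)
    names(out) <- names(models)
    return(out)
  }
  if (object$mode != "strict_binary")
    stop_fmll("label sets are only defined for strict-binary models")
  pos <- vapply(object$labels, function(l) {
    m <- models[[l$name]]
    ## strict binary targets are coded "0"/"1"
    "1"
  }, "")
  n <- nrow(df)
  lab_names <- names(models)
  lapply(seq_len(n), function(i) {
    present <- vapply(seq_along(models),
                      function(j) cls[[j]][i] == pos[j], NA)
    lab_names[present]
  })
}

#' @export
print.fmll <- function(x, ...) {
  cat(sprintf("Federated multi-label model '%s' (%s mode)\n",
              x$dataset_name, x$mode))
  cat(sprintf("  %d client models over %d training rows\n",
              length(x$global$models), x$n_train))
  for (m in x$global$models)
    cat(sprintf("  %-24s %3d nodes, depth %d\n", m$target$name,
                count_nodes(m$root), tree_depth(m$root)))
  invisible(x)
}

#' @export
summary.fmll <- function(object, ...) {
  tab <- data.frame(
    label = names(object$global$models),
    classes = vapply(object$global$models, function(m) length(m$classes), 0L),
    nodes = vapply(object$global$models, function(m) count_nodes(m$root), 0L),
    leaves = vapply(object$global$models, function(m) count_leaves(m$root), 0L),
    depth = vapply(object$global$models, function(m) tree_depth(m$root), 0L),
    row.names = NULL)
  structure(list(dataset = object$dataset_name, mode = object$mode,
                 n_train = object$n_train, trees = tab),
            class = "summary.fmll")
}

#' @export
print.summary.fmll <- function(x, ...) {
  cat(sprintf("FMLL model on '%s' (%s, %d rows)\n", x$dataset, x$mode, x$n_train))
  print(x$trees, row.names = FALSE)
  invisible(x)
}

fmll_to_list <- function(model) {
  list(format = "fmll-global", version = 1L, mode = model$mode,
       dataset_name = model$dataset_name, n_train = model$n_train,
       label_order = vapply(model$labels, `[[`, "", "name"),
       labels = lapply(model$labels, label_to_list),
       features = lapply(model$features, feature_to_list),
       control = unclass(model$control),
       models = lapply(model$global$models, reptree_to_list))
}

fmll_from_list <- function(x) {
  models <- lapply(x$models, reptree_from_list)
  labels <- lapply(x$labels, label_from_list)
  global <- server_aggregate(models, labels)
  ctl <- models[[1L]]$control
  structure(list(global = global, mode = x$mode, labels = labels,
                 features = lapply(x$features, feature_from_list),
                 control = ctl, dataset_name = x$dataset_name,
                 n_train = as.integer(x$n_train), call = NULL),
            class = "fmll")
}
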