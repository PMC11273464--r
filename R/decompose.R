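## Binary Relevance decomposition: the multi-label training set D is turned
## into q single-target sets D_yj, one per label, each keeping all N rows and
## the full feature schema. In strict binary mode the j-th target is 1 when
## y_j is in the sample's label set and 0 otherwise; per-label mode keeps the
## label's (possibly multi-class) value as the target.

#' Decompose a multi-label dataset into per-label single-target datasets
#'
#' @param dataset A [multilabel_dataset()].
#' @param mode `"strict_binary"` (targets in \{0,1\}; every label must be
#'   binary) or `"per_label"` (target is the label's class value, admitting
#'   multi-class labels).
#' @return A list of `q` `single_target_dataset` objects, in label order.
#'   Each holds the parent's feature schema, a feature-only data.frame with
#'   all N rows, and a `target` vector (integer 0/1 in strict binary mode,
#'   character class values otherwise).
#' @export
br_decompose <- function(dataset, mode = c("strict_binary", "per_label")) {
  stopifnot(inherits(dataset, "multilabel_dataset"))
  mode <- match.arg(mode)
  fnames <- vapply(dataset$features, `[[`, "", "name")
  fdata <- dataset$data[, fnames, drop = FALSE]
  out <- lapply(dataset$labels, function(l) {
    v <- dataset$data[[l$name]]
    if (mode == "strict_binary") {
      if (!l$is_binary)
        stop_fmll("strict_binary decomposition requires binary labels; '%s' has %d classes",
                  l$name, length(l$classes))
      target <- as.integer(v == l$positive)
      target_classes <- c("0", "1")
    } else {
      target <- as.character(v)
      target_classes <- l$classes
    }
    structure(list(source_label = l, features = dataset$features,
                   data = fdata, target = target,
                   target_classes = target_classes, mode = mode),
              class = "single_target_dataset")
  })
  names(out) <- vapply(dataset$labels, `[[`, "", "name")
  out
}

#' @export
print.single_target_dataset <- function(x, ...) {
  cat(sprintf("Single-target dataset for label '%s' (%s): %d rows, %d features\n",
              x$source_label$name, x$mode, nrow(x$data), length(x$features)))
  invisible(x)
}

## target as character class values regardless of mode
target_values <- function(stds) {
  if (stds$mode == "strict_binary") as.character(stds$target) else stds$target
}
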