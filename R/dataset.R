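## Multi-label dataset model: feature schema, label schema, rows.
##
## A multi-label training set D holds N samples (x_i, Y_i): a K-place feature
## vector plus a label assignment for each of q labels y_1..y_q. Binary labels
## carry a designated "present" class so a sample's label set Y_i is the set
## of binary labels whose value equals their positive class.

FEATURE_KINDS <- c("numeric", "nominal", "ordinal")
COLUMN_ROLES <- c("input", "identifier", "excluded", "target")

#' Declare one feature column of a multi-label dataset
#'
#' @param name Column name.
#' @param kind One of `"numeric"`, `"nominal"`, `"ordinal"`. Nominal and
#'   ordinal features enumerate their categories; ordinal categories are kept
#'   in their declared (rank) order and by default offered to the tree as
#'   numeric split candidates on that rank.
#' @param categories Character vector of category values (empty for numeric).
#' @param role `"input"` features reach the learner; `"identifier"` and
#'   `"excluded"` columns are retained in the data but never used for
#'   splitting.
#' @return A `feature_spec` object.
#' @export
feature_spec <- function(name, kind = "numeric", categories = character(),
                         role = "input") {
  kind <- match.arg(kind, FEATURE_KINDS)
  role <- match.arg(role, COLUMN_ROLES)
  if (!is_string(name)) stop_fmll("feature name must be a single string")
  categories <- as.character(categories)
  if (kind == "numeric" && length(categories))
    stop_fmll("numeric feature '%s' must not declare categories", name)
  if (kind != "numeric") {
    if (!length(categories))
      stop_fmll("%s feature '%s' needs at least one category", kind, name)
    if (anyDuplicated(categories))
      stop_fmll("duplicate categories in feature '%s'", name)
  }
  structure(list(name = name, kind = kind, categories = categories,
                 role = role), class = "feature_spec")
}

#' Declare one label of a multi-label dataset
#'
#' @param name Label name (one of the y_j in L = \{y_1..y_q\}).
#' @param classes Character vector of at least two distinct class values, in
#'   declaration order.
#' @param positive For binary labels, the class meaning "label present"
#'   (default: the second declared class, so `c("0","1")` reads naturally).
#' @return A `label_spec` object; `$is_binary` is `TRUE` iff exactly two
#'   classes are declared.
#' @export
label_spec <- function(name, classes, positive = NULL) {
  if (!is_string(name)) stop_fmll("label name must be a single string")
  classes <- as.character(classes)
  if (length(classes) < 2L || anyDuplicated(classes))
    stop_fmll("label '%s' needs >= 2 distinct classes", name)
  is_binary <- length(classes) == 2L
  if (is_binary) {
    positive <- positive %||% classes[2L]
    if (!positive %in% classes)
      stop_fmll("positive class '%s' is not a class of label '%s'",
                positive, name)
  } else positive <- NULL
  structure(list(name = name, classes = classes, is_binary = is_binary,
                 positive = positive), class = "label_spec")
}

#' Assemble a multi-label dataset
#'
#' @param data A data.frame holding one column per declared feature and label.
#'   Feature cells may be `NA` (missing); label cells must not be.
#' @param features List of [feature_spec()] objects (K input features plus any
#'   identifier/excluded columns).
#' @param labels List of [label_spec()] objects (q >= 1 labels, in the order
#'   that fixes client indexing and report rows).
#' @param name Dataset name used in reports.
#' @return A `multilabel_dataset` object.
#' @export
multilabel_dataset <- function(data, features, labels, name = "dataset") {
  stopifnot(is.data.frame(data))
  if (!length(labels)) stop_fmll("at least one label is required")
  if (!nrow(data)) stop_fmll("dataset must contain at least one row")
  features <- lapply(features, function(f) {
    if (!inherits(f, "feature_spec")) stop_fmll("features must be feature_spec objects")
    f
  })
  labels <- lapply(labels, function(l) {
    if (!inherits(l, "label_spec")) stop_fmll("labels must be label_spec objects")
    l
  })
  fnames <- vapply(features, `[[`, "", "name")
  lnames <- vapply(labels, `[[`, "", "name")
  names(features) <- fnames
  names(labels) <- lnames
  if (anyDuplicated(c(fnames, lnames)))
    stop_fmll("duplicate column names in schema")
  missing_cols <- setdiff(c(fnames, lnames), names(data))
  if (length(missing_cols))
    stop_fmll("column(s) absent from data: %s", paste(missing_cols, collapse = ", "))
  ## coerce feature columns to their declared kinds
  for (f in features) {
    v <- data[[f$name]]
    if (f$kind == "numeric") {
      v <- suppressWarnings(as.numeric(as.character(v)))
      data[[f$name]] <- v
    } else {
      v <- as.character(v)
      bad <- !is.na(v) & !v %in% f$categories
      if (any(bad))
        stop_fmll("feature '%s' has value(s) outside declared categories: %s",
                  f$name, paste(unique(v[bad]), collapse = ", "))
      data[[f$name]] <- v
    }
  }
  for (l in labels) {
    v <- as.character(data[[l$name]])
    if (anyNA(v)) stop_fmll("label '%s' has missing values", l$name)
    bad <- !v %in% l$classes
    if (any(bad))
      stop_fmll("label '%s' has value(s) outside declared classes: %s",
                l$name, paste(unique(v[bad]), collapse = ", "))
    data[[l$name]] <- v
  }
  structure(list(data = data[, c(fnames, lnames), drop = FALSE],
                 features = features, labels = labels, name = name),
            class = "multilabel_dataset")
}

## input features only (role == "input")
input_features <- function(x) {
  x$features[vapply(x$features, function(f) f$role == "input", NA)]
}

#' @export
dim.multilabel_dataset <- function(x) {
  c(nrow(x$data), length(input_features(x)), length(x$labels))
}

#' @export
print.multilabel_dataset <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("Multi-label dataset '%s': %d samples, %d input features, %d labels\n",
              x$name, d[1], d[2], d[3]))
  for (l in x$labels)
    cat(sprintf("  label %-20s %d classes%s\n", l$name, length(l$classes),
                if (l$is_binary) sprintf(" (positive: %s)", l$positive) else ""))
  invisible(x)
}

#' Summary statistics of a numeric feature
#'
#' Reports minimum, maximum, mean, mode, sample (n-1) standard deviation and
#' the missing-cell count of one numeric feature, computed over non-missing
#' values. The mode is the most frequent value; when every value is unique it
#' is reported as absent (`NA`), the convention used for feature tables whose
#' mode column prints "No".
#'
#' @param dataset A [multilabel_dataset()].
#' @param feature Name of a numeric feature.
#' @return A `feature_summary` list with fields `name`, `min`, `max`, `mean`,
#'   `mode`, `std`, `n_missing`.
#' @export
summarize_feature <- function(dataset, feature) {
  stopifnot(inherits(dataset, "multilabel_dataset"))
  f <- NULL
  for (fs in dataset$features) if (fs$name == feature) f <- fs
  if (is.null(f)) stop_fmll("unknown feature '%s'", feature)
  if (f$kind != "numeric") stop_fmll("feature '%s' is not numeric", feature)
  v <- dataset$data[[feature]]
  n_missing <- sum(is.na(v))
  v <- v[!is.na(v)]
  if (!length(v)) stop_fmll("feature '%s' has no non-missing values", feature)
  tab <- table(v)
  mode <- if (max(tab) > 1L) as.numeric(names(tab)[which.max(tab)]) else NA_real_
  structure(list(name = feature, min = min(v), max = max(v), mean = mean(v),
                 mode = mode, std = if (length(v) > 1L) stats::sd(v) else 0,
                 n_missing = n_missing),
            class = "feature_summary")
}

#' @export
print.feature_summary <- function(x, ...) {
  cat(sprintf("%s: min %g, max %g, mean %g, mode %s, sd %g (%d missing)\n",
              x$name, x$min, x$max, x$mean,
              if (is.na(x$mode)) "none" else format(x$mode), x$std, x$n_missing))
  invisible(x)
}
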