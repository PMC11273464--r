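## Stratified k-fold cross-validation of the federated pipeline, and the
## per-label report (one metric row per label plus an unweighted Average
## row): Accuracy (percent), Precision, TNR, ROC, PRC, Recall, F-Score.

#' Stratified k-fold index partition
#'
#' Indices are shuffled per class under the seed and dealt round-robin with a
#' single global fold cursor, so fold sizes differ by at most one (the first
#' `n %% k` folds are larger) and every class's per-fold count deviates from
#' exact proportionality by at most one instance.
#'
#' @param target Class values of the n instances (stratification variable).
#' @param k Number of folds (`2 <= k <= n`).
#' @param seed Integer seed.
#' @return A list of `k` integer index vectors partitioning `1..n`.
#' @export
stratified_folds <- function(target, k, seed = 1L) {
  n <- length(target)
  k <- as.integer(k)
  if (k < 2L) stop_fmll("k must be >= 2")
  if (k > n) stop_fmll("k = %d exceeds the number of instances (%d)", k, n)
  target <- as.character(target)
  folds <- vector("list", k)
  with_seed(seed, {
    cursor <- 0L
    for (cl in unique(target)) {
      idx <- which(target == cl)
      idx <- if (length(idx) > 1L) sample(idx) else idx
      for (i in idx) {
        f <- cursor %% k + 1L
        folds[[f]] <- c(folds[[f]], i)
        cursor <- cursor + 1L
      }
    }
  })
  lapply(folds, sort)
}

#' Unweighted mean of per-label values
#'
#' The arithmetic used by the report's Average row (macro-averaging over
#' labels). Rounding happens only at rendering.
#'
#' @param values Non-empty numeric vector.
#' @return The arithmetic mean.
#' @export
macro_average <- function(values) {
  if (!length(values)) stop_fmll("macro_average of empty input")
  mean(as.numeric(values))
}

## a curve area undefined on a single-class truth degrades to 0.5 (chance
## ordering) with a warning, keeping reports total like the other ratios
auc_or_chance <- function(fun, truth, scores) {
  tryCatch(fun(truth, scores), error = function(e) {
    warning(conditionMessage(e), "; returning 0.5", call. = FALSE)
    0.5
  })
}

label_metric_row <- function(label, truth, pred, prob, classes, mode) {
  if (mode == "strict_binary") {
    m <- binary_metrics(confusion_counts(truth == "1", pred == "1"))
    roc <- auc_or_chance(roc_auc, truth == "1", prob[, "1"])
    prc <- auc_or_chance(prc_auc, truth == "1", prob[, "1"])
  } else {
    m <- multiclass_metrics(truth, pred, classes)
    roc <- multiclass_auc(truth, prob, classes, roc_auc)
    prc <- multiclass_auc(truth, prob, classes, prc_auc)
  }
  data.frame(Label = label, Accuracy = 100 * m$accuracy,
             Precision = m$precision, TNR = m$tnr, ROC = roc, PRC = prc,
             Recall = m$recall, F_Score = m$f_score,
             stringsAsFactors = FALSE)
}

#' Cross-validate the federated multi-label pipeline
#'
#' For each label, the rows are split by [stratified_folds()] on that label's
#' own target (by default; `shared_folds = TRUE` reuses the first label's
#' partition for all labels). Per fold, the label's client is trained on the
#' training part and predicts the held-out part; test predictions are pooled
#' over the folds and the label's metric row is computed from the pooled
#' predictions. The report's Average row is the unweighted mean of the label
#' rows.
#'
#' @param dataset A [multilabel_dataset()].
#' @param k Number of folds (default 10).
#' @param control A [reptree_control()].
#' @param seed Integer seed for the fold shuffles.
#' @param mode Decomposition mode, as in [fmll()].
#' @param shared_folds Use one shared partition for every label (only
#'   possible when a single stratification target is acceptable).
#' @param pooling `"pooled"` (default) computes each metric once from the
#'   pooled test predictions; `"foldwise"` averages per-fold metric values.
#' @return An `fmll_report`: a data.frame of per-label rows plus an
#'   `"Average"` row, with the pooled predictions attached as attributes.
#' @export
cv_fmll <- function(dataset, k = 10L, control = reptree_control(),
                    seed = 1L, mode = c("auto", "strict_binary", "per_label"),
                    shared_folds = FALSE,
                    pooling = c("pooled", "foldwise")) {
  stopifnot(inherits(dataset, "multilabel_dataset"))
  mode <- match.arg(mode)
  pooling <- match.arg(pooling)
  if (mode == "auto") {
    all_binary <- all(vapply(dataset$labels, `[[`, NA, "is_binary"))
    mode <- if (all_binary) "strict_binary" else "per_label"
  }
  clients <- client_prepare(dataset, mode)
  n <- nrow(dataset$data)
  rows <- list()
  predictions <- list()
  shared <- NULL
  for (j in seq_along(clients)) {
    cl <- clients[[j]]
    stds <- cl$local_data
    truth <- target_values(stds)
    classes <- stds$target_classes
    if (shared_folds) {
      if (is.null(shared)) shared <- stratified_folds(truth, k, seed)
      folds <- shared
    } else folds <- stratified_folds(truth, k, seed)
    pred <- character(n)
    prob <- matrix(NA_real_, n, length(classes),
                   dimnames = list(NULL, classes))
    fold_rows <- vector("list", length(folds))
    for (fi in seq_along(folds)) {
      test_idx <- folds[[fi]]
      train <- stds
      train$data <- stds$data[-test_idx, , drop = FALSE]
      train$target <- stds$target[-test_idx]
      model <- reptree(train, control)
      test_df <- stds$data[test_idx, , drop = FALSE]
      pred[test_idx] <- predict(model, test_df, type = "class")
      prob[test_idx, ] <- predict(model, test_df, type = "prob")
      if (pooling == "foldwise")
        fold_rows[[fi]] <- label_metric_row(cl$label$name, truth[test_idx],
                                            pred[test_idx],
                                            prob[test_idx, , drop = FALSE],
                                            classes, mode)
    }
    row <- if (pooling == "pooled")
      label_metric_row(cl$label$name, truth, pred, prob, classes, mode)
    else {
      agg <- do.call(rbind, fold_rows)
      out <- agg[1L, , drop = FALSE]
      for (col in names(out)[-1L]) out[[col]] <- mean(agg[[col]])
      out
    }
    rows[[j]] <- row
    predictions[[cl$label$name]] <- list(truth = truth, pred = pred,
                                         prob = prob)
  }
  report <- do.call(rbind, rows)
  avg <- report[1L, , drop = FALSE]
  avg$Label <- "Average"
  for (col in names(report)[-1L]) avg[[col]] <- macro_average(report[[col]])
  out <- rbind(report, avg)
  rownames(out) <- NULL
  structure(out, class = c("fmll_report", "data.frame"),
            dataset = dataset$name, k = k, seed = seed, mode = mode,
            pooling = pooling, predictions = predictions)
}

#' @export
print.fmll_report <- function(x, ...) {
  cat(sprintf("FMLL %d-fold cross-validation report for '%s' (%s, seed %d)\n\n",
              attr(x, "k") %||% NA_integer_, attr(x, "dataset") %||% "?",
              attr(x, "mode") %||% "?", attr(x, "seed") %||% NA_integer_))
  print(format_report(x), row.names = FALSE)
  invisible(x)
}

## accuracy rendered with 2 decimals, rates with 3
format_report <- function(report) {
  out <- as.data.frame(report)
  out$Accuracy <- formatC(out$Accuracy, digits = 2, format = "f")
  for (col in c("Precision", "TNR", "ROC", "PRC", "Recall", "F_Score"))
    out[[col]] <- formatC(out[[col]], digits = 3, format = "f")
  names(out)[names(out) == "F_Score"] <- "F-Score"
  out
}

#' Write a cross-validation report as delimited text and JSON
#'
#' The tab-separated file mirrors the on-screen rendering (accuracy at 2
#' decimals, rates at 3, an `Average` row last); the JSON document carries
#' the unrounded values.
#'
#' @param report An `fmll_report` from [cv_fmll()].
#' @param path Output path for the TSV; a `.json` sibling is written next to
#'   it.
#' @return `path`, invisibly.
#' @export
write_fmll_report <- function(report, path) {
  stopifnot(inherits(report, "fmll_report"))
  utils::write.table(format_report(report), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  json_path <- sub("(\\.[a-zA-Z0-9]+)?$", ".json", path)
  doc <- list(dataset = attr(report, "dataset"), k = attr(report, "k"),
              seed = attr(report, "seed"), mode = attr(report, "mode"),
              rows = as.data.frame(report))
  jsonlite::write_json(doc, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
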