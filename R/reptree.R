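## Reduced-error pruning tree (REPTree): a decision tree grown by
## information-gain splitting (numeric thresholds at midpoints between
## consecutive distinct values, multiway splits on nominal categories) and
## simplified by reduced-error pruning against an internal hold-out fold.
## Missing values route to the heaviest child, both in training and at
## prediction time; no fractional instance weighting is used.

#' Control parameters of the REPTree learner
#'
#' Defaults follow the standard REPTree configuration: unlimited depth,
#' minimum of 2 instances per admissible child, 3 internal folds (the first
#' is the pruning hold-out), seed 1, no additive smoothing of leaf
#' distributions, 2 decimal places when rendering.
#'
#' @param max_depth Maximum tree depth; `-1` means unlimited.
#' @param min_num Minimum total instance weight each child of a split must
#'   carry for the split to be admissible.
#' @param min_variance_prop Minimal variance proportion for numeric-target
#'   splits. Carried for configuration fidelity; all targets here are
#'   categorical, so it never affects fitting.
#' @param no_pruning If `TRUE`, grow on all rows and skip pruning.
#' @param num_folds Number of internal folds; fold 0 (1/`num_folds` of the
#'   rows, after a seeded shuffle) is held out for pruning, the rest grow the
#'   tree.
#' @param seed Integer seed for the internal shuffle.
#' @param initial_count Additive smoothing count for leaf class
#'   distributions.
#' @param spread_initial_count If `TRUE`, `initial_count` is spread over the
#'   classes instead of added per class.
#' @param num_decimal_places Decimal places used when rendering thresholds
#'   and counts.
#' @param ordinal_as_nominal If `TRUE`, ordinal features are split multiway
#'   like nominal ones; by default their declared category rank is offered to
#'   the tree as a numeric split candidate, respecting the order.
#' @param ... Tolerated Weka-style keys (`batchSize`, `debug`,
#'   `doNotCheckCapabilities`) are accepted and ignored with a notice; any
#'   other unknown key is an error.
#' @return A `reptree_control` list.
#' @export
reptree_control <- function(max_depth = -1L, min_num = 2.0,
                            min_variance_prop = 0.001, no_pruning = FALSE,
                            num_folds = 3L, seed = 1L, initial_count = 0.0,
                            spread_initial_count = FALSE,
                            num_decimal_places = 2L,
                            ordinal_as_nominal = FALSE, ...) {
  extra <- list(...)
  if (length(extra)) {
    tolerated <- c("batchSize", "debug", "doNotCheckCapabilities")
    unknown <- setdiff(names(extra), tolerated)
    if (length(unknown))
      stop_fmll("unknown control parameter(s): %s", paste(unknown, collapse = ", "))
    message("ignoring inert control parameter(s): ",
            paste(intersect(names(extra), tolerated), collapse = ", "))
  }
  if (min_num <= 0) stop_fmll("min_num must be positive")
  if (!no_pruning && num_folds < 2L)
    stop_fmll("num_folds must be >= 2 when pruning is enabled")
  structure(list(max_depth = as.integer(max_depth), min_num = min_num,
                 min_variance_prop = min_variance_prop,
                 no_pruning = isTRUE(no_pruning),
                 num_folds = as.integer(num_folds), seed = as.integer(seed),
                 initial_count = initial_count,
                 spread_initial_count = isTRUE(spread_initial_count),
                 num_decimal_places = as.integer(num_decimal_places),
                 ordinal_as_nominal = isTRUE(ordinal_as_nominal)),
            class = "reptree_control")
}

#' Shannon entropy of a class-count vector, in bits
#'
#' @param counts Non-negative per-class counts with a positive total.
#' @return `-sum(p * log2(p))` over classes with positive count; 0 for a pure
#'   node.
#' @export
shannon_entropy <- function(counts) {
  if (any(counts < 0) || sum(counts) <= 0)
    stop_fmll("counts must be non-negative with a positive total")
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

## row-wise entropy of a counts matrix (rows = candidate children)
ent_rows <- function(m) {
  tot <- rowSums(m)
  p <- m / ifelse(tot > 0, tot, 1)
  lp <- ifelse(m > 0, p * log2(p), 0)
  -rowSums(lp)
}

## Encode input features for fast splitting: numeric and (by default)
## ordinal features become doubles (ordinal = declared rank), nominal become
## integer category indices. Unknown categories at prediction time become NA.
encode_features <- function(df, features, control) {
  cols <- list()
  for (f in features) {
    if (f$role != "input") next
    v <- df[[f$name]]
    if (f$kind == "numeric") {
      cols[[f$name]] <- list(name = f$name, type = "num",
                             v = as.numeric(v), categories = NULL)
    } else if (f$kind == "ordinal" && !control$ordinal_as_nominal) {
      cols[[f$name]] <- list(name = f$name, type = "num",
                             v = as.numeric(match(as.character(v), f$categories)),
                             categories = f$categories, ordinal = TRUE)
    } else {
      cols[[f$name]] <- list(name = f$name, type = "cat",
                             v = match(as.character(v), f$categories),
                             ncat = length(f$categories),
                             categories = f$categories)
    }
  }
  cols
}

split_numeric <- function(x, y, n_classes, min_num) {
  ok <- !is.na(x)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2L * min_num) return(NULL)
  ord <- order(x)
  xs <- x[ord]; ys <- y[ord]
  bound <- which(diff(xs) > 0)
  bound <- bound[bound >= min_num & (n - bound) >= min_num]
  if (!length(bound)) return(NULL)
  cum <- vapply(seq_len(n_classes), function(cl) cumsum(ys == cl),
                numeric(n))
  total <- cum[n, ]
  left <- cum[bound, , drop = FALSE]
  right <- rep(total, each = length(bound)) - left
  dim(right) <- dim(left)
  h_parent <- shannon_entropy(total)
  gain <- h_parent -
    (bound * ent_rows(left) + (n - bound) * ent_rows(right)) / n
  best <- which.max(gain)
  if (gain[best] <= 1e-12) return(NULL)
  i <- bound[best]
  list(type = "num", threshold = (xs[i] + xs[i + 1L]) / 2,
       gain = gain[best])
}

split_nominal <- function(x, ncat, y, n_classes, min_num) {
  ok <- !is.na(x)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2L * min_num || ncat < 2L) return(NULL)
  counts <- matrix(tabulate((x - 1L) * n_classes + y, ncat * n_classes),
                   nrow = ncat, byrow = TRUE)
  w <- rowSums(counts)
  if (any(w < min_num)) return(NULL)
  gain <- shannon_entropy(colSums(counts)) - sum(w * ent_rows(counts)) / n
  if (gain <= 1e-12) return(NULL)
  list(type = "cat", gain = gain)
}

#' Best admissible split of one feature
#'
#' Numeric features are searched over midpoint thresholds between consecutive
#' distinct sorted values; nominal features use the multiway split over all
#' declared categories. A split is admissible only when every child carries
#' at least `min_num` instances (among rows with a non-missing feature
#' value); the candidate maximizing information gain is returned, or `NULL`
#' when no admissible candidate has positive gain.
#'
#' @param x Feature values (numeric, or character categories).
#' @param y Class values (character or factor).
#' @param feature A [feature_spec()] describing `x`.
#' @param classes Ordered class inventory of `y` (default: observed).
#' @param min_num Minimum child weight.
#' @return A list with `type` (`"num"`/`"cat"`), `gain`, and `threshold` for
#'   numeric splits; or `NULL`.
#' @export
best_split <- function(x, y, feature, classes = NULL, min_num = 2.0) {
  stopifnot(inherits(feature, "feature_spec"))
  classes <- classes %||% unique(as.character(y))
  yi <- match(as.character(y), classes)
  if (feature$kind == "numeric")
    split_numeric(as.numeric(x), yi, length(classes), min_num)
  else {
    s <- split_nominal(match(as.character(x), feature$categories),
                       length(feature$categories), yi, length(classes), min_num)
    if (!is.null(s)) s$categories <- feature$categories
    s
  }
}

make_leaf <- function(counts, depth) {
  list(split = NULL, children = list(), class_counts = counts,
       prune_counts = rep(0, length(counts)),
       predicted = which.max(counts), depth = depth)
}

## route row indices to children of a split node; missing values go to the
## heaviest child (ties: earliest child)
route_indices <- function(node, enc, idx) {
  col <- enc[[node$split$feature]]
  v <- col$v[idx]
  if (node$split$type == "num") {
    child <- ifelse(v < node$split$threshold, 1L, 2L)
  } else {
    child <- v
  }
  miss <- is.na(child)
  if (any(miss)) child[miss] <- node$heaviest
  split(idx, factor(child, levels = seq_along(node$children)))
}

grow_node <- function(enc, y, n_classes, idx, depth, control) {
  counts <- tabulate(y[idx], n_classes)
  weight <- length(idx)
  pure <- sum(counts > 0) <= 1L
  depth_capped <- control$max_depth >= 0L && depth >= control$max_depth
  if (pure || depth_capped || weight < 2 * control$min_num)
    return(make_leaf(counts, depth))
  best <- NULL; best_feature <- NULL
  for (col in enc) {
    s <- if (col$type == "num")
      split_numeric(col$v[idx], y[idx], n_classes, control$min_num)
    else
      split_nominal(col$v[idx], col$ncat, y[idx], n_classes, control$min_num)
    if (!is.null(s) && (is.null(best) || s$gain > best$gain)) {
      best <- s; best_feature <- col
    }
  }
  if (is.null(best)) return(make_leaf(counts, depth))
  node <- make_leaf(counts, depth)
  node$split <- list(feature = best_feature$name, type = best$type,
                     threshold = best$threshold,
                     categories = best_feature$categories)
  n_children <- if (best$type == "num") 2L else best_feature$ncat
  ## provisional routing to find child weights (missing not yet routed)
  v <- best_feature$v[idx]
  child_of <- if (best$type == "num") ifelse(v < best$threshold, 1L, 2L) else v
  w <- tabulate(child_of[!is.na(child_of)], n_children)
  node$heaviest <- which.max(w)
  node$children <- vector("list", n_children)
  child_of[is.na(child_of)] <- node$heaviest
  parts <- split(idx, factor(child_of, levels = seq_len(n_children)))
  for (i in seq_len(n_children)) {
    ci <- parts[[i]]
    node$children[[i]] <-
      if (length(ci)) grow_node(enc, y, n_classes, ci, depth + 1L, control)
      else make_leaf(tabulate(integer(), n_classes), depth + 1L)
  }
  ## an empty child predicts like its parent
  for (i in seq_len(n_children))
    if (sum(node$children[[i]]$class_counts) == 0)
      node$children[[i]]$predicted <- node$predicted
  node
}

## Bottom-up reduced-error pruning on routed hold-out rows. A subtree is
## collapsed to its training-majority leaf whenever the leaf's hold-out
## misclassification count is <= the subtree's (ties prune). Hold-out class
## counts are recorded on every surviving node. Returns list(node, err).
prune_node <- function(node, enc, y, n_classes, idx) {
  node$prune_counts <- tabulate(y[idx], n_classes)
  leaf_err <- length(idx) - node$prune_counts[node$predicted]
  if (is.null(node$split)) return(list(node = node, err = leaf_err))
  parts <- route_indices(node, enc, idx)
  sub_err <- 0
  for (i in seq_along(node$children)) {
    res <- prune_node(node$children[[i]], enc, y, n_classes, parts[[i]])
    node$children[[i]] <- res$node
    sub_err <- sub_err + res$err
  }
  if (leaf_err <= sub_err) {
    node["split"] <- list(NULL)   # keep the element, like a grown leaf
    node$children <- list()
    node$heaviest <- NULL
    return(list(node = node, err = leaf_err))
  }
  list(node = node, err = sub_err)
}

#' Fit a reduced-error pruning tree on a single-target dataset
#'
#' With pruning enabled (the default), the rows are shuffled by
#' `control$seed` and dealt into `control$num_folds` parts; fold 0 becomes
#' the pruning hold-out and the remaining folds grow the tree by recursive
#' maximum-information-gain splitting. The grown tree is then pruned bottom-up
#' against the hold-out and the hold-out class counts are recorded on each
#' node. With `no_pruning = TRUE` all rows grow the tree.
#'
#' @param data A `single_target_dataset` from [br_decompose()].
#' @param control A [reptree_control()].
#' @return A `reptree` model object; see [predict.reptree()] and
#'   [render_tree()].
#' @export
reptree <- function(data, control = reptree_control()) {
  stopifnot(inherits(data, "single_target_dataset"),
            inherits(control, "reptree_control"))
  n <- nrow(data$data)
  if (n < 1L) stop_fmll("empty training data")
  classes <- data$target_classes
  y <- match(target_values(data), classes)
  enc <- encode_features(data$data, data$features, control)
  if (!length(enc)) stop_fmll("no input features to train on")
  if (control$no_pruning) {
    root <- grow_node(enc, y, length(classes), seq_len(n), 0L, control)
  } else {
    if (n < control$num_folds)
      stop_fmll("pruning requires at least num_folds = %d rows (got %d)",
                control$num_folds, n)
    perm <- with_seed(control$seed, sample.int(n))
    fold <- rep_len(seq_len(control$num_folds) - 1L, n)
    hold <- perm[fold == 0L]
    grow <- perm[fold != 0L]
    root <- grow_node(enc, y, length(classes), grow, 0L, control)
    root <- prune_node(root, enc, y, length(classes), hold)$node
  }
  structure(list(root = root, control = control, classes = classes,
                 target = data$source_label, mode = data$mode,
                 features = data$features, n_train = n),
            class = "reptree")
}

count_nodes <- function(node) {
  1L + sum(vapply(node$children, count_nodes, 0L))
}

tree_depth <- function(node) {
  if (is.null(node$split)) return(0L)
  1L + max(vapply(node$children, tree_depth, 0L))
}

check_schema <- function(model, df) {
  need <- vapply(model$features[vapply(model$features,
                                       function(f) f$role == "input", NA)],
                 `[[`, "", "name")
  absent <- setdiff(need, names(df))
  if (length(absent))
    stop_fmll("prediction data lacks feature(s): %s",
              paste(absent, collapse = ", "))
}

#' Predict classes or class distributions from a REPTree
#'
#' Rows are routed by the tree's splits; a missing (or unseen-category) value
#' at a split routes to the child that carried the greatest training weight.
#' `type = "class"` returns the reached leaf's majority class (ties broken by
#' class declaration order). `type = "prob"` returns leaf class counts with
#' `initial_count` additive smoothing, normalized; a leaf with no training
#' counts inherits the distribution of its nearest non-empty ancestor.
#'
#' @param object A [reptree()] model.
#' @param newdata A data.frame (or `multilabel_dataset` /
#'   `single_target_dataset`) with the training feature columns.
#' @param type `"class"` or `"prob"`.
#' @param ... Unused.
#' @return A character vector of classes, or a numeric matrix of class
#'   probabilities with one column per class.
#' @export
predict.reptree <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  df <- if (inherits(newdata, "multilabel_dataset") ||
            inherits(newdata, "single_target_dataset")) newdata$data
        else as.data.frame(newdata)
  check_schema(object, df)
  enc <- encode_features(df, object$features, object$control)
  n <- nrow(df)
  C <- length(object$classes)
  ic <- object$control$initial_count
  if (object$control$spread_initial_count) ic <- ic / C
  dist_of <- function(counts, fallback) {
    sm <- counts + ic
    if (sum(sm) <= 0) return(fallback)
    sm / sum(sm)
  }
  out_class <- character(n)
  out_prob <- matrix(0, n, C, dimnames = list(NULL, object$classes))
  for (i in seq_len(n)) {
    node <- object$root
    fallback <- rep(1 / C, C)
    repeat {
      if (sum(node$class_counts) > 0)
        fallback <- dist_of(node$class_counts, fallback)
      if (is.null(node$split)) break
      col <- enc[[node$split$feature]]
      v <- col$v[i]
      child <- if (is.na(v)) node$heaviest
               else if (node$split$type == "num") {
                 if (v < node$split$threshold) 1L else 2L
               } else v
      if (is.na(child)) child <- node$heaviest
      node <- node$children[[child]]
    }
    out_class[i] <- object$classes[node$predicted]
    if (type == "prob") out_prob[i, ] <- dist_of(node$class_counts, fallback)
  }
  if (type == "class") out_class else out_prob
}

#' @export
print.reptree <- function(x, ...) {
  cat(sprintf("REPTree for target '%s' (%d nodes, depth %d, %d training rows)\n\n",
              x$target$name, count_nodes(x$root), tree_depth(x$root), x$n_train))
  cat(render_tree(x), "\n")
  invisible(x)
}

#' @export
summary.reptree <- function(object, ...) {
  res <- list(target = object$target$name, nodes = count_nodes(object$root),
              leaves = count_leaves(object$root),
              depth = tree_depth(object$root), classes = object$classes)
  class(res) <- "summary.reptree"
  res
}

#' @export
print.summary.reptree <- function(x, ...) {
  cat(sprintf("REPTree '%s': %d nodes (%d leaves), depth %d, classes: %s\n",
              x$target, x$nodes, x$leaves, x$depth,
              paste(x$classes, collapse = ", ")))
  invisible(x)
}

count_leaves <- function(node) {
  if (is.null(node$split)) return(1L)
  sum(vapply(node$children, count_leaves, 0L))
}
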