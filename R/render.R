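## Text rendering of a fitted tree, Weka-style: nominal branches print
## "FEATURE = category", numeric ones "FEATURE < t" / "FEATURE >= t", and a
## leaf prints "CLASS (a/b) [c/d]" where a is the training weight reaching
## the leaf and b the training misclassifications. The hold-out bracket
## [c/d] has two readings (see `bracket`).

fmt_count <- function(x, dp) {
  ifelse(abs(x - round(x)) < 1e-9, format(round(x)),
         formatC(x, digits = dp, format = "f"))
}

leaf_text <- function(node, classes, dp, bracket) {
  a <- sum(node$class_counts)
  b <- a - node$class_counts[node$predicted]
  pc <- node$prune_counts
  if (bracket == "majority_minority") {
    cc <- if (sum(pc) > 0) max(pc) else 0
    dd <- sum(pc) - cc
  } else {
    cc <- sum(pc)
    dd <- sum(pc) - pc[node$predicted]
  }
  sprintf("%s (%s/%s) [%s/%s]", classes[node$predicted],
          fmt_count(a, dp), fmt_count(b, dp),
          fmt_count(cc, dp), fmt_count(dd, dp))
}

branch_labels <- function(node, dp) {
  s <- node$split
  if (s$type == "num") {
    t <- formatC(s$threshold, digits = dp, format = "f")
    c(sprintf("%s < %s", s$feature, t), sprintf("%s >= %s", s$feature, t))
  } else {
    sprintf("%s = %s", s$feature, s$categories)
  }
}

render_node <- function(node, classes, dp, bracket, indent) {
  if (is.null(node$split))
    return(paste0(indent, leaf_text(node, classes, dp, bracket)))
  labs <- branch_labels(node, dp)
  out <- character(0)
  for (i in seq_along(node$children)) {
    ch <- node$children[[i]]
    if (is.null(ch$split)) {
      out <- c(out, paste0(indent, labs[i], " : ",
                           leaf_text(ch, classes, dp, bracket)))
    } else {
      out <- c(out, paste0(indent, labs[i]),
               render_node(ch, classes, dp, bracket, paste0(indent, "|   ")))
    }
  }
  paste(out, collapse = "\n")
}

#' Render a fitted REPTree as indented text
#'
#' @param model A [reptree()] model.
#' @param bracket Reading of the hold-out bracket `[c/d]` printed at each
#'   leaf: `"majority_minority"` (the default) prints the hold-out counts of
#'   the leaf's majority and minority classes; `"holdout_error"` prints the
#'   hold-out total and the hold-out misclassifications (the conventional
#'   Weka reading).
#' @return A single string; one line per branch or leaf.
#' @export
render_tree <- function(model, bracket = c("majority_minority", "holdout_error")) {
  stopifnot(inherits(model, "reptree"))
  bracket <- match.arg(bracket)
  render_node(model$root, model$classes, model$control$num_decimal_places,
              bracket, "")
}
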