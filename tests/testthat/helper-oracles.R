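# Independent brute-force oracles used to validate the package's
# implementations, plus small fixture builders. The oracles share no code
# with the implementation paths they check.

entropy_oracle <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

# Exhaustive split search over one feature: every midpoint threshold for
# numeric values, the multiway partition over all declared categories for
# nominal ones. Returns NULL or list(gain, threshold).
split_oracle <- function(x, y, kind, categories = NULL, min_num = 2) {
  ok <- !is.na(x)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  parent <- entropy_oracle(table(y))
  best <- NULL
  if (kind == "numeric") {
    vals <- sort(unique(x))
    if (length(vals) < 2) return(NULL)
    for (i in seq_len(length(vals) - 1)) {
      t <- (vals[i] + vals[i + 1]) / 2
      left <- y[x < t]; right <- y[x >= t]
      if (length(left) < min_num || length(right) < min_num) next
      gain <- parent - (length(left) * entropy_oracle(table(left)) +
                        length(right) * entropy_oracle(table(right))) / n
      if (is.null(best) || gain > best$gain)
        best <- list(gain = gain, threshold = t)
    }
  } else {
    groups <- split(y, factor(x, levels = categories))
    sizes <- vapply(groups, length, 0L)
    if (any(sizes < min_num)) return(NULL)
    gain <- parent -
      sum(vapply(groups, function(g) length(g) * entropy_oracle(table(g)), 0)) / n
    best <- list(gain = gain, threshold = NULL)
  }
  if (!is.null(best) && best$gain <= 1e-12) best <- NULL
  best
}

# AUC by explicit pair counting over all positive-negative pairs
auc_pair_oracle <- function(y_true, scores) {
  pos <- scores[as.logical(y_true)]
  neg <- scores[!as.logical(y_true)]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# Precision-recall area by an explicit threshold-by-threshold sweep with
# trapezoidal integration, anchored at recall 0
prc_sweep_oracle <- function(y_true, scores) {
  t <- as.logical(y_true)
  P <- sum(t)
  thresholds <- sort(unique(scores), decreasing = TRUE)
  rec <- 0; prec <- NULL; area <- 0; prev_rec <- 0; prev_prec <- NULL
  for (th in thresholds) {
    sel <- scores >= th
    precision <- sum(t & sel) / sum(sel)
    recall <- sum(t & sel) / P
    if (is.null(prev_prec)) {
      area <- area + (recall - 0) * (precision + precision) / 2
    } else {
      area <- area + (recall - prev_rec) * (precision + prev_prec) / 2
    }
    prev_rec <- recall; prev_prec <- precision
  }
  area
}

# Exact two-sided Mann-Whitney p-value by full enumeration of all
# choose(n+m, n) group assignments of the pooled tie-free sample
mwu_enum_oracle <- function(a, b) {
  pooled <- c(a, b)
  n <- length(a)
  u_of <- function(idx) {
    x <- pooled[idx]; y <- pooled[-idx]
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  u_obs <- u_of(seq_len(n))
  us <- apply(utils::combn(length(pooled), n), 2, u_of)
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# A tiny fully-specified multi-label dataset mirroring the canonical
# 4-label Binary Relevance worked example: S1 carries {y2, y4},
# S2 carries {y1, y3, y4}, S3 carries {y3}.
toy_mld <- function() {
  df <- data.frame(
    x1 = c(1.0, 2.0, 3.0),
    x2 = c("a", "b", "a"),
    y1 = c("0", "1", "0"),
    y2 = c("1", "0", "0"),
    y3 = c("0", "1", "1"),
    y4 = c("1", "1", "0"),
    stringsAsFactors = FALSE)
  multilabel_dataset(
    df,
    features = list(feature_spec("x1"),
                    feature_spec("x2", "nominal", c("a", "b"))),
    labels = lapply(paste0("y", 1:4), label_spec, classes = c("0", "1")),
    name = "toy")
}

# The 4-row threshold fixture: x < 2.5 separates A from B perfectly
four_row_stds <- function() {
  ds <- multilabel_dataset(
    data.frame(x = c(1, 2, 3, 4), cls = c("A", "A", "B", "B"),
               stringsAsFactors = FALSE),
    features = list(feature_spec("x")),
    labels = list(label_spec("cls", c("A", "B"))),
    name = "four-row")
  br_decompose(ds, "per_label")[[1]]
}

# Random small single-target dataset for property sweeps
random_stds <- function(n, n_num, n_nom, n_classes, seed) {
  set.seed(seed)
  cols <- list()
  feats <- list()
  for (i in seq_len(n_num)) {
    nm <- paste0("x", i)
    cols[[nm]] <- round(runif(n), 2)
    feats[[nm]] <- feature_spec(nm)
  }
  for (i in seq_len(n_nom)) {
    nm <- paste0("g", i)
    cats <- c("u", "v", "w")[seq_len(sample(2:3, 1))]
    cols[[nm]] <- sample(cats, n, replace = TRUE)
    feats[[nm]] <- feature_spec(nm, "nominal", cats)
  }
  classes <- LETTERS[seq_len(n_classes)]
  cols[["cls"]] <- sample(classes, n, replace = TRUE)
  ds <- multilabel_dataset(as.data.frame(cols, stringsAsFactors = FALSE),
                           features = unname(feats),
                           labels = list(label_spec("cls", classes)),
                           name = "random")
  br_decompose(ds, "per_label")[[1]]
}

published_path <- function(file) {
  system.file("extdata", "published", file, package = "fmll", mustWork = TRUE)
}
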