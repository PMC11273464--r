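## Method comparison: improvement of a proposed result over the unweighted
## mean of published baselines, and the two nonparametric rank tests used to
## compare classifiers (Mann-Whitney U for two independent samples, Quade
## for blocked designs).

#' Improvement of a proposed value over baseline methods
#'
#' @param proposed The proposed method's value.
#' @param baselines Non-empty numeric vector of baseline values on the same
#'   scale.
#' @param scale Multiplier applied to the improvement before reporting:
#'   leave at 1 for values already in percent (accuracy tables), use 100 to
#'   express a rate difference in percentage points.
#' @return A `comparison_result` list: `proposed`, `baselines`,
#'   `baseline_mean`, `improvement` (`(proposed - baseline_mean) * scale`).
#' @export
improvement_over_baselines <- function(proposed, baselines, scale = 1) {
  if (!length(baselines)) stop_fmll("no baseline values supplied")
  baselines <- as.numeric(baselines)
  bm <- mean(baselines)
  structure(list(proposed = proposed, baselines = baselines,
                 baseline_mean = bm,
                 improvement = (proposed - bm) * scale),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("proposed %.4g vs %d baseline(s), mean %.4g: improvement %+.4g\n",
              x$proposed, length(x$baselines), x$baseline_mean, x$improvement))
  invisible(x)
}

#' Mann-Whitney U test
#'
#' Rank-sum test with midranks for ties. The U statistic counts, over all
#' pairs, how often a value of `a` exceeds a value of `b` (ties count half).
#' Under `method = "auto"` the p-value is exact (full enumeration of the
#' rank distribution) when `length(a) + length(b) <= 12` and there are no
#' ties, otherwise a normal approximation with tie and continuity correction
#' is used.
#'
#' @param a,b Non-empty numeric samples.
#' @param alternative `"two.sided"` (default), `"greater"`, `"less"`.
#' @param method `"auto"`, `"exact"`, or `"normal_approx"`.
#' @return A `rank_test_result` list: `test`, `statistic` (U for `a`),
#'   `p_value`, `method` used, `alternative`.
#' @export
mann_whitney_u <- function(a, b, alternative = c("two.sided", "greater", "less"),
                           method = c("auto", "exact", "normal_approx")) {
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  if (!length(a) || !length(b)) stop_fmll("both samples must be non-empty")
  a <- as.numeric(a); b <- as.numeric(b)
  n <- length(a); m <- length(b)
  has_ties <- anyDuplicated(c(a, b)) > 0L
  if (method == "auto")
    method <- if (n + m <= 12L && !has_ties) "exact" else "normal_approx"
  if (method == "exact" && has_ties) {
    warning("ties present; falling back to the normal approximation",
            call. = FALSE)
    method <- "normal_approx"
  }
  r <- rank(c(a, b), ties.method = "average")
  U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  ht <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = alternative,
                       exact = method == "exact", correct = TRUE))
  structure(list(test = "mann_whitney_u", statistic = U,
                 p_value = ht$p.value, method = method,
                 alternative = alternative),
            class = "rank_test_result")
}

#' Quade test for blocked method comparison
#'
#' Conover's procedure: within-block ranks `r_ij`, block weights `Q_i` (the
#' ranks of the within-block ranges), scores
#' `S_ij = Q_i * (r_ij - (k+1)/2)`, and the statistic
#' `F = (b-1) * B / (A - B)` with `A = sum(S_ij^2)` and
#' `B = sum(S_j^2) / b`, referred to the F distribution with
#' `(k-1, (b-1)(k-1))` degrees of freedom. When the treatments tie exactly
#' within every block the test is degenerate and an error is raised; when
#' the treatment ordering is perfectly consistent (`A == B`) the p-value is
#' taken as `(1/k!)^(b-1)`.
#'
#' @param blocks A numeric matrix or data.frame, rows = blocks (e.g.
#'   datasets), columns = treatments (methods); no missing cells.
#' @return A `rank_test_result` with `statistic` (F), `p_value`, `df`, and
#'   `method = "f_distribution"`.
#' @export
quade_test <- function(blocks) {
  m <- as.matrix(blocks)
  if (anyNA(m)) stop_fmll("blocks must have no missing cells")
  b <- nrow(m); k <- ncol(m)
  if (b < 2L || k < 2L) stop_fmll("need >= 2 blocks and >= 2 treatments")
  ranges <- apply(m, 1L, function(x) diff(range(x)))
  if (all(ranges == 0))
    stop_fmll("degenerate table: all treatments tie within every block")
  r <- t(apply(m, 1L, rank))
  Q <- rank(ranges)
  S <- Q * (r - (k + 1) / 2)
  A <- sum(S^2)
  B <- sum(colSums(S)^2) / b
  if (A - B < .Machine$double.eps^0.5 * A) {
    stat <- Inf
    p <- (1 / factorial(k))^(b - 1)
  } else {
    stat <- (b - 1) * B / (A - B)
    p <- stats::pf(stat, k - 1, (b - 1) * (k - 1), lower.tail = FALSE)
  }
  structure(list(test = "quade", statistic = stat, p_value = p,
                 df = c(k - 1, (b - 1) * (k - 1)),
                 method = "f_distribution", alternative = "two.sided"),
            class = "rank_test_result")
}

#' @export
print.rank_test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.5g (%s%s)\n", x$test, x$statistic,
              x$p_value, x$method,
              if (!is.null(x$df)) sprintf(", df = (%g, %g)", x$df[1], x$df[2])
              else ""))
  invisible(x)
}
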