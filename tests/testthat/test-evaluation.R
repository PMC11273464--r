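test_that("confusion counts tally element-by-element", {
  cc <- confusion_counts(c(1, 1, 0, 0, 1), c(1, 0, 0, 1, 1))
  expect_equal(unclass(cc)[c("TP", "FN", "FP", "TN")],
               list(TP = 2L, FN = 1L, FP = 1L, TN = 1L))
  perfect <- confusion_counts(c(1, 0, 1), c(1, 0, 1))
  expect_equal(perfect$FP + perfect$FN, 0L)
  allneg <- confusion_counts(rep(0, 5), rep(0, 5))
  expect_equal(allneg$TN, 5L)
  expect_error(confusion_counts(c(1, 0), c(1)), "lengths differ")
})

test_that("binary rates follow the standard confusion formulas", {
  m <- binary_metrics(confusion_counts(c(1, 1, 0, 0, 1), c(1, 0, 0, 1, 1)))
  expect_equal(m$accuracy, 0.6)
  expect_equal(m$precision, 2 / 3)
  expect_equal(m$recall, 2 / 3)
  expect_equal(m$f_score, 2 / 3)
  expect_equal(m$tnr, 0.5)
  expect_equal(m$fpr, 0.5)

  # all-positive truth: TNR/FPR denominators are legitimately zero
  perfect <- suppressWarnings(binary_metrics(confusion_counts(rep(1, 4),
                                                              rep(1, 4))))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$f_score, 1)

  # zero-denominator convention: 0 with a warning
  expect_warning(z <- binary_metrics(confusion_counts(c(1, 0), c(0, 0))),
                 "precision")
  expect_equal(z$precision, 0)
  expect_equal(z$tnr, 1)
})

test_that("rate identities hold across random confusion tables", {
  set.seed(42)
  for (i in 1:25) {
    t <- sample(0:1, 30, replace = TRUE)
    p <- sample(0:1, 30, replace = TRUE)
    if (length(unique(t)) < 2) next
    m <- suppressWarnings(binary_metrics(confusion_counts(t, p)))
    expect_equal(m$tnr + m$fpr, 1, tolerance = 1e-12)
    if (m$precision + m$recall > 0)
      expect_equal(m$f_score,
                   2 * m$precision * m$recall / (m$precision + m$recall),
                   tolerance = 1e-9)
    cc <- confusion_counts(t, p)
    if (cc$TP + cc$FN > 0)
      expect_equal(m$recall + cc$FN / (cc$TP + cc$FN), 1, tolerance = 1e-12)
  }
})

test_that("multi-class rates are prevalence-weighted one-vs-rest", {
  all_right <- multiclass_metrics(c("A", "B", "C"), c("A", "B", "C"),
                                  c("A", "B", "C"))
  expect_equal(all_right$accuracy, 1)
  expect_equal(all_right$precision, 1)
  expect_equal(all_right$recall, 1)

  m <- suppressWarnings(
    multiclass_metrics(c("A", "A", "B", "C"), c("A", "B", "B", "C"),
                       c("A", "B", "C")))
  expect_equal(m$accuracy, 0.75)

  single <- suppressWarnings(
    multiclass_metrics(rep("A", 3), rep("A", 3), c("A", "B")))
  expect_equal(single$precision, 1)
  expect_error(multiclass_metrics("A", "Z", c("A", "B")), "outside declared")
})

test_that("ROC area equals the pair-counting probability", {
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1.0)
  expect_equal(roc_auc(c(1, 0, 1, 0), rep(0.5, 4)), 0.5)
  expect_equal(roc_auc(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.6)), 0.75)
  expect_error(roc_auc(c(1, 1), c(0.5, 0.6)), "both classes")

  set.seed(7)
  for (i in 1:20) {
    n <- sample(4:12, 1)
    truth <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)
    expect_equal(roc_auc(truth, scores), auc_pair_oracle(truth, scores),
                 tolerance = 1e-12)
  }
})

test_that("ROC area agrees with an external reference implementation", {
  set.seed(11)
  truth <- sample(0:1, 50, replace = TRUE)
  scores <- runif(50)
  ref <- as.numeric(pROC::auc(pROC::roc(truth, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_auc(truth, scores), ref, tolerance = 1e-12)
})

test_that("PR area follows the descending-score trapezoidal sweep", {
  expect_equal(prc_auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1.0)
  expect_equal(prc_auc(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.6)), 19 / 24,
               tolerance = 1e-12)
  expect_equal(prc_auc(c(1, 0, 0), c(0.9, 0.5, 0.4)), 1.0)
  expect_error(prc_auc(c(0, 0), c(0.5, 0.6)), "positive")

  set.seed(13)
  for (i in 1:20) {
    n <- sample(5:14, 1)
    truth <- c(1, sample(0:1, n - 1, replace = TRUE))
    scores <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)
    expect_equal(prc_auc(truth, scores), prc_sweep_oracle(truth, scores),
                 tolerance = 1e-12)
  }
})

test_that("stratified folds partition with balanced sizes and class shares", {
  target <- rep(c("a", "b", "c"), times = c(90, 60, 39))
  folds <- stratified_folds(target, k = 10, seed = 4)
  sizes <- lengths(folds)
  expect_equal(sort(sizes, decreasing = TRUE), c(rep(19, 9), 18))
  expect_equal(sizes[10], 18L)                       # trailing fold is smaller
  expect_setequal(unlist(folds), seq_along(target))  # exact partition
  expect_equal(sum(lengths(folds)), 189L)

  # exact stratification when classes divide evenly
  t2 <- rep(c("pos", "neg"), each = 10)
  f2 <- stratified_folds(t2, k = 5, seed = 1)
  for (f in f2) {
    expect_equal(sum(t2[f] == "pos"), 2L)
    expect_equal(sum(t2[f] == "neg"), 2L)
  }

  # per-class counts never deviate from proportionality by more than one
  set.seed(9)
  t3 <- sample(c("x", "y", "z"), 83, replace = TRUE, prob = c(0.5, 0.3, 0.2))
  f3 <- stratified_folds(t3, k = 7, seed = 2)
  for (cl in unique(t3)) {
    per <- vapply(f3, function(f) sum(t3[f] == cl), 0L)
    expect_lte(max(per) - min(per), 1L)
  }

  # leave-one-out degenerate case and precondition breaches
  expect_equal(lengths(stratified_folds(c("a", "b", "a"), k = 3, seed = 1)),
               rep(1L, 3))
  expect_error(stratified_folds(c("a", "b"), k = 3), "exceeds")
  expect_error(stratified_folds(c("a", "b"), k = 1), ">= 2")
})

test_that("cross-validation pools one prediction per instance per label", {
  ds <- toy_mld()
  rep3 <- suppressWarnings(
    cv_fmll(ds, k = 3, control = reptree_control(no_pruning = TRUE, min_num = 1),
            seed = 1))
  preds <- attr(rep3, "predictions")
  for (lab in paste0("y", 1:4)) {
    expect_length(preds[[lab]]$pred, 3L)
    expect_false(any(preds[[lab]]$pred == ""))
  }
  expect_equal(rep3$Label, c(paste0("y", 1:4), "Average"))

  # determinism: identical reports from identical seeds
  gen <- synth_generate(synth_config(n_samples = 100, numeric_features = 3,
                                     labels = c(a = 2L, b = 2L), rule_depth = 2,
                                     seed = 5))
  r1 <- cv_fmll(gen$dataset, k = 5, seed = 7)
  r2 <- cv_fmll(gen$dataset, k = 5, seed = 7)
  expect_identical(as.data.frame(r1), as.data.frame(r2))

  # the Average row is the unweighted column mean of the label rows
  body <- as.data.frame(r1)[r1$Label != "Average", ]
  avg <- as.data.frame(r1)[r1$Label == "Average", ]
  for (col in c("Accuracy", "Precision", "TNR", "ROC", "PRC", "Recall", "F_Score"))
    expect_equal(avg[[col]], mean(body[[col]]), tolerance = 1e-12)
})

test_that("reports render and write with the published column layout", {
  gen <- synth_generate(synth_config(n_samples = 80, numeric_features = 3,
                                     labels = c(a = 2L), rule_depth = 1, seed = 2))
  r <- cv_fmll(gen$dataset, k = 4, seed = 1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_fmll_report(r, path)
  tab <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  expect_equal(names(tab),
               c("Label", "Accuracy", "Precision", "TNR", "ROC", "PRC",
                 "Recall", "F-Score"))
  expect_equal(tab$Label[nrow(tab)], "Average")
  expect_true(file.exists(sub("\\.tsv$", ".json", path)))
})

test_that("macro averages and baseline improvements are plain arithmetic", {
  expect_equal(macro_average(c(1, 2, 3)), 2)
  expect_equal(macro_average(5), 5)
  expect_error(macro_average(numeric(0)), "empty")

  imp <- improvement_over_baselines(10, c(8, 6))
  expect_equal(imp$baseline_mean, 7)
  expect_equal(imp$improvement, 3)
  expect_equal(improvement_over_baselines(5, 5)$improvement, 0)
  imp_rate <- improvement_over_baselines(0.9, c(0.7, 0.6), scale = 100)
  expect_equal(imp_rate$improvement, 25, tolerance = 1e-12)
  expect_error(improvement_over_baselines(1, numeric(0)), "no baseline")
})

test_that("Mann-Whitney U matches exact enumeration on small samples", {
  r <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 2 / 6, tolerance = 1e-12)
  expect_equal(r$method, "exact")

  expect_equal(mann_whitney_u(1, 2)$p_value, 1.0)
  expect_equal(mann_whitney_u(1:4, 5:8)$p_value, 2 / 70, tolerance = 1e-12)

  set.seed(3)
  for (i in 1:15) {
    n <- sample(2:5, 1); m <- sample(2:5, 1)
    pool <- sample(1:50, n + m)          # tie-free
    a <- pool[seq_len(n)]; b <- pool[-seq_len(n)]
    expect_equal(mann_whitney_u(a, b)$p_value, mwu_enum_oracle(a, b),
                 tolerance = 1e-12)
  }

  # ties or large samples: normal approximation with corrections
  big <- mann_whitney_u(rnorm(20), rnorm(20) + 1)
  expect_equal(big$method, "normal_approx")
  expect_lt(big$p_value, 0.05)
  expect_warning(tied <- mann_whitney_u(c(1, 1, 2), c(2, 3, 3),
                                        method = "exact"), "ties")
  expect_equal(tied$method, "normal_approx")
  expect_error(mann_whitney_u(numeric(0), 1), "non-empty")
})

test_that("the Quade statistic follows the blocked rank procedure", {
  q <- quade_test(cbind(A = c(1, 2, 3), B = c(2, 4, 6)))
  expect_equal(q$statistic, 12, tolerance = 1e-12)
  expect_equal(q$df, c(1, 2))
  expect_equal(q$p_value, stats::pf(12, 1, 2, lower.tail = FALSE),
               tolerance = 1e-12)

  expect_error(quade_test(matrix(1, 3, 2)), "degenerate")
  expect_error(quade_test(matrix(1:3, 3, 1)), ">= 2")

  # agreement with the base-R reference on a general table
  set.seed(8)
  m <- matrix(rnorm(24), nrow = 6)
  ref <- stats::quade.test(m)
  got <- quade_test(m)
  expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-9)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-9)
  expect_equal(unname(got$df), unname(as.numeric(ref$parameter)))
})
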