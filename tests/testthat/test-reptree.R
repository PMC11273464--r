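test_that("entropy matches hand-computed values in bits", {
  expect_equal(shannon_entropy(c(4, 4)), 1.0)
  expect_equal(shannon_entropy(c(8, 0)), 0.0)
  expect_equal(shannon_entropy(c(9, 5)), 0.9403, tolerance = 1e-4)
  expect_error(shannon_entropy(c(0, 0)), "positive total")
})

test_that("best_split finds the maximal-gain midpoint threshold", {
  f <- feature_spec("x")
  s <- best_split(c(1, 2, 3, 4), c("A", "A", "B", "B"), f, classes = c("A", "B"))
  expect_equal(s$threshold, 2.5)
  expect_equal(s$gain, 1.0)
  # single distinct value: no candidate thresholds
  expect_null(best_split(c(2, 2, 2, 2), c("A", "A", "B", "B"), f,
                         classes = c("A", "B")))
  # nominal two-branch fixture: children (6,2) and (3,3) under parent (9,5)
  g <- feature_spec("g", "nominal", c("a", "b"))
  x <- c(rep("a", 8), rep("b", 6))
  y <- c(rep("A", 6), rep("B", 2), rep("A", 3), rep("B", 3))
  s2 <- best_split(x, y, g, classes = c("A", "B"))
  expect_equal(s2$gain, 0.0481, tolerance = 1e-3)
})

test_that("split search agrees with exhaustive enumeration on tiny data", {
  for (seed in 1:30) {
    set.seed(seed)
    n <- sample(4:6, 1)
    x_num <- sample(1:5, n, replace = TRUE) + 0
    x_nom <- sample(c("u", "v", "w"), n, replace = TRUE)
    y <- sample(c("A", "B"), n, replace = TRUE)
    got_num <- best_split(x_num, y, feature_spec("x"), classes = c("A", "B"))
    want_num <- split_oracle(x_num, y, "numeric")
    if (is.null(want_num)) {
      expect_null(got_num)
    } else {
      expect_equal(got_num$gain, want_num$gain, tolerance = 1e-12)
      expect_equal(got_num$threshold, want_num$threshold)
    }
    got_nom <- best_split(x_nom, y, feature_spec("g", "nominal", c("u", "v", "w")),
                          classes = c("A", "B"))
    want_nom <- split_oracle(x_nom, y, "nominal", categories = c("u", "v", "w"))
    if (is.null(want_nom)) expect_null(got_nom)
    else expect_equal(got_nom$gain, want_nom$gain, tolerance = 1e-12)
  }
})

test_that("tree growth stops on purity, depth cap, and inadmissible splits", {
  stds <- four_row_stds()
  ctl <- reptree_control(no_pruning = TRUE)
  m <- reptree(stds, ctl)
  expect_equal(m$root$split$feature, "x")
  expect_equal(m$root$split$threshold, 2.5)
  expect_null(m$root$children[[1]]$split)   # both children pure leaves
  expect_null(m$root$children[[2]]$split)

  # pure target: single leaf
  pure <- stds; pure$target <- rep("A", 4)
  mp <- reptree(pure, ctl)
  expect_null(mp$root$split)
  expect_equal(predict(mp, stds$data), rep("A", 4))

  # depth cap 0: majority leaf regardless of separability
  m0 <- reptree(stds, reptree_control(no_pruning = TRUE, max_depth = 0))
  expect_null(m0$root$split)
  expect_equal(predict(m0, stds$data), rep("A", 4))  # tie broken by class order
})

test_that("prediction routes thresholds and missing values deterministically", {
  m <- reptree(four_row_stds(), reptree_control(no_pruning = TRUE))
  expect_equal(predict(m, data.frame(x = 1.7)), "A")
  expect_equal(predict(m, data.frame(x = 3.0)), "B")
  # missing split value: heaviest child, ties favoring the first child
  expect_equal(predict(m, data.frame(x = NA_real_)), "A")
  expect_error(predict(m, data.frame(z = 1)), "lacks feature")
})

test_that("leaf distributions are smoothed counts with parent fallback", {
  stds <- four_row_stds()
  stds$target <- c("A", "A", "A", "B")     # single leaf with counts (3,1)
  m <- reptree(stds, reptree_control(no_pruning = TRUE, max_depth = 0))
  p <- predict(m, data.frame(x = 1), type = "prob")
  expect_equal(unname(p[1, ]), c(0.75, 0.25))
  m1 <- reptree(stds, reptree_control(no_pruning = TRUE, max_depth = 0,
                                      initial_count = 1))
  p1 <- predict(m1, data.frame(x = 1), type = "prob")
  expect_equal(unname(p1[1, ]), c(4 / 6, 2 / 6))
})

test_that("distributions normalize to one at every reachable leaf", {
  stds <- random_stds(n = 120, n_num = 2, n_nom = 1, n_classes = 3, seed = 4)
  m <- reptree(stds, reptree_control())
  p <- predict(m, stds$data, type = "prob")
  expect_equal(rowSums(p), rep(1, nrow(p)), tolerance = 1e-9)
  expect_true(all(p >= 0))
})

test_that("reduced-error pruning never increases hold-out error or size", {
  for (seed in 1:8) {
    stds <- random_stds(n = 80, n_num = 2, n_nom = 1, n_classes = 2,
                        seed = 100 + seed)
    ctl <- reptree_control(seed = seed)
    n <- nrow(stds$data)
    classes <- stds$target_classes
    y <- match(fmll:::target_values(stds), classes)
    enc <- fmll:::encode_features(stds$data, stds$features, ctl)
    perm <- fmll:::with_seed(ctl$seed, sample.int(n))
    fold <- rep_len(seq_len(ctl$num_folds) - 1L, n)
    hold <- perm[fold == 0L]; grow <- perm[fold != 0L]
    grown <- fmll:::grow_node(enc, y, length(classes), grow, 0L, ctl)
    err_before <- fmll:::prune_node(grown, enc, y, length(classes), hold)
    pruned <- err_before$node
    # measure the unpruned tree's hold-out error independently
    route_err <- function(node, idx) {
      if (is.null(node$split))
        return(sum(y[idx] != node$predicted))
      parts <- fmll:::route_indices(node, enc, idx)
      sum(vapply(seq_along(parts),
                 function(i) route_err(node$children[[i]], parts[[i]]), 0))
    }
    expect_lte(err_before$err, route_err(grown, hold))
    expect_lte(fmll:::count_nodes(pruned), fmll:::count_nodes(grown))
  }
})

test_that("a subtree that errs more than its majority leaf is collapsed", {
  # grown tree separates x perfectly on the training part, but the hold-out
  # contradicts the split, so pruning must collapse it to a leaf
  stds <- four_row_stds()
  ctl <- reptree_control(no_pruning = TRUE)
  m <- reptree(stds, ctl)
  enc <- fmll:::encode_features(stds$data, stds$features, ctl)
  y_hold <- match(c("B", "B", "A", "A"), c("A", "B"))   # anti-correlated
  res <- fmll:::prune_node(m$root, enc, y_hold, 2L, 1:4)
  expect_null(res$node$split)
  # and a subtree with zero hold-out error is retained
  y_ok <- match(c("A", "A", "B", "B"), c("A", "B"))
  res2 <- fmll:::prune_node(m$root, enc, y_ok, 2L, 1:4)
  expect_false(is.null(res2$node$split))
  expect_equal(res2$err, 0)
})

test_that("fitting is deterministic and respects its preconditions", {
  stds <- random_stds(n = 60, n_num = 2, n_nom = 1, n_classes = 2, seed = 77)
  m1 <- reptree(stds, reptree_control(seed = 3))
  m2 <- reptree(stds, reptree_control(seed = 3))
  expect_identical(m1$root, m2$root)
  expect_identical(render_tree(m1), render_tree(m2))
  tiny <- stds
  tiny$data <- tiny$data[1:2, ]; tiny$target <- tiny$target[1:2]
  expect_error(reptree(tiny, reptree_control(num_folds = 3)), "at least num_folds")
  expect_error(reptree_control(num_folds = 1), "num_folds")
  expect_error(reptree_control(min_num = 0), "min_num")
  expect_error(reptree_control(bogus = 1), "unknown control")
  expect_message(reptree_control(batchSize = 100), "inert")
})

test_that("the learner recovers a planted rule at depth 2", {
  gen <- synth_generate(synth_config(n_samples = 2000, numeric_features = 5,
                                     labels = c(lab = 2L), rule_depth = 2,
                                     seed = 21))
  stds <- br_decompose(gen$dataset, "strict_binary")[[1]]
  m <- reptree(stds, reptree_control())
  acc <- mean(predict(m, stds$data) == as.character(stds$target))
  expect_gte(acc, 0.95)
})

test_that("depth never exceeds max_depth", {
  for (d in c(1L, 2L, 3L)) {
    stds <- random_stds(n = 150, n_num = 3, n_nom = 1, n_classes = 3,
                        seed = 300 + d)
    m <- reptree(stds, reptree_control(max_depth = d, no_pruning = TRUE))
    expect_lte(fmll:::tree_depth(m$root), d)
  }
})

test_that("rendered trees carry branch tests and leaf count annotations", {
  # hand-built leaf: predicted class "0", training counts (a=10, b=4
  # misclassified), hold-out majority/minority (5, 1)
  leaf <- list(split = NULL, children = list(), class_counts = c(6, 4),
               prune_counts = c(5, 1), predicted = 1L, depth = 0L)
  model <- structure(list(root = leaf, control = reptree_control(),
                          classes = c("0", "1"),
                          target = label_spec("t", c("0", "1")),
                          mode = "strict_binary", features = list(),
                          n_train = 14L), class = "reptree")
  expect_equal(render_tree(model), "0 (10/4) [5/1]")
  expect_equal(render_tree(model, bracket = "holdout_error"), "0 (10/4) [6/1]")

  # nominal branches print "FEATURE = category"
  ds <- multilabel_dataset(
    data.frame(TR = c("1", "1", "2", "2", "1", "2"),
               y = c("0", "0", "1", "1", "0", "1"), stringsAsFactors = FALSE),
    features = list(feature_spec("TR", "nominal", c("1", "2"))),
    labels = list(label_spec("y", c("0", "1"))))
  m <- reptree(br_decompose(ds, "strict_binary")[[1]],
               reptree_control(no_pruning = TRUE, min_num = 1))
  txt <- render_tree(m)
  expect_match(txt, "TR = 1 : 0 \\(3/0\\) \\[0/0\\]")
  expect_match(txt, "TR = 2 : 1 \\(3/0\\) \\[0/0\\]")
})

test_that("models serialize to JSON and back without loss", {
  stds <- random_stds(n = 80, n_num = 2, n_nom = 1, n_classes = 3, seed = 55)
  m <- reptree(stds, reptree_control(seed = 2))
  path <- withr::local_tempfile(fileext = ".json")
  write_fmll_model(m, path)
  back <- read_fmll_model(path)
  expect_equal(back$root, m$root)
  expect_equal(back$classes, m$classes)
  expect_identical(render_tree(back), render_tree(m))
  expect_equal(predict(back, stds$data), predict(m, stds$data))
})
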