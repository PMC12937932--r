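test_that("cumulative importance bookkeeping matches hand computation", {
  att <- list(c(a = 0.5, b = 0.3, c = 0.15, d = 0.05))
  g <- aggregate_global(att)
  expect_equal(unname(g$cumulative), c(0.5, 0.8, 0.95, 1.0))
  expect_equal(g$top_set, c("a", "b", "c"))
  # single dominant feature
  g1 <- aggregate_global(list(c(x = 1, y = 0, z = 0)))
  expect_equal(g1$top_set, "x")
  # uniform mass over 100 features reaches 0.95 at exactly 95
  u <- setNames(rep(0.01, 100), sprintf("f%03d", 1:100))
  gu <- aggregate_global(list(u))
  expect_length(gu$top_set, 95)
  # curve properties
  expect_true(all(diff(g$cumulative) >= -1e-12))
  expect_equal(unname(g$cumulative[length(g$cumulative)]), 1,
               tolerance = 1e-9)
})

test_that("aggregation averages folds and is order invariant", {
  a1 <- c(a = 0.2, b = 0.6, c = 0.2)
  a2 <- c(a = 0.8, b = 0.0, c = 0.2)
  g12 <- aggregate_global(list(a1, a2))
  g21 <- aggregate_global(list(a2, a1))
  expect_identical(g12, g21)
  expect_equal(unname(g12$importance[c("a", "b", "c")]),
               c(0.5, 0.3, 0.2))
})

test_that("selection stability counts fold membership and intersects the top set", {
  lists <- list(c("a", "b"), c("a", "b"), c("a", "c"))
  st <- selection_stability(lists, top_set = c("a", "b", "c"))
  expect_equal(unname(st$stability[c("a", "b", "c")]),
               c(100, 200 / 3, 100 / 3))
  expect_equal(st$stable_set, "a")
  # full and half membership
  st30 <- selection_stability(rep(list("x"), 30))
  expect_equal(unname(st30$stability["x"]), 100)
  st15 <- selection_stability(c(rep(list("x"), 15), rep(list("y"), 15)))
  expect_equal(unname(st15$stability["x"]), 50)
  # the stable set shrinks weakly as the cutoff rises
  sizes <- vapply(seq(0, 100, by = 10), function(cut) {
    length(selection_stability(lists, cutoff = cut)$stable_set)
  }, 0L)
  expect_true(all(diff(sizes) <= 0))
})

test_that("fold attributions satisfy additivity and zero out unselected features", {
  tf <- toy_separable(n_per_group = 12, p_noise = 5)
  params <- list(vfs_k = 3, vfs_lr_c = 1, nrounds = 80, max_depth = 3,
                 eta = 0.2, subsample = 1, colsample_bytree = 1,
                 alpha = 0.01, lambda = 1)
  train <- 1:18
  pl <- kinectome:::fit_pipeline(tf$X[train, ], tf$y[train], params,
                                 seed = 4)
  test_rows <- 19:24
  att <- fold_attributions(pl, tf$X[test_rows, ], tf$y[test_rows])
  # local accuracy: contributions + bias reproduce the margin output
  Xc <- kinectome:::apply_clean_stats(tf$X[test_rows, ], pl$clean_stats)
  marg <- predict(pl$model,
                  xgboost::xgb.DMatrix(Xc[, pl$selected, drop = FALSE]),
                  outputmargin = TRUE)
  expect_equal(unname(rowSums(att$per_subject)), unname(marg),
               tolerance = 1e-4)
  unselected <- setdiff(colnames(tf$X), pl$selected)
  expect_true(all(att$mean_abs[unselected] == 0))
  expect_error(fold_attributions(pl, tf$X[0, , drop = FALSE]), "empty")
})

test_that("a single-feature model carries all attribution mass", {
  set.seed(41)
  n <- 40
  y <- rep(c(1L, 0L), each = n / 2)
  X <- cbind(only = ifelse(y == 1, 1.5, -1.5) + rnorm(n, 0, 0.2))
  params <- list(vfs_k = 1, vfs_lr_c = 1, nrounds = 50, max_depth = 2,
                 eta = 0.3, subsample = 1, colsample_bytree = 1,
                 alpha = 0.01, lambda = 1)
  pl <- kinectome:::fit_pipeline(X, y, params, seed = 1)
  att <- fold_attributions(pl, X, y)
  expect_equal(names(which(att$mean_abs > 0)), "only")
})

test_that("body-network export maps features to nodes and edges", {
  imp <- c("A_Pelvis_Head" = 0.6, "clustering_Left Forearm" = 0.3,
           "global_avg_clustering" = 0.1)
  summ <- structure(list(
    importance = sort(imp, decreasing = TRUE),
    cumulative = cumsum(sort(imp, decreasing = TRUE)),
    top_set = names(imp), stable_set = names(imp),
    stability = setNames(rep(100, 3), names(imp)),
    signed_case = c("A_Pelvis_Head" = 0.2,
                    "clustering_Left Forearm" = -0.1,
                    "global_avg_clustering" = -0.05),
    n_folds = 5), class = "ShapSummary")
  doc <- export_body_network(summ)
  expect_length(doc$edges, 1)
  expect_equal(doc$edges[[1]]$pair, c("Pelvis", "Head"))
  expect_equal(doc$edges[[1]]$direction, 1)
  expect_length(doc$nodes, 1)
  expect_equal(doc$nodes[[1]]$segment, "Left Forearm")
  expect_equal(doc$nodes[[1]]$direction, -1)
  expect_equal(doc$unmapped, "global_avg_clustering")
  # adjacency-only summary yields one edge and no nodes
  doc2 <- export_body_network(summ, features = "A_Pelvis_Head")
  expect_length(doc2$nodes, 0)
  expect_length(doc2$edges, 1)
  # multi-word segment pairs resolve unambiguously
  m <- kinectome:::map_feature("A_Left Upper Arm_Left Lower Leg")
  expect_equal(m$kind, "edge")
  expect_equal(c(m$from, m$to), c("Left Upper Arm", "Left Lower Leg"))
})
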