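test_that("KDE pair estimation recovers known densities on a shared grid", {
  set.seed(4)
  z <- rnorm(1e5)
  pq <- estimate_pdf_pair(z, z + 1)
  expect_identical(pq[[1]]$grid, pq[[2]]$grid)
  at0 <- approx(pq[[1]]$grid, pq[[1]]$density, xout = 0)$y
  expect_equal(at0, dnorm(0), tolerance = 0.02)
  # unit trapezoid integral
  tr <- kinectome:::trapz(pq[[1]]$grid, pq[[1]]$density)
  expect_equal(tr, 1, tolerance = 1e-6)
})

test_that("KDE is symmetric under mirroring and deterministic", {
  set.seed(5)
  x <- rnorm(500, 1, 0.7); y <- rnorm(500, -0.5, 1.2)
  a <- estimate_pdf_pair(x, y)
  b <- estimate_pdf_pair(-x, -y)
  expect_equal(a[[1]]$density, rev(b[[1]]$density), tolerance = 1e-9)
  c1 <- estimate_pdf_pair(x, x)
  expect_identical(c1[[1]], c1[[2]])
  expect_error(estimate_pdf_pair(rep(1, 20), x), "zero-variance")
  expect_error(estimate_pdf_pair(1:3, x), ">= 8")
})

test_that("JS divergence has the right fixed points and symmetry", {
  grid <- seq(-5, 5, length.out = 512)
  boxify <- function(lo, hi) {
    d <- ifelse(grid >= lo & grid <= hi, 1, 0)
    list(grid = grid, density = d / kinectome:::trapz(grid, d))
  }
  p <- boxify(-4, -1); q <- boxify(1, 4)
  expect_equal(js_divergence(p, p), 0, tolerance = 1e-9)
  expect_equal(js_divergence(p, q), 1, tolerance = 1e-6)
  expect_equal(js_divergence(p, q), js_divergence(q, p))
  p2 <- list(grid = grid + 1, density = p$density)
  expect_error(js_divergence(p, p2), "grid")
})

test_that("JS on discretized Gaussians matches dense quadrature", {
  f_p <- function(x) dnorm(x, 0, 1)
  f_q <- function(x) dnorm(x, 2, 1)
  grid <- seq(-6, 8, length.out = 512)
  mk <- function(f) {
    d <- f(grid)
    list(grid = grid, density = d / kinectome:::trapz(grid, d))
  }
  js <- js_divergence(mk(f_p), mk(f_q))
  expect_equal(js, oracle_js_quadrature(f_p, f_q, -6, 8), tolerance = 1e-3)
})

test_that("similarity networks are symmetric, bounded, and match a brute-force JS loop", {
  fx <- small_cohort_features()
  net <- fx$nets[[1]]
  A <- net$A
  expect_identical(A, t(A))
  expect_true(all(diag(A) == 0))
  expect_true(all(A >= 0 & A <= 1, na.rm = TRUE))
  # brute-force recomputation of a subset of pairs
  mags <- fx$kin[[1]]$magnitudes
  for (pair in list(c(1, 2), c(3, 17), c(7, 23))) {
    pq <- estimate_pdf_pair(mags[[pair[1]]], mags[[pair[2]]])
    expect_equal(A[pair[1], pair[2]],
                 1 - js_divergence(pq[[1]], pq[[2]]), tolerance = 1e-12)
  }
  # identical signals give similarity 1
  two <- build_network(list(a = mags[[1]], b = mags[[1]]))
  expect_equal(two$A["a", "b"], 1, tolerance = 1e-6)
  # non-overlapping amplitude ranges give similarity ~ 0
  far <- build_network(list(a = rnorm(300), b = rnorm(300, 50)))
  expect_lt(far$A["a", "b"], 1e-3)
})

test_that("thresholding keeps exactly the edges at or above tau and is monotone", {
  A <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  A["a", "b"] <- A["b", "a"] <- 0.3
  A["a", "c"] <- A["c", "a"] <- 0.5
  A["b", "c"] <- A["c", "b"] <- 0.7
  net <- structure(list(nodes = letters[1:3], A = A),
                   class = "SubjectNetwork")
  expect_equal(igraph::ecount(threshold_graph(net, 0)), 3)
  expect_equal(igraph::ecount(threshold_graph(net, 0.5)), 2)
  expect_equal(igraph::ecount(threshold_graph(net, 1)), 0)
  g <- threshold_graph(net, 0.5, mode = "binary")
  expect_true(all(igraph::E(g)$weight == 1))
  # monotone edge counts on a random network
  set.seed(11)
  B <- matrix(runif(100), 10); B <- (B + t(B)) / 2; diag(B) <- 0
  dimnames(B) <- list(paste0("n", 1:10), paste0("n", 1:10))
  netB <- structure(list(nodes = rownames(B), A = B),
                    class = "SubjectNetwork")
  counts <- vapply(seq(0, 1, by = 0.05), function(tau) {
    igraph::ecount(threshold_graph(netB, tau))
  }, 0)
  expect_true(all(diff(counts) <= 0))
})

test_that("local metrics match hand-computed small-graph values", {
  tri <- igraph::make_full_graph(3)
  igraph::V(tri)$name <- c("a", "b", "c")
  igraph::E(tri)$weight <- 1
  lm <- local_metrics(tri)
  expect_equal(lm$degree, rep(2, 3))
  expect_equal(lm$clustering, rep(1, 3))
  expect_equal(lm$betweenness, rep(0, 3))
  # path a-b-c: b lies on the single a-c shortest path
  path <- igraph::graph_from_literal(a - b - c)
  igraph::E(path)$weight <- 1
  lmp <- local_metrics(path)
  expect_equal(lmp$betweenness[lmp$node == "b"], 1)
  # vertex-transitive ring: eigenvector and pagerank equal across nodes
  ring <- igraph::make_ring(6)
  igraph::V(ring)$name <- paste0("n", 1:6)
  igraph::E(ring)$weight <- 1
  lmr <- local_metrics(ring)
  expect_lt(diff(range(lmr$eigenvector)), 1e-6)
  expect_lt(diff(range(lmr$pagerank)), 1e-6)
})

test_that("global metrics match hand-computed values on canonical graphs", {
  k4 <- igraph::make_full_graph(4)
  igraph::V(k4)$name <- letters[1:4]
  igraph::E(k4)$weight <- 1
  gm <- global_metrics(k4)
  expect_equal(gm$density, 1)
  expect_equal(gm$transitivity, 1)
  expect_equal(gm$avg_clustering, 1)
  expect_equal(gm$char_path_length, 1)
  expect_equal(gm$global_efficiency, 1)
  expect_equal(gm$n_components, 1)

  empty5 <- igraph::make_empty_graph(5, directed = FALSE)
  igraph::V(empty5)$name <- letters[1:5]
  gm0 <- global_metrics(empty5)
  expect_equal(gm0$density, 0)
  expect_equal(gm0$n_components, 5)
  expect_true(is.na(gm0$char_path_length))

  # two disjoint triangles: greedy modularity partition scores 0.5
  tt <- igraph::graph_from_literal(a - b, b - c, c - a, d - e, e - f, f - d)
  igraph::E(tt)$weight <- 1
  gm2 <- global_metrics(tt)
  expect_equal(gm2$n_components, 2)
  expect_equal(gm2$char_path_length, 1)
  expect_equal(gm2$modularity, 0.5)
})

test_that("threshold averaging uses only thresholds where a metric is defined", {
  fx <- small_cohort_features()
  net <- fx$nets[[2]]
  gm <- metrics_across_thresholds(net)
  expect_length(gm$per_tau, 9)
  expect_equal(vapply(gm$per_tau, function(x) x$tau, 0),
               seq(0.20, 0.60, by = 0.05))
  # hand-average one metric over defined thresholds
  per <- vapply(gm$per_tau, function(x) x$global$assortativity, 0)
  expect_equal(gm$global[["assortativity"]],
               mean(per[is.finite(per)]))
  per_cpl <- vapply(gm$per_tau, function(x) x$global$char_path_length, 0)
  expect_equal(gm$global[["char_path_length"]],
               mean(per_cpl[is.finite(per_cpl)]))
})

test_that("node relabelling permutes the network and metrics consistently", {
  fx <- small_cohort_features()
  mags <- fx$kin[[3]]$magnitudes[1:6]
  net <- build_network(mags)
  perm <- c(4, 1, 6, 2, 5, 3)
  net_p <- build_network(mags[perm])
  expect_equal(net_p$A, net$A[perm, perm], tolerance = 1e-12)
  lm <- local_metrics(threshold_graph(net, 0.3))
  lm_p <- local_metrics(threshold_graph(net_p, 0.3))
  expect_equal(lm_p$strength, lm$strength[perm], tolerance = 1e-9)
  expect_equal(lm_p$betweenness, lm$betweenness[perm], tolerance = 1e-9)
})
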