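#' Default edge-retention threshold grid
#'
#' Thresholds swept when binarizing/pruning similarity networks:
#' 0.20 to 0.60 in steps of 0.05 (9 values). Graph metrics are averaged
#' across the sweep so no single arbitrary cutoff drives the topology.
#'
#' @param min,max,step Grid limits and spacing, all within \[0, 1\].
#' @return Strictly increasing numeric vector of thresholds.
#' @export
threshold_grid <- function(min = 0.20, max = 0.60, step = 0.05) {
  if (min < 0 || max > 1 || step <= 0 || min >= max) {
    stop("invalid threshold grid", call. = FALSE)
  }
  seq(min, max, by = step)
}

#' Kernel density estimates of two sample sets on a shared grid
#'
#' Gaussian-kernel KDE with Silverman's rule-of-thumb bandwidth per sample
#' set, evaluated on a common grid of 512 points spanning the pooled range
#' extended by three bandwidths (using the larger of the two bandwidths), so
#' the two densities are directly comparable. Each density is renormalized
#' to unit trapezoid integral on the grid.
#'
#' @param samples_i,samples_j Numeric vectors, each with >= 8 finite values
#'   and positive variance.
#' @param n_grid Number of grid points (default 512).
#' @return List of two `DiscretePDF` objects (`grid`, `density`).
#' @export
estimate_pdf_pair <- function(samples_i, samples_j, n_grid = 512L) {
  check <- function(x, nm) {
    x <- x[is.finite(x)]
    if (length(x) < 8L) stop(nm, ": need >= 8 finite samples", call. = FALSE)
    if (var(x) <= 0) {
      stop(nm, ": zero-variance (degenerate) signal", call. = FALSE)
    }
    x
  }
  samples_i <- check(samples_i, "samples_i")
  samples_j <- check(samples_j, "samples_j")
  h_i <- stats::bw.nrd0(samples_i)
  h_j <- stats::bw.nrd0(samples_j)
  h <- max(h_i, h_j)
  lo <- min(samples_i, samples_j) - 3 * h
  hi <- max(samples_i, samples_j) + 3 * h
  kde <- function(x, bw) {
    d <- density(x, bw = bw, kernel = "gaussian", from = lo, to = hi,
                 n = n_grid)
    dens <- pmax(d$y, 0)
    dens <- dens / trapz(d$x, dens)
    list(grid = d$x, density = dens)
  }
  list(kde(samples_i, h_i), kde(samples_j, h_j))
}

trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1L] - x[-n]) * (y[-1L] + y[-n])) / 2
}

#' Jensen-Shannon divergence between two discretized densities
#'
#' `JS(p, q) = KL(p || M)/2 + KL(q || M)/2` with mixture `M = (p + q)/2`,
#' logarithms base 2 so the result lies in \[0, 1\] (0 for identical
#' densities, 1 for disjoint supports). Kullback-Leibler terms are evaluated
#' by trapezoid quadrature on the shared grid with the `0 log 0 = 0`
#' convention and a 1e-12 floor inside logarithms.
#'
#' @param p,q `DiscretePDF` objects (lists with `grid` and `density`) on an
#'   identical grid, each integrating to 1.
#' @return Scalar in \[0, 1\].
#' @export
js_divergence <- function(p, q) {
  if (length(p$grid) != length(q$grid) ||
      max(abs(p$grid - q$grid)) > 1e-12 * max(1, max(abs(p$grid)))) {
    stop("densities must share an identical grid", call. = FALSE)
  }
  eps <- 1e-12
  m <- (p$density + q$density) / 2
  kl <- function(a) {
    integrand <- ifelse(a > 0, a * log2(pmax(a, eps) / pmax(m, eps)), 0)
    trapz(p$grid, integrand)
  }
  js <- (kl(p$density) + kl(q$density)) / 2
  min(max(js, 0), 1)
}

#' Build a subject-specific similarity network
#'
#' Nodes are body segments; the edge weight between segments i and j is
#' `A_ij = 1 - JS(p_i, p_j)`, where `p_i`, `p_j` are kernel density
#' estimates of the two segments' position-magnitude amplitude
#' distributions, compared on a per-pair shared grid. High weight means the
#' two segments' movement amplitude distributions are similar. The matrix is
#' symmetric with zero diagonal (self-similarity is excluded).
#'
#' @param magnitudes Named list of per-segment magnitude signals `m_i(t)`
#'   (e.g. the `magnitudes` element of [kinematic_features()]).
#' @param n_grid KDE grid size per pair (default 512).
#' @return A `SubjectNetwork`: list with `nodes` and symmetric weight matrix
#'   `A` (dimnames = nodes). Segments whose KDE fails (degenerate signals)
#'   get `NA` rows/columns and are listed in `attr(net, "failed")`.
#' @export
build_network <- function(magnitudes, n_grid = 512L) {
  segs <- names(magnitudes)
  n <- length(segs)
  if (n < 2L) stop("need at least 2 segments", call. = FALSE)
  A <- matrix(0, n, n, dimnames = list(segs, segs))
  ok <- vapply(magnitudes, function(x) {
    x <- x[is.finite(x)]
    length(x) >= 8L && var(x) > 0
  }, TRUE)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (!ok[i] || !ok[j]) {
        A[i, j] <- A[j, i] <- NA_real_
        next
      }
      pq <- estimate_pdf_pair(magnitudes[[i]], magnitudes[[j]],
                              n_grid = n_grid)
      A[i, j] <- A[j, i] <- 1 - js_divergence(pq[[1L]], pq[[2L]])
    }
  }
  if (any(!ok)) A[!ok, ] <- NA_real_
  diag(A) <- 0
  structure(list(nodes = segs, A = A), class = "SubjectNetwork",
            failed = segs[!ok])
}

#' Threshold a similarity network
#'
#' Retains edge (i, j) iff `A_ij >= tau`. In `"weighted"` mode (default)
#' surviving edges keep their similarity weight; in `"binary"` mode they get
#' weight 1. `NA` entries (failed segments) never form edges.
#'
#' @param net A `SubjectNetwork`.
#' @param tau Threshold in \[0, 1\].
#' @param mode `"weighted"` or `"binary"`.
#' @return An `igraph` undirected graph with a `weight` edge attribute.
#' @export
threshold_graph <- function(net, tau, mode = c("weighted", "binary")) {
  mode <- match.arg(mode)
  if (tau < 0 || tau > 1) stop("tau must lie in [0, 1]", call. = FALSE)
  A <- net$A
  keep <- !is.na(A) & A >= tau
  W <- ifelse(keep, if (mode == "binary") 1 else A, 0)
  diag(W) <- 0
  igraph::graph_from_adjacency_matrix(W, mode = "undirected", weighted = TRUE)
}

#' Per-node graph metrics
#'
#' Computes, for every node: `degree` (unweighted edge count), `strength`
#' (sum of incident edge weights), `clustering` (weighted local clustering
#' coefficient, geometric-mean triangle weights scaled by the maximum edge
#' weight; reduces to the standard local clustering coefficient on binary
#' graphs), `betweenness` and `closeness` (shortest paths with edge length =
#' edge weight, i.e. the similarity weight read literally as a distance;
#' both normalized, isolated nodes get closeness 0), `eigenvector`
#' (principal eigenvector of the weight matrix by power iteration, tolerance
#' 1e-6, at most 1000 iterations, unit Euclidean norm; `NA` for all nodes if
#' the iteration does not converge), and `pagerank` (weighted, damping
#' 0.85).
#'
#' @param g An `igraph` graph with `weight` edge attributes.
#' @param distance How edge weights map to path lengths for betweenness /
#'   closeness: `"identity"` (weight itself, default), `"one_minus"`
#'   (`1 - w`), or `"inverse"` (`1 / w`).
#' @return data.frame with one row per node.
#' @export
local_metrics <- function(g, distance = c("identity", "one_minus", "inverse")) {
  distance <- match.arg(distance)
  n <- igraph::vcount(g)
  if (n < 1L) stop("graph must have at least 1 node", call. = FALSE)
  W <- weight_matrix(g)
  deg <- rowSums(W > 0)
  strength <- rowSums(W)
  clust <- weighted_clustering(W)
  dl <- edge_lengths(g, distance)
  btw <- igraph::betweenness(g, weights = dl, normalized = TRUE)
  clo <- closeness_reach(g, dl)
  eig <- eigenvector_power(W)
  pr <- igraph::page_rank(g, damping = 0.85,
                          weights = edge_weights(g))$vector
  if (igraph::ecount(g) == 0L) pr <- rep(1 / n, n)
  data.frame(
    node = igraph::V(g)$name, degree = deg, strength = strength,
    clustering = clust, betweenness = btw, closeness = clo,
    eigenvector = eig, pagerank = unname(pr),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

edge_lengths <- function(g, distance) {
  w <- edge_weights(g)
  switch(distance,
    identity = w,
    one_minus = pmax(1 - w, 1e-12),
    inverse = 1 / w
  )
}

# Edge weights, defaulting to 1 when the graph carries no weight attribute.
edge_weights <- function(g) {
  if ("weight" %in% igraph::edge_attr_names(g)) igraph::E(g)$weight
  else rep(1, igraph::ecount(g))
}

weight_matrix <- function(g) {
  if ("weight" %in% igraph::edge_attr_names(g)) {
    as.matrix(igraph::as_adjacency_matrix(g, attr = "weight",
                                          sparse = FALSE))
  } else {
    as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  }
}

# Onnela-style weighted local clustering: geometric mean of triangle edge
# weights scaled by max weight; equals binary clustering when weights are 1.
weighted_clustering <- function(W) {
  n <- nrow(W)
  k <- rowSums(W > 0)
  wmax <- max(W)
  if (wmax <= 0) return(rep(0, n))
  Wh <- (W / wmax)^(1 / 3)
  tri <- diag(Wh %*% Wh %*% Wh)
  out <- ifelse(k >= 2, tri / (k * (k - 1)), 0)
  pmin(pmax(out, 0), 1)
}

# Closeness with reachability scaling (the component-aware convention):
# for node i with R reachable nodes at total distance D,
# closeness = (R / (n-1)) * (R / D); isolated nodes get 0.
closeness_reach <- function(g, dl) {
  n <- igraph::vcount(g)
  if (n == 1L) return(0)
  D <- igraph::distances(g, weights = dl)
  vapply(seq_len(n), function(i) {
    d <- D[i, -i]
    d <- d[is.finite(d)]
    r <- length(d)
    if (r == 0L || sum(d) == 0) return(0)
    (r / (n - 1)) * (r / sum(d))
  }, 0)
}

eigenvector_power <- function(W, tol = 1e-6, max_iter = 1000L) {
  n <- nrow(W)
  if (all(W == 0)) return(rep(1 / sqrt(n), n))
  v <- rep(1 / sqrt(n), n)
  for (it in seq_len(max_iter)) {
    v_new <- W %*% v
    nrm <- sqrt(sum(v_new^2))
    if (nrm == 0) return(rep(NA_real_, n))
    v_new <- as.numeric(v_new / nrm)
    if (max(abs(v_new - v)) < tol) return(abs(v_new))
    v <- v_new
  }
  rep(NA_real_, n)
}

#' Global graph metrics
#'
#' Computes `density` (fraction of possible edges present), `avg_clustering`
#' (mean of the local clustering coefficients), `global_efficiency` (mean
#' over ordered pairs of 1/shortest-path-length, unreachable pairs
#' contributing 0), `char_path_length` (mean shortest-path length, computed
#' on the largest connected component when the graph is disconnected; `NA`
#' on edgeless graphs), `modularity` (of the greedy agglomerative community
#' partition), `assortativity` (degree assortativity; `NA` when undefined,
#' e.g. on regular graphs), `transitivity` (global, triangle-based),
#' `avg_strength`, and `n_components`.
#'
#' @inheritParams local_metrics
#' @return Named list of scalars (possibly `NA` where undefined).
#' @export
global_metrics <- function(g, distance = c("identity", "one_minus", "inverse")) {
  distance <- match.arg(distance)
  n <- igraph::vcount(g)
  if (n < 2L) stop("graph must have at least 2 nodes", call. = FALSE)
  W <- weight_matrix(g)
  m <- igraph::ecount(g)
  dens <- m / (n * (n - 1) / 2)
  avg_clust <- mean(weighted_clustering(W))
  dl <- edge_lengths(g, distance)
  D <- igraph::distances(g, weights = dl)
  offdiag <- D[row(D) != col(D)]
  geff <- mean(ifelse(is.finite(offdiag) & offdiag > 0, 1 / offdiag, 0))
  comp <- igraph::components(g)
  cpl <- NA_real_
  if (m > 0L) {
    big <- which.max(comp$csize)
    idx <- which(comp$membership == big)
    if (length(idx) >= 2L) {
      Dc <- D[idx, idx]
      cpl <- mean(Dc[row(Dc) != col(Dc)])
    }
  }
  mod <- NA_real_
  if (m > 0L) {
    cl <- tryCatch(
      igraph::cluster_fast_greedy(g, weights = edge_weights(g)),
      error = function(e) NULL)
    if (!is.null(cl)) {
      mod <- igraph::modularity(g, igraph::membership(cl),
                                weights = edge_weights(g))
    }
  }
  assort <- suppressWarnings(igraph::assortativity_degree(g))
  if (!is.finite(assort)) assort <- NA_real_
  trans <- igraph::transitivity(g, type = "global")
  if (!is.finite(trans)) trans <- NA_real_
  list(
    density = dens, avg_clustering = avg_clust, global_efficiency = geff,
    char_path_length = cpl, modularity = mod, assortativity = assort,
    transitivity = trans, avg_strength = mean(rowSums(W)),
    n_components = comp$no
  )
}

#' Threshold-averaged graph metrics of a subject network
#'
#' Sweeps the threshold grid, computes all local and global metrics at each
#' threshold, and averages each metric arithmetically over the thresholds at
#' which it is defined (finite). Metrics undefined at every threshold are
#' reported as `NA`. The per-threshold values are retained for audit.
#'
#' @param net A `SubjectNetwork`.
#' @param grid Threshold vector (default [threshold_grid()]).
#' @param mode Passed to [threshold_graph()].
#' @param distance Passed to [local_metrics()] / [global_metrics()].
#' @return A `GraphMetricVector`: list with `local` (data.frame node x
#'   metric, threshold-averaged), `global` (named numeric vector), and
#'   `per_tau` (list of per-threshold raw results).
#' @export
metrics_across_thresholds <- function(net, grid = threshold_grid(),
                                      mode = "weighted",
                                      distance = "identity") {
  per_tau <- lapply(grid, function(tau) {
    g <- threshold_graph(net, tau, mode = mode)
    list(tau = tau, local = local_metrics(g, distance = distance),
         global = global_metrics(g, distance = distance))
  })
  loc_names <- c("degree", "strength", "clustering", "betweenness",
                 "closeness", "eigenvector", "pagerank")
  nodes <- net$nodes
  loc_avg <- sapply(loc_names, function(mname) {
    vals <- sapply(per_tau, function(pt) pt$local[[mname]])  # node x tau
    apply(as.matrix(vals), 1L, mean_defined)
  })
  loc <- data.frame(node = nodes, loc_avg, row.names = NULL,
                    stringsAsFactors = FALSE)
  glob_names <- names(per_tau[[1L]]$global)
  glob <- vapply(glob_names, function(mname) {
    mean_defined(vapply(per_tau, function(pt) pt$global[[mname]], 0))
  }, 0)
  structure(list(local = loc, global = glob, per_tau = per_tau),
            class = "GraphMetricVector")
}

mean_defined <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) NA_real_ else mean(x)
}
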