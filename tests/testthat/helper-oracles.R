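# Independent brute-force oracles used to validate the package's
# implementations. These deliberately use naive algorithms (loops,
# enumeration, dense quadrature) distinct from the implementation paths.

# Jensen-Shannon divergence between two analytic density functions by dense
# trapezoid quadrature (base-2 logs).
oracle_js_quadrature <- function(f_p, f_q, lo, hi, n = 1e5L) {
  x <- seq(lo, hi, length.out = n)
  p <- f_p(x); q <- f_q(x)
  trap <- function(y) sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
  p <- p / trap(p); q <- q / trap(q)
  m <- (p + q) / 2
  term <- function(a) ifelse(a > 0, a * log2(pmax(a, 1e-300) /
                                               pmax(m, 1e-300)), 0)
  (trap(term(p)) + trap(term(q))) / 2
}

# All-pairs shortest path distances by Floyd-Warshall on an edge-length
# matrix (Inf = no edge).
oracle_fw <- function(L) {
  n <- nrow(L)
  D <- L
  diag(D) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
      }
    }
  }
  D
}

# Enumerate every simple path between two nodes by depth-first search.
oracle_all_simple_paths <- function(adj, s, t) {
  n <- nrow(adj)
  paths <- list()
  walk <- function(v, visited, path) {
    if (v == t) {
      paths[[length(paths) + 1L]] <<- path
      return(invisible())
    }
    for (w in seq_len(n)) {
      if (adj[v, w] > 0 && !visited[w]) {
        vis <- visited; vis[w] <- TRUE
        walk(w, vis, c(path, w))
      }
    }
  }
  visited <- rep(FALSE, n); visited[s] <- TRUE
  walk(s, visited, s)
  paths
}

path_len <- function(path, L) {
  if (length(path) < 2L) return(0)
  sum(L[cbind(path[-length(path)], path[-1L])])
}

# Normalized betweenness by explicit enumeration of all shortest simple
# paths (ties counted fractionally).
oracle_betweenness <- function(adj, L = ifelse(adj > 0, 1, Inf)) {
  n <- nrow(adj)
  b <- numeric(n)
  if (n < 3L) return(b)
  for (s in seq_len(n - 1L)) {
    for (t in (s + 1L):n) {
      paths <- oracle_all_simple_paths(adj, s, t)
      if (length(paths) == 0L) next
      lens <- vapply(paths, path_len, 0, L = L)
      short <- paths[abs(lens - min(lens)) < 1e-12]
      sigma <- length(short)
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        through <- sum(vapply(short, function(p) v %in% p, TRUE))
        b[v] <- b[v] + through / sigma
      }
    }
  }
  b / ((n - 1) * (n - 2) / 2)
}

# Reachability-scaled closeness from Floyd-Warshall distances.
oracle_closeness <- function(adj, L = ifelse(adj > 0, 1, Inf)) {
  n <- nrow(adj)
  D <- oracle_fw(L)
  vapply(seq_len(n), function(i) {
    d <- D[i, -i]
    d <- d[is.finite(d)]
    if (length(d) == 0L || sum(d) == 0) return(0)
    (length(d) / (n - 1)) * (length(d) / sum(d))
  }, 0)
}

# Local clustering by explicit triangle counting (binary graphs).
oracle_clustering <- function(adj) {
  n <- nrow(adj)
  vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] > 0)
    k <- length(nb)
    if (k < 2L) return(0)
    tri <- 0
    for (a in seq_len(k - 1L)) {
      for (b in (a + 1L):k) {
        if (adj[nb[a], nb[b]] > 0) tri <- tri + 1
      }
    }
    2 * tri / (k * (k - 1))
  }, 0)
}

oracle_transitivity <- function(adj) {
  n <- nrow(adj)
  triangles <- 0; triples <- 0
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] > 0)
    k <- length(nb)
    if (k < 2L) next
    triples <- triples + k * (k - 1) / 2
    for (a in seq_len(k - 1L)) {
      for (b in (a + 1L):k) {
        if (adj[nb[a], nb[b]] > 0) triangles <- triangles + 1
      }
    }
  }
  if (triples == 0) return(NA_real_)
  triangles / triples  # each triangle appears once per corner
}

oracle_components <- function(adj) {
  n <- nrow(adj)
  seen <- rep(FALSE, n)
  comps <- 0
  for (s in seq_len(n)) {
    if (seen[s]) next
    comps <- comps + 1
    stack <- s
    while (length(stack) > 0L) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (seen[v]) next
      seen[v] <- TRUE
      stack <- c(stack, which(adj[v, ] > 0 & !seen))
    }
  }
  comps
}

# Benjamini-Hochberg step-up by direct implementation of the definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  q[o[m]] <- p[o[m]]
  for (i in (m - 1L):1L) {
    q[o[i]] <- min(p[o[i]] * m / i, q[o[i + 1L]])
  }
  pmin(q, 1)
}

# MultiSURF by naive triple loop, mirroring the documented definition.
oracle_multisurf <- function(X, y) {
  n <- nrow(X); p <- ncol(X)
  rngs <- apply(X, 2, function(v) diff(range(v)))
  Xn <- X
  for (f in seq_len(p)) {
    Xn[, f] <- if (rngs[f] > 0) X[, f] / rngs[f] else 0
  }
  D <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      D[i, j] <- sum(abs(Xn[i, ] - Xn[j, ]))
    }
  }
  pri <- c(mean(y == 0), mean(y == 1))
  S <- numeric(p)
  for (i in seq_len(n)) {
    d <- D[i, -i]
    thr <- mean(d) - sd(d) / 2
    nb <- setdiff(which(D[i, ] < thr), i)
    if (length(nb) == 0L) next
    n_hit <- sum(y[nb] == y[i]); n_miss <- sum(y[nb] != y[i])
    for (j in nb) {
      for (f in seq_len(p)) {
        diff_f <- abs(Xn[i, f] - Xn[j, f])
        if (y[j] == y[i]) {
          S[f] <- S[f] - diff_f / n_hit
        } else {
          w <- pri[y[j] + 1] / (1 - pri[y[i] + 1])
          S[f] <- S[f] + w * diff_f / n_miss
        }
      }
    }
  }
  S / n
}

# Exhaustive re-sort oracle for the voting selection given precomputed
# normalized scores (methods x features matrix).
oracle_vote_order <- function(norm_scores, k) {
  feat <- colnames(norm_scores)
  topk <- apply(norm_scores, 1L, function(s) {
    feat[order(-s, feat)][seq_len(k)]
  })
  votes <- sapply(feat, function(f) sum(apply(topk, 2L, function(tk) f %in% tk)))
  tiesum <- colSums(norm_scores)
  feat[order(-votes, -tiesum, feat)]
}
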