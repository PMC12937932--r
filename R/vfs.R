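#' Rank features with one of the four voting-selector methods
#'
#' The four rankers cover complementary notions of relevance: `anova_f`
#' (one-way F statistic; univariate linear separation), `l1_logistic`
#' (absolute coefficients of an L1-penalized logistic regression at inverse
#' regularization strength `vfs_lr_c`; sparse multivariate linear effects),
#' `gbt_importance` (gain importance of a gradient-boosted tree ensemble at
#' fixed settings: 300 trees, depth 3, learning rate 0.1; non-linear and
#' hierarchical effects), and `multisurf` (nearest-neighbour relevance with
#' adaptive neighbourhoods; interaction-aware, see [rank_multisurf()]).
#' Raw scores are shifted to be nonnegative and min-max normalized to
#' \[0, 1\].
#'
#' @param method One of `"anova_f"`, `"l1_logistic"`, `"gbt_importance"`,
#'   `"multisurf"`.
#' @param X Numeric matrix (subjects x features), cleaned and standardized.
#' @param y Binary labels (0/1 or two-level factor/character).
#' @param vfs_lr_c Inverse regularization strength for `l1_logistic`
#'   (default 1).
#' @param seed Seed for the tree ranker (default 0).
#' @return A `RankerOutput`: list with `method`, `raw`, and `normalized`
#'   per-feature scores (named).
#' @export
rank_features <- function(method = c("anova_f", "l1_logistic",
                                     "gbt_importance", "multisurf"),
                          X, y, vfs_lr_c = 1, seed = 0L) {
  method <- match.arg(method)
  y <- as_binary(y)
  if (length(unique(y)) < 2L) {
    stop("y must contain both classes", call. = FALSE)
  }
  raw <- switch(method,
    anova_f = anova_f_scores(X, y),
    l1_logistic = {
      if (vfs_lr_c <= 0) stop("vfs_lr_c must be positive", call. = FALSE)
      lam <- 1 / (vfs_lr_c * nrow(X))
      # glmnet needs >= 2 columns; pad degenerate input with a zero column
      Xl <- if (ncol(X) < 2L) cbind(X, `..pad` = 0) else X
      # glmnet warns about small classes on toy-sized folds; not actionable
      fit <- suppressWarnings(
        glmnet::glmnet(Xl, y, family = "binomial", alpha = 1,
                       lambda = lam, standardize = FALSE))
      abs(as.numeric(fit$beta))[seq_len(ncol(X))]
    },
    gbt_importance = gbt_gain_scores(X, y, seed = seed),
    multisurf = rank_multisurf(X, y)
  )
  names(raw) <- colnames(X)
  shifted <- raw - min(raw)
  rng <- max(shifted)
  normalized <- if (rng > 0) shifted / rng else rep(0, length(raw))
  names(normalized) <- colnames(X)
  structure(list(method = method, raw = raw, normalized = normalized),
            class = "RankerOutput")
}

as_binary <- function(y) {
  if (is.numeric(y) && all(y %in% c(0, 1))) return(as.integer(y))
  f <- as.factor(y)
  if (nlevels(f) != 2L) stop("y must be binary", call. = FALSE)
  # "case" (or alphabetically first level) maps to 1 if present
  pos <- if ("case" %in% levels(f)) "case" else levels(f)[1L]
  as.integer(f == pos)
}

anova_f_scores <- function(X, y) {
  g1 <- y == 1L
  n1 <- sum(g1); n0 <- sum(!g1); n <- n1 + n0
  m1 <- colMeans(X[g1, , drop = FALSE])
  m0 <- colMeans(X[!g1, , drop = FALSE])
  gm <- colMeans(X)
  ss_between <- n1 * (m1 - gm)^2 + n0 * (m0 - gm)^2
  ss_within <- colSums(sweep(X[g1, , drop = FALSE], 2L, m1)^2) +
    colSums(sweep(X[!g1, , drop = FALSE], 2L, m0)^2)
  f <- (ss_between / 1) / (ss_within / (n - 2))
  if (any(!is.finite(f))) {
    cap <- max(f[is.finite(f)], 1)
    f[!is.finite(f)] <- cap * 2
  }
  f
}

gbt_gain_scores <- function(X, y, seed = 0L, nrounds = 300L) {
  # a single feature trivially carries all the gain
  if (ncol(X) == 1L) return(setNames(1, colnames(X)))
  dtrain <- xgboost::xgb.DMatrix(X, label = y)
  params <- list(objective = "binary:logistic", max_depth = 3, eta = 0.1,
                 nthread = 1, seed = seed)
  bst <- xgboost::xgb.train(params = params, data = dtrain,
                            nrounds = nrounds, verbose = 0)
  imp <- xgboost::xgb.importance(model = bst)
  scores <- setNames(rep(0, ncol(X)), colnames(X))
  if (!is.null(imp) && nrow(imp) > 0L) scores[imp$Feature] <- imp$Gain
  scores
}

#' MultiSURF feature relevance
#'
#' Relief-family ranker with per-instance adaptive neighbourhoods. For each
#' target instance the distances to all other instances (Manhattan on
#' range-normalized features) are summarized by their mean and standard
#' deviation; neighbours are the instances closer than mean minus half the
#' standard deviation. For each neighbour and feature, the score decreases
#' by the normalized feature difference when the neighbour shares the
#' target's class (hit) and increases by it, weighted by the miss class
#' prior over one minus the target class prior, when it does not (miss).
#' Hit and miss contributions are each averaged over their own neighbour
#' counts (the classic Relief normalization, which keeps pure-noise
#' features centred at zero), and scores are then averaged over target
#' instances. Constant features score 0.
#'
#' @param X Numeric matrix (instances x features).
#' @param y Binary labels; each class needs at least 2 members.
#' @return Named numeric vector of per-feature scores.
#' @export
rank_multisurf <- function(X, y) {
  y <- as_binary(y)
  n <- nrow(X)
  if (n < 4L) stop("need at least 4 instances", call. = FALSE)
  if (min(table(y)) < 2L) {
    stop("each class needs at least 2 members", call. = FALSE)
  }
  rngs <- apply(X, 2L, function(v) diff(range(v)))
  active <- rngs > 0
  Xn <- X
  Xn[, active] <- sweep(X[, active, drop = FALSE], 2L, rngs[active], "/")
  Xn[, !active] <- 0
  D <- as.matrix(dist(Xn, method = "manhattan"))
  priors <- table(factor(y, levels = c(0L, 1L))) / n
  S <- numeric(ncol(X))
  for (i in seq_len(n)) {
    d <- D[i, -i]
    thr <- mean(d) - sd(d) / 2
    nb <- setdiff(which(D[i, ] < thr), i)
    if (length(nb) == 0L) next
    diffs <- abs(sweep(Xn[nb, , drop = FALSE], 2L, Xn[i, ]))
    hit <- y[nb] == y[i]
    if (any(hit)) {
      S <- S - colSums(diffs[hit, , drop = FALSE]) / sum(hit)
    }
    if (any(!hit)) {
      w <- priors[as.character(y[nb[!hit]])] / (1 - priors[as.character(y[i])])
      S <- S + colSums(diffs[!hit, , drop = FALSE] * as.numeric(w)) /
        sum(!hit)
    }
  }
  setNames(S / n, colnames(X))
}

#' Voting feature selection
#'
#' Runs the four rankers, gives each feature one vote per method whose
#' top-`vfs_k` list contains it, and orders features by total votes with
#' ties resolved by the summed min-max-normalized importance scores
#' (tie-sum) and finally by feature name for full determinism. The first
#' `vfs_k` features of that ordering are selected.
#'
#' @param X Numeric matrix (subjects x features), cleaned and standardized.
#' @param y Binary labels.
#' @param vfs_k Number of features to retain (clipped to the number of
#'   available features, with a warning).
#' @param vfs_lr_c Inverse regularization strength of the L1-logistic
#'   ranker.
#' @param seed Seed for the tree ranker.
#' @return List with `selected` (ordered character vector of length
#'   `vfs_k`) and `audit` (per-method normalized scores and ranks, votes,
#'   tie-sums, and the full ordering).
#' @export
vote_select <- function(X, y, vfs_k, vfs_lr_c = 1, seed = 0L) {
  p <- ncol(X)
  if (vfs_k > p) {
    warning("vfs_k exceeds the number of features; clipping to ", p)
    vfs_k <- p
  }
  if (vfs_k < 1L) stop("vfs_k must be >= 1", call. = FALSE)
  methods <- c("anova_f", "l1_logistic", "gbt_importance", "multisurf")
  rankers <- lapply(methods, function(m) {
    rank_features(m, X, y, vfs_lr_c = vfs_lr_c, seed = seed)
  })
  names(rankers) <- methods
  norm <- do.call(rbind, lapply(rankers, function(r) r$normalized))
  colnames(norm) <- colnames(X)
  selected <- select_from_scores(norm, vfs_k)
  feat <- colnames(X)
  topk <- lapply(rankers, function(r) {
    feat[order(-r$normalized, feat)][seq_len(vfs_k)]
  })
  votes <- colSums(do.call(rbind, lapply(topk, function(tk) feat %in% tk)))
  tie_sum <- colSums(norm)
  audit <- list(
    methods = methods,
    normalized = norm,
    top_k = topk,
    votes = setNames(votes, feat),
    tie_sum = tie_sum,
    ordering = select_from_scores(norm, vfs_k, n_return = p),
    vfs_k = vfs_k, vfs_lr_c = vfs_lr_c
  )
  list(selected = selected, audit = audit)
}

# Core of the voting rule, separated from the rankers: given a methods x
# features matrix of min-max normalized scores, each method votes for its
# top-k features (score desc, name asc); features are ordered by votes
# desc, tie-sum desc, name asc, and the first n_return are returned.
select_from_scores <- function(norm_scores, k, n_return = k) {
  feat <- colnames(norm_scores)
  p <- length(feat)
  k <- min(k, p)
  votes <- setNames(numeric(p), feat)
  for (m in seq_len(nrow(norm_scores))) {
    tk <- feat[order(-norm_scores[m, ], feat)][seq_len(k)]
    votes[tk] <- votes[tk] + 1
  }
  tie_sum <- colSums(norm_scores)
  feat[order(-votes, -tie_sum, feat)][seq_len(min(n_return, p))]
}
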