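#' Per-feature group comparisons with FDR control
#'
#' Welch two-sample t-test per feature between the two groups, with
#' Benjamini-Hochberg adjustment of the p-values across features.
#'
#' @param table A `FeatureTable` or numeric matrix (subjects x features).
#' @param labels Binary group labels.
#' @return data.frame with `feature`, `statistic`, `p`, `q` (BH-adjusted),
#'   and the group means.
#' @export
group_tests <- function(table, labels) {
  V <- if (inherits(table, "FeatureTable")) table$values else as.matrix(table)
  y <- as_binary(labels)
  if (min(sum(y == 1L), sum(y == 0L)) < 2L) {
    stop("both groups need at least 2 subjects", call. = FALSE)
  }
  res <- lapply(seq_len(ncol(V)), function(j) {
    a <- V[y == 1L, j]; b <- V[y == 0L, j]
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    tt <- if (length(a) < 2L || length(b) < 2L ||
              (var(a) == 0 && var(b) == 0)) {
      # degenerate column: no evidence against equal means
      list(statistic = c(t = 0), p.value = 1)
    } else {
      t.test(a, b)
    }
    c(statistic = unname(tt$statistic), p = tt$p.value,
      mean_case = mean(a), mean_control = mean(b))
  })
  out <- as.data.frame(do.call(rbind, res))
  out$q <- p.adjust(out$p, method = "BH")
  data.frame(feature = colnames(V), out[, c("statistic", "p", "q",
                                            "mean_case", "mean_control")],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Demographic group tests
#'
#' Fisher's exact test (two-sided, hypergeometric) for the sex-by-group
#' 2x2 table and the Kruskal-Wallis rank-sum test (with tie correction)
#' for age.
#'
#' @param metadata data.frame with `group`, `sex`, `age` columns.
#' @return List with `fisher_p`, `kruskal_p`, the 2x2 `sex_table`, and the
#'   Kruskal-Wallis statistic.
#' @export
demographic_tests <- function(metadata) {
  tab <- table(metadata$sex, metadata$group)
  if (!all(dim(tab) == c(2L, 2L))) {
    stop("sex-by-group table must be 2x2 with positive margins",
         call. = FALSE)
  }
  ft <- fisher.test(tab)
  kw <- kruskal.test(metadata$age, factor(metadata$group))
  list(fisher_p = ft$p.value, kruskal_p = kw$p.value, sex_table = tab,
       kruskal_statistic = unname(kw$statistic))
}

#' Spearman screening of features against clinical scores
#'
#' Computes Spearman's rank correlation (midranks for ties) and its
#' two-sided p-value for every feature x clinical-score pair, restricted to
#' subjects with clinical scores (i.e. cases; controls carry none). Pairs
#' with absolute correlation of at least `rho_cutoff` and p below
#' `p_cutoff` are flagged as relevant.
#'
#' @param features Numeric matrix (subjects x features), typically
#'   restricted to the stable feature set.
#' @param clinical data.frame of clinical scores for the same subjects.
#' @param rho_cutoff,p_cutoff Relevance rule (defaults 0.30 and 0.05).
#' @return data.frame with `feature`, `score`, `rho`, `p`, `n`,
#'   `relevant`.
#' @export
spearman_screen <- function(features, clinical, rho_cutoff = 0.30,
                            p_cutoff = 0.05) {
  features <- as.matrix(features)
  out <- list()
  for (f in colnames(features)) {
    for (s in colnames(clinical)) {
      x <- features[, f]; y <- clinical[[s]]
      ok <- is.finite(x) & is.finite(y)
      if (sum(ok) < 5L) next
      ct <- suppressWarnings(cor.test(x[ok], y[ok], method = "spearman",
                                      exact = FALSE))
      rho <- unname(ct$estimate)
      out[[length(out) + 1L]] <- data.frame(
        feature = f, score = s, rho = rho, p = ct$p.value, n = sum(ok),
        relevant = abs(rho) >= rho_cutoff & ct$p.value < p_cutoff,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Sensitivity (post hoc) power analysis
#'
#' Achieved power at two-sided alpha for the demographic comparisons:
#' Cohen's w for a 2x2 contingency table (`w = sqrt(chi2 / N)` from the
#' Pearson chi-squared statistic without continuity correction), with
#' power from the noncentral chi-squared distribution at noncentrality
#' `N w^2` (df = 1); and Cohen's d for a two-group mean difference
#' (pooled-SD standardized difference with (n-1) weights), with power from
#' the noncentral t distribution at noncentrality
#' `d sqrt(n1 n2 / (n1 + n2))`.
#'
#' Effect sizes can be supplied directly (`w =`, `d =`) or computed from a
#' contingency `counts` table and/or group `means`, `sds`, `ns`.
#'
#' @param counts Optional 2x2 contingency table (matrix).
#' @param means,sds,ns Optional length-2 vectors of group means, SDs and
#'   sizes for Cohen's d.
#' @param w,d Optional effect sizes given directly; `ns` (and `counts` for
#'   N) still determine the sample sizes.
#' @param alpha Two-sided significance level (default 0.05).
#' @return A `PowerReport`: list with `w`, `power_w`, `d`, `power_d`, and
#'   the sample sizes used. Components not computable from the inputs are
#'   `NULL`.
#' @export
sensitivity_power <- function(counts = NULL, means = NULL, sds = NULL,
                              ns = NULL, w = NULL, d = NULL,
                              alpha = 0.05) {
  out <- list(alpha = alpha)
  if (!is.null(counts) || !is.null(w)) {
    if (is.null(w)) {
      counts <- as.matrix(counts)
      if (any(counts < 0) || any(rowSums(counts) == 0) ||
          any(colSums(counts) == 0)) {
        stop("contingency table needs positive margins", call. = FALSE)
      }
      N <- sum(counts)
      chi2 <- suppressWarnings(
        stats::chisq.test(counts, correct = FALSE)$statistic)
      w <- sqrt(unname(chi2) / N)
    } else {
      N <- if (!is.null(counts)) sum(counts) else sum(ns)
    }
    ncp <- N * w^2
    out$w <- w
    out$N <- N
    out$power_w <- pchisq(qchisq(1 - alpha, df = 1), df = 1, ncp = ncp,
                          lower.tail = FALSE)
  }
  if (!is.null(d) || !is.null(means)) {
    if (is.null(ns)) stop("group sizes ns required for Cohen's d power",
                          call. = FALSE)
    n1 <- ns[1L]; n2 <- ns[2L]
    if (is.null(d)) {
      sp <- sqrt(((n1 - 1) * sds[1L]^2 + (n2 - 1) * sds[2L]^2) /
                   (n1 + n2 - 2))
      if (sp == 0) stop("zero pooled SD", call. = FALSE)
      d <- (means[1L] - means[2L]) / sp
    }
    ncp <- abs(d) * sqrt(n1 * n2 / (n1 + n2))
    df <- n1 + n2 - 2
    tc <- qt(1 - alpha / 2, df)
    out$d <- d
    out$ns <- c(n1, n2)
    out$power_d <- pt(tc, df, ncp, lower.tail = FALSE) + pt(-tc, df, ncp)
  }
  structure(out, class = "PowerReport")
}
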