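#' Assemble the subject-by-feature table
#'
#' Combines, for every subject, the kinematic dispersion features
#' (`pos_<Segment>`, `vel_<Segment>` IQRs), the raw (unthresholded) upper
#' triangle of the similarity matrix (`A_<Seg1>_<Seg2>`), the
#' threshold-averaged local graph metrics (`<metric>_<Segment>` for degree,
#' strength, clustering, betweenness, closeness, eigenvector, pagerank), and
#' the 9 threshold-averaged global metrics (`global_*`). With 23 segments
#' this yields 46 + 253 + 161 + 9 = 469 uniquely named columns.
#'
#' @param kin Named list (by subject id) of [kinematic_features()] results.
#' @param nets Named list of `SubjectNetwork` objects.
#' @param gms Named list of `GraphMetricVector` objects
#'   ([metrics_across_thresholds()]).
#' @return A `FeatureTable`: list with `subjects`, numeric matrix `values`
#'   (subjects x features, `NA` = missing), and provenance flags
#'   `residualized`, `standardized`.
#' @export
assemble_features <- function(kin, nets, gms) {
  subj <- names(kin)
  for (other in list(nets, gms)) {
    extra <- setdiff(names(other), subj)
    missing <- setdiff(subj, names(other))
    if (length(extra) > 0L || length(missing) > 0L) {
      stop("subject sets differ across inputs; missing: ",
           paste(missing, collapse = ", "), "; extra: ",
           paste(extra, collapse = ", "), call. = FALSE)
    }
  }
  segs <- nets[[1L]]$nodes
  ut <- which(upper.tri(nets[[1L]]$A), arr.ind = TRUE)
  ut <- ut[order(ut[, 1L], ut[, 2L]), , drop = FALSE]
  adj_names <- paste0("A_", segs[ut[, 1L]], "_", segs[ut[, 2L]])
  loc_metrics <- c("degree", "strength", "clustering", "betweenness",
                   "closeness", "eigenvector", "pagerank")
  glob_names0 <- names(gms[[1L]]$global)
  glob_names <- ifelse(grepl("^global_", glob_names0), glob_names0,
                       paste0("global_", glob_names0))
  feat_names <- c(
    paste0("pos_", segs), paste0("vel_", segs), adj_names,
    unlist(lapply(loc_metrics, function(m) paste0(m, "_", segs))),
    glob_names
  )
  rows <- lapply(subj, function(id) {
    kf <- kin[[id]]$features
    stopifnot(identical(kf$segment, segs))
    A <- nets[[id]]$A
    loc <- gms[[id]]$local
    stopifnot(identical(loc$node, segs))
    c(kf$pos_iqr, kf$vel_iqr, A[ut],
      unlist(lapply(loc_metrics, function(m) loc[[m]])),
      unname(gms[[id]]$global))
  })
  values <- do.call(rbind, rows)
  dimnames(values) <- list(subj, feat_names)
  structure(list(subjects = subj, values = values,
                 residualized = FALSE, standardized = FALSE),
            class = "FeatureTable")
}

#' Residualize features on age and sex
#'
#' Replaces every feature by the residuals of an ordinary least-squares
#' regression on intercept + age + sex, removing linear confounding.
#' Missing entries stay missing; each feature's regression uses its complete
#' cases.
#'
#' @param table A `FeatureTable`.
#' @param age Numeric vector (years), one per subject.
#' @param sex Numeric 0/1 vector (1 = male), one per subject.
#' @return The residualized `FeatureTable`.
#' @export
residualize <- function(table, age, sex) {
  V <- table$values
  n <- nrow(V)
  if (length(age) != n || length(sex) != n) {
    stop("age and sex must be available for all subjects", call. = FALSE)
  }
  if (n < 3L) stop("need at least 3 subjects to residualize", call. = FALSE)
  if (anyNA(age) || anyNA(sex)) {
    stop("age and sex must be complete", call. = FALSE)
  }
  D <- cbind(1, age, sex)
  for (j in seq_len(ncol(V))) {
    ok <- is.finite(V[, j])
    if (sum(ok) < 3L) next
    fit <- lm.fit(D[ok, , drop = FALSE], V[ok, j])
    V[ok, j] <- fit$residuals
  }
  table$values <- V
  table$residualized <- TRUE
  table
}

# Fit cleaning statistics on a row subset: columns to drop (missingness >
# 80% or zero variance on the fit rows), imputation medians, and
# standardization mean/SD. Kept separate from the transform so
# cross-validation can fit on training rows only.
fit_clean_stats <- function(V, fit_rows, max_missing = 0.8) {
  Vf <- V[fit_rows, , drop = FALSE]
  miss_frac <- colMeans(is.na(Vf))
  drop_missing <- miss_frac > max_missing
  med <- apply(Vf, 2L, median, na.rm = TRUE)
  imputed <- Vf
  for (j in seq_len(ncol(imputed))) {
    imputed[is.na(imputed[, j]), j] <- med[j]
  }
  sds <- apply(imputed, 2L, sd)
  drop_zerovar <- !drop_missing & (!is.finite(sds) | sds < 1e-12)
  keep <- !(drop_missing | drop_zerovar)
  mu <- colMeans(imputed)
  report <- data.frame(
    column = colnames(V)[!keep],
    rule = ifelse(drop_missing[!keep], "missingness", "zero_variance"),
    stringsAsFactors = FALSE
  )
  list(keep = colnames(V)[keep], median = med[keep], mean = mu[keep],
       sd = sds[keep], report = report)
}

apply_clean_stats <- function(V, stats) {
  V <- V[, stats$keep, drop = FALSE]
  for (j in seq_len(ncol(V))) {
    V[is.na(V[, j]), j] <- stats$median[j]
  }
  sweep(sweep(V, 2L, stats$mean, "-"), 2L, stats$sd, "/")
}

#' Clean and standardize a feature table
#'
#' Applies the cleaning rules in order: drop columns with more than 80%
#' missing values, impute remaining missing entries with the median, drop
#' zero-variance columns, and z-score to zero mean and unit variance. All
#' statistics (missingness fractions, medians, variances, means, SDs) are
#' computed on the `fit_rows` subset only, so test rows of a
#' cross-validation split never influence them; the transform is then
#' applied to all rows. Applying `clean_features` twice with the same fit
#' subset is a no-op.
#'
#' @param table A `FeatureTable`.
#' @param fit_rows Indices (or logical mask) of the rows used to fit the
#'   statistics; defaults to all rows.
#' @param max_missing Missingness fraction above which a column is dropped
#'   (default 0.8).
#' @return List with `table` (cleaned `FeatureTable`) and `report`
#'   (data.frame of dropped columns and the rule that fired).
#' @export
clean_features <- function(table, fit_rows = seq_len(nrow(table$values)),
                           max_missing = 0.8) {
  V <- table$values
  if (is.logical(fit_rows)) fit_rows <- which(fit_rows)
  if (length(fit_rows) == 0L) stop("fit subset is empty", call. = FALSE)
  stats <- fit_clean_stats(V, fit_rows, max_missing = max_missing)
  table$values <- apply_clean_stats(V, stats)
  table$standardized <- TRUE
  list(table = table, report = stats$report)
}
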