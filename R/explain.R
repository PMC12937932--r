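#' Per-fold Shapley attributions on held-out subjects
#'
#' Computes tree-based Shapley attributions of a fitted fold pipeline on
#' its held-out test rows. Attributions are computed on the fold's selected
#' features and mapped back to the full feature space, with features the
#' fold did not select contributing exactly 0. The additivity property
#' holds per subject: the attributions plus the base value reproduce the
#' model's margin output.
#'
#' @param pipeline A fitted pipeline from [nested_cv()] fold results.
#' @param V_test Numeric matrix of held-out rows in the full (uncleaned)
#'   feature space.
#' @param y_test Binary labels of the held-out rows (used for the
#'   case-signed direction summary; optional).
#' @return List with `mean_abs` (named mean |SHAP| per feature over test
#'   subjects, full feature space), `signed_case` (mean signed SHAP among
#'   case-labelled test subjects; 0 where undefined), and `per_subject`
#'   (test subjects x selected features matrix plus `BIAS` column).
#' @export
fold_attributions <- function(pipeline, V_test, y_test = NULL) {
  if (nrow(V_test) == 0L) stop("empty test set", call. = FALSE)
  Xc <- apply_clean_stats(V_test, pipeline$clean_stats)
  Xs <- Xc[, pipeline$selected, drop = FALSE]
  contrib <- predict(pipeline$model, xgboost::xgb.DMatrix(Xs),
                     predcontrib = TRUE)
  colnames(contrib) <- c(pipeline$selected, "BIAS")
  shap <- contrib[, pipeline$selected, drop = FALSE]
  full <- setNames(rep(0, length(pipeline$feature_names)),
                   pipeline$feature_names)
  mean_abs <- full
  mean_abs[pipeline$selected] <- colMeans(abs(shap))
  signed_case <- full
  if (!is.null(y_test)) {
    yb <- as_binary(y_test)
    if (any(yb == 1L)) {
      signed_case[pipeline$selected] <-
        colMeans(shap[yb == 1L, , drop = FALSE])
    }
  } else {
    signed_case[pipeline$selected] <- colMeans(shap)
  }
  list(mean_abs = mean_abs, signed_case = signed_case,
       per_subject = contrib)
}

#' Aggregate per-fold attributions into a global importance summary
#'
#' Averages the per-fold mean |SHAP| vectors across folds into a global
#' importance vector, sorts it descending (ties broken by feature name),
#' computes the normalized cumulative importance curve `C(k)`, and the
#' top-95% set: the smallest prefix whose cumulative share of total
#' importance reaches the cutoff.
#'
#' @param attributions List of named per-feature mean |SHAP| vectors, one
#'   per fold (all on the same feature space).
#' @param cumulative_cutoff Cumulative-importance cutoff (default 0.95).
#' @return List with `importance` (sorted named vector), `cumulative`
#'   (C(k) over the sorted features), `top_set` (names of the smallest
#'   prefix reaching the cutoff), and `total_mass`.
#' @export
aggregate_global <- function(attributions, cumulative_cutoff = 0.95) {
  stopifnot(length(attributions) >= 1L)
  M <- do.call(rbind, attributions)
  s_bar <- colMeans(M)
  ord <- order(-s_bar, names(s_bar))
  s_bar <- s_bar[ord]
  total <- sum(s_bar)
  if (total <= 0) {
    return(list(importance = s_bar, cumulative = rep(NA_real_,
                                                     length(s_bar)),
                top_set = character(0), total_mass = 0))
  }
  cum <- cumsum(s_bar) / total
  k <- which(cum >= cumulative_cutoff - 1e-12)[1L]
  list(importance = s_bar, cumulative = cum,
       top_set = names(s_bar)[seq_len(k)], total_mass = total)
}

#' Cross-fold selection stability
#'
#' `stab_j` is the percentage of folds whose selected-feature list contains
#' feature j. The stable set contains the features selected in at least
#' `cutoff`% of folds that also belong to the top cumulative-importance
#' set.
#'
#' @param selected_lists List of per-fold selected feature name vectors.
#' @param top_set Feature names of the top cumulative-importance set
#'   (from [aggregate_global()]); `NULL` skips that restriction.
#' @param cutoff Stability cutoff in percent (default 95).
#' @return List with `stability` (named percentages over all features ever
#'   selected, plus the top set) and `stable_set`.
#' @export
selection_stability <- function(selected_lists, top_set = NULL,
                                cutoff = 95) {
  stopifnot(length(selected_lists) >= 1L)
  N <- length(selected_lists)
  feats <- sort(unique(c(unlist(selected_lists), top_set)))
  f_j <- vapply(feats, function(f) {
    sum(vapply(selected_lists, function(l) f %in% l, TRUE))
  }, 0)
  stab <- 100 * f_j / N
  stable <- names(stab)[stab >= cutoff]
  if (!is.null(top_set)) stable <- intersect(stable, top_set)
  list(stability = stab, stable_set = stable, n_folds = N)
}

#' Full Shapley stability summary of a nested cross-validation run
#'
#' Convenience wrapper combining [aggregate_global()] and
#' [selection_stability()] over the folds of a [nested_cv()] result, plus
#' the cross-fold mean signed attribution used for direction-of-effect
#' encoding.
#'
#' @param cv_result A [nested_cv()] result.
#' @param cumulative_cutoff,stability_cutoff Cutoffs (defaults 0.95, 95).
#' @return A `ShapSummary`: list with `importance`, `cumulative`,
#'   `top_set`, `stability`, `stable_set`, `signed_case` (mean over folds),
#'   and `n_folds`.
#' @export
shap_summary <- function(cv_result, cumulative_cutoff = 0.95,
                         stability_cutoff = 95) {
  atts <- lapply(cv_result$folds, function(x) x$shap_mean_abs)
  glob <- aggregate_global(atts, cumulative_cutoff)
  sel <- lapply(cv_result$folds, function(x) x$selected)
  stab <- selection_stability(sel, glob$top_set, stability_cutoff)
  signed <- colMeans(do.call(rbind, lapply(cv_result$folds,
                                           function(x) x$shap_signed_case)))
  structure(list(
    importance = glob$importance, cumulative = glob$cumulative,
    top_set = glob$top_set, stability = stab$stability,
    stable_set = stab$stable_set, signed_case = signed,
    n_folds = length(cv_result$folds)
  ), class = "ShapSummary")
}

# Map a feature name to a body-network element: a node (per-segment
# feature), an edge (adjacency feature), or neither (global metrics).
map_feature <- function(name) {
  segs <- body_segments()
  if (startsWith(name, "A_")) {
    rest <- substring(name, 3L)
    for (s1 in segs) {
      if (startsWith(rest, paste0(s1, "_"))) {
        s2 <- substring(rest, nchar(s1) + 2L)
        if (s2 %in% segs) return(list(kind = "edge", from = s1, to = s2))
      }
    }
    return(list(kind = "none"))
  }
  for (s in segs) {
    if (endsWith(name, paste0("_", s))) return(list(kind = "node",
                                                    segment = s))
  }
  list(kind = "none")
}

#' Export a body-network document of stable explanatory features
#'
#' Projects per-segment features onto nodes and adjacency features onto
#' edges of a 2D stickman layout, with importance = global mean |SHAP| and
#' direction = sign of the case-conditional mean signed attribution
#' (positive = associated with the case class). Features that map to no
#' body segment (global network metrics) are listed separately.
#'
#' @param summary A [shap_summary()] result.
#' @param features Which features to export (default the stable set; fall
#'   back to the top set if empty).
#' @param path Optional path to write the document as JSON.
#' @return The document (list with `nodes`, `edges`, `unmapped`,
#'   `layout`), invisibly if `path` is given.
#' @export
export_body_network <- function(summary, features = NULL, path = NULL) {
  if (is.null(features)) {
    features <- if (length(summary$stable_set) > 0L) summary$stable_set
    else summary$top_set
  }
  nodes <- list(); edges <- list(); unmapped <- character(0)
  for (f in features) {
    m <- map_feature(f)
    imp <- unname(summary$importance[f])
    dir <- sign(unname(summary$signed_case[f]))
    if (m$kind == "node") {
      nodes[[length(nodes) + 1L]] <- list(
        segment = m$segment, feature = f, importance = imp, direction = dir)
    } else if (m$kind == "edge") {
      edges[[length(edges) + 1L]] <- list(
        pair = c(m$from, m$to), feature = f, importance = imp,
        direction = dir)
    } else {
      unmapped <- c(unmapped, f)
    }
  }
  doc <- list(nodes = nodes, edges = edges, unmapped = unmapped,
              layout = segment_layout())
  if (!is.null(path)) {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
    return(invisible(doc))
  }
  doc
}
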