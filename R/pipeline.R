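#' Default pipeline configuration
#'
#' Fully describes a run: every stage parameter has an explicit value, and
#' the configuration actually used is serialized with each stage's
#' manifest, so any run is reproducible from its emitted configuration and
#' seed.
#'
#' @return Nested named list of configuration blocks.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    simulate = list(n_group_a = 25L, n_group_b = 25L, n_segments = 23L,
                    fs = 100, duration = 15,
                    effect = unclass(effect_spec())),
    filter = list(cutoff = 10, order = 4L),
    kde = list(n_grid = 512L),
    threshold = list(min = 0.20, max = 0.60, step = 0.05),
    network = list(mode = "weighted", distance = "identity"),
    residualize = list(mode = "global"),
    cv = list(outer_folds = 10L, outer_repeats = 3L, inner_folds = 4L,
              search_iterations = 20L, vfs_k_min = 25L, vfs_k_max = 100L,
              vfs_lr_c_min = 1e-3, vfs_lr_c_max = 1e3),
    explain = list(cumulative_cutoff = 0.95, stability_cutoff = 95),
    stats = list(rho_cutoff = 0.30, p_cutoff = 0.05)
  )
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML file and merges it over [default_config()]. Unknown keys
#' at any level are rejected (fail-fast), so typos cannot silently fall
#' back to defaults.
#'
#' @param path YAML file path, or `NULL` for the defaults.
#' @return Validated configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  merge_config(cfg, user, "config")
}

merge_config <- function(base, user, where) {
  unknown <- setdiff(names(user), names(base))
  if (length(unknown) > 0L) {
    stop("unknown configuration key(s) under ", where, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], user[[nm]],
                                 paste(where, nm, sep = "."))
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

stage_paths <- function(outdir) {
  list(
    kinematics = file.path(outdir, "kinematics.csv"),
    metadata = file.path(outdir, "metadata.csv"),
    features = file.path(outdir, "features.csv"),
    features_meta = file.path(outdir, "features_provenance.json"),
    networks_dir = file.path(outdir, "networks"),
    results_rds = file.path(outdir, "train_results.rds"),
    results_json = file.path(outdir, "train_results.json"),
    metrics_csv = file.path(outdir, "fold_metrics.csv"),
    shap_csv = file.path(outdir, "shap_summary.csv"),
    body_json = file.path(outdir, "body_network.json"),
    stats_csv = file.path(outdir, "group_tests.csv"),
    corr_csv = file.path(outdir, "clinical_correlations.csv"),
    power_json = file.path(outdir, "power_report.json")
  )
}

require_artifact <- function(path, producer) {
  if (!file.exists(path)) {
    stop("missing upstream artifact ", sQuote(path),
         "; run the ", sQuote(producer), " stage first", call. = FALSE)
  }
  invisible(path)
}

write_manifest <- function(outdir, stage, inputs, outputs, config) {
  manifest_path <- file.path(outdir, "manifest.json")
  manifest <- if (file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path)
  } else list()
  manifest[[stage]] <- list(
    stage = stage, time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    inputs = inputs, outputs = outputs, seed = config$seed,
    config = config,
    package_version = as.character(utils::packageVersion("kinectome"))
  )
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null")
}

#' Run pipeline stages
#'
#' Orchestrates the analysis end to end. Stages: `simulate` (synthetic
#' cohort to tidy CSVs), `features` (filtering, similarity networks,
#' threshold-averaged graph metrics, assembly and age/sex residualization
#' to a feature CSV), `network` (per-subject adjacency CSV and GraphML
#' exports), `train` (nested cross-validation), `explain` (Shapley
#' stability summary and body-network export), `stats` (group tests with
#' FDR, demographic tests, clinical correlation screening, sensitivity
#' power), and `all` (the full chain). Each stage writes its artifacts
#' under `outdir` together with a manifest entry recording inputs, outputs,
#' seed and the full configuration.
#'
#' @param stage One of `"simulate"`, `"features"`, `"network"`, `"train"`,
#'   `"explain"`, `"stats"`, `"all"`.
#' @param config Configuration list (see [default_config()] /
#'   [load_config()]).
#' @param outdir Output directory (created if needed).
#' @param seed Optional override of `config$seed`.
#' @return Invisibly, a list of the artifacts produced.
#' @export
run_pipeline <- function(stage = c("all", "simulate", "features", "network",
                                   "train", "explain", "stats"),
                         config = default_config(), outdir, seed = NULL) {
  stage <- match.arg(stage)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- stage_paths(outdir)
  if (stage == "all") {
    out <- list()
    for (st in c("simulate", "features", "network", "train", "explain",
                 "stats")) {
      out[[st]] <- run_pipeline(st, config = config, outdir = outdir)
    }
    return(invisible(out))
  }
  switch(stage,
    simulate = stage_simulate(config, p, outdir),
    features = stage_features(config, p, outdir),
    network = stage_network(config, p, outdir),
    train = stage_train(config, p, outdir),
    explain = stage_explain(config, p, outdir),
    stats = stage_stats(config, p, outdir)
  )
}

stage_simulate <- function(config, p, outdir) {
  sc <- config$simulate
  spec <- cohort_spec(
    n_group_a = sc$n_group_a, n_group_b = sc$n_group_b,
    n_segments = sc$n_segments, fs = sc$fs, duration = sc$duration,
    effect = do.call(effect_spec, sc$effect), seed = config$seed
  )
  cohort <- generate_cohort(spec)
  write_cohort(cohort, p$kinematics, p$metadata)
  write_manifest(outdir, "simulate", inputs = list(),
                 outputs = list(p$kinematics, p$metadata), config)
  invisible(list(kinematics = p$kinematics, metadata = p$metadata))
}

compute_cohort_features <- function(cohort, config) {
  grid <- threshold_grid(config$threshold$min, config$threshold$max,
                         config$threshold$step)
  kin <- lapply(cohort$recordings, kinematic_features,
                cutoff = config$filter$cutoff, order = config$filter$order)
  nets <- lapply(kin, function(k) build_network(k$magnitudes,
                                                n_grid = config$kde$n_grid))
  gms <- lapply(nets, metrics_across_thresholds, grid = grid,
                mode = config$network$mode,
                distance = config$network$distance)
  tab <- assemble_features(kin, nets, gms)
  list(kin = kin, nets = nets, gms = gms, table = tab)
}

stage_features <- function(config, p, outdir) {
  require_artifact(p$kinematics, "simulate")
  require_artifact(p$metadata, "simulate")
  cohort <- read_cohort(p$kinematics, p$metadata)
  cf <- compute_cohort_features(cohort, config)
  tab <- cf$table
  if (identical(config$residualize$mode, "global")) {
    tab <- residualize(tab, cohort$metadata$age, cohort$metadata$sex)
  }
  df <- data.frame(subject_id = tab$subjects, tab$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  data.table::fwrite(df, p$features)
  jsonlite::write_json(list(
    residualized = tab$residualized, residualize_mode =
      config$residualize$mode, standardized = tab$standardized,
    sex_coding = "1=male", n_features = ncol(tab$values)
  ), p$features_meta, auto_unbox = TRUE)
  write_manifest(outdir, "features",
                 inputs = list(p$kinematics, p$metadata),
                 outputs = list(p$features, p$features_meta), config)
  invisible(list(features = p$features, table = tab))
}

stage_network <- function(config, p, outdir) {
  require_artifact(p$kinematics, "simulate")
  require_artifact(p$metadata, "simulate")
  cohort <- read_cohort(p$kinematics, p$metadata)
  dir.create(p$networks_dir, showWarnings = FALSE)
  outs <- lapply(names(cohort$recordings), function(id) {
    k <- kinematic_features(cohort$recordings[[id]],
                            cutoff = config$filter$cutoff,
                            order = config$filter$order)
    net <- build_network(k$magnitudes, n_grid = config$kde$n_grid)
    csv <- file.path(p$networks_dir, paste0(id, "_adjacency.csv"))
    gml <- file.path(p$networks_dir, paste0(id, ".graphml"))
    write.csv(net$A, csv)
    g <- threshold_graph(net, 0, mode = config$network$mode)
    igraph::write_graph(g, gml, format = "graphml")
    c(csv, gml)
  })
  write_manifest(outdir, "network",
                 inputs = list(p$kinematics, p$metadata),
                 outputs = as.list(unlist(outs)), config)
  invisible(list(networks_dir = p$networks_dir))
}

read_feature_table <- function(p) {
  df <- as.data.frame(data.table::fread(p$features, check.names = FALSE))
  V <- as.matrix(df[, -1L, drop = FALSE])
  rownames(V) <- df$subject_id
  prov <- if (file.exists(p$features_meta)) {
    jsonlite::read_json(p$features_meta)
  } else list(residualized = FALSE, standardized = FALSE)
  structure(list(subjects = df$subject_id, values = V,
                 residualized = isTRUE(prov$residualized),
                 standardized = isTRUE(prov$standardized)),
            class = "FeatureTable")
}

stage_train <- function(config, p, outdir) {
  require_artifact(p$features, "features")
  require_artifact(p$metadata, "simulate")
  tab <- read_feature_table(p)
  meta <- as.data.frame(data.table::fread(p$metadata))
  cvc <- cv_config(
    outer_folds = config$cv$outer_folds,
    outer_repeats = config$cv$outer_repeats,
    inner_folds = config$cv$inner_folds,
    search_iterations = config$cv$search_iterations,
    vfs_k_range = c(config$cv$vfs_k_min, config$cv$vfs_k_max),
    vfs_lr_c_range = c(config$cv$vfs_lr_c_min, config$cv$vfs_lr_c_max),
    seed = config$seed
  )
  res <- nested_cv(tab, meta$group, cvc)
  saveRDS(res, p$results_rds)
  metrics <- do.call(rbind, lapply(res$folds, function(f) {
    data.frame(repeat_id = f$repeat_id, fold_id = f$fold_id,
               t(f$metrics), vfs_k = f$best_params$vfs_k)
  }))
  data.table::fwrite(metrics, p$metrics_csv)
  jsonlite::write_json(list(summary = res$summary, folds = metrics),
                       p$results_json, auto_unbox = TRUE, digits = NA)
  write_manifest(outdir, "train",
                 inputs = list(p$features, p$metadata),
                 outputs = list(p$results_rds, p$results_json,
                                p$metrics_csv), config)
  invisible(list(results = res))
}

stage_explain <- function(config, p, outdir) {
  require_artifact(p$results_rds, "train")
  res <- readRDS(p$results_rds)
  summ <- shap_summary(res,
                       cumulative_cutoff = config$explain$cumulative_cutoff,
                       stability_cutoff = config$explain$stability_cutoff)
  df <- data.frame(
    feature = names(summ$importance),
    mean_abs_shap = unname(summ$importance),
    cumulative = summ$cumulative,
    in_top_set = names(summ$importance) %in% summ$top_set,
    stability_pct = unname(summ$stability[names(summ$importance)]),
    stable = names(summ$importance) %in% summ$stable_set,
    stringsAsFactors = FALSE
  )
  df$stability_pct[is.na(df$stability_pct)] <- 0
  data.table::fwrite(df, p$shap_csv)
  export_body_network(summ, path = p$body_json)
  write_manifest(outdir, "explain", inputs = list(p$results_rds),
                 outputs = list(p$shap_csv, p$body_json), config)
  invisible(list(summary = summ))
}

stage_stats <- function(config, p, outdir) {
  require_artifact(p$features, "features")
  require_artifact(p$metadata, "simulate")
  tab <- read_feature_table(p)
  meta <- as.data.frame(data.table::fread(p$metadata))
  gt <- group_tests(tab, meta$group)
  data.table::fwrite(gt, p$stats_csv)
  dem <- demographic_tests(meta)
  power <- sensitivity_power(counts = as.matrix(dem$sex_table),
                             means = tapply(meta$age, meta$group, mean),
                             sds = tapply(meta$age, meta$group, sd),
                             ns = as.numeric(base::table(meta$group)))
  jsonlite::write_json(list(
    fisher_p = dem$fisher_p, kruskal_p = dem$kruskal_p,
    cohens_w = power$w, power_w = power$power_w,
    cohens_d = power$d, power_d = power$power_d
  ), p$power_json, auto_unbox = TRUE, digits = NA)
  outputs <- list(p$stats_csv, p$power_json)
  if (file.exists(p$shap_csv)) {
    shap <- as.data.frame(data.table::fread(p$shap_csv))
    stable <- shap$feature[shap$stable]
    clin_cols <- intersect(names(meta), names(generate_clinical_scores(0)))
    cases <- meta$group == "case"
    if (length(stable) > 0L && length(clin_cols) > 0L && any(cases)) {
      corr <- spearman_screen(
        tab$values[cases, stable, drop = FALSE],
        meta[cases, clin_cols, drop = FALSE],
        rho_cutoff = config$stats$rho_cutoff,
        p_cutoff = config$stats$p_cutoff)
      if (!is.null(corr)) {
        data.table::fwrite(corr, p$corr_csv)
        outputs <- c(outputs, list(p$corr_csv))
      }
    }
  }
  write_manifest(outdir, "stats",
                 inputs = list(p$features, p$metadata),
                 outputs = outputs, config)
  invisible(list(group_tests = gt, power = power))
}
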