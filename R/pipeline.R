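#' Run the full analysis pipeline from a configuration
#'
#' Executes, on one cohort: preprocessing (normexp, quantile, log10),
#' per-feature association models, trajectory clustering of the
#' age-significant features, the DE-SWAN scan with wave detection and
#' overlaps, optional enrichment of the increasing/decreasing age signatures
#' against user-supplied annotation sets, and the resampled elastic-net /
#' top-k ridge aging classifier. Every stage's output is written as a
#' delimited table under `out_dir`, together with a YAML manifest (config
#' echo, seed, per-stage child seeds, output checksums) sufficient to
#' reproduce the run bit-identically.
#'
#' The configuration is a YAML file or an equivalent nested list with
#' top-level keys `input` (paths `profile` and `metadata`, optional
#' `orientation` and `geo_series_matrix: true`) or `simulate` (arguments
#' for [synthetic_spec()]); optional parameter blocks `association`,
#' `trajectory`, `deswan`, `enrichment` (path `gmt`), `prediction`; and
#' `seed` plus `out_dir`. Unknown keys are rejected before any computation.
#' One global seed is expanded into named per-stage child seeds (drawn by a
#' fixed scheme), so stage-level reruns reproduce full-run results.
#'
#' @param config Path to a YAML file, or a nested list.
#' @param out_dir Output directory; overrides `config$out_dir`.
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  known <- c("input", "simulate", "association", "trajectory", "deswan",
             "enrichment", "prediction", "seed", "out_dir")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (is.null(config$input) == is.null(config$simulate))
    stop("config needs exactly one of 'input' or 'simulate'")
  if (!is.null(config$input)) {
    for (f in c("profile", "metadata")) {
      if (is.null(config$input[[f]]))
        stop("config$input is missing '", f, "'")
      if (!file.exists(config$input[[f]]))
        stop("input file not found: ", config$input[[f]])
    }
  }
  if (!is.null(config$enrichment$gmt) && !file.exists(config$enrichment$gmt))
    stop("annotation file not found: ", config$enrichment$gmt)
  out_dir <- out_dir %||% config$out_dir %||% stop("no 'out_dir' configured")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  stages <- c("simulate", "match", "prediction")
  stage_seeds <- setNames(.child_seeds(seed, length(stages)), stages)
  outputs <- character(0)
  emit <- function(x, name) {
    path <- file.path(out_dir, name)
    if (inherits(x, "profile_matrix")) write_profile_table(x, path)
    else utils::write.table(x, path, sep = "\t", quote = FALSE,
                            row.names = FALSE)
    outputs <<- c(outputs, path)
    path
  }

  # --- input -----------------------------------------------------------
  if (!is.null(config$simulate)) {
    spec_args <- config$simulate
    spec_args$seed <- spec_args$seed %||% stage_seeds[["simulate"]]
    cohort <- generate_cohort(do.call(synthetic_spec, spec_args))
    raw <- cohort$profile
    meta <- cohort$metadata
    emit(raw, "simulated_profile_raw.tsv")
    emit(meta, "simulated_metadata.tsv")
    emit(cohort$truth, "simulated_ground_truth.tsv")
  } else {
    raw <- if (isTRUE(config$input$geo_series_matrix))
      read_geo_series_matrix(config$input$profile)
    else
      read_profile_table(config$input$profile,
                         orientation = config$input$orientation %||%
                           "features_in_rows")
    meta <- read_metadata(config$input$metadata)
    keep <- intersect(sample_ids(raw), meta$sample_id)
    raw <- profile_matrix(raw$values[, keep, drop = FALSE], stage = "raw")
  }

  # --- preprocess ------------------------------------------------------
  norm <- preprocess_pipeline(raw)
  emit(norm, "profile_log10.tsv")
  emit(attr(norm, "normexp_params"), "normexp_params.tsv")

  # --- association -----------------------------------------------------
  assoc_cfg <- config$association %||% list()
  terms <- unlist(assoc_cfg$terms %||% c("age", "sex"))
  q_thr <- assoc_cfg$q_threshold %||% 0.05
  assoc <- fit_feature_models(norm, meta, terms = terms)
  emit(assoc, "association_table.tsv")
  dirs <- classify_directions(assoc, term = "age", q_threshold = q_thr)

  # --- trajectories ----------------------------------------------------
  traj_cfg <- config$trajectory %||% list()
  sig_age <- c(dirs$increasing, dirs$decreasing)
  traj_features <- if (length(sig_age) >= max(10, traj_cfg$k %||% 6))
    sig_age else feature_ids(norm)
  sub <- profile_matrix(norm$values[traj_features, , drop = FALSE],
                        stage = "log10")
  ts <- fit_trajectories(sub, meta, span = traj_cfg$span %||% 0.75,
                         grid_size = traj_cfg$grid_size %||% 50)
  cl <- cluster_trajectories(ts, k = traj_cfg$k %||% 6)
  emit(data.frame(feature_id = names(cl$assignment),
                  cluster = unname(cl$assignment)),
       "trajectory_clusters.tsv")
  emit(data.frame(cluster = seq_len(cl$k),
                  round(cl$means, 6), check.names = FALSE),
       "trajectory_cluster_means.tsv")

  # --- deswan ----------------------------------------------------------
  dw_cfg <- config$deswan %||% list()
  wp <- deswan_scan(norm, meta,
                    window = dw_cfg$window %||% 20,
                    step = dw_cfg$step %||% 1,
                    q_threshold = dw_cfg$q_threshold %||% 0.05,
                    min_per_parcel = dw_cfg$min_per_parcel %||% 5)
  emit(data.frame(center_age = wp$centers,
                  n_significant = unname(wp$n_significant),
                  n_low = wp$n_low, n_high = wp$n_high),
       "deswan_profile.tsv")
  waves <- detect_waves(wp,
                        min_separation = dw_cfg$min_separation %||% 8,
                        min_count = dw_cfg$min_count %||% 5)
  if (length(waves)) {
    emit(do.call(rbind, lapply(waves, function(w)
      data.frame(peak_age = w$peak_age, feature_id = w$features,
                 direction = unname(w$direction)))),
      "deswan_waves.tsv")
    if (length(waves) >= 2L)
      emit(wave_overlap(waves), "deswan_wave_overlap.tsv")
  }

  # --- enrichment ------------------------------------------------------
  if (!is.null(config$enrichment$gmt)) {
    sets <- read_gmt(config$enrichment$gmt)
    for (dname in c("increasing", "decreasing")) {
      h <- dirs[[dname]]
      if (length(h))
        emit(fisher_enrichment(h, feature_ids(norm), sets),
             sprintf("enrichment_age_%s.tsv", dname))
    }
  }

  # --- prediction ------------------------------------------------------
  pred_cfg <- config$prediction %||% list()
  labels <- binarize_age(meta, cutoff = pred_cfg$cutoff %||% 65)
  pm_pred <- norm
  if (!is.null(pred_cfg$feature_subset)) {
    feats <- readLines(pred_cfg$feature_subset)
    feats <- intersect(trimws(feats), feature_ids(norm))
    if (length(feats) < 2L) stop("feature subset matches fewer than 2 features")
    pm_pred <- profile_matrix(norm$values[feats, , drop = FALSE],
                              stage = "log10")
  }
  task <- classification_task(pm_pred, labels, positive = "old")
  cfg <- penalized_config(alpha = pred_cfg$alpha %||% 0.8,
                          n_lambda = pred_cfg$n_lambda %||% 100,
                          n_folds = pred_cfg$n_folds %||% 10,
                          train_fraction = pred_cfg$train_fraction %||% 2 / 3,
                          n_iter = pred_cfg$n_iter %||% 500,
                          seed = stage_seeds[["prediction"]])
  fit <- resampled_elastic_net(task, cfg)
  emit(fit$importance, "prediction_importance.tsv")
  emit(data.frame(metric = c("mean_accuracy", "mean_sensitivity",
                             "mean_specificity", "sd_accuracy"),
                  value = c(fit$report$mean_accuracy,
                            fit$report$mean_sensitivity,
                            fit$report$mean_specificity,
                            fit$report$sd_accuracy)),
       "prediction_report.tsv")
  ks <- unlist(pred_cfg$ks %||% c(2, 5, 10, 15, 20))
  ks <- ks[ks <= sum(fit$importance$importance > 0)]
  if (length(ks))
    emit(top_k_ridge(task, fit$importance, ks = ks, cfg = cfg),
         "prediction_topk.tsv")

  manifest_path <- file.path(out_dir, "manifest.yaml")
  manifest <- list(config = config, seed = seed,
                   stage_seeds = as.list(stage_seeds))
  write_manifest(manifest_path, manifest, seed, outputs)
  invisible(c(manifest, list(outputs = outputs, manifest = manifest_path)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
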