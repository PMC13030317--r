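#' Pipeline run configuration
#'
#' Bundles every stage's options: the synthetic cohort config, windowing,
#' model config, statistics options, stage toggles, and a single global seed
#' that fans out deterministically to per-stage sub-seeds (so stages can be
#' rerun in isolation reproducibly).
#'
#' @param out_dir output directory.
#' @param stages stages to run, in pipeline order.
#' @param synthetic a [synthetic_config()].
#' @param window_ms,stride_ms analysis window length and stride in
#'   milliseconds.
#' @param model a [expression_model()] config.
#' @param lopo run leave-one-participant-out cross-validation in the train
#'   stage (needs >= 3 participants).
#' @param n_components PCA components to retain.
#' @param fdr_q FDR threshold; `fdr_family` as in
#'   [fit_feature_workload_models()].
#' @param write_recordings write the per-scene signal CSV/JSON files
#'   (disabled by default; they dominate disk use).
#' @param seed global integer seed.
#' @return List of class `femg_run_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("femg-run-"),
                            stages = c("simulate", "preprocess", "train",
                                       "infer", "features", "stats"),
                            synthetic = synthetic_config(),
                            window_ms = 1000, stride_ms = window_ms,
                            model = expression_model(),
                            lopo = TRUE, n_components = 2,
                            fdr_q = 0.05, fdr_family = "all",
                            write_recordings = FALSE,
                            seed = 1L) {
  structure(list(out_dir = out_dir,
                 stages = match.arg(stages, several.ok = TRUE),
                 synthetic = synthetic, window_ms = window_ms,
                 stride_ms = stride_ms, model = model, lopo = lopo,
                 n_components = n_components, fdr_q = fdr_q,
                 fdr_family = fdr_family,
                 write_recordings = write_recordings,
                 seed = as.integer(seed)),
            class = "femg_run_config")
}

#' Validate a pipeline configuration
#'
#' Schema and consistency checks with actionable messages; report-only
#' (never throws). [run_pipeline()] refuses to start when the report
#' contains errors.
#'
#' @param config a [pipeline_config()].
#' @return Data frame with columns `level` ("error"/"warning"), `field`,
#'   `message`; zero rows when the config is clean.
#' @export
validate_config <- function(config) {
  rep <- list()
  add <- function(level, field, message)
    rep[[length(rep) + 1L]] <<- data.frame(level = level, field = field,
                                           message = message)
  if (!inherits(config, "femg_run_config")) {
    add("error", "config", "not a femg_run_config")
    return(do.call(rbind, rep))
  }
  sy <- tryCatch({ validate_synth_config(config$synthetic); NULL },
                 error = function(e) conditionMessage(e))
  if (!is.null(sy)) add("error", "synthetic", sy)
  if (config$window_ms <= 0) add("error", "window_ms", "must be > 0")
  if (config$stride_ms <= 0) add("error", "stride_ms", "stride must be > 0")
  w <- round(config$window_ms / 1000 * config$synthetic$sample_rate)
  if (w < 1) add("error", "window_ms", "window shorter than one sample")
  pool_depth <- length(config$model$cnn$filters)
  if (config$model$architecture %in% c("cnn-tcn", "cnn", "cnn-lstm") &&
      w < 2^pool_depth)
    add("error", "window_ms",
        sprintf("window of %d samples incompatible with %d pooling stages",
                w, pool_depth))
  else if (config$model$architecture %in% c("cnn-tcn", "cnn", "cnn-lstm") &&
           w %/% 2^pool_depth < receptive_field(config$model) / 4)
    add("warning", "window_ms",
        "pooled window much shorter than the TCN receptive field")
  if (config$lopo && "train" %in% config$stages &&
      config$synthetic$n_participants < 3)
    add("error", "synthetic$n_participants",
        "LOPO cross-validation needs >= 3 participants")
  if (length(rep) == 0)
    data.frame(level = character(0), field = character(0),
               message = character(0))
  else do.call(rbind, rep)
}

write_stage_csv <- function(df, dir, name) {
  path <- file.path(dir, name)
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full pipeline
#'
#' Executes the enabled stages in order — simulate, preprocess (profiles,
#' normalization, calibration windows), train (optional LOPO + final
#' retrain), infer (scene sequences + summaries), features, stats (PCA +
#' mixed models + FDR) — and writes per-stage CSV outputs plus a JSON run
#' manifest holding the config hash, seeds, package version, and an MD5
#' checksum of every output file. Identical config + seed reproduce
#' identical checksums.
#'
#' @param config a [pipeline_config()].
#' @return The manifest (invisibly also written to `manifest.json`), with
#'   the in-memory stage results attached as attribute `"results"`.
#' @export
run_pipeline <- function(config) {
  report <- validate_config(config)
  if (any(report$level == "error"))
    stop("invalid configuration:\n",
         paste(sprintf("  [%s] %s: %s", report$level, report$field,
                       report$message), collapse = "\n"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  res <- list()
  stage_log <- list()
  t_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    v <- tryCatch(force(expr), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    stage_log[[name]] <<- round(proc.time()[["elapsed"]] - t0, 2)
    v
  }
  syn <- config$synthetic
  syn$seed <- derive_seed(config$seed, "simulate")

  if ("simulate" %in% config$stages) {
    res$cohort <- t_stage("simulate", generate_cohort(syn))
    co <- res$cohort
    scr_rows <- list()
    for (p in names(co$scripts)) for (sc in names(co$scripts[[p]])) {
      s <- co$scripts[[p]][[sc]]
      scr_rows[[paste(p, sc)]] <- data.frame(
        participant = p, scene = sc,
        step_index = seq_along(s$labels) - 1L,
        label = as.character(s$labels))
    }
    outputs <- c(outputs,
      write_stage_csv(do.call(rbind, scr_rows), config$out_dir,
                      "scripts.csv"),
      write_stage_csv(co$ratings, config$out_dir, "ratings.csv"),
      write_stage_csv(co$true_features, config$out_dir,
                      "features_true.csv"))
    if (config$write_recordings) {
      sig_dir <- file.path(config$out_dir, "recordings")
      dir.create(sig_dir, showWarnings = FALSE)
      for (p in names(co$recordings)) for (sc in names(co$recordings[[p]])) {
        base <- file.path(sig_dir, paste0(p, "_", sc))
        write_recording(co$recordings[[p]][[sc]], paste0(base, ".csv"),
                        paste0(base, ".json"))
        outputs <- c(outputs, paste0(base, ".csv"), paste0(base, ".json"))
      }
    }
  }

  w <- as.integer(round(config$window_ms / 1000 * syn$sample_rate))
  s <- as.integer(round(config$stride_ms / 1000 * syn$sample_rate))
  wp <- windowing_params(w, s)

  if ("preprocess" %in% config$stages) {
    if (is.null(res$cohort)) stop("preprocess stage needs the simulate stage")
    res$preprocess <- t_stage("preprocess", {
      co <- res$cohort
      profiles <- lapply(co$calibration, compute_calibration_profile)
      calib_windows <- list()
      norm_scenes <- list()
      for (p in names(profiles)) {
        nc <- normalize_recording(co$calibration[[p]], profiles[[p]])
        calib_windows <- c(calib_windows, segment_windows(nc, wp))
        norm_scenes[[p]] <- lapply(co$recordings[[p]], normalize_recording,
                                   profile = profiles[[p]])
      }
      list(profiles = profiles, calib_windows = calib_windows,
           norm_scenes = norm_scenes)
    })
    prof_df <- do.call(rbind, lapply(res$preprocess$profiles, function(pr)
      data.frame(participant = pr$participant, channel = femg_channels(),
                 neutral_baseline = unname(pr$neutral_baseline),
                 mvic = unname(pr$mvic))))
    outputs <- c(outputs, write_stage_csv(prof_df, config$out_dir,
                                          "profiles.csv"))
  }

  if ("train" %in% config$stages) {
    if (is.null(res$preprocess)) stop("train stage needs the preprocess stage")
    mcfg <- config$model
    mcfg$seed <- derive_seed(config$seed, "train")
    if (config$lopo) {
      res$lopo <- t_stage("train-lopo",
        lopo_cross_validate(res$preprocess$calib_windows, mcfg))
      fold_df <- do.call(rbind, lapply(res$lopo$folds, function(f)
        data.frame(test_participant = f$test_participant,
                   t(vapply(metric_names(), function(nm) f$test[[nm]],
                            numeric(1))))))
      outputs <- c(outputs,
        write_stage_csv(fold_df, config$out_dir, "lopo_folds.csv"),
        write_stage_csv(res$lopo$aggregate$test, config$out_dir,
                        "lopo_aggregate.csv"))
    }
    res$model <- t_stage("train-final",
      retrain_full(res$preprocess$calib_windows, mcfg,
                   expected_participants = names(res$preprocess$profiles)))
  }

  if ("infer" %in% config$stages) {
    if (is.null(res$model)) stop("infer stage needs the train stage")
    res$sequences <- t_stage("infer", {
      seqs <- list()
      for (p in names(res$preprocess$norm_scenes))
        for (sc in names(res$preprocess$norm_scenes[[p]]))
          seqs[[paste(p, sc)]] <- predict_sequence(
            res$model, res$preprocess$norm_scenes[[p]][[sc]], wp)
      seqs
    })
    seq_df <- do.call(rbind, lapply(res$sequences, function(sq)
      data.frame(participant = sq$participant, scene = sq$scene,
                 window_start_s = sq$window_times,
                 label = as.character(sq$labels))))
    res$scene_table <- cohort_scene_table(
      baseline_corrected(scene_summary(res$sequences)))
    outputs <- c(outputs,
      write_stage_csv(seq_df, config$out_dir, "sequences.csv"),
      write_stage_csv(res$scene_table$table, config$out_dir,
                      "scene_summary.csv"),
      write_stage_csv(res$scene_table$scene_means, config$out_dir,
                      "scene_means.csv"))
  }

  if ("features" %in% config$stages) {
    if (is.null(res$sequences)) stop("features stage needs the infer stage")
    res$features <- t_stage("features", feature_table(res$sequences))
    outputs <- c(outputs, write_stage_csv(res$features, config$out_dir,
                                          "features.csv"))
  }

  if ("stats" %in% config$stages) {
    if (is.null(res$features)) stop("stats stage needs the features stage")
    ratings <- res$cohort$ratings
    if (is.null(ratings))
      stop("stats stage is missing its ratings input (ratings.csv): ",
           "run the simulate stage or supply ratings")
    res$stats <- t_stage("stats", {
      std <- suppressWarnings(standardize_features(res$features))
      pca <- run_pca(std, config$n_components)
      scene_mod <- lapply(seq_len(config$n_components), function(j)
        fit_scene_model(pca$scores[, j], std$data$scene,
                        std$data$participant))
      mm <- fit_feature_workload_models(std, ratings,
                                        fdr_family = config$fdr_family,
                                        q_threshold = config$fdr_q)
      list(std = std, pca = pca, scene_models = scene_mod, models = mm)
    })
    load_df <- data.frame(feature = rownames(res$stats$pca$loadings),
                          res$stats$pca$loadings, row.names = NULL)
    score_df <- data.frame(participant = res$stats$std$data$participant,
                           scene = res$stats$std$data$scene,
                           res$stats$pca$scores, row.names = NULL)
    outputs <- c(outputs,
      write_stage_csv(load_df, config$out_dir, "pca_loadings.csv"),
      write_stage_csv(score_df, config$out_dir, "pca_scores.csv"),
      write_stage_csv(as.data.frame(res$stats$models), config$out_dir,
                      "models.csv"))
  }

  cfg_file <- tempfile(fileext = ".rds")
  cfg_ser <- config
  cfg_ser$out_dir <- NULL
  saveRDS(cfg_ser, cfg_file, version = 2)
  manifest <- list(
    package_version = as.character(utils::packageVersion("femgxdyn")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config_hash = unname(tools::md5sum(cfg_file)),
    stages = config$stages,
    stage_seconds = stage_log,
    outputs = as.list(stats::setNames(unname(tools::md5sum(outputs)),
                                      basename(outputs))))
  unlink(cfg_file)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  attr(manifest, "results") <- res
  invisible(manifest)
}
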