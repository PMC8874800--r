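#' Pipeline configuration
#'
#' Bundles every tunable of the analysis chain with the study defaults:
#' 89 Hz sampling, intrinsic z-x-y Tait-Bryan order, mean-of-speeds
#' movement statistic thresholded at 0.077 m/s for longer than 0.2 s, 25%
#' calibration threshold fraction, 13-step windows and 5-fold
#' cross-validation. Round-trips losslessly through JSON.
#'
#' @param sample_rate_hz sampling rate, Hz.
#' @param convention Tait-Bryan rotation order.
#' @param omega_rule combination rule for [omega_series()].
#' @param speed_threshold movement threshold, m/s.
#' @param min_duration minimal movement duration, s.
#' @param calibration_fraction cursor threshold fraction of the average
#'   excursion.
#' @param window_length classification window, time steps.
#' @param n_trees trees in the bagged ensemble.
#' @param k_folds cross-validation folds.
#' @param reps calibration repetitions per gesture.
#' @param seed run seed.
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(sample_rate_hz = 89,
                            convention = "zxy",
                            omega_rule = "mean",
                            speed_threshold = 0.077,
                            min_duration = 0.2,
                            calibration_fraction = 0.25,
                            window_length = 13,
                            n_trees = 100,
                            k_folds = 5,
                            reps = 5,
                            seed = 1) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path JSON file path.
#' @param config a \code{pipeline_config}.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, x)
}

#' Run the full analysis pipeline
#'
#' Simulates (or loads) a calibration session and runs every stage in order:
#' variable-table assembly, calibration profile, segmentation,
#' motor-performance metrics, per-segment saliency, window featurization,
#' cross-validated bagged-trees evaluation and out-of-bag importance. When
#' \code{out_dir} is given, each stage's artifact is written there as
#' CSV/JSON.
#'
#' @param config a [pipeline_config()].
#' @param session optional [vr_session()]; by default a synthetic
#'   calibration session is generated from the config seed.
#' @param out_dir optional output directory for stage artifacts.
#' @param n_trees_importance trees used for the (more expensive) importance
#'   stage; defaults to \code{config$n_trees}.
#' @return list with \code{session}, \code{table}, \code{profile},
#'   \code{intervals}, \code{segments}, \code{metrics}, \code{saliency},
#'   \code{salient_sets}, \code{dataset}, \code{evaluation},
#'   \code{importance}.
#' @export
run_pipeline <- function(config = pipeline_config(), session = NULL,
                         out_dir = NULL,
                         n_trees_importance = config$n_trees) {
  t0 <- proc.time()[["elapsed"]]
  log_stage <- function(name)
    message(sprintf("[vrmotion] %-12s %7.2f s", name,
                    proc.time()[["elapsed"]] - t0))
  if (is.null(session)) {
    sim <- generate_calibration_session(
      subject_params(sample_rate_hz = config$sample_rate_hz),
      reps = config$reps, seed = config$seed)
    session <- sim$session
  }
  log_stage("simulate")
  dt <- 1 / session$sample_rate_hz

  table <- assemble_variable_table(session)
  log_stage("kinematics")

  omega <- omega_series(as.matrix(session$right[c("x", "y", "z")]),
                        as.matrix(session$left[c("x", "y", "z")]),
                        dt, rule = config$omega_rule)
  intervals <- detect_intervals(omega, config$speed_threshold,
                                config$min_duration, dt)
  segments <- build_segments(intervals, reps = config$reps)
  log_stage("segmentation")

  mid <- (as.matrix(session$right[c("x", "y", "z")]) +
            as.matrix(session$left[c("x", "y", "z")])) / 2
  rep_slices <- lapply(seq_len(nrow(segments)), function(i)
    seq.int(segments$start[i] + 1L, segments$end[i]))
  profile <- make_profile(
    average_excursion(rep_slices, mid,
                      as.matrix(session$hmd[c("x", "y", "z")])),
    config$calibration_fraction)
  log_stage("calibration")

  metrics <- if (!any(is.na(segments$class)))
    summarize_metrics(table, segments)
  log_stage("metrics")

  saliency <- segment_saliency(table, segments)
  salient_sets <- aggregate_saliency(saliency)
  log_stage("saliency")

  dataset <- build_window_dataset(table,
                                  feature_spec(config$window_length))
  log_stage("featurize")

  feat_cols <- setdiff(names(dataset), c("class", "window_start"))
  evaluation <- kfold_evaluate(dataset[feat_cols], dataset$class,
                               k = config$k_folds,
                               n_trees = config$n_trees,
                               seed = config$seed)
  log_stage("evaluate")

  model <- bagged_trees(dataset[feat_cols], dataset$class,
                        n_trees = n_trees_importance, seed = config$seed)
  importance <- oob_importance(model, dataset[feat_cols], dataset$class)
  log_stage("importance")

  result <- list(session = session, table = table, profile = profile,
                 intervals = intervals, segments = segments,
                 metrics = metrics, saliency = saliency,
                 salient_sets = salient_sets, dataset = dataset,
                 model = model, evaluation = evaluation,
                 importance = importance, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_config(config, file.path(out_dir, "config.json"))
    write_session(session, file.path(out_dir, "session.csv"))
    write_variable_table(table, file.path(out_dir, "variables.csv"))
    write_profile(profile, file.path(out_dir, "profile.json"))
    write_segments(segments, file.path(out_dir, "segments.csv"))
    if (!is.null(metrics))
      utils::write.csv(metrics$summary,
                       file.path(out_dir, "metrics.csv"), row.names = FALSE)
    write_salient_sets(salient_sets,
                       file.path(out_dir, "salient_sets.json"))
    write_window_dataset(dataset, file.path(out_dir, "windows.csv"))
    utils::write.csv(as.data.frame(evaluation$confusion),
                     file.path(out_dir, "confusion.csv"), row.names = FALSE)
    utils::write.csv(importance, file.path(out_dir, "importance.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(accuracy = evaluation$accuracy,
           per_class_tpr = as.list(evaluation$per_class_tpr)),
      file.path(out_dir, "evaluation.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(result)
}
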