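# End-to-end pipeline: manifest -> kinematic session summaries -> condition
# mixed models, and (where traces exist) per-experiment neuron rates and
# weight-sensitivity classification. All result tables are written as
# delimited text; run metadata (config, hash, versions) as JSON.

#' Default pipeline configuration
#'
#' One serializable source of truth for every stage parameter; any entry can
#' be overridden via the `config` argument of [run_pipeline()] or a YAML
#' file.
#'
#' @return A named list of parameters.
#' @export
default_config <- function() {
  list(
    px_per_cm = 1,
    confidence_floor = 0.6,
    smooth_window = 5,
    v_threshold = 2,
    min_bout_s = 0.5,
    min_step_cm = 0.2,
    baseline_percentile = 20,
    k_mad = 3,
    min_duration_s = 0.66,
    tol = 0.20,
    alpha = 0.05,
    responses = c("distance_m", "turning_rad", "mean_walk_v", "mean_walk_w")
  )
}

load_config <- function(config) {
  base <- default_config()
  if (is.null(config)) return(base)
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  base[names(config)] <- config
  base
}

log_msg <- function(...) message("[mouselift] ", ...)

#' Run the full analysis pipeline
#'
#' Reads a session manifest, computes kinematic session summaries, fits the
#' condition mixed model per behavioral response (when at least two animals
#' with all three conditions are present), and classifies weight-sensitive
#' neurons per experiment wherever trace files exist for all three
#' conditions. Missing modalities are skipped with a warning. Result tables
#' are deterministic functions of the inputs and configuration.
#'
#' @param manifest Manifest path or the tibble from [read_manifest()].
#' @param out_dir Directory for result tables and run metadata.
#' @param config `NULL` for defaults, a named list of overrides, or a YAML
#'   file path (see [default_config()]).
#' @return A list: `sessions` (summary tibble), `stats` (tibble of mixed-fit
#'   results per response), `fits` (the `condition_fit` objects),
#'   `classification` (per-experiment list with calls and counts), and
#'   `paths` of everything written.
#' @export
run_pipeline <- function(manifest, out_dir, config = NULL) {
  cfg <- load_config(config)
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  if (!is.data.frame(manifest) || nrow(manifest) == 0) {
    stop("manifest is empty", call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  base_dir <- attr(manifest, "dir") %||% "."

  log_msg("kinematics: ", nrow(manifest), " sessions")
  sessions <- lapply(seq_len(nrow(manifest)), function(i) {
    m <- manifest[i, ]
    traj <- read_trajectory(file.path(base_dir, m$trajectory_file),
                            arena_size = m$arena_size %||% ARENA_SIDE_CM)
    traj <- preprocess_trajectory(traj,
                                  px_per_cm = m$px_per_cm %||% cfg$px_per_cm,
                                  confidence_floor = cfg$confidence_floor,
                                  smooth_window = cfg$smooth_window)
    series <- kinematic_series(traj)
    seg <- segment_locomotion(series, v_threshold = cfg$v_threshold,
                              min_bout_s = cfg$min_bout_s)
    session_summary(traj, seg, animal_id = m$animal_id,
                    condition = m$condition, session_id = m$session_id,
                    min_step_cm = cfg$min_step_cm)
  })
  sessions <- do.call(rbind, sessions)
  paths <- list(sessions = file.path(out_dir, "sessions.csv"))
  utils::write.csv(sessions, paths$sessions, row.names = FALSE)

  # condition-level inference
  fits <- list()
  stats_rows <- list()
  can_fit <- length(unique(sessions$animal_id)) >= 2 &&
    all(CONDITIONS %in% sessions$condition)
  if (can_fit) {
    for (resp in cfg$responses) {
      ds <- tryCatch(suppressWarnings(condition_dataset(sessions, resp)),
                     error = function(e) NULL)
      if (is.null(ds)) next
      fit <- fit_condition_model(ds, alpha = cfg$alpha)
      fits[[resp]] <- fit
      stats_rows[[resp]] <- tibble::tibble(
        response = resp,
        fixed_effect_p = fit$fixed_effect_p,
        random_effect_p = fit$random_effect_p,
        contrast = fit$pairwise$contrast,
        p_adjusted = fit$pairwise$p_adjusted)
    }
  } else {
    warning("fewer than 2 animals or missing conditions; ",
            "skipping mixed-model inference", call. = FALSE)
  }
  stats_tbl <- if (length(stats_rows)) do.call(rbind, stats_rows) else NULL
  if (!is.null(stats_tbl)) {
    paths$stats <- file.path(out_dir, "stats.csv")
    utils::write.csv(stats_tbl, paths$stats, row.names = FALSE)
  }

  # calcium branch, per experiment with all three conditions imaged
  classification <- list()
  if ("trace_file" %in% names(manifest) &&
      any(!is.na(manifest$trace_file))) {
    traced <- manifest[!is.na(manifest$trace_file), , drop = FALSE]
    for (e in unique(traced$experiment)) {
      sub <- traced[traced$experiment == e, , drop = FALSE]
      if (!all(CONDITIONS %in% sub$condition)) {
        warning("experiment ", e, " lacks traces for all conditions; skipped",
                call. = FALSE)
        next
      }
      rates <- lapply(CONDITIONS, function(cond) {
        m <- sub[sub$condition == cond, ][1, ]
        ts <- read_traces(file.path(base_dir, m$trace_file),
                          frame_rate = m$trace_fps %||% NULL,
                          condition = cond)
        neuron_rates(ts, baseline_percentile = cfg$baseline_percentile,
                     k_mad = cfg$k_mad, min_duration_s = cfg$min_duration_s)
      })
      cls <- cohort_classification(rates[[1]], rates[[2]], rates[[3]],
                                   tol = cfg$tol)
      key <- paste0("experiment_", e)
      classification[[key]] <- cls
      f <- file.path(out_dir, paste0("classification_", key, ".csv"))
      utils::write.csv(cls$calls, f, row.names = FALSE)
      paths[[paste0("classification_", key)]] <- f
      log_msg(key, ": ", cls$counts["suppressed"], " suppressed, ",
              cls$counts["enhanced"], " enhanced of ", nrow(cls$calls))
    }
  }

  meta <- list(
    package_version = as.character(utils::packageVersion("mouselift")),
    config = cfg,
    config_hash = rlang::hash(cfg),
    n_sessions = nrow(sessions),
    counts = lapply(classification, function(x) as.list(x$counts))
  )
  paths$metadata <- file.path(out_dir, "run_metadata.json")
  jsonlite::write_json(meta, paths$metadata, auto_unbox = TRUE, digits = NA)

  list(sessions = sessions, stats = stats_tbl, fits = fits,
       classification = classification, paths = paths)
}

`%||%` <- function(a, b) {
  if (is.null(a) || (length(a) == 1 && is.na(a))) b else a
}
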