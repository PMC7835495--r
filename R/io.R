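## CSV readers/writers for the series types, run manifests, and the umbrella
## pipeline runner. Files store angles in degrees and velocities in deg/s
## (human-readable); the package works in radians internally. Frame indices
## in files and interval tables are 0-based with half-open intervals.

require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
}

check_csv_times <- function(t, path) {
  bad <- which(!is.finite(t))
  if (length(bad))
    stop(sprintf("%s: non-finite time at data line %d", path, bad[1L]),
         call. = FALSE)
  d <- diff(t)
  if (any(d == 0))
    stop(sprintf("%s: duplicated timestamp at data line %d", path,
                 which(d == 0)[1L] + 1L), call. = FALSE)
  if (any(d < 0))
    stop(sprintf("%s: non-monotonic time at data line %d", path,
                 which(d < 0)[1L] + 1L), call. = FALSE)
  if (length(d) && max(d) - min(d) > 1e-9)
    stop(sprintf("%s: non-uniform time grid (spread %.3g s)", path,
                 max(d) - min(d)), call. = FALSE)
  1 / stats::median(d)
}

#' Read a markers CSV
#'
#' Expects a header with columns `t, part, lx, ly, lz, rx, ry, rz, fx, fy, fz`
#' (times in seconds, positions in meters, `.` decimal separator). Validates a
#' uniform time grid per part (fps inferred from the median spacing and
#' checked uniform within 1e-9 s) and rejects NaN rows, duplicated or
#' non-monotonic timestamps with the offending line number.
#'
#' @param path CSV file path.
#' @return a named list of [marker_series()], one element per part present.
#' @export
read_markers_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("t", "part", "lx", "ly", "lz", "rx", "ry", "rz",
                        "fx", "fy", "fz"), path)
  num_cols <- setdiff(names(df), "part")
  bad <- which(!stats::complete.cases(df[num_cols]) |
                 !apply(is.finite(as.matrix(df[num_cols])), 1L, all))
  if (length(bad))
    stop(sprintf("%s: NaN/missing values at data line %d", path, bad[1L]),
         call. = FALSE)
  out <- lapply(split(df, df$part), function(d) {
    fps <- check_csv_times(d$t, path)
    marker_series(d$t, left = cbind(d$lx, d$ly, d$lz),
                  right = cbind(d$rx, d$ry, d$rz),
                  front = cbind(d$fx, d$fy, d$fz),
                  part = d$part[1L], fps = fps)
  })
  out[order(names(out))]
}

#' Write series to CSV
#'
#' Counterparts of the readers; `write_markers_csv` accepts a single series or
#' a list of per-part series written into one file.
#'
#' @param x the series (or list of series) to write.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_markers_csv <- function(x, path) {
  if (inherits(x, "marker_series")) x <- list(x)
  df <- do.call(rbind, lapply(x, as.data.frame))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_markers_csv
#' @export
write_pose_csv <- function(x, path) {
  if (inherits(x, "pose_series")) x <- list(x)
  df <- do.call(rbind, lapply(x, as.data.frame))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a pose CSV (`t, part, yaw_deg, pitch_deg, roll_deg`)
#'
#' @param path CSV file path.
#' @return a named list of [pose_series()] per part, angles converted to
#'   radians.
#' @export
read_pose_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("t", "part", "yaw_deg", "pitch_deg", "roll_deg"), path)
  out <- lapply(split(df, df$part), function(d) {
    fps <- check_csv_times(d$t, path)
    pose_series(d$t, d$yaw_deg * DEG2RAD, d$pitch_deg * DEG2RAD,
                d$roll_deg * DEG2RAD, part = d$part[1L], fps = fps)
  })
  out[order(names(out))]
}

#' @rdname write_markers_csv
#' @export
write_velocity_csv <- function(x, path) {
  if (inherits(x, "velocity_series")) x <- list(x)
  df <- do.call(rbind, lapply(x, as.data.frame))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a velocity CSV (`t, part, omega_z_degps`)
#'
#' @param path CSV file path.
#' @return a named list of [velocity_series()] per part.
#' @export
read_velocity_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("t", "part", "omega_z_degps"), path)
  out <- lapply(split(df, df$part), function(d) {
    fps <- check_csv_times(d$t, path)
    velocity_series(d$t, d$omega_z_degps, part = d$part[1L], fps = fps)
  })
  out[order(names(out))]
}

#' @rdname write_markers_csv
#' @export
write_labels_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a labels CSV (`t, label`)
#'
#' @param path CSV file path.
#' @return a [label_series()].
#' @export
read_labels_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("t", "label"), path)
  fps <- check_csv_times(df$t, path)
  label_series(df$t, df$label, fps = fps)
}

#' Build a run manifest
#'
#' Records everything needed to reproduce a run: the configuration snapshot,
#' every seed in play, MD5 digests of input files, and the package version.
#'
#' @param config named list: the configuration snapshot.
#' @param seeds named list or vector of all seeds used.
#' @param input_files character vector of input file paths (digested).
#' @return a list of class `run_manifest`.
#' @export
run_manifest <- function(config = list(), seeds = list(), input_files = character(0)) {
  digests <- if (length(input_files)) {
    md5 <- tools::md5sum(input_files)
    stats::setNames(as.character(md5), basename(input_files))
  } else NULL
  structure(list(package = "beechoreo",
                 version = as.character(utils::packageVersion("beechoreo")),
                 created = format(Sys.time(), tz = "UTC", usetz = TRUE),
                 config = config, seeds = seeds, input_digests = digests,
                 outputs = character(0)),
            class = "run_manifest")
}

#' Write pipeline outputs and manifest to a directory
#'
#' Data frames are written as CSV, other list-like outputs as JSON, and the
#' manifest (updated with the output file list) as `manifest.json`.
#' Overwrites idempotently.
#'
#' @param manifest a [run_manifest()].
#' @param outputs named list of outputs (data.frames or lists).
#' @param dir output directory (created if needed).
#' @return the updated manifest, invisibly.
#' @export
write_results <- function(manifest, outputs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(dir, 2L) != 0L)
    stop(sprintf("output directory not writable: %s", dir), call. = FALSE)
  files <- character(0)
  for (nm in names(outputs)) {
    out <- outputs[[nm]]
    if (is.data.frame(out)) {
      f <- file.path(dir, paste0(nm, ".csv"))
      utils::write.csv(out, f, row.names = FALSE, quote = FALSE)
    } else {
      f <- file.path(dir, paste0(nm, ".json"))
      jsonlite::write_json(out, f, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, force = TRUE)
    }
    files <- c(files, basename(f))
  }
  manifest$outputs <- files
  jsonlite::write_json(unclass(manifest), file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(manifest)
}

PIPELINE_STAGES <- c("simulate", "orient", "segment", "benchmark",
                     "train-clf", "sweep", "train-map", "shift-scan")

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order on simulated flights
#' (stage `simulate`) or on marker CSV files (`config$markers_files`), logging
#' stage boundaries with timings to stderr. Stages:
#' `simulate` (synthetic flights), `orient` (markers to pose and angular
#' velocity), `segment` (head two-threshold ground truth), `benchmark`
#' (optimized thorax double threshold), `train-clf` (classifier on the
#' chronological split, evaluated on the held-out flight), `sweep` (frame-rate
#' and top-view robustness), `train-map` (velocity mapper at tau = 0),
#' `shift-scan` (correlation versus temporal shift).
#'
#' @param config named list. Recognised fields: `stages` (character subset
#'   above; default all), `seed`, `out` (output directory or `NULL`),
#'   `n_flights`, `flight` (arguments for [flight_config()]), `markers_files`
#'   (character vector of CSV paths, alternative to `simulate`), `classifier`
#'   (list: `family`, `depth`, `delta_t_ms`, `n_trees`), `benchmark` (list:
#'   `high_grid`, `low_grid`), `sweep_fps`, `mapper` (arguments for
#'   [mapper_config()]), `tau_grid_ms`.
#' @return a [run_manifest()] with a `results` element holding each executed
#'   stage's outputs.
#' @export
run_pipeline <- function(config = list()) {
  stages <- config$stages %||% PIPELINE_STAGES
  unknown <- setdiff(stages, PIPELINE_STAGES)
  if (length(unknown))
    stop(sprintf("unknown stage(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  stages <- PIPELINE_STAGES[PIPELINE_STAGES %in% stages]
  seed <- config$seed %||% 1L
  n_flights <- config$n_flights %||% 6L
  results <- list()
  flights <- NULL

  log_stage <- function(name, expr) {
    t0 <- Sys.time()
    message(sprintf("[%s] starting", name))
    out <- force(expr)
    message(sprintf("[%s] done in %.1f s", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    out
  }

  if ("simulate" %in% stages) {
    flights <- log_stage("simulate", {
      lapply(seq_len(n_flights), function(i) {
        args <- config$flight %||% list()
        args$seed <- seed * 1000L + i
        generate_flight(do.call(flight_config, args))
      })
    })
    results$simulate <- list(n_flights = n_flights,
                             n_events = vapply(flights, function(f)
                               nrow(f$events), 0L))
  } else if (!is.null(config$markers_files)) {
    flights <- log_stage("orient", {
      lapply(config$markers_files, function(path) {
        parts <- read_markers_csv(path)
        poses <- lapply(parts, pose_from_markers)
        vs <- lapply(poses, angular_velocity_z)
        labels <- two_threshold_segment(vs$head)
        list(head_pose = poses$head, thorax_pose = poses$thorax,
             head_v = vs$head, thorax_v = vs$thorax, true_labels = labels)
      })
    })
  }
  if (is.null(flights) && length(setdiff(stages, "simulate")))
    stop("no input: request the simulate stage or provide markers_files",
         call. = FALSE)

  clf_flights <- lapply(flights, function(f)
    list(v = f$thorax_v, labels = f$true_labels))

  if ("segment" %in% stages) {
    results$segment <- log_stage("segment", {
      segs <- lapply(flights, function(f) segments_from_labels(f$true_labels))
      list(n_segments = vapply(segs, nrow, 0L),
           saccade_fraction = vapply(flights, function(f)
             mean(f$true_labels$labels), 0))
    })
  }

  if ("benchmark" %in% stages) {
    results$benchmark <- log_stage("benchmark", {
      v_all <- unlist(lapply(flights, function(f) f$thorax_v$omega_z))
      l_all <- unlist(lapply(flights, function(f) f$true_labels$labels))
      args <- config$benchmark %||% list()
      do.call(optimize_benchmark_thresholds,
              c(list(v_thorax = v_all, head_labels = l_all), args))
    })
  }

  model <- NULL
  if (any(c("train-clf", "sweep") %in% stages)) {
    clf_cfg <- config$classifier %||% list()
    model_res <- log_stage("train-clf", {
      sp <- split_flights(clf_flights)
      spec <- window_spec(clf_cfg$delta_t_ms %||% 20, flights[[1L]]$fps)
      train_ds <- windows_for_flights(sp$train, spec)
      m <- train_classifier(train_ds,
                            family = clf_cfg$family %||% "random_forest",
                            depth = clf_cfg$depth %||% 10L,
                            n_trees = clf_cfg$n_trees %||% 100L, seed = seed)
      list(model = m,
           validation = evaluate_classifier(m, windows_for_flights(sp$validation, spec)),
           test = evaluate_classifier(m, windows_for_flights(sp$test, spec)))
    })
    model <- model_res$model
    if ("train-clf" %in% stages)
      results$`train-clf` <- model_res[c("validation", "test")]
  }

  if ("sweep" %in% stages) {
    results$sweep <- log_stage("sweep", {
      thr <- if (!is.null(results$benchmark))
        c(results$benchmark$high, results$benchmark$low)
      else c(SACCADE_HIGH_DEFAULT, SACCADE_LOW_DEFAULT)
      fps_list <- config$sweep_fps %||% c(25, 50, 100, 250, 500)
      test_fl <- flights[length(flights)]
      rbind(cbind(framerate_sweep(test_fl, fps_list, model, thr), topview = FALSE),
            cbind(topview_sweep(test_fl, fps_list, model, thr), topview = TRUE))
    })
  }

  if (any(c("train-map", "shift-scan") %in% stages)) {
    map_args <- config$mapper %||% list()
    map_args$fps <- flights[[1L]]$fps
    map_args$seed <- map_args$seed %||% seed
    map_cfg <- do.call(mapper_config, map_args)
    pairs <- lapply(flights, function(f)
      list(source = f$thorax_v, target = f$head_v))
    if ("train-map" %in% stages) {
      results$`train-map` <- log_stage("train-map", {
        mdl <- train_mapper(lapply(pairs[-length(pairs)], `[[`, "source"),
                            lapply(pairs[-length(pairs)], `[[`, "target"),
                            map_cfg)
        held <- pairs[[length(pairs)]]
        ev <- evaluate_mapper(mdl, held$source, held$target)
        list(final_training_loss = mdl$loss_history[length(mdl$loss_history)],
             test_r = ev$r, test_median_error_angle = ev$median_error_angle)
      })
    }
    if ("shift-scan" %in% stages) {
      results$`shift-scan` <- log_stage("shift-scan", {
        correlation_vs_shift(pairs, config$tau_grid_ms %||% seq(-20, 20, by = 4),
                             map_cfg)
      })
    }
  }

  manifest <- run_manifest(config = config,
                           seeds = list(run = seed),
                           input_files = config$markers_files %||% character(0))
  manifest$results <- results
  if (!is.null(config$out)) {
    writable <- Filter(function(nm) is.data.frame(results[[nm]]) ||
                         is.list(results[[nm]]), names(results))
    manifest <- write_results(manifest, results[writable], config$out)
    manifest$results <- results
  }
  manifest
}

`%||%` <- function(a, b) if (is.null(a)) b else a
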