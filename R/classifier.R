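## Head-saccade prediction from windowed thorax angular velocity with
## decision-tree and random-forest classifiers, hyperparameter grid search,
## and robustness sweeps over frame rate and top-view degradation.

#' Centered time-window specification
#'
#' Describes the window of angular-velocity samples fed to a classifier or
#' mapper: total width `delta_t_ms` milliseconds centered on the labelled
#' frame, hence `n_samples = 2 * floor(delta_t_ms * fps / 2000) + 1` samples
#' (always odd; the floor of the half-width keeps odd ms-by-fps products
#' well-defined).
#'
#' @param delta_t_ms total window width in milliseconds (>= 0).
#' @param fps frame rate of the series the window is applied to.
#' @return an object of class `window_spec` with fields `delta_t_ms`, `fps`,
#'   `n_samples` and `half_width` (samples on each side of the center).
#' @export
window_spec <- function(delta_t_ms, fps = 500) {
  if (delta_t_ms < 0) stop("delta_t_ms must be >= 0", call. = FALSE)
  half <- as.integer(floor(delta_t_ms * fps / 2000))
  structure(list(delta_t_ms = delta_t_ms, fps = fps,
                 n_samples = 2L * half + 1L, half_width = half),
            class = "window_spec")
}

#' @export
print.window_spec <- function(x, ...) {
  cat(sprintf("<window_spec: %g ms @ %g fps -> %d samples>\n",
              x$delta_t_ms, x$fps, x$n_samples))
  invisible(x)
}

#' Build a windowed dataset from a velocity series and labels
#'
#' One row per frame that admits a complete centered window of
#' `spec$n_samples` velocity samples; frames within half a window of either
#' end are dropped. The class label is taken from the window's center frame.
#'
#' @param v a [velocity_series()].
#' @param labels an aligned [label_series()] (or `NULL` for unlabeled data).
#' @param spec a [window_spec()].
#' @param flight_id identifier recorded per row (provenance).
#' @return an object of class `windowed_dataset`: list with matrix `X`
#'   (rows = frames, columns = velocities in deg/s, past to future), integer
#'   `y`, `frame_index` (center frame per row, 1-based) and `flight_id`.
#' @export
build_windows <- function(v, labels = NULL, spec = window_spec(0, v$fps),
                          flight_id = 1L) {
  stopifnot(inherits(v, "velocity_series"), inherits(spec, "window_spec"))
  x <- v$omega_z
  n <- length(x)
  m <- spec$n_samples
  if (!is.null(labels)) {
    yl <- if (inherits(labels, "label_series")) labels$labels else as.integer(labels)
    if (length(yl) != n) stop("labels must align with the velocity series",
                              call. = FALSE)
  } else yl <- rep(NA_integer_, n)
  if (n < m) {
    warning("series shorter than the window; empty dataset")
    X <- matrix(numeric(0), 0L, m)
    colnames(X) <- window_colnames(m)
    return(structure(list(X = X, y = integer(0), frame_index = integer(0),
                          flight_id = integer(0), spec = spec),
                     class = "windowed_dataset"))
  }
  ## embed() returns rows in reverse time order; flip columns so column 1 is
  ## the earliest sample and the center column is the labelled frame
  X <- stats::embed(x, m)[, m:1, drop = FALSE]
  colnames(X) <- window_colnames(m)
  center <- seq.int(spec$half_width + 1L, n - spec$half_width)
  structure(list(X = X, y = yl[center], frame_index = center,
                 flight_id = rep(as.integer(flight_id), length(center)),
                 spec = spec),
            class = "windowed_dataset")
}

window_colnames <- function(m) paste0("w", seq_len(m))

#' @export
print.windowed_dataset <- function(x, ...) {
  cat(sprintf("<windowed_dataset: %d rows x %d samples, %s>\n",
              nrow(x$X), ncol(x$X),
              if (all(is.na(x$y))) "unlabeled"
              else sprintf("%.1f%% saccade", 100 * mean(x$y, na.rm = TRUE))))
  invisible(x)
}

## rbind windowed datasets (same spec)
bind_windows <- function(ds_list) {
  ds_list <- Filter(function(d) nrow(d$X) > 0L, ds_list)
  if (!length(ds_list)) stop("no rows in any dataset", call. = FALSE)
  structure(list(X = do.call(rbind, lapply(ds_list, `[[`, "X")),
                 y = unlist(lapply(ds_list, `[[`, "y")),
                 frame_index = unlist(lapply(ds_list, `[[`, "frame_index")),
                 flight_id = unlist(lapply(ds_list, `[[`, "flight_id")),
                 spec = ds_list[[1L]]$spec),
            class = "windowed_dataset")
}

#' Chronological train/validation/test split over flights
#'
#' Training data are the first `train_frac` (by frame count, floor) of each of
#' the first K-1 flights; validation the remaining frames of those flights;
#' the last flight is held out in full as the test set.
#'
#' @param flights a list of at least two flights, each a list with elements
#'   `v` (a [velocity_series()]) and `labels` (a [label_series()]).
#' @param train_frac fraction of frames per learning flight used for
#'   training (default 0.7).
#' @return a list with elements `train`, `validation`, `test`, each a list of
#'   flights in the same `(v, labels)` form (plus `flight_id`).
#' @export
split_flights <- function(flights, train_frac = 0.7) {
  if (length(flights) < 2L)
    stop("need at least 2 flights (the last is held out for testing)",
         call. = FALSE)
  K <- length(flights)
  cut_flight <- function(fl, idx, id) {
    list(v = subset_series(fl$v, idx),
         labels = subset_series(fl$labels, idx),
         flight_id = id)
  }
  train <- list(); validation <- list()
  for (i in seq_len(K - 1L)) {
    n <- series_length(flights[[i]]$v)
    n_train <- floor(train_frac * n)
    train[[i]] <- cut_flight(flights[[i]], seq_len(n_train), i)
    validation[[i]] <- cut_flight(flights[[i]], seq.int(n_train + 1L, n), i)
  }
  test <- list(cut_flight(flights[[K]], seq_len(series_length(flights[[K]]$v)), K))
  list(train = train, validation = validation, test = test)
}

#' Build and bind windowed datasets for a list of flights
#'
#' Applies [build_windows()] to each flight (a list with `v` and `labels`,
#' as produced by [split_flights()]) and row-binds the results; windows never
#' span flight boundaries.
#'
#' @param flights list of flights with elements `v`, `labels` and optionally
#'   `flight_id`.
#' @param spec a [window_spec()].
#' @return a single `windowed_dataset`.
#' @export
windows_for_flights <- function(flights, spec) {
  bind_windows(lapply(seq_along(flights), function(i) {
    fl <- flights[[i]]
    build_windows(fl$v, fl$labels, spec,
                  flight_id = if (!is.null(fl$flight_id)) fl$flight_id else i)
  }))
}

#' Train a saccade/intersaccade classifier
#'
#' Fits a decision tree ([rpart::rpart()]) or a random forest
#' ([ranger::ranger()], probability forest, single thread) on a windowed
#' dataset. Depth is the maximum tree depth; training is deterministic given
#' `seed`.
#'
#' @param ds a labelled [build_windows()] dataset with both classes present.
#' @param family `"decision_tree"` or `"random_forest"`.
#' @param depth maximum tree depth, in `[1, 20]`.
#' @param n_trees number of trees for the forest (default 100; ignored for the
#'   decision tree).
#' @param seed integer seed recorded in the model.
#' @param bootstrap forest only: draw bootstrap resamples per tree (default
#'   `TRUE`). With `bootstrap = FALSE` and `n_trees = 1` the forest degenerates
#'   to a single tree grown on the full data.
#' @return an object of class `saccade_classifier`.
#' @export
train_classifier <- function(ds, family = c("random_forest", "decision_tree"),
                             depth = 10L, n_trees = 100L, seed = 1L,
                             bootstrap = TRUE) {
  family <- match.arg(family)
  stopifnot(inherits(ds, "windowed_dataset"))
  if (depth < 1L || depth > 20L) stop("depth must lie in [1, 20]", call. = FALSE)
  if (length(unique(ds$y)) < 2L)
    stop("training data contain a single class", call. = FALSE)
  imb <- max(mean(ds$y), 1 - mean(ds$y)) / min(mean(ds$y), 1 - mean(ds$y))
  if (imb > 4) warning(sprintf("class imbalance %.1f:1 exceeds 4:1", imb))
  df <- data.frame(y = factor(ds$y, levels = c(0L, 1L)), ds$X,
                   check.names = FALSE)
  fit <- if (family == "decision_tree") {
    with_seed(seed,
      rpart::rpart(y ~ ., data = df, method = "class",
                   control = rpart::rpart.control(maxdepth = depth, cp = 0,
                                                  minsplit = 2L, minbucket = 1L,
                                                  xval = 0L)))
  } else {
    ranger::ranger(y ~ ., data = df, num.trees = n_trees, max.depth = depth,
                   probability = TRUE, seed = seed, num.threads = 1L,
                   replace = bootstrap, sample.fraction = 1,
                   mtry = if (bootstrap) NULL else ncol(ds$X))
  }
  structure(list(family = family, depth = as.integer(depth),
                 n_trees = if (family == "random_forest") as.integer(n_trees) else NA_integer_,
                 spec = ds$spec, seed = as.integer(seed), fit = fit),
            class = "saccade_classifier")
}

#' @export
print.saccade_classifier <- function(x, ...) {
  cat(sprintf("<saccade_classifier: %s, depth %d%s, window %g ms @ %g fps, seed %d>\n",
              x$family, x$depth,
              if (!is.na(x$n_trees)) sprintf(", %d trees", x$n_trees) else "",
              x$spec$delta_t_ms, x$spec$fps, x$seed))
  invisible(x)
}

#' Predict saccade labels or scores
#'
#' @param object a [train_classifier()] model.
#' @param ds a [build_windows()] dataset (or a bare matrix with matching
#'   columns).
#' @param type `"class"` for 0/1 labels, `"prob"` for the saccade-class
#'   probability score in `[0, 1]`.
#' @param ... unused.
#' @return integer labels or numeric scores, one per row.
#' @export
predict.saccade_classifier <- function(object, ds, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  X <- if (inherits(ds, "windowed_dataset")) ds$X else as.matrix(ds)
  newdata <- data.frame(X, check.names = FALSE)
  prob <- if (object$family == "decision_tree") {
    unname(stats::predict(object$fit, newdata = newdata, type = "prob")[, "1"])
  } else {
    unname(stats::predict(object$fit, data = newdata,
                          num.threads = 1L)$predictions[, "1"])
  }
  if (type == "prob") prob else as.integer(prob > 0.5)
}

#' Evaluate a classifier on a windowed dataset
#'
#' Reports the frame-wise accuracy (fraction of frames classified as the
#' reference), the error rate `1 - accuracy`, and the area under the ROC curve
#' of the continuous class scores against the reference labels. For a
#' degenerate single-class reference the AUC is undefined and reported as
#' `NA` with a warning.
#'
#' @param model a [train_classifier()] model.
#' @param ds a labelled [build_windows()] dataset.
#' @return a list with `accuracy`, `error_rate` and `auc`.
#' @export
evaluate_classifier <- function(model, ds) {
  stopifnot(inherits(ds, "windowed_dataset"), nrow(ds$X) > 0L)
  scores <- predict(model, ds, type = "prob")
  pred <- as.integer(scores > 0.5)
  acc <- mean(pred == ds$y)
  list(accuracy = acc, error_rate = 1 - acc, auc = score_auc(scores, ds$y))
}

## AUC of continuous (or binary) scores against binary labels. Explicit
## direction and levels so pROC never auto-flips a below-chance classifier.
score_auc <- function(scores, labels) {
  if (length(unique(labels)) < 2L) {
    warning("single-class reference; AUC undefined")
    return(NA_real_)
  }
  as.numeric(pROC::auc(pROC::roc(response = labels, predictor = scores,
                                 levels = c(0L, 1L), direction = "<",
                                 quiet = TRUE)))
}

#' Grid search over depth and window width
#'
#' Trains one classifier per `(depth, delta_t)` cell on the training split and
#' scores frame-wise accuracy on the validation split; returns the best model
#' with the full results table. Ties are broken toward the smaller depth, then
#' the smaller window.
#'
#' @param flights list of flights (`v`, `labels`) passed to [split_flights()].
#' @param family,n_trees,seed passed to [train_classifier()].
#' @param depth_grid integer depths (default 1:20).
#' @param delta_t_grid window widths in ms (default `seq(0, 50, by = 2)`).
#' @return a list with `model` (refit on the training split at the best cell),
#'   `depth`, `delta_t_ms`, `accuracy` (validation), and `table` (a data.frame
#'   with one row per cell).
#' @export
grid_search_classifier <- function(flights, family = "random_forest",
                                   depth_grid = 1:20,
                                   delta_t_grid = seq(0, 50, by = 2),
                                   n_trees = 100L, seed = 1L) {
  if (!length(depth_grid) || !length(delta_t_grid))
    stop("hyperparameter grids must be non-empty", call. = FALSE)
  sp <- split_flights(flights)
  fps <- sp$train[[1L]]$v$fps
  tab <- expand.grid(depth = sort(depth_grid),
                     delta_t_ms = sort(delta_t_grid))
  tab$accuracy <- NA_real_
  for (dt in sort(unique(tab$delta_t_ms))) {
    spec <- window_spec(dt, fps)
    train_ds <- windows_for_flights(sp$train, spec)
    val_ds <- windows_for_flights(sp$validation, spec)
    for (D in sort(unique(tab$depth))) {
      model <- train_classifier(train_ds, family, depth = D,
                                n_trees = n_trees, seed = seed)
      acc <- mean(predict(model, val_ds) == val_ds$y)
      tab$accuracy[tab$depth == D & tab$delta_t_ms == dt] <- acc
    }
  }
  ## argmax with ties broken toward smaller depth, then smaller window
  ord <- order(-tab$accuracy, tab$depth, tab$delta_t_ms)
  top <- tab[ord[1L], ]
  spec <- window_spec(top$delta_t_ms, fps)
  model <- train_classifier(windows_for_flights(sp$train, spec), family,
                            depth = top$depth, n_trees = n_trees, seed = seed)
  list(model = model, depth = top$depth, delta_t_ms = top$delta_t_ms,
       accuracy = top$accuracy, table = tab)
}

#' Robustness sweep over frame rate (and optionally top-view degradation)
#'
#' For each target frame rate, every evaluation flight is degraded with
#' [degrade()] (decimate-and-respline round trip; with `topview = TRUE` the
#' markers are flattened first), the thorax angular velocity is recomputed,
#' windows are rebuilt, and both the pretrained classifier and the fixed
#' benchmark double threshold are scored against the original full-rate head
#' ground truth.
#'
#' @param flights list of [generate_flight()] objects to evaluate on.
#' @param fps_list frame rates to emulate, each in `(0, fps]`.
#' @param model a pretrained [train_classifier()] model (trained at the native
#'   rate).
#' @param thresholds benchmark threshold pair as `c(high, low)` deg/s,
#'   typically from [optimize_benchmark_thresholds()] at the native rate.
#' @param topview if `TRUE`, apply the null-pitch/roll (top-view) assumption
#'   before down-sampling.
#' @return a data.frame with columns `fps`, `method` (`"classifier"` /
#'   `"benchmark"`), `auc` and `accuracy`.
#' @export
framerate_sweep <- function(flights, fps_list, model, thresholds,
                            topview = FALSE) {
  stopifnot(inherits(model, "saccade_classifier"))
  rows <- list()
  for (fps_target in fps_list) {
    accs <- c(classifier = 0, benchmark = 0)
    sc_all <- list(classifier = numeric(0), benchmark = numeric(0))
    y_all <- list(classifier = integer(0), benchmark = integer(0))
    for (fl in flights) {
      dg <- degrade(fl, fps_target = fps_target, topview = topview)
      ds <- build_windows(dg$thorax_v, fl$true_labels, model$spec)
      scores <- predict(model, ds, type = "prob")
      sc_all$classifier <- c(sc_all$classifier, scores)
      y_all$classifier <- c(y_all$classifier, ds$y)
      bench <- two_threshold_segment(dg$thorax_v, high = thresholds[1L],
                                     low = thresholds[2L])
      sc_all$benchmark <- c(sc_all$benchmark, bench$labels)
      y_all$benchmark <- c(y_all$benchmark, fl$true_labels$labels)
    }
    for (mth in c("classifier", "benchmark")) {
      pred <- as.integer(sc_all[[mth]] > 0.5)
      rows[[length(rows) + 1L]] <- data.frame(
        fps = fps_target, method = mth,
        auc = score_auc(sc_all[[mth]], y_all[[mth]]),
        accuracy = mean(pred == y_all[[mth]]))
    }
  }
  do.call(rbind, rows)
}

#' @rdname framerate_sweep
#' @param ... passed on to [framerate_sweep()].
#' @export
topview_sweep <- function(flights, fps_list, model, thresholds, ...) {
  framerate_sweep(flights, fps_list, model, thresholds, topview = TRUE, ...)
}
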