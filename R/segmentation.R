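## Two-threshold (hysteresis) saccade extraction, the frame-wise accuracy
## metric, and benchmark threshold optimization on thorax angular velocity.
##
## Default thresholds: a frame seeds a saccade when |omega_z| exceeds
## 372.42 deg/s; the saccade extends over contiguous neighbours while
## |omega_z| exceeds 200.54 deg/s.

SACCADE_HIGH_DEFAULT <- 372.42
SACCADE_LOW_DEFAULT <- 200.54

#' Two-threshold (hysteresis) saccade segmentation
#'
#' Frames where the (by default absolute) angular velocity exceeds `high` seed
#' a saccade; labels then propagate outward from each seed over contiguous
#' frames whose velocity exceeds `low`. All other frames are intersaccade (0).
#'
#' @param v a [velocity_series()] or a numeric vector of angular velocities in
#'   deg/s.
#' @param high seed threshold, deg/s (default 372.42).
#' @param low extension threshold, deg/s (default 200.54); must satisfy
#'   `0 < low <= high`.
#' @param signed if `TRUE`, thresholds are applied to the signed velocity
#'   instead of its absolute value (saccades in one turn direction only).
#' @return a [label_series()] (or, for numeric input, an integer vector) with
#'   1 = saccade, 0 = intersaccade.
#' @export
#' @examples
#' two_threshold_segment(c(0, 250, 400, 250, 0))        # 0 1 1 1 0
#' two_threshold_segment(c(0, -400, -250, 0))           # 0 1 1 0
two_threshold_segment <- function(v, high = SACCADE_HIGH_DEFAULT,
                                  low = SACCADE_LOW_DEFAULT, signed = FALSE) {
  if (!(low > 0 && low <= high))
    stop("thresholds must satisfy 0 < low <= high", call. = FALSE)
  is_series <- inherits(v, "velocity_series")
  x <- if (is_series) v$omega_z else as.numeric(v)
  if (!signed) x <- abs(x)
  labels <- hysteresis_labels(x, high, low)
  if (is_series) label_series(v$times, labels, fps = v$fps) else labels
}

## Core hysteresis labelling on a prepared signal: keep every maximal run of
## x > low that contains at least one sample with x > high.
hysteresis_labels <- function(x, high, low) {
  n <- length(x)
  if (n == 0L) return(integer(0))
  above_low <- x > low
  r <- rle(above_low)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  labels <- integer(n)
  seed <- x > high
  cs <- cumsum(seed)
  for (i in which(r$values)) {
    n_seed <- cs[ends[i]] - (if (starts[i] > 1L) cs[starts[i] - 1L] else 0L)
    if (n_seed > 0L) labels[starts[i]:ends[i]] <- 1L
  }
  labels
}

#' Frame-wise classification accuracy
#'
#' Fraction of frames on which two label series agree:
#' `mean([pred(t) == ref(t)])` over all frames (Iverson bracket).
#'
#' @param pred,ref [label_series()] objects or binary vectors of equal length.
#' @return a fraction in `[0, 1]`.
#' @export
label_accuracy <- function(pred, ref) {
  p <- if (inherits(pred, "label_series")) pred$labels else as.integer(pred)
  r <- if (inherits(ref, "label_series")) ref$labels else as.integer(ref)
  if (length(p) != length(r))
    stop(sprintf("label length mismatch: %d vs %d", length(p), length(r)),
         call. = FALSE)
  mean(p == r)
}

#' Optimize benchmark double thresholds on thorax velocity
#'
#' Exhaustive search over threshold pairs (restricted to `low <= high`) for
#' the pair maximizing the frame-wise accuracy of
#' `two_threshold_segment(v_thorax, high, low)` against reference head labels.
#' Ties are broken deterministically toward the largest `high`, then the
#' largest `low`.
#'
#' The search is exact: for each `low` the runs of `|omega_z| > low` are
#' computed once and the accuracy as a function of `high` is updated
#' incrementally over runs sorted by their velocity maximum, which is
#' algebraically identical to evaluating every pair directly.
#'
#' @param v_thorax a [velocity_series()] (thorax angular velocity) or numeric
#'   vector, deg/s.
#' @param head_labels reference [label_series()] or binary vector (head ground
#'   truth).
#' @param high_grid,low_grid candidate thresholds in deg/s. By default `high`
#'   spans 200 to 1000 deg/s and `low` 50 to 1000 deg/s, both in 5 deg/s
#'   steps; pairs with `low > high` are skipped.
#' @param signed passed to [two_threshold_segment()].
#' @return a list with `high`, `low`, `accuracy`, and `n_pairs` (number of
#'   candidate pairs examined).
#' @export
optimize_benchmark_thresholds <- function(v_thorax, head_labels,
                                          high_grid = seq(200, 1000, by = 5),
                                          low_grid = seq(50, 1000, by = 5),
                                          signed = FALSE) {
  if (!length(high_grid) || !length(low_grid))
    stop("threshold grids must be non-empty", call. = FALSE)
  x <- if (inherits(v_thorax, "velocity_series")) v_thorax$omega_z else as.numeric(v_thorax)
  if (!signed) x <- abs(x)
  ref <- if (inherits(head_labels, "label_series")) head_labels$labels else as.integer(head_labels)
  if (length(ref) != length(x))
    stop("v_thorax and head_labels must have equal length", call. = FALSE)
  n <- length(x)
  if (length(unique(ref)) < 2L)
    warning("reference labels are constant; threshold optimization is degenerate")

  high_grid <- sort(unique(as.numeric(high_grid)))
  low_grid <- sort(unique(as.numeric(low_grid)))
  acc0_base <- sum(ref == 0L)  # matches when everything is labelled 0

  best <- list(high = NA_real_, low = NA_real_, accuracy = -Inf)
  n_pairs <- 0L
  for (low in low_grid) {
    highs <- high_grid[high_grid >= low]
    if (!length(highs)) next
    n_pairs <- n_pairs + length(highs)
    above <- x > low
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    if (length(runs)) {
      run_max <- vapply(runs, function(i) max(x[starts[i]:ends[i]]), 0)
      csum_ref <- c(0L, cumsum(ref))
      run_pos <- csum_ref[ends[runs] + 1L] - csum_ref[starts[runs]]
      run_len <- ends[runs] - starts[runs] + 1L
      ## labelling a run as saccade changes matches by (#ref==1) - (#ref==0)
      run_delta <- 2L * run_pos - run_len
      ord <- order(run_max, decreasing = TRUE)
      run_max <- run_max[ord]; run_delta <- run_delta[ord]
      cdelta <- cumsum(run_delta)
      ## for threshold `high`, the active runs are those with run_max > high
      k <- findInterval(-highs, -run_max, left.open = TRUE)
      matches <- acc0_base + ifelse(k > 0L, cdelta[pmax(k, 1L)], 0L)
    } else {
      matches <- rep(acc0_base, length(highs))
    }
    acc <- matches / n
    ## tie-break: largest high then largest low; iterate lows ascending and
    ## highs ascending, accept strictly-better or equal-with-larger keys
    for (j in seq_along(highs)) {
      a <- acc[j]
      if (a > best$accuracy + 1e-15 ||
          (abs(a - best$accuracy) <= 1e-15 &&
           (highs[j] > best$high ||
            (highs[j] == best$high && low > best$low)))) {
        best <- list(high = highs[j], low = low, accuracy = a)
      }
    }
  }
  if (!is.finite(best$accuracy))
    stop("no candidate pair with low <= high in the grids", call. = FALSE)
  best$n_pairs <- n_pairs
  best
}

#' Saccade intervals from a label series
#'
#' Maximal runs of saccade labels as 0-based half-open `[start, end)` frame
#' intervals, ordered and non-overlapping.
#'
#' @param labels a [label_series()] or binary vector.
#' @return a two-column integer matrix with columns `start`, `end`.
#' @export
#' @examples
#' segments_from_labels(c(0, 1, 1, 0, 1))  # rows (1, 3) and (4, 5)
segments_from_labels <- function(labels) {
  l <- if (inherits(labels, "label_series")) labels$labels else as.integer(labels)
  out <- matrix(integer(0), 0L, 2L, dimnames = list(NULL, c("start", "end")))
  if (!length(l)) return(out)
  r <- rle(l == 1L)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  if (!length(keep)) return(out)
  cbind(start = starts[keep] - 1L, end = ends[keep])
}
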