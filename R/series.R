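## Lightweight S3 containers for the time series moved through the pipeline.
## All series share: `times` (seconds, strictly increasing, uniformly spaced),
## `fps` (frames per second) and, where meaningful, `part` ("head"/"thorax").
## Angles are radians internally; angular velocities are deg/s; files store
## angles in degrees (see read/write functions).

check_times <- function(times, fps = NULL, tol = 1e-9) {
  if (length(times) >= 2L) {
    dt <- diff(times)
    if (any(dt <= 0)) stop("times must be strictly increasing", call. = FALSE)
    if (max(dt) - min(dt) > tol) stop("times must be uniformly spaced", call. = FALSE)
    if (is.null(fps)) fps <- 1 / stats::median(dt)
  }
  if (is.null(fps)) stop("fps must be given for series shorter than 2 samples",
                         call. = FALSE)
  fps
}

check_part <- function(part) {
  match.arg(part, c("head", "thorax"))
}

#' Marker position series for one body part
#'
#' Holds the three tracked marker positions (left, right, front) of a rigid
#' body part, one 3-D position per marker per frame, in meters.
#'
#' @param times numeric vector of frame times in seconds, strictly increasing
#'   and uniformly spaced.
#' @param left,right,front n x 3 matrices of marker positions (meters).
#' @param part `"head"` or `"thorax"`.
#' @param fps frames per second; inferred from `times` when omitted.
#' @return an object of class `marker_series`.
#' @export
marker_series <- function(times, left, right, front, part = "head", fps = NULL) {
  left <- as.matrix(left); right <- as.matrix(right); front <- as.matrix(front)
  n <- length(times)
  for (m in list(left, right, front)) {
    if (!is.numeric(m) || ncol(m) != 3L || nrow(m) != n)
      stop("left/right/front must be numeric n x 3 matrices matching times",
           call. = FALSE)
  }
  stopifnot_finite(cbind(left, right, front), "marker positions")
  fps <- check_times(times, fps)
  structure(list(times = as.numeric(times), fps = fps, part = check_part(part),
                 left = left, right = right, front = front),
            class = "marker_series")
}

#' Yaw-pitch-roll pose series for one body part
#'
#' @param times frame times in seconds (uniform).
#' @param yaw,pitch,roll numeric vectors of Euler angles in radians under the
#'   yaw-pitch-roll (ZYX) convention. Yaw is unwrapped on construction so it is
#'   continuous across +/-pi.
#' @param part `"head"` or `"thorax"`.
#' @param fps frames per second; inferred from `times` when omitted.
#' @return an object of class `pose_series`.
#' @export
pose_series <- function(times, yaw, pitch, roll, part = "head", fps = NULL) {
  n <- length(times)
  if (length(yaw) != n || length(pitch) != n || length(roll) != n)
    stop("yaw/pitch/roll must match the length of times", call. = FALSE)
  stopifnot_finite(c(yaw, pitch, roll), "pose angles")
  if (any(abs(pitch) > pi / 2 + 1e-9))
    stop("|pitch| must not exceed pi/2", call. = FALSE)
  fps <- check_times(times, fps)
  structure(list(times = as.numeric(times), fps = fps, part = check_part(part),
                 yaw = unwrap_angle(as.numeric(yaw)),
                 pitch = as.numeric(pitch), roll = as.numeric(roll)),
            class = "pose_series")
}

#' Body-frame z angular velocity series
#'
#' @param times frame times in seconds (uniform).
#' @param omega_z numeric vector, angular velocity about the body z-axis in
#'   deg/s.
#' @param part `"head"` or `"thorax"`.
#' @param fps frames per second; inferred from `times` when omitted.
#' @return an object of class `velocity_series`.
#' @export
velocity_series <- function(times, omega_z, part = "head", fps = NULL) {
  if (length(omega_z) != length(times))
    stop("omega_z must match the length of times", call. = FALSE)
  stopifnot_finite(omega_z, "omega_z")
  fps <- check_times(times, fps)
  structure(list(times = as.numeric(times), fps = fps, part = check_part(part),
                 omega_z = as.numeric(omega_z)),
            class = "velocity_series")
}

#' Binary saccade/intersaccade label series
#'
#' @param times frame times in seconds.
#' @param labels integer vector of 0 (intersaccade) / 1 (saccade) per frame.
#' @param fps frames per second; inferred from `times` when omitted.
#' @return an object of class `label_series`.
#' @export
label_series <- function(times, labels, fps = NULL) {
  if (length(labels) != length(times))
    stop("labels must match the length of times", call. = FALSE)
  labels <- as.integer(labels)
  if (length(labels) && !all(labels %in% c(0L, 1L)))
    stop("labels must be 0 or 1", call. = FALSE)
  fps <- check_times(times, fps)
  structure(list(times = as.numeric(times), fps = fps, labels = labels),
            class = "label_series")
}

series_length <- function(x) length(x$times)

## Subset a series to an index range, keeping class and metadata.
subset_series <- function(x, idx) {
  out <- x
  for (f in intersect(names(x), c("times", "yaw", "pitch", "roll",
                                  "omega_z", "labels"))) {
    out[[f]] <- x[[f]][idx]
  }
  for (f in intersect(names(x), c("left", "right", "front"))) {
    out[[f]] <- x[[f]][idx, , drop = FALSE]
  }
  out
}

#' @export
print.marker_series <- function(x, ...) {
  cat(sprintf("<marker_series: %s, %d frames @ %g fps>\n",
              x$part, series_length(x), x$fps))
  invisible(x)
}

#' @export
print.pose_series <- function(x, ...) {
  cat(sprintf("<pose_series: %s, %d frames @ %g fps, yaw range [%.1f, %.1f] deg>\n",
              x$part, series_length(x), x$fps,
              min(x$yaw) * RAD2DEG, max(x$yaw) * RAD2DEG))
  invisible(x)
}

#' @export
print.velocity_series <- function(x, ...) {
  cat(sprintf("<velocity_series: %s, %d frames @ %g fps, |omega_z| max %.0f deg/s>\n",
              x$part, series_length(x), x$fps, max(abs(x$omega_z))))
  invisible(x)
}

#' @export
print.label_series <- function(x, ...) {
  cat(sprintf("<label_series: %d frames, %d saccade frames (%.1f%%)>\n",
              series_length(x), sum(x$labels),
              if (series_length(x)) 100 * mean(x$labels) else 0))
  invisible(x)
}

#' @export
as.data.frame.pose_series <- function(x, ...) {
  data.frame(t = x$times, part = x$part, yaw_deg = x$yaw * RAD2DEG,
             pitch_deg = x$pitch * RAD2DEG, roll_deg = x$roll * RAD2DEG)
}

#' @export
as.data.frame.velocity_series <- function(x, ...) {
  data.frame(t = x$times, part = x$part, omega_z_degps = x$omega_z)
}

#' @export
as.data.frame.label_series <- function(x, ...) {
  data.frame(t = x$times, label = x$labels)
}

#' @export
as.data.frame.marker_series <- function(x, ...) {
  data.frame(t = x$times, part = x$part,
             lx = x$left[, 1], ly = x$left[, 2], lz = x$left[, 3],
             rx = x$right[, 1], ry = x$right[, 2], rz = x$right[, 3],
             fx = x$front[, 1], fy = x$front[, 2], fz = x$front[, 3])
}
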