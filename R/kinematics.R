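## Rigid-body orientation from three markers, Euler angle extraction,
## smoothing, differentiation to body-frame angular velocity, and emulation
## of degraded recordings (low frame rate, top-view-only).
##
## Conventions (used everywhere in the package):
##   * body axes: x forward, y left, z up (right-handed);
##   * y is the unit vector from the right marker to the left marker;
##   * body->world rotation R = Rz(yaw) %*% Ry(pitch) %*% Rx(roll);
##   * yaw is unwrapped before smoothing/interpolation/differentiation.

#' Body coordinate frame from three markers
#'
#' Builds the body-fixed coordinate system from one frame's (or a whole
#' series of) marker positions: the origin is the centroid of the three
#' markers, y is the unit vector from the right to the left marker, x is the
#' component of (front - origin) orthogonal to y, normalised, and z = x cross
#' y, so that z points up for a level animal.
#'
#' @param left,right,front 3-vectors (one frame) or n x 3 matrices of marker
#'   positions.
#' @return a list with `origin` (n x 3, or 3-vector for a single frame) and
#'   `R` (3 x 3 rotation for a single frame, n x 9 column-major stack
#'   otherwise; columns of each rotation are the body x, y, z axes in world
#'   coordinates).
#' @export
#' @examples
#' f <- body_frame_from_markers(c(0, 1, 0), c(0, -1, 0), c(3, 0, 0))
#' f$origin  # (1, 0, 0)
#' f$R       # identity
body_frame_from_markers <- function(left, right, front) {
  single <- is.null(dim(left))
  to_mat <- function(p) if (is.null(dim(p))) matrix(p, 1L, 3L) else as.matrix(p)
  left <- to_mat(left); right <- to_mat(right); front <- to_mat(front)
  origin <- (left + right + front) / 3

  yv <- left - right
  ny <- row_norm(yv)
  fo <- front - origin
  ## x: component of (front - origin) orthogonal to y
  bad <- ny < 1e-12
  yv <- yv / pmax(ny, 1e-300)
  xv <- fo - yv * rowSums(fo * yv)
  nx <- row_norm(xv)
  bad <- bad | nx < 1e-12
  if (any(bad))
    stop(sprintf("degenerate marker geometry (collinear or coincident markers) at frame %d",
                 which(bad)[1L]), call. = FALSE)
  xv <- xv / nx
  zv <- cross3(xv, yv)
  R <- cbind(xv, yv, zv)
  colnames(R) <- c("R11", "R21", "R31", "R12", "R22", "R32", "R13", "R23", "R33")
  if (single) list(origin = origin[1L, ], R = matrix(R[1L, ], 3, 3))
  else list(origin = origin, R = R)
}

#' Extract yaw, pitch and roll from a rotation matrix
#'
#' Decomposes a proper rotation under the yaw-pitch-roll (ZYX) convention,
#' i.e. finds angles with `Rz(yaw) %*% Ry(pitch) %*% Rx(roll) == R`. Pitch is
#' confined to `[-pi/2, pi/2]`. At gimbal lock (|pitch| within 1e-8 of pi/2)
#' roll is set to 0, yaw absorbs the remaining rotation, and a warning is
#' emitted.
#'
#' @param R a 3 x 3 rotation matrix, or an n x 9 column-major stack as
#'   returned by [body_frame_from_markers()].
#' @return a list with numeric vectors `yaw`, `pitch`, `roll` (radians).
#' @export
rotation_to_ypr <- function(R) {
  R <- as_rotmat_rows(R)
  r31 <- pmin(1, pmax(-1, R[, 3]))
  pitch <- -asin(r31)
  yaw <- atan2(R[, 2], R[, 1])
  roll <- atan2(R[, 6], R[, 9])
  lock <- abs(abs(r31) - 1) < 1e-8
  if (any(lock)) {
    warning(sprintf("gimbal lock (|pitch| ~ pi/2) at %d frame(s); roll set to 0",
                    sum(lock)))
    ## at lock cos(pitch) = 0: yaw and roll are not separable; put everything
    ## in yaw. Reconstructing Rz(yaw')Ry(+-pi/2) gives R12 = -sin(yaw'),
    ## R22 = cos(yaw') for either sign of pitch.
    yaw[lock] <- atan2(-R[lock, 4], R[lock, 5])
    roll[lock] <- 0
  }
  list(yaw = yaw, pitch = pitch, roll = roll)
}

#' Pose series from marker series
#'
#' Runs [body_frame_from_markers()] on every frame and converts the rotations
#' to yaw-pitch-roll, returning a [pose_series()] with unwrapped yaw.
#'
#' @param markers a [marker_series()].
#' @return a [pose_series()] for the same frames and part.
#' @export
pose_from_markers <- function(markers) {
  stopifnot(inherits(markers, "marker_series"))
  frame <- body_frame_from_markers(markers$left, markers$right, markers$front)
  ypr <- rotation_to_ypr(frame$R)
  pose_series(markers$times, ypr$yaw, ypr$pitch, ypr$roll,
              part = markers$part, fps = markers$fps)
}

#' Smooth a pose series with penalized cubic smoothing splines
#'
#' Each angle channel is replaced by a cubic smoothing spline evaluated at the
#' original times. The spline penalty is chosen so that the smoother's
#' effective degrees of freedom equals `lambda_df` (the search over the
#' penalty is performed by [stats::smooth.spline()]). Yaw is smoothed on its
#' unwrapped values. `lambda_df` equal to the number of samples is the exact
#' zero-penalty (interpolating) limit and returns the input unchanged.
#'
#' @param pose a [pose_series()] with at least 4 samples.
#' @param lambda_df target effective degrees of freedom, in `[2, n]`.
#'   Default 150.
#' @return a smoothed [pose_series()] on the same time grid.
#' @export
smooth_pose <- function(pose, lambda_df = 150) {
  stopifnot(inherits(pose, "pose_series"))
  n <- series_length(pose)
  if (n < 4L) stop("smooth_pose needs at least 4 samples", call. = FALSE)
  if (lambda_df < 2 || lambda_df > n)
    stop(sprintf("lambda_df must lie in [2, %d]", n), call. = FALSE)
  if (lambda_df >= n) return(pose)  # zero-penalty limit: identity at the samples
  sm <- function(y) {
    if (max(y) - min(y) < 1e-15) return(y)  # constant channel
    fit <- stats::smooth.spline(pose$times, y, df = lambda_df, all.knots = TRUE,
                                keep.data = FALSE)
    stats::predict(fit, pose$times)$y
  }
  pose_series(pose$times, sm(pose$yaw), sm(pose$pitch), sm(pose$roll),
              part = pose$part, fps = pose$fps)
}

#' Body-frame angular velocity about z
#'
#' Rebuilds the rotation matrix per frame from the pose, differentiates it by
#' central differences (one-sided at the endpoints), and returns the z
#' component of the body-frame angular velocity `Omega = unskew(t(R) %*%
#' dR/dt)` in deg/s. This is exact under nonzero pitch/roll and coincides with
#' the yaw rate when pitch = roll = 0.
#'
#' @param pose a [pose_series()] with at least 3 samples.
#' @return a [velocity_series()] on the same time grid.
#' @export
angular_velocity_z <- function(pose) {
  stopifnot(inherits(pose, "pose_series"))
  n <- series_length(pose)
  if (n < 3L) stop("angular_velocity_z needs at least 3 samples", call. = FALSE)
  R <- ypr_to_rotation(pose$yaw, pose$pitch, pose$roll)
  dt <- 1 / pose$fps
  ## dR/dt by central differences, one-sided at the ends
  dR <- matrix(0, n, 9L)
  dR[2:(n - 1), ] <- (R[3:n, ] - R[1:(n - 2), ]) / (2 * dt)
  dR[1L, ] <- (R[2L, ] - R[1L, ]) / dt
  dR[n, ] <- (R[n, ] - R[n - 1L, ]) / dt
  ## S = t(R) %*% dR; omega_z (body) = (S21 - S12) / 2
  ## S21 = col_y(R) . col_x(dR), S12 = col_x(R) . col_y(dR)
  s21 <- rowSums(R[, 4:6, drop = FALSE] * dR[, 1:3, drop = FALSE])
  s12 <- rowSums(R[, 1:3, drop = FALSE] * dR[, 4:6, drop = FALSE])
  omega_z <- (s21 - s12) / 2 * RAD2DEG
  velocity_series(pose$times, omega_z, part = pose$part, fps = pose$fps)
}

#' Emulate a lower frame rate by decimation and spline interpolation
#'
#' Decimates the pose by the integer stride nearest `fps / target_fps`, then
#' interpolates each (unwrapped) angle channel back onto the original time
#' grid with an interpolating cubic spline, emulating a recording made at
#' `target_fps` and upsampled for analysis. The output keeps the original
#' length and fps.
#'
#' @param pose a [pose_series()].
#' @param target_fps emulated frame rate, in `(0, fps]`. Non-integer
#'   `fps / target_fps` ratios are rounded to the nearest stride.
#' @return a [pose_series()] on the original time grid.
#' @export
resample_roundtrip <- function(pose, target_fps) {
  stopifnot(inherits(pose, "pose_series"))
  if (target_fps <= 0 || target_fps > pose$fps)
    stop("target_fps must lie in (0, fps]", call. = FALSE)
  stride <- max(1L, as.integer(round(pose$fps / target_fps)))
  if (stride == 1L) return(pose)
  n <- series_length(pose)
  keep <- seq(1L, n, by = stride)
  if (length(keep) < 4L)
    stop("target_fps too low: fewer than 4 samples retained", call. = FALSE)
  interp <- function(y) {
    stats::spline(pose$times[keep], y[keep], xout = pose$times,
                  method = "fmm")$y
  }
  pose_series(pose$times, interp(pose$yaw), interp(pose$pitch),
              interp(pose$roll), part = pose$part, fps = pose$fps)
}

## Same decimate-and-respline round trip applied to a velocity channel;
## used when emulating low-rate recordings of measured angular velocity.
resample_roundtrip_velocity <- function(v, target_fps) {
  stopifnot(inherits(v, "velocity_series"))
  if (target_fps <= 0 || target_fps > v$fps)
    stop("target_fps must lie in (0, fps]", call. = FALSE)
  stride <- max(1L, as.integer(round(v$fps / target_fps)))
  if (stride == 1L) return(v)
  keep <- seq(1L, series_length(v), by = stride)
  om <- stats::spline(v$times[keep], v$omega_z[keep], xout = v$times,
                      method = "fmm")$y
  velocity_series(v$times, om, part = v$part, fps = v$fps)
}

#' Emulate a top-view-only recording
#'
#' Replaces, per frame, the z-coordinates of all three markers by their mean,
#' mimicking a recording in which only the horizontal marker positions are
#' known. Downstream pose reconstruction then yields pitch = roll = 0 exactly,
#' while yaw is unaffected. Idempotent.
#'
#' @param markers a [marker_series()].
#' @return a [marker_series()] with coplanar-horizontal markers per frame.
#' @export
flatten_to_topview <- function(markers) {
  stopifnot(inherits(markers, "marker_series"))
  zbar <- (markers$left[, 3] + markers$right[, 3] + markers$front[, 3]) / 3
  out <- markers
  out$left[, 3] <- zbar
  out$right[, 3] <- zbar
  out$front[, 3] <- zbar
  out
}
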