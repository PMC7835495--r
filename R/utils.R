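#' @keywords internal
"_PACKAGE"

DEG2RAD <- pi / 180
RAD2DEG <- 180 / pi

## Run `code` under a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Unwrap a phase angle sequence
#'
#' Removes jumps larger than pi between consecutive samples by adding
#' multiples of 2*pi, making the sequence continuous across the +/-pi branch
#' cut. Used on yaw before smoothing, interpolation or differentiation.
#'
#' @param theta numeric vector of angles in radians.
#' @return numeric vector of the same length, continuous (no step exceeds pi).
#' @export
#' @examples
#' unwrap_angle(c(3.1, -3.1, -3.0))  # increases past pi instead of jumping
unwrap_angle <- function(theta) {
  if (length(theta) < 2L) return(theta)
  d <- diff(theta)
  jumps <- -2 * pi * cumsum(round(d / (2 * pi)))
  theta + c(0, jumps)
}

## Elementary rotations (body -> world), 3 x 3.
rot_x <- function(a) {
  c_ <- cos(a); s <- sin(a)
  matrix(c(1, 0, 0, 0, c_, s, 0, -s, c_), 3, 3)
}
rot_y <- function(a) {
  c_ <- cos(a); s <- sin(a)
  matrix(c(c_, 0, -s, 0, 1, 0, s, 0, c_), 3, 3)
}
rot_z <- function(a) {
  c_ <- cos(a); s <- sin(a)
  matrix(c(c_, s, 0, -s, c_, 0, 0, 0, 1), 3, 3)
}

#' Compose a rotation matrix from yaw, pitch and roll
#'
#' Uses the yaw-pitch-roll (ZYX) convention throughout the package:
#' `R = Rz(yaw) %*% Ry(pitch) %*% Rx(roll)` maps body coordinates to world
#' coordinates. Vectorised: given n angles it returns an n x 9 matrix whose
#' rows are rotation matrices stored column-major (R11, R21, R31, R12, ...).
#'
#' @param yaw,pitch,roll numeric vectors of angles in radians (recycled to a
#'   common length).
#' @return if the inputs have length 1, a 3 x 3 rotation matrix; otherwise an
#'   n x 9 matrix of column-major flattened rotations.
#' @export
ypr_to_rotation <- function(yaw, pitch, roll) {
  n <- max(length(yaw), length(pitch), length(roll))
  yaw <- rep_len(yaw, n); pitch <- rep_len(pitch, n); roll <- rep_len(roll, n)
  cy <- cos(yaw); sy <- sin(yaw)
  cp <- cos(pitch); sp <- sin(pitch)
  cr <- cos(roll); sr <- sin(roll)
  R <- cbind(
    cy * cp,                 sy * cp,                -sp,       # column x
    cy * sp * sr - sy * cr,  sy * sp * sr + cy * cr,  cp * sr,  # column y
    cy * sp * cr + sy * sr,  sy * sp * cr - cy * sr,  cp * cr   # column z
  )
  colnames(R) <- c("R11", "R21", "R31", "R12", "R22", "R32", "R13", "R23", "R33")
  if (n == 1L) matrix(R, 3, 3) else R
}

## Coerce a single 3x3 matrix or an n x 9 row-flattened stack to n x 9.
as_rotmat_rows <- function(R) {
  if (is.matrix(R) && ncol(R) == 3L && nrow(R) == 3L) {
    matrix(as.numeric(R), 1L, 9L)
  } else if (is.matrix(R) && ncol(R) == 9L) {
    R
  } else {
    stop("expected a 3x3 rotation matrix or an n x 9 stack of rotations")
  }
}

## Row-wise cross product of n x 3 matrices.
cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

row_norm <- function(a) sqrt(rowSums(a * a))

stopifnot_finite <- function(x, what) {
  if (!all(is.finite(x))) stop(sprintf("non-finite values in %s", what), call. = FALSE)
}
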