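## Synthetic head/thorax flights with known ground truth: saccadic yaw
## velocity built from Gaussian pulses (head pulses narrow and fast, thorax
## pulses starting earlier, broader and lower-peaked, with equal angular
## integral), Ornstein-Uhlenbeck measurement noise, optional pitch/roll
## oscillation, and rigid equilateral-triangle marker geometry - so every
## analysis stage can be validated without the original recordings.

#' Configuration of a synthetic flight
#'
#' Defaults emulate a convoluted saccadic learning flight: ~4 saccade events
#' per second with a 100 ms refractory period, head velocity pulses of 12 ms
#' Gaussian width (saccades lasting several tens of ms whose peaks comfortably
#' exceed the 372.42 deg/s seed threshold), thorax pulses of the same angular
#' integral but starting 8 ms earlier and 1.5x broader (hence lower-peaked),
#' and coloured measurement noise (OU, 20 ms correlation time) of 30 deg/s SD
#' on the head and 80 deg/s on the thorax, the thorax trace being the less
#' cleanly segmented one.
#'
#' @param duration flight duration in seconds (default 10).
#' @param fps frame rate (default 500).
#' @param saccade_rate mean saccade events per second (default 4). Must be
#'   below `1000 / refractory_ms`.
#' @param refractory_ms minimum gap between events (default 100); must exceed
#'   four head pulse widths.
#' @param amplitude_deg range of saccade amplitudes in degrees; each event
#'   draws its magnitude uniformly from this range with a random sign
#'   (default `c(20, 60)`).
#' @param head_pulse_sd_ms Gaussian SD of the head velocity pulse in ms
#'   (default 12).
#' @param thorax_lead_ms the thorax pulse center precedes the head pulse by
#'   this many ms (default 8; negative values make the head lead).
#' @param thorax_width_factor thorax pulse width relative to the head pulse
#'   (default 1.5, > 1 means broader and lower-peaked at equal integral).
#' @param noise_sd_head,noise_sd_thorax stationary SD of the OU measurement
#'   noise, deg/s (defaults 30 and 80).
#' @param noise_tc_ms correlation time of the OU noise (default 20 ms).
#' @param pitch_roll_amplitude_deg amplitude of a slow sinusoidal pitch and
#'   roll oscillation (default 0 = level flight).
#' @param marker_side side length of the equilateral marker triangle in meters
#'   (default 0.005).
#' @param seed run seed; the flight is bitwise reproducible from it.
#' @return an object of class `flight_config`.
#' @export
flight_config <- function(duration = 10, fps = 500, saccade_rate = 4,
                          refractory_ms = 100, amplitude_deg = c(20, 60),
                          head_pulse_sd_ms = 12, thorax_lead_ms = 8,
                          thorax_width_factor = 1.5, noise_sd_head = 30,
                          noise_sd_thorax = 80, noise_tc_ms = 20,
                          pitch_roll_amplitude_deg = 0, marker_side = 0.005,
                          seed = 1L) {
  if (duration <= 0 || fps <= 0) stop("duration and fps must be positive",
                                      call. = FALSE)
  if (saccade_rate < 0) stop("saccade_rate must be >= 0", call. = FALSE)
  if (refractory_ms <= 4 * head_pulse_sd_ms)
    stop("refractory_ms must exceed 4 * head_pulse_sd_ms", call. = FALSE)
  if (saccade_rate > 0 && 1 / saccade_rate <= refractory_ms / 1000)
    stop("infeasible: saccade_rate too high for the refractory period",
         call. = FALSE)
  if (thorax_width_factor <= 1)
    stop("thorax_width_factor must be > 1", call. = FALSE)
  if (marker_side <= 0) stop("marker_side must be positive", call. = FALSE)
  if (abs(pitch_roll_amplitude_deg) >= 80)
    stop("pitch_roll_amplitude_deg must be below 80", call. = FALSE)
  structure(as.list(environment()), class = "flight_config")
}

## Ornstein-Uhlenbeck noise with stationary SD `sd` and correlation time `tc`.
ou_noise <- function(n, dt, sd, tc) {
  if (sd <= 0) return(numeric(n))
  a <- exp(-dt / tc)
  innov <- stats::rnorm(n, 0, sd * sqrt(1 - a * a))
  x <- numeric(n)
  x[1L] <- stats::rnorm(1L, 0, sd)
  for (i in seq_len(n - 1L)) x[i + 1L] <- a * x[i] + innov[i + 1L]
  x
}

#' Generate a synthetic coupled head/thorax flight
#'
#' Event times follow a renewal process (refractory period plus an exponential
#' gap matching the requested mean rate). Each event adds to the head yaw
#' velocity a Gaussian pulse whose time integral equals the event amplitude,
#' and to the thorax a pulse of equal integral, centered `thorax_lead_ms`
#' earlier and `thorax_width_factor` broader. Yaw is the exact integral of the
#' noise-free pulse train; OU noise is added to the measured velocity series
#' only. Ground-truth labels are the two-threshold segmentation (package
#' default thresholds) of the noise-free head velocity.
#'
#' The stored pose and velocity series are computed through the same pipeline
#' an analysis of real markers would use: markers are laid out from the
#' generating pose, the pose is reconstructed from the markers, and the
#' angular velocity is differentiated from the reconstructed pose (plus the
#' measurement noise), so [degrade()] at the native rate is an exact identity.
#'
#' @param cfg a [flight_config()].
#' @return an object of class `synthetic_flight` with marker, pose, velocity
#'   and label series for both parts, the event table, and the noise-free
#'   velocity signals (`omega_true_head`, `omega_true_thorax`).
#' @export
generate_flight <- function(cfg = flight_config()) {
  stopifnot(inherits(cfg, "flight_config"))
  n <- round(cfg$duration * cfg$fps)
  dt <- 1 / cfg$fps
  times <- seq.int(0L, n - 1L) * dt
  sd_h <- cfg$head_pulse_sd_ms / 1000
  sd_t <- sd_h * cfg$thorax_width_factor
  lead <- cfg$thorax_lead_ms / 1000
  margin <- 6 * sd_t + abs(lead)

  gen <- with_seed(cfg$seed, {
    ## renewal event times with refractory period
    ev_t <- numeric(0)
    if (cfg$saccade_rate > 0) {
      mean_exp <- 1 / cfg$saccade_rate - cfg$refractory_ms / 1000
      t_cur <- margin + stats::rexp(1L, 1 / mean_exp)
      while (t_cur < cfg$duration - margin) {
        ev_t <- c(ev_t, t_cur)
        t_cur <- t_cur + cfg$refractory_ms / 1000 + stats::rexp(1L, 1 / mean_exp)
      }
    }
    amp <- if (length(ev_t)) {
      sample(c(-1, 1), length(ev_t), replace = TRUE) *
        stats::runif(length(ev_t), min(cfg$amplitude_deg), max(cfg$amplitude_deg))
    } else numeric(0)
    list(events = data.frame(time = ev_t, amplitude = amp),
         noise_head = ou_noise(n, dt, cfg$noise_sd_head, cfg$noise_tc_ms / 1000),
         noise_thorax = ou_noise(n, dt, cfg$noise_sd_thorax, cfg$noise_tc_ms / 1000))
  })
  events <- gen$events

  pulse_train <- function(centers, sds) {
    om <- numeric(n); yaw <- numeric(n)
    for (i in seq_len(nrow(events))) {
      om <- om + events$amplitude[i] * stats::dnorm(times, centers[i], sds)
      yaw <- yaw + events$amplitude[i] * stats::pnorm(times, centers[i], sds)
    }
    list(omega = om, yaw_deg = yaw)
  }
  head_sig <- pulse_train(events$time, sd_h)
  thorax_sig <- pulse_train(events$time - lead, sd_t)

  ## slow pitch/roll oscillation (zero by default)
  pr_amp <- cfg$pitch_roll_amplitude_deg * DEG2RAD
  pitch <- pr_amp * sin(2 * pi * 1.3 * times)
  roll <- pr_amp * sin(2 * pi * 0.9 * times + 1)

  ## gentle 3-D drift of the animal through the tracking volume
  origin <- cbind(0.05 * cos(2 * pi * 0.1 * times),
                  0.05 * sin(2 * pi * 0.1 * times),
                  0.10 + 0.02 * sin(2 * pi * 0.25 * times))

  build_part <- function(part, sig, noise, origin_offset) {
    raw_pose <- pose_series(times, sig$yaw_deg * DEG2RAD, pitch, roll,
                            part = part, fps = cfg$fps)
    markers <- markers_from_pose(raw_pose, side = cfg$marker_side,
                                 origin = sweep(origin, 2L,
                                                origin_offset, `+`))
    pose <- pose_from_markers(markers)
    v <- angular_velocity_z(pose)
    v$omega_z <- v$omega_z + noise
    list(markers = markers, pose = pose, v = v)
  }
  head <- build_part("head", head_sig, gen$noise_head, c(0.004, 0, 0.001))
  thorax <- build_part("thorax", thorax_sig, gen$noise_thorax, c(0, 0, 0))

  true_labels <- two_threshold_segment(
    velocity_series(times, head_sig$omega, part = "head", fps = cfg$fps))

  structure(list(times = times, fps = cfg$fps, config = cfg, events = events,
                 head_markers = head$markers, thorax_markers = thorax$markers,
                 head_pose = head$pose, thorax_pose = thorax$pose,
                 head_v = head$v, thorax_v = thorax$v,
                 noise_head = gen$noise_head, noise_thorax = gen$noise_thorax,
                 omega_true_head = head_sig$omega,
                 omega_true_thorax = thorax_sig$omega,
                 true_labels = true_labels,
                 fps_emulated = cfg$fps, topview = FALSE),
            class = "synthetic_flight")
}

#' @export
print.synthetic_flight <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_flight: %.1f s @ %g fps, %d saccade events, ",
                     "%.1f%% saccade frames%s%s>\n"),
              x$config$duration, x$fps, nrow(x$events),
              100 * mean(x$true_labels$labels),
              if (x$fps_emulated < x$fps)
                sprintf(", emulated @ %g fps", x$fps_emulated) else "",
              if (x$topview) ", top view" else ""))
  invisible(x)
}

#' Marker positions from a pose series
#'
#' Lays out the canonical equilateral marker triangle (front marker on +x,
#' left/right markers symmetric about the x-axis, centroid at the body
#' origin), rotates it by `Rz(yaw) Ry(pitch) Rx(roll)` per frame and
#' translates it along an origin path.
#'
#' @param pose a [pose_series()].
#' @param side marker triangle side length in meters (default 0.005).
#' @param origin optional n x 3 matrix of body origin positions per frame
#'   (meters); defaults to the world origin.
#' @return a [marker_series()].
#' @export
markers_from_pose <- function(pose, side = 0.005, origin = NULL) {
  stopifnot(inherits(pose, "pose_series"))
  n <- series_length(pose)
  if (is.null(origin)) origin <- matrix(0, n, 3L)
  origin <- as.matrix(origin)
  stopifnot(nrow(origin) == n, ncol(origin) == 3L)
  d <- side / sqrt(3)  # centroid-to-vertex distance of an equilateral triangle
  canon <- list(front = c(d, 0, 0),
                left = c(-d / 2, side / 2, 0),
                right = c(-d / 2, -side / 2, 0))
  R <- ypr_to_rotation(pose$yaw, pose$pitch, pose$roll)
  R <- as_rotmat_rows(R)
  place <- function(p) {
    cbind(R[, 1] * p[1] + R[, 4] * p[2] + R[, 7] * p[3],
          R[, 2] * p[1] + R[, 5] * p[2] + R[, 8] * p[3],
          R[, 3] * p[1] + R[, 6] * p[2] + R[, 9] * p[3]) + origin
  }
  marker_series(pose$times, left = place(canon$left),
                right = place(canon$right), front = place(canon$front),
                part = pose$part, fps = pose$fps)
}

#' Degrade a synthetic flight (lower frame rate, top view)
#'
#' Re-runs the marker-to-velocity pipeline under degraded recording
#' conditions: optionally flattens the markers to a top view
#' ([flatten_to_topview()]), reconstructs the poses, applies the
#' decimate-and-respline round trip ([resample_roundtrip()]) at `fps_target`,
#' and re-derives the measured angular velocities (the stored OU measurement
#' noise is round-tripped through the same decimation). Ground-truth labels
#' are kept on the original full-rate grid. At the native rate with
#' `topview = FALSE` this is an exact identity.
#'
#' @param flight a [generate_flight()] object.
#' @param fps_target emulated frame rate in `(0, fps]` (default: native rate).
#' @param topview apply the null-pitch/roll (top-view) assumption first.
#' @return a new `synthetic_flight` with degraded series.
#' @export
degrade <- function(flight, fps_target = flight$fps, topview = FALSE) {
  stopifnot(inherits(flight, "synthetic_flight"))
  if (fps_target <= 0 || fps_target > flight$fps)
    stop("fps_target must lie in (0, fps]", call. = FALSE)
  out <- flight
  redo_part <- function(markers, noise) {
    if (topview) markers <- flatten_to_topview(markers)
    pose <- pose_from_markers(markers)
    if (fps_target < flight$fps) pose <- resample_roundtrip(pose, fps_target)
    v <- angular_velocity_z(pose)
    nz <- velocity_series(flight$times, noise, part = markers$part,
                          fps = flight$fps)
    if (fps_target < flight$fps)
      nz <- resample_roundtrip_velocity(nz, fps_target)
    v$omega_z <- v$omega_z + nz$omega_z
    list(markers = markers, pose = pose, v = v)
  }
  h <- redo_part(flight$head_markers, flight$noise_head)
  t_ <- redo_part(flight$thorax_markers, flight$noise_thorax)
  out$head_markers <- h$markers; out$head_pose <- h$pose; out$head_v <- h$v
  out$thorax_markers <- t_$markers; out$thorax_pose <- t_$pose
  out$thorax_v <- t_$v
  out$fps_emulated <- fps_target
  out$topview <- topview
  out
}
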