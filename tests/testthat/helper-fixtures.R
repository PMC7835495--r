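## Shared fixtures and independent oracles used across test files.

## Brute-force hysteresis oracle: mark seed frames, then repeat one-step
## neighbour expansion over frames above the low threshold until a fixpoint.
## Deliberately independent of the package's run-based implementation.
oracle_hysteresis <- function(x, high, low) {
  lab <- abs(x) > high
  pass <- abs(x) > low
  repeat {
    neigh <- c(FALSE, lab[-length(lab)]) | c(lab[-1L], FALSE)
    grown <- lab | (pass & neigh)
    if (identical(grown, lab)) break
    lab <- grown
  }
  as.integer(lab)
}

## Independent ZYX composition for the Euler decomposition oracle.
oracle_ypr_matrix <- function(yaw, pitch, roll) {
  rz <- matrix(c(cos(yaw), sin(yaw), 0, -sin(yaw), cos(yaw), 0, 0, 0, 1), 3, 3)
  ry <- matrix(c(cos(pitch), 0, -sin(pitch), 0, 1, 0, sin(pitch), 0, cos(pitch)), 3, 3)
  rx <- matrix(c(1, 0, 0, 0, cos(roll), sin(roll), 0, -sin(roll), cos(roll)), 3, 3)
  rz %*% ry %*% rx
}

## Independent per-unit forward pass for the network oracle.
oracle_mlp_forward <- function(w, x) {
  h <- numeric(ncol(w$W1))
  for (j in seq_along(h)) h[j] <- max(sum(x * w$W1[, j]) + w$b1[j], 0)
  o <- numeric(2L)
  for (k in 1:2) o[k] <- tanh(sum(h * w$W2[, k]) + w$b2[k])
  o
}

## A batch of synthetic flights with distinct seeds.
make_flights <- function(n, seed, duration = 6, ...) {
  lapply(seq_len(n), function(i)
    generate_flight(flight_config(duration = duration, seed = seed * 100 + i, ...)))
}

## Classifier-ready (v, labels) view of a flight list.
as_clf_flights <- function(flights) {
  lapply(flights, function(f) list(v = f$thorax_v, labels = f$true_labels))
}

## (source, target) mapper pairs from a flight list.
as_mapper_pairs <- function(flights, source = "head_v", target = "thorax_v") {
  lapply(flights, function(f) list(source = f[[source]], target = f[[target]]))
}

## Constant-length pose series on a uniform grid, handy for small fixtures.
simple_pose <- function(yaw, pitch = 0 * yaw, roll = 0 * yaw, fps = 500,
                        part = "head") {
  n <- length(yaw)
  pose_series(seq.int(0L, n - 1L) / fps, yaw, pitch, roll, part = part, fps = fps)
}
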