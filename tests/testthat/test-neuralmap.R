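test_that("velocity encoding and decoding invert each other", {
  scale <- pi / 180 / 500
  expect_equal(unname(encode_velocity(0, scale)[1, ]), c(1, 0))
  theta90 <- (pi / 2) / scale
  expect_equal(unname(encode_velocity(theta90, scale)[1, ]), c(0, 1),
               tolerance = 1e-12)
  expect_equal(decode_velocity(1, 0, scale = scale), 0)
  expect_equal(decode_velocity(0, -1, scale = scale), (-pi / 2) / scale)
  expect_equal(decode_velocity(0.5, 0, scale = scale),
               decode_velocity(1, 0, scale = scale))

  set.seed(1)
  omega <- runif(1000, -0.9 * pi, 0.9 * pi) / scale
  enc <- encode_velocity(omega, scale)
  expect_equal(decode_velocity(enc, scale = scale), omega, tolerance = 1e-9)

  expect_error(encode_velocity(pi / scale, scale), "frame 1")
  expect_error(decode_velocity(0, 0, scale = scale), "zero direction")
})

test_that("mlp_forward matches an independently coded per-unit oracle", {
  w0 <- list(W1 = matrix(0, 5, 3), b1 = rep(0, 3),
             W2 = matrix(0, 3, 2), b2 = c(0, 0))
  expect_equal(unname(mlp_forward(w0, rep(1, 5))), c(0, 0))
  wb <- w0; wb$b2 <- c(0.7, -0.3)
  expect_equal(unname(mlp_forward(wb, rnorm(5))), tanh(c(0.7, -0.3)))

  set.seed(33)
  for (i in 1:20) {
    n_in <- sample(1:9, 1); n_h <- sample(1:8, 1)
    w <- list(W1 = matrix(rnorm(n_in * n_h), n_in, n_h), b1 = rnorm(n_h),
              W2 = matrix(rnorm(n_h * 2), n_h, 2), b2 = rnorm(2))
    x <- rnorm(n_in)
    expect_equal(unname(mlp_forward(w, x)), oracle_mlp_forward(w, x),
                 tolerance = 1e-9)
  }
  expect_error(mlp_forward(w0, rep(1, 4)), "expects 5")
})

test_that("the anti-identity loss evaluates hand-computed cases exactly", {
  ## outputs reproduce the target: zero numerator
  h <- encode_velocity(c(100, -50, 0), 1e-3)
  s <- encode_velocity(c(80, -60, 10), 1e-3)
  expect_equal(mapper_loss(h, s, h), 0)

  ## outputs reproduce the source: denominator collapses to epsilon
  d <- sum((h[1, ] - s[1, ])^2)
  expect_equal(mapper_loss(h[1, , drop = FALSE], s[1, , drop = FALSE],
                           s[1, , drop = FALSE]), d / 0.1)

  ## right-angle case: |(0,1)-(1,0)|^2 / (0.5*0 + 0.1) = 20
  head_enc <- matrix(c(0, 1), 1)   # theta = pi/2
  thorax_enc <- matrix(c(1, 0), 1) # theta = 0
  expect_equal(mapper_loss(head_enc, thorax_enc, matrix(c(1, 0), 1)), 20)

  expect_error(mapper_loss(h, s, h, epsilon = 0), "epsilon")
  expect_error(mapper_loss(h, s[1:2, ], h), "batch")
  ## non-negative on random batches, and maximal at the identity solution
  set.seed(2)
  for (i in 1:20) {
    he <- encode_velocity(runif(10, -500, 500), 1e-3)
    se <- encode_velocity(runif(10, -500, 500), 1e-3)
    O <- encode_velocity(runif(10, -500, 500), 1e-3)
    expect_gte(mapper_loss(he, se, O), 0)
    expect_equal(mapper_loss(he, se, se),
                 sum(rowSums((he - se)^2)) / 0.1)
  }
})

test_that("shift_pairs aligns windows and targets across temporal shifts", {
  fps <- 500
  n <- 60
  src <- velocity_series(seq_len(n) / fps, rnorm(n), fps = fps)
  tgt <- velocity_series(seq_len(n) / fps, seq_len(n), fps = fps)  # ramp
  spec <- window_spec(8, fps)  # half-width 2

  p0 <- shift_pairs(src, tgt, 0, spec)
  ds <- build_windows(src, NULL, spec)
  expect_equal(p0$X, ds$X)
  expect_equal(p0$target_omega, tgt$omega_z[ds$frame_index])

  ## +2 samples = +4 ms backcast: the predicted instant trails the window
  ## center by 2 frames, so on the ramp the target column is advanced 2 steps
  p2 <- shift_pairs(src, tgt, 4, spec)
  expect_equal(p2$target_omega, as.numeric(p2$frame_index))
  expect_equal(p2$frame_index[1], 1L)
  expect_equal(p2$target_omega, p0$target_omega[seq_along(p2$target_omega)] - 2)

  ## counting oracle: pairs = L - window span - |tau samples|
  set.seed(14)
  for (i in 1:30) {
    L <- sample(20:80, 1)
    s2 <- velocity_series(seq_len(L) / fps, rnorm(L), fps = fps)
    tau <- sample(seq(-10, 10, by = 2), 1)
    h <- sample(0:4, 1)
    sp <- window_spec(h * 2 * 1000 / fps, fps)
    got <- shift_pairs(s2, s2, tau, sp)
    expect_equal(nrow(got$X), L - (sp$n_samples - 1L) - abs(tau * fps / 1000))
  }
  expect_error(shift_pairs(src, tgt, 3, spec), "whole number")
  expect_warning(empty <- shift_pairs(
    velocity_series(1:5 / fps, rnorm(5), fps = fps),
    velocity_series(1:5 / fps, rnorm(5), fps = fps), 20, spec), "no supported")
  expect_equal(nrow(empty$X), 0L)
})

test_that("training descends the loss and is bit-reproducible", {
  fl <- generate_flight(flight_config(duration = 4, seed = 51))
  cfg <- mapper_config(n_hidden = 4, delta_t_ms = 9, epochs = 5, seed = 12)
  m1 <- train_mapper(fl$thorax_v, fl$head_v, cfg)
  expect_lt(m1$loss_history[5], m1$loss_history[1])
  m2 <- train_mapper(fl$thorax_v, fl$head_v, cfg)
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$loss_history, m2$loss_history)
})

test_that("a scaled copy of the source is learned better than any constant output", {
  fps <- 500
  with_cfg <- function(seed) {
    set.seed(seed)
    n <- 3000
    src <- 400 * sin(2 * pi * 3 * seq_len(n) / fps) + rnorm(n, 0, 60)
    tgt <- 0.8 * src + rnorm(n, 0, 20)
    list(source = velocity_series(seq_len(n) / fps, src, fps = fps),
         target = velocity_series(seq_len(n) / fps, tgt, fps = fps))
  }
  tr <- with_cfg(1); va <- with_cfg(2)
  ## encode near full range so the angular loss is well conditioned
  cfg <- mapper_config(n_hidden = 8, delta_t_ms = 9, epochs = 30, seed = 3,
                       velocity_scale = pi / 1000)
  m <- train_mapper(tr$source, tr$target, cfg)
  ev <- evaluate_mapper(m, va$source, va$target)

  ## best constant predictor: scan candidate constant angles
  pr <- shift_pairs(va$source, va$target, 0, cfg$spec)
  t_enc <- encode_velocity(pr$target_omega, cfg$velocity_scale)
  const_med <- vapply(seq(-0.2, 0.2, length.out = 401), function(th)
    median(unsigned_error_angle(matrix(rep(c(cos(th), sin(th)),
                                           each = nrow(t_enc)), ncol = 2),
                                t_enc)), 0)
  expect_lt(ev$median_error_angle, min(const_med))
  expect_gt(ev$r, 0.8)
})

test_that("independent white-noise source and target stay uncorrelated", {
  fps <- 500
  rs <- vapply(1:5, function(seed) {
    set.seed(seed * 17)
    n <- 2500
    src <- velocity_series(seq_len(n) / fps, rnorm(n, 0, 200), fps = fps)
    tgt <- velocity_series(seq_len(n) / fps, rnorm(n, 0, 200), fps = fps)
    va_s <- velocity_series(seq_len(n) / fps, rnorm(n, 0, 200), fps = fps)
    va_t <- velocity_series(seq_len(n) / fps, rnorm(n, 0, 200), fps = fps)
    cfg <- mapper_config(n_hidden = 4, delta_t_ms = 5, epochs = 10, seed = seed)
    m <- train_mapper(src, tgt, cfg)
    evaluate_mapper(m, va_s, va_t)$r
  }, 0)
  expect_true(all(abs(rs) < 0.1))
})

test_that("unsigned error angle is the absolute angle between encodings", {
  e <- encode_velocity(c(100, 200), 1e-3)
  expect_equal(unsigned_error_angle(e, e), c(0, 0))
  expect_equal(unsigned_error_angle(c(1, 0), c(-1, 0)), pi)
  expect_equal(unsigned_error_angle(c(1, 0), c(0, 1)), pi / 2)
  ## insensitive to vector norms, always within [0, pi]
  set.seed(4)
  a <- matrix(rnorm(40), ncol = 2); b <- matrix(rnorm(40), ncol = 2)
  ang <- unsigned_error_angle(a, b)
  expect_true(all(ang >= 0 & ang <= pi))
  expect_equal(unsigned_error_angle(2 * a, 0.5 * b), ang)
  expect_error(unsigned_error_angle(c(0, 0), c(1, 0)), "zero")
})

test_that("mapper grid search prefers windows wide enough for the coupling", {
  ## target depends on the source 2 samples (4 ms) back: a 9 ms window can
  ## see it, a 1 ms (single-sample) window cannot
  fps <- 500
  mk <- function(seed) {
    set.seed(seed)
    n <- 2500
    src <- 400 * sin(2 * pi * 3 * seq_len(n) / fps) + rnorm(n, 0, 80)
    tgt <- c(rep(0, 2), 0.8 * src[1:(n - 2)]) + rnorm(n, 0, 20)
    list(source = velocity_series(seq_len(n) / fps, src, fps = fps),
         target = velocity_series(seq_len(n) / fps, tgt, fps = fps))
  }
  pairs <- list(mk(5), mk(6))
  cfg <- mapper_config(n_hidden = 8, epochs = 12, seed = 2)
  gs <- grid_search_mapper(pairs, n_grid = 8, delta_t_grid = c(1, 9),
                           config = cfg)
  expect_equal(nrow(gs$table), 2L)
  med9 <- gs$table$median_error_angle[gs$table$delta_t_ms == 9]
  med1 <- gs$table$median_error_angle[gs$table$delta_t_ms == 1]
  expect_lte(med9, med1)
  expect_equal(gs$config$delta_t_ms, 9)
  expect_error(grid_search_mapper(pairs, n_grid = integer(0)), "non-empty")
})

test_that("the identity task is learnable when the anti-identity term is off", {
  fl <- generate_flight(flight_config(duration = 5, seed = 61))
  fl2 <- generate_flight(flight_config(duration = 5, seed = 62))
  pairs <- list(list(source = fl$head_v, target = fl$head_v),
                list(source = fl2$head_v, target = fl2$head_v))
  cfg <- mapper_config(n_hidden = 8, delta_t_ms = 9, seed = 7, lambda_reg = 0)
  curve <- correlation_vs_shift(pairs, tau_grid_ms = 0, cfg)
  expect_gt(curve$r[1], 0.99)
})
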