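## Feed-forward network mapping one body part's angular-velocity window to
## another's sine/cosine-encoded angular velocity, trained with an
## anti-identity loss that penalises reproducing the source signal, and a
## temporal-shift (forecast/backcast) scan of predictive causality.
##
## The network: input (n_samples velocity samples + bias) -> N relu hidden
## units (+ constant bias unit) -> 2 tanh outputs (O_c, O_s).
##
## The loss, summed over frames t of a batch:
##     L = sum_t |enc_target(t) - O(t)|^2 /
##               (lambda * |enc_source(t) - O(t)|^2 + epsilon)
## The denominator makes the loss large when the network merely reproduces
## the source (the "identity" solution), with lambda = 0.5 and epsilon = 0.1.

#' Configuration for the velocity mapper network
#'
#' @param n_hidden number of relu hidden units N (the layer additionally
#'   carries one constant bias unit). The canonical search grid is
#'   `2^(0:7)`.
#' @param delta_t_ms observation window width in ms (canonical grid
#'   `seq(1, 53, by = 2)`).
#' @param fps frame rate of the velocity series.
#' @param tau_ms temporal shift in ms between the window center and the
#'   predicted instant: negative = forecasting (the prediction lies after the
#'   observations), positive = backcasting. Must be a whole number of samples
#'   at `fps`.
#' @param lambda_reg anti-identity regularization weight (default 0.5).
#' @param epsilon denominator guard, must be > 0 (default 0.1).
#' @param epochs training epochs (default 30).
#' @param seed run seed controlling weight initialisation and minibatch
#'   shuffling.
#' @param velocity_scale radians-per-(deg/s) conversion used by the sine/cosine
#'   encoding. Default `pi/180/fps`: the encoded angle is the rotation in
#'   radians per sample interval, which keeps even extreme insect saccade
#'   velocities well inside (-pi, pi).
#' @param learning_rate,batch_size Adam step size (default 1e-3) and minibatch
#'   size (default 64).
#' @return an object of class `mapper_config`.
#' @export
mapper_config <- function(n_hidden = 32L, delta_t_ms = 29, fps = 500,
                          tau_ms = 0, lambda_reg = 0.5, epsilon = 0.1,
                          epochs = 30L, seed = 1L, velocity_scale = NULL,
                          learning_rate = 1e-3, batch_size = 64L) {
  if (epsilon <= 0) stop("epsilon must be > 0", call. = FALSE)
  if (epochs < 1L) stop("epochs must be >= 1", call. = FALSE)
  if (n_hidden < 1L) stop("n_hidden must be >= 1", call. = FALSE)
  tau_samples <- tau_ms * fps / 1000
  if (abs(tau_samples - round(tau_samples)) > 1e-9)
    stop(sprintf("tau_ms = %g is not a whole number of samples at %g fps",
                 tau_ms, fps), call. = FALSE)
  if (is.null(velocity_scale)) velocity_scale <- pi / 180 / fps
  structure(list(n_hidden = as.integer(n_hidden), delta_t_ms = delta_t_ms,
                 fps = fps, tau_ms = tau_ms,
                 tau_samples = as.integer(round(tau_samples)),
                 lambda_reg = lambda_reg, epsilon = epsilon,
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 velocity_scale = velocity_scale,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 spec = window_spec(delta_t_ms, fps)),
            class = "mapper_config")
}

#' @export
print.mapper_config <- function(x, ...) {
  cat(sprintf(paste0("<mapper_config: N=%d, window %g ms (%d samples), ",
                     "tau %g ms (%d samples), lambda=%g, eps=%g, %d epochs, seed %d>\n"),
              x$n_hidden, x$delta_t_ms, x$spec$n_samples, x$tau_ms,
              x$tau_samples, x$lambda_reg, x$epsilon, x$epochs, x$seed))
  invisible(x)
}

#' Sine/cosine encoding of an angular velocity
#'
#' Maps a velocity to the direction vector `(cos theta, sin theta)` with
#' `theta = omega * scale` (radians per sample interval under the default
#' scale). The encoding requires `|theta| < pi`.
#'
#' @param omega numeric vector, deg/s.
#' @param scale radians per (deg/s); see [mapper_config()].
#' @return an n x 2 matrix with columns `c` and `s`.
#' @export
encode_velocity <- function(omega, scale) {
  theta <- omega * scale
  bad <- which(abs(theta) >= pi)
  if (length(bad))
    stop(sprintf("velocity out of encodable range (|theta| >= pi) at frame %d",
                 bad[1L]), call. = FALSE)
  cbind(c = cos(theta), s = sin(theta))
}

#' Decode a sine/cosine pair back to an angular velocity
#'
#' Inverse of [encode_velocity()]: `omega = atan2(s, c) / scale`. Insensitive
#' to a common positive rescaling of `(c, s)`, so it applies directly to the
#' network's tanh outputs, whose norm is not constrained to 1.
#'
#' @param c,s cosine and sine components (vectors), or `c` an n x 2 matrix
#'   with `s` missing.
#' @param scale radians per (deg/s).
#' @return numeric vector, deg/s.
#' @export
decode_velocity <- function(c, s = NULL, scale) {
  if (is.null(s)) { s <- c[, 2L]; c <- c[, 1L] }
  if (any(c == 0 & s == 0))
    stop("cannot decode a zero direction vector", call. = FALSE)
  atan2(s, c) / scale
}

## Weight initialisation: uniform +-1/sqrt(fan_in), from the run seed.
mlp_init <- function(n_in, n_hidden, seed) {
  with_seed(seed, {
    r1 <- 1 / sqrt(n_in)
    r2 <- 1 / sqrt(n_hidden + 1L)  # hidden relu units + constant bias unit
    list(W1 = matrix(stats::runif(n_in * n_hidden, -r1, r1), n_in, n_hidden),
         b1 = stats::runif(n_hidden, -r1, r1),
         W2 = matrix(stats::runif(n_hidden * 2L, -r2, r2), n_hidden, 2L),
         b2 = stats::runif(2L, -r2, r2))
  })
}

#' Forward pass of the mapper network
#'
#' `affine -> relu -> affine -> tanh`, deterministic. Accepts a single window
#' (vector of `n_samples` velocities in encoded input units) or a batch
#' (rows = windows).
#'
#' @param model a [train_mapper()] model, or any list with `W1`, `b1`, `W2`,
#'   `b2`.
#' @param window numeric vector of length `n_samples`, or a matrix with
#'   `n_samples` columns.
#' @return a length-2 vector `(O_c, O_s)` for a single window, or an n x 2
#'   matrix for a batch. Components lie in `(-1, 1)`.
#' @export
mlp_forward <- function(model, window) {
  w <- if (!is.null(model$weights)) model$weights else model
  single <- is.null(dim(window))
  X <- if (single) matrix(window, 1L) else as.matrix(window)
  if (ncol(X) != nrow(w$W1))
    stop(sprintf("window has %d samples; the network expects %d",
                 ncol(X), nrow(w$W1)), call. = FALSE)
  H <- pmax(X %*% w$W1 + rep(w$b1, each = nrow(X)), 0)
  O <- tanh(H %*% w$W2 + rep(w$b2, each = nrow(X)))
  colnames(O) <- c("c", "s")
  if (single) O[1L, ] else O
}

#' Anti-identity mapper loss
#'
#' Sum over frames of
#' `|target_enc - O|^2 / (lambda_reg * |source_enc - O|^2 + epsilon)`.
#' Zero exactly when the outputs reproduce the target encoding; maximal (the
#' denominator collapses to `epsilon`) exactly when they reproduce the source
#' encoding, discouraging the identity solution.
#'
#' @param target_enc,source_enc n x 2 encoding matrices ([encode_velocity()]):
#'   the predicted body part (numerator) and the observed body part
#'   (denominator).
#' @param outputs n x 2 matrix of network outputs.
#' @param lambda_reg,epsilon loss parameters; `epsilon` must be > 0.
#' @return a non-negative scalar.
#' @export
mapper_loss <- function(target_enc, source_enc, outputs, lambda_reg = 0.5,
                        epsilon = 0.1) {
  if (epsilon <= 0) stop("epsilon must be > 0", call. = FALSE)
  target_enc <- rbind(target_enc); source_enc <- rbind(source_enc)
  outputs <- rbind(outputs)
  if (nrow(target_enc) != nrow(outputs) || nrow(source_enc) != nrow(outputs))
    stop("batch lengths differ", call. = FALSE)
  num <- rowSums((target_enc - outputs)^2)
  den <- lambda_reg * rowSums((source_enc - outputs)^2) + epsilon
  sum(num / den)
}

#' Build shifted training pairs from two velocity series
#'
#' Pairs an observation window of the source series with the target velocity
#' at frame `t - tau`. With `tau = 0` the window is centered on the predicted
#' instant. With negative `tau` (forecasting) the window ends at frame `t`, so
#' the observations lie entirely before the predicted instant `t + |tau|`;
#' with positive `tau` (backcasting) the window starts at `t` and the
#' predicted instant precedes it. Frames without full support for both the
#' window and the shifted target are dropped, leaving
#' `L - (n_samples - 1) - |tau_samples|` pairs.
#'
#' @param source,target aligned [velocity_series()] objects.
#' @param tau_ms temporal shift in ms (whole samples at the series fps).
#' @param spec a [window_spec()].
#' @return a list with `X` (windows, deg/s), `target_omega` and `source_omega`
#'   (deg/s at the predicted instant), and `frame_index` (predicted instant,
#'   1-based). Empty, with a warning, when the shift exceeds the series.
#' @export
shift_pairs <- function(source, target, tau_ms = 0, spec) {
  stopifnot(inherits(source, "velocity_series"),
            inherits(target, "velocity_series"),
            inherits(spec, "window_spec"))
  n <- series_length(source)
  if (series_length(target) != n)
    stop("source and target series must be aligned", call. = FALSE)
  k <- tau_ms * source$fps / 1000
  if (abs(k - round(k)) > 1e-9)
    stop(sprintf("tau_ms = %g is not a whole number of samples at %g fps",
                 tau_ms, source$fps), call. = FALSE)
  k <- as.integer(round(k))
  h <- spec$half_width
  m <- spec$n_samples
  if (k < 0L) {          # forecasting: window ends at t, predict t + |tau|
    offs <- seq.int(-(m - 1L), 0L)
    t_lo <- m; t_hi <- n + k
  } else if (k > 0L) {   # backcasting: window starts at t, predict t - tau
    offs <- seq.int(0L, m - 1L)
    t_lo <- 1L + k; t_hi <- n - (m - 1L)
  } else {               # unshifted: window centered on the predicted instant
    offs <- seq.int(-h, h)
    t_lo <- h + 1L; t_hi <- n - h
  }
  if (t_lo > t_hi) {
    warning("shift and window leave no supported frames; empty pairing")
    return(list(X = matrix(numeric(0), 0L, spec$n_samples),
                target_omega = numeric(0), source_omega = numeric(0),
                frame_index = integer(0)))
  }
  centers <- seq.int(t_lo, t_hi)
  X <- matrix(source$omega_z[rep(centers, each = length(offs)) +
                               rep(offs, times = length(centers))],
              ncol = length(offs), byrow = TRUE)
  colnames(X) <- window_colnames(spec$n_samples)
  pred_at <- centers - k
  list(X = X, target_omega = target$omega_z[pred_at],
       source_omega = source$omega_z[pred_at], frame_index = pred_at)
}

## Gradient of the batch loss (mean over rows) w.r.t. the weights.
mapper_backprop <- function(w, X, target_enc, source_enc, lambda_reg, epsilon) {
  B <- nrow(X)
  pre1 <- X %*% w$W1 + rep(w$b1, each = B)
  H <- pmax(pre1, 0)
  O <- tanh(H %*% w$W2 + rep(w$b2, each = B))
  dT <- O - target_enc
  dS <- O - source_enc
  num <- rowSums(dT * dT)
  den <- lambda_reg * rowSums(dS * dS) + epsilon
  loss <- sum(num / den)
  ## dL/dO per row: 2 dT / den - 2 lambda num dS / den^2
  gO <- (2 / den) * dT - (2 * lambda_reg * num / den^2) * dS
  g2 <- gO * (1 - O * O)            # through tanh
  gW2 <- crossprod(H, g2) / B
  gb2 <- colSums(g2) / B
  g1 <- (g2 %*% t(w$W2)) * (pre1 > 0)  # through relu
  gW1 <- crossprod(X, g1) / B
  gb1 <- colSums(g1) / B
  list(loss = loss, gW1 = gW1, gb1 = gb1, gW2 = gW2, gb2 = gb2)
}

#' Train the velocity mapper network
#'
#' Minimises the anti-identity loss ([mapper_loss()]) with the Adam update
#' rule (step size and minibatch size from the config, moment decay 0.9 /
#' 0.999), for `config$epochs` passes over the shuffled training pairs. Bit
#' reproducible given `(seed, data, config)`.
#'
#' @param source,target a [velocity_series()] each, or lists of aligned
#'   series (one per flight); windows never span flight boundaries.
#' @param config a [mapper_config()].
#' @return an object of class `velocity_mapper`: the config, the weights, and
#'   the per-epoch mean training-loss trajectory.
#' @export
train_mapper <- function(source, target, config = mapper_config()) {
  stopifnot(inherits(config, "mapper_config"))
  if (inherits(source, "velocity_series")) source <- list(source)
  if (inherits(target, "velocity_series")) target <- list(target)
  stopifnot(length(source) == length(target))
  pairs <- lapply(seq_along(source), function(i)
    shift_pairs(source[[i]], target[[i]], config$tau_ms, config$spec))
  X <- do.call(rbind, lapply(pairs, `[[`, "X")) * config$velocity_scale
  t_enc <- encode_velocity(unlist(lapply(pairs, `[[`, "target_omega")),
                           config$velocity_scale)
  s_enc <- encode_velocity(unlist(lapply(pairs, `[[`, "source_omega")),
                           config$velocity_scale)
  n <- nrow(X)
  if (n < config$batch_size) stop("too few training pairs", call. = FALSE)

  w <- mlp_init(ncol(X), config$n_hidden, config$seed)
  m <- lapply(w, function(p) p * 0)  # first moments
  v <- lapply(w, function(p) p * 0)  # second moments
  b1m <- 0.9; b2m <- 0.999; adam_eps <- 1e-8
  lr <- config$learning_rate
  step <- 0L
  loss_history <- numeric(config$epochs)
  grad_names <- c(W1 = "gW1", b1 = "gb1", W2 = "gW2", b2 = "gb2")

  with_seed(config$seed + 1L, {
    for (epoch in seq_len(config$epochs)) {
      idx <- sample.int(n)
      epoch_loss <- 0
      for (start in seq(1L, n, by = config$batch_size)) {
        rows <- idx[start:min(start + config$batch_size - 1L, n)]
        g <- mapper_backprop(w, X[rows, , drop = FALSE],
                             t_enc[rows, , drop = FALSE],
                             s_enc[rows, , drop = FALSE],
                             config$lambda_reg, config$epsilon)
        if (!is.finite(g$loss))
          stop(sprintf("non-finite loss at epoch %d; aborting training", epoch),
               call. = FALSE)
        epoch_loss <- epoch_loss + g$loss
        step <- step + 1L
        for (p in names(grad_names)) {
          gp <- g[[grad_names[[p]]]]
          m[[p]] <- b1m * m[[p]] + (1 - b1m) * gp
          v[[p]] <- b2m * v[[p]] + (1 - b2m) * gp * gp
          mhat <- m[[p]] / (1 - b1m^step)
          vhat <- v[[p]] / (1 - b2m^step)
          w[[p]] <- w[[p]] - lr * mhat / (sqrt(vhat) + adam_eps)
        }
      }
      loss_history[epoch] <- epoch_loss / n
    }
  })
  structure(list(config = config, weights = w, loss_history = loss_history),
            class = "velocity_mapper")
}

#' @export
print.velocity_mapper <- function(x, ...) {
  cat(sprintf(paste0("<velocity_mapper: N=%d, window %g ms, tau %g ms; ",
                     "final training loss %.4f>\n"),
              x$config$n_hidden, x$config$delta_t_ms, x$config$tau_ms,
              x$loss_history[length(x$loss_history)]))
  invisible(x)
}

#' Predict a target velocity series from a source series
#'
#' Applies the trained network to every supported window of the source series
#' and decodes the outputs back to deg/s.
#'
#' @param object a [train_mapper()] model.
#' @param source a [velocity_series()] of the observed body part.
#' @param target optional aligned [velocity_series()]; when given, the decoded
#'   target at the predicted instants is returned alongside.
#' @param ... unused.
#' @return a data.frame with `frame_index` (predicted instant), `pred_omega`,
#'   and - when `target` is supplied - `target_omega` (deg/s).
#' @export
predict.velocity_mapper <- function(object, source, target = NULL, ...) {
  cfg <- object$config
  tgt <- if (is.null(target)) source else target
  pr <- shift_pairs(source, tgt, cfg$tau_ms, cfg$spec)
  O <- mlp_forward(object, pr$X * cfg$velocity_scale)
  out <- data.frame(frame_index = pr$frame_index,
                    pred_omega = decode_velocity(O, scale = cfg$velocity_scale))
  if (!is.null(target)) out$target_omega <- pr$target_omega
  out
}

#' Unsigned error angle between two direction encodings
#'
#' Absolute angle in `[0, pi]` between predicted and measured velocity
#' direction vectors; the mapper's validation metric.
#'
#' @param pred_enc,target_enc n x 2 matrices (or length-2 vectors) of
#'   `(cos, sin)` direction components; rows need not be normalised but must
#'   be nonzero.
#' @return numeric vector of angles in radians, in `[0, pi]`.
#' @export
unsigned_error_angle <- function(pred_enc, target_enc) {
  p <- rbind(pred_enc); q <- rbind(target_enc)
  if (any(rowSums(p * p) == 0) || any(rowSums(q * q) == 0))
    stop("zero direction vector", call. = FALSE)
  unname(abs(atan2(p[, 1L] * q[, 2L] - p[, 2L] * q[, 1L],
                   p[, 1L] * q[, 1L] + p[, 2L] * q[, 2L])))
}

#' Evaluate a trained mapper on a held-out pair
#'
#' Reports the Pearson correlation between the decoded prediction and the
#' target velocity, and the median unsigned error angle between the raw
#' outputs and the target encoding, on all supported frames of an aligned
#' (source, target) pair.
#'
#' @param model a [train_mapper()] model.
#' @param source,target aligned [velocity_series()] objects.
#' @return a list with `r`, `median_error_angle` (radians) and `n` (pairs).
#' @export
evaluate_mapper <- function(model, source, target) {
  cfg <- model$config
  pr <- shift_pairs(source, target, cfg$tau_ms, cfg$spec)
  if (!nrow(pr$X)) return(list(r = NA_real_, median_error_angle = NA_real_, n = 0L))
  O <- mlp_forward(model, pr$X * cfg$velocity_scale)
  pred <- decode_velocity(O, scale = cfg$velocity_scale)
  t_enc <- encode_velocity(pr$target_omega, cfg$velocity_scale)
  r <- if (stats::sd(pred) < 1e-12 || stats::sd(pr$target_omega) < 1e-12) {
    warning("degenerate variance; correlation undefined")
    NA_real_
  } else stats::cor(pred, pr$target_omega)
  list(r = r,
       median_error_angle = stats::median(unsigned_error_angle(O, t_enc)),
       n = nrow(pr$X))
}

#' Grid search over hidden-layer size and window width
#'
#' Trains one mapper per `(N, delta_t)` cell on the first 70% of each learning
#' pair and scores the median unsigned error angle on the remaining 30%;
#' returns the cell minimising it (ties toward smaller N, then smaller
#' window).
#'
#' @param pairs list of flights, each a list with aligned `source` and
#'   `target` [velocity_series()]. All but the last flight form the learning
#'   set (70/30 chronological split); the last is held out untouched.
#' @param n_grid hidden sizes (default `2^(0:7)`).
#' @param delta_t_grid window widths in ms (default `seq(1, 53, by = 2)`).
#' @param config base [mapper_config()] supplying everything except `n_hidden`
#'   and `delta_t_ms`.
#' @return list with `config` (the winning configuration), `model` (trained at
#'   the winning cell), `median_error_angle` (validation) and `table`.
#' @export
grid_search_mapper <- function(pairs, n_grid = 2^(0:7),
                               delta_t_grid = seq(1, 53, by = 2),
                               config = mapper_config()) {
  if (!length(n_grid) || !length(delta_t_grid))
    stop("hyperparameter grids must be non-empty", call. = FALSE)
  if (length(pairs) < 2L) stop("need at least 2 flights", call. = FALSE)
  learn <- pairs[-length(pairs)]
  cut70 <- function(vs, which) {
    n <- series_length(vs)
    k <- floor(0.7 * n)
    subset_series(vs, if (which == "train") seq_len(k) else seq.int(k + 1L, n))
  }
  tr_src <- lapply(learn, function(p) cut70(p$source, "train"))
  tr_tgt <- lapply(learn, function(p) cut70(p$target, "train"))
  va_src <- lapply(learn, function(p) cut70(p$source, "val"))
  va_tgt <- lapply(learn, function(p) cut70(p$target, "val"))

  tab <- expand.grid(n_hidden = sort(n_grid), delta_t_ms = sort(delta_t_grid))
  tab$median_error_angle <- NA_real_
  fit_cell <- function(N, dt) {
    cfg <- mapper_config(n_hidden = N, delta_t_ms = dt, fps = config$fps,
                         tau_ms = config$tau_ms,
                         lambda_reg = config$lambda_reg,
                         epsilon = config$epsilon, epochs = config$epochs,
                         seed = config$seed,
                         velocity_scale = config$velocity_scale,
                         learning_rate = config$learning_rate,
                         batch_size = config$batch_size)
    train_mapper(tr_src, tr_tgt, cfg)
  }
  for (i in seq_len(nrow(tab))) {
    model <- fit_cell(tab$n_hidden[i], tab$delta_t_ms[i])
    med <- vapply(seq_along(va_src), function(j)
      evaluate_mapper(model, va_src[[j]], va_tgt[[j]])$median_error_angle, 0)
    tab$median_error_angle[i] <- stats::median(med)
  }
  ord <- order(tab$median_error_angle, tab$n_hidden, tab$delta_t_ms)
  top <- tab[ord[1L], ]
  model <- fit_cell(top$n_hidden, top$delta_t_ms)
  list(config = model$config, model = model,
       median_error_angle = top$median_error_angle, table = tab)
}

#' Correlation between prediction and target across temporal shifts
#'
#' For each shift tau, retrains a fresh mapper (same seed and config) on the
#' learning flights with the observation window shifted by tau relative to the
#' predicted instant, decodes its predictions on the held-out last flight, and
#' reports the Pearson correlation r(tau) between decoded prediction and
#' target, together with the median unsigned error angle. Negative tau =
#' forecasting, positive = backcasting.
#'
#' @param pairs list of flights with aligned `source` and `target`
#'   [velocity_series()]; the last flight is held out for evaluation, the
#'   others are used for training in full.
#' @param tau_grid_ms shifts to scan, each a whole number of samples at the
#'   series fps.
#' @param config base [mapper_config()] (its `tau_ms` is ignored).
#' @return a data.frame with `tau_ms`, `tau_samples`, `r`,
#'   `median_error_angle` and `n` (evaluation pairs).
#' @export
correlation_vs_shift <- function(pairs, tau_grid_ms = seq(-20, 20, by = 2),
                                 config = mapper_config()) {
  if (length(pairs) < 2L) stop("need at least 2 flights", call. = FALSE)
  learn <- pairs[-length(pairs)]
  held <- pairs[[length(pairs)]]
  rows <- lapply(tau_grid_ms, function(tau) {
    cfg <- mapper_config(n_hidden = config$n_hidden,
                         delta_t_ms = config$delta_t_ms, fps = config$fps,
                         tau_ms = tau, lambda_reg = config$lambda_reg,
                         epsilon = config$epsilon, epochs = config$epochs,
                         seed = config$seed,
                         velocity_scale = config$velocity_scale,
                         learning_rate = config$learning_rate,
                         batch_size = config$batch_size)
    model <- train_mapper(lapply(learn, `[[`, "source"),
                          lapply(learn, `[[`, "target"), cfg)
    ev <- evaluate_mapper(model, held$source, held$target)
    data.frame(tau_ms = tau, tau_samples = cfg$tau_samples, r = ev$r,
               median_error_angle = ev$median_error_angle, n = ev$n)
  })
  do.call(rbind, rows)
}
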