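test_that("window_spec derives an odd sample count from the ms width", {
  expect_equal(window_spec(0, 500)$n_samples, 1L)
  expect_equal(window_spec(4, 500)$n_samples, 3L)
  expect_equal(window_spec(20, 500)$n_samples, 11L)
  expect_equal(window_spec(29, 500)$n_samples, 15L)  # odd ms grid stays defined
  expect_error(window_spec(-1), ">= 0")
})

test_that("build_windows centers windows on the labelled frame", {
  fps <- 500
  n <- 20
  v <- velocity_series(seq.int(0, n - 1) / fps, seq_len(n), fps = fps)
  l <- label_series(v$times, rep(c(0L, 1L), n / 2))

  ds0 <- build_windows(v, l, window_spec(0, fps))
  expect_equal(ncol(ds0$X), 1L)
  expect_equal(ds0$X[, 1], v$omega_z)
  expect_equal(ds0$y, l$labels)

  ds <- build_windows(v, l, window_spec(4, fps))  # half-width 1
  expect_equal(nrow(ds$X), n - 2L)
  ## direct indexing oracle on the ramp
  h <- ds$spec$half_width
  for (r in c(1L, 5L, nrow(ds$X))) {
    t <- ds$frame_index[r]
    expect_equal(unname(ds$X[r, ]), v$omega_z[(t - h):(t + h)])
    expect_equal(ds$y[r], l$labels[t])
  }
  expect_warning(short <- build_windows(
    velocity_series(0:1 / fps, c(0, 0), fps = fps), c(0L, 0L),
    window_spec(10, fps)), "shorter")
  expect_equal(nrow(short$X), 0L)
})

test_that("split_flights takes the first 70% per learning flight and holds out the last", {
  mk <- function(n) {
    v <- velocity_series(seq_len(n) / 500, rnorm(n), fps = 500)
    list(v = v, labels = label_series(v$times, rbinom(n, 1, 0.2)))
  }
  set.seed(2)
  sp <- split_flights(replicate(6, mk(1000), simplify = FALSE))
  expect_length(sp$train, 5)
  expect_length(sp$validation, 5)
  expect_length(sp$test, 1)
  expect_true(all(vapply(sp$train, function(f) length(f$v$omega_z), 0) == 700))
  expect_true(all(vapply(sp$validation, function(f) length(f$v$omega_z), 0) == 300))
  expect_equal(length(sp$test[[1]]$v$omega_z), 1000)

  ## floor convention and the two-flight minimum
  sp2 <- split_flights(replicate(2, mk(15), simplify = FALSE))
  expect_equal(length(sp2$train[[1]]$v$omega_z), floor(0.7 * 15))
  expect_error(split_flights(list(mk(100))), "2 flights")
})

test_that("classifiers are deterministic and solve a one-split problem at depth 1", {
  set.seed(4)
  n <- 400
  x <- runif(n, -600, 600)
  v <- velocity_series(seq_len(n) / 500, x, fps = 500)
  l <- label_series(v$times, as.integer(x > 150))
  ds <- build_windows(v, l, window_spec(0, 500))

  m <- train_classifier(ds, "decision_tree", depth = 1L, seed = 9)
  expect_equal(mean(predict(m, ds) == ds$y), 1)
  mf <- train_classifier(ds, "random_forest", depth = 1L, seed = 9,
                         n_trees = 20L, bootstrap = FALSE)
  expect_equal(mean(predict(mf, ds) == ds$y), 1)
  for (fam in c("decision_tree", "random_forest")) {
    a <- train_classifier(ds, fam, depth = 2L, seed = 9)
    b <- train_classifier(ds, fam, depth = 2L, seed = 9)
    expect_identical(predict(a, ds, type = "prob"), predict(b, ds, type = "prob"))
  }
  expect_error(train_classifier(
    structure(list(X = ds$X, y = rep(1L, n), frame_index = ds$frame_index,
                   flight_id = ds$flight_id, spec = ds$spec),
              class = "windowed_dataset"), "decision_tree"),
    "single class")
  expect_error(train_classifier(ds, "decision_tree", depth = 0), "depth")
})

test_that("a one-tree forest without bootstrap matches the decision tree", {
  set.seed(8)
  n <- 300
  x <- runif(n, -600, 600)
  v <- velocity_series(seq_len(n) / 500, x, fps = 500)
  l <- label_series(v$times, as.integer(x > 100))
  ds <- build_windows(v, l, window_spec(4, 500))
  tree <- train_classifier(ds, "decision_tree", depth = 3L, seed = 1)
  forest1 <- train_classifier(ds, "random_forest", depth = 3L, n_trees = 1L,
                              seed = 1, bootstrap = FALSE)
  expect_identical(predict(tree, ds), predict(forest1, ds))
})

test_that("evaluation reports accuracy, error rate and a calibrated AUC", {
  set.seed(6)
  n <- 500
  x <- runif(n, -600, 600)
  v <- velocity_series(seq_len(n) / 500, x, fps = 500)
  l <- label_series(v$times, as.integer(x > 0))
  ds <- build_windows(v, l, window_spec(0, 500))
  m <- train_classifier(ds, "decision_tree", depth = 2L, seed = 1)
  ev <- evaluate_classifier(m, ds)
  expect_equal(ev$accuracy, 1)
  expect_equal(ev$error_rate, 0)
  expect_equal(ev$auc, 1)

  ## label-independent scores sit at chance AUC
  set.seed(10)
  auc0 <- beechoreo:::score_auc(runif(2000), rbinom(2000, 1, 0.5))
  expect_lt(abs(auc0 - 0.5), 0.05)
  ## a binary all-zero predictor on balanced labels: accuracy one half
  expect_equal(label_accuracy(rep(0L, 100), rep(c(0L, 1L), 50)), 0.5)
  expect_warning(a <- beechoreo:::score_auc(runif(10), rep(1L, 10)), "single-class")
  expect_true(is.na(a))
})

test_that("grid search scores every cell and prefers informative windows", {
  ## labels depend on the velocity 5 samples (10 ms) in the past: a centered
  ## window of >= 20 ms sees it, a single-sample window cannot
  mk <- function(seed) {
    set.seed(seed)
    n <- 1500
    x <- rnorm(n, 0, 300)
    lab <- c(rep(0L, 5), as.integer(abs(x[1:(n - 5)]) > 350))
    v <- velocity_series(seq_len(n) / 500, x, fps = 500)
    list(v = v, labels = label_series(v$times, lab))
  }
  flights <- lapply(1:3, mk)
  gs <- suppressWarnings(
    grid_search_classifier(flights, family = "decision_tree",
                           depth_grid = 6L, delta_t_grid = c(0, 24), seed = 2))
  expect_equal(nrow(gs$table), 2L)
  acc_wide <- gs$table$accuracy[gs$table$delta_t_ms == 24]
  acc_point <- gs$table$accuracy[gs$table$delta_t_ms == 0]
  expect_gt(acc_wide, acc_point)
  expect_equal(gs$delta_t_ms, 24)

  one <- suppressWarnings(
    grid_search_classifier(flights, family = "decision_tree",
                           depth_grid = 3L, delta_t_grid = 8, seed = 2))
  expect_equal(one$depth, 3L)
  expect_equal(one$delta_t_ms, 8)
  expect_equal(nrow(one$table), 1L)
  expect_error(grid_search_classifier(flights, depth_grid = integer(0)),
               "non-empty")
})

test_that("shuffled training labels fall back to the majority class", {
  flights <- as_clf_flights(make_flights(3, seed = 7, duration = 5))
  sp <- split_flights(flights)
  spec <- window_spec(20, 500)
  tr <- windows_for_flights(sp$train, spec)
  va <- windows_for_flights(sp$validation, spec)
  tr$y <- local({ set.seed(99); sample(tr$y) })
  m <- suppressWarnings(train_classifier(tr, "random_forest", depth = 8L, seed = 3))
  acc <- mean(predict(m, va) == va$y)
  majority <- max(mean(va$y), 1 - mean(va$y))
  expect_lt(abs(acc - majority), 0.05)
})

test_that("a depth-1 tree on the center column equals single-threshold segmentation", {
  fl <- generate_flight(flight_config(duration = 5, seed = 31))
  ds <- build_windows(fl$thorax_v, fl$true_labels, window_spec(0, 500))
  m <- suppressWarnings(train_classifier(ds, "decision_tree", depth = 1L, seed = 1))
  ## the tree's hard prediction must be a single threshold on the lone column:
  ## sorted by velocity, predictions form one block of 0s and one of 1s
  pred <- predict(m, ds)
  ord <- order(ds$X[, 1])
  expect_lte(sum(diff(pred[ord]) != 0), 1L)
  ## and its accuracy equals that threshold's segmentation accuracy
  cut <- max(ds$X[ord, 1][pred[ord] == pred[ord][1]])
  seg <- as.integer(ds$X[, 1] > cut)
  expect_equal(max(mean(seg == ds$y), mean((1L - seg) == ds$y)),
               mean(pred == ds$y), tolerance = 1e-12)
})

test_that("sweeps keep the native-rate row equal to the plain evaluation", {
  flights <- make_flights(3, seed = 13, duration = 5)
  clf <- as_clf_flights(flights)
  sp <- split_flights(clf)
  spec <- window_spec(20, 500)
  m <- suppressWarnings(train_classifier(
    windows_for_flights(sp$train, spec), "random_forest",
    depth = 8L, seed = 1))
  thr <- c(372.42, 200.54)
  tab <- framerate_sweep(flights[3], c(100, 500), m, thr)
  expect_equal(nrow(tab), 4L)
  expect_setequal(tab$method, c("classifier", "benchmark"))

  direct <- evaluate_classifier(m, build_windows(flights[[3]]$thorax_v,
                                                 flights[[3]]$true_labels, spec))
  row <- tab[tab$fps == 500 & tab$method == "classifier", ]
  expect_equal(row$auc, direct$auc)
  expect_equal(row$accuracy, direct$accuracy)

  ## topview sweep has the same schema and, at zero pitch/roll, equal values
  tv <- topview_sweep(flights[3], c(100, 500), m, thr)
  expect_identical(names(tv), names(tab))
  expect_equal(tv$auc, tab$auc, tolerance = 1e-12)
  expect_equal(tv$accuracy, tab$accuracy, tolerance = 1e-12)
})
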