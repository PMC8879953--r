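# Small network configurations are used throughout for speed; the full-size
# study configuration is exercised by the end-to-end acceptance suite.

toy_set <- function(classes, windows_per_class = 30, seed = 5,
                    sensor = "head") {
  set.seed(seed)
  logs <- lapply(classes, function(cl)
    generate_posture_signal(cl, windows_per_class, seed = NULL))
  stats <- fit_stats(dplyr::bind_rows(logs))
  wins <- lapply(logs, function(l) normalize_windows(segment_windows(l), stats))
  list(x = to_tensor(dplyr::bind_rows(wins)),
       labels = rep(classes, each = windows_per_class), stats = stats)
}

small_cfg <- function(classes, sensor = "head") {
  classifier_config(sensor, units = 8, classes = classes)
}

test_that("classifier configuration fixes shapes per sensor", {
  head_cfg <- classifier_config("head")
  body_cfg <- classifier_config("body")
  expect_equal(head_cfg$n_classes, 3)
  expect_equal(body_cfg$n_classes, 6)
  expect_equal(head_cfg$layers, 2)
  expect_equal(head_cfg$units, 64)
  expect_equal(c(head_cfg$timesteps, head_cfg$features), c(50, 3))
  expect_error(classifier_config("head", units = 0), ">= 1")
  expect_error(classifier_config("head", layers = 0), ">= 1")
  expect_error(training_config(folds = 1), ">= 2")
  expect_error(training_config(learning_rate = 0), "> 0")
})

test_that("analytic gradients agree with finite differences", {
  set.seed(1)
  cfg <- classifier_config("head", layers = 2, units = 3, timesteps = 4,
                           features = 2)
  params <- sawatch:::lstm_init(cfg)
  n <- 3
  X <- array(runif(n * 4 * 2), c(n, 4, 2))
  Y <- matrix(0, n, 3)
  Y[cbind(1:n, 1:3)] <- 1
  lg <- sawatch:::lstm_loss_grad(params, X, Y)
  flat <- sawatch:::flatten_params(params)
  gflat <- sawatch:::flatten_grads(lg$grads)
  eps <- 1e-6
  for (k in names(flat)) {
    for (i in seq_len(min(length(flat[[k]]), 6))) {
      bump <- function(sign) {
        fp <- flat
        fp[[k]][i] <- fp[[k]][i] + sign * eps
        sawatch:::lstm_loss_grad(sawatch:::unflatten_params(fp, params),
                                 X, Y)$loss
      }
      num <- (bump(1) - bump(-1)) / (2 * eps)
      expect_equal(gflat[[k]][i], num, tolerance = 1e-4)
    }
  }
})

test_that("a separable two-class toy trains to high per-fold F1", {
  ts <- toy_set(c("Up", "Down"), windows_per_class = 25)
  model <- build_model(small_cfg(c("Up", "Down")))
  tc <- training_config(epochs = 8, folds = 5, seed = 9)
  fitted <- train_posture_model(model, ts$x, ts$labels, tc)
  folds <- tidy(fitted)
  per_fold <- folds[folds$class == "Average", ]
  expect_equal(nrow(per_fold), 5)
  expect_true(all(per_fold$f1 >= 0.95))
  expect_gte(glance(fitted)$macro_f1, 0.95)
})

test_that("training rejects degenerate label sets and is seed-reproducible", {
  ts <- toy_set(c("Up", "Down"), windows_per_class = 10)
  model <- build_model(small_cfg(c("Up", "Down")))
  tc <- training_config(epochs = 2, seed = 3)
  expect_error(train_posture_model(model, ts$x, rep("Up", 20), tc),
               "absent")
  one_class <- toy_set("Up", windows_per_class = 10)
  expect_error(train_posture_model(model, one_class$x, one_class$labels, tc),
               "absent")
  f1 <- train_posture_model(model, ts$x, ts$labels, tc, cv_folds = 2)
  f2 <- train_posture_model(model, ts$x, ts$labels, tc, cv_folds = 2)
  expect_identical(f1$params, f2$params)      # bitwise reproducible
  expect_identical(f1$fold_metrics, f2$fold_metrics)
})

test_that("predictions are softmax-normalized events with tie-breaking", {
  ts <- toy_set(c("Up", "Down"), windows_per_class = 10)
  model <- build_model(small_cfg(c("Up", "Down")))
  fitted <- train_posture_model(model, ts$x, ts$labels,
                                training_config(epochs = 4, seed = 2),
                                cv_folds = 0)
  pr <- predict_posture(fitted, ts$x, subject_id = "d")
  probs <- as.matrix(pr[, c("p_Up", "p_Down")])
  expect_equal(rowSums(probs), rep(1, nrow(probs)), tolerance = 1e-6)
  expect_true(all(probs >= 0))
  expect_equal(pr$sensor_id, rep("head", nrow(pr)))
  # a trained model recovers the generator's label
  expect_gte(mean(pr$posture == ts$labels), 0.95)
  # exact ties resolve to the lowest-ordered class
  tied <- fitted
  tied$params$Wy[] <- 0
  tied$params$by[] <- 0
  pr_tied <- predict_posture(tied, ts$x[1, , , drop = FALSE])
  expect_equal(pr_tied$posture, "Up")
  expect_equal(as.numeric(pr_tied[, c("p_Up", "p_Down")]), c(0.5, 0.5))
  # un-normalized input warns and clips
  expect_warning(predict_posture(fitted, ts$x * 2), "clip")
  expect_error(predict_posture(build_model(small_cfg(c("Up", "Down"))),
                               ts$x), "untrained")
})

test_that("statistical features match a direct summation oracle", {
  w <- segment_windows(generate_posture_signal("Walk", 2, seed = 8))
  fv <- extract_features(w)
  expect_equal(ncol(fv), 12)
  m <- w$values[[1]]
  # direct per-element oracle for axis y
  v <- m[, 2]
  expect_equal(fv$ay_min[1], min(v))
  expect_equal(fv$ay_max[1], max(v))
  expect_equal(fv$ay_mean[1], sum(v) / 50)
  expect_equal(fv$ay_sd[1], sqrt(sum((v - sum(v) / 50)^2) / 49))
  expect_true(all(fv$ax_min <= fv$ax_mean & fv$ax_mean <= fv$ax_max))
  # constant window
  wc <- w
  wc$values[[1]][] <- 0.7
  fc <- extract_features(wc[1, ])
  expect_equal(unlist(fc[1, c("az_min", "az_max", "az_mean", "az_sd")],
                      use.names = FALSE), c(0.7, 0.7, 0.7, 0))
  # alternating 0/1 axis
  wa <- w
  wa$values[[1]][, 1] <- rep(c(0, 1), 25)
  fa <- extract_features(wa[1, ])
  expect_equal(unlist(fa[1, c("ax_min", "ax_max", "ax_mean")],
                      use.names = FALSE), c(0, 1, 0.5))
})

test_that("feature baselines separate the toy classes and are deterministic", {
  ts <- toy_set(c("Up", "Down", "Bark"), windows_per_class = 20)
  w <- tibble::tibble(values = lapply(seq_len(dim(ts$x)[1]),
                                      function(i) ts$x[i, , ]))
  fv <- extract_features(w)
  for (kind in c("svm", "naive_bayes", "decision_tree")) {
    fit <- train_baseline(fv, ts$labels, kind = kind, seed = 4)
    acc <- mean(predict(fit, fv) == ts$labels)
    expect_gte(acc, 0.9)
    fit2 <- train_baseline(fv, ts$labels, kind = kind, seed = 4)
    expect_equal(predict(fit, fv), predict(fit2, fv))
  }
  expect_error(train_baseline(fv, rep("Up", nrow(fv))), "two classes")
})

test_that("model checkpoints round-trip with a versioned header", {
  ts <- toy_set(c("Up", "Down"), windows_per_class = 5)
  fitted <- train_posture_model(build_model(small_cfg(c("Up", "Down"))),
                                ts$x, ts$labels,
                                training_config(epochs = 1, seed = 1),
                                cv_folds = 0)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(fitted, path)
  back <- load_model(path)
  expect_identical(back$params, fitted$params)
  saveRDS(list(format = "something-else"), path)
  expect_error(load_model(path), "not a sawatch")
})
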