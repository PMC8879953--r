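# Level-1 posture recognition. Two parallel stacked recurrent networks (one
# per sensor), each two LSTM layers of 64 units over 50x3 one-second windows
# with a softmax output, trained with Adam on categorical cross-entropy.
# Implemented directly on base matrix operations; gradients are exercised by
# a finite-difference check in the test suite. Statistical-feature baselines
# (SVM, naive Bayes, decision tree) are provided for comparison.

#' Classifier and training configuration
#'
#' `classifier_config()` fixes the network shape: two stacked LSTM layers of
#' 64 units over 50 timesteps x 3 features, with one softmax unit per
#' posture class of the sensor (3 head, 6 body). `training_config()` fixes
#' the optimization: categorical cross-entropy, Adam with decay rates
#' `beta1 = 0.9` and `beta2 = 0.999`, learning rate 0.0025, batch size 25,
#' 50 epochs, 5-fold cross-validation, and a mandatory RNG seed.
#'
#' @param sensor `"head"` or `"body"`.
#' @param layers Number of stacked recurrent layers (`>= 1`).
#' @param units Hidden units per layer (`>= 1`).
#' @param timesteps,features Input window shape.
#' @param classes Posture classes of the softmax layer; defaults to the
#'   sensor's full vocabulary, and may be restricted to a subset for
#'   reduced-vocabulary experiments.
#' @return A configuration list.
#' @export
classifier_config <- function(sensor, layers = 2, units = 64, timesteps = 50,
                              features = 3,
                              classes = posture_classes(sensor)) {
  sensor <- match.arg(sensor, sensor_ids())
  if (layers < 1 || units < 1) abort("layers and units must be >= 1")
  if (timesteps < 1 || features < 1) abort("invalid input shape")
  if (!all(classes %in% posture_classes(sensor))) {
    abort(paste0("classes must be ", sensor, " postures"))
  }
  list(sensor = sensor, layers = as.integer(layers),
       units = as.integer(units), timesteps = as.integer(timesteps),
       features = as.integer(features), classes = classes,
       n_classes = length(classes))
}

#' @rdname classifier_config
#' @param learning_rate,beta1,beta2 Adam parameters (all `> 0`).
#' @param batch_size,epochs Minibatch size and training epochs.
#' @param folds Cross-validation folds (`>= 2`).
#' @param seed Integer RNG seed governing initialization, shuffling and fold
#'   assignment.
#' @export
training_config <- function(learning_rate = 0.0025, beta1 = 0.9,
                            beta2 = 0.999, batch_size = 25, epochs = 50,
                            folds = 5, seed = 1) {
  if (any(c(learning_rate, beta1, beta2) <= 0)) abort("rates must be > 0")
  if (folds < 2) abort("folds must be >= 2")
  list(learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
       batch_size = as.integer(batch_size), epochs = as.integer(epochs),
       folds = as.integer(folds), seed = as.integer(seed))
}

#' Build an untrained posture classifier
#'
#' @param config A [classifier_config()].
#' @return An unfitted `posture_model` (weights are initialized by
#'   [train_posture_model()] from the training seed).
#' @export
build_model <- function(config) {
  structure(list(config = config, params = NULL, training = NULL,
                 fold_metrics = NULL),
            class = "posture_model")
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Glorot-uniform initialization; forget-gate bias +1.
lstm_init <- function(config) {
  U <- config$units
  layers <- vector("list", config$layers)
  f_in <- config$features
  for (l in seq_len(config$layers)) {
    r <- sqrt(6 / (f_in + U + U))
    b <- numeric(4 * U)
    b[(U + 1):(2 * U)] <- 1
    layers[[l]] <- list(
      Wx = matrix(runif(f_in * 4 * U, -r, r), f_in, 4 * U),
      Wh = matrix(runif(U * 4 * U, -r, r), U, 4 * U),
      b = b)
    f_in <- U
  }
  ro <- sqrt(6 / (U + config$n_classes))
  list(layers = layers,
       Wy = matrix(runif(U * config$n_classes, -ro, ro), U, config$n_classes),
       by = numeric(config$n_classes))
}

slice_t <- function(A, t) matrix(A[, t, ], nrow = dim(A)[1], ncol = dim(A)[3])

# Forward pass. X: n x T x F array. Returns softmax probabilities and, when
# requested, the per-layer gate/state caches needed for BPTT.
lstm_forward <- function(params, X, caches = FALSE) {
  n <- dim(X)[1]
  Tn <- dim(X)[2]
  L <- length(params$layers)
  U <- ncol(params$layers[[1]]$Wh)
  U <- U / 4
  cache <- vector("list", L)
  input <- X
  for (l in seq_len(L)) {
    p <- params$layers[[l]]
    h <- matrix(0, n, U)
    cc <- matrix(0, n, U)
    # all state arrays share the input layout: (batch, time, units)
    st <- list(I = array(0, c(n, Tn, U)), Fg = array(0, c(n, Tn, U)),
               G = array(0, c(n, Tn, U)), O = array(0, c(n, Tn, U)),
               C = array(0, c(n, Tn, U)), H = array(0, c(n, Tn, U)))
    for (t in seq_len(Tn)) {
      xt <- slice_t(input, t)
      z <- xt %*% p$Wx + h %*% p$Wh
      z <- z + rep(p$b, each = n)
      i <- sigmoid(z[, 1:U, drop = FALSE])
      f <- sigmoid(z[, (U + 1):(2 * U), drop = FALSE])
      g <- tanh(z[, (2 * U + 1):(3 * U), drop = FALSE])
      o <- sigmoid(z[, (3 * U + 1):(4 * U), drop = FALSE])
      cc <- f * cc + i * g
      h <- o * tanh(cc)
      st$I[, t, ] <- i
      st$Fg[, t, ] <- f
      st$G[, t, ] <- g
      st$O[, t, ] <- o
      st$C[, t, ] <- cc
      st$H[, t, ] <- h
    }
    if (caches) {
      st$input <- input
      cache[[l]] <- st
    }
    input <- st$H
  }
  hT <- slice_t(input, Tn)
  logits <- hT %*% params$Wy + rep(params$by, each = n)
  m <- apply(logits, 1, max)
  e <- exp(logits - m)
  probs <- e / rowSums(e)
  list(probs = probs, hT = hT, cache = if (caches) cache else NULL)
}

# Backward pass through one LSTM layer. d_h_ext: n x U x T upstream gradient.
lstm_layer_backward <- function(p, st, d_h_ext) {
  dims <- dim(st$H)
  n <- dims[1]
  Tn <- dims[2]
  U <- dims[3]
  Fdim <- nrow(p$Wx)
  dWx <- matrix(0, Fdim, 4 * U)
  dWh <- matrix(0, U, 4 * U)
  db <- numeric(4 * U)
  dX <- array(0, c(n, Tn, Fdim))
  dh_next <- matrix(0, n, U)
  dc_next <- matrix(0, n, U)
  for (t in rev(seq_len(Tn))) {
    dh <- slice_t(d_h_ext, t) + dh_next
    o <- slice_t(st$O, t)
    tc <- tanh(slice_t(st$C, t))
    i <- slice_t(st$I, t)
    f <- slice_t(st$Fg, t)
    g <- slice_t(st$G, t)
    do <- dh * tc
    dc <- dc_next + dh * o * (1 - tc^2)
    c_prev <- if (t > 1) slice_t(st$C, t - 1) else matrix(0, n, U)
    h_prev <- if (t > 1) slice_t(st$H, t - 1) else matrix(0, n, U)
    di <- dc * g
    df <- dc * c_prev
    dg <- dc * i
    dc_next <- dc * f
    dz <- cbind(di * i * (1 - i), df * f * (1 - f), dg * (1 - g^2),
                do * o * (1 - o))
    xt <- slice_t(st$input, t)
    dWx <- dWx + crossprod(xt, dz)
    dWh <- dWh + crossprod(h_prev, dz)
    db <- db + colSums(dz)
    dh_next <- dz %*% t(p$Wh)
    dX[, t, ] <- dz %*% t(p$Wx)
  }
  list(dWx = dWx, dWh = dWh, db = db, dX = dX)
}

# Loss and full gradient for one minibatch. Y: n x K one-hot matrix.
lstm_loss_grad <- function(params, X, Y) {
  n <- dim(X)[1]
  Tn <- dim(X)[2]
  fw <- lstm_forward(params, X, caches = TRUE)
  loss <- -sum(Y * log(pmax(fw$probs, 1e-12))) / n
  dlogits <- (fw$probs - Y) / n
  dWy <- crossprod(fw$hT, dlogits)
  dby <- colSums(dlogits)
  L <- length(params$layers)
  U <- nrow(params$Wy)
  d_h_ext <- array(0, c(n, Tn, U))
  d_h_ext[, Tn, ] <- dlogits %*% t(params$Wy)
  grads_layers <- vector("list", L)
  for (l in rev(seq_len(L))) {
    bl <- lstm_layer_backward(params$layers[[l]], fw$cache[[l]], d_h_ext)
    grads_layers[[l]] <- bl[c("dWx", "dWh", "db")]
    d_h_ext <- bl$dX
  }
  list(loss = loss, grads = list(layers = grads_layers, dWy = dWy, dby = dby))
}

flatten_params <- function(p) {
  out <- list()
  for (l in seq_along(p$layers)) {
    out[[paste0("l", l, ".Wx")]] <- p$layers[[l]]$Wx
    out[[paste0("l", l, ".Wh")]] <- p$layers[[l]]$Wh
    out[[paste0("l", l, ".b")]] <- p$layers[[l]]$b
  }
  out$Wy <- p$Wy
  out$by <- p$by
  out
}

flatten_grads <- function(g) {
  out <- list()
  for (l in seq_along(g$layers)) {
    out[[paste0("l", l, ".Wx")]] <- g$layers[[l]]$dWx
    out[[paste0("l", l, ".Wh")]] <- g$layers[[l]]$dWh
    out[[paste0("l", l, ".b")]] <- g$layers[[l]]$db
  }
  out$Wy <- g$dWy
  out$by <- g$dby
  out
}

unflatten_params <- function(flat, template) {
  p <- template
  for (l in seq_along(p$layers)) {
    p$layers[[l]]$Wx <- flat[[paste0("l", l, ".Wx")]]
    p$layers[[l]]$Wh <- flat[[paste0("l", l, ".Wh")]]
    p$layers[[l]]$b <- flat[[paste0("l", l, ".b")]]
  }
  p$Wy <- flat$Wy
  p$by <- flat$by
  p
}

adam_fit <- function(params, X, y_idx, n_classes, tc) {
  n <- dim(X)[1]
  Y <- matrix(0, n, n_classes)
  Y[cbind(seq_len(n), y_idx)] <- 1
  flat <- flatten_params(params)
  m <- purrr::map(flat, ~ .x * 0)
  v <- purrr::map(flat, ~ .x * 0)
  step <- 0
  eps <- 1e-8
  for (epoch in seq_len(tc$epochs)) {
    ord <- sample.int(n)
    for (b0 in seq(1, n, by = tc$batch_size)) {
      idx <- ord[b0:min(b0 + tc$batch_size - 1, n)]
      lg <- lstm_loss_grad(unflatten_params(flat, params),
                           X[idx, , , drop = FALSE],
                           Y[idx, , drop = FALSE])
      g <- flatten_grads(lg$grads)
      step <- step + 1
      corr1 <- 1 - tc$beta1^step
      corr2 <- 1 - tc$beta2^step
      for (k in names(flat)) {
        m[[k]] <- tc$beta1 * m[[k]] + (1 - tc$beta1) * g[[k]]
        v[[k]] <- tc$beta2 * v[[k]] + (1 - tc$beta2) * g[[k]]^2
        flat[[k]] <- flat[[k]] - tc$learning_rate * (m[[k]] / corr1) /
          (sqrt(v[[k]] / corr2) + eps)
      }
    }
  }
  unflatten_params(flat, params)
}

check_tensor <- function(model, x) {
  cfg <- model$config
  if (length(dim(x)) != 3 || dim(x)[2] != cfg$timesteps ||
      dim(x)[3] != cfg$features) {
    abort(sprintf("input tensor must be n x %d x %d", cfg$timesteps,
                  cfg$features))
  }
  if (any(x < 0 | x > 1)) {
    warn("input values outside [0, 1]; clipping (windows should be normalized)")
    x[] <- pmin(1, pmax(0, x))  # in-place keeps the array dims
  }
  x
}

#' Train the posture classifier
#'
#' Fits the stacked LSTM with Adam on categorical cross-entropy. With
#' `cv_folds >= 2`, per-fold precision/recall/F1 are computed by seeded,
#' class-stratified cross-validation before the final model is fitted on all
#' data. Training is deterministic given the training seed. Every class of
#' the model's sensor must be present in `labels`.
#'
#' @param model A [build_model()] result.
#' @param x Normalized input tensor `n x timesteps x features`
#'   (see [to_tensor()]).
#' @param labels Character vector of posture labels, length `n`.
#' @param training A [training_config()].
#' @param cv_folds Cross-validation folds; 0 skips cross-validation,
#'   the default uses `training$folds`.
#' @return The fitted `posture_model`, with `fold_metrics` (a tibble) when
#'   cross-validation ran.
#' @export
train_posture_model <- function(model, x, labels,
                                training = training_config(),
                                cv_folds = NULL) {
  stopifnot(inherits(model, "posture_model"))
  cfg <- model$config
  x <- check_tensor(model, x)
  labels <- as.character(labels)
  if (length(labels) != dim(x)[1]) abort("labels must match tensor rows")
  missing <- setdiff(cfg$classes, labels)
  if (length(missing)) {
    abort(paste0("class absent from training data: ",
                 paste(missing, collapse = ", ")))
  }
  bad <- setdiff(labels, cfg$classes)
  if (length(bad)) abort(paste0("label not valid for sensor ", cfg$sensor,
                                ": ", paste(bad, collapse = ", ")))
  y_idx <- match(labels, cfg$classes)
  cv_folds <- cv_folds %||% training$folds
  fold_metrics <- NULL
  if (cv_folds >= 2) {
    set.seed(training$seed)
    fold <- integer(length(labels))
    for (k in unique(y_idx)) {
      idx <- which(y_idx == k)
      fold[idx] <- sample(rep_len(seq_len(cv_folds), length(idx)))
    }
    fold_metrics <- purrr::map_dfr(seq_len(cv_folds), function(fd) {
      tr <- fold != fd
      set.seed(training$seed + fd)
      params <- lstm_init(cfg)
      params <- adam_fit(params, x[tr, , , drop = FALSE], y_idx[tr],
                         cfg$n_classes, training)
      probs <- lstm_forward(params, x[!tr, , , drop = FALSE])$probs
      pred <- cfg$classes[max.col(probs, ties.method = "first")]
      counts <- label_confusion(labels[!tr], pred, cfg$classes)
      dplyr::mutate(precision_recall_f1(counts), fold = fd,
                    .before = 1)
    })
  }
  set.seed(training$seed)
  params <- lstm_init(cfg)
  params <- adam_fit(params, x, y_idx, cfg$n_classes, training)
  model$params <- params
  model$training <- training
  model$fold_metrics <- fold_metrics
  model
}

#' Classify normalized windows into posture events
#'
#' Runs the forward pass and emits one Level-1 posture event per window; the
#' posture is the argmax of the softmax distribution, ties broken toward the
#' lowest-ordered class of [posture_classes()]. Values outside `[0, 1]`
#' raise a warning and are clipped.
#'
#' @param model A fitted `posture_model`.
#' @param x Input tensor `n x timesteps x features`, or a normalized window
#'   tibble from [normalize_windows()] (whose `start_t` supplies `t`).
#' @param subject_id Subject identifier for the emitted events.
#' @param t Event timestamps (seconds); required for tensor input, defaults
#'   to `start_t` for window input.
#' @return A tibble of posture events with one probability column
#'   `p_<class>` per class.
#' @export
predict_posture <- function(model, x, subject_id = "dog1", t = NULL) {
  stopifnot(inherits(model, "posture_model"))
  if (is.null(model$params)) abort("model is untrained; call train_posture_model()")
  cfg <- model$config
  if (is.data.frame(x)) {
    t <- t %||% x$start_t
    x <- to_tensor(x)
  }
  x <- check_tensor(model, x)
  n <- dim(x)[1]
  if (is.null(t)) t <- seq_len(n) - 1
  probs <- lstm_forward(model$params, x)$probs
  pred <- cfg$classes[max.col(probs, ties.method = "first")]
  ev <- posture_events(subject_id, cfg$sensor, pred, t)
  colnames(probs) <- paste0("p_", cfg$classes)
  dplyr::bind_cols(ev, as_tibble(probs))
}

#' Classify a raw sensor log end to end
#'
#' Segments, normalizes and classifies a single-sensor log. Normalization
#' statistics default to a calibration prefix of the stream itself
#' (`calibration_s` seconds); pass the training-pool statistics explicitly
#' to reuse the deployment calibration.
#'
#' @param samples Single-sensor sample tibble.
#' @param model A fitted `posture_model` for that sensor.
#' @param subject_id Subject identifier.
#' @param stats Optional [fit_stats()] result; default fits on the prefix.
#' @param calibration_s Calibration prefix length, seconds.
#' @return A posture-event tibble (see [predict_posture()]).
#' @export
classify_stream <- function(samples, model, subject_id = "dog1", stats = NULL,
                            calibration_s = 60) {
  if (is.null(stats)) {
    prefix <- samples[samples$timestamp < samples$timestamp[1] + calibration_s, ]
    stats <- fit_stats(prefix)
  }
  win <- normalize_windows(segment_windows(samples), stats)
  if (nrow(win) == 0) {
    return(posture_events(character(), character(), character(), numeric()))
  }
  predict_posture(model, win, subject_id = subject_id)
}

#' Windowed statistical features
#'
#' The hand-crafted 12-value feature vector used by the baseline
#' classifiers: per-axis minimum, maximum, mean and standard deviation, in
#' axis-major order (x, then y, then z).
#'
#' @param windows A window tibble ([segment_windows()] or
#'   [normalize_windows()]).
#' @return A tibble with columns `<axis>_min`, `<axis>_max`, `<axis>_mean`,
#'   `<axis>_sd` for axes `ax`, `ay`, `az`, one row per window.
#' @export
extract_features <- function(windows) {
  purrr::map_dfr(windows$values, function(m) {
    if (!is.matrix(m) || ncol(m) != 3) {
      abort("window values must be timesteps x 3 matrices")
    }
    vals <- purrr::map(1:3, function(j) {
      v <- m[, j]
      c(min(v), max(v), mean(v), sd(v))
    })
    names <- as.vector(outer(c("min", "max", "mean", "sd"), axis_cols,
                             function(s, a) paste0(a, "_", s)))
    stats_vec <- unlist(vals)
    names(stats_vec) <- names
    as_tibble(as.list(stats_vec))
  })
}

#' Statistical-feature baseline classifiers
#'
#' Trains an SVM (RBF kernel), naive Bayes or decision tree on the 12
#' windowed statistical features, for comparison with the recurrent
#' classifier.
#'
#' @param features Feature tibble from [extract_features()].
#' @param labels Character posture labels, at least two classes.
#' @param kind `"svm"`, `"naive_bayes"` or `"decision_tree"`.
#' @param seed RNG seed (fits are deterministic given the seed).
#' @return An `sa_baseline` model object.
#' @export
train_baseline <- function(features, labels,
                           kind = c("svm", "naive_bayes", "decision_tree"),
                           seed = 1) {
  kind <- match.arg(kind)
  labels <- factor(as.character(labels))
  if (nlevels(labels) < 2) abort("need at least two classes to fit a baseline")
  df <- as.data.frame(features)
  set.seed(seed)
  fit <- switch(kind,
    svm = e1071::svm(df, labels, kernel = "radial"),
    naive_bayes = e1071::naiveBayes(df, labels),
    decision_tree = rpart::rpart(label ~ ., data = cbind(df, label = labels),
                                 method = "class"))
  structure(list(kind = kind, fit = fit, classes = levels(labels),
                 feature_names = names(df)),
            class = "sa_baseline")
}

#' @rdname train_baseline
#' @param object An `sa_baseline`.
#' @param newdata Feature tibble.
#' @param ... Unused.
#' @export
predict.sa_baseline <- function(object, newdata, ...) {
  df <- as.data.frame(newdata)[, object$feature_names]
  out <- switch(object$kind,
    svm = predict(object$fit, df),
    naive_bayes = predict(object$fit, df),
    decision_tree = {
      p <- predict(object$fit, df, type = "class")
      p
    })
  as.character(out)
}

#' Save and load posture model checkpoints
#'
#' Single-file checkpoints with a versioned header; refuses to load files
#' written in another format.
#'
#' @param model A `posture_model`.
#' @param path File path.
#' @return `load_model()`: the `posture_model`; `save_model()`: `path`,
#'   invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "posture_model"))
  saveRDS(list(format = "sawatch-posture-model", version = 1L, model = model),
          path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "sawatch-posture-model")) {
    abort("not a sawatch posture model checkpoint")
  }
  obj$model
}

#' @export
print.posture_model <- function(x, ...) {
  cfg <- x$config
  cat("Stacked LSTM posture classifier (", cfg$sensor, " sensor)\n",
      "  ", cfg$layers, " recurrent layers x ", cfg$units, " units, input ",
      cfg$timesteps, " x ", cfg$features, ", classes: ",
      paste(cfg$classes, collapse = ", "), "\n",
      "  ", if (is.null(x$params)) "untrained" else "trained", "\n", sep = "")
  invisible(x)
}

#' Tidy methods for fitted posture models
#'
#' `tidy()` returns the per-fold, per-class cross-validation metrics;
#' `glance()` a one-row summary with the macro-averaged F1.
#'
#' @param x A fitted `posture_model`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.posture_model <- function(x, ...) {
  if (is.null(x$fold_metrics)) {
    abort("model has no cross-validation metrics (trained with cv_folds = 0?)")
  }
  x$fold_metrics
}

#' @rdname tidy.posture_model
#' @export
glance.posture_model <- function(x, ...) {
  cfg <- x$config
  macro <- if (is.null(x$fold_metrics)) NA_real_ else {
    x$fold_metrics |>
      dplyr::filter(.data$class == "Average") |>
      dplyr::pull(.data$f1) |>
      mean()
  }
  tibble(sensor = cfg$sensor, layers = cfg$layers, units = cfg$units,
         n_classes = cfg$n_classes,
         epochs = if (is.null(x$training)) NA_integer_ else x$training$epochs,
         folds = if (is.null(x$fold_metrics)) 0L else
           max(x$fold_metrics$fold),
         macro_f1 = macro)
}

#' @rdname tidy.posture_model
#' @param object A fitted `posture_model` with cross-validation metrics.
#' @export
autoplot.posture_model <- function(object, ...) {
  tidy(object) |>
    dplyr::filter(.data$class != "Average") |>
    ggplot2::ggplot(ggplot2::aes(.data$class, .data$f1)) +
    ggplot2::geom_boxplot() +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$fold))) +
    ggplot2::labs(x = NULL, y = "F1 (per fold)", colour = "fold",
                  title = paste0("Cross-validated posture recognition (",
                                 object$config$sensor, " sensor)"))
}

#' Generate a labeled synthetic training set for one sensor
#'
#' Synthesizes `windows_per_class` seconds of signal per posture class of
#' the sensor, pools them to fit min-max statistics, and returns the
#' normalized tensor with labels — the study-sized training input for
#' [train_posture_model()].
#'
#' @param sensor `"head"` or `"body"`.
#' @param windows_per_class One-second windows per posture class.
#' @param seed RNG seed.
#' @param templates Signal templates ([signal_templates()]).
#' @return A list: `x` (tensor), `labels`, `stats` (the pooled
#'   normalization statistics to reuse at inference).
#' @export
synthetic_training_set <- function(sensor, windows_per_class = 100, seed = 1,
                                   templates = signal_templates()) {
  sensor <- match.arg(sensor, sensor_ids())
  classes <- posture_classes(sensor)
  set.seed(seed)
  logs <- purrr::map(classes, function(cl) {
    generate_posture_signal(cl, windows_per_class, seed = NULL,
                            templates = templates)
  })
  stats <- fit_stats(dplyr::bind_rows(logs))
  wins <- purrr::map(logs, ~ normalize_windows(segment_windows(.x), stats))
  x <- to_tensor(dplyr::bind_rows(wins))
  labels <- rep(classes, purrr::map_int(wins, nrow))
  list(x = x, labels = labels, stats = stats)
}
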