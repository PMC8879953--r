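test_that("posture signals follow their template and are seed-deterministic", {
  lie <- generate_posture_signal("Lie", 2, seed = 3)
  expect_equal(nrow(lie), 100)
  tpl <- signal_templates()
  tpl_lie <- tpl[tpl$posture == "Lie", ]
  # static pose: spread stays within twice the noise sigma
  expect_lte(sd(lie$ax), 2 * tpl_lie$sigma)
  expect_lte(abs(mean(lie$ax) - tpl_lie$bx), 4 * tpl_lie$sigma / sqrt(100))
  expect_identical(generate_posture_signal("Lie", 2, seed = 3), lie)
  expect_error(generate_posture_signal("Moonwalk", 1, seed = 1), "unknown")
})

test_that("gait oscillation dominates the spectrum at the template frequency", {
  walk <- generate_posture_signal("Walk", 10, seed = 4)
  tpl <- signal_templates()
  f_gait <- tpl$freq_hz[tpl$posture == "Walk"]
  z <- walk$az - mean(walk$az)
  spec <- Mod(fft(z))[2:(length(z) / 2)]         # discrete Fourier oracle
  freqs <- (seq_along(spec)) * 50 / length(z)
  expect_equal(freqs[which.max(spec)], f_gait, tolerance = 1e-9)
})

test_that("templates keep same-sensor classes at least 4 sigma apart", {
  tpl <- signal_templates()
  for (s in sensor_ids()) {
    sub <- tpl[tpl$sensor_id == s, ]
    base <- as.matrix(sub[, c("bx", "by", "bz")])
    for (i in seq_len(nrow(sub) - 1)) {
      for (j in (i + 1):nrow(sub)) {
        gap <- max(abs(base[i, ] - base[j, ]))
        expect_gte(gap, 4 * sub$sigma[i])
      }
    }
  }
})

test_that("scripts validate ordering and expand with gap filling", {
  expect_error(scenario_script(c("Walking", "Lying"), c(0, 5), c(10, 10)),
               "overlap")
  expect_error(scenario_script("Walking", 0, 0), "positive")
  expect_error(scenario_script("Moonwalking", 0, 10), "unknown")
  sc <- scenario_script(c("Walking", "Barking"), c(0, 20), c(10, 10),
                        seed = 2)
  out <- script_to_streams(sc)
  expect_equal(out$duration, 30)
  expect_equal(nrow(out$head), 30 * 50)
  expect_equal(nrow(out$body), 30 * 50)
  l1 <- out$truth$l1
  body <- l1[l1$sensor_id == "body", ]
  expect_equal(body$posture[body$t %in% 10:19], rep("Lie", 10))  # gap filler
  empty <- script_to_streams(scenario_script(character(), numeric(),
                                             numeric()))
  expect_equal(empty$duration, 0)
  expect_equal(nrow(empty$head), 0)
  expect_equal(nrow(empty$truth$l3), 0)
})

test_that("scripted symptomatic windows carry Abnormal ground truth", {
  filled <- scenario_script(c("Walking", "Sniffing"), c(0, 7), c(7, 8),
                            seed = 6)
  truth <- script_to_streams(filled)$truth
  expl <- truth$l3[truth$l3$behavior == "Exploratory", ]
  expect_equal(expl$d, "Abnormal")
  quiet <- script_to_streams(scenario_script("Lying", 0, 15, seed = 6))$truth
  expect_true(all(quiet$l3$d == "Normal"))
})

test_that("generated streams are consistent with their own ground truth", {
  for (seed in c(14, 15)) {
    sc <- script_to_streams(scenario_preset("sa_episode", seed = seed))
    redo <- run_hierarchy(sc$truth$l1, t_end = sc$duration)
    expect_equal(as.data.frame(redo$l2), as.data.frame(sc$truth$l2))
    expect_equal(as.data.frame(redo$l3), as.data.frame(sc$truth$l3))
  }
})

test_that("script expansion is fully seed-deterministic", {
  a <- script_to_streams(scenario_preset("sa_episode", seed = 10))
  b <- script_to_streams(scenario_preset("sa_episode", seed = 10))
  expect_identical(a, b)
  c <- script_to_streams(scenario_preset("sa_episode", seed = 11))
  expect_false(identical(a$head, c$head))
})

test_that("window slicing counts follow the closed-form formula", {
  s <- generate_posture_signal("Walk", 4, seed = 1)
  expect_equal(length(window_slice_augment(s[1:200, ], 100, 0.5)), 3)
  expect_equal(length(window_slice_augment(s[1:100, ], 100, 0.5)), 1)
  expect_equal(length(window_slice_augment(s[1:99, ], 100, 0.5)), 0)
  sl <- window_slice_augment(s[1:200, ], 100, 0.5)
  expect_equal(sl[[2]]$frame_number[1], 51)
  expect_equal(nrow(sl[[3]]), 100)
  expect_error(window_slice_augment(s, 100, 1), "overlap")
  expect_error(window_slice_augment(s, 0, 0.5), "width")
})

test_that("a features classifier separates default templates near-perfectly", {
  set.seed(77)
  classes <- posture_classes("body")
  logs <- lapply(classes, function(cl)
    generate_posture_signal(cl, 100, seed = NULL))
  stats <- fit_stats(dplyr::bind_rows(logs))
  wins <- dplyr::bind_rows(lapply(logs, function(l)
    normalize_windows(segment_windows(l), stats)))
  labels <- rep(classes, each = 100)
  fv <- extract_features(wins)
  fit <- train_baseline(fv, labels, kind = "svm", seed = 1)
  counts <- label_confusion(labels, predict(fit, fv), classes)
  rep <- precision_recall_f1(counts)
  expect_gte(rep$f1[rep$class == "Average"], 0.95)
})
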