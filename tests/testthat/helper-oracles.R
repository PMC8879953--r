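# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: plain loops instead of the engine's run/consume
# bookkeeping, direct summation instead of vectorized statistics, and a
# separate fine-grid integrator for centroids.

# Brute-force atomic-behavior matcher: enumerates every (window start, rule)
# pair and scans events linearly, with its own consumption bookkeeping.
oracle_scan_atomic <- function(l1, rules = default_rules()) {
  l1 <- as.data.frame(l1)
  l1 <- l1[order(l1$t), ]
  arules <- rules[rules$kind %in% c("repeat_c1", "follow_c2"), ]
  out <- data.frame(subject_id = character(), behavior = character(),
                    ts = numeric(), te = numeric())
  for (sid in unique(l1$subject_id)) {
    ev <- l1[l1$subject_id == sid, ]
    consumed <- matrix(FALSE, nrow(ev), nrow(arules))
    for (w0 in seq(floor(min(ev$t)), floor(max(ev$t)))) {
      for (r in seq_len(nrow(arules))) {
        rule <- arules[r, ]
        hit <- integer(0)
        if (rule$kind == "repeat_c1") {
          # walk the sensor's events in time order, tracking the current
          # uninterrupted run of operand-class events
          run <- integer(0)
          for (i in seq_len(nrow(ev))) {
            if (ev$sensor_id[i] != rule$sensor1) next
            if (ev$t[i] < w0 || ev$t[i] >= w0 + rule$window_s) next
            if (ev$posture[i] %in% rule$operand1[[1]]) {
              run <- c(run, i)
            } else {
              avail <- run[!consumed[run, r]]
              if (length(hit) == 0 && length(avail) >= 2) hit <- avail
              run <- integer(0)
            }
          }
          avail <- run[!consumed[run, r]]
          if (length(hit) == 0 && length(avail) >= 2) hit <- avail
        } else {
          found <- FALSE
          for (i in seq_len(nrow(ev))) {
            if (found) break
            if (ev$sensor_id[i] != rule$sensor1) next
            if (ev$t[i] < w0 || ev$t[i] >= w0 + rule$window_s) next
            if (!(ev$posture[i] %in% rule$operand1[[1]])) next
            if (consumed[i, r]) next
            for (j in seq_len(nrow(ev))) {
              if (ev$sensor_id[j] != rule$sensor2) next
              if (ev$t[j] <= ev$t[i] || ev$t[j] >= w0 + rule$window_s) next
              if (!(ev$posture[j] %in% rule$operand2[[1]])) next
              if (consumed[j, r]) next
              hit <- c(i, j)
              found <- TRUE
              break
            }
          }
        }
        if (length(hit)) {
          consumed[hit, r] <- TRUE
          out <- rbind(out, data.frame(subject_id = sid,
                                       behavior = rule$output,
                                       ts = ev$t[hit[1]],
                                       te = ev$t[hit[1]] + rule$window_s))
        }
      }
    }
  }
  out[order(out$ts, out$behavior), ]
}

# Random 1 Hz two-sensor posture stream.
random_l1_stream <- function(seconds, subject_id = "dog") {
  t <- seq_len(seconds) - 1
  dplyr::arrange(dplyr::bind_rows(
    posture_events(subject_id, "head",
                   sample(posture_classes("head"), seconds, replace = TRUE),
                   t),
    posture_events(subject_id, "body",
                   sample(posture_classes("body"), seconds, replace = TRUE),
                   t)), t)
}

# Independent centroid: evaluates the clipped-and-combined membership
# function from the raw activation levels and set breakpoints, then
# integrates on a fine midpoint grid.
oracle_centroid <- function(levels, output = default_diagnosis_variable(),
                            step = 1e-5) {
  trap <- function(x, a, b, c, d) {
    y <- numeric(length(x))
    if (b > a) {
      r <- x >= a & x < b
      y[r] <- (x[r] - a) / (b - a)
    }
    y[x >= b & x <= c] <- 1
    if (d > c) {
      f <- x > c & x <= d
      y[f] <- (d - x[f]) / (d - c)
    }
    y
  }
  x <- seq(output$universe[1] + step / 2, output$universe[2] - step / 2,
           by = step)
  mu <- numeric(length(x))
  for (nm in names(levels)) {
    bp <- output$sets[output$sets$set == nm, ]
    mu <- pmax(mu, pmin(levels[[nm]], trap(x, bp$a, bp$b, bp$c, bp$d)))
  }
  sum(x * mu) / sum(mu)
}

# Random scenario script of 15-s-aligned segments totalling 60-300 s.
random_script <- function(seed, noise = 0) {
  set.seed(seed)
  n_seg <- sample(4:10, 1)
  behaviors <- sample(c(atomic_classes(), complex_classes()), n_seg,
                      replace = TRUE)
  durations <- sample(c(15, 15, 30), n_seg, replace = TRUE)
  total <- cumsum(durations)
  keep <- total <= 300
  scenario_script(behaviors[keep], c(0, head(total[keep], -1)),
                  durations[keep], noise = noise, seed = seed)
}
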