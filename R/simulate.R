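# Seeded synthetic data at every hierarchy level: per-posture 50 Hz signal
# templates (orientation offset + sinusoid + Gaussian noise), scripted
# behavior timelines expanded to two synchronized sensor streams, and
# three-level ground truth computed with the package's own rule set and
# fuzzy engine. Realism is deliberately minimal -- enough to exercise the
# pipeline, not to mimic canine biomechanics.

#' Per-posture signal templates
#'
#' Each posture class has a baseline orientation vector (arbitrary
#' accelerometer units, roughly gravity-scaled), an oscillation amplitude
#' and frequency (0 for static poses; well below the 25 Hz Nyquist limit of
#' 50 Hz sampling) and a Gaussian noise sigma. Baselines of classes sharing
#' a sensor are separated by at least 4 sigma on some axis, so classes are
#' separable in windowed statistical features by construction.
#'
#' @param sigma Noise standard deviation applied to every template.
#' @return A tibble with columns `sensor_id`, `posture`, `bx`, `by`, `bz`
#'   (baseline), `amp`, `freq_hz`, `sigma`.
#' @export
signal_templates <- function(sigma = 0.05) {
  stopifnot(sigma >= 0)
  tibble(
    sensor_id = c(rep("head", 3), rep("body", 6)),
    posture = c("Up", "Down", "Bark",
                "Walk", "Lie", "Sit", "Stand", "Dig", "Jump"),
    bx = c(0.00, 0.80, 0.35, 0.00, 0.90, 0.00, 0.30, 0.00, 0.00),
    by = c(0.30, 0.00, 0.20, 0.00, 0.00, 0.55, 0.10, 0.35, -0.50),
    bz = c(0.95, 0.45, 0.80, 1.00, 0.30, 0.80, 0.95, 0.70, 0.80),
    amp = c(0, 0, 0.5, 0.4, 0, 0, 0, 0.6, 1.0),
    freq_hz = c(0, 0, 5.0, 2.5, 0, 0, 0, 4.0, 1.5),
    sigma = sigma
  )
}

#' Generate a synthetic single-posture sensor signal
#'
#' Draws `50 * seconds` samples of the posture's template: baseline plus a
#' sinusoid (on the z axis, with a half-amplitude copy on x) plus i.i.d.
#' Gaussian noise. Deterministic for a given seed.
#'
#' @param posture A posture class (see [posture_classes()]).
#' @param seconds Positive duration in seconds.
#' @param seed Integer RNG seed; `NULL` continues the current RNG stream.
#' @param templates Template tibble ([signal_templates()]).
#' @param t0 Timestamp of the first sample.
#' @param rate_hz Sampling rate.
#' @return A sample tibble (`sensor_id`, `frame_number`, `timestamp`, `ax`,
#'   `ay`, `az`).
#' @examples
#' generate_posture_signal("Lie", seconds = 1, seed = 42)
#' @export
generate_posture_signal <- function(posture, seconds, seed = NULL,
                                    templates = signal_templates(), t0 = 0,
                                    rate_hz = 50) {
  stopifnot(seconds > 0)
  tpl <- templates[templates$posture == posture, ]
  if (nrow(tpl) != 1) abort(paste0("unknown posture class: ", posture))
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(round(rate_hz * seconds))
  tt <- t0 + (seq_len(n) - 1) / rate_hz
  phase <- 2 * pi * tpl$freq_hz * tt
  tibble(
    sensor_id = tpl$sensor_id,
    frame_number = seq_len(n),
    timestamp = tt,
    ax = tpl$bx + 0.5 * tpl$amp * sin(phase) + rnorm(n, 0, tpl$sigma),
    ay = tpl$by + rnorm(n, 0, tpl$sigma),
    az = tpl$bz + tpl$amp * sin(phase) + rnorm(n, 0, tpl$sigma)
  )
}

# Per-second (head, body) posture expansion of each scriptable behavior.
# Complex behaviors repeat their related atomic behaviors at high frequency.
behavior_posture_plan <- function(behavior, n_seconds) {
  sec <- seq_len(n_seconds) - 1
  alt2 <- function(a, b) ifelse(sec %% 4 < 2, a, b)  # 2-s alternating blocks
  plan <- switch(behavior,
    Walking = tibble(head = "Up", body = "Walk"),
    Lying = tibble(head = "Up", body = "Lie"),
    Sitting = tibble(head = "Up", body = "Sit"),
    Standing = tibble(head = "Up", body = "Stand"),
    Digging = tibble(head = "Down", body = "Dig"),
    Escaping = tibble(head = "Up", body = "Jump"),
    Barking = tibble(head = "Bark", body = "Stand"),
    Sniffing = tibble(head = "Down",
                      body = ifelse(sec %% 2 == 0, "Walk", "Stand")),
    Destructive = tibble(head = "Down", body = alt2("Dig", "Jump")),
    Exploratory = tibble(head = alt2("Up", "Down"),
                         body = ifelse(sec %% 4 < 2, "Walk",
                                       ifelse(sec %% 2 == 0, "Walk", "Stand"))),
    Vocalization = tibble(head = "Bark", body = "Stand"),
    abort(paste0("unknown scripted behavior: ", behavior))
  )
  tibble(second = sec, head = rep_len(plan$head, n_seconds),
         body = rep_len(plan$body, n_seconds))
}

scriptable_behaviors <- function() {
  c(atomic_classes(), complex_classes())
}

#' Script a behavior timeline
#'
#' A scenario script lists non-overlapping, time-ordered behavior segments
#' (atomic or complex classes) with integer-second starts and durations.
#' Gaps between segments are filled with Lying when the script is expanded.
#'
#' @param behavior Character vector of behavior labels (see
#'   [atomic_classes()] and [complex_classes()]).
#' @param start,duration Integer seconds.
#' @param subject_id Subject identifier.
#' @param noise Gaussian noise sigma of the generated signals.
#' @param seed Integer RNG seed.
#' @return A `scenario_script` tibble with the segments plus attributes
#'   `subject_id`, `noise`, `seed`.
#' @examples
#' scenario_script(c("Walking", "Destructive"), start = c(0, 30),
#'                 duration = c(30, 30), seed = 1)
#' @export
scenario_script <- function(behavior, start, duration, subject_id = "dog1",
                            noise = 0.05, seed = 1) {
  seg <- tibble(behavior = as.character(behavior),
                start = as.numeric(start), duration = as.numeric(duration))
  bad <- setdiff(seg$behavior, scriptable_behaviors())
  if (length(bad)) abort(paste0("unknown scripted behavior: ",
                                paste(bad, collapse = ", ")))
  if (any(seg$duration <= 0)) abort("segment durations must be positive")
  seg <- dplyr::arrange(seg, .data$start)
  if (nrow(seg) > 1 &&
      any(seg$start[-1] < (seg$start + seg$duration)[-nrow(seg)])) {
    abort("script segments must not overlap")
  }
  structure(seg, subject_id = subject_id, noise = noise, seed = seed,
            class = c("scenario_script", class(tibble())))
}

#' Preset scenario scripts
#'
#' `"normal_day"` is a calm routine (lying, sitting, short walks, standing);
#' `"sa_episode"` interleaves separation-anxiety symptomatic episodes
#' (destructive, exploratory, vocalization blocks) with calm stretches.
#'
#' @param preset `"normal_day"` or `"sa_episode"`.
#' @param seed,noise,subject_id Passed to [scenario_script()].
#' @return A `scenario_script`.
#' @export
scenario_preset <- function(preset = c("normal_day", "sa_episode"), seed = 1,
                            noise = 0.05, subject_id = "dog1") {
  preset <- match.arg(preset)
  seg <- switch(preset,
    normal_day = tibble(
      behavior = c("Lying", "Sitting", "Walking", "Standing", "Lying",
                   "Walking", "Sitting", "Standing", "Lying"),
      start = c(0, 30, 45, 48, 60, 90, 93, 105, 120),
      duration = c(30, 15, 3, 12, 30, 3, 12, 15, 30)),
    sa_episode = tibble(
      behavior = c("Standing", "Exploratory", "Vocalization", "Walking",
                   "Lying", "Destructive", "Lying", "Exploratory",
                   "Destructive"),
      start = c(0, 15, 45, 60, 63, 75, 105, 120, 135),
      duration = c(15, 30, 15, 3, 12, 30, 15, 15, 15)))
  scenario_script(seg$behavior, seg$start, seg$duration,
                  subject_id = subject_id, noise = noise, seed = seed)
}

#' Expand a scenario script into sensor streams and ground truth
#'
#' Expands every segment into its defining per-second head and body posture
#' plan (e.g. Sniffing alternates body Walk/Stand under a lowered head;
#' Destructive repeats Digging and Escaping blocks), fills gaps with Lying,
#' synthesizes both 50 Hz sensor logs from the posture templates, and
#' computes ground truth at all three levels by running the supplied rule
#' set and fuzzy engine on the intended (noise-free) posture labels.
#'
#' @param script A [scenario_script()].
#' @param templates Signal templates ([signal_templates()]); segment noise is
#'   taken from the script.
#' @param rules,engine Rule set and fuzzy engine defining the ground truth.
#' @return A list: `head` and `body` sample tibbles, `truth` (list of `l1`
#'   posture events, `l2`/`l3` event channels), and `duration` (seconds).
#' @examples
#' sc <- script_to_streams(scenario_preset("sa_episode", seed = 7))
#' sc$truth$l3
#' @export
script_to_streams <- function(script, templates = signal_templates(),
                              rules = default_rules(),
                              engine = fuzzy_engine()) {
  subject <- attr(script, "subject_id") %||% "dog1"
  noise <- attr(script, "noise") %||% 0.05
  seed <- attr(script, "seed") %||% 1
  empty <- list(
    head = generate_posture_signal("Up", 1, seed = 0)[0, ],
    body = generate_posture_signal("Walk", 1, seed = 0)[0, ],
    truth = list(l1 = posture_events(character(), character(), character(),
                                     numeric()),
                 l2 = event_channel("L2"), l3 = event_channel("L3")),
    duration = 0)
  if (nrow(script) == 0) return(empty)
  duration <- max(script$start + script$duration)
  # per-second posture plan over the whole timeline, gaps filled with Lying
  plan <- tibble(second = 0:(duration - 1), head = "Up", body = "Lie")
  for (i in seq_len(nrow(script))) {
    p <- behavior_posture_plan(script$behavior[i], script$duration[i])
    rows <- script$start[i] + p$second + 1
    plan$head[rows] <- p$head
    plan$body[rows] <- p$body
  }
  tpl <- dplyr::mutate(templates, sigma = noise)
  set.seed(seed)
  gen_stream <- function(col, sensor) {
    runs <- rle(plan[[col]])
    t0s <- c(0, cumsum(runs$lengths))[seq_along(runs$lengths)]
    parts <- purrr::map2(runs$values, seq_along(runs$values), function(p, k) {
      generate_posture_signal(p, runs$lengths[k], seed = NULL,
                              templates = tpl, t0 = t0s[k])
    })
    out <- dplyr::bind_rows(parts)
    out$frame_number <- seq_len(nrow(out))
    out
  }
  head_log <- gen_stream("head", "head")
  body_log <- gen_stream("body", "body")
  l1 <- dplyr::bind_rows(
    posture_events(subject, "head", plan$head, plan$second),
    posture_events(subject, "body", plan$body, plan$second)) |>
    dplyr::arrange(.data$t)
  hier <- run_hierarchy(l1, rules, engine, origin = 0, t_end = duration)
  list(head = head_log, body = body_log,
       truth = list(l1 = l1, l2 = hier$l2, l3 = hier$l3),
       duration = duration)
}

#' Window-slicing augmentation
#'
#' Cuts an augmentation sequence of fixed-width, overlapping slices out of a
#' sample stream: slices start every `width * (1 - overlap)` samples, so a
#' 200-sample stream with width 100 and 50% overlap yields 3 slices at
#' offsets 0, 50 and 100.
#'
#' @param samples A sample tibble (or any data frame of consecutive rows).
#' @param width Slice width in samples (`>= 1`).
#' @param overlap Fractional overlap between consecutive slices, in `[0, 1)`.
#' @return A list of sample tibbles of `width` rows each; empty if the input
#'   is shorter than `width`.
#' @export
window_slice_augment <- function(samples, width = 100, overlap = 0.5) {
  if (!is.numeric(width) || width < 1) abort("width must be >= 1")
  if (!is.numeric(overlap) || overlap < 0 || overlap >= 1) {
    abort("overlap must be in [0, 1)")
  }
  n <- nrow(samples)
  if (n < width) return(list())
  stride <- max(1L, as.integer(round(width * (1 - overlap))))
  offsets <- seq(0L, n - width, by = stride)
  purrr::map(offsets, ~ samples[(.x + 1):(.x + width), ])
}
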