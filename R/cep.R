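# Complex-event-processing core. Two-second repeat (C1) and follow (C2)
# pattern rules turn the 1 Hz posture stream into atomic behavior events;
# a 15-s aggregation rule (A) per complex behavior computes the coverage
# fraction of its related atomic behaviors and hands it to the fuzzy engine.

#' The default behavior pattern-rule set
#'
#' Eight atomic rules and three complex rules:
#' * C1 (repeat): an atomic behavior is emitted when the same posture is
#'   held, without any change, for the 2-s observation window — Walking from
#'   Walk, Lying from Lie, Sitting from Sit, Standing from Stand, Digging
#'   from Dig, Escaping from repeated Jump, Barking from repeated Bark.
#' * C2 (follow): Sniffing is emitted when a body Walk or Stand posture is
#'   followed, within 2 s, by a head Down posture.
#' * A (aggregate): over a 15-s window, Destructive collects Escaping and
#'   Digging, Exploratory collects Walking and Sniffing, and Vocalization
#'   collects Barking; the coverage fraction feeds the fuzzy diagnosis.
#'
#' @param sniffing_first Posture classes accepted as the first element of the
#'   Sniffing follow rule (`c("Walk", "Stand")` by default).
#' @return A rule tibble with columns `kind` (`repeat_c1`, `follow_c2`,
#'   `aggregate_a`), `output`, `window_s`, `sensor1`, `sensor2`, and
#'   list-columns `operand1`, `operand2`.
#' @examples
#' default_rules()
#' @export
default_rules <- function(sniffing_first = c("Walk", "Stand")) {
  c1 <- tibble(
    kind = "repeat_c1",
    output = c("Walking", "Lying", "Sitting", "Standing", "Digging",
               "Escaping", "Barking"),
    window_s = 2,
    sensor1 = c(rep("body", 6), "head"),
    sensor2 = NA_character_,
    operand1 = as.list(c("Walk", "Lie", "Sit", "Stand", "Dig", "Jump",
                         "Bark")),
    operand2 = list(NULL))
  c2 <- tibble(kind = "follow_c2", output = "Sniffing", window_s = 2,
               sensor1 = "body", sensor2 = "head",
               operand1 = list(sniffing_first), operand2 = list("Down"))
  agg <- tibble(
    kind = "aggregate_a",
    output = complex_classes(),
    window_s = 15,
    sensor1 = NA_character_, sensor2 = NA_character_,
    operand1 = list(c("Escaping", "Digging"), c("Walking", "Sniffing"),
                    "Barking"),
    operand2 = list(NULL))
  dplyr::bind_rows(c1, c2, agg)
}

#' Read and write rule sets as YAML
#'
#' Human-editable serialization of a rule tibble; `write_rules(default_rules(),
#' path)` round-trips exactly.
#'
#' @param rules A rule tibble ([default_rules()]).
#' @param path File path.
#' @return `read_rules()`: a rule tibble; `write_rules()`: `path`, invisibly.
#' @export
write_rules <- function(rules, path) {
  lst <- purrr::pmap(rules, function(kind, output, window_s, sensor1, sensor2,
                                     operand1, operand2) {
    r <- list(kind = kind, output = output, window_s = window_s)
    if (!is.na(sensor1)) r$sensor1 <- sensor1
    if (!is.na(sensor2)) r$sensor2 <- sensor2
    r$operand1 <- as.list(operand1)
    if (!is.null(operand2)) r$operand2 <- as.list(operand2)
    r
  })
  yaml::write_yaml(list(rules = lst), path)
  invisible(path)
}

#' @rdname write_rules
#' @export
read_rules <- function(path) {
  lst <- yaml::read_yaml(path)$rules
  purrr::map_dfr(lst, function(r) {
    tibble(kind = r$kind, output = r$output, window_s = r$window_s,
           sensor1 = r$sensor1 %||% NA_character_,
           sensor2 = r$sensor2 %||% NA_character_,
           operand1 = list(unlist(r$operand1)),
           operand2 = list(if (is.null(r$operand2)) NULL
                           else unlist(r$operand2)))
  })
}

# Run-based matcher shared by match_c1() and scan_atomic(). `avail` marks
# events of the rule's sensor still unconsumed for the rule's output class.
# A maximal run of operand-class events (uninterrupted by any other posture
# of the same sensor inside the window) matches when it holds >= 2 available
# events; those events are the match.
c1_match_idx <- function(postures, avail, operand) {
  is_op <- postures %in% operand
  run <- rle(is_op)
  ends <- cumsum(run$lengths)
  starts <- ends - run$lengths + 1
  for (k in seq_along(run$values)) {
    if (!run$values[k]) next
    idx <- seq(starts[k], ends[k])
    idx <- idx[avail[idx]]
    if (length(idx) >= 2) return(idx)
  }
  integer(0)
}

# Follow matcher: earliest available first-operand event on sensor1, then the
# earliest available second-operand event on sensor2 strictly later in time.
c2_match_idx <- function(tt, postures, sensors, avail, rule) {
  i1 <- which(sensors == rule$sensor1 & postures %in% rule$operand1[[1]] &
                avail)
  if (!length(i1)) return(integer(0))
  for (i in i1) {
    j <- which(sensors == rule$sensor2 & postures %in% rule$operand2[[1]] &
                 avail & tt > tt[i])
    if (length(j)) return(c(i, j[1]))
  }
  integer(0)
}

#' Match a single pattern rule inside one observation window
#'
#' `match_c1()` applies a repeat rule to a 2-s view of the Level-1 stream:
#' the output atomic behavior is emitted iff at least two consecutive events
#' of the operand posture, with no different posture from the same sensor in
#' between, occur in the window. `match_c2()` applies a follow rule: a first
#' posture (body Walk/Stand for Sniffing) must be followed strictly later by
#' the second posture (head Down) within the window. The emitted event has
#' `ts` equal to the first matched posture's timestamp and `te = ts +
#' window_s`.
#'
#' These are the pure single-window matchers; [scan_atomic()] adds window
#' sliding and event consumption.
#'
#' @param l1_view A window of Level-1 events for one subject (see
#'   [window_view()]).
#' @param rule One rule row of the matching kind (see [default_rules()]).
#' @return An atomic-event tibble with zero or one row.
#' @examples
#' l1 <- posture_events("d", "body", c("Dig", "Dig"), c(0, 1))
#' match_c1(l1, dplyr::filter(default_rules(), output == "Digging"))
#' @export
match_c1 <- function(l1_view, rule) {
  stopifnot(nrow(rule) == 1, rule$kind == "repeat_c1")
  v <- dplyr::arrange(as_tibble(l1_view), .data$t)
  v <- v[v$sensor_id == rule$sensor1, ]
  idx <- c1_match_idx(v$posture, rep(TRUE, nrow(v)), rule$operand1[[1]])
  if (!length(idx)) return(atomic_events(character(), character(),
                                         numeric(), numeric()))
  atomic_events(v$subject_id[idx[1]], rule$output, v$t[idx[1]],
                v$t[idx[1]] + rule$window_s)
}

#' @rdname match_c1
#' @export
match_c2 <- function(l1_view, rule) {
  stopifnot(nrow(rule) == 1, rule$kind == "follow_c2")
  v <- dplyr::arrange(as_tibble(l1_view), .data$t)
  idx <- c2_match_idx(v$t, v$posture, v$sensor_id, rep(TRUE, nrow(v)), rule)
  if (!length(idx)) return(atomic_events(character(), character(),
                                         numeric(), numeric()))
  atomic_events(v$subject_id[idx[1]], rule$output, v$t[idx[1]],
                v$t[idx[1]] + rule$window_s)
}

#' Detect atomic behaviors over a Level-1 stream
#'
#' Slides the 2-s observation window in 1-s steps over the sorted posture
#' stream and applies every atomic rule at every step. Each emitted event
#' consumes its matched posture events for that output class, so one posture
#' event contributes to at most one atomic event of a given class (four
#' seconds of Walk yield exactly two Walking events). Subjects are processed
#' independently; rules see only their own sensor's events (both sensors for
#' follow rules).
#'
#' @param l1_channel A sorted L1 [event_channel()] or posture-event tibble.
#' @param rules Rule tibble; only `repeat_c1`/`follow_c2` rows are used.
#' @return An L2 [event_channel()] sorted by `ts`.
#' @export
scan_atomic <- function(l1_channel, rules = default_rules()) {
  l1 <- as_tibble(l1_channel)
  if (nrow(l1) && is.unsorted(l1$t)) {
    abort("Level-1 channel must be sorted by timestamp")
  }
  out <- event_channel("L2")
  if (!nrow(l1)) return(out)
  arules <- rules[rules$kind %in% c("repeat_c1", "follow_c2"), ]
  res <- list()
  for (sid in unique(l1$subject_id)) {
    ev <- l1[l1$subject_id == sid, ]
    ev <- ev[order(ev$t), ]
    n <- nrow(ev)
    consumed <- matrix(FALSE, n, nrow(arules))
    starts <- seq(floor(min(ev$t)), floor(max(ev$t)), by = 1)
    for (w0 in starts) {
      in_win <- which(ev$t >= w0 & ev$t < w0 + 2)
      if (!length(in_win)) next
      for (r in seq_len(nrow(arules))) {
        rule <- arules[r, ]
        win <- in_win[ev$t[in_win] < w0 + rule$window_s]
        if (rule$kind == "repeat_c1") {
          sub <- win[ev$sensor_id[win] == rule$sensor1]
          hit <- sub[c1_match_idx(ev$posture[sub], !consumed[sub, r],
                                  rule$operand1[[1]])]
        } else {
          hit <- win[c2_match_idx(ev$t[win], ev$posture[win],
                                  ev$sensor_id[win], !consumed[win, r], rule)]
        }
        if (length(hit)) {
          consumed[hit, r] <- TRUE
          res[[length(res) + 1]] <-
            atomic_events(sid, rule$output, ev$t[hit[1]],
                          ev$t[hit[1]] + rule$window_s)
        }
      }
    }
  }
  if (length(res)) out <- publish(out, dplyr::bind_rows(res))
  out
}

#' Coverage fraction of atomic behaviors in an observation window
#'
#' The crisp input of the fuzzy diagnosis: the fraction of the 15-s
#' observation window covered by the union of the `[ts, te]` intervals of
#' the listed atomic behaviors, clipped to the window. Overlapping intervals
#' count once. A count-based alternative (`mode = "count"`: events divided
#' by the window's atomic-event capacity `window_s / 2`, capped at 1) is
#' retained for experimentation.
#'
#' @param l2_view A window of Level-2 events (see [window_view()]).
#' @param atomic_classes Character vector of contributing atomic classes.
#' @param t_start Window start; defaults to the floor of the earliest event
#'   start (0 for an empty view).
#' @param window_s Observation window length, seconds.
#' @param mode `"coverage"` (default) or `"count"`.
#' @return A one-row tibble with columns `ts`, `te`, `f`.
#' @export
coverage_fraction <- function(l2_view, atomic_classes, t_start = NULL,
                              window_s = 15, mode = c("coverage", "count")) {
  mode <- match.arg(mode)
  v <- as_tibble(l2_view)
  v <- v[v$behavior %in% atomic_classes, ]
  if (is.null(t_start)) t_start <- if (nrow(v)) floor(min(v$ts)) else 0
  t_end <- t_start + window_s
  lo <- pmax(v$ts, t_start)
  hi <- pmin(v$te, t_end)
  keep <- hi > lo
  lo <- lo[keep]
  hi <- hi[keep]
  if (mode == "count") {
    f <- min(1, length(lo) / (window_s / 2))
    return(tibble(ts = t_start, te = t_end, f = f))
  }
  if (!length(lo)) return(tibble(ts = t_start, te = t_end, f = 0))
  ord <- order(lo)
  lo <- lo[ord]
  hi <- hi[ord]
  total <- 0
  cur_lo <- lo[1]
  cur_hi <- hi[1]
  for (i in seq_along(lo)[-1]) {
    if (lo[i] <= cur_hi) {
      cur_hi <- max(cur_hi, hi[i])
    } else {
      total <- total + (cur_hi - cur_lo)
      cur_lo <- lo[i]
      cur_hi <- hi[i]
    }
  }
  total <- total + (cur_hi - cur_lo)
  tibble(ts = t_start, te = t_end, f = total / window_s)
}

#' Diagnose complex behaviors over a Level-2 stream
#'
#' Cuts the stream into consecutive tumbling 15-s observation windows
#' starting at `origin` and, for every window and every aggregation rule,
#' computes the coverage fraction of the rule's atomic classes, runs the
#' fuzzy pipeline (fuzzify, infer, center-of-gravity, threshold) and emits
#' one complex behavior event carrying the Normal/Abnormal symptom state.
#' All three complex behaviors are evaluated on every window.
#'
#' @param l2_channel A sorted L2 [event_channel()] or atomic-event tibble.
#' @param rules Rule tibble; only `aggregate_a` rows are used.
#' @param engine A [fuzzy_engine()].
#' @param origin Start of the first observation window, seconds.
#' @param t_end End of the monitored span; defaults to the latest event end
#'   rounded up to a whole window. Only complete windows are diagnosed.
#' @param mode Frequency mode passed to [coverage_fraction()].
#' @return An L3 [event_channel()].
#' @export
detect_complex <- function(l2_channel, rules = default_rules(),
                           engine = fuzzy_engine(), origin = 0, t_end = NULL,
                           mode = "coverage") {
  l2 <- as_tibble(l2_channel)
  if (nrow(l2) && is.unsorted(l2$ts)) {
    abort("Level-2 channel must be sorted by start time")
  }
  out <- event_channel("L3")
  crules <- rules[rules$kind == "aggregate_a", ]
  if (!nrow(l2) && is.null(t_end)) return(out)
  res <- list()
  subjects <- if (nrow(l2)) unique(l2$subject_id) else character()
  for (sid in subjects) {
    ev <- l2[l2$subject_id == sid, ]
    for (r in seq_len(nrow(crules))) {
      rule <- crules[r, ]
      w <- rule$window_s
      end_s <- t_end %||% (origin + w * ceiling((max(ev$te) - origin) / w))
      starts <- seq(origin, by = w, length.out = max(0, floor((end_s - origin) / w)))
      for (w0 in starts) {
        view <- ev[ev$ts >= w0 & ev$ts < w0 + w, ]
        fobs <- coverage_fraction(view, rule$operand1[[1]], t_start = w0,
                                  window_s = w, mode = mode)
        dg <- diagnose(fobs$f, rule$output, engine)
        res[[length(res) + 1]] <-
          complex_events(sid, rule$output, dg$d, w0, w0 + w)
      }
    }
  }
  if (length(res)) out <- publish(out, dplyr::bind_rows(res))
  out
}

#' Run the full behavior hierarchy
#'
#' Composes [scan_atomic()] and [detect_complex()]: posture events in,
#' atomic and complex behavior events out. Deterministic.
#'
#' @inheritParams scan_atomic
#' @inheritParams detect_complex
#' @param t_end End of the monitored span; defaults to one second past the
#'   last posture event (a posture observation covers one second).
#' @return A list with elements `l2` and `l3` ([event_channel()]s).
#' @export
run_hierarchy <- function(l1_channel, rules = default_rules(),
                          engine = fuzzy_engine(), origin = 0, t_end = NULL,
                          mode = "coverage") {
  l1 <- as_tibble(l1_channel)
  if (is.null(t_end) && nrow(l1)) t_end <- max(l1$t) + 1
  l2 <- scan_atomic(l1_channel, rules)
  l3 <- detect_complex(l2, rules, engine, origin = origin, t_end = t_end,
                       mode = mode)
  list(l2 = l2, l3 = l3)
}
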