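# Typed events for the three-level behavior hierarchy and the ordered,
# time-windowed channels that connect the processing stages.

#' Posture, behavior and sensor vocabularies
#'
#' The fixed class vocabularies of the three-level hierarchy. Head postures
#' are observed by the neck-mounted sensor, body postures by the back-mounted
#' sensor; each posture has a one-second observation time. Atomic behaviors
#' span two seconds and symptomatic complex behaviors fifteen seconds.
#'
#' @param sensor_id For `posture_classes()`, one of `"head"`, `"body"`, or
#'   `NULL` for the union (head classes first).
#' @return Character vector of class names, in the fixed enumeration order
#'   used everywhere in the package (e.g. for softmax tie-breaking).
#' @examples
#' posture_classes("head")
#' atomic_classes()
#' @export
posture_classes <- function(sensor_id = NULL) {
  head <- c("Up", "Down", "Bark")
  body <- c("Walk", "Lie", "Sit", "Stand", "Dig", "Jump")
  if (is.null(sensor_id)) return(c(head, body))
  switch(match.arg(sensor_id, c("head", "body")), head = head, body = body)
}

#' @rdname posture_classes
#' @export
atomic_classes <- function() {
  c("Sniffing", "Escaping", "Barking", "Walking",
    "Lying", "Sitting", "Standing", "Digging")
}

#' @rdname posture_classes
#' @export
complex_classes <- function() {
  c("Destructive", "Exploratory", "Vocalization")
}

#' @rdname posture_classes
#' @export
sensor_ids <- function() c("head", "body")

#' Observation time (seconds) of one hierarchy level
#' @param level `"L1"`, `"L2"` or `"L3"`.
#' @return Window length in seconds: 1, 2 or 15.
#' @export
observation_time <- function(level) {
  switch(match.arg(level, c("L1", "L2", "L3")), L1 = 1, L2 = 2, L3 = 15)
}

level_schema <- function(level) {
  switch(level,
    L1 = c(subject_id = "character", sensor_id = "character",
           posture = "character", t = "numeric"),
    L2 = c(subject_id = "character", behavior = "character",
           ts = "numeric", te = "numeric"),
    L3 = c(subject_id = "character", behavior = "character", d = "character",
           ts = "numeric", te = "numeric"))
}

time_col <- function(level) if (level == "L1") "t" else "ts"

#' Construct Level-1 posture events
#'
#' A posture event records one classified pose or motion of the head or body
#' at a given stream-relative time: `E(id, s, p, t)`. Inputs are recycled by
#' [tibble::tibble()], so vectors build a whole stream at once.
#'
#' @param subject_id Subject identifier (coerced to character).
#' @param sensor_id `"head"` or `"body"`.
#' @param posture Posture class, valid for the sensor (see
#'   [posture_classes()]).
#' @param t Timestamp in seconds since stream start, `>= 0`.
#' @return A tibble with columns `subject_id`, `sensor_id`, `posture`, `t`.
#' @examples
#' posture_events("dog1", "body", c("Walk", "Walk"), c(0, 1))
#' @export
posture_events <- function(subject_id, sensor_id, posture, t) {
  ev <- tibble(subject_id = as.character(subject_id),
               sensor_id = as.character(sensor_id),
               posture = as.character(posture), t = as.numeric(t))
  validate_events(ev, "L1")
  ev
}

#' Construct Level-2 atomic behavior events
#'
#' An atomic behavior event `E(id, ab, ts, te)` spans a start and end time
#' with `ts < te`; the default observation interval is 2 s.
#'
#' @inheritParams posture_events
#' @param behavior Atomic behavior class (see [atomic_classes()]).
#' @param ts,te Start and end timestamps in seconds, `ts < te`.
#' @return A tibble with columns `subject_id`, `behavior`, `ts`, `te`.
#' @export
atomic_events <- function(subject_id, behavior, ts, te) {
  ev <- tibble(subject_id = as.character(subject_id),
               behavior = as.character(behavior),
               ts = as.numeric(ts), te = as.numeric(te))
  validate_events(ev, "L2")
  ev
}

#' Construct Level-3 complex behavior events
#'
#' A symptomatic complex behavior event `E(id, cb, d, ts, te)` carries the
#' fuzzy diagnosis `d` (`"Normal"` or `"Abnormal"`) over a 15-s observation
#' window.
#'
#' @inheritParams atomic_events
#' @param behavior Complex behavior class (see [complex_classes()]).
#' @param d Symptom state, `"Normal"` or `"Abnormal"`.
#' @return A tibble with columns `subject_id`, `behavior`, `d`, `ts`, `te`.
#' @export
complex_events <- function(subject_id, behavior, d, ts, te) {
  ev <- tibble(subject_id = as.character(subject_id),
               behavior = as.character(behavior), d = as.character(d),
               ts = as.numeric(ts), te = as.numeric(te))
  validate_events(ev, "L3")
  ev
}

validate_events <- function(ev, level) {
  if (nrow(ev) == 0) return(invisible(ev))
  if (level == "L1") {
    bad <- !ev$sensor_id %in% sensor_ids()
    if (any(bad)) abort(paste0("unknown sensor_id: ",
                               paste(unique(ev$sensor_id[bad]), collapse = ", ")))
    ok <- purrr::map2_lgl(ev$posture, ev$sensor_id,
                          ~ .x %in% posture_classes(.y))
    if (!all(ok)) {
      abort(paste0("posture not valid for its sensor: ",
                   paste(unique(paste0(ev$sensor_id, "/", ev$posture)[!ok]),
                         collapse = ", ")))
    }
    if (any(ev$t < 0)) abort("timestamps must be >= 0")
  } else {
    classes <- if (level == "L2") atomic_classes() else complex_classes()
    bad <- !ev$behavior %in% classes
    if (any(bad)) abort(paste0("unknown ", level, " behavior: ",
                               paste(unique(ev$behavior[bad]), collapse = ", ")))
    if (any(!(ev$ts < ev$te))) abort("event start must precede end (ts < te)")
    if (any(ev$ts < 0)) abort("timestamps must be >= 0")
    if (level == "L3" && any(!ev$d %in% c("Normal", "Abnormal"))) {
      abort("symptom state d must be 'Normal' or 'Abnormal'")
    }
  }
  invisible(ev)
}

#' Create an empty, time-ordered event channel
#'
#' An event channel is a tibble of one level's events kept sorted
#' non-decreasing by primary timestamp (`t` for L1, `ts` for L2/L3). Events
#' enter through [publish()] and are read back through [window_view()].
#'
#' @param level `"L1"`, `"L2"` or `"L3"`.
#' @return An empty `event_channel` tibble with the level's columns.
#' @examples
#' ch <- event_channel("L1")
#' ch <- publish(ch, posture_events("d", "body", "Walk", 0))
#' @export
event_channel <- function(level) {
  level <- match.arg(level, c("L1", "L2", "L3"))
  schema <- level_schema(level)
  cols <- purrr::map(schema, ~ vector(.x, 0))
  ch <- as_tibble(cols)
  new_event_channel(ch, level)
}

new_event_channel <- function(tbl, level) {
  structure(tbl, level = level,
            class = c("event_channel", class(tibble())))
}

#' @export
print.event_channel <- function(x, ...) {
  cat("# Event channel <", attr(x, "level"), ">: ", nrow(x), " events\n",
      sep = "")
  NextMethod()
}

#' Channel level
#' @param channel An `event_channel`.
#' @return `"L1"`, `"L2"` or `"L3"`.
#' @export
channel_level <- function(channel) {
  lvl <- attr(channel, "level")
  if (is.null(lvl)) abort("not an event channel (missing level attribute)")
  lvl
}

#' Publish events onto a channel
#'
#' Inserts events while preserving non-decreasing time order (stable with
#' respect to previously published events). Events whose type does not match
#' the channel's level are rejected. Duplicate events (identical fields) are
#' allowed.
#'
#' @param channel An [event_channel()].
#' @param events A tibble of events of the channel's level (one or many rows).
#' @return The channel with the events inserted, still sorted.
#' @export
publish <- function(channel, events) {
  level <- channel_level(channel)
  schema <- level_schema(level)
  if (!all(names(schema) %in% names(events))) {
    abort(paste0("event type does not match channel level ", level,
                 ": expected columns ", paste(names(schema), collapse = ", ")))
  }
  extra <- setdiff(names(events), names(schema))
  if (length(extra)) {
    # an L2/L3 mix-up (e.g. a 'd' column on an L2 channel) is a level error
    if (any(extra %in% c("d", "posture", "sensor_id", "t", "ts", "te"))) {
      abort(paste0("event type does not match channel level ", level))
    }
    events <- events[names(schema)]
  }
  events <- events[names(schema)]
  validate_events(events, level)
  out <- dplyr::bind_rows(as_tibble(channel), events)
  ord <- order(out[[time_col(level)]])  # stable sort
  new_event_channel(out[ord, ], level)
}

#' View the events of a half-open time window
#'
#' Returns the events whose primary timestamp falls in `[t_start, t_start +
#' length)`. The channel itself is not modified. Half-open windows tile a
#' stream without gap or double-counting.
#'
#' @param channel An [event_channel()] (or any event tibble of that level).
#' @param t_start Window start, seconds.
#' @param length Window length, seconds; must be positive.
#' @return A tibble of the events in the window, in time order.
#' @export
window_view <- function(channel, t_start, length) {
  if (!is.numeric(length) || length(length) != 1 || length <= 0) {
    abort("window length must be a single positive number")
  }
  tc <- time_col(channel_level(channel))
  tt <- channel[[tc]]
  as_tibble(channel)[tt >= t_start & tt < t_start + length, ]
}

#' Read and write JSON-lines event files
#'
#' One event per line as a JSON object; keys are the level's columns
#' (`subject_id`, `sensor_id`, `posture`, `t` for L1; `subject_id`,
#' `behavior`, `ts`, `te` for L2, plus `d` for L3). The reader tolerates
#' unknown extra keys and infers the level from the keys present unless
#' `level` is given.
#'
#' @param path File path.
#' @param level Optional level override (`"L1"`, `"L2"`, `"L3"`).
#' @return `read_events_jsonl()`: an [event_channel()];
#'   `write_events_jsonl()`: `path`, invisibly.
#' @export
read_events_jsonl <- function(path, level = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  rows <- purrr::map(lines, ~ jsonlite::fromJSON(.x, simplifyVector = TRUE))
  if (is.null(level)) {
    keys <- if (length(rows)) names(rows[[1]]) else character()
    level <- if ("posture" %in% keys) "L1"
             else if ("d" %in% keys) "L3"
             else "L2"
  }
  schema <- level_schema(level)
  ch <- event_channel(level)
  if (!length(rows)) return(ch)
  tbl <- purrr::map_dfr(rows, function(r) {
    missing <- setdiff(names(schema), names(r))
    if (length(missing)) {
      abort(paste0("event line missing keys: ", paste(missing, collapse = ", ")))
    }
    as_tibble(r[names(schema)])
  })
  publish(ch, tbl)
}

#' @rdname read_events_jsonl
#' @param events An event tibble or channel to write.
#' @export
write_events_jsonl <- function(events, path) {
  lines <- purrr::pmap_chr(as_tibble(events), function(...) {
    jsonlite::toJSON(list(...), auto_unbox = TRUE, digits = NA)
  })
  writeLines(lines, path)
  invisible(path)
}

#' Plot an event channel as a timeline
#'
#' L1 events are drawn as points per sensor; L2/L3 events as horizontal
#' segments per class (L3 colored by symptom state).
#'
#' @param object An [event_channel()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.event_channel <- function(object, ...) {
  level <- channel_level(object)
  tbl <- as_tibble(object)
  if (level == "L1") {
    ggplot2::ggplot(tbl, ggplot2::aes(x = .data$t, y = .data$posture,
                                      colour = .data$sensor_id)) +
      ggplot2::geom_point(shape = 108, size = 4) +
      ggplot2::facet_grid(rows = ggplot2::vars(.data$sensor_id),
                          scales = "free_y", space = "free_y") +
      ggplot2::labs(x = "time (s)", y = NULL, colour = "sensor",
                    title = "Level-1 posture stream")
  } else {
    aes_col <- if (level == "L3") ggplot2::aes(colour = .data$d) else NULL
    p <- ggplot2::ggplot(tbl,
      ggplot2::aes(x = .data$ts, xend = .data$te,
                   y = .data$behavior, yend = .data$behavior)) +
      ggplot2::geom_segment(mapping = aes_col, linewidth = 3) +
      ggplot2::labs(x = "time (s)", y = NULL,
                    title = paste0("Level-", substr(level, 2, 2),
                                   " behavior events"))
    if (level == "L3") p <- p + ggplot2::labs(colour = "state")
    p
  }
}
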