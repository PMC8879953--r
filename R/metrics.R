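# Per-class precision / recall / F1 and the event-matching rules that turn
# truth and predicted event streams into confusion counts at each level.

#' Precision, recall and F1 from confusion counts
#'
#' `P = TP / (TP + FP)`, `R = TP / (TP + FN)`, `F1 = 2PR / (P + R)`;
#' zero-denominator cases yield 0. A final `Average` row carries the
#' unweighted macro mean over classes.
#'
#' @param counts A tibble with columns `class`, `tp`, `fp`, `fn`
#'   (non-negative integers).
#' @return The counts tibble with `precision`, `recall`, `f1` columns and an
#'   appended `Average` row.
#' @examples
#' precision_recall_f1(tibble::tibble(class = "Walk", tp = 8, fp = 2, fn = 2))
#' @export
precision_recall_f1 <- function(counts) {
  if (any(counts$tp < 0 | counts$fp < 0 | counts$fn < 0)) {
    abort("confusion counts must be non-negative")
  }
  safe_div <- function(num, den) ifelse(den > 0, num / den, 0)
  out <- counts |>
    dplyr::mutate(
      precision = safe_div(.data$tp, .data$tp + .data$fp),
      recall = safe_div(.data$tp, .data$tp + .data$fn),
      f1 = safe_div(2 * .data$precision * .data$recall,
                    .data$precision + .data$recall))
  avg <- out |>
    dplyr::summarise(class = "Average", tp = NA_integer_, fp = NA_integer_,
                     fn = NA_integer_, precision = mean(.data$precision),
                     recall = mean(.data$recall), f1 = mean(.data$f1))
  dplyr::bind_rows(out, avg)
}

#' Confusion counts from paired label vectors
#'
#' @param truth,pred Equal-length label vectors.
#' @param classes Classes to report; defaults to those present in `truth`.
#' @return A counts tibble (`class`, `tp`, `fp`, `fn`).
#' @export
label_confusion <- function(truth, pred, classes = NULL) {
  classes <- classes %||% sort(unique(as.character(truth)))
  purrr::map_dfr(classes, function(cl) {
    tibble(class = cl,
           tp = sum(truth == cl & pred == cl),
           fp = sum(truth != cl & pred == cl),
           fn = sum(truth == cl & pred != cl))
  })
}

interval_overlap <- function(ts1, te1, ts2, te2) {
  pmax(0, pmin(te1, te2) - pmax(ts1, ts2))
}

#' Match predicted events against ground truth
#'
#' Level 1 compares posture labels second by second (a missing or differing
#' prediction at a truth second counts FN; a prediction with no or a
#' differing truth counts FP). Levels 2 and 3 match event intervals: a
#' predicted event is a true positive iff a not-yet-matched truth event of
#' the same class (and, at Level 3, the same symptom state) overlaps it by
#' more than `min_overlap` of the truth event's duration; each truth event
#' matches at most once.
#'
#' @param truth,pred Event tibbles/channels of the level.
#' @param level 1, 2 or 3.
#' @param min_overlap Fractional overlap threshold (default 0.5).
#' @return A counts tibble (`class`, `tp`, `fp`, `fn`); Level-3 classes are
#'   `"<behavior>/<state>"`.
#' @export
match_events <- function(truth, pred, level, min_overlap = 0.5) {
  truth <- as_tibble(truth)
  pred <- as_tibble(pred)
  if (level == 1) {
    j <- dplyr::full_join(
      dplyr::rename(truth, truth_label = "posture"),
      dplyr::rename(pred, pred_label = "posture"),
      by = c("subject_id", "sensor_id", "t"))
    classes <- sort(unique(c(truth$posture, pred$posture)))
    return(purrr::map_dfr(classes, function(cl) {
      tibble(class = cl,
             tp = sum(j$truth_label == cl & j$pred_label == cl, na.rm = TRUE),
             fp = sum(j$pred_label == cl &
                        (is.na(j$truth_label) | j$truth_label != cl)),
             fn = sum(j$truth_label == cl &
                        (is.na(j$pred_label) | j$pred_label != cl)))
    }))
  }
  key <- function(x) {
    if (level == 3) paste(x$behavior, x$d, sep = "/") else x$behavior
  }
  truth$.class <- if (nrow(truth)) key(truth) else character()
  pred$.class <- if (nrow(pred)) key(pred) else character()
  classes <- sort(unique(c(truth$.class, pred$.class)))
  purrr::map_dfr(classes, function(cl) {
    tp <- 0
    fp <- 0
    tr <- truth[truth$.class == cl, ]
    pr <- pred[pred$.class == cl, ]
    for (sid in unique(c(tr$subject_id, pr$subject_id))) {
      trs <- tr[tr$subject_id == sid, ]
      prs <- pr[pr$subject_id == sid, ]
      prs <- prs[order(prs$ts), ]
      used <- rep(FALSE, nrow(trs))
      for (i in seq_len(nrow(prs))) {
        ov <- interval_overlap(prs$ts[i], prs$te[i], trs$ts, trs$te) /
          (trs$te - trs$ts)
        cand <- which(!used & ov > min_overlap)
        if (length(cand)) {
          used[cand[1]] <- TRUE
          tp <- tp + 1
        } else {
          fp <- fp + 1
        }
      }
    }
    tibble(class = cl, tp = tp, fp = fp, fn = nrow(tr) - tp)
  })
}

#' Score predicted events against ground truth
#'
#' Composes [match_events()] and [precision_recall_f1()].
#'
#' @inheritParams match_events
#' @return A metrics tibble with per-class rows and an `Average` row, plus a
#'   `level` attribute.
#' @export
evaluate_events <- function(truth, pred, level, min_overlap = 0.5) {
  rep <- precision_recall_f1(match_events(truth, pred, level, min_overlap))
  attr(rep, "level") <- level
  rep
}

#' Render a metrics tibble as a plain-text table
#'
#' @param report A metrics tibble from [evaluate_events()] or
#'   [precision_recall_f1()].
#' @return The lines of the table, invisibly; printed as a side effect.
#' @export
render_metrics_table <- function(report) {
  fmt <- function(x) ifelse(is.na(x), "", formatC(x, digits = 3,
                                                  format = "f"))
  lines <- c(
    sprintf("%-28s %6s %8s %8s %8s", "Category", "Num.", "Precision",
            "Recall", "F1-Score"),
    purrr::pmap_chr(report, function(class, tp, fp, fn, precision, recall,
                                     f1, ...) {
      num <- if (is.na(tp)) "" else as.character(tp + fn)
      sprintf("%-28s %6s %8s %8s %8s", class, num, fmt(precision),
              fmt(recall), fmt(f1))
    }))
  writeLines(lines)
  invisible(lines)
}
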