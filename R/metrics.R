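# The five-parameter metric set: task time, per-hand efficiency of movement,
# economy of diathermy, the weighted error tally, and the final score
# 100 - sum(error_count x error_value). Continuous penalties (off-path time,
# excess burn time) enter the score through their own error classes after
# ceiling-of-seconds discretisation, which keeps the score formula exact.

EXCESS_BURN_THRESHOLD_S <- 2  # strict: only time beyond 2 s is excess

#' Efficiency of movement for one hand
#'
#' Two complementary readings of the same construct: the excess of the
#' actual tip-path length over the ideal path length (mm), and the time the
#' tip spent outside the ideal-path corridor (s). Both are reported.
#'
#' @param traj A `lapskill_trajectory`.
#' @param hand `"left"` or `"right"`.
#' @param task The task supplying the hand's ideal path.
#' @param params Detection parameters (corridor radius).
#' @return List with `path_excess_mm` and `off_path_seconds`.
#' @export
movement_efficiency <- function(traj, hand, task, params = detection_params()) {
  p <- task$ideal_path[[hand]]
  if (is.null(p)) stop("task ", task$task_id, " defines no ideal path for hand '",
                       hand, "'", call. = FALSE)
  tips <- traj_tips(traj, hand)
  steps <- sqrt(rowSums((tips[-1L, , drop = FALSE] - tips[-nrow(tips), , drop = FALSE])^2))
  actual <- sum(steps)
  excess <- max(0, actual - polyline_length(p))
  ep <- off_path_intervals(traj, hand, p, params$corridor_mm, debounce_ms = 0)
  list(path_excess_mm = excess,
       off_path_seconds = if (nrow(ep)) sum(ep$t_end - ep$t_start) else 0)
}

#' Economy of diathermy
#'
#' Total excess burn time: for each on-target burn episode, the time beyond
#' the threshold (strictly more than `threshold_s` seconds counts).
#'
#' @param episodes Burn episodes from [burn_episodes()].
#' @param threshold_s Burn-time threshold in seconds (default 2).
#' @return Excess burn time in seconds (>= 0).
#' @export
diathermy_economy <- function(episodes, threshold_s = EXCESS_BURN_THRESHOLD_S) {
  if (!nrow(episodes)) return(0)
  on <- episodes[episodes$on_target, , drop = FALSE]
  if (!nrow(on)) return(0)
  sum(pmax(0, (on$t_end - on$t_start) - threshold_s))
}

#' Tally errors from an event log
#'
#' Counts each applicable error class per episode; continuous classes are
#' discretised (off-path time and excess burn time as ceiling of seconds);
#' classes not applicable to the task are forced to zero. Tip contacts
#' flagged as grasps (`counted = FALSE`) are not errors.
#'
#' @param log A `lapskill_eventlog` from [detect_events()].
#' @param task The matching task.
#' @param params Detection parameters (unused thresholds are carried for
#'   provenance).
#' @return A `lapskill_tally`: list with `counts` (named integer vector over
#'   the nine classes), `off_path_seconds` (named per hand) and
#'   `excess_burn_seconds`.
#' @export
tally_errors <- function(log, task, params = detection_params()) {
  ev <- log$events
  counts <- stats::setNames(integer(length(ERROR_CLASSES)), ERROR_CLASSES)
  nk <- function(kind, extra = TRUE) sum(ev$kind == kind & extra)
  counts["OFF_TIP_CONTACT"] <- sum(ev$kind == "OFFTIP_TARGET_CONTACT" & ev$counted)
  counts["WORKSPACE_BOUNDARY"] <- nk("BOUNDARY_CONTACT")
  counts["TARGET_CONTACT_EXCESS"] <- sum(ev$kind == "TIP_TARGET_CONTACT" & ev$counted)
  counts["CONTAINER_CONTACT"] <- nk("CONTAINER_CONTACT")
  counts["INSTRUMENT_CLASH"] <- nk("INSTRUMENT_CLASH")
  n_oval <- nk("OVAL_CONTACT")
  permitted <- task$permitted_oval_contacts
  counts["OVAL_CONTACT_EXCESS"] <-
    if (is.na(permitted)) 0L else max(0L, n_oval - permitted)
  off_path <- vapply(c("left", "right"), function(h) {
    rows <- ev$kind == "OFF_PATH_INTERVAL" & ev$hand == h
    sum(ev$t_end[rows] - ev$t_start[rows])
  }, numeric(1))
  counts["OFF_PATH_TIME"] <- as.integer(ceiling(sum(off_path)))
  counts["DIATHERMY_OFF_TARGET"] <- nk("BURN_OFF_TARGET")
  on_rows <- ev$kind == "BURN_ON_TARGET"
  excess <- sum(pmax(0, (ev$t_end[on_rows] - ev$t_start[on_rows]) -
                       EXCESS_BURN_THRESHOLD_S))
  counts["EXCESS_BURN_TIME"] <- as.integer(ceiling(excess))
  counts[setdiff(ERROR_CLASSES, task$error_classes)] <- 0L
  structure(list(counts = counts, off_path_seconds = off_path,
                 excess_burn_seconds = excess),
            class = "lapskill_tally")
}

tally_counts <- function(tally) {
  if (inherits(tally, "lapskill_tally")) tally$counts
  else {
    counts <- stats::setNames(integer(length(ERROR_CLASSES)), ERROR_CLASSES)
    counts[names(tally)] <- as.integer(tally)
    counts
  }
}

#' Final score
#'
#' `S = 100 - sum(n_i * v_i)` over the nine error classes: counts times
#' weights, subtracted from 100. An empty tally scores exactly 100; the
#' score is not clamped by default (information about very poor attempts is
#' preserved), so it may be negative.
#'
#' @param tally A `lapskill_tally` or a named count vector.
#' @param weights Weight table from [default_weights()].
#' @param clamp Clamp the score at 0 (display parity with front-ends).
#' @return The score (numeric scalar, <= 100).
#' @export
final_score <- function(tally, weights = default_weights(), clamp = FALSE) {
  viol <- validate_weights(weights)
  if (length(viol)) stop("invalid weight table: ", paste(viol, collapse = "; "),
                         call. = FALSE)
  counts <- tally_counts(tally)
  if (any(counts < 0)) stop("error counts must be non-negative", call. = FALSE)
  s <- 100 - sum(counts * as.numeric(weights[names(counts)]))
  if (clamp) max(0, s) else s
}

#' Score a session
#'
#' The full pipeline for one attempt: detect events, compute per-hand
#' efficiency of movement, economy of diathermy, the error tally and the
#' final score, and report completion against the task's criterion.
#'
#' @param traj A `lapskill_trajectory`.
#' @param task The matching `lapskill_task`.
#' @param weights Error-weight table.
#' @param params Detection parameters.
#' @param clamp Clamp the final score at 0.
#' @return A `lapskill_metrics` object: `time_s`, `efficiency` (per-hand
#'   `path_excess_mm` / `off_path_seconds`, `NA` for hands without an ideal
#'   path), `economy_excess_burn_s`, `tally`, `final_score`, `completed`,
#'   `t_complete`, and the event log under `events`.
#' @export
score_session <- function(traj, task, weights = default_weights(),
                          params = detection_params(), clamp = FALSE) {
  log <- detect_events(traj, task, params)
  t <- traj_times(traj)
  eff <- lapply(stats::setNames(c("left", "right"), c("left", "right")), function(h) {
    if (h %in% task$path_hands && !is.null(task$ideal_path[[h]]))
      movement_efficiency(traj, h, task, params)
    else list(path_excess_mm = NA_real_, off_path_seconds = NA_real_)
  })
  economy <- if (task$task_id %in% c(5L, 6L))
    diathermy_economy(burn_episodes(traj, task, params)) else 0
  tally <- tally_errors(log, task, params)
  structure(list(
    task_id = task$task_id,
    dominant_hand = traj$dominant_hand,
    time_s = t[length(t)] - t[1L],
    efficiency = eff,
    economy_excess_burn_s = economy,
    tally = tally,
    weights = weights,
    final_score = final_score(tally, weights, clamp = clamp),
    completed = log$completed,
    t_complete = log$t_complete,
    events = log
  ), class = "lapskill_metrics")
}

#' @export
print.lapskill_metrics <- function(x, ...) {
  cat(sprintf("Task %d attempt: score %.1f (%s), %.2f s\n", x$task_id,
              x$final_score, if (x$completed) "completed" else "not completed",
              x$time_s))
  for (h in c("left", "right")) {
    e <- x$efficiency[[h]]
    if (!is.na(e$path_excess_mm))
      cat(sprintf("  %s hand: path excess %.1f mm, off-path %.2f s\n",
                  h, e$path_excess_mm, e$off_path_seconds))
  }
  if (x$economy_excess_burn_s > 0)
    cat(sprintf("  excess burn time: %.2f s\n", x$economy_excess_burn_s))
  nz <- x$tally$counts[x$tally$counts > 0]
  if (length(nz)) {
    cat("  errors:\n")
    for (nm in names(nz)) cat(sprintf("    %s: %d (weight %d)\n", nm, nz[[nm]],
                                      x$weights[[nm]]))
  } else cat("  errors: none\n")
  invisible(x)
}

metrics_to_list <- function(m) {
  list(task_id = m$task_id, dominant_hand = m$dominant_hand, time_s = m$time_s,
       efficiency = m$efficiency, economy_excess_burn_s = m$economy_excess_burn_s,
       errors = as.list(m$tally$counts),
       off_path_seconds = as.list(m$tally$off_path_seconds),
       excess_burn_seconds = m$tally$excess_burn_seconds,
       weights = as.list(m$weights), final_score = m$final_score,
       completed = m$completed, t_complete = m$t_complete)
}

#' Write a metrics result as JSON
#'
#' @param m A `lapskill_metrics`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(m, path) {
  jsonlite::write_json(metrics_to_list(m), path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Session store: append an attempt, load a history
#'
#' One JSON file per subject holds the chronologically ordered attempt
#' records (an append-only performance history).
#'
#' @param m A `lapskill_metrics` result.
#' @param subject Subject identifier (used as the file name).
#' @param store_dir Directory of the session store.
#' @param timestamp Attempt timestamp (seconds; defaults to the record
#'   count so that histories are reproducible without a wall clock).
#' @return `save_attempt()`: the attempt index, invisibly.
#'   `load_history()`: list of attempt records.
#' @export
save_attempt <- function(m, subject, store_dir, timestamp = NULL) {
  dir.create(store_dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(store_dir, paste0(subject, ".json"))
  hist <- if (file.exists(path))
    jsonlite::read_json(path, simplifyVector = FALSE) else list()
  rec <- metrics_to_list(m)
  rec$subject <- subject
  rec$attempt <- length(hist) + 1L
  rec$timestamp <- timestamp %||% as.numeric(length(hist) + 1L)
  hist[[length(hist) + 1L]] <- rec
  jsonlite::write_json(hist, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(rec$attempt)
}

#' @rdname save_attempt
#' @param task_id Optional filter on task.
#' @export
load_history <- function(subject, store_dir, task_id = NULL) {
  path <- file.path(store_dir, paste0(subject, ".json"))
  if (!file.exists(path)) stop("no history for subject '", subject, "'", call. = FALSE)
  hist <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!is.null(task_id)) hist <- Filter(function(r) r$task_id == task_id, hist)
  hist
}

#' Feedback reports
#'
#' Immediate feedback is the latest attempt's metric table; terminal
#' feedback is the per-attempt score/time/error series across a history,
#' with a trend (score difference between the last and the first attempt;
#' undefined and flagged for a single attempt).
#'
#' @param history A list of attempt records ([load_history()]) or of
#'   `lapskill_metrics` objects.
#' @param kind `"immediate"` or `"terminal"`.
#' @return A `lapskill_report`: for terminal reports `series` is a
#'   data.frame (attempt_index, score, time_s, total_errors) and `trend` is
#'   the first-to-last score difference (`NA` for a single attempt).
#' @export
feedback_report <- function(history, kind = c("immediate", "terminal")) {
  kind <- match.arg(kind)
  if (!length(history)) stop("empty history", call. = FALSE)
  recs <- lapply(history, function(r)
    if (inherits(r, "lapskill_metrics")) metrics_to_list(r) else r)
  if (kind == "immediate") {
    structure(list(kind = "immediate", latest = recs[[length(recs)]]),
              class = "lapskill_report")
  } else {
    series <- data.frame(
      attempt_index = seq_along(recs),
      score = vapply(recs, function(r) as.numeric(r$final_score), numeric(1)),
      time_s = vapply(recs, function(r) as.numeric(r$time_s), numeric(1)),
      total_errors = vapply(recs, function(r) sum(unlist(r$errors)), numeric(1))
    )
    trend <- if (nrow(series) >= 2L)
      series$score[nrow(series)] - series$score[1L] else NA_real_
    structure(list(kind = "terminal", series = series, trend = trend,
                   single_attempt = nrow(series) < 2L),
              class = "lapskill_report")
  }
}

#' Write a feedback report
#'
#' Terminal reports are written both as JSON and, for plotting, as a CSV
#' series `<path>.csv` (attempt_index, score, time_s, total_errors).
#'
#' @param report A `lapskill_report`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  x <- unclass(report)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, na = "null",
                       dataframe = "rows")
  if (identical(report$kind, "terminal"))
    utils::write.csv(report$series, paste0(path, ".csv"), row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(x$kind, "terminal"))
    x$series <- as.data.frame(x$series)
  structure(x, class = "lapskill_report")
}

#' @export
print.lapskill_report <- function(x, ...) {
  if (x$kind == "immediate") {
    cat(sprintf("Immediate feedback: task %d, score %.1f, %.2f s, completed: %s\n",
                x$latest$task_id, x$latest$final_score, x$latest$time_s,
                x$latest$completed))
  } else {
    cat(sprintf("Terminal feedback: %d attempts, trend %+.1f points\n",
                nrow(x$series), if (is.na(x$trend)) 0 else x$trend))
    print(x$series)
    if (isTRUE(x$single_attempt)) cat("  (single attempt: trend undefined)\n")
  }
  invisible(x)
}
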