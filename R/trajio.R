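# Instrument-trajectory logs: the engine's substitute for a live optical
# tracker stream. Canonical CSV dialect (bit-exact):
#   header: time_s,left_tip_x_mm,left_tip_y_mm,left_tip_z_mm,left_jaw_closed,
#           left_diathermy_on,right_tip_x_mm,right_tip_y_mm,right_tip_z_mm,
#           right_jaw_closed,right_diathermy_on
#   booleans 0/1, UTF-8, LF line endings. Metadata travels in a sidecar
#   JSON (<path>.meta.json); the JSONL dialect puts it on the first line.
# The engine never assumes uniform sampling: all time integrals use the
# actual timestamps.

TRAJ_COLUMNS <- c(
  "time_s",
  "left_tip_x_mm", "left_tip_y_mm", "left_tip_z_mm",
  "left_jaw_closed", "left_diathermy_on",
  "right_tip_x_mm", "right_tip_y_mm", "right_tip_z_mm",
  "right_jaw_closed", "right_diathermy_on"
)

DEFAULT_PARK <- list(left = c(-60, 40, 60), right = c(60, 40, 60))

#' Construct a trajectory
#'
#' Assembles a validated two-instrument trajectory from per-hand tip tracks.
#' A `NULL` hand is filled as "parked": held at `parked[[hand]]` (the trocar
#' pivot by default) with the jaw open and diathermy off.
#'
#' @param t Strictly increasing sample times in seconds (length n >= 2).
#' @param left,right n x 3 matrices of tip positions in mm, or `NULL`.
#' @param left_jaw,right_jaw Logical vectors: jaw closed?
#' @param left_dia,right_dia Logical vectors: diathermy active?
#' @param task_id Task the log belongs to (1..6).
#' @param dominant_hand `"left"` or `"right"`.
#' @param sample_rate_hz Nominal sampling rate (informative only).
#' @param meta List of metadata (subject, session, seed, ...).
#' @param parked Park positions used for absent hands.
#' @return A `lapskill_trajectory` object.
#' @export
trajectory <- function(t, left = NULL, right = NULL,
                       left_jaw = FALSE, right_jaw = FALSE,
                       left_dia = FALSE, right_dia = FALSE,
                       task_id = NA_integer_, dominant_hand = "right",
                       sample_rate_hz = 60, meta = list(),
                       parked = DEFAULT_PARK) {
  n <- length(t)
  fill <- function(tips, hand) {
    if (is.null(tips)) matrix(parked[[hand]], n, 3L, byrow = TRUE)
    else as_point_matrix(tips)
  }
  left <- fill(left, "left"); right <- fill(right, "right")
  df <- data.frame(
    time_s = as.numeric(t),
    left_tip_x_mm = left[, 1], left_tip_y_mm = left[, 2], left_tip_z_mm = left[, 3],
    left_jaw_closed = as.logical(rep_len(left_jaw, n)),
    left_diathermy_on = as.logical(rep_len(left_dia, n)),
    right_tip_x_mm = right[, 1], right_tip_y_mm = right[, 2], right_tip_z_mm = right[, 3],
    right_jaw_closed = as.logical(rep_len(right_jaw, n)),
    right_diathermy_on = as.logical(rep_len(right_dia, n))
  )
  new_trajectory(df, task_id = task_id, dominant_hand = dominant_hand,
                 sample_rate_hz = sample_rate_hz, meta = meta)
}

new_trajectory <- function(samples, task_id, dominant_hand, sample_rate_hz, meta) {
  validate_samples(samples)
  structure(list(
    samples = samples,
    task_id = if (is.na(task_id)) NA_integer_ else as.integer(task_id),
    dominant_hand = match.arg(dominant_hand, c("right", "left")),
    sample_rate_hz = as.numeric(sample_rate_hz),
    meta = meta
  ), class = "lapskill_trajectory")
}

validate_samples <- function(df) {
  missing <- setdiff(TRAJ_COLUMNS, names(df))
  if (length(missing))
    stop("trajectory is missing columns: ", paste(missing, collapse = ", "), call. = FALSE)
  if (nrow(df) < 2L) stop("a trajectory needs at least 2 samples", call. = FALSE)
  num <- TRAJ_COLUMNS[c(1:4, 7:9)]
  for (col in num) {
    bad <- which(!is.finite(df[[col]]))
    if (length(bad))
      stop("non-finite value in column '", col, "' at row ", bad[1L], call. = FALSE)
  }
  dt <- diff(df$time_s)
  bad <- which(dt <= 0)
  if (length(bad))
    stop("timestamps must be strictly increasing; violation at row ", bad[1L] + 1L,
         call. = FALSE)
  invisible(df)
}

#' Extract per-hand series from a trajectory
#'
#' @param traj A `lapskill_trajectory`.
#' @param hand `"left"` or `"right"`.
#' @return `traj_tips()`: n x 3 matrix of tip positions; `traj_jaw()` and
#'   `traj_diathermy()`: logical vectors; `traj_times()`: numeric vector.
#' @export
traj_tips <- function(traj, hand) {
  s <- traj$samples
  cbind(s[[paste0(hand, "_tip_x_mm")]], s[[paste0(hand, "_tip_y_mm")]],
        s[[paste0(hand, "_tip_z_mm")]])
}

#' @rdname traj_tips
#' @export
traj_jaw <- function(traj, hand) traj$samples[[paste0(hand, "_jaw_closed")]]

#' @rdname traj_tips
#' @export
traj_diathermy <- function(traj, hand) traj$samples[[paste0(hand, "_diathermy_on")]]

#' @rdname traj_tips
#' @export
traj_times <- function(traj) traj$samples$time_s

#' Write a trajectory log
#'
#' Output is byte-deterministic for identical input. The CSV dialect writes
#' a metadata sidecar `<path>.meta.json`; the JSONL dialect embeds metadata
#' on its first line.
#'
#' @param traj A `lapskill_trajectory`.
#' @param path Output file path.
#' @param format `"csv"` or `"jsonl"`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  stopifnot(inherits(traj, "lapskill_trajectory"))
  validate_samples(traj$samples)
  s <- traj$samples
  con <- file(path, open = "wb")
  on.exit(close(con))
  meta <- list(task_id = traj$task_id, dominant_hand = traj$dominant_hand,
               sample_rate_hz = traj$sample_rate_hz)
  meta <- c(meta, traj$meta)
  if (format == "csv") {
    lines <- c(paste(TRAJ_COLUMNS, collapse = ","),
               sprintf("%.12g,%.12g,%.12g,%.12g,%d,%d,%.12g,%.12g,%.12g,%d,%d",
                       s$time_s, s$left_tip_x_mm, s$left_tip_y_mm, s$left_tip_z_mm,
                       as.integer(s$left_jaw_closed), as.integer(s$left_diathermy_on),
                       s$right_tip_x_mm, s$right_tip_y_mm, s$right_tip_z_mm,
                       as.integer(s$right_jaw_closed), as.integer(s$right_diathermy_on)))
    writeLines(lines, con, sep = "\n", useBytes = TRUE)
    jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                         digits = NA, null = "null")
  } else {
    hdr <- jsonlite::toJSON(c(list(format = "lapskill-trajectory-jsonl"), meta),
                            auto_unbox = TRUE, digits = NA, null = "null")
    rows <- sprintf(paste0(
      '{"t":%.12g,"left":{"tip":[%.12g,%.12g,%.12g],"jaw_closed":%s,"diathermy_on":%s},',
      '"right":{"tip":[%.12g,%.12g,%.12g],"jaw_closed":%s,"diathermy_on":%s}}'),
      s$time_s, s$left_tip_x_mm, s$left_tip_y_mm, s$left_tip_z_mm,
      tolower(s$left_jaw_closed), tolower(s$left_diathermy_on),
      s$right_tip_x_mm, s$right_tip_y_mm, s$right_tip_z_mm,
      tolower(s$right_jaw_closed), tolower(s$right_diathermy_on))
    writeLines(c(as.character(hdr), rows), con, sep = "\n", useBytes = TRUE)
  }
  invisible(path)
}

#' Read a trajectory log
#'
#' Validates the file on ingestion: missing columns, non-finite values and
#' non-monotone timestamps are rejected with the offending row number. A CSV
#' with one hand's columns entirely absent is accepted; the missing hand is
#' filled as parked (at `parked[[hand]]`, jaw open, diathermy off).
#'
#' @param path Input file path.
#' @param format `"csv"` or `"jsonl"`.
#' @param parked Park positions for absent hands (default: trocar pivots of
#'   the packaged scene).
#' @return A `lapskill_trajectory`.
#' @export
read_trajectory <- function(path, format = c("csv", "jsonl"), parked = DEFAULT_PARK) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("trajectory file not found: ", path, call. = FALSE)
  if (format == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (nrow(df) == 0L) stop("empty trajectory file: ", path, call. = FALSE)
    for (hand in c("left", "right")) {
      cols <- grep(paste0("^", hand, "_"), TRAJ_COLUMNS, value = TRUE)
      if (!any(cols %in% names(df))) {
        df[[paste0(hand, "_tip_x_mm")]] <- parked[[hand]][1]
        df[[paste0(hand, "_tip_y_mm")]] <- parked[[hand]][2]
        df[[paste0(hand, "_tip_z_mm")]] <- parked[[hand]][3]
        df[[paste0(hand, "_jaw_closed")]] <- 0L
        df[[paste0(hand, "_diathermy_on")]] <- 0L
      }
    }
    for (col in c("left_jaw_closed", "left_diathermy_on",
                  "right_jaw_closed", "right_diathermy_on"))
      if (col %in% names(df)) df[[col]] <- as.logical(df[[col]])
    meta_path <- paste0(path, ".meta.json")
    meta <- if (file.exists(meta_path))
      jsonlite::read_json(meta_path, simplifyVector = TRUE) else list()
    new_trajectory(df[TRAJ_COLUMNS],
                   task_id = meta$task_id %||% NA_integer_,
                   dominant_hand = meta$dominant_hand %||% "right",
                   sample_rate_hz = meta$sample_rate_hz %||% 60,
                   meta = meta[setdiff(names(meta),
                                       c("task_id", "dominant_hand", "sample_rate_hz"))])
  } else {
    lines <- readLines(path)
    if (length(lines) < 3L) stop("empty or truncated trajectory file: ", path, call. = FALSE)
    meta <- jsonlite::fromJSON(lines[1L], simplifyVector = TRUE)
    rows <- lapply(seq.int(2L, length(lines)), function(i) {
      x <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
                    error = function(e) stop("malformed JSONL at line ", i, ": ",
                                             conditionMessage(e), call. = FALSE))
      fill <- function(h, hand) {
        if (is.null(h)) h <- list(tip = parked[[hand]], jaw_closed = FALSE,
                                  diathermy_on = FALSE)
        c(h$tip, as.integer(isTRUE(h$jaw_closed)), as.integer(isTRUE(h$diathermy_on)))
      }
      c(x$t, fill(x$left, "left"), fill(x$right, "right"))
    })
    m <- do.call(rbind, rows)
    df <- data.frame(time_s = m[, 1],
                     left_tip_x_mm = m[, 2], left_tip_y_mm = m[, 3], left_tip_z_mm = m[, 4],
                     left_jaw_closed = m[, 5] == 1, left_diathermy_on = m[, 6] == 1,
                     right_tip_x_mm = m[, 7], right_tip_y_mm = m[, 8], right_tip_z_mm = m[, 9],
                     right_jaw_closed = m[, 10] == 1, right_diathermy_on = m[, 11] == 1)
    new_trajectory(df,
                   task_id = meta$task_id %||% NA_integer_,
                   dominant_hand = meta$dominant_hand %||% "right",
                   sample_rate_hz = meta$sample_rate_hz %||% 60,
                   meta = meta[setdiff(names(meta),
                                       c("format", "task_id", "dominant_hand",
                                         "sample_rate_hz"))])
  }
}

#' Instrument pose under the fulcrum constraint
#'
#' The shaft of a laparoscopic instrument always passes through the trocar
#' pivot (the entry portal): the intracorporeal shaft is the segment from
#' the tip to the pivot.
#'
#' @param traj A `lapskill_trajectory`.
#' @param hand `"left"` or `"right"`.
#' @param index Sample index.
#' @param task The task supplying the pivot positions.
#' @return List with `tip` (point) and `shaft` (list of `a` = tip, `b` =
#'   pivot) in mm.
#' @export
pose_at <- function(traj, hand, index, task) {
  tips <- traj_tips(traj, hand)
  if (index < 1L || index > nrow(tips)) stop("sample index out of range", call. = FALSE)
  pivot <- task$pivots[[hand]]
  if (is.null(pivot)) stop("task scene has no pivot for hand '", hand, "'", call. = FALSE)
  tip <- tips[index, ]
  if (sqrt(sum((tip - pivot)^2)) < 1e-9)
    stop("degenerate shaft: tip coincides with the pivot", call. = FALSE)
  list(tip = tip, shaft = list(a = tip, b = pivot))
}

#' @export
print.lapskill_trajectory <- function(x, ...) {
  n <- nrow(x$samples)
  cat(sprintf("Trajectory: %d samples, %.2f s, task %s, dominant hand %s\n",
              n, x$samples$time_s[n] - x$samples$time_s[1],
              ifelse(is.na(x$task_id), "?", x$task_id), x$dominant_hand))
  invisible(x)
}
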