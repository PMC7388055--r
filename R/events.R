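# Event detection: trajectory + task -> timestamped event log. Contact
# episodes are maximal intervals of a thresholded distance signal, with
# boundaries linearly interpolated to sub-sample precision and episodes
# separated by less than the debounce window merged. A small state machine
# over jaw transitions tracks grasps, transfers and placements so that the
# graspable object's position follows the holding hand.

#' Detection parameters
#'
#' Tunable thresholds of the event-detection layer. All are package
#' defaults; none is prescribed by the metric definitions themselves.
#'
#' @param contact_eps_mm Contact tolerance beyond a shape boundary (mm).
#' @param debounce_ms Episodes of the same kind separated by a shorter gap
#'   are merged (ms). Set to 0 for raw per-sample episodes.
#' @param tip_zone_mm Length of the distal "tip zone" excluded from off-tip
#'   shaft contact (mm).
#' @param corridor_mm Radius of the ideal-path corridor; the tip is
#'   off-path when farther than this from the path (mm).
#' @param grasp_radius_mm Jaw closure within this distance of a graspable
#'   object's centre counts as a grasp (mm).
#' @param clash_mm Shaft-to-shaft distance at or below which the
#'   instruments clash (mm).
#' @param reinsert_hysteresis_mm Hysteresis band around the pivot plane for
#'   removal/reinsertion detection (mm).
#' @param release_grace_s Withdrawal grace after a release: contact episodes
#'   with the just-released object starting within this window are part of
#'   the put-down, not errors (s).
#' @param container_wall_mm Wall thickness attributed to container shells;
#'   contact means reaching within `contact_eps_mm` of the wall band (mm).
#' @param trocar_clearance_mm Workspace-boundary contacts within this
#'   distance of the hand's own pivot are exempt: the instrument must cross
#'   the boundary there to enter or leave through the entry portal (mm).
#' @param traversal_bins Number of arc-length bins used for traversal
#'   coverage in task 3.
#' @return A `lapskill_detection_params` list.
#' @export
detection_params <- function(contact_eps_mm = 1, debounce_ms = 100,
                             tip_zone_mm = 5, corridor_mm = 10,
                             grasp_radius_mm = 10, clash_mm = 5,
                             container_wall_mm = 4,
                             reinsert_hysteresis_mm = 10, release_grace_s = 2,
                             trocar_clearance_mm = 40, traversal_bins = 100L) {
  structure(list(
    contact_eps_mm = contact_eps_mm, debounce_ms = debounce_ms,
    tip_zone_mm = tip_zone_mm, corridor_mm = corridor_mm,
    grasp_radius_mm = grasp_radius_mm, clash_mm = clash_mm,
    container_wall_mm = container_wall_mm,
    reinsert_hysteresis_mm = reinsert_hysteresis_mm,
    release_grace_s = release_grace_s,
    trocar_clearance_mm = trocar_clearance_mm,
    traversal_bins = as.integer(traversal_bins)
  ), class = "lapskill_detection_params")
}

FAR <- 1e9  # sentinel distance for suppressed samples

empty_events <- function() {
  data.frame(kind = character(), hand = character(), t_start = numeric(),
             t_end = numeric(), object = character(), value = numeric(),
             counted = logical(), stringsAsFactors = FALSE)
}

event_row <- function(kind, hand, t_start, t_end = t_start, object = NA_character_,
                      value = NA_real_, counted = TRUE) {
  data.frame(kind = kind, hand = hand, t_start = t_start, t_end = t_end,
             object = object, value = value, counted = counted,
             stringsAsFactors = FALSE)
}

# Maximal intervals where signal <= thresh, boundaries interpolated
# linearly in the signal. Returns data.frame(t_start, t_end).
episodes_where <- function(t, signal, thresh, debounce_s = 0) {
  cond <- !is.na(signal) & signal <= thresh
  n <- length(t)
  if (!any(cond)) return(data.frame(t_start = numeric(), t_end = numeric()))
  r <- rle(cond)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  idx <- which(r$values)
  cross <- function(i0, i1) {
    # signal crosses thresh between samples i0 and i1
    g0 <- signal[i0]; g1 <- signal[i1]
    if (!is.finite(g0) || !is.finite(g1) || g0 == g1) return(t[i1])
    w <- (g0 - thresh) / (g0 - g1)
    min(max(t[i0] + w * (t[i1] - t[i0]), t[i0]), t[i1])
  }
  ep <- lapply(idx, function(k) {
    i <- starts[k]; j <- ends[k]
    ts <- if (i == 1L) t[1L] else cross(i - 1L, i)
    te <- if (j == n) t[n] else cross(j + 1L, j)
    c(ts, te)
  })
  ep <- do.call(rbind, ep)
  out <- data.frame(t_start = ep[, 1], t_end = ep[, 2])
  merge_episodes(out, debounce_s)
}

merge_episodes <- function(ep, debounce_s) {
  if (nrow(ep) < 2L || debounce_s <= 0) return(ep)
  ts <- ep$t_start[1]; te <- ep$t_end[1]
  out <- list()
  for (k in seq.int(2L, nrow(ep))) {
    if (ep$t_start[k] - te < debounce_s) {
      te <- max(te, ep$t_end[k])
    } else {
      out[[length(out) + 1L]] <- c(ts, te)
      ts <- ep$t_start[k]; te <- ep$t_end[k]
    }
  }
  out[[length(out) + 1L]] <- c(ts, te)
  m <- do.call(rbind, out)
  data.frame(t_start = m[, 1], t_end = m[, 2])
}

# Distance from a fixed point to the per-sample shaft segment with the
# distal tip_zone excluded: segment runs from tip + tz*u to the pivot,
# u = unit(pivot - tip). `centers` may be a single point or an n x 3 matrix
# (moving object). Returns n distances.
offtip_shaft_distance <- function(tips, pivot, centers, tip_zone) {
  n <- nrow(tips)
  pv <- matrix(pivot, n, 3L, byrow = TRUE)
  dirs <- pv - tips
  len <- sqrt(rowSums(dirs^2))
  len[len < 1e-12] <- 1e-12
  u <- dirs / len
  a <- tips + pmin(tip_zone, len) * u   # proximal end of the countable shaft
  b <- pv
  if (!is.matrix(centers)) centers <- matrix(centers, n, 3L, byrow = TRUE)
  ab <- b - a
  den <- rowSums(ab^2); den[den < 1e-12] <- 1e-12
  tt <- pmin(1, pmax(0, rowSums((centers - a) * ab) / den))
  foot <- a + ab * tt
  sqrt(rowSums((centers - foot)^2))
}

# Per-sample shaft-to-shaft distance between the two instruments.
clash_distance <- function(tips_l, tips_r, pivot_l, pivot_r) {
  n <- nrow(tips_l)
  vapply(seq_len(n), function(i)
    dist_segments(tips_l[i, ], pivot_l, tips_r[i, ], pivot_r), numeric(1))
}

# A contact episode is the task itself, not an error, when it brackets a
# grasp or release of that object (pick-up, hand-over, put-down: the giving
# hand is still in contact at the instant the receiving hand takes over), or
# starts during the withdrawal grace after a grasp/release (the shaft
# inevitably sweeps past a freshly placed or handed-over object on the way
# out).
contact_counted <- function(ep, obj_events, hand, obj, params) {
  tol <- 0.05
  gt <- obj_events$t_start[obj_events$kind %in% c("GRASP", "RELEASE") &
                             obj_events$object == obj]
  vapply(seq_len(nrow(ep)), function(k) {
    brackets <- any(gt >= ep$t_start[k] - tol & gt <= ep$t_end[k] + tol)
    in_grace <- length(gt) > 0 && any(ep$t_start[k] >= gt - tol &
                                        ep$t_start[k] <= gt + params$release_grace_s)
    !(brackets || in_grace)
  }, logical(1))
}

# Grasp/transfer/placement state machine over jaw transitions. Returns the
# instantaneous events plus the object's per-sample position and per-sample
# holder, for each graspable object.
track_objects <- function(traj, task, params) {
  t <- traj_times(traj)
  n <- length(t)
  graspables <- task$roles$graspable
  events <- empty_events()
  objpos <- list(); holder_of <- list()
  if (is.null(graspables) || !length(graspables)) {
    return(list(events = events, objpos = objpos, holder = holder_of,
                transferred = logical(0), placed = stats::setNames(numeric(0), character(0))))
  }
  tips <- list(left = traj_tips(traj, "left"), right = traj_tips(traj, "right"))
  jaw <- list(left = traj_jaw(traj, "left"), right = traj_jaw(traj, "right"))
  # jaw transition table: (index, hand, closed?)
  trans <- do.call(rbind, lapply(c("left", "right"), function(h) {
    ch <- which(diff(jaw[[h]]) != 0) + 1L
    if (!length(ch)) return(NULL)
    data.frame(i = ch, hand = h, closed = jaw[[h]][ch], stringsAsFactors = FALSE)
  }))
  if (!is.null(trans)) trans <- trans[order(trans$i), , drop = FALSE]

  transferred <- stats::setNames(logical(length(graspables)), graspables)
  placed <- stats::setNames(rep(NA_real_, length(graspables)), graspables)

  for (obj in graspables) {
    r_obj <- task$shapes[[obj]]$radius
    pos <- matrix(NA_real_, n, 3L)
    hold <- character(n)
    cur_pos <- task$shapes[[obj]]$center
    holder <- NA_character_
    grasp_hands <- character(0)
    seg_start <- 1L
    flush <- function(i_end) {
      idx <- seg_start:i_end
      if (is.na(holder)) {
        pos[idx, 1] <<- cur_pos[1]; pos[idx, 2] <<- cur_pos[2]; pos[idx, 3] <<- cur_pos[3]
        hold[idx] <<- ""
      } else {
        pos[idx, ] <<- tips[[holder]][idx, , drop = FALSE]
        hold[idx] <<- holder
      }
    }
    if (!is.null(trans)) for (k in seq_len(nrow(trans))) {
      i <- trans$i[k]; h <- trans$hand[k]
      here <- if (is.na(holder)) cur_pos else tips[[holder]][i, ]
      d <- sqrt(sum((tips[[h]][i, ] - here)^2))
      if (trans$closed[k]) {
        if (d <= params$grasp_radius_mm && (is.na(holder) || holder != h)) {
          flush(i - 1L); seg_start <- i
          is_transfer <- !is.na(holder)
          if (is_transfer) transferred[obj] <- TRUE
          holder <- h
          grasp_hands <- union(grasp_hands, h)
          events <- rbind(events, event_row("GRASP", h, t[i], t[i], object = obj,
                                            value = as.numeric(is_transfer)))
        }
      } else {
        if (!is.na(holder) && holder == h) {
          flush(i - 1L); seg_start <- i
          cur_pos <- tips[[h]][i, ]
          holder <- NA_character_
          events <- rbind(events, event_row("RELEASE", h, t[i], t[i], object = obj))
          goal <- task$roles$goal
          if (!is.null(goal) && shape_contains(task$shapes[[goal]], cur_pos)) {
            events <- rbind(events, event_row("PLACEMENT", h, t[i], t[i], object = obj,
                                              value = as.numeric(transferred[obj])))
            if (is.na(placed[obj])) placed[obj] <- t[i]
          }
        }
      }
    }
    flush(n)
    objpos[[obj]] <- pos
    holder_of[[obj]] <- hold
  }
  list(events = events, objpos = objpos, holder = holder_of,
       transferred = transferred, placed = placed)
}

#' Off-path intervals for one hand
#'
#' Maximal intervals during which the tip is farther than `corridor_mm`
#' from the hand's ideal path; the total off-path time is the sum of the
#' interval durations.
#'
#' @param traj A `lapskill_trajectory`.
#' @param hand `"left"` or `"right"`.
#' @param ideal_path A polyline (see [polyline3()]).
#' @param corridor_mm Corridor radius in mm.
#' @param debounce_ms Merge window in ms (default 0: raw intervals).
#' @return data.frame with columns `t_start`, `t_end`.
#' @export
off_path_intervals <- function(traj, hand, ideal_path, corridor_mm = 10,
                               debounce_ms = 0) {
  if (is.null(ideal_path)) stop("no ideal path supplied for hand '", hand, "'",
                                call. = FALSE)
  t <- traj_times(traj)
  d <- dist_point_polyline(traj_tips(traj, hand), ideal_path)
  episodes_where(t, -d, -corridor_mm, debounce_ms / 1000)
}

#' Diathermy burn episodes
#'
#' One episode per maximal interval with the diathermy pedal active, split
#' into on-target and off-target by the tip's distance to the designated
#' targets at episode start.
#'
#' @param traj A `lapskill_trajectory`.
#' @param task A task with diathermy targets (tasks 5 and 6).
#' @param params Detection parameters.
#' @return data.frame with columns `hand`, `target`, `t_start`, `t_end`,
#'   `on_target`.
#' @export
burn_episodes <- function(traj, task, params = detection_params()) {
  targets <- task$roles$diathermy_targets
  if (is.null(targets)) stop("task ", task$task_id, " has no diathermy targets",
                             call. = FALSE)
  t <- traj_times(traj)
  out <- list()
  for (h in c("left", "right")) {
    on <- traj_diathermy(traj, h)
    if (!any(on)) next
    tips <- traj_tips(traj, h)
    r <- rle(on)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      i <- starts[k]; j <- ends[k]
      d <- vapply(targets, function(nm) shape_sdf(task$shapes[[nm]], tips[i, ]),
                  numeric(1))
      hit <- d <= params$contact_eps_mm
      out[[length(out) + 1L]] <- data.frame(
        hand = h, target = if (any(hit)) targets[which.min(d)] else NA_character_,
        t_start = t[i], t_end = t[j], on_target = any(hit),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(hand = character(), target = character(), t_start = numeric(),
                      t_end = numeric(), on_target = logical(), stringsAsFactors = FALSE))
  ep <- do.call(rbind, out)
  ep[order(ep$t_start), , drop = FALSE]
}

# Removal/reinsertion: signed coordinate of the tip along the entry
# direction, with hysteresis. REMOVAL when the tip retreats past the pivot
# (s < -h), REINSERTION when it re-enters (s > +h).
removal_events <- function(traj, task, hand, params) {
  t <- traj_times(traj)
  tips <- traj_tips(traj, hand)
  pivot <- task$pivots[[hand]]
  ctr <- (task$workspace$min_corner + task$workspace$max_corner) / 2
  u <- ctr - pivot; u <- u / sqrt(sum(u^2))
  s <- drop(sweep(tips, 2L, pivot) %*% u)
  h <- params$reinsert_hysteresis_mm
  state_in <- s[1] > 0
  events <- empty_events()
  lo <- s < -h; hi <- s > h
  change <- which(diff(lo) != 0 | diff(hi) != 0) + 1L
  for (i in change) {
    if (state_in && lo[i]) {
      state_in <- FALSE
      events <- rbind(events, event_row("REMOVAL", hand, t[i]))
    } else if (!state_in && hi[i]) {
      state_in <- TRUE
      events <- rbind(events, event_row("REINSERTION", hand, t[i]))
    }
  }
  events
}

# Traversal coverage over time for one hand: fraction of arc-length bins of
# the ideal path visited while inside the corridor. Returns the first time
# the required fraction is reached (NA if never) and the final fraction.
traversal_progress <- function(traj, hand, path, corridor, bins, fraction) {
  t <- traj_times(traj)
  na <- polyline_nearest_arclength(traj_tips(traj, hand), path)
  ok <- na$distance <= corridor
  if (!any(ok)) return(list(t_reach = NA_real_, fraction = 0))
  bin <- pmin(bins, pmax(1L, ceiling(na$arclength[ok] / na$total * bins)))
  first_visit <- tapply(t[ok], bin, min)
  frac <- length(first_visit) / bins
  need <- ceiling(fraction * bins)
  t_reach <- if (length(first_visit) >= need) sort(first_visit)[need] else NA_real_
  list(t_reach = t_reach, fraction = frac)
}

#' Detect events in a trajectory
#'
#' Classifies every sample of a trajectory against the task scene and
#' returns a time-ordered event log: target contacts (tip and off-tip),
#' grasps, releases, placements, workspace-boundary contacts, container
#' contacts, instrument clashes, oval contacts, removals/reinsertions,
#' diathermy burn episodes, off-path intervals and task completion.
#'
#' Contact episodes are maximal intervals of the thresholded distance
#' signal, boundaries interpolated to sub-sample precision, and episodes
#' separated by less than the debounce window merged. A tip contact episode
#' during which the object is grasped is the task itself, not an error: it
#' is flagged `counted = FALSE`. Contacts of the held object with the
#' holding hand are suppressed (the object sits in the jaws).
#'
#' @param traj A `lapskill_trajectory`.
#' @param task The matching `lapskill_task`.
#' @param params Detection parameters from [detection_params()].
#' @return A `lapskill_eventlog`.
#' @export
detect_events <- function(traj, task, params = detection_params()) {
  stopifnot(inherits(traj, "lapskill_trajectory"), inherits(task, "lapskill_task"))
  if (!is.na(traj$task_id) && traj$task_id != task$task_id)
    stop("trajectory is for task ", traj$task_id, ", not task ", task$task_id,
         call. = FALSE)
  t <- traj_times(traj)
  n <- length(t)
  eps <- params$contact_eps_mm
  dbs <- params$debounce_ms / 1000
  tips <- list(left = traj_tips(traj, "left"), right = traj_tips(traj, "right"))
  if (task$task_id %in% c(5L, 6L) &&
      any(traj_diathermy(traj, "left") & traj_diathermy(traj, "right")))
    warning("both hands have diathermy active in the same sample", call. = FALSE)

  events <- empty_events()

  ## grasp / transfer / placement
  objs <- track_objects(traj, task, params)
  events <- rbind(events, objs$events)

  ## tip and off-tip contacts with targets
  graspables <- task$roles$graspable %||% character(0)
  dia_targets <- task$roles$diathermy_targets %||% character(0)
  all_targets <- union(graspables, dia_targets)
  for (obj in all_targets) {
    movable <- obj %in% graspables
    centers <- if (movable) objs$objpos[[obj]] else task$shapes[[obj]]$center
    r_obj <- task$shapes[[obj]]$radius
    hold <- if (movable) objs$holder[[obj]] else rep("", n)
    for (h in c("left", "right")) {
      suppress <- hold == h
      if (movable || obj %in% graspables) {
        cmat <- if (is.matrix(centers)) centers else matrix(centers, n, 3L, byrow = TRUE)
        d_tip <- sqrt(rowSums((tips[[h]] - cmat)^2)) - r_obj
        d_tip[suppress] <- FAR
        ep <- episodes_where(t, d_tip, eps, dbs)
        if (nrow(ep)) {
          events <- rbind(events, event_row("TIP_TARGET_CONTACT", h, ep$t_start,
                                            ep$t_end, object = obj,
                                            value = ep$t_end - ep$t_start,
                                            counted = contact_counted(
                                              ep, objs$events, h, obj, params)))
        }
      }
      d_shaft <- offtip_shaft_distance(tips[[h]], task$pivots[[h]], centers,
                                       params$tip_zone_mm) - r_obj
      d_shaft[suppress] <- FAR
      ep <- episodes_where(t, d_shaft, eps, dbs)
      if (nrow(ep))
        events <- rbind(events, event_row("OFFTIP_TARGET_CONTACT", h, ep$t_start,
                                          ep$t_end, object = obj,
                                          value = ep$t_end - ep$t_start,
                                          counted = contact_counted(
                                            ep, objs$events, h, obj, params)))
    }
  }

  ## workspace boundary (exempt near the hand's own entry portal)
  for (h in c("left", "right")) {
    g <- -shape_sdf(task$workspace, tips[[h]])  # <= eps means at/through the limit
    near_portal <- sqrt(rowSums(sweep(tips[[h]], 2L, task$pivots[[h]])^2)) <=
      params$trocar_clearance_mm
    g[near_portal] <- FAR
    ep <- episodes_where(t, g, eps, dbs)
    if (nrow(ep))
      events <- rbind(events, event_row("BOUNDARY_CONTACT", h, ep$t_start, ep$t_end,
                                        object = "workspace",
                                        value = ep$t_end - ep$t_start))
  }

  ## container margins: instrument tip, or the held object, against the shell
  containers <- task$roles$containers %||% character(0)
  for (cn in containers) {
    shell <- task$shapes[[cn]]
    for (h in c("left", "right")) {
      d <- shape_sdf(shell, tips[[h]]) - params$container_wall_mm / 2
      for (obj in graspables) {
        held <- objs$holder[[obj]] == h
        if (any(held)) {
          r_obj <- task$shapes[[obj]]$radius
          d[held] <- d[held] - r_obj  # held-object margin: shell distance - object radius
        }
      }
      ep <- episodes_where(t, d, eps, dbs)
      if (nrow(ep))
        events <- rbind(events, event_row("CONTAINER_CONTACT", h, ep$t_start,
                                          ep$t_end, object = cn,
                                          value = ep$t_end - ep$t_start))
    }
  }

  ## oval contacts (task 4 scene feature)
  oval <- task$roles$oval
  if (!is.null(oval)) {
    for (h in c("left", "right")) {
      d <- shape_sdf(task$shapes[[oval]], tips[[h]])
      ep <- episodes_where(t, d, eps, dbs)
      if (nrow(ep))
        events <- rbind(events, event_row("OVAL_CONTACT", h, ep$t_start, ep$t_end,
                                          object = oval,
                                          value = ep$t_end - ep$t_start))
    }
  }

  ## instrument clash (shaft-to-shaft)
  dclash <- clash_distance(tips$left, tips$right, task$pivots$left, task$pivots$right)
  ep <- episodes_where(t, dclash, params$clash_mm, dbs)
  if (nrow(ep))
    events <- rbind(events, event_row("INSTRUMENT_CLASH", "both", ep$t_start,
                                      ep$t_end, value = ep$t_end - ep$t_start))

  ## removal / reinsertion
  for (h in c("left", "right"))
    events <- rbind(events, removal_events(traj, task, h, params))

  ## diathermy burns
  burns <- NULL
  if (task$task_id %in% c(5L, 6L)) {
    burns <- burn_episodes(traj, task, params)
    if (nrow(burns))
      events <- rbind(events, event_row(
        ifelse(burns$on_target, "BURN_ON_TARGET", "BURN_OFF_TARGET"),
        burns$hand, burns$t_start, burns$t_end, object = burns$target,
        value = burns$t_end - burns$t_start))
  }

  ## off-path intervals
  for (h in intersect(task$path_hands, c("left", "right"))) {
    p <- task$ideal_path[[h]]
    if (is.null(p)) next
    ep <- off_path_intervals(traj, h, p, params$corridor_mm, params$debounce_ms)
    if (nrow(ep))
      events <- rbind(events, event_row("OFF_PATH_INTERVAL", h, ep$t_start, ep$t_end,
                                        value = ep$t_end - ep$t_start))
  }

  ## completion
  cpl <- completion_status(events, traj, task, params, objs)
  if (cpl$completed)
    events <- rbind(events, event_row("TASK_COMPLETE", "both", cpl$t_complete))

  events <- events[order(events$t_start, events$kind), , drop = FALSE]
  rownames(events) <- NULL
  structure(list(events = events, task_id = task$task_id,
                 completed = cpl$completed, t_complete = cpl$t_complete,
                 params = params),
            class = "lapskill_eventlog")
}

completion_status <- function(events, traj, task, params, objs) {
  cmp <- task$completion
  none <- list(completed = FALSE, t_complete = NA_real_)
  pl <- function(need_transfer = FALSE) {
    e <- events[events$kind == "PLACEMENT" & events$object == cmp$object, , drop = FALSE]
    if (need_transfer) e <- e[e$value == 1, , drop = FALSE]
    if (nrow(e)) list(completed = TRUE, t_complete = min(e$t_start)) else none
  }
  switch(cmp$kind,
    PLACED_IN_SHAPE = pl(),
    TRANSFER_THEN_PLACED = pl(need_transfer = TRUE),
    TRAVERSAL_COMPLETE = {
      reach <- vapply(cmp$hands, function(h) {
        tp <- traversal_progress(traj, h, task$ideal_path[[h]],
                                 params$corridor_mm, params$traversal_bins,
                                 cmp$fraction)
        tp$t_reach
      }, numeric(1))
      if (any(is.na(reach))) none
      else list(completed = TRUE, t_complete = max(reach))
    },
    REMOVE_REINSERT_COUNT = {
      e <- events[events$kind == "REINSERTION" & events$hand == cmp$hand, , drop = FALSE]
      if (nrow(e) >= cmp$cycles)
        list(completed = TRUE, t_complete = sort(e$t_start)[cmp$cycles])
      else none
    },
    ALL_TARGETS_CAUTERIZED = {
      e <- events[events$kind == "BURN_ON_TARGET", , drop = FALSE]
      done <- vapply(cmp$targets, function(nm) {
        hits <- e$t_end[!is.na(e$object) & e$object == nm]
        if (length(hits)) min(hits) else NA_real_
      }, numeric(1))
      if (any(is.na(done))) none else list(completed = TRUE, t_complete = max(done))
    },
    PLACED_AND_CAUTERIZED = {
      p <- pl()
      e <- events[events$kind == "BURN_ON_TARGET", , drop = FALSE]
      done <- vapply(cmp$targets, function(nm) {
        hits <- e$t_end[!is.na(e$object) & e$object == nm]
        if (length(hits)) min(hits) else NA_real_
      }, numeric(1))
      if (!p$completed || any(is.na(done))) none
      else list(completed = TRUE, t_complete = max(p$t_complete, max(done)))
    },
    none)
}

#' Export / import an event log as JSON-Lines
#'
#' One event per line; a header line carries the task id and completion.
#'
#' @param log A `lapskill_eventlog`.
#' @param path File path.
#' @return `path` (write) or a `lapskill_eventlog` (read).
#' @export
write_event_log <- function(log, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  hdr <- jsonlite::toJSON(list(format = "lapskill-events-jsonl",
                               task_id = log$task_id, completed = log$completed,
                               t_complete = log$t_complete),
                          auto_unbox = TRUE, digits = NA, na = "null")
  rows <- vapply(seq_len(nrow(log$events)), function(i)
    as.character(jsonlite::toJSON(as.list(log$events[i, ]), auto_unbox = TRUE,
                                  digits = NA, na = "null")), character(1))
  writeLines(c(as.character(hdr), rows), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' @rdname write_event_log
#' @export
read_event_log <- function(path) {
  lines <- readLines(path)
  hdr <- jsonlite::fromJSON(lines[1L])
  ev <- if (length(lines) > 1L) {
    do.call(rbind, lapply(lines[-1L], function(l) {
      x <- jsonlite::fromJSON(l)
      event_row(x$kind, x$hand, x$t_start, x$t_end,
                object = x$object %||% NA_character_,
                value = x$value %||% NA_real_,
                counted = isTRUE(x$counted))
    }))
  } else empty_events()
  structure(list(events = ev, task_id = hdr$task_id,
                 completed = isTRUE(hdr$completed),
                 t_complete = hdr$t_complete %||% NA_real_,
                 params = NULL),
            class = "lapskill_eventlog")
}

#' @export
print.lapskill_eventlog <- function(x, ...) {
  cat(sprintf("Event log: task %d, %d events, completed: %s\n",
              x$task_id, nrow(x$events), x$completed))
  if (nrow(x$events)) print(table(x$events$kind))
  invisible(x)
}
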