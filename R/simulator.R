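# Seeded synthetic-trajectory generator: two-handed, fulcrum-consistent
# instrument motion executing each task's completion criterion as piecewise
# minimum-jerk reaches along the ideal path, perturbed by exponentially
# correlated (Ornstein-Uhlenbeck) tremor and path deviation. Errors are
# injected explicitly as scheduled excursions and recorded in a manifest, so
# the detection layer has exact ground truth. Noise is attenuated during
# precision phases (grasps, burns, touches): skilled and unskilled movers
# alike converge when they slow down; transit noise is what separates them.

#' Skill profiles
#'
#' Kinematic and error-rate parameters of a simulated operator. The three
#' presets order as expected: the expert has less tremor and path deviation
#' than the intermediate, who has less than the novice.
#'
#' @param name `"novice"`, `"intermediate"`, `"expert"`, or `"custom"`.
#' @param ... For `name = "custom"`, overrides of any profile field:
#'   `speed_mm_s`, `tremor_sd_mm`, `tremor_corr_time_s`,
#'   `path_deviation_sd_mm`, `deviation_corr_time_s`, `overshoot_prob`,
#'   `boundary_hit_rate_per_min`, `clash_rate_per_min`,
#'   `off_target_burn_prob`, `burn_overhold_sd_s`,
#'   `target_contact_rate_per_min`, `container_contact_rate_per_min`,
#'   `offtip_contact_rate_per_min`, `oval_contact_rate_per_min`,
#'   `off_path_rate_per_min`.
#' @return A `lapskill_skill_profile` list.
#' @export
skill_profile <- function(name = c("novice", "intermediate", "expert", "custom"), ...) {
  name <- match.arg(name)
  presets <- list(
    novice = list(
      speed_mm_s = 35, tremor_sd_mm = 3.0, tremor_corr_time_s = 0.25,
      path_deviation_sd_mm = 4.5, deviation_corr_time_s = 1.5,
      overshoot_prob = 0.3,
      boundary_hit_rate_per_min = 6, clash_rate_per_min = 10,
      off_target_burn_prob = 0.5, burn_overhold_sd_s = 1.2,
      target_contact_rate_per_min = 5, container_contact_rate_per_min = 4,
      offtip_contact_rate_per_min = 2.5, oval_contact_rate_per_min = 4,
      off_path_rate_per_min = 4),
    intermediate = list(
      speed_mm_s = 55, tremor_sd_mm = 1.8, tremor_corr_time_s = 0.25,
      path_deviation_sd_mm = 3.0, deviation_corr_time_s = 1.5,
      overshoot_prob = 0.15,
      boundary_hit_rate_per_min = 2, clash_rate_per_min = 3.5,
      off_target_burn_prob = 0.2, burn_overhold_sd_s = 0.5,
      target_contact_rate_per_min = 2, container_contact_rate_per_min = 1.5,
      offtip_contact_rate_per_min = 1, oval_contact_rate_per_min = 1.5,
      off_path_rate_per_min = 1.5),
    expert = list(
      speed_mm_s = 80, tremor_sd_mm = 0.8, tremor_corr_time_s = 0.25,
      path_deviation_sd_mm = 1.5, deviation_corr_time_s = 1.5,
      overshoot_prob = 0.05,
      boundary_hit_rate_per_min = 0.3, clash_rate_per_min = 0.15,
      off_target_burn_prob = 0.05, burn_overhold_sd_s = 0.1,
      target_contact_rate_per_min = 0.3, container_contact_rate_per_min = 0.2,
      offtip_contact_rate_per_min = 0.2, oval_contact_rate_per_min = 0.2,
      off_path_rate_per_min = 0.3))
  p <- presets[[if (name == "custom") "intermediate" else name]]
  over <- list(...)
  bad <- setdiff(names(over), names(p))
  if (length(bad)) stop("unknown profile field: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  p[names(over)] <- over
  rates <- unlist(p[setdiff(names(p), "overshoot_prob")])
  if (any(rates < 0)) stop("profile rates and SDs must be >= 0", call. = FALSE)
  structure(c(list(name = name), p), class = "lapskill_skill_profile")
}

resolve_profile <- function(profile) {
  if (inherits(profile, "lapskill_skill_profile")) profile
  else skill_profile(profile)
}

# ---- RNG: single generator, no global state leaks -------------------------

with_rng <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(expr)
}

# Exponentially correlated (OU) noise, stationary SD `sd`, correlation time
# `tau`, sampled at constant dt.
ou_noise <- function(n, dt, sd, tau) {
  if (sd <= 0) return(numeric(n))
  phi <- exp(-dt / tau)
  innov <- c(stats::rnorm(1, 0, sd), sd * sqrt(1 - phi^2) * stats::rnorm(n - 1))
  as.numeric(stats::filter(innov, phi, method = "recursive"))
}

# ---- motion plans ----------------------------------------------------------

new_plan <- function(pos0) {
  list(t = 0, pos = pos0, jaw = FALSE, dia = FALSE, segs = list())
}

plan_add <- function(pl, kind, to, T, jaw = pl$jaw, dia = pl$dia, precision = FALSE) {
  T <- max(T, 1e-3)
  pl$segs[[length(pl$segs) + 1L]] <- list(
    kind = kind, from = pl$pos, to = to, t0 = pl$t, t1 = pl$t + T,
    jaw = jaw, dia = dia, precision = precision)
  pl$t <- pl$t + T; pl$pos <- to; pl$jaw <- jaw; pl$dia <- dia
  pl
}

plan_move <- function(pl, to, speed, precision = FALSE, min_T = 0.1) {
  d <- sqrt(sum((to - pl$pos)^2))
  if (d < 1e-9) return(pl)
  plan_add(pl, "minjerk", to, max(d / speed, min_T), precision = precision)
}

# reach with optional overshoot past the goal, then settle
plan_reach <- function(pl, to, prof) {
  d <- sqrt(sum((to - pl$pos)^2))
  if (d > 30 && stats::runif(1) < prof$overshoot_prob) {
    u <- (to - pl$pos) / d
    pl <- plan_move(pl, to + 6 * u, prof$speed_mm_s)
    pl <- plan_move(pl, to, prof$speed_mm_s * 0.5, precision = TRUE)
  } else {
    pl <- plan_move(pl, to, prof$speed_mm_s)
  }
  pl
}

plan_hold <- function(pl, T, jaw = pl$jaw, dia = pl$dia, precision = TRUE) {
  plan_add(pl, "hold", pl$pos, T, jaw = jaw, dia = dia, precision = precision)
}

plan_pad_until <- function(pl, t_target) {
  if (t_target > pl$t + 1e-9) pl <- plan_hold(pl, t_target - pl$t, precision = FALSE)
  pl
}

sync_plans <- function(plans) {
  tmax <- max(vapply(plans, function(p) p$t, numeric(1)))
  lapply(plans, plan_pad_until, t_target = tmax)
}

minjerk_s <- function(u) u^3 * (10 - 15 * u + 6 * u^2)

sample_plan <- function(pl, t) {
  n <- length(t)
  tips <- matrix(0, n, 3L)
  jaw <- logical(n); dia <- logical(n); prec <- logical(n)
  t0s <- vapply(pl$segs, `[[`, numeric(1), "t0")
  idx <- findInterval(t, t0s, rightmost.closed = FALSE)
  idx[idx < 1L] <- 1L
  nseg <- length(pl$segs)
  for (k in seq_len(nseg)) {
    rows <- which(idx == k)
    if (!length(rows)) next
    sg <- pl$segs[[k]]
    u <- pmin(1, pmax(0, (t[rows] - sg$t0) / (sg$t1 - sg$t0)))
    w <- switch(sg$kind, minjerk = minjerk_s(u), hold = rep(0, length(u)), u)
    tips[rows, ] <- matrix(sg$from, length(rows), 3L, byrow = TRUE) +
      outer(w, sg$to - sg$from)
    jaw[rows] <- sg$jaw; dia[rows] <- sg$dia; prec[rows] <- sg$precision
  }
  beyond <- t > pl$segs[[nseg]]$t1
  if (any(beyond)) {
    sg <- pl$segs[[nseg]]
    tips[beyond, ] <- matrix(sg$to, sum(beyond), 3L, byrow = TRUE)
    jaw[beyond] <- sg$jaw; dia[beyond] <- sg$dia; prec[beyond] <- sg$precision
  }
  list(tips = tips, jaw = jaw, dia = dia, precision = prec)
}

# precision envelope: noise multiplier, ramping linearly over `ramp` seconds
# between full noise (1) in transit and `floor` in precision phases
precision_envelope <- function(t, prec, floor = 0.25, ramp = 0.3) {
  if (!any(prec)) return(rep(1, length(t)))
  # distance in time to the nearest precision sample
  dtp <- rep(Inf, length(t))
  tp <- t[prec]
  if (length(tp)) {
    i <- findInterval(t, tp)
    lo <- pmax(i, 1L); hi <- pmin(i + 1L, length(tp))
    dtp <- pmin(abs(t - tp[lo]), abs(t - tp[hi]))
    dtp[prec] <- 0
  }
  floor + (1 - floor) * pmin(1, dtp / ramp)
}

# ---- task scripts ----------------------------------------------------------

entry_dir <- function(task, hand) {
  ctr <- (task$workspace$min_corner + task$workspace$max_corner) / 2
  unit_to(task$pivots[[hand]], ctr)
}

park_point <- function(task, hand) task$pivots[[hand]] + 12 * entry_dir(task, hand)

other_hand <- function(h) if (h == "left") "right" else "left"

# A tap on a sphere: approach collinearly with the shaft through a standoff
# point (so the shaft never grazes the sphere), touch briefly, withdraw.
plan_tap <- function(pl, shape, pivot, retreat, prof, hold_s = 0.25, pen = 1) {
  so <- shape$center + 30 * unit_to(shape$center, pivot)
  pl <- plan_move(pl, so, prof$speed_mm_s)
  pl <- plan_move(pl, touch_point(shape, pivot, pen), prof$speed_mm_s,
                  precision = TRUE)
  pl <- plan_hold(pl, hold_s)
  pl <- plan_move(pl, so, prof$speed_mm_s, precision = TRUE)
  plan_move(pl, retreat, prof$speed_mm_s)
}

# Base task execution. Returns plans (list left/right) positioned at safe
# end points, plus bookkeeping the injection phase needs.
build_base_plans <- function(task, prof, plans) {
  dh <- task$dominant_hand; nh <- other_hand(dh)
  sp <- prof$speed_mm_s
  id <- task$task_id
  shapes <- task$shapes
  home <- task$homes
  wp <- scene_waypoints(id, shapes, task$pivots, home, task$workspace, dh)

  grasp_approach <- function(pl) {
    # collinear approach along the shaft line keeps the shaft off the target
    pl <- plan_move(pl, wp$grasp_standoff, sp)
    plan_move(pl, wp$grasp, sp, precision = TRUE)
  }

  if (id == 1L) {
    plans[[dh]] <- grasp_approach(plans[[dh]])
    plans[[dh]] <- plan_hold(plans[[dh]], 0.25, jaw = TRUE)
    plans[[dh]] <- plan_move(plans[[dh]], wp$entry, sp)
    plans[[dh]] <- plan_move(plans[[dh]], wp$place, sp, precision = TRUE)
    plans[[dh]] <- plan_hold(plans[[dh]], 0.25, jaw = FALSE)
    plans[[dh]] <- plan_move(plans[[dh]], wp$entry, sp)
    plans[[dh]] <- plan_move(plans[[dh]], wp$via, sp)
    plans[[dh]] <- plan_move(plans[[dh]], home[[dh]], sp)
  } else if (id == 2L) {
    plans[[dh]] <- grasp_approach(plans[[dh]])
    plans[[dh]] <- plan_hold(plans[[dh]], 0.25, jaw = TRUE)
    plans[[dh]] <- plan_move(plans[[dh]], wp$xfer, sp)
    plans[[nh]] <- plan_reach(plans[[nh]], wp$recv, prof)
    plans <- sync_plans(plans)
    plans[[nh]] <- plan_hold(plans[[nh]], 0.25, jaw = TRUE)   # take over
    plans[[dh]] <- plan_pad_until(plans[[dh]], plans[[nh]]$t)
    plans[[dh]] <- plan_hold(plans[[dh]], 0.25, jaw = FALSE)  # let go
    plans[[dh]] <- plan_move(plans[[dh]], home[[dh]], sp)
    plans[[nh]] <- plan_hold(plans[[nh]], 0.25)
    plans[[nh]] <- plan_move(plans[[nh]], wp$entry, sp)
    plans[[nh]] <- plan_move(plans[[nh]], wp$place, sp, precision = TRUE)
    plans[[nh]] <- plan_hold(plans[[nh]], 0.25, jaw = FALSE)
    plans[[nh]] <- plan_move(plans[[nh]], wp$entry, sp)
    plans[[nh]] <- plan_move(plans[[nh]], wp$via, sp)
    plans[[nh]] <- plan_move(plans[[nh]], home[[nh]], sp)
  } else if (id == 3L) {
    for (h in c("left", "right")) {
      p <- task$ideal_path[[h]]
      plans[[h]] <- plan_reach(plans[[h]], p[1L, ], prof)
    }
    plans <- sync_plans(plans)
    # out-and-back sweep, paced well below free reaching speed
    for (h in c("left", "right")) {
      p <- task$ideal_path[[h]]
      Tsweep <- 400 / sp
      plans[[h]] <- plan_add(plans[[h]], "linear", p[nrow(p), ], Tsweep)
      plans[[h]] <- plan_hold(plans[[h]], 0.2, precision = FALSE)
      plans[[h]] <- plan_add(plans[[h]], "linear", p[1L, ], Tsweep)
      plans[[h]] <- plan_move(plans[[h]], home[[h]], sp)
    }
  } else if (id == 4L) {
    # non-dominant hand stabilises the oval throughout
    plans[[nh]] <- plan_reach(plans[[nh]], wp$oval_touch, prof)
    plans[[dh]] <- plan_reach(plans[[dh]], wp$work, prof)
    plans[[dh]] <- plan_hold(plans[[dh]], 0.3)
    plans[[dh]] <- plan_move(plans[[dh]], wp$out, sp)      # withdraw
    plans[[dh]] <- plan_hold(plans[[dh]], 0.5, precision = FALSE)
    plans[[dh]] <- plan_move(plans[[dh]], wp$work, sp)     # reinsert
    plans[[dh]] <- plan_hold(plans[[dh]], 0.3)
    plans <- sync_plans(plans)
    # stabiliser holds until the working hand is done, then withdraws radially
    plans[[nh]] <- plan_hold(plans[[nh]], 0.2)
    plans[[nh]] <- plan_move(plans[[nh]], wp$oval_away, sp)
    plans[[nh]] <- plan_move(plans[[nh]], home[[nh]], sp)
    plans[[dh]] <- plan_move(plans[[dh]], home[[dh]], sp)
  } else if (id == 5L || id == 6L) {
    burn_hand <- wp$burn_hand
    if (id == 6L) {
      plans[[dh]] <- grasp_approach(plans[[dh]])
      plans[[dh]] <- plan_hold(plans[[dh]], 0.25, jaw = TRUE)
      plans[[dh]] <- plan_move(plans[[dh]], wp$place, sp, precision = TRUE)
      plans[[dh]] <- plan_hold(plans[[dh]], 0.25, jaw = FALSE)
      plans[[dh]] <- plan_move(plans[[dh]], home[[dh]], sp)
      # keep the cautery hand (and its shaft) left of the sphere
      plans[[burn_hand]] <- plan_move(plans[[burn_hand]], wp$burn_via, sp)
    }
    for (i in seq_len(nrow(wp$burn_touches))) {
      # approach along the shaft line through a standoff point so the shaft
      # clears the neighbouring targets, then touch shallowly
      burn_s <- 1.5 + abs(stats::rnorm(1, 0, prof$burn_overhold_sd_s))
      plans[[burn_hand]] <- plan_move(plans[[burn_hand]], wp$burn_standoffs[i, ], sp)
      plans[[burn_hand]] <- plan_move(plans[[burn_hand]], wp$burn_touches[i, ], sp,
                                      precision = TRUE)
      plans[[burn_hand]] <- plan_hold(plans[[burn_hand]], 0.15)
      plans[[burn_hand]] <- plan_hold(plans[[burn_hand]], burn_s, dia = TRUE)
      plans[[burn_hand]] <- plan_hold(plans[[burn_hand]], 0.15, dia = FALSE)
      plans[[burn_hand]] <- plan_move(plans[[burn_hand]], wp$burn_standoffs[i, ], sp,
                                      precision = TRUE)
    }
    plans[[burn_hand]] <- plan_move(plans[[burn_hand]], home[[burn_hand]], sp)
  }
  sync_plans(plans)
}

# fixed injection anchor points, chosen clear of every scene shape
inj_points <- function(task, hand) {
  sx <- if (hand == "right") 1 else -1
  list(
    wall_via = c(sx * 80, 165, 50),
    wall = c(sx * 102, 170, 60),
    off_burn = c(50, 140, 40),
    cross = list(left = c(25, 140, 25), right = c(-25, 140, 25)),
    off_path = c(-sx * 20, 215, 60)
  )
}

#' Simulate a task trajectory
#'
#' Generates a two-instrument trajectory that executes the task's completion
#' criterion, at the kinematic quality and error rates of the given skill
#' profile, together with an injection manifest recording the ground truth
#' every injected error episode. Identical `(task, profile, seed)` yield
#' bitwise-identical output.
#'
#' Injected discrete errors (target/container/oval taps, off-tip shaft
#' sweeps, boundary touches, instrument crossings, off-target burns) are
#' scheduled as separate excursions before or after the task proper, so each
#' corresponds to exactly one detectable episode. The manifest's continuous
#' quantities (off-path seconds, excess burn seconds) are measured on the
#' noise-free nominal trajectory; planned deviation time is padded to a
#' half-integer of seconds so its ceiling discretisation is robust to
#' tremor.
#'
#' @param task A `lapskill_task`.
#' @param profile A `lapskill_skill_profile` or preset name.
#' @param seed Integer seed.
#' @param duration_cap_s Trajectory is truncated here if the plan runs long.
#' @param rate_hz Sampling rate (default 60).
#' @param params Detection parameters used for the manifest's nominal
#'   measurements (corridor radius).
#' @return List with `trajectory` (a `lapskill_trajectory`) and `manifest`
#'   (class `lapskill_manifest`: `schedule` data.frame, expected error
#'   `counts`, `off_path_seconds`, `excess_burn_seconds`).
#' @export
simulate_trajectory <- function(task, profile, seed, duration_cap_s = 180,
                                rate_hz = 60, params = detection_params()) {
  prof <- resolve_profile(profile)
  stopifnot(inherits(task, "lapskill_task"))
  with_rng(seed, {
    dh <- task$dominant_hand; nh <- other_hand(dh)
    id <- task$task_id
    sp <- prof$speed_mm_s
    sched <- list()
    note <- function(class, hand, t, mag = NA_real_)
      sched[[length(sched) + 1L]] <<- data.frame(
        class = class, hand = hand, t_nominal = t, magnitude = mag,
        stringsAsFactors = FALSE)

    start <- list(left = if (id == 3L || id == 2L || id == 4L || id == 6L)
                    task$homes$left else
                      if (dh == "left") task$homes$left else park_point(task, "left"),
                  right = if (id == 3L || id == 2L || id == 4L || id == 6L)
                    task$homes$right else
                      if (dh == "right") task$homes$right else park_point(task, "right"))

    # dry run to estimate base duration for the rate draws
    T_base <- {
      pl0 <- list(left = new_plan(start$left), right = new_plan(start$right))
      pls <- build_base_plans(task, prof, pl0)
      max(vapply(pls, function(p) p$t, numeric(1)))
    }
    mins <- max(T_base, 5) / 60
    draw <- function(rate) stats::rpois(1, rate * mins)
    n_target <- if (id %in% 1:2) draw(prof$target_contact_rate_per_min) else 0L
    n_container <- if (id %in% 1:2) draw(prof$container_contact_rate_per_min) else 0L
    n_offtip <- if (id %in% c(1L, 2L, 5L, 6L)) draw(prof$offtip_contact_rate_per_min) else 0L
    n_oval <- if (id == 4L) draw(prof$oval_contact_rate_per_min) else 0L
    n_bnd <- draw(prof$boundary_hit_rate_per_min)
    n_clash <- if (id %in% 3:4) draw(prof$clash_rate_per_min) else 0L
    n_offpath <- if (id %in% c(1L, 2L, 4L, 6L)) draw(prof$off_path_rate_per_min) else 0L
    n_offburn <- if (id %in% 5:6)
      stats::rbinom(1, length(task$roles$diathermy_targets), prof$off_target_burn_prob) else 0L

    plans <- list(left = new_plan(start$left), right = new_plan(start$right))
    pts <- inj_points(task, dh)
    burn_hand <- if (id == 5L) dh else nh

    ## --- pre-task injections: taps while the scene is pristine ---
    if (n_target > 0) {
      for (k in seq_len(n_target)) {
        note("TARGET_CONTACT_EXCESS", dh, plans[[dh]]$t)
        plans[[dh]] <- plan_tap(plans[[dh]], task$shapes$target, task$pivots[[dh]],
                                task$homes[[dh]], prof)
      }
    }
    if (n_container > 0) {
      cn <- task$shapes[[task$roles$containers[1L]]]
      mid <- (cn$axis_a + cn$axis_b) / 2
      wallp <- mid + cn$radius * c(1, 0, 0)
      appr <- mid + (cn$radius + 25) * c(1, 0, 0)
      high <- c(appr[1], 230, appr[3])  # drop in from above: the direct leg
      plans[[dh]] <- plan_move(plans[[dh]], high, sp)  # could cross the shell
      plans[[dh]] <- plan_move(plans[[dh]], appr, sp)
      for (k in seq_len(n_container)) {
        note("CONTAINER_CONTACT", dh, plans[[dh]]$t)
        plans[[dh]] <- plan_move(plans[[dh]], wallp, sp, precision = TRUE)
        plans[[dh]] <- plan_hold(plans[[dh]], 0.25)
        plans[[dh]] <- plan_move(plans[[dh]], appr, sp, precision = TRUE)
      }
      plans[[dh]] <- plan_move(plans[[dh]], high, sp)
      plans[[dh]] <- plan_move(plans[[dh]], task$homes[[dh]], sp)
    }
    if (n_offtip > 0) {
      # sweep the shaft through one target: the graspable sphere where there
      # is one, else the outermost diathermy target on this hand's side (the
      # approach then never crosses the other targets)
      tgt_name <- if (id %in% 1:2 || id == 6L) task$roles$graspable[1L]
                  else {
                    tn <- task$roles$diathermy_targets
                    if (dh == "right") tn[length(tn)] else tn[1L]
                  }
      tg <- task$shapes[[tgt_name]]
      d_out <- unit_to(task$pivots[[dh]], tg$center)
      beyond <- tg$center + 40 * d_out
      lat <- c(if (dh == "right") 1 else -1, 0, 0)
      lat <- lat - sum(lat * d_out) * d_out
      if (sqrt(sum(lat^2)) < 0.3) lat <- c(0, 1, 0) - sum(c(0, 1, 0) * d_out) * d_out
      lat <- lat / sqrt(sum(lat^2))
      side <- beyond + 30 * lat
      for (k in seq_len(n_offtip)) {
        note("OFF_TIP_CONTACT", dh, plans[[dh]]$t)
        plans[[dh]] <- plan_move(plans[[dh]], side, sp)
        plans[[dh]] <- plan_move(plans[[dh]], beyond, sp)
        plans[[dh]] <- plan_hold(plans[[dh]], 0.3)
        plans[[dh]] <- plan_move(plans[[dh]], side, sp)
      }
      plans[[dh]] <- plan_move(plans[[dh]], task$homes[[dh]], sp)
    }
    if (n_oval > 0) {
      for (k in seq_len(n_oval)) {
        note("OVAL_CONTACT", dh, plans[[dh]]$t)
        plans[[dh]] <- plan_tap(plans[[dh]], task$shapes$oval, task$pivots[[dh]],
                                task$homes[[dh]], prof)
      }
    }
    plans <- sync_plans(plans)

    ## --- the task itself ---
    plans <- build_base_plans(task, prof, plans)

    ## --- post-task injections ---
    if (n_bnd > 0) {
      for (k in seq_len(n_bnd)) {
        note("WORKSPACE_BOUNDARY", dh, plans[[dh]]$t)
        plans[[dh]] <- plan_move(plans[[dh]], pts$wall_via, sp)
        plans[[dh]] <- plan_move(plans[[dh]], pts$wall, sp)
        plans[[dh]] <- plan_hold(plans[[dh]], 0.25)
        plans[[dh]] <- plan_move(plans[[dh]], pts$wall_via, sp)
      }
      plans[[dh]] <- plan_move(plans[[dh]], task$homes[[dh]], sp)
      plans <- sync_plans(plans)
    }
    if (n_offpath > 0) {
      for (k in seq_len(n_offpath)) {
        note("OFF_PATH_TIME", dh, plans[[dh]]$t)
        plans[[dh]] <- plan_move(plans[[dh]], pts$off_path, sp)
        plans[[dh]] <- plan_hold(plans[[dh]], 0.8, precision = FALSE)
        plans[[dh]] <- plan_move(plans[[dh]], task$homes[[dh]], sp)
      }
      plans <- sync_plans(plans)
    }
    if (n_clash > 0) {
      for (k in seq_len(n_clash)) {
        note("INSTRUMENT_CLASH", "both", max(plans$left$t, plans$right$t))
        plans$left <- plan_move(plans$left, pts$cross$left, sp)
        plans$right <- plan_move(plans$right, pts$cross$right, sp)
        plans <- sync_plans(plans)
        plans$left <- plan_hold(plans$left, 0.4)
        plans$right <- plan_hold(plans$right, 0.4)
        plans$left <- plan_move(plans$left, task$homes$left, sp)
        plans$right <- plan_move(plans$right, task$homes$right, sp)
        plans <- sync_plans(plans)
      }
    }
    if (n_offburn > 0) {
      for (k in seq_len(n_offburn)) {
        note("DIATHERMY_OFF_TARGET", burn_hand, plans[[burn_hand]]$t)
        plans[[burn_hand]] <- plan_move(plans[[burn_hand]], pts$off_burn, sp)
        plans[[burn_hand]] <- plan_hold(plans[[burn_hand]], 0.15)
        plans[[burn_hand]] <- plan_hold(plans[[burn_hand]], 1.0, dia = TRUE)
        plans[[burn_hand]] <- plan_hold(plans[[burn_hand]], 0.15, dia = FALSE)
      }
      plans[[burn_hand]] <- plan_move(plans[[burn_hand]], task$homes[[burn_hand]], sp)
      plans <- sync_plans(plans)
    }

    ## --- sample the nominal (noise-free) trajectory ---
    dt <- 1 / rate_hz
    sample_all <- function(plans) {
      T_total <- min(max(plans$left$t, plans$right$t), duration_cap_s)
      t <- seq(0, T_total, by = dt)
      list(t = t, left = sample_plan(plans$left, t), right = sample_plan(plans$right, t))
    }
    nom <- sample_all(plans)
    nominal_traj <- function(s) trajectory(
      s$t, left = s$left$tips, right = s$right$tips,
      left_jaw = s$left$jaw, right_jaw = s$right$jaw,
      left_dia = s$left$dia, right_dia = s$right$dia,
      task_id = task$task_id, dominant_hand = dh, sample_rate_hz = rate_hz)

    measure_off_path <- function(s) {
      tr <- nominal_traj(s)
      sum(vapply(intersect(task$path_hands, c("left", "right")), function(h) {
        p <- task$ideal_path[[h]]
        if (is.null(p)) return(0)
        ep <- off_path_intervals(tr, h, p, params$corridor_mm, debounce_ms = 0)
        if (nrow(ep)) sum(ep$t_end - ep$t_start) else 0
      }, numeric(1)))
    }

    off_path_applicable <- id %in% c(1L, 2L, 4L, 6L)
    S <- if (off_path_applicable) measure_off_path(nom) else 0
    if (off_path_applicable && S > 0.05) {
      # pad planned deviation time to a half-integer of seconds so the
      # ceiling discretisation is stable under tremor
      target_S <- ceiling(S - 0.5) + 0.5
      if (target_S < S) target_S <- target_S + 1
      # append a padding excursion, measure again, then stretch its hold by
      # exactly the missing time (holding at a far point adds off-path time
      # one-for-one)
      plans[[dh]] <- plan_move(plans[[dh]], pts$off_path, sp)
      plans[[dh]] <- plan_hold(plans[[dh]], 0.2, precision = FALSE)
      plans[[dh]] <- plan_move(plans[[dh]], task$homes[[dh]], sp)
      plans <- sync_plans(plans)
      nom <- sample_all(plans)
      S2 <- measure_off_path(nom)
      target_S <- ceiling(S2 - 0.5) + 0.5
      if (target_S < S2) target_S <- target_S + 1
      pad2 <- target_S - S2
      if (pad2 > 1e-6) {
        nseg <- length(plans[[dh]]$segs)
        hold_idx <- nseg - 1L
        plans[[dh]]$segs[[hold_idx]]$t1 <- plans[[dh]]$segs[[hold_idx]]$t1 + pad2
        for (j in seq.int(hold_idx + 1L, nseg)) {
          plans[[dh]]$segs[[j]]$t0 <- plans[[dh]]$segs[[j]]$t0 + pad2
          plans[[dh]]$segs[[j]]$t1 <- plans[[dh]]$segs[[j]]$t1 + pad2
        }
        plans[[dh]]$t <- plans[[dh]]$t + pad2
        plans <- sync_plans(plans)
        nom <- sample_all(plans)
      }
      S <- measure_off_path(nom)
    }

    ## --- manifest ---
    sched_df <- if (length(sched)) do.call(rbind, sched) else
      data.frame(class = character(), hand = character(), t_nominal = numeric(),
                 magnitude = numeric(), stringsAsFactors = FALSE)
    counts <- stats::setNames(integer(length(ERROR_CLASSES)), ERROR_CLASSES)
    for (cl in c("TARGET_CONTACT_EXCESS", "CONTAINER_CONTACT", "OFF_TIP_CONTACT",
                 "WORKSPACE_BOUNDARY", "INSTRUMENT_CLASH", "DIATHERMY_OFF_TARGET"))
      counts[cl] <- sum(sched_df$class == cl)
    if (id == 4L) {
      oval_total <- 1L + sum(sched_df$class == "OVAL_CONTACT")  # 1 = stabiliser hold
      counts["OVAL_CONTACT_EXCESS"] <- max(0L, oval_total - task$permitted_oval_contacts)
    }
    excess <- 0
    if (id %in% 5:6) {
      eps <- burn_episodes(nominal_traj(nom), task, params)
      excess <- diathermy_economy(eps)
      counts["EXCESS_BURN_TIME"] <- as.integer(ceiling(excess))
    }
    counts["OFF_PATH_TIME"] <- if (off_path_applicable) as.integer(ceiling(S)) else 0L
    counts[setdiff(ERROR_CLASSES, task$error_classes)] <- 0L

    ## --- add tremor and path deviation, attenuated in precision phases ---
    n <- length(nom$t)
    mk_noise <- function(prec_flags) {
      env <- precision_envelope(nom$t, prec_flags)
      noise <- sapply(1:3, function(j)
        ou_noise(n, dt, prof$tremor_sd_mm, prof$tremor_corr_time_s) +
        ou_noise(n, dt, prof$path_deviation_sd_mm, prof$deviation_corr_time_s))
      noise * env
    }
    tips_l <- nom$left$tips + mk_noise(nom$left$precision)
    tips_r <- nom$right$tips + mk_noise(nom$right$precision)

    traj <- trajectory(
      nom$t, left = tips_l, right = tips_r,
      left_jaw = nom$left$jaw, right_jaw = nom$right$jaw,
      left_dia = nom$left$dia, right_dia = nom$right$dia,
      task_id = task$task_id, dominant_hand = dh, sample_rate_hz = rate_hz,
      meta = list(synthetic = TRUE, seed = as.integer(seed), profile = prof$name))

    manifest <- structure(list(
      schedule = sched_df, counts = counts,
      off_path_seconds = S, excess_burn_seconds = excess,
      seed = as.integer(seed), profile = prof$name, task_id = task$task_id
    ), class = "lapskill_manifest")

    list(trajectory = traj, manifest = manifest)
  })
}

#' @export
print.lapskill_manifest <- function(x, ...) {
  cat(sprintf("Injection manifest: task %d, profile %s, seed %d\n",
              x$task_id, x$profile, x$seed))
  nz <- x$counts[x$counts > 0]
  if (length(nz)) for (nm in names(nz)) cat(sprintf("  %s: %d\n", nm, nz[[nm]]))
  else cat("  no injected errors\n")
  invisible(x)
}

#' Generate a cohort of synthetic trajectories
#'
#' Writes `n_per_cell` trajectories per (task, profile) cell, with seeds
#' derived deterministically from `base_seed`, plus an index CSV listing
#' every file with its injected error counts.
#'
#' @param task_ids Integer vector of tasks (subset of 1..6).
#' @param profiles Character vector of profile preset names.
#' @param n_per_cell Trajectories per cell (>= 1).
#' @param base_seed Base seed; the i-th file uses a seed derived from it by
#'   counter.
#' @param out_dir Output directory (created if needed).
#' @param format Trajectory file format.
#' @return The index data.frame, invisibly; written to
#'   `file.path(out_dir, "index.csv")`.
#' @export
generate_cohort <- function(task_ids, profiles, n_per_cell, base_seed, out_dir,
                            format = "csv") {
  stopifnot(n_per_cell >= 1)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list(); counter <- 0L
  for (tid in task_ids) {
    task <- load_task(tid)
    for (pf in profiles) {
      for (rep in seq_len(n_per_cell)) {
        counter <- counter + 1L
        seed <- (as.integer(base_seed) + 7919L * counter) %% 2147483647L
        sim <- simulate_trajectory(task, pf, seed)
        fname <- sprintf("traj_task%d_%s_%03d.%s", tid, pf, rep, format)
        write_trajectory(sim$trajectory, file.path(out_dir, fname), format = format)
        cnt <- as.list(sim$manifest$counts)
        rows[[counter]] <- data.frame(
          file = fname, task_id = tid, profile = pf, seed = seed,
          off_path_seconds = sim$manifest$off_path_seconds,
          excess_burn_seconds = sim$manifest$excess_burn_seconds,
          as.data.frame(cnt), stringsAsFactors = FALSE)
      }
    }
  }
  index <- do.call(rbind, rows)
  utils::write.csv(index, file.path(out_dir, "index.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(index)
}
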