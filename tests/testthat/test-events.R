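p0 <- detection_params(debounce_ms = 0)

test_that("a straight pass through a target yields one contact episode of the right duration", {
  task <- load_task(1)
  # constant 40 mm/s along x through the target sphere (radius 8, eps 1):
  # contact while |x + 30| <= 9, i.e. 18 mm of travel = 0.45 s
  tips <- lin_tips(rbind(c(-60, 150, 0), c(0, 150, 0)), per_leg = 1.5)
  log <- detect_events(make_traj(tips, task_id = 1L), task, p0)
  ep <- log$events[log$events$kind == "TIP_TARGET_CONTACT", ]
  expect_equal(nrow(ep), 1L)
  expect_equal(ep$t_end - ep$t_start, 18 / 40, tolerance = 0.02)
  expect_true(ep$counted)  # jaw never closed: an undue contact
})

test_that("jaw closing near the target then opening in the goal yields GRASP and PLACEMENT", {
  task <- load_task(1)
  hz <- 60
  leg1 <- lin_tips(rbind(c(0, 120, 60), c(-30, 150, 0)), per_leg = 1)
  hold1 <- matrix(c(-30, 150, 0), 12, 3, byrow = TRUE)
  leg2 <- lin_tips(rbind(c(-30, 150, 0), c(45, 225, -25), c(45, 165, -25)), per_leg = 1)
  hold2 <- matrix(c(45, 165, -25), 12, 3, byrow = TRUE)
  tips <- rbind(leg1, hold1, leg2, hold2)
  n1 <- nrow(leg1); n2 <- nrow(hold1); n3 <- nrow(leg2)
  jaw <- c(rep(FALSE, n1), rep(TRUE, n2 + n3), rep(FALSE, nrow(hold2)))
  tr <- make_traj(tips, task_id = 1L, jaw = jaw)
  log <- detect_events(tr, task, p0)
  kinds <- log$events$kind
  expect_true("GRASP" %in% kinds)
  expect_true("PLACEMENT" %in% kinds)
  expect_true(log$completed)
  expect_lt(log$events$t_start[kinds == "GRASP"],
            log$events$t_start[kinds == "PLACEMENT"])
  # the pick-up and put-down contacts are the task, not errors
  tt <- log$events[kinds == "TIP_TARGET_CONTACT", ]
  expect_false(any(tt$counted))
})

test_that("a trajectory idling mid-workspace produces no contact events", {
  task <- load_task(1)
  tips <- matrix(MID_WORKSPACE, 120, 3, byrow = TRUE) +
    matrix(stats::rnorm(360, 0, 0.5), 120, 3)
  log <- detect_events(make_traj(tips, task_id = 1L), task, p0)
  contact_kinds <- c("TIP_TARGET_CONTACT", "OFFTIP_TARGET_CONTACT",
                     "BOUNDARY_CONTACT", "CONTAINER_CONTACT", "INSTRUMENT_CLASH",
                     "GRASP", "PLACEMENT", "BURN_ON_TARGET", "BURN_OFF_TARGET")
  expect_false(any(log$events$kind %in% contact_kinds))
})

test_that("off-path intervals match a per-sample threshold scan", {
  task <- load_task(1)
  path <- task$ideal_path$right

  glued <- make_traj(lin_tips(unclass(path), per_leg = 0.5), task_id = 1L)
  expect_equal(nrow(off_path_intervals(glued, "right", path, 10)), 0L)

  far <- make_traj(matrix(c(-30, 220, 80), 90, 3, byrow = TRUE), task_id = 1L)
  ep <- off_path_intervals(far, "right", path, 10)
  expect_equal(nrow(ep), 1L)
  expect_equal(ep$t_start, 0)
  expect_equal(ep$t_end, 89 / 60)

  # sinusoidal excursion across the corridor
  t <- seq(0, 3, by = 1 / 60)
  base <- c(-30, 150, 0)
  tips <- cbind(base[1], base[2] + 18 * sin(2 * pi * t / 1.5), base[3])
  tr <- make_traj(tips, task_id = 1L)
  ep <- off_path_intervals(tr, "right", path, 10)
  d <- dist_point_polyline(tips, path)
  oracle_runs <- rle(d > 10)
  expect_equal(nrow(ep), sum(oracle_runs$values))
  on_ep <- vapply(t[d > 10], function(ti)
    any(ti >= ep$t_start - 1e-9 & ti <= ep$t_end + 1e-9), logical(1))
  expect_true(all(on_ep))
})

test_that("burn episodes split on-target and off-target with sample-accurate bounds", {
  task <- load_task(5)
  tgt <- task$shapes$target1$center
  n <- 60 * 5
  tips <- matrix(tgt, n, 3, byrow = TRUE)
  dia <- rep(FALSE, n); dia[31:(30 + 210)] <- TRUE  # 3.5 s activation
  tr <- make_traj(tips, task_id = 5L, dia = dia)
  ep <- burn_episodes(tr, task)
  expect_equal(nrow(ep), 1L)
  expect_true(ep$on_target)
  expect_equal(ep$target, "target1")
  expect_equal(ep$t_end - ep$t_start, 209 / 60, tolerance = 1e-9)

  faraway <- matrix(c(60, 120, 60), n, 3, byrow = TRUE)
  ep2 <- burn_episodes(make_traj(faraway, task_id = 5L, dia = dia), task)
  expect_false(ep2$on_target)

  # pedal toggled: on,on,off,on,off at 60 Hz
  dia3 <- c(TRUE, TRUE, FALSE, TRUE, FALSE, rep(FALSE, 5))
  tr3 <- make_traj(matrix(tgt, 10, 3, byrow = TRUE), task_id = 5L, dia = dia3)
  ep3 <- burn_episodes(tr3, task)
  expect_equal(nrow(ep3), 2L)
  expect_equal(ep3$t_start, c(0, 3) / 60)
  expect_equal(ep3$t_end, c(1, 3) / 60)
})

test_that("episode detection agrees with a per-sample classifier on random trajectories", {
  task <- load_task(1)
  eps <- p0$contact_eps_mm
  set.seed(31)
  for (rep in 1:100) {
    wp <- cbind(stats::runif(4, -70, 10), stats::runif(4, 120, 180),
                stats::runif(4, -40, 40))
    tips <- lin_tips(wp, per_leg = 0.6)
    tr <- make_traj(tips, task_id = 1L)
    log <- detect_events(tr, task, p0)
    t <- traj_times(tr)
    cond <- shape_sdf(task$shapes$target, tips) <= eps
    ep <- log$events[log$events$kind == "TIP_TARGET_CONTACT", ]
    runs <- rle(cond)
    expect_equal(nrow(ep), sum(runs$values))
    if (any(cond)) {
      inside <- vapply(t[cond], function(ti)
        any(ti >= ep$t_start - 1e-9 & ti <= ep$t_end + 1e-9), logical(1))
      expect_true(all(inside))
    }
  }
})

test_that("enlarging a target never decreases its total contact duration", {
  set.seed(32)
  for (rep in 1:10) {
    wp <- cbind(stats::runif(3, -70, 10), stats::runif(3, 120, 180),
                stats::runif(3, -40, 40))
    tr <- make_traj(lin_tips(wp, per_leg = 0.6), task_id = 1L)
    dur <- vapply(c(6, 8, 12, 16), function(r) {
      f <- tempfile(fileext = ".json")
      jsonlite::write_json(list(task_id = 1,
                                shapes = list(list(name = "target", kind = "sphere",
                                                   center = c(-30, 150, 0), radius = r))),
                           f, auto_unbox = TRUE)
      task <- load_task(1, scene_file = f)
      log <- detect_events(tr, task, p0)
      ep <- log$events[log$events$kind == "TIP_TARGET_CONTACT", ]
      if (nrow(ep)) sum(ep$t_end - ep$t_start) else 0
    }, numeric(1))
    expect_true(all(diff(dur) >= -1e-9))
  }
})

test_that("withdrawal past the pivot and re-entry are detected with hysteresis", {
  task <- load_task(4)
  pivot <- task$pivots$right
  ctr <- c(0, 150, 0)
  u <- (ctr - pivot) / sqrt(sum((ctr - pivot)^2))
  inside <- pivot + 80 * u
  outside <- pivot - 30 * u
  tips <- lin_tips(rbind(inside, outside, inside), per_leg = 1)
  log <- detect_events(make_traj(tips, task_id = 4L), task, p0)
  expect_equal(sum(log$events$kind == "REMOVAL" & log$events$hand == "right"), 1L)
  expect_equal(sum(log$events$kind == "REINSERTION" & log$events$hand == "right"), 1L)
  expect_true(log$completed)  # one remove/reinsert cycle by the dominant hand
})

test_that("event detection is reproducible and logs round-trip as JSONL", {
  task <- load_task(5)
  sim <- simulate_trajectory(task, "intermediate", seed = 5)
  l1 <- detect_events(sim$trajectory, task, p0)
  l2 <- detect_events(sim$trajectory, task, p0)
  expect_identical(l1$events, l2$events)

  f <- tempfile(fileext = ".jsonl")
  write_event_log(l1, f)
  back <- read_event_log(f)
  expect_equal(back$events$kind, l1$events$kind)
  expect_equal(back$events$t_start, l1$events$t_start, tolerance = 1e-12)
  expect_equal(back$task_id, l1$task_id)
  expect_equal(back$completed, l1$completed)
})
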