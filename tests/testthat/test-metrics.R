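test_that("movement efficiency: identity case and additive detour", {
  task <- load_task(1)
  path <- task$ideal_path$right
  tr <- make_traj(lin_tips(unclass(path), per_leg = 0.5), task_id = 1L)
  eff <- movement_efficiency(tr, "right", task)
  expect_equal(eff$path_excess_mm, 0, tolerance = 1e-9)
  expect_equal(eff$off_path_seconds, 0)

  # a closed 20 mm detour loop inserted mid-path adds exactly 20 mm
  mid <- (path[1, ] + path[2, ]) / 2
  detour <- rbind(path[1, ], mid, mid + c(0, 5, 0), mid, path[2:nrow(path), ])
  tr2 <- make_traj(lin_tips(detour, per_leg = 0.3), task_id = 1L)
  eff2 <- movement_efficiency(tr2, "right", task)
  expect_equal(eff2$path_excess_mm, 10, tolerance = 1e-9)

  expect_error(movement_efficiency(tr, "left", task), "no ideal path")
})

test_that("economy of diathermy penalises only time strictly beyond 2 s", {
  ep <- function(durs, on = TRUE)
    data.frame(hand = "right", target = "target1", t_start = cumsum(durs) - durs,
               t_end = cumsum(durs), on_target = on)
  expect_equal(diathermy_economy(ep(3.5)), 1.5)
  expect_equal(diathermy_economy(ep(c(1.9, 2.0))), 0)
  expect_equal(diathermy_economy(ep(2.0 + 1e-6)), 1e-6, tolerance = 1e-9)
  expect_equal(diathermy_economy(ep(5, on = FALSE)), 0)  # off-target is a count, not time

  set.seed(41)
  durs <- stats::runif(10, 0.5, 4)
  loop <- 0
  for (d in durs) loop <- loop + max(0, d - 2)
  expect_equal(diathermy_economy(ep(durs)), loop, tolerance = 1e-12)
})

test_that("the final score is 100 minus the weighted error sum", {
  empty <- stats::setNames(integer(9), error_classes()$class)
  expect_identical(final_score(empty), 100)

  two_burns <- empty; two_burns[["DIATHERMY_OFF_TARGET"]] <- 2L
  expect_equal(final_score(two_burns), 90)  # printed weight 5, twice

  bad <- default_weights(); bad[["OFF_PATH_TIME"]] <- 0L
  expect_error(final_score(empty, bad), "invalid weight")

  # unclamped scores may go negative; the clamp floor is 0
  many <- empty; many[["DIATHERMY_OFF_TARGET"]] <- 30L
  expect_equal(final_score(many), -50)
  expect_equal(final_score(many, clamp = TRUE), 0)
})

test_that("incrementing any applicable count strictly decreases the score", {
  w <- default_weights()
  base <- stats::setNames(integer(9), names(w))
  for (cl in names(w)) {
    up <- base; up[[cl]] <- 1L
    expect_lt(final_score(up, w), final_score(base, w))
  }
})

test_that("tally restricts counts to the task's applicable classes", {
  task <- load_task(5)
  sim <- simulate_trajectory(task, "novice", seed = 8)
  tly <- tally_errors(detect_events(sim$trajectory, task), task)
  inapplicable <- setdiff(error_classes()$class, task$error_classes)
  expect_true(all(tly$counts[inapplicable] == 0L))
  expect_true(all(tly$counts >= 0L))
})

test_that("score_session composes the pipeline deterministically", {
  task <- load_task(6)
  sim <- simulate_trajectory(task, "intermediate", seed = 12)
  r1 <- score_session(sim$trajectory, task)
  r2 <- score_session(sim$trajectory, task)
  expect_identical(r1$final_score, r2$final_score)
  expect_identical(r1$tally$counts, r2$tally$counts)
  expect_lte(r1$final_score, 100)
  expect_gt(r1$time_s, 0)
  # conservation: off-path time cannot exceed task time
  expect_lte(sum(r1$tally$off_path_seconds), r1$time_s)
  # excess burn cannot exceed total diathermy-on time
  dia_time <- sum(diff(traj_times(sim$trajectory))[
    traj_diathermy(sim$trajectory, "left")[-1] |
      traj_diathermy(sim$trajectory, "right")[-1]])
  expect_lte(r1$tally$excess_burn_seconds, dia_time)
})

test_that("an attempt that never completes is still fully scored", {
  task <- load_task(1)
  tips <- matrix(MID_WORKSPACE, 120, 3, byrow = TRUE)
  r <- score_session(make_traj(tips, task_id = 1L), task)
  expect_false(r$completed)
  expect_true(is.finite(r$final_score))
  expect_gt(r$time_s, 0)
})

test_that("session store appends attempts and reports trends", {
  store <- tempfile("store")
  task <- load_task(1)
  scores <- numeric(3)
  for (k in 1:3) {
    sim <- simulate_trajectory(task, c("novice", "intermediate", "expert")[k],
                               seed = 100 + k)
    m <- score_session(sim$trajectory, task)
    scores[k] <- m$final_score
    save_attempt(m, "subj1", store, timestamp = k)
  }
  hist <- load_history("subj1", store)
  expect_length(hist, 3L)

  rep_term <- feedback_report(hist, "terminal")
  expect_equal(rep_term$series$score, scores)
  expect_equal(rep_term$trend, scores[3] - scores[1])
  expect_false(rep_term$single_attempt)

  rep_imm <- feedback_report(hist, "immediate")
  expect_equal(rep_imm$latest$final_score, scores[3])

  single <- feedback_report(hist[1], "terminal")
  expect_true(single$single_attempt)
  expect_true(is.na(single$trend))
  expect_error(feedback_report(list(), "terminal"), "empty")

  f <- tempfile(fileext = ".json")
  write_report(rep_term, f)
  back <- read_report(f)
  expect_equal(back$series$score, rep_term$series$score)
  expect_equal(back$trend, rep_term$trend)
  expect_true(file.exists(paste0(f, ".csv")))
  csv <- utils::read.csv(paste0(f, ".csv"))
  expect_equal(names(csv), c("attempt_index", "score", "time_s", "total_errors"))
})
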