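test_that("skill presets order correctly and custom profiles validate", {
  nov <- skill_profile("novice"); int <- skill_profile("intermediate")
  exp_ <- skill_profile("expert")
  expect_lte(exp_$tremor_sd_mm, int$tremor_sd_mm)
  expect_lte(int$tremor_sd_mm, nov$tremor_sd_mm)
  expect_lte(exp_$path_deviation_sd_mm, int$path_deviation_sd_mm)
  expect_lte(int$path_deviation_sd_mm, nov$path_deviation_sd_mm)
  expect_error(skill_profile("custom", tremor_sd_mm = -1), ">= 0")
  expect_error(skill_profile("custom", bogus_field = 1), "unknown profile field")
})

test_that("a noiseless profile follows the ideal route exactly", {
  pf <- zero_noise_profile()
  for (tid in c(1L, 4L)) {
    task <- load_task(tid)
    sim <- simulate_trajectory(task, pf, seed = 1)
    r <- score_session(sim$trajectory, task)
    eff <- r$efficiency[[task$dominant_hand]]
    expect_equal(eff$off_path_seconds, 0)
    expect_lt(eff$path_excess_mm, 1)
    expect_true(r$completed)
    expect_equal(r$final_score, 100)
  }
})

test_that("identical seeds give bitwise-identical trajectory files", {
  task <- load_task(2)
  f1 <- tempfile(); f2 <- tempfile()
  write_trajectory(simulate_trajectory(task, "novice", seed = 11)$trajectory, f1, "csv")
  write_trajectory(simulate_trajectory(task, "novice", seed = 11)$trajectory, f2, "csv")
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  f3 <- tempfile()
  write_trajectory(simulate_trajectory(task, "novice", seed = 12)$trajectory, f3, "csv")
  expect_false(identical(readBin(f1, "raw", file.size(f1)),
                         readBin(f3, "raw", file.size(f3))))
})

test_that("the simulator does not disturb the caller's RNG stream", {
  set.seed(77)
  a <- stats::runif(1)
  set.seed(77)
  invisible(simulate_trajectory(load_task(1), "expert", seed = 3))
  b <- stats::runif(1)
  expect_identical(a, b)
})

test_that("the fulcrum constraint holds at every sample", {
  # shafts are tip->pivot segments by construction, so the reconstructed
  # shaft passes through the pivot to machine precision; verify via pose_at
  task <- load_task(3)
  sim <- simulate_trajectory(task, "intermediate", seed = 4)
  for (i in c(1L, 50L, 200L)) {
    pose <- pose_at(sim$trajectory, "left", i, task)
    expect_equal(pose$shaft$b, task$pivots$left)
  }
})

test_that("doubling tremor increases expected off-path time (sign test)", {
  task <- load_task(1)
  lo <- zero_noise_profile(tremor_sd_mm = 4, path_deviation_sd_mm = 4)
  hi <- zero_noise_profile(tremor_sd_mm = 8, path_deviation_sd_mm = 8)
  off_path <- function(pf, seed) {
    sim <- simulate_trajectory(task, pf, seed = seed)
    movement_efficiency(sim$trajectory, task$dominant_hand, task)$off_path_seconds
  }
  seeds <- 1:30
  d_lo <- vapply(seeds, function(s) off_path(lo, s), numeric(1))
  d_hi <- vapply(seeds, function(s) off_path(hi, s), numeric(1))
  wins <- sum(d_hi > d_lo)
  # one-sided sign test at alpha = 0.01
  expect_lt(stats::binom.test(wins, length(seeds), alternative = "greater")$p.value,
            0.01)
})

test_that("injected errors are announced in the manifest schedule", {
  task <- load_task(5)
  pf <- zero_noise_profile(off_target_burn_prob = 1)
  sim <- simulate_trajectory(task, pf, seed = 2)
  expect_equal(sum(sim$manifest$schedule$class == "DIATHERMY_OFF_TARGET"), 5L)
  expect_equal(unname(sim$manifest$counts[["DIATHERMY_OFF_TARGET"]]), 5L)
  log <- detect_events(sim$trajectory, task, detection_params(debounce_ms = 0))
  expect_equal(sum(log$events$kind == "BURN_OFF_TARGET"), 5L)
})

test_that("cohort generation is deterministic and fully indexed", {
  out1 <- tempfile("cohort1"); out2 <- tempfile("cohort2")
  idx1 <- generate_cohort(c(1, 4), c("expert", "novice"), 2, base_seed = 9,
                          out_dir = out1)
  idx2 <- generate_cohort(c(1, 4), c("expert", "novice"), 2, base_seed = 9,
                          out_dir = out2)
  expect_equal(nrow(idx1), 8L)  # 2 tasks x 2 profiles x 2 reps
  expect_length(list.files(out1, pattern = "^traj_.*\\.csv$"), 8L)
  expect_identical(idx1, idx2)
  f <- idx1$file[1]
  expect_identical(readBin(file.path(out1, f), "raw", file.size(file.path(out1, f))),
                   readBin(file.path(out2, f), "raw", file.size(file.path(out2, f))))
  expect_true(all(error_classes()$class %in% names(idx1)))
  expect_true(file.exists(file.path(out1, "index.csv")))
})
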