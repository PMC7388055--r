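# Fixtures are built in code: straight-line tip tracks sampled at a constant
# rate, assembled into trajectories against the packaged task scenes.

# tips moving linearly through `points` (one row per waypoint), `per_leg`
# seconds per leg, sampled at `hz`
lin_tips <- function(points, per_leg = 1, hz = 60) {
  points <- as.matrix(points)
  legs <- nrow(points) - 1L
  out <- list()
  for (i in seq_len(legs)) {
    n <- round(per_leg * hz)
    w <- seq(0, 1, length.out = n + 1L)[-(n + 1L)]
    out[[i]] <- matrix(points[i, ], n, 3L, byrow = TRUE) +
      outer(w, points[i + 1L, ] - points[i, ])
  }
  rbind(do.call(rbind, out), points[legs + 1L, , drop = FALSE])
}

make_traj <- function(tips, task_id = 1L, hand = "right", hz = 60,
                      jaw = FALSE, dia = FALSE, dominant_hand = hand) {
  n <- nrow(tips)
  t <- (seq_len(n) - 1L) / hz
  if (hand == "right")
    trajectory(t, right = tips, right_jaw = jaw, right_dia = dia,
               task_id = task_id, dominant_hand = dominant_hand)
  else
    trajectory(t, left = tips, left_jaw = jaw, left_dia = dia,
               task_id = task_id, dominant_hand = dominant_hand)
}

# a quiet spot well inside the task-1 workspace, far from every scene shape
MID_WORKSPACE <- c(0, 120, 60)

zero_noise_profile <- function(...) {
  skill_profile("custom",
    tremor_sd_mm = 0, path_deviation_sd_mm = 0, overshoot_prob = 0,
    boundary_hit_rate_per_min = 0, clash_rate_per_min = 0,
    off_target_burn_prob = 0, burn_overhold_sd_s = 0,
    target_contact_rate_per_min = 0, container_contact_rate_per_min = 0,
    offtip_contact_rate_per_min = 0, oval_contact_rate_per_min = 0,
    off_path_rate_per_min = 0, ...)
}
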