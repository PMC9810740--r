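# Builds a minimal trapping_segmentation for state-classification tests.
fake_seg <- function(id, n, state) {
  structure(data.frame(start_index = 1L, end_index = n,
                       start_frame = 0L, end_frame = n - 1L,
                       state = state,
                       p_block = if (state == "trapped") 0.001 else NA_real_),
            traj_id = id, n = n, D_hat = NA_real_, candidates = NULL,
            class = c("trapping_segmentation", "data.frame"))
}

two_channel_fixture <- function(n = 100, offset = 0) {
  x <- cumsum(c(1, rnorm(n - 1, 0, 0.02)))
  a <- trajectory("a1", 0:(n - 1), x, rep(1, n))
  b <- trajectory("b1", 0:(n - 1), x + offset, rep(1, n))
  list(ts_a = trajectory_set(list(a)), ts_b = trajectory_set(list(b)))
}

test_that("identical trajectories give exactly one full-length event", {
  withr::with_seed(1, {
    fx <- two_channel_fixture(100, offset = 0)
    ev <- detect_coloc_events(fx$ts_a, fx$ts_b, interaction_config())
    expect_equal(nrow(ev), 1)
    expect_equal(ev$start_frame, 0)
    expect_equal(ev$end_frame, 99)
    expect_equal(ev$duration_s, 100 / 35)
    expect_equal(ev$mean_distance_um, 0)
  })
})

test_that("distant trajectories give no events", {
  withr::with_seed(2, {
    fx <- two_channel_fixture(100, offset = 5)
    ev <- detect_coloc_events(fx$ts_a, fx$ts_b, interaction_config())
    expect_equal(nrow(ev), 0)
  })
})

test_that("mismatched frame intervals are rejected", {
  a <- trajectory_set(list(make_traj(1:10, dt = 1 / 35)))
  b <- trajectory_set(list(make_traj(1:10, id = "b", dt = 1 / 25)))
  expect_error(detect_coloc_events(a, b), "frame interval")
})

test_that("gap tolerance and minimum length shape events", {
  # colocalized frames 0..4 and 7..11 (2-frame break), far otherwise
  n <- 20
  xa <- rep(0, n)
  xb <- rep(10, n)
  close_frames <- c(1:5, 8:12)
  xb[close_frames] <- 0.05
  a <- trajectory("a", 0:(n - 1), xa, rep(0, n))
  b <- trajectory("b", 0:(n - 1), xb, rep(0, n))
  tsa <- trajectory_set(list(a)); tsb <- trajectory_set(list(b))
  ev1 <- detect_coloc_events(tsa, tsb, interaction_config(max_gap_frames = 1))
  expect_equal(nrow(ev1), 2)
  ev2 <- detect_coloc_events(tsa, tsb, interaction_config(max_gap_frames = 2))
  expect_equal(nrow(ev2), 1)
  expect_equal(ev2$n_frames_coloc, 10)
  ev3 <- detect_coloc_events(tsa, tsb,
                             interaction_config(min_event_frames = 6))
  expect_equal(nrow(ev3), 0)
})

test_that("raising the radius never loses colocalized frames", {
  withr::with_seed(7, {
    sim <- simulate_interacting_pairs(
      sim_config(motion_model = "interacting_pair", n_particles = 15,
                 n_frames = 300, field_size = 6, k_on = 20, k_off = 2,
                 reflect = TRUE, seed = 7))
    frames <- vapply(c(0.05, 0.1, 0.2), function(r) {
      ev <- detect_coloc_events(sim$set_a, sim$set_b,
                                interaction_config(coloc_radius = r,
                                                   min_event_frames = 1))
      sum(ev$n_frames_coloc)
    }, numeric(1))
    expect_true(all(diff(frames) >= 0))
  })
})

test_that("events are disjoint in time for each pair and quantized in dt", {
  sim <- simulate_interacting_pairs(
    sim_config(motion_model = "interacting_pair", n_particles = 25,
               n_frames = 400, field_size = 7, k_on = 20, k_off = 3,
               reflect = TRUE, seed = 9))
  ev <- detect_coloc_events(sim$set_a, sim$set_b, interaction_config())
  expect_gt(nrow(ev), 5)
  by_pair <- split(ev, paste(ev$id_a, ev$id_b))
  for (sub in by_pair) {
    sub <- sub[order(sub$start_frame), ]
    if (nrow(sub) > 1)
      expect_true(all(sub$start_frame[-1] > sub$end_frame[-nrow(sub)]))
  }
  expect_equal(ev$duration_s * 35,
               round(ev$duration_s * 35), tolerance = 1e-9)
  expect_true(all(ev$duration_s > 0))
})

test_that("event statistics normalize frequency and duration", {
  n <- 7
  a <- trajectory("a", 0:(n - 1), rep(0, n), rep(0, n))
  b <- trajectory("b", 0:(n - 1), rep(0.01, n), rep(0, n))
  tsa <- trajectory_set(list(a))
  ev <- detect_coloc_events(tsa, trajectory_set(list(b)),
                            interaction_config())
  st <- event_stats(ev, tsa, cell_area = 100)
  expect_equal(st$n_events, 1)
  expect_equal(st$duration_mean_s, 0.2, tolerance = 1e-9)  # 7 frames at 35 fps
  expect_equal(st$freq_per_particle_frame, 1 / 7)
  expect_equal(st$freq_per_um2_per_s, 1 / (100 * 0.2), tolerance = 1e-9)
  empty <- detect_coloc_events(tsa, trajectory_set(list()), interaction_config())
  expect_warning(st0 <- event_stats(empty, tsa, 100), "no colocalization")
  expect_equal(st0$n_events, 0)
})

test_that("spatially shuffled channels drop to chance-level frequency", {
  cfg <- sim_config(motion_model = "interacting_pair", n_particles = 30,
                    n_frames = 300, field_size = 8, k_on = 30, k_off = 1,
                    reflect = TRUE, seed = 21)
  sim <- simulate_interacting_pairs(cfg)
  ev <- detect_coloc_events(sim$set_a, sim$set_b, interaction_config())
  # independent channel B from a fresh simulation: chance encounters only
  sim2 <- simulate_interacting_pairs(sim_config(
    motion_model = "interacting_pair", n_particles = 30, n_frames = 300,
    field_size = 8, k_on = 0, reflect = TRUE, seed = 99))
  ev_null <- detect_coloc_events(sim$set_a, sim2$set_b, interaction_config())
  expect_gt(sum(ev$n_frames_coloc), 3 * sum(ev_null$n_frames_coloc))
})

test_that("event state classification covers the four categories", {
  n <- 50
  mk <- function(id, x) trajectory(id, 0:(n - 1), rep(x, n), rep(0, n))
  tsa <- trajectory_set(list(mk("a1", 0)))
  tsb <- trajectory_set(list(mk("b1", 0.02)))
  ev <- detect_coloc_events(tsa, tsb, interaction_config())
  expect_equal(nrow(ev), 1)
  combos <- list(c("free", "free", "co_diffusing"),
                 c("trapped", "trapped", "co_confined"),
                 c("free", "trapped", "free_a_trapped_b"),
                 c("trapped", "free", "trapped_a_free_b"))
  for (cb in combos) {
    res <- classify_event_states(ev, list(a1 = fake_seg("a1", n, cb[1])),
                                 list(b1 = fake_seg("b1", n, cb[2])),
                                 cell_area = 50)
    expect_equal(unname(res$fractions[cb[3]]), 1)
    expect_equal(sum(res$fractions), 1, tolerance = 1e-12)
    expect_equal(sum(res$densities), nrow(ev) / 50, tolerance = 1e-12)
  }
  expect_error(classify_event_states(ev, list(), list(b1 = fake_seg("b1", n, "free")),
                                     50), "missing trapping segmentation")
})

test_that("event states are recovered against simulation ground truth", {
  # channel A switches between free and trapped; channel-B partners co-move
  # with A only in short windows, so each window becomes one event and its
  # state label can be compared with the ground-truth majority state
  cfg <- sim_config(motion_model = "switching", D_free = 0.1,
                    trap_radius = 0.05, k_trap = 1, k_release = 1, seed = 33)
  sw <- simulate_switching_trajectory(cfg, traj_id = "a1")
  tr_a <- sw$trajectory
  tsa <- trajectory_set(list(tr_a))
  windows <- lapply(seq(0, 360, by = 40), function(s) s:(s + 19))
  tr_bs <- lapply(seq_along(windows), function(k) {
    fr <- windows[[k]]
    trajectory(sprintf("b%02d", k), fr, tr_a$x[fr + 1] + 0.02,
               tr_a$y[fr + 1], frame_interval = tr_a$frame_interval)
  })
  tsb <- trajectory_set(tr_bs)
  tcfg <- fast_trap_cfg(test_length = sqrt(0.1^2 + 8 * 0.023^2))
  seg_a <- list(a1 = segment_trajectory(tr_a, tcfg))
  seg_b <- lapply(tsb$trajectories, segment_trajectory, cfg = tcfg)
  ev <- detect_coloc_events(tsa, tsb, interaction_config())
  expect_gte(nrow(ev), 8)
  res <- classify_event_states(ev, seg_a, seg_b, cell_area = 100)
  truth_state <- sw$truth$state
  correct <- vapply(seq_len(nrow(res$events)), function(i) {
    fr <- res$events$start_frame[i]:res$events$end_frame[i]
    maj <- if (mean(truth_state[fr + 1] == "trapped") >= 0.5) "trapped" else "free"
    res$events$state_a[i] == maj
  }, logical(1))
  expect_gte(mean(correct), 0.8)
})
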