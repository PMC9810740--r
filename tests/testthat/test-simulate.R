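test_that("generators are pure functions of (cfg, seed)", {
  cfg <- sim_config(D_free = 0.07, seed = 12)
  a <- simulate_trajectory(cfg)
  b <- simulate_trajectory(cfg)
  expect_identical(a$trajectory$x, b$trajectory$x)
  expect_identical(a$truth$x, b$truth$x)
  c <- simulate_trajectory(cfg, seed = 13)
  expect_false(identical(a$trajectory$x, c$trajectory$x))

  sw <- sim_config(motion_model = "switching", seed = 4)
  expect_identical(simulate_switching_trajectory(sw)$trajectory$y,
                   simulate_switching_trajectory(sw)$trajectory$y)
  pc <- sim_config(motion_model = "interacting_pair", n_particles = 5,
                   n_frames = 50, field_size = 4, reflect = TRUE, seed = 6)
  expect_identical(simulate_interacting_pairs(pc)$truth$bound,
                   simulate_interacting_pairs(pc)$truth$bound)
  expect_error(sim_config(motion_model = "warp"), "unknown motion_model")
})

test_that("degenerate parameters give constant positions", {
  cfg <- sim_config(D_free = 0, sigma_loc = 0, motion_model = "brownian",
                    n_frames = 50, seed = 2)
  tr <- simulate_trajectory(cfg)$trajectory
  expect_equal(diff(range(tr$x)), 0)
  expect_equal(diff(range(tr$y)), 0)
})

test_that("Brownian ensembles satisfy the linear MSD law with noise offset", {
  D <- 0.05
  cfg <- sim_config(n_particles = 150, D_free = D, motion_model = "brownian",
                    seed = 5)
  sim <- simulate_trajectories(cfg)
  m1 <- mean(vapply(sim$set$trajectories, function(tr)
    compute_tamsd(tr, 1)$msd[1], numeric(1)))
  expect_lt(abs(m1 - (4 * D / 35 + 4 * 0.023^2)) / (4 * D / 35 + 4 * 0.023^2),
            0.05)
  # ground truth and emitted positions agree before noise injection
  one <- simulate_trajectory(cfg, seed = 9)
  expect_false(identical(one$trajectory$x, one$truth$x))
  expect_lt(max(abs(one$trajectory$x - one$truth$x)), 6 * 0.023)
})

test_that("fractional Gaussian noise scales as a power law in the lag", {
  for (H in c(0.25, 0.75)) {
    withr::with_seed(31, {
      v <- replicate(800, sum(fgn(16, H)))
      expect_lt(abs(var(v) - 16^(2 * H)) / 16^(2 * H), 0.15)
    })
  }
  expect_error(fgn(10, 1.2), "Hurst")
})

test_that("switching dwell times follow the exponential waiting-time oracle", {
  k_rel <- 2
  cfg <- sim_config(motion_model = "switching", n_frames = 6000, k_trap = 4,
                    k_release = k_rel, trap_radius = 0.05, seed = 44)
  states <- unlist(lapply(1:8, function(k)
    simulate_switching_trajectory(cfg, seed = 100 + k)$truth$state))
  r <- rle(states)
  # drop the censored first/last phases of each trajectory chunk
  trapped_lens <- r$lengths[r$values == "trapped"]
  expect_gt(length(trapped_lens), 500)
  expected <- 1 / (1 - exp(-k_rel / 35))
  expect_lt(abs(mean(trapped_lens) - expected) / expected, 0.1)
  # k_trap = 0: never traps
  free_cfg <- sim_config(motion_model = "switching", k_trap = 0, seed = 3)
  expect_true(all(simulate_switching_trajectory(free_cfg)$truth$state == "free"))
  # k_release = 0 starting trapped: stays trapped
  stuck <- sim_config(motion_model = "switching", k_release = 0,
                      init_state = "trapped", seed = 3)
  expect_true(all(simulate_switching_trajectory(stuck)$truth$state == "trapped"))
  # trapped phases stay within the confinement domain
  sw <- simulate_switching_trajectory(
    sim_config(motion_model = "switching", seed = 8), fiber_points = NULL)
  tt <- sw$truth
  for (run in split(seq_along(tt$state), cumsum(c(1, diff(tt$state == "trapped") != 0)))) {
    if (tt$state[run[1]] == "trapped" && length(run) > 1) {
      cx <- tt$x[run]; cy <- tt$y[run]
      expect_lte(max(sqrt((cx - cx[1])^2 + (cy - cy[1])^2)), 2 * 0.05 + 1e-9)
    }
  }
})

test_that("pair binding follows the exponential bound-time oracle", {
  cfg <- sim_config(motion_model = "interacting_pair", n_particles = 60,
                    n_frames = 800, field_size = 12, D_free = 0.1,
                    k_on = 30, k_off = 2, reflect = TRUE, seed = 14)
  sim <- simulate_interacting_pairs(cfg)
  tb <- sim$truth$bound
  lens <- (tb$end_frame - tb$start_frame + 1)[!tb$censored]
  expect_gt(length(lens), 150)
  expected <- 1 / (1 - exp(-2 / 35))
  expect_lt(abs(mean(lens) - expected) / expected, 0.1)
  # k_on = 0: no bound intervals
  none <- simulate_interacting_pairs(
    sim_config(motion_model = "interacting_pair", n_particles = 10,
               n_frames = 100, field_size = 5, k_on = 0, reflect = TRUE,
               seed = 2))
  expect_equal(nrow(none$truth$bound), 0)
  # very fast unbinding: intervals of at most ~2 frames
  fast <- simulate_interacting_pairs(
    sim_config(motion_model = "interacting_pair", n_particles = 20,
               n_frames = 200, field_size = 5, k_on = 50, k_off = 500,
               reflect = TRUE, seed = 2))
  if (nrow(fast$truth$bound) > 0)
    expect_lte(max(fast$truth$bound$end_frame - fast$truth$bound$start_frame), 1)
})

test_that("fiber masks match their analytic geometry", {
  cfg <- sim_config(seed = 1, fiber_params = list(n_fibers = 4, width_um = 0.4,
                                                  curvature = 0.03))
  fm <- generate_fiber_mask(cfg, seed = 5)
  area <- sum(fm$mask$grid) * 0.16^2
  expect_lt(abs(area - fm$truth$area_estimate_um2) / fm$truth$area_estimate_um2,
            0.2)
  expect_error(generate_fiber_mask(
    sim_config(seed = 1, fiber_params = list(n_fibers = 0))), "n_fibers")
})

test_that("localization placement respects the on-fiber probability", {
  fm <- generate_fiber_mask(sim_config(seed = 1), seed = 1)
  on <- place_localizations(fm$mask, 400, 1, seed = 2)
  expect_true(all(attr(on, "on_fiber")))
  off <- place_localizations(fm$mask, 400, 0, seed = 3)
  expect_true(!any(attr(off, "on_fiber")))
  half <- place_localizations(fm$mask, 2000, 0.5, seed = 4)
  expect_lt(abs(mean(attr(half, "on_fiber")) - 0.5), 0.05)
  expect_equal(nrow(half), 2000)
})

test_that("rendered frames localize particles and scale linearly", {
  cfg <- sim_config(n_frames = 5, field_size = 4, pixel_size = 0.16, seed = 3)
  tr <- trajectory("p", 0:4, rep(2, 5), rep(2, 5), frame_interval = 1 / 35)
  ts <- trajectory_set(list(tr))
  stack <- render_frames(ts, cfg, seed = 3, photons = 3000, background = 5)
  px <- 0.16
  for (f in 1:5) {
    fr <- stack[, , f] - median(stack[, , f])
    fr[fr < 0] <- 0
    rows <- seq_len(nrow(fr)); cols <- seq_len(ncol(fr))
    cy <- sum(rowSums(fr) * (rows - 0.5)) / sum(fr) * px
    cx <- sum(colSums(fr) * (cols - 0.5)) / sum(fr) * px
    expect_lt(max(abs(c(cx, cy) - 2)), px)
  }
  # doubling photons doubles the mean signal above background
  empty <- render_frames(trajectory_set(list()), cfg, seed = 3,
                         photons = 0, background = 5)
  s1 <- mean(render_frames(ts, cfg, seed = 3, photons = 1000,
                           background = 5)) - mean(empty)
  s2 <- mean(render_frames(ts, cfg, seed = 3, photons = 2000,
                           background = 5)) - mean(empty)
  expect_lt(abs(s2 / s1 - 2), 0.1)
})
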