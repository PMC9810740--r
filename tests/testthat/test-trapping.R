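test_that("pairwise distance matrices are exact", {
  tr <- make_traj(c(0, 1))
  expect_equal(pairwise_distance_matrix(tr),
               matrix(c(0, 1, 1, 0), 2), ignore_attr = TRUE)
  same <- make_traj(rep(1, 4), rep(2, 4))
  expect_true(all(pairwise_distance_matrix(same) == 0))
  col <- make_traj(c(0, 3, 4))
  dm <- pairwise_distance_matrix(col)
  expect_equal(dm[1, 3], 4)
  expect_equal(dm, t(dm))
  expect_true(all(diag(dm) == 0))
})

test_that("binarization marks close pairs at the stated cutoff", {
  cfg <- trapping_config(test_length = 0.1, similarity_threshold = 0.36)
  dm <- matrix(c(0, 0.1, 0.1, 0), 2)
  # d = L: exp(-1) ~ 0.368 >= 0.36 -> close
  expect_equal(binarize_matrix(dm, cfg)[1, 2], 1L)
  dm2 <- matrix(c(0, 0.2, 0.2, 0), 2)
  # d = 2L: exp(-4) ~ 0.018 < 0.36 -> far
  expect_equal(binarize_matrix(dm2, cfg)[1, 2], 0L)
  expect_true(all(diag(binarize_matrix(dm2, cfg)) == 1L))
  # threshold -> 1 marks only near-coincident pairs
  tight <- trapping_config(test_length = 0.1, similarity_threshold = 0.999)
  expect_equal(binarize_matrix(dm, tight)[1, 2], 0L)
  expect_equal(binarize_matrix(matrix(c(0, 1e-4, 1e-4, 0), 2), tight)[1, 2], 1L)
})

test_that("diagonal blocks are found in constructed matrices", {
  cfg <- trapping_config()
  # identity: no block
  expect_equal(nrow(find_diagonal_blocks(diag(1L, 10), cfg)), 0)
  # all ones: one full block
  blk <- find_diagonal_blocks(matrix(1L, 8, 8), cfg)
  expect_equal(nrow(blk), 1)
  expect_equal(c(blk$start, blk$end), c(1, 8))
  # two clean blocks separated by zeros
  bm <- matrix(0L, 12, 12)
  bm[1:5, 1:5] <- 1L
  bm[8:12, 8:12] <- 1L  # sizes 5 and 5 with a gap
  diag(bm) <- 1L
  blk2 <- find_diagonal_blocks(bm, cfg)
  expect_equal(nrow(blk2), 2)
  expect_equal(blk2$start, c(1, 8))
  expect_equal(blk2$end, c(5, 12))
  expect_true(all(blk2$fill == 1))
})

test_that("the Brownian null has monotone tails and sane extremes", {
  cfg <- fast_trap_cfg()
  null <- brownian_block_null(120, 0.05, 1 / 35, cfg)
  ks <- 1:50
  p <- trapping_null_p(null, ks)
  expect_equal(p[1], 1)
  expect_true(all(diff(p) <= 0))
  # steps dwarfing the test length produce (almost) no size-3 blocks
  fast <- brownian_block_null(120, 50, 1 / 35, cfg)
  expect_lt(trapping_null_p(fast, 3), 0.05)
  expect_error(brownian_block_null(120, 0.05, 1 / 35,
                                   trapping_config(null_reps = 99)), ">= 100")
})

test_that("immobile trajectories are trapped and ballistic ones free", {
  cfg <- fast_trap_cfg()
  im <- simulate_trajectory(sim_config(motion_model = "immobile",
                                       n_frames = 200, seed = 3))
  seg <- segment_trajectory(im$trajectory, cfg)
  expect_gt(trapped_fraction(seg), 0.95)
  expect_true(all(seg$p_block[seg$state == "trapped"] <= cfg$alpha_fp))

  bal <- make_traj((0:99) * 0.5)  # step = 5x test length
  seg2 <- segment_trajectory(bal, cfg)
  expect_equal(nrow(seg2), 1)
  expect_identical(seg2$state, "free")

  short <- make_traj(c(0, 1, 2))
  expect_warning(seg3 <- segment_trajectory(short, cfg), "too short")
  expect_identical(seg3$state, "free")
})

test_that("segmentation is invariant to rigid motions and joint rescaling", {
  cfg <- fast_trap_cfg(rng_seed = 7)
  sw <- simulate_switching_trajectory(sim_config(motion_model = "switching",
                                                 D_free = 0.1, seed = 77))
  tr <- sw$trajectory
  seg <- segment_trajectory(tr, cfg)

  th <- 0.7
  rot <- trajectory("rot", tr$frames,
                    cos(th) * tr$x - sin(th) * tr$y + 3,
                    sin(th) * tr$x + cos(th) * tr$y - 1,
                    frame_interval = tr$frame_interval)
  seg_rot <- segment_trajectory(rot, cfg)
  expect_equal(as.data.frame(seg)[c("start_index", "end_index", "state")],
               as.data.frame(seg_rot)[c("start_index", "end_index", "state")])

  # joint rescaling of coordinates, test length and localization error
  s <- 2.5
  cfg_s <- fast_trap_cfg(test_length = cfg$test_length * s,
                         sigma_l = cfg$sigma_l * s,
                         d_floor = cfg$d_floor * s^2, rng_seed = 7)
  scl <- trajectory("scl", tr$frames, s * tr$x, s * tr$y,
                    frame_interval = tr$frame_interval)
  seg_scl <- segment_trajectory(scl, cfg_s)
  expect_equal(as.data.frame(seg)[c("start_index", "end_index", "state")],
               as.data.frame(seg_scl)[c("start_index", "end_index", "state")])
})

test_that("Brownian trajectories are rarely trapped, monotone in alpha_fp", {
  sim <- simulate_trajectories(sim_config(n_particles = 15, D_free = 0.05,
                                          motion_model = "brownian", seed = 19))
  fracs <- vapply(c(0.05, 0.01, 0.001), function(afp) {
    cfg <- fast_trap_cfg(alpha_fp = afp)
    segs <- segment_trajectory_set(sim$set, cfg)
    expect_true(all(unlist(lapply(segs, function(s)
      s$p_block[s$state == "trapped"] <= afp))))
    mean(vapply(segs, trapped_fraction, numeric(1)))
  }, numeric(1))
  expect_lt(fracs[1], 0.1)
  expect_true(all(diff(fracs) <= 0))
})

test_that("switching trajectories are segmented near ground truth", {
  cfg <- fast_trap_cfg(test_length = sqrt(0.1^2 + 8 * 0.023^2))
  js <- vapply(1:8, function(k) {
    sw <- simulate_switching_trajectory(
      sim_config(motion_model = "switching", D_free = 0.1, trap_radius = 0.05,
                 k_trap = 1, k_release = 1, seed = 500 + k))
    seg <- segment_trajectory(sw$trajectory, cfg)
    jaccard(trapped_indicator(seg, 400), sw$truth$state == "trapped")
  }, numeric(1))
  expect_gte(stats::median(js), 0.6)
})

test_that("segment export covers each trajectory exactly once", {
  sim <- simulate_trajectories(sim_config(n_particles = 3, D_free = 0.05,
                                          motion_model = "brownian", seed = 8))
  segs <- segment_trajectory_set(sim$set, fast_trap_cfg())
  for (s in segs) {
    expect_equal(s$start_index[1], 1)
    expect_equal(s$end_index[nrow(s)], attr(s, "n"))
    if (nrow(s) > 1) {
      expect_true(all(s$start_index[-1] == s$end_index[-nrow(s)] + 1))
      expect_true(all(s$state[-1] != s$state[-nrow(s)]))
    }
  }
  path <- withr::local_tempfile(fileext = ".csv")
  write_segments(segs, path)
  df <- utils::read.csv(path)
  expect_setequal(unique(df$traj_id), names(sim$set$trajectories))
})
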