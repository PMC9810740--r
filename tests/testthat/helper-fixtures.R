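# Shared fixtures, built in code.

# Trajectory with consecutive frames from coordinate vectors.
make_traj <- function(x, y = rep(0, length(x)), id = "t1", dt = 1 / 35) {
  trajectory(id, seq_along(x) - 1L, x, y, frame_interval = dt)
}

# A tamsd_curve directly from the model, for fit tests.
model_curve <- function(D, alpha, sigma_l, lags_s, n_pairs = 100,
                        duration = max(lags_s) * 4) {
  structure(list(lags = lags_s, msd = 4 * D * lags_s^alpha + 4 * sigma_l^2,
                 n_pairs = rep(n_pairs, length(lags_s)),
                 frame_lags = round(lags_s * 35)),
            duration = duration, class = "tamsd_curve")
}

# Fraction of frames labeled trapped by a segmentation.
trapped_fraction <- function(seg) {
  len <- seg$end_index - seg$start_index + 1
  sum(len[seg$state == "trapped"]) / sum(len)
}

# Per-position trapped indicator of a segmentation.
trapped_indicator <- function(seg, n) {
  out <- rep(FALSE, n)
  for (i in seq_len(nrow(seg)))
    if (seg$state[i] == "trapped")
      out[seg$start_index[i]:seg$end_index[i]] <- TRUE
  out
}

jaccard <- function(a, b) if (!any(a | b)) NA_real_ else sum(a & b) / sum(a | b)

# Small uniform mask fixtures.
full_roi <- function(nr, nc = nr, px = 0.16) binary_mask(matrix(TRUE, nr, nc), px)

# Fast trapping config for unit tests (fewer null replicates).
fast_trap_cfg <- function(...) trapping_config(null_reps = 300, ...)
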