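# Confinement ("trapping") segmentation of trajectories.
#
# The recurrence approach: build the matrix of pairwise distances between all
# positions of a trajectory, rescale by a test length L set to the typical
# size of expected confinement domains, and mark pairs as recurrent when
# exp(-(D_ij/L)^2) >= 0.36 (i.e. D_ij <~ L). Dense square blocks of recurrent
# entries along the diagonal are candidate trapped intervals; candidates are
# kept only if pure Brownian motion at the trajectory's own short-lag
# diffusivity would produce a block of that size with probability <= alpha_fp
# (Monte Carlo null).

#' Trapping-analysis configuration
#'
#' @param test_length um; typical size of expected confinement domains
#'   (default 0.1).
#' @param similarity_threshold recurrence cutoff on `exp(-(D_ij/L)^2)`
#'   (default 0.36); entries at or above it are recurrent, so pairs closer
#'   than about `L * sqrt(-log(threshold))` count as close.
#' @param alpha_fp block-level false-positive probability cutoff against the
#'   Brownian null (default 0.01).
#' @param null_reps Monte Carlo replicates for the null (default 2000,
#'   minimum 100).
#' @param block_fill_min minimum fraction of recurrent entries inside a
#'   candidate block (default 0.95; 1.0 gives strict all-ones blocks).
#' @param sigma_l localization error sd in um used in the null simulations
#'   and in the short-lag diffusivity estimate (default 0.023).
#' @param d_floor um^2/s; lower floor on the null diffusivity estimate
#'   (default 0.01, the immobility threshold). Without a floor, an immobile
#'   or fully trapped trajectory would be compared against an equally
#'   immobile null and no confinement could ever be significant.
#' @param rng_seed seed for the null simulations (default 1).
#' @return A list of class `trapping_config`.
#' @export
trapping_config <- function(test_length = 0.1, similarity_threshold = 0.36,
                            alpha_fp = 0.01, null_reps = 2000,
                            block_fill_min = 0.95, sigma_l = 0.023,
                            d_floor = 0.01, rng_seed = 1) {
  if (test_length <= 0) stop_fmt("test_length must be > 0")
  if (similarity_threshold <= 0 || similarity_threshold >= 1)
    stop_fmt("similarity_threshold must be in (0, 1)")
  if (alpha_fp <= 0 || alpha_fp >= 1) stop_fmt("alpha_fp must be in (0, 1)")
  if (null_reps < 100) stop_fmt("null_reps must be >= 100")
  if (block_fill_min <= 0 || block_fill_min > 1)
    stop_fmt("block_fill_min must be in (0, 1]")
  structure(list(test_length = test_length,
                 similarity_threshold = similarity_threshold,
                 alpha_fp = alpha_fp, null_reps = null_reps,
                 block_fill_min = block_fill_min, sigma_l = sigma_l,
                 d_floor = d_floor, rng_seed = rng_seed),
            class = "trapping_config")
}

#' Pairwise distance matrix of a trajectory
#'
#' @param traj a [trajectory()] (or any list with numeric x, y).
#' @return Symmetric matrix of Euclidean distances in um, zero diagonal.
#' @export
pairwise_distance_matrix <- function(traj) {
  if (length(traj$x) < 2) stop_fmt("need at least 2 localizations")
  as.matrix(stats::dist(cbind(traj$x, traj$y)))
}

#' Binarize a distance matrix into a recurrence matrix
#'
#' Entry (i, j) is 1 iff `exp(-(D_ij / test_length)^2) >= similarity_threshold`,
#' i.e. iff the two positions are within `test_length * sqrt(-log(threshold))`
#' of each other. The diagonal is always 1.
#'
#' @param dm distance matrix (um).
#' @param cfg a [trapping_config()].
#' @return Integer 0/1 matrix of the same dimension.
#' @export
binarize_matrix <- function(dm, cfg = trapping_config()) {
  cutoff <- cfg$test_length * sqrt(-log(cfg$similarity_threshold))
  bm <- (dm <= cutoff) * 1L
  diag(bm) <- 1L
  bm
}

# Column-wise cumulative sums without apply(): one cumsum over the
# column-major vector, with per-column offsets subtracted.
#' @noRd
col_cumsum <- function(m) {
  n <- nrow(m)
  cs <- matrix(cumsum(m), n)
  cs - rep(c(0, cs[n, -ncol(m)]), each = n)
}

# Closure returning the fill fraction of square diagonal blocks, via a
# summed-area table S[i, j] = sum(bm[1:i, 1:j]).
#' @noRd
block_fill_fun <- function(bm) {
  S <- t(col_cumsum(t(col_cumsum(bm))))
  function(a, b) {
    tot <- S[b, b] -
      (if (a > 1) S[b, a - 1] else 0) -
      (if (a > 1) S[a - 1, b] else 0) +
      (if (a > 1) S[a - 1, a - 1] else 0)
    tot / (b - a + 1)^2
  }
}

#' Find dense diagonal blocks in a recurrence matrix
#'
#' Scans the diagonal left to right: every recurrent consecutive pair of
#' positions (super-diagonal 1) not yet covered seeds a 2x2 block, which is
#' grown greedily outward -- with a short look-ahead over single-frame
#' excursions -- while the fraction of 1-entries in the square submatrix
#' stays at or above `block_fill_min`. Overlaps are resolved greedily by
#' descending block size (ties to the earlier start). Blocks have
#' length >= 2.
#'
#' @param bm square 0/1 matrix with unit diagonal.
#' @param cfg a [trapping_config()].
#' @return A data.frame with columns `start`, `end` (1-based position indices),
#'   `size`, `fill`; zero rows when no block qualifies.
#' @export
find_diagonal_blocks <- function(bm, cfg = trapping_config()) {
  n <- nrow(bm)
  empty <- data.frame(start = integer(0), end = integer(0),
                      size = integer(0), fill = numeric(0))
  if (n < 2) return(empty)
  sup <- bm[cbind(seq_len(n - 1), seq(2, n))] == 1
  if (!any(sup)) return(empty)

  fill <- block_fill_fun(bm)
  # Expansion tolerates short non-recurrent interruptions (single-frame
  # excursions) by looking ahead a few positions for an extension that still
  # satisfies the fill constraint.
  lookahead <- 5L
  extend <- function(a, b) {
    repeat {
      grown <- FALSE
      for (j in rev(seq_len(min(lookahead, n - b)))) {
        if (fill(a, b + j) >= cfg$block_fill_min) { b <- b + j; grown <- TRUE; break }
      }
      for (j in rev(seq_len(min(lookahead, a - 1)))) {
        if (fill(a - j, b) >= cfg$block_fill_min) { a <- a - j; grown <- TRUE; break }
      }
      if (!grown) return(c(a, b))
    }
  }
  # Scan left to right: every recurrent consecutive pair not yet covered by a
  # candidate seeds a 2x2 block that is then grown as far as the fill
  # constraint allows.
  cand <- list()
  a <- 1L
  while (a < n) {
    if (!sup[a]) { a <- a + 1L; next }
    res <- extend(a, a + 1L)
    cand[[length(cand) + 1]] <- res
    a <- max(res[2], a) + 1L
  }
  if (length(cand) == 0) return(empty)
  cand <- unique(do.call(rbind, cand))
  df <- data.frame(start = cand[, 1], end = cand[, 2],
                   size = cand[, 2] - cand[, 1] + 1)
  df <- df[order(-df$size, df$start), , drop = FALSE]
  taken <- rep(FALSE, n)
  keep <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    idx <- df$start[i]:df$end[i]
    if (!any(taken[idx])) { keep[i] <- TRUE; taken[idx] <- TRUE }
  }
  df <- df[keep, , drop = FALSE]
  df <- df[order(df$start), , drop = FALSE]
  df$fill <- mapply(fill, df$start, df$end)
  rownames(df) <- NULL
  df
}

# Cache of null distributions, keyed by (n_frames, D bucket, config).
.trap_null_cache <- new.env(parent = emptyenv())

#' @noRd
bucket_d <- function(D) 10^(round(log10(D) * 8) / 8)  # factor ~1.33 buckets

#' Null distribution of the maximal diagonal-block size under Brownian motion
#'
#' Simulates `null_reps` pure Brownian trajectories (diffusivity `D_hat`,
#' localization noise `cfg$sigma_l`), runs each through the same binarize /
#' block-finding pipeline, and records the maximal candidate block size.
#' Results are cached by (n_frames, logarithmic D bucket, config) and are
#' reproducible given `cfg$rng_seed`.
#'
#' @param n_frames number of positions per null trajectory (>= 2).
#' @param D_hat null diffusivity in um^2/s (> 0; bucketed internally).
#' @param frame_interval seconds per frame.
#' @param cfg a [trapping_config()].
#' @return A list of class `trapping_null` with `max_sizes` (one per
#'   replicate; 0 when no block), the bucketed `D`, and `p_block(k)` via
#'   [trapping_null_p()].
#' @export
brownian_block_null <- function(n_frames, D_hat, frame_interval,
                                cfg = trapping_config()) {
  if (n_frames < 2) stop_fmt("n_frames must be >= 2")
  if (D_hat <= 0) stop_fmt("D_hat must be > 0")
  if (cfg$null_reps < 100) stop_fmt("null_reps must be >= 100")
  Db <- bucket_d(D_hat)
  key <- paste(n_frames, signif(Db, 6), signif(frame_interval, 6),
               cfg$test_length, cfg$similarity_threshold, cfg$block_fill_min,
               cfg$null_reps, cfg$sigma_l, cfg$rng_seed, sep = "|")
  if (!is.null(.trap_null_cache[[key]])) return(.trap_null_cache[[key]])
  step_sd <- sqrt(2 * Db * frame_interval)
  max_sizes <- withr::with_seed(cfg$rng_seed, {
    vapply(seq_len(cfg$null_reps), function(r) {
      x <- cumsum(c(0, stats::rnorm(n_frames - 1, 0, step_sd))) +
        stats::rnorm(n_frames, 0, cfg$sigma_l)
      y <- cumsum(c(0, stats::rnorm(n_frames - 1, 0, step_sd))) +
        stats::rnorm(n_frames, 0, cfg$sigma_l)
      bm <- binarize_matrix(as.matrix(stats::dist(cbind(x, y))), cfg)
      blk <- find_diagonal_blocks(bm, cfg)
      if (nrow(blk) == 0) 0L else as.integer(max(blk$size))
    }, integer(1))
  })
  out <- structure(list(max_sizes = max_sizes, D = Db, n_frames = n_frames,
                        frame_interval = frame_interval, cfg = cfg),
                   class = "trapping_null")
  .trap_null_cache[[key]] <- out
  out
}

#' Tail probability of the Brownian block-size null
#'
#' `p(k) = P(max block size >= k)` with an add-one correction, non-increasing
#' in k and equal to 1 at k = 1 (every diagonal entry seeds a trivial block).
#'
#' @param null a [brownian_block_null()] result.
#' @param k block size(s).
#' @return Numeric vector of tail probabilities.
#' @export
trapping_null_p <- function(null, k) {
  vapply(k, function(ki) {
    if (ki <= 1) return(1)
    (1 + sum(null$max_sizes >= ki)) / (length(null$max_sizes) + 1)
  }, numeric(1))
}

#' Short-lag diffusivity estimate used for the Brownian null
#'
#' Lag-1 TAMSD with the localization-error offset removed, floored at
#' `cfg$d_floor` (see [trapping_config()]).
#'
#' @param traj a [trajectory()].
#' @param cfg a [trapping_config()].
#' @return D_hat in um^2/s.
#' @export
estimate_short_lag_d <- function(traj, cfg = trapping_config()) {
  curve <- compute_tamsd(traj, max_lag = min(3, max(traj$frames) - min(traj$frames)))
  msd1 <- curve$msd[1]
  lag1 <- curve$lags[1]
  max((msd1 - 4 * cfg$sigma_l^2) / (4 * lag1), cfg$d_floor)
}

#' Segment a trajectory into free and trapped phases
#'
#' Candidate confinement blocks from [find_diagonal_blocks()] are retained
#' when the Brownian null probability of a block of that size is at most
#' `alpha_fp`; all remaining positions are free. The segmentation covers the
#' trajectory exactly once with alternating states.
#'
#' @param traj a [trajectory()] with >= 4 localizations (shorter trajectories
#'   return a single free segment with a warning).
#' @param cfg a [trapping_config()].
#' @param null optional precomputed [brownian_block_null()] (otherwise built
#'   from the trajectory's own short-lag diffusivity, with caching).
#' @return A data.frame of class `trapping_segmentation` with columns
#'   `start_index`, `end_index` (1-based localization indices), `start_frame`,
#'   `end_frame`, `state` ("free"/"trapped") and `p_block` (NA for free
#'   segments); attributes `traj_id`, `n`, `D_hat`, `candidates` (all
#'   candidate blocks with their p-values, for re-thresholding).
#' @export
segment_trajectory <- function(traj, cfg = trapping_config(), null = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  n <- n_locs(traj)
  if (n < 4) {
    warning("trajectory too short for trapping analysis; returning one free segment",
            call. = FALSE)
    seg <- data.frame(start_index = 1L, end_index = n,
                      start_frame = traj$frames[1], end_frame = traj$frames[n],
                      state = "free", p_block = NA_real_)
    return(structure(seg, traj_id = traj$traj_id, n = n, D_hat = NA_real_,
                     candidates = NULL,
                     class = c("trapping_segmentation", "data.frame")))
  }
  bm <- binarize_matrix(pairwise_distance_matrix(traj), cfg)
  blocks <- find_diagonal_blocks(bm, cfg)
  D_hat <- estimate_short_lag_d(traj, cfg)
  if (is.null(null))
    null <- brownian_block_null(n, D_hat, traj$frame_interval, cfg)
  if (nrow(blocks) > 0) blocks$p_block <- trapping_null_p(null, blocks$size)
  retained <- blocks[blocks$p_block <= cfg$alpha_fp, , drop = FALSE]

  state <- rep("free", n)
  pvec <- rep(NA_real_, n)
  for (i in seq_len(nrow(retained))) {
    idx <- retained$start[i]:retained$end[i]
    state[idx] <- "trapped"
    pvec[idx] <- retained$p_block[i]
  }
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  seg <- data.frame(start_index = starts, end_index = ends,
                    start_frame = traj$frames[starts],
                    end_frame = traj$frames[ends],
                    state = r$values,
                    p_block = ifelse(r$values == "trapped", pvec[starts],
                                     NA_real_))
  structure(seg, traj_id = traj$traj_id, n = n, D_hat = D_hat,
            candidates = blocks,
            class = c("trapping_segmentation", "data.frame"))
}

#' Per-frame trapping state of a segmented trajectory
#'
#' @param seg a [segment_trajectory()] result.
#' @param frames frame indices to look up (default: all frames covered).
#' @return Character vector ("free"/"trapped"; NA for frames outside the
#'   trajectory).
#' @export
trapping_state_at <- function(seg, frames = NULL) {
  lo <- seg$start_frame
  hi <- seg$end_frame
  if (is.null(frames)) frames <- seq(min(lo), max(hi))
  out <- rep(NA_character_, length(frames))
  for (i in seq_len(nrow(seg))) {
    hit <- frames >= lo[i] & frames <= hi[i]
    out[hit] <- seg$state[i]
  }
  out
}

#' Segment every trajectory in a set
#'
#' @param ts a [trajectory_set()].
#' @param cfg a [trapping_config()].
#' @return A named list of [segment_trajectory()] results (by traj_id).
#' @export
segment_trajectory_set <- function(ts, cfg = trapping_config()) {
  stopifnot(inherits(ts, "trajectory_set"))
  lapply(ts$trajectories, segment_trajectory, cfg = cfg)
}

#' Export trapping segments to CSV
#'
#' Columns: traj_id, start_frame, end_frame, state, p_block.
#'
#' @param segs a list of segmentations from [segment_trajectory_set()].
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_segments <- function(segs, path) {
  rows <- do.call(rbind, lapply(segs, function(s)
    data.frame(traj_id = attr(s, "traj_id"), start_frame = s$start_frame,
               end_frame = s$end_frame, state = s$state, p_block = s$p_block,
               stringsAsFactors = FALSE)))
  if (is.null(rows))
    rows <- data.frame(traj_id = character(0), start_frame = integer(0),
                       end_frame = integer(0), state = character(0),
                       p_block = numeric(0))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
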