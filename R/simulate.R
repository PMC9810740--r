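# Synthetic-data generator for two-color single-molecule TIRF experiments.
#
# Emulates the acquisition this package's analyses assume: 400-frame image
# sequences at 35 frames/s, Gaussian localization error of sd 23 nm, particle
# densities of order 0.1-1 um^-2, and a fiber-shaped (actin-like) structure
# channel. Every generator is a pure function of (cfg, seed): the same seed
# reproduces bit-identical output. Ground truth (true positions, per-frame
# states, bound intervals, fiber geometry) is returned alongside the data.

#' Simulation configuration
#'
#' @param n_particles particles per channel (default 1).
#' @param n_frames frames per sequence (default 400).
#' @param frame_interval seconds per frame (default 1/35).
#' @param D_free free diffusion coefficient, um^2/s (default 0.1).
#' @param alpha target anomalous exponent for fBm motion (Hurst = alpha/2).
#' @param sigma_loc localization error sd per axis in um (default 0.023).
#' @param motion_model one of "immobile", "brownian", "fbm", "directed",
#'   "switching", "interacting_pair".
#' @param v drift speed for directed motion, um/s (default 0.5).
#' @param trap_radius reflecting confinement-domain radius, um (default 0.05).
#' @param k_trap,k_release two-state switching rates, 1/s (defaults 1, 1;
#'   mean dwell in each state = 1/rate).
#' @param bind_radius capture radius of the pair model, um (default 0.1).
#' @param k_on,k_off binding/unbinding rates of the pair model, 1/s
#'   (defaults 10 and 4; 1/k_off = 0.25 s mean bound time, matching the
#'   0.2-0.3 s transient colocalization scale of the targeted experiments).
#' @param tether_sd um; spread of the bound-pair tether offset (default 0.02).
#' @param fiber_params list(n_fibers, width_um, curvature) for the structure
#'   channel (defaults 12 fibers, 0.3 um wide, curvature 0.05 rad per step).
#' @param on_fiber_prob probability that a placed localization falls on the
#'   fiber mask (default 0.5).
#' @param field_size square field side in um (default 20).
#' @param pixel_size um per pixel (default 0.16).
#' @param init_state initial state of the switching model ("free"/"trapped").
#' @param reflect if TRUE, free diffusion reflects at the field boundary
#'   (keeps particles in view for long interaction runs); default FALSE.
#' @param seed mandatory RNG seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_particles = 1, n_frames = 400, frame_interval = 1 / 35,
                       D_free = 0.1, alpha = 1, sigma_loc = 0.023,
                       motion_model = "brownian", v = 0.5, trap_radius = 0.05,
                       k_trap = 1, k_release = 1, bind_radius = 0.1,
                       k_on = 10, k_off = 4, tether_sd = 0.02,
                       fiber_params = list(n_fibers = 12, width_um = 0.3,
                                           curvature = 0.05),
                       on_fiber_prob = 0.5, field_size = 20, pixel_size = 0.16,
                       init_state = "free", reflect = FALSE, seed = 1) {
  models <- c("immobile", "brownian", "fbm", "directed", "switching",
              "interacting_pair")
  if (!motion_model %in% models)
    stop_fmt("unknown motion_model '%s' (expected one of: %s)", motion_model,
             paste(models, collapse = ", "))
  stopifnot(n_frames >= 2, frame_interval > 0, D_free >= 0, sigma_loc >= 0,
            alpha > 0, alpha < 2, trap_radius > 0, k_trap >= 0, k_release >= 0,
            bind_radius > 0, k_on >= 0, k_off >= 0, on_fiber_prob >= 0,
            on_fiber_prob <= 1, field_size > 0, pixel_size > 0)
  if (is.null(seed)) stop_fmt("a seed is mandatory for every generator")
  structure(as.list(environment())[setdiff(names(environment()), "models")],
            class = "sim_config")
}

#' @noRd
reflect_into <- function(z, lo, hi) {
  span <- hi - lo
  z <- (z - lo) %% (2 * span)
  lo + ifelse(z > span, 2 * span - z, z)
}

# True (noise-free) 2-D path for the simple motion models.
#' @noRd
simulate_path <- function(cfg) {
  n <- cfg$n_frames
  dt <- cfg$frame_interval
  start <- stats::runif(2, 0.25 * cfg$field_size, 0.75 * cfg$field_size)
  step_sd <- sqrt(2 * cfg$D_free * dt)
  switch(cfg$motion_model,
    immobile = list(x = rep(start[1], n), y = rep(start[2], n)),
    brownian = {
      x <- start[1] + cumsum(c(0, stats::rnorm(n - 1, 0, step_sd)))
      y <- start[2] + cumsum(c(0, stats::rnorm(n - 1, 0, step_sd)))
      if (cfg$reflect) {
        x <- reflect_into(x, 0, cfg$field_size)
        y <- reflect_into(y, 0, cfg$field_size)
      }
      list(x = x, y = y)
    },
    fbm = {
      H <- cfg$alpha / 2
      scale <- sqrt(2 * cfg$D_free) * dt^H
      x <- start[1] + c(0, cumsum(fgn(n - 1, H))) * scale
      y <- start[2] + c(0, cumsum(fgn(n - 1, H))) * scale
      list(x = x, y = y)
    },
    directed = {
      theta <- stats::runif(1, 0, 2 * pi)
      tvec <- (seq_len(n) - 1) * dt
      x <- start[1] + cumsum(c(0, stats::rnorm(n - 1, 0, step_sd))) +
        cfg$v * cos(theta) * tvec
      y <- start[2] + cumsum(c(0, stats::rnorm(n - 1, 0, step_sd))) +
        cfg$v * sin(theta) * tvec
      list(x = x, y = y)
    },
    stop_fmt("motion model '%s' has a dedicated generator", cfg$motion_model))
}

#' @noRd
true_class_of <- function(cfg, thr = classification_thresholds()) {
  switch(cfg$motion_model,
    immobile = "immobile",
    brownian = "normal_diffusion",
    directed = "super_diffusion",
    fbm = if (cfg$alpha < thr$alpha_low) "sub_diffusion"
          else if (cfg$alpha > thr$alpha_high) "super_diffusion"
          else "normal_diffusion",
    NA_character_)
}

#' Simulate one trajectory with localization noise
#'
#' Motion models: `brownian` (Gaussian increments, per-axis variance
#' `2*D_free*dt`); `fbm` (fractional Gaussian increments, Hurst = alpha/2,
#' scaled so TAMSD ~ 4*D*t^alpha); `directed` (Brownian plus constant drift
#' `v` in a random direction); `immobile` (fixed point). All are corrupted by
#' i.i.d. Gaussian localization noise of sd `sigma_loc` per axis.
#'
#' @param cfg a [sim_config()].
#' @param seed RNG seed (default `cfg$seed`).
#' @param traj_id identifier for the emitted trajectory.
#' @return `list(trajectory, truth)`; truth holds the noise-free positions,
#'   the generating (D, alpha) and the generating motion class.
#' @export
simulate_trajectory <- function(cfg, seed = cfg$seed, traj_id = "sim_1") {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$motion_model == "switching")
    return(simulate_switching_trajectory(cfg, seed = seed, traj_id = traj_id))
  withr::with_seed(seed, {
    path <- simulate_path(cfg)
    n <- cfg$n_frames
    x <- path$x + stats::rnorm(n, 0, cfg$sigma_loc)
    y <- path$y + stats::rnorm(n, 0, cfg$sigma_loc)
    list(trajectory = trajectory(traj_id, 0:(n - 1), x, y,
                                 frame_interval = cfg$frame_interval),
         truth = list(x = path$x, y = path$y,
                      D = if (cfg$motion_model == "immobile") 0 else cfg$D_free,
                      alpha = switch(cfg$motion_model, fbm = cfg$alpha,
                                     directed = 2, brownian = 1, immobile = NA_real_),
                      motion_class = true_class_of(cfg)))
  })
}

#' Simulate an ensemble of independent trajectories
#'
#' @param cfg a [sim_config()] (its `n_particles` sets the count).
#' @param seed base seed; trajectory k uses `derive_seed(seed, k)`.
#' @param id_prefix prefix for trajectory ids.
#' @return `list(set, truth)` where `set` is a [trajectory_set()] and `truth`
#'   a named list of per-trajectory ground truths.
#' @export
simulate_trajectories <- function(cfg, seed = cfg$seed, id_prefix = "sim") {
  stopifnot(inherits(cfg, "sim_config"))
  out <- lapply(seq_len(cfg$n_particles), function(k)
    simulate_trajectory(cfg, seed = derive_seed(seed, k),
                        traj_id = sprintf("%s_%04d", id_prefix, k)))
  set <- trajectory_set(lapply(out, `[[`, "trajectory"),
                        pixel_size = cfg$pixel_size, source = "simulation")
  truth <- lapply(out, `[[`, "truth")
  names(truth) <- names(set$trajectories)
  list(set = set, truth = truth)
}

#' Simulate a two-state (free/trapped) switching trajectory
#'
#' A Markov chain with exponential waiting times (rates `k_trap` into and
#' `k_release` out of the trapped state, discretized per frame). Trapped
#' phases are confined to a reflecting disc of radius `trap_radius` centered
#' on the position where trapping began (projected to the nearest fiber point
#' when fiber geometry is supplied); free phases are Brownian with `D_free`.
#'
#' @param cfg a [sim_config()].
#' @param seed RNG seed (default `cfg$seed`).
#' @param traj_id identifier.
#' @param fiber_points optional 2-column matrix of fiber coordinates (um) to
#'   which trap centers are projected.
#' @return `list(trajectory, truth)`; truth includes the per-frame state
#'   ("free"/"trapped") and the noise-free positions.
#' @export
simulate_switching_trajectory <- function(cfg, seed = cfg$seed,
                                          traj_id = "sim_1",
                                          fiber_points = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(seed, {
    n <- cfg$n_frames
    dt <- cfg$frame_interval
    step_sd <- sqrt(2 * cfg$D_free * dt)
    p_trap <- 1 - exp(-cfg$k_trap * dt)
    p_rel <- 1 - exp(-cfg$k_release * dt)
    x <- y <- numeric(n)
    state <- character(n)
    pos <- stats::runif(2, 0.25 * cfg$field_size, 0.75 * cfg$field_size)
    st <- cfg$init_state
    center <- pos
    if (st == "trapped") center <- trap_center(pos, fiber_points)
    for (i in seq_len(n)) {
      x[i] <- pos[1]; y[i] <- pos[2]; state[i] <- st
      # propagate to next frame
      step <- stats::rnorm(2, 0, step_sd)
      if (st == "free") {
        pos <- pos + step
        if (stats::runif(1) < p_trap) {
          st <- "trapped"
          center <- trap_center(pos, fiber_points)
          pos <- reflect_disc(pos, center, cfg$trap_radius)
        }
      } else {
        pos <- reflect_disc(pos + step, center, cfg$trap_radius)
        if (stats::runif(1) < p_rel) st <- "free"
      }
    }
    xo <- x + stats::rnorm(n, 0, cfg$sigma_loc)
    yo <- y + stats::rnorm(n, 0, cfg$sigma_loc)
    list(trajectory = trajectory(traj_id, 0:(n - 1), xo, yo,
                                 frame_interval = dt),
         truth = list(x = x, y = y, state = state, D = cfg$D_free,
                      trap_radius = cfg$trap_radius))
  })
}

#' @noRd
trap_center <- function(pos, fiber_points) {
  if (is.null(fiber_points) || nrow(fiber_points) == 0) return(pos)
  d2 <- (fiber_points[, 1] - pos[1])^2 + (fiber_points[, 2] - pos[2])^2
  as.numeric(fiber_points[which.min(d2), ])
}

# Reflect a position into a disc of radius r around center (radial fold).
#' @noRd
reflect_disc <- function(pos, center, r) {
  v <- pos - center
  d <- sqrt(sum(v^2))
  if (d <= r) return(pos)
  d_new <- 2 * r - d
  if (d_new < 0) d_new <- stats::runif(1, 0, r)  # step >> r: re-place inside
  center + v / d * d_new
}

#' Simulate transiently interacting particle pairs in two channels
#'
#' Channel-B particles diffuse freely (Brownian, `D_free`, reflecting field
#' boundary); channel-A particles diffuse identically while unbound, bind a
#' free B particle within `bind_radius` at rate `k_on`, co-diffuse with it
#' (at a small fixed tether offset of scale `tether_sd`) while bound, and
#' unbind at rate `k_off`. Each B binds at most one A at a time.
#'
#' @param cfg a [sim_config()] (`n_particles` per channel).
#' @param seed RNG seed (default `cfg$seed`).
#' @return `list(set_a, set_b, truth)`; `truth$bound` is a data.frame of
#'   ground-truth bound intervals (id_a, id_b, start_frame, end_frame,
#'   censored = touches the first/last frame).
#' @export
simulate_interacting_pairs <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(seed, {
    n <- cfg$n_frames
    m <- cfg$n_particles
    dt <- cfg$frame_interval
    step_sd <- sqrt(2 * cfg$D_free * dt)
    p_on <- 1 - exp(-cfg$k_on * dt)
    p_off <- 1 - exp(-cfg$k_off * dt)
    ax <- ay <- bx <- by <- matrix(0, n, m)
    ax[1, ] <- stats::runif(m, 0, cfg$field_size)
    ay[1, ] <- stats::runif(m, 0, cfg$field_size)
    bx[1, ] <- stats::runif(m, 0, cfg$field_size)
    by[1, ] <- stats::runif(m, 0, cfg$field_size)
    partner <- rep(NA_integer_, m)       # index of bound B for each A
    tether <- matrix(0, 2, m)
    refrac <- rep(0L, m)                 # post-unbind refractory (frames)
    bound_log <- vector("list", 0)
    open_start <- rep(NA_integer_, m)

    release_one <- function(i, end_frame) {
      bound_log[[length(bound_log) + 1]] <<-
        data.frame(id_a = sprintf("A_%04d", i),
                   id_b = sprintf("B_%04d", partner[i]),
                   start_frame = open_start[i], end_frame = end_frame)
      partner[i] <<- NA_integer_
      open_start[i] <<- NA_integer_
      refrac[i] <<- 2L
    }

    for (f in seq_len(n)) {
      t <- f - 1L  # 0-based frame index
      if (f > 1) {
        # state transitions at the frame boundary: unbinding first, so a
        # 1-frame dwell is possible
        for (i in which(!is.na(partner)))
          if (stats::runif(1) < p_off) release_one(i, t - 1L)
        refrac <- pmax(refrac - 1L, 0L)
        # B particles always diffuse freely
        bx[f, ] <- reflect_into(bx[f - 1, ] + stats::rnorm(m, 0, step_sd),
                                0, cfg$field_size)
        by[f, ] <- reflect_into(by[f - 1, ] + stats::rnorm(m, 0, step_sd),
                                0, cfg$field_size)
        free_a <- is.na(partner)
        ax[f, free_a] <- reflect_into(ax[f - 1, free_a] +
                                        stats::rnorm(sum(free_a), 0, step_sd),
                                      0, cfg$field_size)
        ay[f, free_a] <- reflect_into(ay[f - 1, free_a] +
                                        stats::rnorm(sum(free_a), 0, step_sd),
                                      0, cfg$field_size)
        bnd <- which(!free_a)
        ax[f, bnd] <- bx[f, partner[bnd]] + tether[1, bnd]
        ay[f, bnd] <- by[f, partner[bnd]] + tether[2, bnd]
      }
      # binding attempts for eligible unbound A within bind_radius of a free B
      taken <- partner[!is.na(partner)]
      for (i in which(is.na(partner) & refrac == 0L)) {
        d2 <- (bx[f, ] - ax[f, i])^2 + (by[f, ] - ay[f, i])^2
        d2[taken] <- Inf
        j <- which.min(d2)
        if (length(j) == 1 && d2[j] <= cfg$bind_radius^2 &&
            stats::runif(1) < p_on) {
          partner[i] <- j
          tether[, i] <- stats::rnorm(2, 0, cfg$tether_sd)
          open_start[i] <- t
          ax[f, i] <- bx[f, j] + tether[1, i]
          ay[f, i] <- by[f, j] + tether[2, i]
          taken <- c(taken, j)
        }
      }
    }
    for (i in which(!is.na(partner))) release_one(i, n - 1L)

    noise <- function(mat) mat + stats::rnorm(length(mat), 0, cfg$sigma_loc)
    axn <- noise(ax); ayn <- noise(ay); bxn <- noise(bx); byn <- noise(by)
    make_set <- function(xm, ym, prefix) {
      trajs <- lapply(seq_len(m), function(k)
        trajectory(sprintf("%s_%04d", prefix, k), 0:(n - 1), xm[, k], ym[, k],
                   frame_interval = dt))
      trajectory_set(trajs, pixel_size = cfg$pixel_size, source = "simulation")
    }
    bound <- if (length(bound_log) > 0) do.call(rbind, bound_log) else
      data.frame(id_a = character(0), id_b = character(0),
                 start_frame = integer(0), end_frame = integer(0))
    bound$censored <- bound$start_frame == 0 | bound$end_frame == n - 1
    list(set_a = make_set(axn, ayn, "A"), set_b = make_set(bxn, byn, "B"),
         truth = list(bound = bound,
                      true_a = list(x = ax, y = ay),
                      true_b = list(x = bx, y = by)))
  })
}

#' Generate a synthetic fiber mask and companion intensity image
#'
#' Draws `n_fibers` random smooth curves (persistent random walks of the
#' tangent angle) of width `width_um` across the field, rasterizes them into
#' a binary mask, and renders a companion intensity image (Gaussian-blurred
#' mask plus Poisson shot noise on a constant background), emulating a
#' labeled cytoskeletal structure channel.
#'
#' @param cfg a [sim_config()] (`fiber_params`, `field_size`, `pixel_size`).
#' @param seed RNG seed (default `cfg$seed`).
#' @return `list(mask, image, truth)`: a [binary_mask()], an
#'   [intensity_image()], and truth with the fiber center-line coordinates
#'   (um) and the analytic length x width area estimate.
#' @export
generate_fiber_mask <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"))
  fp <- cfg$fiber_params
  if (is.null(fp$n_fibers) || fp$n_fibers < 1)
    stop_fmt("fiber_params$n_fibers must be >= 1")
  withr::with_seed(seed, {
    px <- cfg$pixel_size
    npix <- max(2L, round(cfg$field_size / px))
    grid <- matrix(FALSE, npix, npix)
    half_w_px <- (fp$width_um / 2) / px
    step_px <- 0.5
    paths <- list()
    total_len <- 0
    for (fb in seq_len(fp$n_fibers)) {
      # start on a random edge, head inward
      edge <- sample(4, 1)
      pos <- switch(edge,
                    c(stats::runif(1, 0, npix), 0),
                    c(stats::runif(1, 0, npix), npix),
                    c(0, stats::runif(1, 0, npix)),
                    c(npix, stats::runif(1, 0, npix)))
      theta <- switch(edge, pi / 2, -pi / 2, 0, pi) +
        stats::runif(1, -pi / 4, pi / 4)
      pts <- matrix(NA_real_, ceiling(3 * npix / step_px), 2)
      k <- 0
      while (pos[1] >= -half_w_px && pos[1] <= npix + half_w_px &&
             pos[2] >= -half_w_px && pos[2] <= npix + half_w_px &&
             k < nrow(pts)) {
        k <- k + 1
        pts[k, ] <- pos
        theta <- theta + stats::rnorm(1, 0, fp$curvature)
        pos <- pos + step_px * c(cos(theta), sin(theta))
      }
      pts <- pts[seq_len(k), , drop = FALSE]
      if (k < 2) next
      total_len <- total_len + (k - 1) * step_px * px
      # rasterize: mark pixels within half width of the center line
      r <- ceiling(half_w_px)
      for (p in seq_len(k)) {
        cx <- pts[p, 1]; cy <- pts[p, 2]
        cols <- max(1, floor(cx - r)):min(npix, ceiling(cx + r) + 1)
        rows <- max(1, floor(cy - r)):min(npix, ceiling(cy + r) + 1)
        if (length(cols) == 0 || length(rows) == 0) next
        cc <- outer(rows * 0, cols - 0.5, "+")
        rr <- outer(rows - 0.5, cols * 0, "+")
        hit <- (cc - cx)^2 + (rr - cy)^2 <= half_w_px^2
        grid[rows, cols] <- grid[rows, cols] | hit
      }
      paths[[length(paths) + 1]] <- pts * px  # um
    }
    mask <- binary_mask(grid, px)
    # companion intensity image: blurred mask + Poisson noise on background
    amp <- 200
    bg <- 10
    sm <- EBImage::gblur(grid * 1, sigma = 1.3)
    img_counts <- matrix(stats::rpois(length(sm), lambda = bg + amp * sm),
                         nrow = nrow(sm))
    img <- intensity_image(img_counts, px)
    list(mask = mask, image = img,
         truth = list(paths = paths, total_length_um = total_len,
                      area_estimate_um2 = total_len * fp$width_um))
  })
}

#' Place point localizations on and off a mask
#'
#' Each of the `n` points lands on a TRUE mask pixel with probability
#' `on_fiber_prob` (uniform over mask pixels, uniform within the pixel) and
#' otherwise uniformly over the off-mask part of the ROI.
#'
#' @param mask a [binary_mask()].
#' @param n number of points.
#' @param on_fiber_prob probability in \[0, 1\].
#' @param seed RNG seed.
#' @param roi optional [binary_mask()] restricting placement (default: whole
#'   grid).
#' @return A [localization_set()] with ground-truth `on_fiber` attribute.
#' @export
place_localizations <- function(mask, n, on_fiber_prob, seed, roi = NULL) {
  stopifnot(inherits(mask, "binary_mask"), on_fiber_prob >= 0,
            on_fiber_prob <= 1, n >= 1)
  roi_grid <- if (is.null(roi)) matrix(TRUE, nrow(mask$grid), ncol(mask$grid))
              else roi$grid
  on_idx <- which(mask$grid & roi_grid)
  off_idx <- which(!mask$grid & roi_grid)
  if (on_fiber_prob > 0 && length(on_idx) == 0)
    stop_fmt("mask has no TRUE pixels inside the ROI")
  if (on_fiber_prob < 1 && length(off_idx) == 0)
    stop_fmt("ROI has no off-mask pixels")
  withr::with_seed(seed, {
    on <- stats::runif(n) < on_fiber_prob
    pick <- integer(n)
    pick[on] <- on_idx[sample.int(length(on_idx), sum(on), replace = TRUE)]
    pick[!on] <- off_idx[sample.int(length(off_idx), sum(!on), replace = TRUE)]
    nr <- nrow(mask$grid)
    row <- ((pick - 1) %% nr) + 1
    col <- ((pick - 1) %/% nr) + 1
    x <- (col - 1 + stats::runif(n)) * mask$pixel_size
    y <- (row - 1 + stats::runif(n)) * mask$pixel_size
    locs <- localization_set(x, y)
    attr(locs, "on_fiber") <- on
    locs
  })
}

#' Render trajectories into a pseudo-TIRF image stack
#'
#' Each particle is drawn as a 2-D Gaussian spot (PSF sd ~ 1.3 px); frames
#' carry Poisson shot noise on signal plus background and Gaussian read
#' noise.
#'
#' @param ts a [trajectory_set()] (positions in um inside the field).
#' @param cfg a [sim_config()] (field and pixel geometry).
#' @param seed RNG seed (default `cfg$seed`).
#' @param photons expected photons per particle per frame (default 500).
#' @param background expected background photons per pixel (default 10).
#' @param read_noise_sd Gaussian read noise sd in counts (default 2).
#' @param psf_sd_px PSF standard deviation in pixels (default 1.3).
#' @return Numeric array \[rows, cols, frames\].
#' @export
render_frames <- function(ts, cfg, seed = cfg$seed, photons = 500,
                          background = 10, read_noise_sd = 2, psf_sd_px = 1.3) {
  stopifnot(inherits(ts, "trajectory_set"), inherits(cfg, "sim_config"))
  px <- cfg$pixel_size
  npix <- max(2L, round(cfg$field_size / px))
  n_frames <- cfg$n_frames
  locs <- as.data.frame(as_localizations(ts))
  withr::with_seed(seed, {
    stack <- array(0, c(npix, npix, n_frames))
    half <- ceiling(4 * psf_sd_px)
    for (f in seq_len(n_frames)) {
      signal <- matrix(0, npix, npix)
      sub <- locs[locs$frame == f - 1, , drop = FALSE]
      for (i in seq_len(nrow(sub))) {
        cx <- sub$x[i] / px
        cy <- sub$y[i] / px
        cols <- max(1, floor(cx - half)):min(npix, ceiling(cx + half))
        rows <- max(1, floor(cy - half)):min(npix, ceiling(cy + half))
        if (length(cols) == 0 || length(rows) == 0) next
        gx <- exp(-((cols - 0.5 - cx)^2) / (2 * psf_sd_px^2))
        gy <- exp(-((rows - 0.5 - cy)^2) / (2 * psf_sd_px^2))
        spot <- outer(gy, gx) / (2 * pi * psf_sd_px^2)
        signal[rows, cols] <- signal[rows, cols] + photons * spot
      }
      counts <- stats::rpois(npix * npix, lambda = background + signal) +
        stats::rnorm(npix * npix, 0, read_noise_sd)
      stack[, , f] <- matrix(pmax(counts, 0), npix, npix)
    }
    stack
  })
}
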