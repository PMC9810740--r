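# Time-averaged MSD analysis: TAMSD curves, anomalous-diffusion model fit
# MSD(t) = 4*D*t^alpha + 4*sigma_l^2, and four-way motion classification.

#' TAMSD fitting configuration
#'
#' @param sigma_l localization error sd in um (default 0.023, i.e. 23 nm).
#' @param sigma_l_fixed if TRUE (default) sigma_l is held fixed in the fit;
#'   if FALSE it is a free parameter (used e.g. to recover the localization
#'   error from immobile emitters).
#' @param max_lag_fraction fraction of the trajectory duration up to which
#'   lags enter the fit (default 0.10; long-lag TAMSD estimates of a single
#'   trajectory are high-variance and bias the anomalous exponent downward,
#'   so short-lag fitting is standard practice).
#' @param min_pairs_per_lag minimum displacement pairs a lag must average over
#'   to be used (default 10).
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(sigma_l = 0.023, sigma_l_fixed = TRUE,
                       max_lag_fraction = 0.10, min_pairs_per_lag = 10) {
  if (sigma_l < 0) stop_fmt("sigma_l must be >= 0")
  if (max_lag_fraction <= 0 || max_lag_fraction > 1)
    stop_fmt("max_lag_fraction must be in (0, 1]")
  structure(list(sigma_l = sigma_l, sigma_l_fixed = sigma_l_fixed,
                 max_lag_fraction = max_lag_fraction,
                 min_pairs_per_lag = min_pairs_per_lag),
            class = "fit_config")
}

#' Motion classification thresholds
#'
#' Particles with D below `d_immobile` are immobile; mobile particles are
#' normal when `alpha_low <= alpha <= alpha_high` (both bounds inclusive),
#' sub-diffusive below and super-diffusive above.
#'
#' @param d_immobile um^2/s (default 0.01).
#' @param alpha_low,alpha_high anomalous-exponent bounds (defaults 0.75, 1.25).
#' @return A list of class `classification_thresholds`.
#' @export
classification_thresholds <- function(d_immobile = 0.01, alpha_low = 0.75,
                                      alpha_high = 1.25) {
  if (!(alpha_low > 0 && alpha_low < alpha_high))
    stop_fmt("need 0 < alpha_low < alpha_high")
  structure(list(d_immobile = d_immobile, alpha_low = alpha_low,
                 alpha_high = alpha_high),
            class = "classification_thresholds")
}

#' @noRd
motion_classes <- function() c("immobile", "sub_diffusion", "normal_diffusion",
                               "super_diffusion")

#' Compute the time-averaged MSD curve of one trajectory
#'
#' For each frame lag n, averages the squared displacement over all pairs of
#' localizations whose frame difference equals n (true frame differences, so
#' gap-closed trajectories are handled without interpolation). Lags with no
#' pairs are omitted.
#'
#' @param traj a [trajectory()].
#' @param max_lag maximum frame lag, `1 <= max_lag < span of frames`
#'   (default: the full span minus one).
#' @return A list of class `tamsd_curve` with `lags` (s), `msd` (um^2),
#'   `n_pairs`, `frame_lags`, and the trajectory duration as attribute.
#' @export
compute_tamsd <- function(traj, max_lag = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  span <- max(traj$frames) - min(traj$frames)
  if (is.null(max_lag)) max_lag <- span
  max_lag <- as.integer(max_lag)
  if (max_lag < 1 || max_lag > span)
    stop_fmt("max_lag must be in [1, %d] for this trajectory", span)
  fr <- traj$frames
  msd <- n_pairs <- numeric(max_lag)
  for (lag in seq_len(max_lag)) {
    j <- match(fr + lag, fr)
    ok <- !is.na(j)
    n_pairs[lag] <- sum(ok)
    if (n_pairs[lag] > 0) {
      jj <- j[ok]
      msd[lag] <- mean((traj$x[jj] - traj$x[ok])^2 +
                       (traj$y[jj] - traj$y[ok])^2)
    }
  }
  keep <- n_pairs > 0
  structure(list(lags = seq_len(max_lag)[keep] * traj$frame_interval,
                 msd = msd[keep], n_pairs = n_pairs[keep],
                 frame_lags = seq_len(max_lag)[keep]),
            duration = span * traj$frame_interval,
            class = "tamsd_curve")
}

#' Ensemble-averaged TAMSD curve of a trajectory set
#'
#' Per-lag average of the individual TAMSD curves, weighted by the number of
#' displacement pairs each trajectory contributes at that lag. Used e.g. to
#' estimate the localization error from a population of immobile emitters.
#'
#' @param ts a [trajectory_set()] (all trajectories share `frame_interval`).
#' @param max_lag maximum frame lag (default: largest common span).
#' @return A `tamsd_curve` (see [compute_tamsd()]).
#' @export
ensemble_tamsd <- function(ts, max_lag = NULL) {
  stopifnot(inherits(ts, "trajectory_set"), length(ts) > 0)
  spans <- vapply(ts$trajectories, function(t) max(t$frames) - min(t$frames),
                  numeric(1))
  if (is.null(max_lag)) max_lag <- min(spans)
  curves <- lapply(ts$trajectories, compute_tamsd,
                   max_lag = min(max_lag, min(spans)))
  all_lags <- sort(unique(unlist(lapply(curves, `[[`, "frame_lags"))))
  msd <- npairs <- numeric(length(all_lags))
  for (cv in curves) {
    i <- match(cv$frame_lags, all_lags)
    msd[i] <- msd[i] + cv$msd * cv$n_pairs
    npairs[i] <- npairs[i] + cv$n_pairs
  }
  keep <- npairs > 0
  dt <- ts$trajectories[[1]]$frame_interval
  structure(list(lags = all_lags[keep] * dt, msd = msd[keep] / npairs[keep],
                 n_pairs = npairs[keep], frame_lags = all_lags[keep]),
            duration = max(spans) * dt,
            class = "tamsd_curve")
}

#' Fit the anomalous diffusion model to a TAMSD curve
#'
#' Unweighted least squares of `msd ~ 4*D*t^alpha + 4*sigma_l^2` in linear
#' space (the localization-error offset is additive in linear space), with
#' bounds `D >= 0`, `0 <= alpha <= 2`. The model is linear in `4*D` (and in
#' `4*sigma_l^2` when sigma_l is free) at fixed alpha, so those parameters
#' are profiled in closed form and alpha is found by a deterministic grid
#' search over \[0, 2\] refined by golden-section optimization -- robust
#' against the flat D-alpha ridge that traps generic nonlinear optimizers on
#' noisy single-trajectory curves. When sigma_l is free, alpha is bounded
#' below by 0.1: as alpha approaches 0 the power term degenerates into a
#' second constant offset and sigma_l would no longer be identifiable.
#'
#' @param curve a [compute_tamsd()] result.
#' @param cfg a [fit_config()].
#' @param fix_alpha optional numeric: hold alpha fixed at this value (used for
#'   cross-checks against linear regression at alpha = 1).
#' @return A list of class `diffusion_fit` with `D` (um^2/s), `alpha`,
#'   `sigma_l` (um), `rss`, `n_lags_used`.
#' @export
fit_msd <- function(curve, cfg = fit_config(), fix_alpha = NULL) {
  stopifnot(inherits(curve, "tamsd_curve"))
  duration <- attr(curve, "duration")
  use <- curve$lags <= cfg$max_lag_fraction * duration &
    curve$n_pairs >= cfg$min_pairs_per_lag
  t <- curve$lags[use]
  y <- curve$msd[use]
  if (length(t) < 3)
    stop_fmt("fewer than 3 usable lags (%d) after max_lag_fraction/min_pairs filters",
             length(t))

  sl_fix <- if (cfg$sigma_l_fixed) cfg$sigma_l else NULL

  # Closed-form profile of the linear parameters at a given alpha.
  profile_at <- function(a) {
    ta <- t^a
    if (!is.null(sl_fix)) {
      yc <- y - 4 * sl_fix^2
      D <- max(0, sum(yc * ta) / (4 * sum(ta^2)))
      sl <- sl_fix
    } else {
      b <- tryCatch(unname(stats::lm.fit(cbind(1, ta), y)$coefficients),
                    error = function(e) c(NA, NA))
      if (anyNA(b) || b[2] < 0) {          # offset-only model
        D <- 0
        sl <- sqrt(max(mean(y), 0)) / 2
      } else if (b[1] < 0) {               # no-offset model
        D <- max(0, sum(y * ta) / (4 * sum(ta^2)))
        sl <- 0
      } else {
        D <- b[2] / 4
        sl <- sqrt(b[1] / 4)
      }
    }
    rss <- sum((y - 4 * D * ta - 4 * sl^2)^2)
    list(D = D, sl = sl, rss = rss)
  }

  if (!is.null(fix_alpha)) {
    alpha <- fix_alpha
  } else {
    # With sigma_l free, alpha is bounded away from 0: as alpha -> 0 the
    # power term degenerates into a second constant offset and the model
    # loses identifiability (D*t^alpha would absorb what is localization
    # error).
    a_min <- if (is.null(sl_fix)) 0.1 else 0
    grid <- seq(a_min, 2, by = 0.02)
    rss_grid <- vapply(grid, function(a) profile_at(a)$rss, numeric(1))
    a0 <- grid[which.min(rss_grid)]
    alpha <- stats::optimize(function(a) profile_at(a)$rss,
                             interval = c(max(a_min, a0 - 0.02),
                                          min(2, a0 + 0.02)),
                             tol = 1e-9)$minimum
    if (profile_at(a0)$rss < profile_at(alpha)$rss) alpha <- a0
  }
  best <- profile_at(alpha)
  structure(list(D = best$D, alpha = alpha, sigma_l = best$sl, rss = best$rss,
                 n_lags_used = length(t)),
            class = "diffusion_fit")
}

#' Classify a diffusion fit into one of four motion classes
#'
#' Immobile iff `D < d_immobile` (strict); otherwise normal diffusion iff
#' `alpha_low <= alpha <= alpha_high` (inclusive), sub-diffusion below,
#' super-diffusion above. A total function on valid (D, alpha).
#'
#' @param fit a [fit_msd()] result (or any list with D and alpha).
#' @param thr a [classification_thresholds()].
#' @return One of `"immobile"`, `"sub_diffusion"`, `"normal_diffusion"`,
#'   `"super_diffusion"`.
#' @export
classify_motion <- function(fit, thr = classification_thresholds()) {
  if (fit$D < thr$d_immobile) return("immobile")
  if (fit$alpha < thr$alpha_low) return("sub_diffusion")
  if (fit$alpha > thr$alpha_high) return("super_diffusion")
  "normal_diffusion"
}

#' TAMSD-fit and classify every trajectory in a set
#'
#' @param ts a [trajectory_set()], typically after [filter_min_length()].
#' @param cfg a [fit_config()].
#' @param thr a [classification_thresholds()].
#' @return A list of class `ensemble_classification`:
#'   `per_trajectory` (data.frame: traj_id, n_frames, D_um2_s, alpha,
#'   sigma_l_um, rss, motion_class), `fractions` (named numeric over the four
#'   classes, summing to 1), `d_summary` (per-class n, mean and sem of D), and
#'   `n_failed` (trajectories whose fit had insufficient data).
#' @export
classify_ensemble <- function(ts, cfg = fit_config(),
                              thr = classification_thresholds()) {
  stopifnot(inherits(ts, "trajectory_set"))
  rows <- list()
  n_failed <- 0L
  for (traj in ts$trajectories) {
    rec <- tryCatch({
      fit <- fit_msd(compute_tamsd(traj), cfg)
      data.frame(traj_id = traj$traj_id, n_frames = n_locs(traj),
                 D_um2_s = fit$D, alpha = fit$alpha, sigma_l_um = fit$sigma_l,
                 rss = fit$rss,
                 motion_class = classify_motion(fit, thr),
                 stringsAsFactors = FALSE)
    }, error = function(e) NULL)
    if (is.null(rec)) n_failed <- n_failed + 1L else rows[[length(rows) + 1]] <- rec
  }
  per <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(traj_id = character(0), n_frames = integer(0),
               D_um2_s = numeric(0), alpha = numeric(0),
               sigma_l_um = numeric(0), rss = numeric(0),
               motion_class = character(0))
  if (nrow(per) == 0) warning("no classifiable trajectories in set", call. = FALSE)
  cls <- factor(per$motion_class, levels = motion_classes())
  counts <- table(cls)
  fractions <- if (nrow(per) > 0) as.numeric(counts) / nrow(per) else
    rep(NA_real_, 4)
  names(fractions) <- motion_classes()
  d_summary <- do.call(rbind, lapply(motion_classes(), function(cl) {
    d <- per$D_um2_s[per$motion_class == cl]
    data.frame(motion_class = cl, n = length(d),
               D_mean = if (length(d) > 0) mean(d) else NA_real_,
               D_sem = sem(d), stringsAsFactors = FALSE)
  }))
  structure(list(per_trajectory = per, fractions = fractions,
                 d_summary = d_summary, n_failed = n_failed),
            class = "ensemble_classification")
}

#' @export
print.ensemble_classification <- function(x, ...) {
  cat(sprintf("<ensemble_classification: %d trajectories, %d failed fits>\n",
              nrow(x$per_trajectory), x$n_failed))
  print(round(x$fractions, 4))
  invisible(x)
}

#' Export per-trajectory fits to CSV
#'
#' Columns: traj_id, n_frames, D_um2_s, alpha, sigma_l_um, rss, motion_class.
#'
#' @param ec a [classify_ensemble()] result.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_fits <- function(ec, path) {
  stopifnot(inherits(ec, "ensemble_classification"))
  utils::write.csv(ec$per_trajectory, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
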