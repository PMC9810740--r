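# End-to-end runs: configuration handling, stage orchestration, reports.
#
# A run configuration is a plain named list (or a YAML file with the same
# structure). Per-module blocks mirror the corresponding *_config()
# constructors:
#
#   seed: 1
#   output_dir: "out"            # optional; outputs written when present
#   input: {trajectories: "a.csv", trajectories_b: "b.csv",
#           frame_interval: 0.02857, image: "actin.tif", roi: "roi.tif",
#           pixel_size: 0.16}
#   tamsd: {sigma_l_um, sigma_l_fixed, max_lag_fraction, min_pairs_per_lag,
#           d_immobile, alpha_low, alpha_high, min_frames}
#   trapping: {test_length_um, similarity_threshold, alpha_fp, null_reps,
#              block_fill_min, seed}
#   coloc: {n_randomizations, seed, mask: {rolling_ball_px, min_component_px}}
#   interaction: {coloc_radius_um, max_gap_frames, min_event_frames,
#                 cell_area_um2}
#
# Stage seeds are derived from the global seed by derive_seed(seed, stage),
# so stages can be re-run in isolation; deterministic outputs replay
# bit-identically from the echoed parameters.

#' Load a run configuration
#'
#' @param config a named list, or the path to a YAML file.
#' @return The configuration as a named list with a `seed` (default 1).
#' @export
load_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop_fmt("config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop_fmt("config must be a list or a YAML file path")
  config$seed <- config$seed %||% 1
  config
}

#' @noRd
cfg_tamsd <- function(block) {
  list(fit = fit_config(sigma_l = block$sigma_l_um %||% 0.023,
                        sigma_l_fixed = block$sigma_l_fixed %||% TRUE,
                        max_lag_fraction = block$max_lag_fraction %||% 0.10,
                        min_pairs_per_lag = block$min_pairs_per_lag %||% 10),
       thr = classification_thresholds(
         d_immobile = block$d_immobile %||% 0.01,
         alpha_low = block$alpha_low %||% 0.75,
         alpha_high = block$alpha_high %||% 1.25),
       min_frames = block$min_frames %||% 120)
}

#' @noRd
cfg_trapping <- function(block, seed) {
  trapping_config(test_length = block$test_length_um %||% 0.1,
                  similarity_threshold = block$similarity_threshold %||% 0.36,
                  alpha_fp = block$alpha_fp %||% 0.01,
                  null_reps = block$null_reps %||% 2000,
                  block_fill_min = block$block_fill_min %||% 0.95,
                  sigma_l = block$sigma_l_um %||% 0.023,
                  rng_seed = block$seed %||% seed)
}

#' @noRd
new_report <- function(stage, config, params, results, warnings = character(0)) {
  structure(list(stage = stage, version = as.character(
    utils::packageVersion("sptdyn")),
    config_echo = config, params = params, results = results,
    n_warnings = length(warnings), warnings = warnings,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report: stage '%s', %d warning(s)>\n", x$stage,
              x$n_warnings))
  invisible(x)
}

#' Write a run report as JSON
#' @param report a `run_report`.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_report <- function(report, path) {
  rep2 <- report
  rep2$timestamp <- NULL  # replays must be bit-identical
  jsonlite::write_json(rep2, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, pretty = TRUE)
  invisible(path)
}

#' @noRd
collect_warnings <- function(expr) {
  warns <- character(0)
  val <- withCallingHandlers(expr, warning = function(w) {
    warns <<- c(warns, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  list(value = val, warnings = warns)
}

#' Run the TAMSD classification stage
#'
#' Filter by minimum length, compute TAMSD curves, fit the anomalous
#' diffusion model, classify, and export class fractions and per-class D
#' summaries.
#'
#' @param config run configuration (list or YAML path); needs
#'   `input$trajectories` unless `trajectories` is given directly.
#' @param trajectories optional [trajectory_set()] overriding the file input.
#' @return A `run_report` whose `results` hold the [classify_ensemble()]
#'   output.
#' @export
run_tamsd <- function(config, trajectories = NULL) {
  config <- load_run_config(config)
  pars <- cfg_tamsd(config$tamsd %||% list())
  ts <- trajectories %||% {
    path <- config$input$trajectories
    if (is.null(path)) stop_fmt("config needs input$trajectories")
    read_trajectories(path,
                      frame_interval = config$input$frame_interval %||% (1 / 35))
  }
  res <- collect_warnings({
    kept <- filter_min_length(ts, pars$min_frames)
    classify_ensemble(kept, pars$fit, pars$thr)
  })
  report <- new_report("tamsd", config,
                       list(fit = unclass(pars$fit), thr = unclass(pars$thr),
                            min_frames = pars$min_frames,
                            n_input = length(ts)),
                       list(fractions = res$value$fractions,
                            d_summary = res$value$d_summary,
                            n_classified = nrow(res$value$per_trajectory),
                            n_failed = res$value$n_failed),
                       res$warnings)
  report$classification <- res$value
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    write_fits(res$value, file.path(config$output_dir, "tamsd_fits.csv"))
    write_report(report, file.path(config$output_dir, "tamsd_report.json"))
  }
  report
}

#' Run the trapping + interaction stage
#'
#' Segments both channels into free/trapped phases, detects colocalization
#' events, classifies each event by partner states, and exports event tables
#' and summary statistics.
#'
#' @param config run configuration; needs `input$trajectories` and
#'   `input$trajectories_b` unless sets are given directly.
#' @param ts_a,ts_b optional [trajectory_set()]s overriding file input.
#' @param cell_area cell area in um^2 (default: bounding box of channel A).
#' @return A `run_report` with events, event statistics and state-pair
#'   densities in `results`.
#' @export
run_interaction <- function(config, ts_a = NULL, ts_b = NULL,
                            cell_area = NULL) {
  config <- load_run_config(config)
  fi <- config$input$frame_interval %||% (1 / 35)
  ts_a <- ts_a %||% read_trajectories(config$input$trajectories,
                                      frame_interval = fi)
  ts_b <- ts_b %||% read_trajectories(config$input$trajectories_b,
                                      frame_interval = fi)
  iblock <- config$interaction %||% list()
  icfg <- interaction_config(
    coloc_radius = iblock$coloc_radius_um %||% 0.1,
    max_gap_frames = iblock$max_gap_frames %||% 1,
    min_event_frames = iblock$min_event_frames %||% 2)
  tcfg <- cfg_trapping(config$trapping %||% list(),
                       derive_seed(config$seed, 2))
  if (is.null(cell_area)) {
    cell_area <- iblock$cell_area_um2 %||% {
      locs <- as.data.frame(as_localizations(ts_a))
      if (nrow(locs) == 0) 1 else
        max(diff(range(locs$x)), 1e-6) * max(diff(range(locs$y)), 1e-6)
    }
  }
  res <- collect_warnings({
    seg_a <- segment_trajectory_set(ts_a, tcfg)
    seg_b <- segment_trajectory_set(ts_b, tcfg)
    events <- detect_coloc_events(ts_a, ts_b, icfg)
    stats <- event_stats(events, ts_a, cell_area)
    states <- if (nrow(events) > 0)
      classify_event_states(events, seg_a, seg_b, cell_area) else NULL
    list(events = events, stats = stats, states = states,
         seg_a = seg_a, seg_b = seg_b)
  })
  v <- res$value
  report <- new_report("interaction", config,
                       list(interaction = unclass(icfg),
                            trapping = unclass(tcfg), cell_area = cell_area),
                       list(n_events = nrow(v$events),
                            duration_mean_s = v$stats$duration_mean_s,
                            freq_per_particle_frame =
                              v$stats$freq_per_particle_frame,
                            freq_per_um2_per_s = v$stats$freq_per_um2_per_s,
                            state_fractions = if (!is.null(v$states))
                              v$states$fractions else NULL,
                            state_densities = if (!is.null(v$states))
                              v$states$densities else NULL),
                       res$warnings)
  report$detail <- v
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    ev_out <- if (!is.null(v$states)) v$states$events else v$events
    write_events(ev_out, file.path(config$output_dir, "events.csv"))
    write_segments(v$seg_a, file.path(config$output_dir, "segments_a.csv"))
    write_segments(v$seg_b, file.path(config$output_dir, "segments_b.csv"))
    write_report(report, file.path(config$output_dir, "interaction_report.json"))
  }
  report
}

#' Run the colocalization stage
#'
#' Builds the fiber mask from the structure image, computes the Manders
#' coefficient of the signal channel against it, the homogeneous-distribution
#' control, and the single-molecule colocalization index of the point
#' localizations, with its randomization null.
#'
#' @param config run configuration; needs `input$image` (structure channel
#'   TIFF) plus either `input$trajectories` or direct arguments.
#' @param locs optional [localization_set()] overriding file input.
#' @param image optional [intensity_image()] (structure channel).
#' @param signal optional [intensity_image()] for the MCC numerator channel.
#' @param roi optional [binary_mask()] cell ROI (default: whole frame).
#' @return A `run_report` with the mask provenance, MCC, control and index in
#'   `results`.
#' @export
run_coloc <- function(config, locs = NULL, image = NULL, signal = NULL,
                      roi = NULL) {
  config <- load_run_config(config)
  px <- config$input$pixel_size %||% 0.16
  if (is.null(image)) {
    if (is.null(config$input$image))
      stop_fmt("config needs input$image (structure channel)")
    image <- read_image_tiff(config$input$image, px)
  }
  if (is.null(roi)) {
    roi <- if (!is.null(config$input$roi)) read_mask_tiff(config$input$roi, px)
           else binary_mask(matrix(TRUE, nrow(image$grid), ncol(image$grid)),
                            image$pixel_size)
  }
  if (is.null(locs)) {
    if (is.null(config$input$trajectories))
      stop_fmt("config needs input$trajectories (or pass locs directly)")
    ts <- read_trajectories(config$input$trajectories,
                            frame_interval = config$input$frame_interval %||% (1 / 35))
    locs <- as_localizations(ts)
  }
  cblock <- config$coloc %||% list()
  mask_pars <- cblock$mask %||% list()
  seed <- cblock$seed %||% derive_seed(config$seed, 3)
  res <- collect_warnings({
    mask <- build_fiber_mask(image, roi,
                             rolling_ball_px = mask_pars$rolling_ball_px %||% 10,
                             min_component_px = mask_pars$min_component_px %||% 5)
    mcc <- if (!is.null(signal)) manders_mcc(signal, mask, roi) else NULL
    ctrl <- homogeneous_control_mcc(mask, roi)
    idx <- sm_coloc_index(locs, mask, roi,
                          n_randomizations = cblock$n_randomizations %||% 100,
                          seed = seed)
    list(mask = mask, mcc = mcc, control = ctrl, index = idx)
  })
  v <- res$value
  report <- new_report("coloc", config,
                       list(mask = attr(v$mask, "method"),
                            threshold = attr(v$mask, "threshold"),
                            n_randomizations = v$index$n_randomizations,
                            seed = seed),
                       list(mcc = if (!is.null(v$mcc)) v$mcc$mcc else NULL,
                            homogeneous_control = v$control$mcc,
                            coloc_index = v$index$index,
                            f_observed = v$index$f_observed,
                            f_expected = v$index$f_expected,
                            n_localizations = v$index$n_localizations),
                       res$warnings)
  report$detail <- v
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    write_report(report, file.path(config$output_dir, "coloc_report.json"))
  }
  report
}
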