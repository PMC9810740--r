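# Transient two-channel colocalization events: detection, frequency/duration
# statistics, and classification by the trapping state of both partners.

#' Interaction-detection configuration
#'
#' @param coloc_radius um; two particles are colocalized in a frame when
#'   their distance is at most this (default 0.1, about 4-5x the combined
#'   localization and channel-registration error of the targeted
#'   acquisitions).
#' @param max_gap_frames frames a pair may exceed the radius without ending
#'   the event (default 1).
#' @param min_event_frames minimum event span in frames (default 2).
#' @return A list of class `interaction_config`.
#' @export
interaction_config <- function(coloc_radius = 0.1, max_gap_frames = 1,
                               min_event_frames = 2) {
  stopifnot(coloc_radius > 0, max_gap_frames >= 0, min_event_frames >= 1)
  structure(list(coloc_radius = coloc_radius, max_gap_frames = max_gap_frames,
                 min_event_frames = min_event_frames),
            class = "interaction_config")
}

#' Detect transient colocalization events between two channels
#'
#' In every frame, channel-A and channel-B particles within `coloc_radius`
#' are paired by greedy closest-pair assignment (each particle in at most one
#' pair per frame). For each (A, B) pair, maximal runs of colocalized frames
#' -- tolerating interruptions of up to `max_gap_frames` -- become events;
#' events spanning fewer than `min_event_frames` frames are discarded.
#'
#' @param ts_a,ts_b [trajectory_set()]s sharing the frame clock and
#'   `frame_interval`.
#' @param cfg an [interaction_config()].
#' @return A data.frame of class `coloc_events` with columns `id_a`, `id_b`,
#'   `start_frame`, `end_frame`, `duration_s`, `n_frames_coloc`,
#'   `mean_distance_um`; attribute `cfg`.
#' @export
detect_coloc_events <- function(ts_a, ts_b, cfg = interaction_config()) {
  stopifnot(inherits(ts_a, "trajectory_set"), inherits(ts_b, "trajectory_set"))
  empty <- structure(
    data.frame(id_a = character(0), id_b = character(0),
               start_frame = integer(0), end_frame = integer(0),
               duration_s = numeric(0), n_frames_coloc = integer(0),
               mean_distance_um = numeric(0)),
    cfg = cfg, class = c("coloc_events", "data.frame"))
  if (length(ts_a) == 0 || length(ts_b) == 0) return(empty)
  dt_a <- ts_a$trajectories[[1]]$frame_interval
  dt_b <- ts_b$trajectories[[1]]$frame_interval
  if (!isTRUE(all.equal(dt_a, dt_b)))
    stop_fmt("channels have different frame intervals (%g vs %g)", dt_a, dt_b)

  la <- as.data.frame(as_localizations(ts_a))
  lb <- as.data.frame(as_localizations(ts_b))
  frames <- intersect(unique(la$frame), unique(lb$frame))
  la_by <- split(la, la$frame)
  lb_by <- split(lb, lb$frame)

  # per-pair colocalized frames, accumulated as (frame, distance)
  pair_frames <- new.env(parent = emptyenv())
  for (f in frames) {
    A <- la_by[[as.character(f)]]
    B <- lb_by[[as.character(f)]]
    dmat <- outer(A$x, B$x, "-")^2 + outer(A$y, B$y, "-")^2
    hits <- which(dmat <= cfg$coloc_radius^2, arr.ind = TRUE)
    if (nrow(hits) == 0) next
    d <- sqrt(dmat[hits])
    ord <- order(d)
    used_a <- logical(nrow(A))
    used_b <- logical(nrow(B))
    for (h in ord) {
      i <- hits[h, 1]; j <- hits[h, 2]
      if (used_a[i] || used_b[j]) next
      used_a[i] <- TRUE; used_b[j] <- TRUE
      key <- paste(A$traj_id[i], B$traj_id[j], sep = "\r")
      pair_frames[[key]] <- rbind(pair_frames[[key]], c(f, d[h]))
    }
  }

  rows <- list()
  for (key in ls(pair_frames)) {
    rec <- pair_frames[[key]]
    rec <- rec[order(rec[, 1]), , drop = FALSE]
    ids <- strsplit(key, "\r", fixed = TRUE)[[1]]
    gaps <- c(0, diff(rec[, 1]))
    run_id <- cumsum(gaps > cfg$max_gap_frames + 1)
    for (rid in unique(run_id)) {
      sub <- rec[run_id == rid, , drop = FALSE]
      span <- sub[nrow(sub), 1] - sub[1, 1] + 1
      if (span < cfg$min_event_frames) next
      rows[[length(rows) + 1]] <- data.frame(
        id_a = ids[1], id_b = ids[2],
        start_frame = sub[1, 1], end_frame = sub[nrow(sub), 1],
        duration_s = span * dt_a,
        n_frames_coloc = nrow(sub),
        mean_distance_um = mean(sub[, 2]),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$start_frame, out$id_a, out$id_b), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, cfg = cfg, class = c("coloc_events", "data.frame"))
}

#' Frequency and duration statistics of colocalization events
#'
#' Reports the mean and sem of event duration (s) and the event frequency
#' under two normalizations: per channel-A particle-frame (events divided by
#' the total number of channel-A localizations) and per um^2 of cell area
#' per second.
#'
#' @param events a [detect_coloc_events()] result.
#' @param ts_a the channel-A [trajectory_set()] used for detection.
#' @param cell_area cell area in um^2 (> 0).
#' @return A list of class `event_stats` with `n_events`, `duration_mean_s`,
#'   `duration_sem_s`, `freq_per_particle_frame`, `freq_per_um2_per_s`.
#' @export
event_stats <- function(events, ts_a, cell_area) {
  stopifnot(inherits(events, "coloc_events"), inherits(ts_a, "trajectory_set"))
  if (cell_area <= 0) stop_fmt("cell_area must be > 0")
  n_ev <- nrow(events)
  locs_a <- sum(vapply(ts_a$trajectories, n_locs, integer(1)))
  if (length(ts_a) > 0) {
    dt <- ts_a$trajectories[[1]]$frame_interval
    frame_range <- range(unlist(lapply(ts_a$trajectories, `[[`, "frames")))
    total_time <- (diff(frame_range) + 1) * dt
  } else {
    total_time <- NA_real_
  }
  if (n_ev == 0) warning("no colocalization events", call. = FALSE)
  structure(list(
    n_events = n_ev,
    duration_mean_s = if (n_ev > 0) mean(events$duration_s) else 0,
    duration_sem_s = if (n_ev > 1) sem(events$duration_s) else NA_real_,
    freq_per_particle_frame = if (locs_a > 0) n_ev / locs_a else 0,
    freq_per_um2_per_s = if (is.finite(total_time) && total_time > 0)
      n_ev / (cell_area * total_time) else 0),
    class = "event_stats")
}

#' @noRd
state_pair_levels <- function() c("co_diffusing", "co_confined",
                                  "free_a_trapped_b", "trapped_a_free_b")

#' Classify colocalization events by the trapping state of both partners
#'
#' Each event is labeled by the majority trapping state ("free"/"trapped") of
#' each partner over the event's frames, ties broken toward trapped (events
#' are short, so per-frame voting with a deterministic tie rule). The four
#' categories are co-diffusing (both free), co-confined (both trapped), and
#' the two mixed states.
#'
#' @param events a [detect_coloc_events()] result.
#' @param seg_a,seg_b named lists of [segment_trajectory()] results covering
#'   every trajectory appearing in the events (see
#'   [segment_trajectory_set()]).
#' @param cell_area cell area in um^2 for the density normalization.
#' @return A list of class `state_pair_density` with `counts`, `densities`
#'   (events per um^2), `fractions` (summing to 1), and the per-event labels
#'   appended to a copy of `events`.
#' @export
classify_event_states <- function(events, seg_a, seg_b, cell_area) {
  stopifnot(inherits(events, "coloc_events"))
  if (cell_area <= 0) stop_fmt("cell_area must be > 0")
  majority_state <- function(segs, id, frames) {
    if (is.null(segs[[id]]))
      stop_fmt("missing trapping segmentation for trajectory '%s'", id)
    st <- trapping_state_at(segs[[id]], frames)
    st <- st[!is.na(st)]
    if (length(st) == 0) return("free")
    n_trap <- sum(st == "trapped")
    if (n_trap >= length(st) / 2) "trapped" else "free"  # ties toward trapped
  }
  ev <- as.data.frame(events)
  n_ev <- nrow(ev)
  state_a <- state_b <- character(n_ev)
  for (i in seq_len(n_ev)) {
    frames <- ev$start_frame[i]:ev$end_frame[i]
    state_a[i] <- majority_state(seg_a, ev$id_a[i], frames)
    state_b[i] <- majority_state(seg_b, ev$id_b[i], frames)
  }
  ev$state_a <- state_a
  ev$state_b <- state_b
  cat_of <- function(sa, sb) {
    ifelse(sa == "free" & sb == "free", "co_diffusing",
    ifelse(sa == "trapped" & sb == "trapped", "co_confined",
    ifelse(sa == "free", "free_a_trapped_b", "trapped_a_free_b")))
  }
  cats <- factor(cat_of(state_a, state_b), levels = state_pair_levels())
  counts <- table(cats)
  fractions <- if (n_ev > 0) as.numeric(counts) / n_ev else rep(NA_real_, 4)
  names(fractions) <- state_pair_levels()
  densities <- as.numeric(counts) / cell_area
  names(densities) <- state_pair_levels()
  structure(list(counts = counts, densities = densities,
                 fractions = fractions, events = ev),
            class = "state_pair_density")
}

#' Export colocalization events to CSV
#'
#' Columns: id_a, id_b, start_frame, end_frame, duration_s, mean_distance_um,
#' and state_a/state_b when present.
#'
#' @param events a [detect_coloc_events()] result or the `events` element of
#'   [classify_event_states()].
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_events <- function(events, path) {
  df <- as.data.frame(events)
  cols <- intersect(c("id_a", "id_b", "start_frame", "end_frame", "duration_s",
                      "mean_distance_um", "state_a", "state_b"), names(df))
  utils::write.csv(df[, cols, drop = FALSE], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
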