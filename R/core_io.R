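# Domain types and file I/O shared by all analysis stages.
#
# Coordinates are stored in micrometers (um) throughout, not pixels; frame
# indices are 0-based integers and may contain gaps (trackers gap-close).
# Frame interval defaults to 1/35 s, the acquisition rate of the image
# sequences this package targets.

#' Construct a single-particle trajectory
#'
#' A trajectory is the time-ordered sequence of 2-D localizations of one
#' particle. Frames are 0-based, strictly increasing and may contain gaps;
#' coordinates are in micrometers.
#'
#' @param traj_id identifier (coerced to character).
#' @param frames integer frame indices, strictly increasing, 0-based.
#' @param x,y coordinates in um; finite, same length as `frames`.
#' @param frame_interval seconds per frame (default 1/35).
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(traj_id, frames, x, y, frame_interval = 1 / 35) {
  frames <- as.integer(frames)
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(frames) < 2)
    stop_fmt("trajectory '%s': needs at least 2 localizations", traj_id)
  if (length(x) != length(frames) || length(y) != length(frames))
    stop_fmt("trajectory '%s': frames, x, y must have equal length", traj_id)
  if (any(diff(frames) <= 0))
    stop_fmt("trajectory '%s': frames must be strictly increasing", traj_id)
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop_fmt("trajectory '%s': coordinates must be finite", traj_id)
  if (!is.numeric(frame_interval) || frame_interval <= 0)
    stop_fmt("frame_interval must be > 0")
  structure(
    list(traj_id = as.character(traj_id), frames = frames, x = x, y = y,
         frame_interval = frame_interval),
    class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory '%s': %d localizations, frames %d..%d, dt = %.4g s>\n",
              x$traj_id, length(x$frames), min(x$frames), max(x$frames),
              x$frame_interval))
  invisible(x)
}

#' Number of localizations in a trajectory
#' @param traj a [trajectory()].
#' @return Integer count.
#' @export
n_locs <- function(traj) length(traj$frames)

#' Construct a set of trajectories
#'
#' @param trajectories list of [trajectory()] objects with unique ids.
#' @param pixel_size um per pixel of the source images (metadata, may be NA).
#' @param source free-text provenance.
#' @return An object of class `trajectory_set`.
#' @export
trajectory_set <- function(trajectories, pixel_size = NA_real_, source = "") {
  stopifnot(is.list(trajectories))
  ids <- vapply(trajectories, function(t) t$traj_id, character(1))
  if (anyDuplicated(ids))
    stop_fmt("trajectory ids must be unique (duplicated: %s)",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(trajectories) <- ids
  structure(list(trajectories = trajectories, pixel_size = pixel_size,
                 source = source),
            class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat(sprintf("<trajectory_set: %d trajectories%s>\n", length(x$trajectories),
              if (nzchar(x$source)) paste0(" from ", x$source) else ""))
  invisible(x)
}

#' @export
length.trajectory_set <- function(x) length(x$trajectories)

#' Binary pixel mask with physical pixel size
#'
#' @param grid logical matrix (rows = y, cols = x); any non-logical input is
#'   binarized as nonzero = TRUE.
#' @param pixel_size um per pixel, > 0.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(grid, pixel_size) {
  if (!is.matrix(grid)) stop_fmt("mask grid must be a matrix")
  if (!is.logical(grid)) grid <- grid != 0
  if (!is.numeric(pixel_size) || pixel_size <= 0)
    stop_fmt("pixel_size must be > 0")
  structure(list(grid = grid, pixel_size = pixel_size), class = "binary_mask")
}

#' Nonnegative intensity image with physical pixel size
#'
#' @param grid numeric matrix, finite and >= 0.
#' @param pixel_size um per pixel, > 0.
#' @return An object of class `intensity_image`.
#' @export
intensity_image <- function(grid, pixel_size) {
  if (!is.matrix(grid) || !is.numeric(grid))
    stop_fmt("image grid must be a numeric matrix")
  if (!all(is.finite(grid)) || any(grid < 0))
    stop_fmt("image values must be finite and >= 0")
  if (!is.numeric(pixel_size) || pixel_size <= 0)
    stop_fmt("pixel_size must be > 0")
  structure(list(grid = grid, pixel_size = pixel_size),
            class = "intensity_image")
}

#' Set of point localizations in micrometers
#'
#' @param x,y coordinates in um, finite.
#' @param frame optional frame indices.
#' @param traj_id optional trajectory ids.
#' @return An object of class `localization_set` (a data.frame).
#' @export
localization_set <- function(x, y, frame = NULL, traj_id = NULL) {
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop_fmt("localization coordinates must be finite")
  df <- data.frame(x = as.numeric(x), y = as.numeric(y))
  if (!is.null(frame)) df$frame <- as.integer(frame)
  if (!is.null(traj_id)) df$traj_id <- as.character(traj_id)
  class(df) <- c("localization_set", "data.frame")
  df
}

#' Flatten a trajectory set to one localization per row
#'
#' @param ts a [trajectory_set()].
#' @return A [localization_set()] with columns x, y, frame, traj_id.
#' @export
as_localizations <- function(ts) {
  stopifnot(inherits(ts, "trajectory_set"))
  if (length(ts$trajectories) == 0) return(localization_set(numeric(0), numeric(0),
                                                            integer(0), character(0)))
  parts <- lapply(ts$trajectories, function(t)
    data.frame(x = t$x, y = t$y, frame = t$frames, traj_id = t$traj_id,
               stringsAsFactors = FALSE))
  df <- do.call(rbind, parts)
  rownames(df) <- NULL
  localization_set(df$x, df$y, df$frame, df$traj_id)
}

#' Read a trajectory table
#'
#' Reads a comma-separated table with header columns `traj_id`, `frame`,
#' `x_um`, `y_um` ('.' decimal, UTF-8), as exported by common SPT trackers.
#' Rows with non-finite coordinates are rejected; extra columns are preserved
#' as an opaque `extra` attribute on the returned set. Single-localization
#' ids are dropped with a warning (they carry no displacement information).
#'
#' @param path file path.
#' @param frame_interval seconds per frame (default 1/35).
#' @param pixel_size optional um per pixel metadata.
#' @return A [trajectory_set()]; trajectories ordered by first appearance,
#'   rows within each ordered by frame.
#' @export
read_trajectories <- function(path, frame_interval = 1 / 35,
                              pixel_size = NA_real_) {
  if (!file.exists(path)) stop_fmt("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("traj_id", "frame", "x_um", "y_um")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop_fmt("trajectory table '%s' is missing column(s): %s", path,
             paste(missing, collapse = ", "))
  if (nrow(df) == 0)
    return(trajectory_set(list(), pixel_size = pixel_size, source = path))
  keep <- is.finite(df$x_um) & is.finite(df$y_um)
  df <- df[keep, , drop = FALSE]
  if (anyDuplicated(df[, c("traj_id", "frame")]))
    stop_fmt("trajectory table '%s' has duplicated (traj_id, frame) rows", path)
  ids <- unique(df$traj_id)
  trajs <- list()
  dropped <- 0L
  for (id in ids) {
    sub <- df[df$traj_id == id, , drop = FALSE]
    sub <- sub[order(sub$frame), , drop = FALSE]
    if (nrow(sub) < 2) { dropped <- dropped + 1L; next }
    trajs[[length(trajs) + 1]] <- trajectory(id, sub$frame, sub$x_um, sub$y_um,
                                             frame_interval = frame_interval)
  }
  if (dropped > 0)
    warning(sprintf("%d single-localization id(s) dropped from %s", dropped, path),
            call. = FALSE)
  ts <- trajectory_set(trajs, pixel_size = pixel_size, source = path)
  extra_cols <- setdiff(names(df), required)
  if (length(extra_cols) > 0)
    attr(ts, "extra") <- df[, c("traj_id", "frame", extra_cols), drop = FALSE]
  ts
}

#' Write a trajectory table
#'
#' Inverse of [read_trajectories()]: the written file re-reads to the same
#' coordinates within 1e-9 um.
#'
#' @param ts a [trajectory_set()].
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_trajectories <- function(ts, path) {
  stopifnot(inherits(ts, "trajectory_set"))
  df <- as.data.frame(as_localizations(ts))
  out <- data.frame(traj_id = df$traj_id %||% character(0),
                    frame = df$frame %||% integer(0),
                    x_um = df$x, y_um = df$y, stringsAsFactors = FALSE)
  if (nrow(out) == 0)
    out <- data.frame(traj_id = character(0), frame = integer(0),
                      x_um = numeric(0), y_um = numeric(0))
  ok <- tryCatch({ utils::write.csv(out, path, row.names = FALSE, quote = FALSE); TRUE },
                 error = function(e) FALSE)
  if (!ok) stop_fmt("cannot write trajectory table to '%s'", path)
  invisible(path)
}

#' Keep only trajectories with a minimum number of localizations
#'
#' Short tracks yield unreliable TAMSD fits; the analysis default retains only
#' trajectories with at least 120 localizations.
#'
#' @param ts a [trajectory_set()].
#' @param min_frames minimum number of localizations (default 120, >= 2).
#' @return A filtered [trajectory_set()], order preserved.
#' @export
filter_min_length <- function(ts, min_frames = 120) {
  stopifnot(inherits(ts, "trajectory_set"))
  if (min_frames < 2) stop_fmt("min_frames must be >= 2")
  keep <- vapply(ts$trajectories, function(t) n_locs(t) >= min_frames, logical(1))
  trajectory_set(unname(ts$trajectories[keep]), pixel_size = ts$pixel_size,
                 source = ts$source)
}

#' Read a binary mask from TIFF
#'
#' Any nonzero pixel is TRUE. Multi-page TIFFs use the first page.
#'
#' @param path TIFF file.
#' @param pixel_size um per pixel.
#' @return A [binary_mask()].
#' @export
read_mask_tiff <- function(path, pixel_size) {
  img <- tiff::readTIFF(path, all = FALSE)
  if (length(dim(img)) == 3) img <- img[, , 1]
  binary_mask(img != 0, pixel_size)
}

#' Write a binary mask to TIFF
#' @param mask a [binary_mask()].
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_mask_tiff <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  tiff::writeTIFF(mask$grid * 1, path, bits.per.sample = 8L)
  invisible(path)
}

#' Read an intensity image from TIFF
#'
#' @param path TIFF file.
#' @param pixel_size um per pixel.
#' @return An [intensity_image()]. Values are as stored by [tiff::readTIFF()]
#'   (scaled to \[0, 1\]); all metrics in this package are invariant to
#'   positive rescaling of intensities.
#' @export
read_image_tiff <- function(path, pixel_size) {
  img <- tiff::readTIFF(path, all = FALSE)
  if (length(dim(img)) == 3) img <- img[, , 1]
  intensity_image(pmax(img, 0), pixel_size)
}

#' Write an intensity image to TIFF
#'
#' Intensities are rescaled to \[0, 1\] by the image maximum (16-bit storage);
#' Manders coefficients and masks are unaffected by positive rescaling.
#'
#' @param img an [intensity_image()].
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_image_tiff <- function(img, path) {
  stopifnot(inherits(img, "intensity_image"))
  g <- img$grid
  m <- max(g)
  if (m > 0) g <- g / m
  tiff::writeTIFF(g, path, bits.per.sample = 16L)
  invisible(path)
}
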