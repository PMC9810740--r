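# Colocalization metrics: image-level Manders coefficients with a
# homogeneous-distribution control, and the chance-corrected point-based
# single-molecule colocalization index against a binary structure mask.

#' Build a binary fiber mask from a structure-channel image
#'
#' Default method: grayscale-opening background subtraction (disc of radius
#' `rolling_ball_px`), Gaussian smoothing (sd 1 px) to suppress shot noise,
#' a threshold at the larger of the Otsu value (computed within the ROI) and
#' half the robust fiber peak (full-width-at-half-maximum rule, keeping the
#' mask width-faithful in the presence of the point-spread halo), then
#' removal of connected components smaller than `min_component_px`.
#' Deterministic given inputs; method parameters are recorded as attributes.
#'
#' @param img an [intensity_image()] of the structure channel.
#' @param roi a [binary_mask()] of the cell ROI (same shape and pixel size).
#' @param rolling_ball_px background structuring-element radius in px
#'   (default 10).
#' @param min_component_px minimum connected-component size in px (default 5).
#' @return A [binary_mask()] restricted to the ROI, with attributes `method`
#'   and `threshold`. Degenerate (empty or ROI-filling) masks trigger a
#'   warning.
#' @export
build_fiber_mask <- function(img, roi, rolling_ball_px = 10,
                             min_component_px = 5) {
  stopifnot(inherits(img, "intensity_image"), inherits(roi, "binary_mask"))
  if (!all(dim(img$grid) == dim(roi$grid)))
    stop_fmt("image and ROI shapes differ")
  if (!isTRUE(all.equal(img$pixel_size, roi$pixel_size)))
    stop_fmt("image and ROI pixel sizes differ")
  if (!any(roi$grid)) stop_fmt("ROI is empty")
  g <- img$grid
  rng <- range(g)
  gn <- if (diff(rng) > 0) (g - rng[1]) / diff(rng) else g * 0
  brush <- EBImage::makeBrush(2 * rolling_ball_px + 1, shape = "disc")
  bg <- EBImage::opening(gn, brush)
  fg <- EBImage::gblur(pmax(gn - bg, 0), sigma = 1)  # suppress shot noise
  vals <- fg[roi$grid]
  if (max(vals) <= 0) {
    warning("structure image is flat within the ROI; returning empty mask",
            call. = FALSE)
    out <- binary_mask(matrix(FALSE, nrow(g), ncol(g)), img$pixel_size)
    attr(out, "method") <- list(rolling_ball_px = rolling_ball_px,
                                min_component_px = min_component_px)
    attr(out, "threshold") <- NA_real_
    return(out)
  }
  fgr <- fg / max(vals)
  fgr[!roi$grid] <- 0
  thr <- EBImage::otsu(EBImage::Image(fgr), range = c(0, 1))
  # Width-faithful segmentation: raise the Otsu threshold to half of the
  # robust fiber peak (full-width-at-half-maximum rule), so the point-spread
  # halo around fibers is not absorbed into the mask.
  above <- fgr[fgr > thr & roi$grid]
  if (length(above) > 0)
    thr <- max(thr, 0.5 * as.numeric(stats::quantile(above, 0.99)))
  bin <- fgr > thr & roi$grid
  lab <- EBImage::bwlabel(EBImage::Image(bin * 1))
  labm <- EBImage::imageData(lab)
  sizes <- tabulate(labm[labm > 0])
  small <- which(sizes < min_component_px)
  if (length(small) > 0) bin[labm %in% small] <- FALSE
  n_on <- sum(bin)
  if (n_on == 0 || n_on == sum(roi$grid))
    warning("degenerate fiber mask (empty or ROI-filling)", call. = FALSE)
  out <- binary_mask(matrix(as.logical(bin), nrow(g), ncol(g)), img$pixel_size)
  attr(out, "method") <- list(rolling_ball_px = rolling_ball_px,
                              min_component_px = min_component_px)
  attr(out, "threshold") <- as.numeric(thr)
  out
}

#' Manders colocalization coefficient
#'
#' Fraction of channel-1 intensity residing on mask-positive pixels within
#' the ROI: `MCC = sum(ch1 over mask & roi) / sum(ch1 over roi)`. In
#' \[0, 1\] and invariant to positive rescaling of ch1.
#'
#' @param ch1 an [intensity_image()].
#' @param ch2_mask a [binary_mask()] of the partner channel.
#' @param roi a [binary_mask()] of the cell ROI (default: whole frame).
#' @return A list of class `mcc_result` with `mcc`, `n_pixels_mask`,
#'   `n_pixels_roi`.
#' @export
manders_mcc <- function(ch1, ch2_mask, roi = NULL) {
  stopifnot(inherits(ch1, "intensity_image"), inherits(ch2_mask, "binary_mask"))
  if (is.null(roi))
    roi <- binary_mask(matrix(TRUE, nrow(ch1$grid), ncol(ch1$grid)),
                       ch1$pixel_size)
  if (!all(dim(ch1$grid) == dim(ch2_mask$grid)) ||
      !all(dim(ch1$grid) == dim(roi$grid)))
    stop_fmt("image, mask and ROI shapes differ")
  if (!any(roi$grid)) stop_fmt("ROI is empty")
  total <- sum(ch1$grid[roi$grid])
  if (total <= 0)
    stop_fmt("MCC undefined: channel-1 intensity sums to 0 over the ROI")
  inside <- sum(ch1$grid[ch2_mask$grid & roi$grid])
  structure(list(mcc = inside / total,
                 n_pixels_mask = sum(ch2_mask$grid & roi$grid),
                 n_pixels_roi = sum(roi$grid)),
            class = "mcc_result")
}

#' Homogeneous-distribution control MCC
#'
#' The MCC obtained when channel 1 is replaced by a perfectly homogeneous
#' distribution over the ROI -- the lowest value any channel-1 distribution
#' concentrated on the mask can attain. Equals the mask's area fraction of
#' the ROI.
#'
#' @param ch2_mask a [binary_mask()].
#' @param roi a [binary_mask()] (default: whole frame).
#' @return A list of class `mcc_result`.
#' @export
homogeneous_control_mcc <- function(ch2_mask, roi = NULL) {
  stopifnot(inherits(ch2_mask, "binary_mask"))
  if (is.null(roi))
    roi <- binary_mask(matrix(TRUE, nrow(ch2_mask$grid), ncol(ch2_mask$grid)),
                       ch2_mask$pixel_size)
  if (!any(roi$grid)) stop_fmt("ROI is empty")
  structure(list(mcc = sum(ch2_mask$grid & roi$grid) / sum(roi$grid),
                 n_pixels_mask = sum(ch2_mask$grid & roi$grid),
                 n_pixels_roi = sum(roi$grid)),
            class = "mcc_result")
}

#' @noRd
mask_membership <- function(locs, mask) {
  p <- points_to_pixels(locs$x, locs$y, mask$pixel_size, dim(mask$grid))
  member <- rep(FALSE, nrow(locs))
  member[p$inside] <- mask$grid[cbind(p$row[p$inside], p$col[p$inside])]
  list(member = member, inside = p$inside, row = p$row, col = p$col)
}

#' Single-molecule colocalization index
#'
#' Chance-corrected fraction of point localizations lying on a binary
#' structure mask. With `f_obs` the fraction of localizations on mask pixels
#' and `f_exp` the chance fraction (mean over `n_randomizations` uniform
#' re-placements of the same number of points within the ROI), the index is
#' `(f_obs - f_exp) / (1 - f_exp)` when `f_obs >= f_exp` and
#' `(f_obs - f_exp) / f_exp` otherwise, clipped to \[-1, 1\]: -1 means
#' perfect avoidance of the structure, 0 chance-level overlap, +1 perfect
#' colocalization.
#'
#' @param locs a [localization_set()] (um).
#' @param fiber_mask a [binary_mask()].
#' @param roi a [binary_mask()] of the cell ROI (default: whole frame).
#'   Localizations outside the ROI are discarded.
#' @param n_randomizations uniform re-placements for the chance estimate
#'   (default 100).
#' @param seed RNG seed for the randomizations (default 1).
#' @return A list of class `coloc_index_result` with `index`, `f_observed`,
#'   `f_expected`, `n_localizations`, `n_randomizations`.
#' @export
sm_coloc_index <- function(locs, fiber_mask, roi = NULL,
                           n_randomizations = 100, seed = 1) {
  stopifnot(inherits(fiber_mask, "binary_mask"))
  if (is.null(roi))
    roi <- binary_mask(matrix(TRUE, nrow(fiber_mask$grid),
                              ncol(fiber_mask$grid)),
                       fiber_mask$pixel_size)
  if (!all(dim(fiber_mask$grid) == dim(roi$grid)))
    stop_fmt("mask and ROI shapes differ")
  roi_member <- mask_membership(locs, roi)$member
  locs <- locs[roi_member, , drop = FALSE]
  n <- nrow(locs)
  if (n < 1) stop_fmt("no localizations inside the ROI")
  mask_in_roi <- fiber_mask$grid & roi$grid
  if (!any(mask_in_roi)) stop_fmt("fiber mask empty within the ROI")
  f_obs <- mean(mask_in_roi[cbind(
    pmin(pmax(floor(locs$y / fiber_mask$pixel_size) + 1L, 1L), nrow(mask_in_roi)),
    pmin(pmax(floor(locs$x / fiber_mask$pixel_size) + 1L, 1L), ncol(mask_in_roi)))])

  roi_idx <- which(roi$grid)
  f_exp <- withr::with_seed(seed, {
    mean(vapply(seq_len(n_randomizations), function(r) {
      pick <- roi_idx[sample.int(length(roi_idx), n, replace = TRUE)]
      mean(mask_in_roi[pick])
    }, numeric(1)))
  })
  if (f_exp <= 0 || f_exp >= 1)
    stop_fmt("colocalization index undefined: chance fraction is %g", f_exp)
  index <- if (f_obs >= f_exp) (f_obs - f_exp) / (1 - f_exp)
           else (f_obs - f_exp) / f_exp
  index <- max(-1, min(1, index))
  structure(list(index = index, f_observed = f_obs, f_expected = f_exp,
                 n_localizations = n, n_randomizations = n_randomizations),
            class = "coloc_index_result")
}

#' @export
print.coloc_index_result <- function(x, ...) {
  cat(sprintf("<coloc index %.4f (f_obs %.4f, f_exp %.4f, n = %d)>\n",
              x$index, x$f_observed, x$f_expected, x$n_localizations))
  invisible(x)
}
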