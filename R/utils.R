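# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)

#' Derive a per-stage integer seed from a base seed
#'
#' Deterministic splitting rule used by the pipeline so that individual stages
#' can be re-run in isolation while remaining reproducible from one global
#' seed. Kept below `.Machine$integer.max`.
#'
#' @param seed base integer seed.
#' @param k stage index (any small integer).
#' @return An integer seed.
#' @export
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1000 + as.numeric(k)) %% .Machine$integer.max)
}

# Map points in micrometers onto pixel indices of a grid.
# Convention: pixel (row 1, col 1) spans [0,1) x [0,1) pixel units, so a point
# (x, y) in um lands in column floor(x/px)+1 and row floor(y/px)+1; points
# exactly on a boundary belong to the lower-index pixel.
#' @noRd
points_to_pixels <- function(x, y, pixel_size, dim) {
  col <- floor(x / pixel_size) + 1L
  row <- floor(y / pixel_size) + 1L
  inside <- row >= 1L & row <= dim[1] & col >= 1L & col <= dim[2]
  list(row = row, col = col, inside = inside)
}

# Centers (um) of a set of pixel (row, col) indices.
#' @noRd
pixel_centers <- function(row, col, pixel_size) {
  list(x = (col - 0.5) * pixel_size, y = (row - 0.5) * pixel_size)
}

#' @noRd
sem <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}
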