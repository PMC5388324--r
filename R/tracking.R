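#' Two-dimensional single-camera view track
#'
#' Per-frame pixel coordinates of the midline points as seen by one of the
#' two synchronized cameras. The side camera images the shared horizontal
#' axis (x) and the vertical axis (z); the top camera images x and the
#' horizontal depth axis (y).
#'
#' @param coords Numeric array `frames x points x 2` (px). Column 1 is always
#'   the shared horizontal axis; column 2 is z (side) or y (top).
#' @param camera `"side"` or `"top"`.
#' @param fps Frames per second.
#' @param px_to_mm Scale factor, mm per pixel (> 0).
#' @return An object of class `view_track`.
#' @export
view_track <- function(coords, camera = c("side", "top"), fps, px_to_mm) {
  camera <- match.arg(camera)
  stopifnot(is.array(coords), length(dim(coords)) == 3, dim(coords)[3] == 2,
            fps > 0, px_to_mm > 0)
  structure(list(coords = coords, camera = camera, fps = fps,
                 px_to_mm = px_to_mm), class = "view_track")
}

#' Project a 3-D midline track into the two camera views
#'
#' The inverse of [merge_views()], used for round-trip verification: the side
#' camera records (x, z), the top camera (x, y), both in pixels at the given
#' scale.
#'
#' @param track A [midline_track()].
#' @param px_to_mm mm-per-pixel scale applied to both views.
#' @return List with elements `side` and `top`, both [view_track()]s.
#' @export
project_views <- function(track, px_to_mm = 0.5) {
  cc <- track$coords
  side <- cc[, , c(1, 3), drop = FALSE] / px_to_mm
  top <- cc[, , c(1, 2), drop = FALSE] / px_to_mm
  list(side = view_track(side, "side", track$fps, px_to_mm),
       top = view_track(top, "top", track$fps, px_to_mm))
}

#' Merge side and top camera tracks into a 3-D midline track
#'
#' Combines two synchronized, scaled 2-D views into millimetre 3-D
#' coordinates: x is the average of the two views' estimates of the shared
#' horizontal axis, y comes from the top view, z from the side view. If the
#' two shared-axis estimates diverge beyond `tolerance_px`, a warning reports
#' the worst per-frame residual; the residual matrix (mm) is attached as
#' attribute `"shared_axis_residual_mm"`.
#'
#' @param side,top [view_track()] objects from the respective cameras.
#' @param tolerance_px Allowed shared-axis disagreement, in pixels.
#' @return A [midline_track()] in mm.
#' @export
merge_views <- function(side, top, tolerance_px = 2) {
  stopifnot(inherits(side, "view_track"), inherits(top, "view_track"),
            side$camera == "side", top$camera == "top")
  if (!identical(dim(side$coords)[1:2], dim(top$coords)[1:2]))
    stop("frame/point count mismatch between side and top views")
  if (side$fps != top$fps) stop("fps mismatch between views")
  x_side <- side$coords[, , 1, drop = FALSE] * side$px_to_mm
  x_top <- top$coords[, , 1, drop = FALSE] * top$px_to_mm
  resid <- abs(x_side - x_top)[, , 1, drop = TRUE]
  tol_mm <- tolerance_px * max(side$px_to_mm, top$px_to_mm)
  if (any(resid > tol_mm)) {
    warning(sprintf(
      "shared-axis estimates diverge: max residual %.2f mm (tolerance %.2f mm) in %d frame-point cells",
      max(resid), tol_mm, sum(resid > tol_mm)))
  }
  d <- dim(side$coords)
  coords <- array(NA_real_, c(d[1], d[2], 3))
  coords[, , 1] <- (x_side + x_top)[, , 1] / 2
  coords[, , 2] <- top$coords[, , 2] * top$px_to_mm
  coords[, , 3] <- side$coords[, , 2] * side$px_to_mm
  out <- midline_track(coords, side$fps)
  attr(out, "shared_axis_residual_mm") <- resid
  out
}

#' Centred moving-average smoothing of a midline track
#'
#' Replaces every coordinate series with its centred moving average of odd
#' width `window` (default 3). Endpoints use the shrinking-window average of
#' the neighbours actually available, so the frame count is unchanged.
#'
#' @param track A [midline_track()].
#' @param window Odd window width, >= 1 and <= frame count.
#' @return A smoothed [midline_track()] with identical dimensions.
#' @export
smooth_moving_average <- function(track, window = 3) {
  stopifnot(window >= 1, window %% 2 == 1)
  d <- dim(track$coords)
  n <- d[1]
  if (window > n) stop("window larger than track length")
  h <- (window - 1) / 2
  smooth1 <- function(x) {
    cs <- c(0, cumsum(x))
    lo <- pmax(seq_len(n) - h, 1)
    hi <- pmin(seq_len(n) + h, n)
    (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  }
  coords <- track$coords
  for (p in seq_len(d[2])) for (k in 1:3)
    coords[, p, k] <- smooth1(track$coords[, p, k])
  midline_track(coords, track$fps)
}
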