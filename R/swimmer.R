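#' Parameters for the synthetic swimmer
#'
#' Bundles the kinematic parameters of the synthetic swimming-fish generator.
#' The simulated animal is a small (~3 cm) surface-swimming fish whose body
#' midline is discretised into `n_points` equally spaced points. Locomotion is
#' a heading-persistent random walk in the horizontal plane with slow, small
#' vertical drift; body motion is a travelling undulation wave running
#' head-to-tail with a laterally growing amplitude envelope.
#'
#' The kinematic defaults (tail-beat frequency, wavelength, cruise speed) are
#' assumptions chosen to be realistic for a small cyprinodontiform swimmer;
#' they are not measurements.
#'
#' @param body_length Body length in mm (default 30, i.e. about 3 cm).
#' @param n_points Number of midline points (default 6; point 1 is the head).
#' @param fps Frames per second of the generated track (default 60).
#' @param duration Track duration in seconds (default 60).
#' @param undulation_freq Tail-beat frequency in Hz (default 3).
#' @param undulation_wavelength Undulation wavelength as a fraction of body
#'   length (default 0.9).
#' @param amplitude_envelope Per-point lateral amplitude in mm, non-negative
#'   and non-decreasing from head to tail. Length `n_points`.
#' @param speed_mean Mean forward speed in mm/s (default 30, one body length
#'   per second).
#' @param heading_persistence Correlation time of the heading process in
#'   seconds (default 2).
#' @param vertical_amplitude Amplitude of slow vertical drift in mm (default 5).
#' @param tank Axis-aligned tank box dimensions in mm, numeric length 3
#'   (x, y, z extents; default `c(300, 150, 80)`).
#' @param seed Integer seed; every random draw in the generator is governed
#'   by it.
#'
#' @return An object of class `swimmer_params` (a validated list).
#' @seealso [simulate_swimmer()]
#' @export
swimmer_params <- function(body_length = 30,
                           n_points = 6,
                           fps = 60,
                           duration = 60,
                           undulation_freq = 3,
                           undulation_wavelength = 0.9,
                           amplitude_envelope = NULL,
                           speed_mean = 30,
                           heading_persistence = 2,
                           vertical_amplitude = 5,
                           tank = c(300, 150, 80),
                           seed = 1L) {
  if (is.null(amplitude_envelope)) {
    # gentle head oscillation growing to a pronounced tail beat
    amplitude_envelope <- body_length * c(0.01, 0.015, 0.03, 0.05, 0.08, 0.10)
    amplitude_envelope <- amplitude_envelope[seq_len(min(n_points, 6))]
    if (n_points > 6) {
      amplitude_envelope <- c(amplitude_envelope,
                              rep(body_length * 0.10, n_points - 6))
    }
  }
  p <- list(body_length = body_length, n_points = as.integer(n_points),
            fps = fps, duration = duration,
            undulation_freq = undulation_freq,
            undulation_wavelength = undulation_wavelength,
            amplitude_envelope = amplitude_envelope,
            speed_mean = speed_mean,
            heading_persistence = heading_persistence,
            vertical_amplitude = vertical_amplitude,
            tank = tank, seed = as.integer(seed))
  class(p) <- "swimmer_params"
  validate_swimmer_params(p)
  p
}

validate_swimmer_params <- function(p) {
  stopifnot(p$n_points >= 2, p$fps > 0, p$duration > 0,
            p$body_length > 0, length(p$tank) == 3, all(p$tank > 0))
  if (length(p$amplitude_envelope) != p$n_points)
    stop("amplitude_envelope must have one value per midline point")
  if (any(p$amplitude_envelope < 0))
    stop("amplitude_envelope must be non-negative")
  if (any(diff(p$amplitude_envelope) < 0))
    stop("amplitude_envelope must be non-decreasing head to tail")
  margin <- p$body_length + max(p$amplitude_envelope)
  if (any(p$tank[1:2] <= 2 * margin))
    stop("tank too small for body_length: horizontal extents must exceed ",
         "twice body length plus maximum undulation amplitude")
  invisible(p)
}

#' Construct a midline track object
#'
#' A midline track holds per-frame 3-D positions (mm) of ordered points along
#' a fish's body midline, head first. Coordinates: x and y horizontal, z
#' vertical.
#'
#' @param coords Numeric array `frames x points x 3` (mm).
#' @param fps Frames per second.
#' @return An object of class `midline_track`.
#' @export
midline_track <- function(coords, fps) {
  stopifnot(is.array(coords), length(dim(coords)) == 3, dim(coords)[3] == 3,
            fps > 0, all(is.finite(coords)))
  dimnames(coords) <- list(NULL, NULL, c("x", "y", "z"))
  structure(list(coords = coords, fps = fps), class = "midline_track")
}

#' @export
print.midline_track <- function(x, ...) {
  d <- dim(x$coords)
  cat(sprintf("midline_track: %d frames x %d points at %g fps (%.1f s)\n",
              d[1], d[2], x$fps, d[1] / x$fps))
  invisible(x)
}

#' Simulate a swimming fish midline track
#'
#' Generates a seeded, fully reproducible midline track with the structure
#' the skeletonisation stage assumes: a smooth planar locomotion path (heading
#' random walk with persistence, constant cruise speed, slow vertical drift)
#' carrying a travelling lateral undulation wave. The analytic midline curve
#' is re-sampled by arc length every frame so consecutive points are equally
#' spaced along the body.
#'
#' @param params A [swimmer_params()] object.
#' @return A [midline_track()] with `duration * fps` frames and
#'   `params$n_points` points per frame.
#' @examples
#' tr <- simulate_swimmer(swimmer_params(duration = 2, seed = 7))
#' dim(tr$coords)
#' @export
simulate_swimmer <- function(params) {
  validate_swimmer_params(params)
  p <- params
  n_frames <- round(p$duration * p$fps)
  dt <- 1 / p$fps
  margin <- p$body_length + max(p$amplitude_envelope) + 1

  withr::with_seed(p$seed, {
    # turn-rate process: AR(1) with correlation time heading_persistence
    a <- exp(-dt / p$heading_persistence)
    omega_sd <- 0.8  # rad/s stationary sd of turn rate
    omega <- numeric(n_frames)
    innov <- rnorm(n_frames, 0, omega_sd * sqrt(1 - a^2))
    omega[1] <- rnorm(1, 0, omega_sd)
    for (i in 2:n_frames) omega[i] <- a * omega[i - 1] + innov[i]

    theta <- numeric(n_frames)
    hx <- numeric(n_frames); hy <- numeric(n_frames)
    centre <- p$tank / 2
    theta[1] <- runif(1, -pi, pi)
    hx[1] <- centre[1]; hy[1] <- centre[2]
    lo <- c(margin, margin); hi <- p$tank[1:2] - margin
    for (i in 2:n_frames) {
      th <- theta[i - 1] + omega[i] * dt
      # steer back toward the tank centre when close to a wall
      pos <- c(hx[i - 1], hy[i - 1])
      near <- pmin(pos - lo, hi - pos)
      if (any(near < 0.25 * p$body_length)) {
        want <- atan2(centre[2] - pos[2], centre[1] - pos[1])
        dth <- ((want - th + pi) %% (2 * pi)) - pi
        th <- th + 0.15 * dth
      }
      theta[i] <- th
      hx[i] <- min(max(hx[i - 1] + p$speed_mean * cos(th) * dt, lo[1]), hi[1])
      hy[i] <- min(max(hy[i - 1] + p$speed_mean * sin(th) * dt, lo[2]), hi[2])
    }

    # a fish that is not translating holds its heading (no pirouette in place)
    if (p$speed_mean == 0) theta[] <- theta[1]

    # slow smooth vertical drift: two seeded sinusoids with long periods, so
    # the vertical velocity stays small relative to the cruise speed
    tt <- (seq_len(n_frames) - 1) * dt
    T1 <- runif(1, 15, 25); T2 <- runif(1, 5, 10)
    ph1 <- runif(1, 0, 2 * pi); ph2 <- runif(1, 0, 2 * pi)
    z_amp <- p$vertical_amplitude
    hz <- centre[3] + z_amp * (0.7 * sin(2 * pi * tt / T1 + ph1) +
                               0.3 * sin(2 * pi * tt / T2 + ph2))
    hz <- pmin(pmax(hz, 1), p$tank[3] - 1)
    if (p$speed_mean == 0 && all(p$amplitude_envelope == 0)) {
      hz <- rep(centre[3], n_frames)  # fully rigid, stationary special case
    }
  })

  L <- p$body_length
  npts <- p$n_points
  lambda_mm <- p$undulation_wavelength * L
  # fine parameter grid along the analytic midline; the output points are
  # placed by equal-chord re-sampling (consecutive points at exactly
  # L/(npts-1) Euclidean distance), the spacing contract the tracker and the
  # rigid-segment skeleton assume
  s_grid <- seq(0, 1.6 * L, length.out = 481)
  env_at <- stats::approxfun(seq(0, L, length.out = npts),
                             p$amplitude_envelope, rule = 2)
  amp_grid <- env_at(pmin(s_grid, L))
  chord <- L / (npts - 1)

  coords <- array(NA_real_, c(n_frames, npts, 3))
  times <- (seq_len(n_frames) - 1) * dt
  for (i in seq_len(n_frames)) {
    u <- c(cos(theta[i]), sin(theta[i]))
    nvec <- c(-u[2], u[1])
    phase <- 2 * pi * (p$undulation_freq * times[i] - s_grid / lambda_mm)
    lat <- amp_grid * sin(phase)
    cx <- hx[i] - s_grid * u[1] + lat * nvec[1]
    cy <- hy[i] - s_grid * u[2] + lat * nvec[2]
    px <- cx[1]; py <- cy[1]
    coords[i, 1, 1] <- px; coords[i, 1, 2] <- py
    kk <- 1L
    for (j in 2:npts) {
      dx <- cx - px; dy <- cy - py
      dist2 <- dx^2 + dy^2
      idx <- which(dist2 >= chord^2)
      idx <- idx[idx > kk]
      if (length(idx) == 0) stop("midline grid too short for chord spacing")
      k2 <- idx[1]; k1 <- k2 - 1L
      # exact chord-length point on the polyline segment (k1, k2)
      ax <- cx[k1] - px; ay <- cy[k1] - py
      bx <- cx[k2] - cx[k1]; by <- cy[k2] - cy[k1]
      aa <- bx^2 + by^2
      bb <- 2 * (ax * bx + ay * by)
      cc0 <- ax^2 + ay^2 - chord^2
      t <- (-bb + sqrt(bb^2 - 4 * aa * cc0)) / (2 * aa)
      px <- cx[k1] + t * bx; py <- cy[k1] + t * by
      coords[i, j, 1] <- px; coords[i, j, 2] <- py
      kk <- k1
    }
    coords[i, , 3] <- hz[i]
  }
  midline_track(coords, p$fps)
}

#' Write / read a midline track as CSV
#'
#' Long-format CSV with columns `frame` (0-based), `point_index` (1-based,
#' head first), `x_mm`, `y_mm`, `z_mm`.
#'
#' @param track A [midline_track()].
#' @param path File path.
#' @param fps Frames per second to attach on read.
#' @param strict If `TRUE` (default), non-finite coordinates are rejected;
#'   otherwise isolated dropouts are filled by linear interpolation along
#'   each coordinate series.
#' @return `read_midline_csv()` returns a [midline_track()];
#'   `write_midline_csv()` returns `path` invisibly.
#' @export
write_midline_csv <- function(track, path) {
  d <- dim(track$coords)
  df <- data.frame(
    frame = rep(seq_len(d[1]) - 1L, each = d[2]),
    point_index = rep(seq_len(d[2]), times = d[1]),
    x_mm = as.vector(t(track$coords[, , 1])),
    y_mm = as.vector(t(track$coords[, , 2])),
    z_mm = as.vector(t(track$coords[, , 3])))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_midline_csv
#' @export
read_midline_csv <- function(path, fps, strict = TRUE) {
  df <- read.csv(path)
  need <- c("frame", "point_index", "x_mm", "y_mm", "z_mm")
  if (!all(need %in% names(df)))
    stop("midline CSV must have columns: ", paste(need, collapse = ", "))
  if (strict && !all(is.finite(as.matrix(df[, c("x_mm", "y_mm", "z_mm")]))))
    stop("non-finite coordinates in midline CSV (strict mode)")
  df <- df[order(df$frame, df$point_index), ]
  n_frames <- length(unique(df$frame))
  npts <- length(unique(df$point_index))
  if (nrow(df) != n_frames * npts)
    stop("midline CSV has missing frame/point combinations")
  coords <- array(NA_real_, c(n_frames, npts, 3))
  coords[, , 1] <- matrix(df$x_mm, n_frames, npts, byrow = TRUE)
  coords[, , 2] <- matrix(df$y_mm, n_frames, npts, byrow = TRUE)
  coords[, , 3] <- matrix(df$z_mm, n_frames, npts, byrow = TRUE)
  if (!strict && !all(is.finite(coords))) {
    for (p in seq_len(npts)) for (k in 1:3) {
      s <- coords[, p, k]
      ok <- is.finite(s)
      if (!all(ok)) {
        if (!any(ok)) stop("coordinate series entirely non-finite")
        coords[, p, k] <- stats::approx(which(ok), s[ok],
                                        xout = seq_len(n_frames),
                                        rule = 2)$y
      }
    }
  }
  midline_track(coords, fps)
}
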