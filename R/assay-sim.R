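#' Parameters for the synthetic social-approach assay
#'
#' Configures the two-state (near/far) occupancy simulator that stands in for
#' tracked assay subjects. Each subject's in-zone indicator follows a
#' discrete-frame two-state Markov chain whose entry/exit hazards may vary by
#' group and by minute bin, so group-by-time response structure (e.g. "the
#' Normal group's attraction rises after stimulus onset") can be planted
#' explicitly.
#'
#' @param n_subjects Total number of subjects; must be divisible by the number
#'   of groups (equal allocation).
#' @param groups Character vector of group labels.
#' @param baseline_s Baseline period length in seconds (default 60).
#' @param stimulus_s Stimulus presentation length in seconds (default 300).
#' @param fps Frames per second of the head-tip tracking (default 30).
#' @param zone_entry_rate,zone_exit_rate Per-second hazards of entering /
#'   leaving the near-display zone. Either a scalar, a per-group vector, or a
#'   `groups x minute-bins` matrix (bins: baseline plus one per stimulus
#'   minute). Recycled to the full matrix.
#' @param zone_mm Width of the near-display zone in mm (default 10); used to
#'   place simulated head-tip distances on the correct side of the boundary.
#' @param tank_mm Inner tank length along the display axis in mm (default 150).
#' @param init_state Initial state of each subject: `"out"` (default), `"in"`,
#'   or `"random"` (stationary draw at the baseline rates).
#' @param seed Integer seed.
#'
#' @return An object of class `assay_params`.
#' @seealso [simulate_assay()]
#' @export
assay_params <- function(n_subjects,
                         groups,
                         baseline_s = 60,
                         stimulus_s = 300,
                         fps = 30,
                         zone_entry_rate = 0.02,
                         zone_exit_rate = 0.10,
                         zone_mm = 10,
                         tank_mm = 150,
                         init_state = c("out", "in", "random"),
                         seed = 1L) {
  init_state <- match.arg(init_state)
  g <- length(groups)
  n_bins <- (baseline_s + stimulus_s) / 60
  if (n_bins != round(n_bins))
    stop("baseline_s + stimulus_s must divide into whole 1-min bins")
  n_bins <- as.integer(n_bins)
  expand <- function(r, what) {
    if (is.matrix(r)) {
      if (nrow(r) != g || ncol(r) != n_bins)
        stop(what, " matrix must be ", g, " groups x ", n_bins, " bins")
      m <- r
    } else if (length(r) == 1) {
      m <- matrix(r, g, n_bins)
    } else if (length(r) == g) {
      m <- matrix(r, g, n_bins)
    } else stop(what, " must be scalar, per-group, or a group x bin matrix")
    if (any(m < 0)) stop(what, " must be non-negative")
    rownames(m) <- groups
    m
  }
  p <- list(n_subjects = as.integer(n_subjects), groups = groups,
            baseline_s = baseline_s, stimulus_s = stimulus_s, fps = fps,
            entry = expand(zone_entry_rate, "zone_entry_rate"),
            exit = expand(zone_exit_rate, "zone_exit_rate"),
            zone_mm = zone_mm, tank_mm = tank_mm,
            init_state = init_state, n_bins = n_bins, seed = as.integer(seed))
  if (p$n_subjects %% g != 0)
    stop("n_subjects must be divisible by the number of groups")
  class(p) <- "assay_params"
  p
}

#' Simulate head-tip occupancy traces for a cohort of assay subjects
#'
#' Runs the two-state Markov chain of [assay_params()] for every subject and
#' emits per-frame head-tip distances from the display-side inner wall:
#' in-zone frames get a distance inside the zone, out-of-zone frames a
#' distance beyond it. Deterministic under the params seed.
#'
#' @param params An [assay_params()] object.
#' @return A list of `occupancy_trace` tibbles (columns `frame` 0-based,
#'   `x_mm`, `period`), each carrying attributes `subject`, `group`, `fps`,
#'   `baseline_s`, `stimulus_s`.
#' @export
simulate_assay <- function(params) {
  p <- params
  stopifnot(inherits(p, "assay_params"))
  n <- p$n_subjects
  per_group <- n / length(p$groups)
  group_of <- rep(p$groups, each = per_group)
  gi <- match(group_of, p$groups)
  total_s <- p$baseline_s + p$stimulus_s
  n_frames <- round(total_s * p$fps)
  bin_of_frame <- pmin(floor((seq_len(n_frames) - 1) / (60 * p$fps)) + 1L,
                       p$n_bins)

  withr::with_seed(p$seed, {
    states <- matrix(FALSE, n_frames, n)  # TRUE = in zone
    s <- switch(p$init_state,
      out = rep(FALSE, n),
      `in` = rep(TRUE, n),
      random = {
        en <- p$entry[cbind(gi, 1L)]; ex <- p$exit[cbind(gi, 1L)]
        pr <- ifelse(en + ex > 0, en / (en + ex), 0)
        runif(n) < pr
      })
    dt <- 1 / p$fps
    for (f in seq_len(n_frames)) {
      b <- bin_of_frame[f]
      p_enter <- 1 - exp(-p$entry[cbind(gi, b)] * dt)
      p_exit <- 1 - exp(-p$exit[cbind(gi, b)] * dt)
      u <- runif(n)
      s <- ifelse(s, u >= p_exit, u < p_enter)
      states[f, ] <- s
    }
    # distances: keep a buffer on each side of the zone boundary so the
    # indicator, not rounding, decides zone membership
    dist <- matrix(NA_real_, n_frames, n)
    n_in <- sum(states)
    dist[states] <- runif(n_in, 0.05 * p$zone_mm, 0.95 * p$zone_mm)
    dist[!states] <- runif(length(states) - n_in,
                           1.2 * p$zone_mm, 0.95 * p$tank_mm)
  })

  period <- rep(c("baseline", "stimulus"),
                c(round(p$baseline_s * p$fps),
                  n_frames - round(p$baseline_s * p$fps)))
  lapply(seq_len(n), function(j) {
    tr <- tibble::tibble(frame = seq_len(n_frames) - 1L,
                         x_mm = dist[, j],
                         period = period)
    attr(tr, "subject") <- sprintf("s%03d", j)
    attr(tr, "group") <- group_of[j]
    attr(tr, "fps") <- p$fps
    attr(tr, "baseline_s") <- p$baseline_s
    attr(tr, "stimulus_s") <- p$stimulus_s
    class(tr) <- c("occupancy_trace", class(tr))
    tr
  })
}

#' Write / read one occupancy trace as CSV
#'
#' Columns: `frame` (0-based), `x_mm` (head-tip distance from the display-side
#' inner wall), `period` (`baseline` / `stimulus`).
#'
#' @param trace An `occupancy_trace` (see [simulate_assay()]).
#' @param path File path.
#' @param fps,subject,group,baseline_s,stimulus_s Metadata attached on read.
#' @return `read_occupancy_csv()` returns an `occupancy_trace`;
#'   `write_occupancy_csv()` returns `path` invisibly.
#' @export
write_occupancy_csv <- function(trace, path) {
  write.csv(as.data.frame(trace[c("frame", "x_mm", "period")]), path,
            row.names = FALSE)
  invisible(path)
}

#' @rdname write_occupancy_csv
#' @export
read_occupancy_csv <- function(path, fps = 30, subject = NA_character_,
                               group = NA_character_,
                               baseline_s = 60, stimulus_s = 300) {
  df <- read.csv(path)
  need <- c("frame", "x_mm", "period")
  if (!all(need %in% names(df)))
    stop("occupancy CSV must have columns: ", paste(need, collapse = ", "))
  tr <- tibble::as_tibble(df[need])
  attr(tr, "subject") <- subject
  attr(tr, "group") <- group
  attr(tr, "fps") <- fps
  attr(tr, "baseline_s") <- baseline_s
  attr(tr, "stimulus_s") <- stimulus_s
  class(tr) <- c("occupancy_trace", class(tr))
  tr
}

#' Deterministic pseudo-random RGB fixture image
#'
#' @param width,height Image dimensions in pixels.
#' @param seed Integer seed.
#' @return Integer array `height x width x 3` with values in 0..255.
#' @export
make_rgb_fixture <- function(width, height, seed = 1L) {
  stopifnot(width >= 1, height >= 1)
  withr::with_seed(seed, {
    vals <- sample.int(256L, height * width * 3L, replace = TRUE) - 1L
  })
  array(vals, dim = c(height, width, 3L))
}

#' Write / read an 8-bit RGB image as PNG
#'
#' @param img Numeric or integer array `height x width x 3`, values 0..255.
#' @param path File path.
#' @return `read_rgb_png()` returns an integer 0..255 array;
#'   `write_rgb_png()` returns `path` invisibly.
#' @export
write_rgb_png <- function(img, path) {
  stopifnot(length(dim(img)) == 3, dim(img)[3] == 3)
  png::writePNG(img / 255, path)
  invisible(path)
}

#' @rdname write_rgb_png
#' @export
read_rgb_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3 && dim(img)[3] == 4) img <- img[, , 1:3]
  array(as.integer(round(img * 255)), dim = dim(img))
}
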