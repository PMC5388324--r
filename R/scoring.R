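#' Time spent inside the near-display zone
#'
#' Counts frames of an occupancy trace whose head-tip distance from the
#' display-side inner wall is at most `zone_mm`, within a half-open time
#' interval `[start, end)` (seconds from trace start), and converts to
#' seconds. Frames with missing distance (tracking dropouts) are excluded
#' from both numerator and denominator and the occupancy is rescaled to the
#' interval length; such intervals are flagged via the `"rescaled"`
#' attribute.
#'
#' @param trace An `occupancy_trace` (see [simulate_assay()],
#'   [read_occupancy_csv()]).
#' @param zone_mm Zone width in mm (default 10).
#' @param interval Numeric `c(start_s, end_s)`; defaults to the whole trace.
#' @return Occupancy time in seconds.
#' @export
occupancy_time <- function(trace, zone_mm = 10, interval = NULL) {
  fps <- attr(trace, "fps")
  t_frame <- trace$frame / fps
  if (is.null(interval)) interval <- c(0, (max(trace$frame) + 1) / fps)
  sel <- t_frame >= interval[1] & t_frame < interval[2]
  if (!any(sel)) stop("empty interval: no frames in [", interval[1], ", ",
                      interval[2], ")")
  x <- trace$x_mm[sel]
  valid <- !is.na(x)
  len_s <- interval[2] - interval[1]
  if (!any(valid)) stop("interval contains no valid (non-missing) frames")
  occ <- sum(x[valid] <= zone_mm) / sum(valid) * len_s
  if (any(!valid)) attr(occ, "rescaled") <- TRUE
  occ
}

#' Score a cohort of occupancy traces
#'
#' Computes, for every subject, the baseline-period occupancy and the
#' occupancy in each 1-min stimulus bin (half-open bins `[m, m+1)` minutes).
#'
#' @param traces List of `occupancy_trace` objects.
#' @param zone_mm Zone width in mm (default 10).
#' @return A `score_table` tibble with columns `subject`, `group`,
#'   `baseline`, `min1` ... `min5` (seconds).
#' @seealso [exclude_baseline()], [difference_scores()]
#' @export
score_traces <- function(traces, zone_mm = 10) {
  rows <- lapply(traces, function(tr) {
    base_s <- attr(tr, "baseline_s")
    stim_s <- attr(tr, "stimulus_s")
    n_bins <- stim_s / 60
    bins <- vapply(seq_len(n_bins), function(m) {
      occupancy_time(tr, zone_mm,
                     interval = base_s + c((m - 1) * 60, m * 60))
    }, numeric(1))
    out <- c(occupancy_time(tr, zone_mm, interval = c(0, base_s)), bins)
    names(out) <- c("baseline", paste0("min", seq_len(n_bins)))
    c(list(subject = attr(tr, "subject"), group = attr(tr, "group")),
      as.list(out))
  })
  tab <- tibble::as_tibble(do.call(rbind.data.frame, rows))
  class(tab) <- c("score_table", class(tab))
  tab
}

#' Flag subjects with excessive baseline occupancy
#'
#' Subjects whose baseline occupancy is strictly greater than `threshold_s`
#' ("over 55 sec" read as a strict inequality) are flagged `excluded = TRUE`;
#' the rows are retained so the filter is auditable.
#'
#' @param table A `score_table` from [score_traces()].
#' @param threshold_s Exclusion threshold in seconds (default 55).
#' @return The table with an `excluded` logical column.
#' @export
exclude_baseline <- function(table, threshold_s = 55) {
  stopifnot("baseline" %in% names(table))
  table$excluded <- table$baseline > threshold_s
  table
}

#' Baseline-difference response scores
#'
#' For each retained subject and each stimulus minute, the response score is
#' that minute's occupancy minus the baseline occupancy (signed, seconds).
#'
#' @param table A `score_table` that has passed through [exclude_baseline()].
#' @return The table with added `diff1` ... `diff5` columns.
#' @export
difference_scores <- function(table) {
  if (!"excluded" %in% names(table))
    stop("apply exclude_baseline() before computing difference scores")
  bins <- grep("^min[0-9]+$", names(table), value = TRUE)
  for (b in bins)
    table[[sub("^min", "diff", b)]] <- table[[b]] - table$baseline
  table
}

#' Long-format scores for the mixed ANOVA
#'
#' Reshapes a scored, exclusion-filtered table into the long format used by
#' [mixed_anova()]: one row per retained subject and time level. With
#' `use = "difference"` (default, matching the assay's analysis) the baseline
#' level is the zero reference and minute levels carry the difference scores;
#' with `use = "occupancy"` the raw per-bin occupancies are used.
#'
#' @param table Output of [difference_scores()].
#' @param use `"difference"` or `"occupancy"`.
#' @return A tibble with columns `subject`, `group`, `time` (factor:
#'   `baseline`, `min1`, ...), `score`.
#' @export
scores_to_long <- function(table, use = c("difference", "occupancy")) {
  use <- match.arg(use)
  keep <- !table$excluded
  tab <- table[keep, , drop = FALSE]
  bins <- grep("^min[0-9]+$", names(tab), value = TRUE)
  levels <- c("baseline", bins)
  vals <- switch(use,
    occupancy = cbind(tab$baseline,
                      as.matrix(tab[, bins, drop = FALSE])),
    difference = cbind(0, as.matrix(tab[, sub("^min", "diff", bins),
                                        drop = FALSE])))
  tibble::tibble(
    subject = rep(tab$subject, times = length(levels)),
    group = rep(tab$group, times = length(levels)),
    time = factor(rep(levels, each = nrow(tab)), levels = levels),
    score = as.vector(vals))
}
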