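#' One-way between-subjects ANOVA
#'
#' Classical fixed-effects decomposition with `F` on `(g - 1, N - g)` degrees
#' of freedom. Used for the baseline-period group comparison. With zero
#' error variance (all observations equal within cells) the `F` ratio is
#' undefined and reported as `NaN` with a warning.
#'
#' @param scores Numeric vector of observations.
#' @param group Factor (or coercible) of group labels, same length.
#' @return An `anova_table` tibble with effect and error rows (`ss`, `df`,
#'   `ms`, `f`, `df1`, `df2`, `p`).
#' @export
oneway_anova <- function(scores, group) {
  group <- factor(group)
  stopifnot(length(scores) == length(group))
  ng <- table(group)
  if (nlevels(group) < 2) stop("need at least 2 groups")
  if (any(ng < 2)) stop("every group needs n >= 2")
  N <- length(scores); g <- nlevels(group)
  grand <- mean(scores)
  gm <- tapply(scores, group, mean)
  ss_b <- sum(ng * (gm - grand)^2)
  ss_w <- sum((scores - gm[group])^2)
  df_b <- g - 1; df_w <- N - g
  ms_b <- ss_b / df_b; ms_w <- ss_w / df_w
  if (ms_w == 0) {
    warning("zero error variance: F undefined, reported as NaN")
    f <- NaN; p <- NaN
  } else {
    f <- ms_b / ms_w
    p <- pf(f, df_b, df_w, lower.tail = FALSE)
  }
  tab <- tibble::tibble(
    effect = c("group", "residuals"),
    stratum = c("between", "error"),
    ss = c(ss_b, ss_w), df = c(df_b, df_w), ms = c(ms_b, ms_w),
    f = c(f, NA), df1 = c(df_b, NA), df2 = c(df_w, NA), p = c(p, NA))
  class(tab) <- c("anova_table", class(tab))
  attr(tab, "design") <- "oneway"
  tab
}

# split-plot sums of squares on a wide subjects x time matrix; the fast path
# used by public mixed_anova() and by the Monte-Carlo calibration loops
mixed_anova_matrix <- function(Y, group) {
  group <- factor(group)
  N <- nrow(Y); k <- ncol(Y); g <- nlevels(group)
  ng <- as.numeric(table(group))
  grand <- mean(Y)
  subj_means <- rowMeans(Y)
  group_means <- tapply(subj_means, group, mean)
  time_means <- colMeans(Y)
  cell_means <- rowsum(Y, group) / ng

  ss_total <- sum((Y - grand)^2)
  ss_bsubj <- k * sum((subj_means - grand)^2)
  ss_group <- k * sum(ng * (group_means - grand)^2)
  ss_serr <- ss_bsubj - ss_group
  ss_time <- N * sum((time_means - grand)^2)
  ss_cells <- sum(ng * (cell_means - grand)^2)
  ss_int <- ss_cells - ss_group - ss_time
  ss_werr <- ss_total - ss_bsubj - ss_time - ss_int

  df_group <- g - 1; df_serr <- N - g
  df_time <- k - 1; df_int <- (g - 1) * (k - 1); df_werr <- (N - g) * (k - 1)
  ms <- c(ss_group / df_group, ss_serr / df_serr, ss_time / df_time,
          ss_int / df_int, ss_werr / df_werr)
  f_group <- if (ms[2] > 0) ms[1] / ms[2] else NaN
  f_time <- if (ms[5] > 0) ms[3] / ms[5] else NaN
  f_int <- if (ms[5] > 0) ms[4] / ms[5] else NaN
  if (ms[2] == 0 || ms[5] == 0)
    warning("zero error variance in at least one stratum: F reported as NaN")
  p_group <- if (is.nan(f_group)) NaN else pf(f_group, df_group, df_serr, lower.tail = FALSE)
  p_time <- if (is.nan(f_time)) NaN else pf(f_time, df_time, df_werr, lower.tail = FALSE)
  p_int <- if (is.nan(f_int)) NaN else pf(f_int, df_int, df_werr, lower.tail = FALSE)

  tab <- tibble::tibble(
    effect = c("group", "subjects(group)", "time", "group:time",
               "time:subjects(group)"),
    stratum = c("between", "error", "within", "within", "error"),
    ss = c(ss_group, ss_serr, ss_time, ss_int, ss_werr),
    df = c(df_group, df_serr, df_time, df_int, df_werr),
    ms = ms,
    f = c(f_group, NA, f_time, f_int, NA),
    df1 = c(df_group, NA, df_time, df_int, NA),
    df2 = c(df_serr, NA, df_werr, df_werr, NA),
    p = c(p_group, NA, p_time, p_int, NA))
  class(tab) <- c("anova_table", class(tab))
  attr(tab, "design") <- "mixed"
  attr(tab, "k") <- k
  attr(tab, "N") <- N
  attr(tab, "g") <- g
  tab
}

#' Two-way mixed (split-plot) ANOVA
#'
#' Decomposes a between-group x within-subject (repeated measures) design:
#' the group effect is tested against the subjects-within-groups error, the
#' time effect and the group-by-time interaction against the
#' time-by-subjects-within-groups error. Raw degrees of freedom: group
#' `(g-1, N-g)`, time `(k-1, (N-g)(k-1))`, interaction
#' `((g-1)(k-1), (N-g)(k-1))`. Sums of squares are the weighted cell-mean
#' decomposition, exact for the balanced designs this assay produces.
#'
#' @param data Long-format data frame with columns `subject`, `group`,
#'   `time`, `score`; every subject must have exactly one score at every time
#'   level (complete data), each group at least 2 subjects.
#' @return An `anova_table` tibble (effects plus error strata).
#' @seealso [huynh_feldt_correction()] for sphericity-corrected p-values;
#'   [mendoza_sphericity()] to estimate the correction.
#' @export
mixed_anova <- function(data) {
  wide <- long_to_wide(data)
  if (any(table(wide$group) < 2)) stop("each group needs n >= 2 subjects")
  if (ncol(wide$Y) < 2) stop("need k >= 2 time levels")
  mixed_anova_matrix(wide$Y, wide$group)
}

# long (subject, group, time, score) -> wide subjects x time matrix + group
long_to_wide <- function(data) {
  need <- c("subject", "group", "time", "score")
  if (!all(need %in% names(data)))
    stop("data must have columns: ", paste(need, collapse = ", "))
  time <- if (is.factor(data$time)) data$time else factor(data$time)
  subject <- factor(data$subject, levels = unique(data$subject))
  counts <- table(subject, time)
  if (any(counts != 1))
    stop("design is incomplete: every subject needs exactly one score per time level")
  k <- nlevels(time)
  Y <- matrix(NA_real_, nlevels(subject), k,
              dimnames = list(levels(subject), levels(time)))
  Y[cbind(as.integer(subject), as.integer(time))] <- data$score
  group_of <- tapply(as.character(data$group), subject, function(x) x[1])
  if (any(tapply(as.character(data$group), subject,
                 function(x) length(unique(x))) != 1))
    stop("each subject must belong to exactly one group")
  list(Y = Y, group = factor(group_of[levels(subject)]))
}

#' Huynh-Feldt correction of within-subject degrees of freedom
#'
#' Multiplies the numerator and denominator degrees of freedom of every
#' within-subject effect by the sphericity estimate `eps` and recomputes the
#' p-values from the F distribution at the corrected df. Between-subject
#' effects are untouched.
#'
#' @param anova An `anova_table` from [mixed_anova()].
#' @param eps Epsilon in `[1/(k-1), 1]`, typically `eps_hf` from
#'   [mendoza_sphericity()].
#' @return The corrected `anova_table`; corrected rows have `df1`, `df2` and
#'   `p` replaced, and the table carries an `"epsilon"` attribute.
#' @export
huynh_feldt_correction <- function(anova, eps) {
  stopifnot(inherits(anova, "anova_table"))
  k <- attr(anova, "k")
  if (!is.null(k) && (eps < 1 / (k - 1) - 1e-12 || eps > 1 + 1e-12))
    stop("eps must lie in [1/(k-1), 1]")
  within <- which(anova$stratum == "within")
  for (i in within) {
    anova$df1[i] <- anova$df1[i] * eps
    anova$df2[i] <- anova$df2[i] * eps
    anova$p[i] <- if (is.nan(anova$f[i])) NaN else
      pf(anova$f[i], anova$df1[i], anova$df2[i], lower.tail = FALSE)
  }
  attr(anova, "epsilon") <- eps
  anova
}

#' Simple main effects after a significant interaction
#'
#' Slices the mixed design both ways: the effect of group at each time level
#' (one-way between-subjects ANOVA on that time slice) and the effect of time
#' within each group (one-way repeated-measures ANOVA on that group's
#' subjects). Each slice is tested against its own error term, which is
#' robust when homogeneity or sphericity across slices is doubtful.
#'
#' @param data Long-format data as for [mixed_anova()].
#' @return A list with tibbles `group_at_time` (one row per time level) and
#'   `time_within_group` (one row per group), each with `ss`, `df1`, `df2`,
#'   `f`, `p`.
#' @export
simple_main_effects <- function(data) {
  wide <- long_to_wide(data)
  Y <- wide$Y; group <- wide$group
  k <- ncol(Y)
  times <- colnames(Y)

  gat <- lapply(seq_len(k), function(t) {
    tab <- oneway_anova(Y[, t], group)
    tibble::tibble(time = times[t], ss = tab$ss[1], df1 = tab$df1[1],
                   df2 = tab$df2[1], f = tab$f[1], p = tab$p[1])
  })
  twg <- lapply(levels(group), function(gl) {
    Yg <- Y[group == gl, , drop = FALSE]
    r <- rm_oneway(Yg)
    tibble::tibble(group = gl, ss = r$ss_time, df1 = r$df1, df2 = r$df2,
                   f = r$f, p = r$p)
  })
  list(group_at_time = do.call(rbind, gat),
       time_within_group = do.call(rbind, twg))
}

# one-way repeated-measures ANOVA on an n x k matrix (single group)
rm_oneway <- function(Y) {
  n <- nrow(Y); k <- ncol(Y)
  grand <- mean(Y)
  ss_time <- n * sum((colMeans(Y) - grand)^2)
  ss_subj <- k * sum((rowMeans(Y) - grand)^2)
  ss_err <- sum((Y - grand)^2) - ss_time - ss_subj
  df1 <- k - 1; df2 <- (n - 1) * (k - 1)
  ms_t <- ss_time / df1; ms_e <- ss_err / df2
  f <- if (ms_e > 0) ms_t / ms_e else NaN
  p <- if (is.nan(f)) NaN else pf(f, df1, df2, lower.tail = FALSE)
  list(ss_time = ss_time, ss_err = ss_err, df1 = df1, df2 = df2, f = f, p = p)
}
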