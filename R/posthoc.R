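#' Nominal significance level for one Ryan-procedure comparison
#'
#' In the stepwise-alpha formulation of Ryan's multiple-comparison procedure,
#' a pair of rank-ordered means spanning `m` of the `k` means is tested at
#' the adjusted per-comparison level
#'
#'   `alpha_m = 2 * alpha / (k * (m - 1))`
#'
#' Wider stretches get smaller nominal levels, which compensates for the
#' selection effect of comparing the extreme order statistics of a stretch
#' with an ordinary t-test: the full-range level `2 alpha / (k (k - 1))`
#' approximates the studentized-range calibration, so the family-wise error
#' under the complete null stays below `alpha`. For `k = 2` the single
#' comparison is tested at exactly `alpha` (a plain two-mean test). Other
#' published variants of "Ryan's method" exist — notably the
#' Ryan-Einot-Gabriel-Welsch refinement `1 - (1 - alpha)^(m/k)` with
#' studentized-range statistics; this package uses the stepwise-alpha t-test
#' formulation above throughout, isolated in this one function.
#'
#' @param m Stretch size (number of ordered means spanned, 2..k).
#' @param k Total number of means.
#' @param alpha Family-wise significance level.
#' @return The nominal per-comparison level.
#' @export
ryan_alpha <- function(m, k, alpha = 0.05) {
  stopifnot(m >= 2, m <= k, k >= 2, alpha > 0, alpha < 1)
  2 * alpha / (k * (m - 1))
}

#' Ryan's stepwise post-hoc multiple comparisons
#'
#' Pairwise t-tests on the pooled error term, processed stepwise over
#' rank-ordered means: each pair spanning `m` ordered means is tested at the
#' adjusted level [ryan_alpha()]`(m, k, alpha)`, and a pair can be declared
#' significant only if no enclosing span has already tested non-significant
#' (stepwise coherence, so no isolated significance can appear inside a
#' non-significant stretch). Under the complete null the family-wise error
#' is bounded by the full-range level `2 alpha / (k - 1) <= alpha`.
#'
#' @param means Named numeric vector of the `k` means to compare.
#' @param n Common cell size, or a vector of per-mean sizes.
#' @param ms_error Pooled error mean square from the relevant ANOVA stratum.
#' @param df_error Degrees of freedom of that error term.
#' @param alpha Family-wise significance level (default 0.05).
#' @return A `ryan_posthoc` tibble, one row per pair: the two labels, means,
#'   stretch size `m`, `alpha_nominal`, `t`, `p`, `blocked`, `significant`.
#' @export
ryan_posthoc <- function(means, n, ms_error, df_error, alpha = 0.05) {
  k <- length(means)
  stopifnot(k >= 2, ms_error >= 0, df_error > 0)
  if (is.null(names(means))) names(means) <- paste0("m", seq_len(k))
  if (length(n) == 1) n <- rep(n, k)
  stopifnot(length(n) == k, all(n >= 1))

  ord <- order(means)
  mo <- means[ord]; no <- n[ord]
  # all rank pairs, largest stretches first
  pairs <- do.call(rbind, lapply(k:2, function(m) {
    i <- seq_len(k - m + 1)
    cbind(i = i, j = i + m - 1L, m = m)
  }))
  npair <- nrow(pairs)
  sig <- logical(npair); blocked <- logical(npair)
  tval <- numeric(npair); pval <- numeric(npair); a_nom <- numeric(npair)
  # significance status lookup by (i, j)
  status <- matrix(NA, k, k)  # TRUE = significant, FALSE = failed/blocked
  for (r in seq_len(npair)) {
    i <- pairs[r, "i"]; j <- pairs[r, "j"]; m <- pairs[r, "m"]
    a_nom[r] <- ryan_alpha(m, k, alpha)
    se <- sqrt(ms_error * (1 / no[i] + 1 / no[j]))
    tval[r] <- if (se > 0) (mo[j] - mo[i]) / se else NaN
    pval[r] <- if (is.nan(tval[r])) NaN else
      2 * pt(abs(tval[r]), df_error, lower.tail = FALSE)
    # immediate enclosing spans (checked top-down, so already decided)
    enc <- c(if (i > 1) status[i - 1, j], if (j < k) status[i, j + 1])
    blocked[r] <- length(enc) > 0 && any(!enc)
    sig[r] <- !blocked[r] && !is.nan(pval[r]) && pval[r] < a_nom[r]
    status[i, j] <- sig[r]
  }
  lab <- names(mo)
  tab <- tibble::tibble(
    level_1 = lab[pairs[, "i"]], level_2 = lab[pairs[, "j"]],
    mean_1 = unname(mo[pairs[, "i"]]), mean_2 = unname(mo[pairs[, "j"]]),
    m = pairs[, "m"], alpha_nominal = a_nom,
    t = tval, p = pval, blocked = blocked, significant = sig)
  class(tab) <- c("ryan_posthoc", class(tab))
  attr(tab, "alpha") <- alpha
  attr(tab, "df_error") <- df_error
  tab
}
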