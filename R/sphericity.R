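#' Multisample sphericity test and epsilon estimates
#'
#' Likelihood-ratio test of multisample sphericity for a repeated-measures
#' design with `g` independent groups: the null hypothesis is that the
#' covariance matrix of the orthonormally contrasted scores is the same
#' spherical matrix `sigma^2 I` in every group (Mendoza 1980, Psychometrika
#' 45, 495-498). The modified (error-df) likelihood ratio decomposes exactly
#' into Box's M statistic for equality of the contrast covariances plus the
#' pooled Mauchly sphericity statistic; each part is scaled by its standard
#' Box (1949) / Bartlett small-sample factor and the sum is referred to a
#' chi-square distribution with `g p (p + 1) / 2 - 1` degrees of freedom,
#' `p = k - 1`.
#'
#' Also returns the Greenhouse-Geisser epsilon computed from the pooled
#' contrast covariance and the multisample Huynh-Feldt epsilon
#' `((N - g + 1) p eps_GG - 2) / (p (N - g - p eps_GG))` (Lecoutre's
#' corrected form), clipped to at most 1.
#'
#' @param data Long-format data as for [mixed_anova()], or a list
#'   `list(Y = subjects x time matrix, group = factor)`.
#' @return An object of class `sphericity_result`: `statistic`, `df`, `p`,
#'   `eps_gg`, `eps_hf`, plus the design constants.
#' @export
mendoza_sphericity <- function(data) {
  wide <- if (is.list(data) && !is.null(data$Y) && is.matrix(data$Y)) {
    list(Y = data$Y, group = factor(data$group))
  } else long_to_wide(data)
  Y <- wide$Y; group <- wide$group
  N <- nrow(Y); k <- ncol(Y); g <- nlevels(group)
  p <- k - 1
  ng <- as.numeric(table(group))
  if (any(ng <= p))
    stop("singular pooled covariance: every group needs n > k - 1 subjects; ",
         "increase the sample size")

  C <- orthonormal_contrasts(k)
  Z <- Y %*% C
  nu_j <- ng - 1
  nu <- N - g
  A <- vector("list", g)
  logdet_j <- numeric(g)
  for (j in seq_len(g)) {
    Zj <- Z[group == levels(group)[j], , drop = FALSE]
    Zc <- sweep(Zj, 2, colMeans(Zj))
    A[[j]] <- crossprod(Zc)
    ld <- determinant(A[[j]] / nu_j[j], logarithm = TRUE)
    if (ld$sign <= 0 || !is.finite(ld$modulus))
      stop("singular within-group contrast covariance in group ",
           levels(group)[j], "; increase the sample size")
    logdet_j[j] <- as.numeric(ld$modulus)
  }
  E <- Reduce(`+`, A)
  ld_pooled <- determinant(E / nu, logarithm = TRUE)
  if (ld_pooled$sign <= 0)
    stop("singular pooled contrast covariance; increase the sample size")
  logdet_pooled <- as.numeric(ld_pooled$modulus)
  tr_pooled <- sum(diag(E)) / nu

  # Box's M for equality of the g contrast covariances, with Box's (1949)
  # chi-square scaling factor
  box_m <- nu * logdet_pooled - sum(nu_j * logdet_j)
  if (g > 1) {
    c1 <- (sum(1 / nu_j) - 1 / nu) *
      (2 * p^2 + 3 * p - 1) / (6 * (p + 1) * (g - 1))
  } else {
    box_m <- 0; c1 <- 0
  }
  # pooled Mauchly sphericity LR with the Bartlett-type multiplier
  lr_sph <- p * nu * log(tr_pooled / p) - nu * logdet_pooled
  rho <- 1 - (2 * p^2 + p + 2) / (6 * p * nu)

  statistic <- (1 - c1) * box_m + rho * lr_sph
  df <- g * p * (p + 1) / 2 - 1
  p_value <- pchisq(statistic, df, lower.tail = FALSE)

  S <- E / nu
  eps_gg <- sum(diag(S))^2 / (p * sum(S * S))
  eps_hf <- ((N - g + 1) * p * eps_gg - 2) / (p * (N - g - p * eps_gg))
  eps_hf <- min(1, max(eps_hf, eps_gg))

  structure(list(statistic = statistic, df = df, p = p_value,
                 eps_gg = eps_gg, eps_hf = eps_hf,
                 box_m = box_m, lr_sphericity = lr_sph,
                 k = k, N = N, g = g),
            class = "sphericity_result")
}

#' @export
print.sphericity_result <- function(x, ...) {
  cat(sprintf(
    "Multisample sphericity test: chi-square(%g) = %.3f, p = %.4g\n",
    x$df, x$statistic, x$p))
  cat(sprintf("  eps_GG = %.4f, eps_HF = %.4f (g = %d, N = %d, k = %d)\n",
              x$eps_gg, x$eps_hf, x$g, x$N, x$k))
  invisible(x)
}

# orthonormal contrast basis of k repeated-measures levels (normalized
# Helmert columns, each orthogonal to the unit vector)
orthonormal_contrasts <- function(k) {
  H <- stats::contr.helmert(k)
  sweep(H, 2, sqrt(colSums(H^2)), `/`)
}
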