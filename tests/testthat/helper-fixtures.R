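# shared fixture builders; everything is generated in code under fixed seeds

quick_track <- function(duration = 2, seed = 7, ...) {
  simulate_swimmer(swimmer_params(duration = duration, seed = seed, ...))
}

# long-format mixed-design data from a wide subjects x time matrix
make_long <- function(Y, group) {
  n <- nrow(Y); k <- ncol(Y)
  if (is.null(colnames(Y))) colnames(Y) <- paste0("t", seq_len(k))
  data.frame(
    subject = rep(sprintf("s%03d", seq_len(n)), k),
    group = rep(as.character(group), k),
    time = factor(rep(colnames(Y), each = n), levels = colnames(Y)),
    score = as.vector(Y))
}

# brute-force split-plot sums of squares via explicit marginal means
naive_mixed_ss <- function(Y, group) {
  group <- factor(group)
  N <- nrow(Y); k <- ncol(Y)
  grand <- mean(Y)
  ss <- list(total = sum((Y - grand)^2))
  subj_mean <- rowMeans(Y)
  ss$between_subj <- 0
  for (s in seq_len(N)) ss$between_subj <- ss$between_subj + k * (subj_mean[s] - grand)^2
  ss$group <- 0
  for (gl in levels(group)) {
    sel <- group == gl
    ss$group <- ss$group + sum(sel) * k * (mean(Y[sel, , drop = FALSE]) - grand)^2
  }
  ss$subj_err <- ss$between_subj - ss$group
  ss$time <- 0
  for (t in seq_len(k)) ss$time <- ss$time + N * (mean(Y[, t]) - grand)^2
  ss$cells <- 0
  for (gl in levels(group)) for (t in seq_len(k)) {
    sel <- group == gl
    ss$cells <- ss$cells + sum(sel) * (mean(Y[sel, t]) - grand)^2
  }
  ss$interaction <- ss$cells - ss$group - ss$time
  ss$within_err <- ss$total - ss$between_subj - ss$time - ss$interaction
  ss
}

# wide matrix with exactly spherical (identity-proportional) within-group
# contrast covariance, identical across groups
spherical_matrix <- function(n_per_group, g, k, scale = 2, seed = 1) {
  withr::with_seed(seed, {
    p <- k - 1
    Z0 <- qr.Q(qr(scale(matrix(rnorm(n_per_group * p), n_per_group, p),
                        scale = FALSE)))
    C <- fishstim:::orthonormal_contrasts(k)
    block <- sqrt(scale) * Z0 %*% t(C)
    Y <- do.call(rbind, replicate(g, block, simplify = FALSE))
    list(Y = Y, group = factor(rep(seq_len(g), each = n_per_group)))
  })
}
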