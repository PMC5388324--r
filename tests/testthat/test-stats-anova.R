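test_that("one-way ANOVA matches its algebraic identities and oracles", {
  # degenerate: all observations equal -> F undefined, NaN with warning
  expect_warning(tab0 <- oneway_anova(rep(3, 9), rep(letters[1:3], 3)),
                 "NaN")
  expect_true(is.nan(tab0$f[1]))
  expect_equal(tab0$ss[1], 0)

  # two groups: F equals the squared pooled-variance t statistic
  withr::with_seed(51, {
    x <- rnorm(12); y <- rnorm(10, mean = 1)
  })
  tab <- oneway_anova(c(x, y), rep(c("a", "b"), c(12, 10)))
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(tab$f[1], unname(tt$statistic)^2, tolerance = 1e-12)
  expect_equal(tab$p[1], tt$p.value, tolerance = 1e-12)
  expect_equal(tab$df[1:2], c(1, 20))

  # seeded data vs brute-force cell-mean sums
  withr::with_seed(52, {
    g <- rep(c("a", "b", "c"), c(5, 7, 6))
    v <- rnorm(length(g), mean = as.integer(factor(g)))
  })
  tab2 <- oneway_anova(v, g)
  grand <- mean(v)
  ss_b <- sum(vapply(unique(g), function(gl)
    sum(g == gl) * (mean(v[g == gl]) - grand)^2, numeric(1)))
  ss_w <- sum(vapply(unique(g), function(gl)
    sum((v[g == gl] - mean(v[g == gl]))^2), numeric(1)))
  expect_equal(tab2$ss, c(ss_b, ss_w), tolerance = 1e-12)
  expect_equal(tab2$f[1], (ss_b / 2) / (ss_w / 15), tolerance = 1e-12)
})

test_that("mixed ANOVA reproduces the split-plot degrees of freedom", {
  for (case in list(list(n = 18, g = 6, k = 6, df2 = 102),
                    list(n = 24, g = 6, k = 6, df2 = 138))) {
    withr::with_seed(53, {
      Y <- matrix(rnorm(case$n * case$g * case$k), case$n * case$g, case$k)
    })
    grp <- rep(paste0("g", seq_len(case$g)), each = case$n)
    tab <- mixed_anova(make_long(Y, grp))
    expect_equal(tab$df1[tab$effect == "group"], case$g - 1)
    expect_equal(tab$df2[tab$effect == "group"], case$df2)
    expect_equal(tab$df1[tab$effect == "time"], case$k - 1)
    expect_equal(tab$df2[tab$effect == "time"], case$df2 * (case$k - 1))
    expect_equal(tab$df1[tab$effect == "group:time"],
                 (case$g - 1) * (case$k - 1))
  }
})

test_that("mixed ANOVA sums of squares match the brute-force oracle", {
  withr::with_seed(54, {
    Y <- matrix(rnorm(6 * 3), 6, 3) + rep(c(0, 2), each = 3)
  })
  grp <- rep(c("a", "b"), each = 3)
  tab <- mixed_anova(make_long(Y, grp))
  ss <- naive_mixed_ss(Y, grp)
  expect_equal(tab$ss[tab$effect == "group"], ss$group, tolerance = 1e-10)
  expect_equal(tab$ss[tab$effect == "subjects(group)"], ss$subj_err,
               tolerance = 1e-10)
  expect_equal(tab$ss[tab$effect == "time"], ss$time, tolerance = 1e-10)
  expect_equal(tab$ss[tab$effect == "group:time"], ss$interaction,
               tolerance = 1e-10)
  expect_equal(tab$ss[tab$effect == "time:subjects(group)"], ss$within_err,
               tolerance = 1e-10)
})

test_that("mixed ANOVA agrees with the aov split-plot oracle", {
  withr::with_seed(55, {
    Y <- matrix(rnorm(15 * 4), 15, 4) + rep(c(0, 1, 3), each = 5)
  })
  long <- make_long(Y, rep(c("a", "b", "c"), each = 5))
  tab <- mixed_anova(long)
  fit <- summary(stats::aov(score ~ group * time + Error(subject),
                            data = long))
  between <- fit[["Error: subject"]][[1]]
  within <- fit[["Error: Within"]][[1]]
  expect_equal(tab$f[tab$effect == "group"], between["group", "F value"],
               tolerance = 1e-10)
  expect_equal(tab$p[tab$effect == "group"], between["group", "Pr(>F)"],
               tolerance = 1e-10)
  expect_equal(tab$f[tab$effect == "time"], within["time", "F value"],
               tolerance = 1e-10)
  expect_equal(tab$f[tab$effect == "group:time"],
               within["group:time", "F value"], tolerance = 1e-10)
})

test_that("sums of squares are conserved and subject order is irrelevant", {
  for (seed in 56:58) {
    withr::with_seed(seed, {
      Y <- matrix(rnorm(12 * 5, sd = 2), 12, 5)
      perm <- sample(12)
    })
    grp <- rep(c("a", "b", "c"), each = 4)
    tab <- mixed_anova(make_long(Y, grp))
    grand <- mean(Y)
    expect_equal(sum(tab$ss), sum((Y - grand)^2), tolerance = 1e-10)

    tab_perm <- mixed_anova(make_long(Y[perm, ], grp[perm]))
    expect_equal(tab_perm$ss, tab$ss, tolerance = 1e-10)
    expect_equal(tab_perm$f, tab$f, tolerance = 1e-10)
  }
})

test_that("invalid mixed designs are rejected", {
  withr::with_seed(59, Y <- matrix(rnorm(8), 4, 2))
  long <- make_long(Y, rep(c("a", "b"), each = 2))
  expect_error(mixed_anova(long[-1, ]), "incomplete")
  long2 <- make_long(Y, c("a", "a", "a", "b"))
  expect_error(mixed_anova(long2), "n >= 2")
})

test_that("zero within-cell variance yields NaN F with a warning", {
  Y <- matrix(rep(c(1, 2), each = 4), 4, 2)  # identical subjects
  expect_warning(tab <- mixed_anova(make_long(Y, rep(c("a", "b"), 2))),
                 "NaN")
  expect_true(is.nan(tab$f[tab$effect == "group"]))
})
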