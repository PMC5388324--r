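make_trace <- function(x_mm, fps = 30, baseline_s = 60, stimulus_s = 300,
                       subject = "s001", group = "g") {
  tr <- tibble::tibble(
    frame = seq_along(x_mm) - 1L,
    x_mm = x_mm,
    period = rep(c("baseline", "stimulus"),
                 c(baseline_s * fps, length(x_mm) - baseline_s * fps)))
  attr(tr, "subject") <- subject
  attr(tr, "group") <- group
  attr(tr, "fps") <- fps
  attr(tr, "baseline_s") <- baseline_s
  attr(tr, "stimulus_s") <- stimulus_s
  class(tr) <- c("occupancy_trace", class(tr))
  tr
}

test_that("occupancy time counts in-zone frames over the interval", {
  always <- make_trace(rep(5, 360 * 30))
  never <- make_trace(rep(20, 360 * 30))
  expect_equal(occupancy_time(always, interval = c(0, 60)), 60)
  expect_equal(occupancy_time(never, interval = c(0, 60)), 0)
  expect_error(occupancy_time(always, interval = c(400, 410)), "empty")

  withr::with_seed(81, x <- runif(360 * 30, 0, 40))
  tr <- make_trace(x)
  fps <- 30
  for (iv in list(c(0, 60), c(60, 120), c(300, 360))) {
    cnt <- 0
    for (f in seq_along(x)) {
      t <- (f - 1) / fps
      if (t >= iv[1] && t < iv[2] && x[f] <= 10) cnt <- cnt + 1
    }
    expect_equal(occupancy_time(tr, 10, iv), cnt / fps)
  }
})

test_that("occupancy is monotone in the zone width", {
  withr::with_seed(82, x <- runif(60 * 30, 0, 40))
  tr <- make_trace(x, stimulus_s = 0)
  occ <- vapply(c(2, 5, 10, 20, 40), function(z)
    occupancy_time(tr, z, c(0, 60)), numeric(1))
  expect_true(all(diff(occ) >= 0))
})

test_that("tracking dropouts are rescaled to the bin length", {
  x <- rep(c(5, NA), 30 * 30)  # half the frames missing, all valid in zone
  tr <- make_trace(x, stimulus_s = 0)
  occ <- occupancy_time(tr, 10, c(0, 60))
  expect_equal(as.numeric(occ), 60)
  expect_true(isTRUE(attr(occ, "rescaled")))
})

test_that("baseline exclusion is strict at the threshold", {
  in_zone_for <- function(s) make_trace(rep(c(5, 20), c(s * 30, (360 - s) * 30)))
  tab <- score_traces(list(in_zone_for(55), in_zone_for(56), in_zone_for(10)))
  tab <- exclude_baseline(tab)
  expect_equal(tab$excluded, c(FALSE, TRUE, FALSE))
  # threshold at the bin length can exclude nobody
  expect_false(any(exclude_baseline(tab, threshold_s = 60)$excluded))
  # raising the threshold never excludes more subjects
  for (th in c(0, 20, 40, 55, 60)) {
    n_th <- sum(exclude_baseline(tab, th)$excluded)
    n_hi <- sum(exclude_baseline(tab, th + 5)$excluded)
    expect_gte(n_th, n_hi)
  }
})

test_that("a planted cohort of baseline sitters is filtered exactly", {
  sitter <- function(id) make_trace(rep(3, 360 * 30), subject = id)
  roamer <- function(id) make_trace(rep(c(3, 30), 360 * 15), subject = id)
  cohort <- c(lapply(sprintf("sit%02d", 1:4), sitter),
              lapply(sprintf("roam%02d", 1:8), roamer))
  tab <- exclude_baseline(score_traces(cohort))
  expect_equal(sum(tab$excluded), 4)
  expect_equal(sum(!tab$excluded), 8)
  expect_true(all(grepl("^sit", tab$subject[tab$excluded])))
})

test_that("difference scores subtract the baseline occupancy per minute", {
  x <- rep(c(5, 20), c(60 * 30, 300 * 30))     # all baseline, never after
  tab <- difference_scores(exclude_baseline(score_traces(list(
    make_trace(x),
    make_trace(rep(c(20, 5, 20), c(60 * 30, 60 * 30, 240 * 30)))))))
  # subject 1: baseline 60, all stimulus minutes 0 -> diffs -60
  expect_equal(unlist(tab[1, paste0("diff", 1:5)], use.names = FALSE),
               rep(-60, 5))
  # subject 2: baseline 0, minute 1 fully in zone -> +60, others 0
  expect_equal(tab$diff1[2], 60)
  expect_equal(unlist(tab[2, paste0("diff", 2:5)], use.names = FALSE),
               rep(0, 4))
  # bounds
  d <- as.matrix(tab[, paste0("diff", 1:5)])
  expect_true(all(d >= -60 & d <= 60))
  expect_error(difference_scores(score_traces(list(make_trace(x)))),
               "exclude_baseline")
})

test_that("stimulus equal to baseline gives zero difference", {
  x <- rep(5, 360 * 30)
  tab <- difference_scores(exclude_baseline(score_traces(list(make_trace(x))),
                                            threshold_s = 61))
  expect_equal(unlist(tab[1, paste0("diff", 1:5)], use.names = FALSE),
               rep(0, 5))
})

test_that("a rate step-up yields the analytic stationary occupancy gap", {
  e1 <- 0.05; e2 <- 0.45; ex <- 0.15
  entry <- matrix(c(e1, rep(e2, 5)), 1, 6, byrow = TRUE,
                  dimnames = list("g", NULL))
  p <- assay_params(100, "g", zone_entry_rate = entry, zone_exit_rate = ex,
                    init_state = "random", seed = 83)
  tab <- difference_scores(exclude_baseline(score_traces(simulate_assay(p)),
                                            threshold_s = 61))
  # stationary occupancy fractions before/after the step
  f1 <- e1 / (e1 + ex); f2 <- e2 / (e2 + ex)
  gap <- (f2 - f1) * 60
  late <- rowMeans(as.matrix(tab[, c("diff3", "diff4", "diff5")]))
  expect_gt(mean(late), 0)
  expect_lt(abs(mean(late) - gap), 3)
})
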