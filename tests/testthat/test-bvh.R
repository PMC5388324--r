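straight_track <- function(n = 10, npts = 6, step = 2) {
  coords <- array(0, c(n, npts, 3))
  for (i in seq_len(n)) coords[i, , 1] <- i * step + seq(0, -30, length.out = npts)
  coords[, , 3] <- 40
  midline_track(coords, 60)
}

test_that("segment vectors are unit normalized differences", {
  tr <- straight_track()
  v <- segment_vectors(tr)
  expect_equal(dim(v), c(10, 5, 3))
  expect_true(all(abs(v[, , 1] - (-1)) < 1e-12))  # body extends along -x
  expect_true(all(abs(v[, , 2]) < 1e-12))

  sw <- quick_track(duration = 0.5, seed = 21)
  vs <- segment_vectors(sw)
  norms <- sqrt(vs[, , 1]^2 + vs[, , 2]^2 + vs[, , 3]^2)
  expect_true(all(abs(norms - 1) < 1e-12))
  # brute-force recomputation on one frame
  for (j in 1:5) {
    d <- sw$coords[3, j + 1, ] - sw$coords[3, j, ]
    expect_equal(unname(vs[3, j, ]), unname(d / sqrt(sum(d^2))),
                 tolerance = 1e-12)
  }
})

test_that("coincident consecutive points raise a located error", {
  tr <- straight_track()
  tr$coords[4, 3, ] <- tr$coords[4, 2, ]
  expect_error(segment_vectors(tr), "frame 4, segment 2")
})

test_that("euler angles of reference directions and reconstruction", {
  expect_equal(unname(vector_to_euler(c(1, 0, 0))), c(0, 0, 0))
  expect_equal(unname(vector_to_euler(c(0, 1, 0))), c(90, 0, 0))

  withr::with_seed(42, {
    v <- matrix(rnorm(3000), ncol = 3)
    v <- v / sqrt(rowSums(v^2))
  })
  err <- vapply(seq_len(nrow(v)), function(i) {
    e <- vector_to_euler(v[i, ])
    max(abs(euler_to_matrix(e[1], e[2], e[3]) %*% c(1, 0, 0) - v[i, ]))
  }, numeric(1))
  expect_lt(max(err), 1e-9)
})

test_that("near-vertical vectors carry the previous yaw", {
  e <- vector_to_euler(c(1e-9, 0, 1), prev_yaw = 33)
  expect_equal(unname(e[1]), 33)
  expect_equal(unname(e[2]), 90, tolerance = 1e-6)
})

test_that("a rigid straight translating fish yields zero joint angles", {
  tr <- straight_track()
  anim <- track_to_animation(tr)
  expect_equal(max(abs(anim$angles[, 2:5, ])), 0)
  expect_equal(anim$root_pos, matrix(tr$coords[, 1, ], 10, 3))
  expect_equal(unname(anim$skeleton$offsets), rep(6, 5))
})

test_that("forward kinematics inverts track_to_animation on swimmer tracks", {
  for (seed in c(23, 24)) {
    tr <- quick_track(duration = 2, seed = seed)
    anim <- track_to_animation(tr)
    rec <- forward_kinematics(anim)
    expect_lt(max(abs(rec$coords - tr$coords)), 1e-6)
    expect_equal(anim$frame_time, 1 / 60)
    # vertical-axis lock: roll channels identically zero
    expect_equal(max(abs(anim$angles[, , 3])), 0)
  }
})

test_that("forward kinematics of simple channel settings", {
  sk <- skeleton_def(rep(5, 5))
  n <- 3
  zero <- array(0, c(n, 5, 3))
  anim <- skeletal_animation(sk, matrix(0, n, 3), zero, 1 / 60)
  fk <- forward_kinematics(anim)
  expect_equal(unname(fk$coords[1, , 1]), seq(0, 25, by = 5))
  expect_equal(max(abs(fk$coords[, , 2:3])), 0)

  # 90 degree yaw at the first interior joint turns downstream points in plane
  ang <- zero; ang[, 2, 1] <- 90
  anim2 <- skeletal_animation(sk, matrix(0, n, 3), ang, 1 / 60)
  fk2 <- forward_kinematics(anim2)
  expect_equal(unname(fk2$coords[1, 2, ]), c(5, 0, 0))
  expect_equal(unname(fk2$coords[1, 3, ]), c(5, 5, 0))
  expect_equal(unname(fk2$coords[1, 6, ]), c(5, 20, 0))
  expect_equal(max(abs(fk2$coords[, , 3])), 0)
})

test_that("bvh write/read round trips at print precision", {
  tr <- quick_track(duration = 1, seed = 25)
  anim <- track_to_animation(tr)
  f <- withr::local_tempfile(fileext = ".bvh")
  write_bvh(anim, f)
  back <- read_bvh(f)
  expect_lt(max(abs(back$angles - anim$angles)), 1e-5)
  expect_lt(max(abs(back$root_pos - anim$root_pos)), 1e-5)
  expect_equal(back$frames, anim$frames)
  expect_equal(back$skeleton$offsets, anim$skeleton$offsets,
               tolerance = 1e-5)
  expect_equal(back$skeleton$joint_names, anim$skeleton$joint_names)

  lines <- readLines(f)
  expect_equal(sum(lines == "HIERARCHY"), 1)
  expect_equal(sum(lines == "MOTION"), 1)
  expect_true(any(grepl("^Frame Time: 0.0166667$", lines)))
})

test_that("degenerate animations and malformed files are rejected", {
  tr <- quick_track(duration = 0.5, seed = 26)
  anim <- track_to_animation(tr)
  empty <- anim
  empty$frames <- 0
  f <- withr::local_tempfile(fileext = ".bvh")
  expect_error(write_bvh(empty, f), "zero frames")

  write_bvh(anim, f)
  txt <- readLines(f)
  txt[grep("^MOTION$", txt)] <- "NOTION"
  writeLines(txt, f)
  expect_error(read_bvh(f), "line [0-9]+")

  write_bvh(anim, f)
  txt <- readLines(f)
  txt[length(txt)] <- paste(txt[length(txt)], "0.5")  # extra channel value
  writeLines(txt, f)
  expect_error(read_bvh(f), "channel values")
})
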