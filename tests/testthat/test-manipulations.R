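demo_anim <- function(duration = 1, seed = 31) {
  track_to_animation(quick_track(duration = duration, seed = seed))
}

test_that("removing locomotion freezes root position and heading only", {
  anim <- demo_anim()
  out <- remove_locomotion(anim)
  for (k in 1:3) expect_equal(var(out$root_pos[, k]), 0)
  expect_equal(var(out$angles[, 1, 1]), 0)              # yaw frozen
  expect_identical(out$angles[, 2:5, ], anim$angles[, 2:5, ])  # joints intact
  expect_identical(out$angles[, 1, 2], anim$angles[, 1, 2])    # pitch intact
  expect_identical(remove_locomotion(out), out)         # idempotent

  # body articulation survives: bend between first and last segment unchanged
  bend <- function(a) {
    fk <- forward_kinematics(a)$coords
    v1 <- fk[, 2, ] - fk[, 1, ]
    v5 <- fk[, 6, ] - fk[, 5, ]
    rowSums(v1 * v5) / sqrt(rowSums(v1^2) * rowSums(v5^2))
  }
  expect_equal(bend(out), bend(anim), tolerance = 1e-9)
  # and the head stays put in the horizontal plane
  fk_out <- forward_kinematics(out)$coords
  expect_equal(var(fk_out[, 1, 1]), 0)
  expect_equal(var(fk_out[, 1, 2]), 0)
})

test_that("removing body motion zeroes joints but keeps the trajectory", {
  anim <- demo_anim(seed = 32)
  out <- remove_body_motion(anim)
  expect_equal(max(abs(out$angles[, 2:5, ])), 0)
  expect_identical(out$root_pos, anim$root_pos)         # bit-identical root
  expect_identical(out$angles[, 1, ], anim$angles[, 1, ])
  expect_identical(remove_body_motion(out), out)        # idempotent
  # FK head path is exactly the input head path
  expect_equal(forward_kinematics(out)$coords[, 1, ],
               forward_kinematics(anim)$coords[, 1, ], tolerance = 1e-12)
})

test_that("motion removals commute and compose towards the static pose", {
  anim <- demo_anim(seed = 33)
  ab <- remove_body_motion(remove_locomotion(anim))
  ba <- remove_locomotion(remove_body_motion(anim))
  expect_identical(ab$angles, ba$angles)
  expect_identical(ab$root_pos, ba$root_pos)

  st <- make_static(anim)
  # composition equals the static stimulus except for per-frame root pitch,
  # which is body posture and is deliberately retained
  expect_equal(ab$root_pos, st$root_pos)
  expect_equal(ab$angles[, 1, 1], st$angles[, 1, 1])
  expect_equal(ab$angles[, 2:5, ], st$angles[, 2:5, ] * 0)
})

test_that("pressed shape scales width x3 and height x1/3, keeping volume", {
  geo <- fish_geometry(30)
  out <- press_shape(geo)
  expect_equal(out[, 2], geo[, 2] * 3)
  expect_equal(out[, 3], geo[, 3] / 3)
  expect_equal(out[, 1], geo[, 1])
  bbox_vol <- function(m) prod(apply(m, 2, function(x) diff(range(x))))
  expect_equal(bbox_vol(out), bbox_vol(geo), tolerance = 1e-12)
  expect_equal(press_shape(geo, 1, 1, 1), geo)
  expect_error(press_shape(geo, width_factor = 0), "positive")
})

test_that("greyscale conversion matches the per-pixel weighted sum", {
  img <- make_rgb_fixture(6, 4, seed = 35)
  out <- to_greyscale(img)
  w <- c(0.2126, 0.7152, 0.0722)
  for (i in seq_len(nrow(img))) for (j in seq_len(ncol(img))) {
    g <- round(sum(img[i, j, ] * w))
    expect_equal(out[i, j, 1], as.integer(g))
  }
  expect_identical(out[, , 1], out[, , 2])
  expect_identical(out[, , 1], out[, , 3])
  expect_identical(to_greyscale(out), out)  # idempotent / fixed point
  white <- array(255L, c(2, 2, 3))
  expect_identical(to_greyscale(white), white)
  expect_error(to_greyscale(array(0, c(2, 2, 2))), "3 channels")
})

test_that("static stimuli hold frame one", {
  anim <- demo_anim(seed = 36)
  st <- make_static(anim)
  expect_equal(st$frames, anim$frames)
  for (i in c(1, 7, anim$frames)) {
    expect_equal(st$angles[i, , ], anim$angles[1, , ])
    expect_equal(st$root_pos[i, ], anim$root_pos[1, ])
  }
  expect_equal(make_static(st)$angles, st$angles)  # static of static
  fk <- forward_kinematics(st)$coords
  for (i in seq_len(dim(fk)[1])) expect_equal(fk[i, , ], fk[1, , ])
})

test_that("loop concatenation repeats the motion block", {
  anim <- demo_anim(seed = 37)
  n <- anim$frames
  looped <- loop_concatenate(anim, repeats = 5)
  expect_equal(looped$frames, 5 * n)
  expect_equal(looped$frame_time, anim$frame_time)
  expect_equal(loop_concatenate(anim, 1)$angles, anim$angles)
  # join discontinuity equals the input's last-to-first wrap difference
  jump_join <- looped$angles[n + 1, , ] - looped$angles[n, , ]
  jump_wrap <- anim$angles[1, , ] - anim$angles[n, , ]
  expect_equal(jump_join, jump_wrap, tolerance = 1e-12)
})

test_that("factorial specs compose the operators consistently", {
  anim <- demo_anim(seed = 38)
  geo <- fish_geometry(30)
  tex <- make_rgb_fixture(8, 4, seed = 39)

  natural <- apply_spec(anim, geo, tex, stimulus_spec(), repeats = 5)
  expect_equal(natural$animation$angles, loop_concatenate(anim, 5)$angles)
  expect_identical(natural$geometry, geo)
  expect_identical(natural$texture, tex)

  full <- apply_spec(anim, geo, tex,
                     stimulus_spec(colour = "grey", shape = "pressed",
                                   locomotion = FALSE, body_motion = FALSE,
                                   static = TRUE), repeats = 5)
  expect_equal(full$animation$frames, 5 * anim$frames)
  expect_equal(var(full$animation$root_pos[, 1]), 0)
  expect_equal(max(abs(apply(full$animation$angles, c(2, 3), var))), 0)
  expect_identical(full$geometry, press_shape(geo))
  expect_identical(full$texture, to_greyscale(tex))

  # colour and shape operators act on disjoint slots: order cannot matter
  a <- to_greyscale(tex); g <- press_shape(geo)
  expect_identical(list(g, a), list(press_shape(geo), to_greyscale(tex)))

  blank <- apply_spec(anim, geo, tex, NULL)
  expect_null(blank$animation)

  expect_error(stimulus_spec(static = TRUE, locomotion = TRUE),
               "inconsistent")
})
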