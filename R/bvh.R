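#' Skeleton definition for the midline chain
#'
#' A 6-point midline is represented as a chain of 5 bone segments: a root
#' joint at the head carrying translation plus rotation, four interior joints
#' carrying rotation only, and an end site at the tail tip. Each segment's
#' offset lies along the local forward (+x) axis.
#'
#' @param offsets Numeric vector of segment lengths in mm (one per segment,
#'   all > 0).
#' @param joint_names Names for root and interior joints (length
#'   `length(offsets)`); defaults to `head, j1, j2, ...`.
#' @return An object of class `skeleton_def`.
#' @export
skeleton_def <- function(offsets,
                         joint_names = c("head", paste0("j", seq_len(length(offsets) - 1)))) {
  stopifnot(length(offsets) >= 1, all(offsets > 0),
            length(joint_names) == length(offsets))
  structure(list(offsets = as.numeric(offsets), joint_names = joint_names),
            class = "skeleton_def")
}

#' Skeletal animation container
#'
#' Holds a [skeleton_def()] plus per-frame root translation (mm) and Euler
#' angles (degrees) for the root and each interior joint.
#'
#' Angle convention: each joint triple is `(yaw, pitch, roll)` where yaw is
#' the rotation about the global/parent vertical (z) axis, pitch is the
#' elevation of the bone above the horizontal, and roll (rotation about the
#' bone axis) is locked to zero by the vertical-axis constraint. The rotation
#' matrix is `Rz(yaw) %*% Ry(-pitch) %*% Rx(roll)`, matching the BVH channel
#' order `Zrotation Yrotation Xrotation` (the file's Yrotation value is
#' `-pitch`).
#'
#' @param skeleton A [skeleton_def()].
#' @param root_pos Numeric matrix `frames x 3`, root translation in mm.
#' @param angles Numeric array `frames x joints x 3` (yaw, pitch, roll in
#'   degrees), `joints == length(skeleton$offsets)`.
#' @param frame_time Seconds per frame (> 0).
#' @return An object of class `skeletal_animation`.
#' @export
skeletal_animation <- function(skeleton, root_pos, angles, frame_time) {
  stopifnot(inherits(skeleton, "skeleton_def"), frame_time > 0,
            is.matrix(root_pos), ncol(root_pos) == 3,
            length(dim(angles)) == 3, dim(angles)[3] == 3,
            dim(angles)[1] == nrow(root_pos),
            dim(angles)[2] == length(skeleton$offsets),
            nrow(root_pos) >= 1)
  if (!all(is.finite(angles)) || !all(is.finite(root_pos)))
    stop("non-finite values in animation channels")
  if (any(abs(angles[, , 2]) > 90))
    stop("pitch outside (-90, 90) degrees (gimbal guard)")
  dimnames(angles) <- list(NULL, skeleton$joint_names,
                           c("yaw", "pitch", "roll"))
  structure(list(skeleton = skeleton, root_pos = root_pos, angles = angles,
                 frame_time = frame_time, frames = nrow(root_pos)),
            class = "skeletal_animation")
}

#' @export
print.skeletal_animation <- function(x, ...) {
  cat(sprintf(
    "skeletal_animation: %d frames, %d segments, frame_time %.7f s (%.1f s)\n",
    x$frames, length(x$skeleton$offsets), x$frame_time,
    x$frames * x$frame_time))
  invisible(x)
}

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

rot_z <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3, 3)
}
rot_y <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, 0, -sa, 0, 1, 0, sa, 0, ca), 3, 3)
}
rot_x <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(1, 0, 0, 0, ca, sa, 0, -sa, ca), 3, 3)
}

#' Rotation matrix of a (yaw, pitch, roll) Euler triple
#'
#' `Rz(yaw) %*% Ry(-pitch) %*% Rx(roll)`, angles in degrees. Applying it to
#' the reference forward axis (1, 0, 0) yields the unit vector with the given
#' heading (yaw) and elevation (pitch).
#'
#' @param yaw,pitch,roll Angles in degrees.
#' @return A 3x3 rotation matrix.
#' @export
euler_to_matrix <- function(yaw, pitch, roll = 0) {
  rot_z(deg2rad(yaw)) %*% rot_y(-deg2rad(pitch)) %*% rot_x(deg2rad(roll))
}

#' Per-frame unit segment vectors of a midline track
#'
#' Vector `i` in each frame is `normalize(point[i+1] - point[i])`.
#'
#' @param track A [midline_track()].
#' @return Numeric array `frames x (points-1) x 3` of unit vectors.
#' @export
segment_vectors <- function(track) {
  cc <- track$coords
  d <- dim(cc)
  nseg <- d[2] - 1
  diffs <- cc[, -1, , drop = FALSE] - cc[, -d[2], , drop = FALSE]
  norms <- sqrt(diffs[, , 1]^2 + diffs[, , 2]^2 + diffs[, , 3]^2)
  norms <- array(norms, c(d[1], nseg))
  bad <- which(norms < 1e-9, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("coincident consecutive points at frame %d, segment %d",
                 bad[1, 1], bad[1, 2]))
  for (k in 1:3) diffs[, , k] <- diffs[, , k] / norms
  diffs
}

#' Euler angles of a unit direction vector
#'
#' Returns the no-roll Euler triple `(yaw, pitch, roll = 0)` in degrees whose
#' rotation ([euler_to_matrix()]) carries the reference forward axis
#' (1, 0, 0) onto `v`: yaw is the heading of the horizontal projection, pitch
#' the elevation from the horizontal. For a vector within `1e-6` of vertical
#' the yaw is undefined; `prev_yaw` (default 0) is carried forward, the
#' documented convention for continuity across frames.
#'
#' @param v Unit 3-vector.
#' @param prev_yaw Yaw (degrees) to carry when `v` is numerically vertical.
#' @return Numeric `c(yaw, pitch, roll)` in degrees.
#' @export
vector_to_euler <- function(v, prev_yaw = 0) {
  stopifnot(length(v) == 3)
  h <- sqrt(v[1]^2 + v[2]^2)
  if (h < 1e-6) {
    yaw <- prev_yaw
  } else {
    yaw <- rad2deg(atan2(v[2], v[1]))
  }
  pitch <- rad2deg(atan2(v[3], h))
  c(yaw = yaw, pitch = pitch, roll = 0)
}

#' Convert a midline track to a skeletal animation
#'
#' Root translation is the head-point path; the root rotation is the Euler
#' triple of the first segment; each interior joint carries the rotation of
#' its segment expressed in the parent segment's frame. Joint-local rotations
#' are constructed as the no-roll (yaw, pitch) rotation taking the local
#' forward axis onto the parent-frame image of the child segment direction,
#' so every roll channel is identically zero while forward kinematics
#' reproduces the global segment directions exactly. Segment offsets are the
#' per-segment median chord lengths (robust to tracking jitter), so the
#' forward-kinematics reconstruction is exact on equal-spacing tracks and
#' accurate to the chord-length spread otherwise.
#'
#' Tracks should be smoothed ([smooth_moving_average()]) before conversion if
#' they carry tracking noise.
#'
#' @param track A [midline_track()].
#' @return A [skeletal_animation()] with `frames` equal to the track's and
#'   `frame_time = 1/fps`.
#' @seealso [forward_kinematics()] for the inverse reconstruction.
#' @export
track_to_animation <- function(track) {
  vecs <- segment_vectors(track)
  d <- dim(vecs)
  n <- d[1]; nseg <- d[2]
  cc <- track$coords
  chord <- sqrt((cc[, -1, 1] - cc[, -(nseg + 1), 1])^2 +
                (cc[, -1, 2] - cc[, -(nseg + 1), 2])^2 +
                (cc[, -1, 3] - cc[, -(nseg + 1), 3])^2)
  chord <- matrix(chord, n, nseg)
  offsets <- apply(chord, 2, median)

  angles <- array(0, c(n, nseg, 3))
  prev_yaw <- numeric(nseg)
  for (i in seq_len(n)) {
    R_parent <- diag(3)
    for (j in seq_len(nseg)) {
      w <- if (j == 1) vecs[i, 1, ] else drop(crossprod(R_parent, vecs[i, j, ]))
      e <- vector_to_euler(w, prev_yaw = prev_yaw[j])
      prev_yaw[j] <- e[1]
      angles[i, j, ] <- e
      R_parent <- R_parent %*% euler_to_matrix(e[1], e[2], 0)
    }
  }
  skeletal_animation(skeleton_def(offsets),
                     root_pos = matrix(cc[, 1, ], n, 3),
                     angles = angles,
                     frame_time = 1 / track$fps)
}

#' Forward kinematics: reconstruct midline points from an animation
#'
#' Composes the root translation and the chained joint rotations over the
#' segment offsets to recover the global position of every midline point in
#' every frame. This is the verification oracle for [track_to_animation()].
#'
#' @param anim A [skeletal_animation()].
#' @return A [midline_track()] with `length(offsets) + 1` points per frame.
#' @export
forward_kinematics <- function(anim) {
  nseg <- length(anim$skeleton$offsets)
  n <- anim$frames
  coords <- array(NA_real_, c(n, nseg + 1, 3))
  for (i in seq_len(n)) {
    pos <- anim$root_pos[i, ]
    coords[i, 1, ] <- pos
    R <- diag(3)
    for (j in seq_len(nseg)) {
      R <- R %*% euler_to_matrix(anim$angles[i, j, 1], anim$angles[i, j, 2],
                                 anim$angles[i, j, 3])
      pos <- pos + R %*% c(anim$skeleton$offsets[j], 0, 0)
      coords[i, j + 1, ] <- pos
    }
  }
  midline_track(coords, 1 / anim$frame_time)
}

#' Write a skeletal animation as a standard BVH file
#'
#' Emits the usual two-section BVH text: `HIERARCHY` with nested
#' `ROOT`/`JOINT`/`End Site` blocks (offsets along +x), and `MOTION` with
#' `Frames:` and `Frame Time:` followed by one line of channel values per
#' frame. The root has 6 channels (`Xposition Yposition Zposition Zrotation
#' Yrotation Xrotation`), interior joints 3 rotation channels. Angles are
#' written in degrees; the Yrotation channel holds `-pitch` (see
#' [skeletal_animation()]). Values are printed with 6 decimals, so a
#' write/read round trip reproduces channels to about 1e-6.
#'
#' @param anim A [skeletal_animation()] with at least one frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bvh <- function(anim, path) {
  stopifnot(inherits(anim, "skeletal_animation"))
  if (anim$frames < 1) stop("cannot write an animation with zero frames")
  sk <- anim$skeleton
  nseg <- length(sk$offsets)
  ind <- function(k) strrep("  ", k)
  lines <- c("HIERARCHY", sprintf("ROOT %s", sk$joint_names[1]), "{",
             paste0(ind(1), "OFFSET 0.000000 0.000000 0.000000"),
             paste0(ind(1),
                    "CHANNELS 6 Xposition Yposition Zposition Zrotation Yrotation Xrotation"))
  for (j in 2:nseg) {
    k <- j - 1
    lines <- c(lines,
               paste0(ind(k), "JOINT ", sk$joint_names[j]),
               paste0(ind(k), "{"),
               sprintf("%sOFFSET %.6f 0.000000 0.000000", ind(k + 1),
                       sk$offsets[j - 1]),
               paste0(ind(k + 1), "CHANNELS 3 Zrotation Yrotation Xrotation"))
  }
  lines <- c(lines,
             paste0(ind(nseg - 1), "End Site"),
             paste0(ind(nseg - 1), "{"),
             sprintf("%sOFFSET %.6f 0.000000 0.000000", ind(nseg),
                     sk$offsets[nseg]),
             paste0(ind(nseg - 1), "}"))
  for (k in rev(seq_len(nseg) - 1)) lines <- c(lines, paste0(ind(k), "}"))

  # channel matrix: root pos, root (z, y, x) rotations, then joints 2..nseg
  chan <- matrix(NA_real_, anim$frames, 3 + 3 * nseg)
  chan[, 1:3] <- anim$root_pos
  for (j in seq_len(nseg)) {
    base <- 3 + 3 * (j - 1)
    chan[, base + 1] <- anim$angles[, j, 1]    # Zrotation = yaw
    chan[, base + 2] <- -anim$angles[, j, 2]   # Yrotation = -pitch
    chan[, base + 3] <- anim$angles[, j, 3]    # Xrotation = roll
  }
  motion <- apply(chan, 1, function(r) paste(sprintf("%.6f", r), collapse = " "))
  lines <- c(lines, "MOTION",
             sprintf("Frames: %d", anim$frames),
             sprintf("Frame Time: %.7f", anim$frame_time),
             motion)
  writeLines(lines, path)
  invisible(path)
}

#' Read a BVH file written by [write_bvh()]
#'
#' Parses the single-chain hierarchy and motion section back into a
#' [skeletal_animation()]. Malformed files raise an error naming the
#' offending line.
#'
#' @param path BVH file path.
#' @return A [skeletal_animation()].
#' @export
read_bvh <- function(path) {
  lines <- readLines(path)
  strip <- trimws(lines)
  fail <- function(i, msg) stop(sprintf("BVH parse error at line %d: %s", i, msg))
  i <- 1
  expect <- function(pattern, msg) {
    while (i <= length(strip) && strip[i] == "") i <<- i + 1
    if (i > length(strip) || !grepl(pattern, strip[i])) fail(i, msg)
    res <- strip[i]; i <<- i + 1
    res
  }
  expect("^HIERARCHY$", "expected HIERARCHY")
  root_line <- expect("^ROOT\\s+\\S+", "expected ROOT <name>")
  joint_names <- sub("^ROOT\\s+", "", root_line)
  expect("^\\{$", "expected {")
  expect("^OFFSET\\s", "expected root OFFSET")
  expect("^CHANNELS 6 Xposition Yposition Zposition Zrotation Yrotation Xrotation$",
         "unsupported root CHANNELS layout")
  offsets <- numeric(0)
  depth <- 1
  repeat {
    while (i <= length(strip) && strip[i] == "") i <- i + 1
    if (i > length(strip)) fail(i, "unexpected end of file in HIERARCHY")
    ln <- strip[i]
    if (grepl("^JOINT\\s+\\S+", ln)) {
      joint_names <- c(joint_names, sub("^JOINT\\s+", "", ln)); i <- i + 1
      expect("^\\{$", "expected {"); depth <- depth + 1
      off <- expect("^OFFSET\\s", "expected OFFSET")
      vals <- as.numeric(strsplit(sub("^OFFSET\\s+", "", off), "\\s+")[[1]])
      if (length(vals) != 3 || any(!is.finite(vals))) fail(i - 1, "bad OFFSET")
      offsets <- c(offsets, vals[1])
      expect("^CHANNELS 3 Zrotation Yrotation Xrotation$",
             "unsupported joint CHANNELS layout")
    } else if (grepl("^End Site$", ln)) {
      i <- i + 1
      expect("^\\{$", "expected {")
      off <- expect("^OFFSET\\s", "expected End Site OFFSET")
      vals <- as.numeric(strsplit(sub("^OFFSET\\s+", "", off), "\\s+")[[1]])
      if (length(vals) != 3 || any(!is.finite(vals))) fail(i - 1, "bad OFFSET")
      offsets <- c(offsets, vals[1])
      expect("^\\}$", "expected } after End Site")
    } else if (ln == "}") {
      i <- i + 1; depth <- depth - 1
      if (depth == 0) break
    } else fail(i, paste("unexpected token:", ln))
  }
  nseg <- length(offsets)
  if (nseg < 1) fail(i, "hierarchy contains no segments")
  if (length(joint_names) != nseg)
    fail(i, "joint/offset count mismatch (single chain expected)")

  expect("^MOTION$", "expected MOTION")
  fr_line <- expect("^Frames:\\s*\\d+$", "expected Frames: <n>")
  n <- as.integer(sub("^Frames:\\s*", "", fr_line))
  ft_line <- expect("^Frame Time:\\s*[0-9.eE+-]+$", "expected Frame Time:")
  frame_time <- as.numeric(sub("^Frame Time:\\s*", "", ft_line))
  if (n < 1) fail(i - 2, "zero frames")
  nchan <- 3 + 3 * nseg
  chan <- matrix(NA_real_, n, nchan)
  for (f in seq_len(n)) {
    while (i <= length(strip) && strip[i] == "") i <- i + 1
    if (i > length(strip)) fail(i, "missing motion frames")
    vals <- as.numeric(strsplit(strip[i], "\\s+")[[1]])
    if (length(vals) != nchan || any(!is.finite(vals)))
      fail(i, sprintf("expected %d channel values", nchan))
    chan[f, ] <- vals
    i <- i + 1
  }
  angles <- array(0, c(n, nseg, 3))
  for (j in seq_len(nseg)) {
    base <- 3 + 3 * (j - 1)
    angles[, j, 1] <- chan[, base + 1]
    angles[, j, 2] <- -chan[, base + 2]
    angles[, j, 3] <- chan[, base + 3]
  }
  skeletal_animation(skeleton_def(offsets, joint_names),
                     root_pos = chan[, 1:3, drop = FALSE],
                     angles = angles, frame_time = frame_time)
}
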