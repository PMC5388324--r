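#' Factorial stimulus specification
#'
#' Encodes one row of the factorial stimulus design: which of the four
#' naturalistic features (colour, shape, locomotion, body motion) are kept
#' natural and whether the stimulus is a static first-frame image. A static
#' stimulus implies both motion cues are off. The blank (no-stimulus) control
#' is represented by `NULL`, the absence of any spec.
#'
#' @param colour `"natural"` or `"grey"`.
#' @param shape `"normal"` or `"pressed"`.
#' @param locomotion `TRUE` (natural trajectory) or `FALSE` (stopped).
#' @param body_motion `TRUE` (natural body-axis articulation) or `FALSE`
#'   (rigid straight body).
#' @param static `TRUE` for a first-frame still.
#' @return An object of class `stimulus_spec`.
#' @export
stimulus_spec <- function(colour = c("natural", "grey"),
                          shape = c("normal", "pressed"),
                          locomotion = TRUE,
                          body_motion = TRUE,
                          static = FALSE) {
  colour <- match.arg(colour)
  shape <- match.arg(shape)
  stopifnot(is.logical(locomotion), is.logical(body_motion),
            is.logical(static))
  if (static && (locomotion || body_motion))
    stop("inconsistent spec: a static stimulus cannot carry locomotion or body motion")
  structure(list(colour = colour, shape = shape, locomotion = locomotion,
                 body_motion = body_motion, static = static),
            class = "stimulus_spec")
}

#' @export
print.stimulus_spec <- function(x, ...) {
  cat(sprintf("stimulus_spec: colour=%s shape=%s locomotion=%s body_motion=%s static=%s\n",
              x$colour, x$shape, x$locomotion, x$body_motion, x$static))
  invisible(x)
}

#' Freeze locomotion while keeping body-axis motion
#'
#' Stops the virtual fish's locomotion: the root translation and root yaw
#' (heading) are frozen at their first-frame values, so the fish neither
#' translates nor drifts in heading, while every interior joint channel — the
#' body-axis/tail articulation — is left untouched. Root pitch keeps its
#' per-frame values (treated as body posture, not locomotion).
#'
#' @param anim A [skeletal_animation()].
#' @param freeze_yaw If `FALSE`, only the translation is frozen and heading
#'   may still drift; the default `TRUE` freezes both.
#' @return A [skeletal_animation()].
#' @export
remove_locomotion <- function(anim, freeze_yaw = TRUE) {
  stopifnot(inherits(anim, "skeletal_animation"))
  out <- anim
  out$root_pos[, 1] <- anim$root_pos[1, 1]
  out$root_pos[, 2] <- anim$root_pos[1, 2]
  out$root_pos[, 3] <- anim$root_pos[1, 3]
  if (freeze_yaw) out$angles[, 1, 1] <- anim$angles[1, 1, 1]
  out
}

#' Remove body-axis motion while keeping the trajectory
#'
#' Sets every interior joint rotation channel to zero, straightening the body
#' into a rigid rod, while the root translation and root rotation are left
#' bit-identical — the moving trajectory stays intact.
#'
#' @param anim A [skeletal_animation()].
#' @return A [skeletal_animation()].
#' @export
remove_body_motion <- function(anim) {
  stopifnot(inherits(anim, "skeletal_animation"))
  out <- anim
  nj <- dim(anim$angles)[2]
  if (nj > 1) out$angles[, 2:nj, ] <- 0
  out
}

#' Anisotropic body-shape scaling ("pressed" model)
#'
#' Scales geometry in body-local axes (x = length, y = width, z = height).
#' The default triples the width and reduces the height to one third, so the
#' bounding-box volume is unchanged (3 x 1/3 x 1 = 1).
#'
#' @param geometry Numeric matrix `n x 3` of body-local points (mm), or any
#'   object coercible with `as.matrix()`.
#' @param length_factor,width_factor,height_factor Positive scale factors.
#' @return The scaled geometry matrix.
#' @export
press_shape <- function(geometry, width_factor = 3, height_factor = 1 / 3,
                        length_factor = 1) {
  if (width_factor <= 0 || height_factor <= 0 || length_factor <= 0)
    stop("scale factors must be positive")
  g <- as.matrix(geometry)
  stopifnot(ncol(g) == 3)
  g[, 1] <- g[, 1] * length_factor
  g[, 2] <- g[, 2] * width_factor
  g[, 3] <- g[, 3] * height_factor
  g
}

#' Convert an RGB image to greyscale
#'
#' Replaces each pixel by its luminance, computed with the declared channel
#' weights (defaults: Rec. 709 coefficients 0.2126, 0.7152, 0.0722), written
#' into all three channels so the output is still an RGB array. Integer 8-bit
#' inputs give integer 8-bit outputs; the operation is idempotent.
#'
#' @param image Numeric or integer array `height x width x 3`.
#' @param weights Length-3 non-negative channel weights summing to 1.
#' @return Greyscale RGB array of the same type and dimensions.
#' @export
to_greyscale <- function(image, weights = c(0.2126, 0.7152, 0.0722)) {
  if (length(dim(image)) != 3 || dim(image)[3] != 3)
    stop("expected an RGB array with 3 channels")
  stopifnot(length(weights) == 3, all(weights >= 0),
            abs(sum(weights) - 1) < 1e-8)
  grey <- image[, , 1] * weights[1] + image[, , 2] * weights[2] +
    image[, , 3] * weights[3]
  if (is.integer(image)) grey <- as.integer(round(grey))
  out <- image
  for (k in 1:3) out[, , k] <- grey
  out
}

#' Hold the first frame as a static stimulus
#'
#' Returns an animation whose every frame equals frame 1 of the input
#' (repeated to `n_frames`, by default the input length, so the stimulus
#' duration is preserved).
#'
#' @param anim A [skeletal_animation()] with at least one frame.
#' @param n_frames Number of frames in the output.
#' @return A [skeletal_animation()].
#' @export
make_static <- function(anim, n_frames = anim$frames) {
  stopifnot(inherits(anim, "skeletal_animation"), anim$frames >= 1,
            n_frames >= 1)
  nj <- dim(anim$angles)[2]
  root <- matrix(anim$root_pos[1, ], n_frames, 3, byrow = TRUE)
  ang <- anim$angles[rep(1L, n_frames), , , drop = FALSE]
  dim(ang) <- c(n_frames, nj, 3)
  skeletal_animation(anim$skeleton, root, ang, anim$frame_time)
}

#' Concatenate an animation with itself
#'
#' Repeats the motion block `repeats` times (the standard way a one-minute
#' clip is extended to a five-minute presentation). Frame time is unchanged;
#' the output has `repeats * frames` frames.
#'
#' @param anim A [skeletal_animation()].
#' @param repeats Number of copies (>= 1, default 5).
#' @return A [skeletal_animation()].
#' @export
loop_concatenate <- function(anim, repeats = 5) {
  stopifnot(inherits(anim, "skeletal_animation"), repeats >= 1)
  repeats <- as.integer(repeats)
  idx <- rep(seq_len(anim$frames), times = repeats)
  nj <- dim(anim$angles)[2]
  ang <- anim$angles[idx, , , drop = FALSE]
  dim(ang) <- c(length(idx), nj, 3)
  skeletal_animation(anim$skeleton, anim$root_pos[idx, , drop = FALSE],
                     ang, anim$frame_time)
}

#' Apply a factorial stimulus specification
#'
#' Composes the individual manipulation operators according to the spec
#' flags, in the documented order shape -> colour -> motion edits ->
#' static/loop. The operators act on disjoint parts of the bundle (geometry,
#' texture, animation channels), so the order cannot change the result; tests
#' verify pairwise commutation.
#'
#' @param anim A [skeletal_animation()] (typically one 1-min block).
#' @param geometry Body-local point geometry (`n x 3` matrix), or `NULL`.
#' @param texture RGB array, or `NULL`.
#' @param spec A [stimulus_spec()], or `NULL` for the blank control.
#' @param repeats Loop count applied to moving stimuli (default 5).
#' @return A list (`stimulus_bundle`) with elements `animation`, `geometry`,
#'   `texture`, `spec`; for `spec = NULL` all stimulus slots are `NULL`.
#' @export
apply_spec <- function(anim, geometry = NULL, texture = NULL, spec,
                       repeats = 5) {
  if (is.null(spec)) {
    return(structure(list(animation = NULL, geometry = NULL, texture = NULL,
                          spec = NULL), class = "stimulus_bundle"))
  }
  stopifnot(inherits(spec, "stimulus_spec"))
  if (spec$shape == "pressed" && !is.null(geometry))
    geometry <- press_shape(geometry)
  if (spec$colour == "grey" && !is.null(texture))
    texture <- to_greyscale(texture)
  if (!spec$locomotion && !spec$static) anim <- remove_locomotion(anim)
  if (!spec$body_motion && !spec$static) anim <- remove_body_motion(anim)
  anim <- if (spec$static) {
    make_static(anim, n_frames = anim$frames * as.integer(repeats))
  } else {
    loop_concatenate(anim, repeats)
  }
  structure(list(animation = anim, geometry = geometry, texture = texture,
                 spec = spec), class = "stimulus_bundle")
}
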