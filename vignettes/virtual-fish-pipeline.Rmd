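---
title: "Virtual-fish stimuli and the social approach assay: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual-fish stimuli and the social approach assay: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fishstim)
```

`fishstim` implements a pipeline with two halves: construction of virtual-fish
motion stimuli from tracked swimming trajectories (tracking → skeletal
animation → factorial manipulation), and quantification of the social
approach behaviour those stimuli elicit (zone occupancy → exclusion →
difference scores → mixed-design ANOVA with post-hoc comparisons). This
vignette documents the underlying models, the conventions and numerical
choices, and the limits of what the synthetic generators can show.

## The skeletal model

A fish's trunk is tracked as `n = 6` points at equal spacing along the body
midline, head first, at 60 fps. The skeleton is the chain of the 5 segments
between adjacent points: a root joint at the head carrying 3 translation and
3 rotation channels, four interior joints with 3 rotation channels each, and
an end site at the tail tip. Segment offsets lie along each joint's local
forward (+x) axis and are set to the per-segment *median* chord length
across frames, which is robust to tracking jitter; on tracks whose chords
are constant (as the bundled generator produces) the forward-kinematics
reconstruction is then exact to floating-point precision.

### Angle conventions

Each unit segment direction $v$ is described by a no-roll Euler triple:
yaw $\psi = \operatorname{atan2}(v_y, v_x)$ (heading of the horizontal
projection), pitch $\theta = \operatorname{atan2}(v_z, \lVert v_{xy}\rVert)$
(elevation), and roll fixed at zero — the body's vertical axis is locked to
the global vertical, which is how a fish that does not bank is naturally
parameterised. The rotation matrix is $R = R_z(\psi)\,R_y(-\theta)$, and BVH
files declare the matching channel order `Zrotation Yrotation Xrotation`
(with the Yrotation value equal to $-\theta$; degrees in files, radians
internally).

Interior joints store *parent-relative* rotations, as BVH semantics
compose hierarchically. A subtlety: decomposing the full relative rotation
matrix between consecutive segment frames would generally require a nonzero
roll component. Instead, each joint's local rotation is constructed as the
no-roll $(\psi, \theta)$ rotation that carries the local forward axis onto
the parent-frame image of the child segment direction,
$w = R_\text{parent}^{\top} v_\text{child}$. Forward kinematics only
propagates bone forward-axes, so this reproduces every global segment
direction exactly while keeping all roll channels identically zero. The
invariant that matters — FK applied to the animation reconstructs the
tracked points — is what the tests assert, rather than raw channel values.

### Numerical choices

* Segments shorter than $10^{-9}$ mm (coincident tracked points) are an
  error naming the frame and segment; they indicate a broken track, not a
  recoverable state.
* A segment within $10^{-6}$ of vertical has undefined yaw; the previous
  frame's yaw for that joint is carried forward to avoid channel
  discontinuities. Pitch is kept in $(-90°, 90°)$ as a gimbal guard.
* BVH motion values are printed with 6 decimals, so a write/read round trip
  is reproducible to about $10^{-6}$ per channel (tests allow $10^{-5}$).
  `Frame Time` is printed with 7 decimals (`0.0166667` at 60 fps).
* Zero-frame animations are rejected on write; malformed files raise parse
  errors with line numbers.

## Stimulus manipulations

The factorial design manipulates four features; each is a pure operator on
a disjoint part of the stimulus bundle, so composition order cannot change
the result (the tests verify pairwise commutation):

| Operator | Acts on | Effect |
|---|---|---|
| `to_greyscale()` | texture | per-pixel luminance (Rec. 709 weights 0.2126/0.7152/0.0722, configurable) written to all channels |
| `press_shape()` | geometry | width ×3, height ×1/3, length ×1 — bounding-box volume unchanged |
| `remove_locomotion()` | root channels | translation and yaw frozen at frame 1; joints and root pitch untouched |
| `remove_body_motion()` | joint channels | all interior joints zeroed; root bit-identical |
| `make_static()` | all channels | frame 1 held for the whole duration |
| `loop_concatenate()` | frames | one-minute block repeated (default 5×) |

Two readings of "stopped locomotion" are possible: freezing translation
only, or freezing translation and heading. The package freezes both by
default (`freeze_yaw = TRUE`), because a fish whose heading drifts while
its position is pinned still conveys trajectory information; root pitch is
retained as body posture. The frozen pose is frame 1 — where the stationary
fish is held is otherwise arbitrary, and frame 1 makes static and
motion-removed stimuli start identically. The greyscale weighting is a
declared choice: the original conversion tool's mode is not specified
anywhere, so the standard luminance coefficients are used and exposed as an
argument.

## The synthetic swimmer

Real tracking data behind such experiments are rarely redistributable, so
the generator produces midline tracks with exactly the structure the
skeletonisation stage assumes:

* **Locomotion** — a heading-persistent random walk: the turn rate is an
  AR(1) process with correlation time `heading_persistence` (default 2 s,
  stationary sd 0.8 rad/s), integrated at `fps`; cruise speed is constant
  at `speed_mean`; near tank walls the heading steers back toward the
  centre and positions are clamped with a body-length margin, which
  guarantees every midline point stays inside the tank.
* **Body motion** — a travelling lateral undulation wave running head to
  tail, $A(s)\sin 2\pi(ft - s/\lambda)$, with tail-beat frequency `f`
  (default 3 Hz), wavelength 0.9 body lengths, and a non-decreasing
  amplitude envelope from 1% of body length at the head to 10% at the tail.
* **Vertical motion** — slow seeded sinusoidal drift (periods 15–25 s and
  5–10 s, amplitude 5 mm), so the vertical velocity stays small relative to
  the cruise speed, matching a fish that swims essentially level.

Defaults: body length 30 mm ("about 3 cm"), 6 points, 60 fps, 60 s. The
kinematic values (3 Hz, 0.9 BL, 30 mm/s — one body length per second) are
*assumptions* chosen to be realistic for a small cyprinodontiform swimmer;
no quantitative kinematics of the original recorded females are available,
and none of the package's conclusions depend on them.

Points are placed on the analytic midline by equal-**chord** re-sampling:
consecutive points at exactly $L/5$ Euclidean distance, found by walking a
fine (481-point) polyline discretisation and solving the final position on
each polyline segment in closed form. Chord spacing (rather than arc-length
spacing) is what a tracker clicking equally spaced trunk points records, it
makes the inter-point distance invariant exact by construction, and it is
the condition under which a rigid-offset skeleton can reproduce the track
exactly. A fish that neither translates (`speed_mean = 0`) nor undulates
(zero amplitude envelope) produces identical frames — no hidden motion
sources.

What the generator does *not* emulate: tracking noise and dropouts (add
noise explicitly and smooth, as the tests do), lens distortion, fin and
head-yaw articulation beyond the midline wave, burst-and-glide speed
profiles, or interactions between fish. Passing tests therefore show the
pipeline is correct on clean, complete midline tracks; they do not certify
robustness to pathological tracker output.

## The assay and its simulator

The response measure is the time a subject's head tip spends within
`zone_mm` (default 10 mm) of the display-side inner wall, at 30 fps, over a
1-min baseline and five 1-min stimulus bins (half-open intervals
$[m, m+1)$). Subjects with baseline occupancy strictly over 55 s are
excluded — "over" is read as a strict inequality, and the threshold is an
argument. Responses are difference scores: each stimulus minute's occupancy
minus the baseline occupancy, signed, in seconds, bounded in
$[-60, +60]$. Frames with missing positions are dropped from numerator and
denominator and the bin occupancy rescaled to the bin length, flagged via
an attribute.

The subject simulator is a two-state (near/far) Markov chain in discrete
frames: per-second entry and exit hazards, converted to per-frame
probabilities $1 - e^{-r/\mathrm{fps}}$, with hazards allowed to vary by
group and minute bin. Its stationary occupancy fraction is
$r_\text{entry}/(r_\text{entry} + r_\text{exit})$, which the tests check
against simulation, and which makes effect sizes interpretable: the demo's
planted pattern raises the Normal group's entry hazard from 0.02/s to
0.12/s at stimulus onset (stationary occupancy from ~10 to ~33 s/min)
against 0.05/s for other stimulus groups, and the power check in the
acceptance suite uses a large 0.20/s effect. The simulator emulates the
group × time *occupancy structure* the statistics assume — it does not
model spatial trajectories, habituation within bins, or inter-subject
heterogeneity beyond the Markov noise.

## Statistical procedures

**Split-plot ANOVA.** Groups are between-subjects, time (baseline + 5
minute bins, $k = 6$) within-subjects. Sums of squares are the weighted
cell-mean decomposition; the group effect is tested against subjects-
within-groups ($g-1$, $N-g$), time and group × time against
time × subjects-within-groups ($(N-g)(k-1)$ df). The decomposition is
exact for balanced designs (all cohorts here are balanced; the exclusion
filter can unbalance groups slightly, which the weighted decomposition
absorbs). Degenerate inputs with zero error variance report `NaN` F-ratios
with a warning rather than an error, since such fixtures are legitimate in
testing. The implementation is cross-checked against
`aov(y ~ group*time + Error(subject))` in the tests.

**Multisample sphericity.** The test statistic is the modified
(error-df) likelihood ratio for $H_0$: the covariance of orthonormally
contrasted scores is the same $\sigma^2 I$ in every group. It decomposes
exactly as Box's M statistic for equality of the $g$ contrast covariances
plus the pooled Mauchly sphericity statistic; each part is scaled by its
standard small-sample factor (Box 1949 for M; the Bartlett-type multiplier
$1 - (2p^2+p+2)/(6p\nu)$ for Mauchly, $p = k-1$, $\nu = N-g$) and the sum
referred to $\chi^2$ with $g\,p(p+1)/2 - 1$ df. Monte-Carlo calibration
under the null (2000 replicates, $g=3$, $n=20$, $k=4$) is part of the
acceptance suite. Groups need $n > k-1$ subjects or the within-group
covariance is singular and the test errors with advice.

**Epsilon and Huynh–Feldt correction.** $\hat\varepsilon_{GG} =
(\operatorname{tr} S)^2 / (p \operatorname{tr} S^2)$ from the pooled
contrast covariance $S$; the multisample Huynh–Feldt estimate uses
Lecoutre's corrected form
$\tilde\varepsilon = \frac{(N-g+1)p\,\hat\varepsilon_{GG} - 2}
{p\,(N-g-p\,\hat\varepsilon_{GG})}$, clipped to $[\hat\varepsilon_{GG}, 1]$.
The correction multiplies numerator and denominator df of within-subject
effects by $\varepsilon$ and recomputes p-values; it is applied when the
sphericity test rejects at $\alpha$, mirroring standard practice.

**Simple main effects** are computed with own-slice error terms: the group
effect at each time level is the one-way ANOVA on that time slice, and the
time effect within each group is the one-way repeated-measures ANOVA on
that group. Pooled-error variants exist and have more power when the
homogeneity assumptions hold; the own-slice choice is robust when variance
heterogeneity or sphericity violations differ across slices, which is
exactly the situation that triggered the correction upstream.

**Ryan's procedure.** Pairwise t-tests on the pooled error term over
rank-ordered means, stepwise: a pair spanning $m$ of the $k$ means is
tested at the adjusted level $\alpha'_m = 2\alpha/(k(m-1))$, and a pair
can only be significant if no enclosing span tested non-significant
(coherence). Wider spans get *smaller* nominal levels, which compensates
the selection effect of comparing extreme order statistics with an
ordinary t-test: the full-range level $2\alpha/(k(k-1))$ approximates the
studentized-range calibration, and the measured family-wise error under
the complete null ($k=6$) in the acceptance suite stays below $\alpha$.
At $k=2$ the procedure is a plain two-mean test at $\alpha$. "Ryan's
method" has several published variants (notably REGW with studentized-range
statistics); the stepwise-alpha t-test formulation is implemented, and the
formula is isolated in `ryan_alpha()` so an alternative can be swapped in
one place.

## Problem sizes

The test and acceptance workloads are sized for a single CPU: 60-s swimmer
tracks (3600 frames) for the kinematic round trips, 2000 null replicates at
$g=3$, $n=20$, $k=4$ for ANOVA/sphericity calibration, 3000 replicates at
$k=6$, $n=12$ for post-hoc family-wise error, and 20 end-to-end replicates
(72 subjects each, 6 groups) for the planted-effect power check. These
sizes give binomial Monte-Carlo bands of roughly ±0.013 around a 0.05 rate,
which the calibration assertions use explicitly.

## Known limitations

* The split-plot decomposition assumes complete data; subjects with missing
  cells must be dropped before analysis (the exclusion filter already
  yields complete tables).
* Severely unbalanced groups make the weighted SS decomposition order-
  dependent in principle; the assay designs here are balanced to within a
  few exclusions.
* The BVH reader accepts the single-chain hierarchy this package writes,
  not arbitrary multi-limb skeletons.
* The view-merging model assumes synchronized cameras and known mm-per-px
  scales, with no lens-distortion model; the shared-axis residual report is
  the diagnostic for violations.
* Mesh skinning, texturing and video encoding are out of scope; the
  package ends at BVH animations plus geometry/texture transforms.
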