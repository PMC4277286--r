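---
title: "Corrected bell kinematics from in situ video: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Corrected bell kinematics from in situ video: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bellkin)
```

## The measurement problem

Large gelatinous swimmers such as the lion's mane jellyfish *Cyanea
capillata* cannot be brought into a laboratory tank, so their swimming
kinematics must be read off hand-held underwater video. Such footage
violates the assumptions of standard 2-D kinematic analysis in two ways
that can be repaired in post-processing and one that cannot:

1. the camera approaches or recedes from the animal, so the image
   magnification changes over time;
2. the animal rolls about the optical axis, so the body frame rotates in
   the image; and
3. the animal may rotate about the in-plane axes — this loses profile
   information in projection and **cannot** be compensated from a single
   view; `bellkin` assumes footage where such rotation is negligible.

`bellkin` turns manually digitized exumbrella (upper bell surface)
outlines — the output of frame-by-frame edge clicking in an image
analysis tool, not produced here — into corrected, apex-rooted,
uniformly resampled half profiles in the animal's body frame, and then
into a compact, time-periodic model of the bell gait.

## Magnification correction

Two multiplicative scale factors are estimated per frame and applied
about the image center.

**Reference-point scale.** A fixed landmark on the sea floor (a rock) is
tracked. If the camera keeps the animal centered and moves only along
its optical axis, magnification moves the landmark away from the image
center in proportion to the zoom, so

$$ s_{\mathrm{ref}}(j) = \frac{|x_r(1) - x_c|}{|x_r(j) - x_c|}, $$

where $x_r(j)$ is the landmark x-position in frame $j$ and $x_c$ the
frame-center x. Multiplying frame-$j$ coordinates about the center by
$s_{\mathrm{ref}}(j)$ restores the first frame's scale. A landmark at
the frame center carries no scale information and is rejected
(`reference_scale()`).

**Arclength linear-fit scale.** The landmark only sees camera motion
relative to the sea floor; the animal also drifts relative to the
camera. The bell has no fixed-length feature, and the exumbrella
arclength itself pulses (it lengthens during contraction as the muscles
compress the subumbrella), so raw arclength cannot be used as a ruler.
But bell kinematics are cyclical: the arclength at the *fully
contracted* instant — the moment just before relaxation begins — should
be the same in every cycle. `arclength_lf_scale()` fits a least-squares
line $L(t)=\alpha+\beta t$ through the contracted-instant arclengths
and applies $s_{\mathrm{lf}}(j) = L_{\mathrm{fit}}(t_1) /
L_{\mathrm{fit}}(t_j)$, which flattens the contracted arclengths
exactly when the residual drift is linear in time. Least squares is
used for the fit; with only two or three contracted instants the line is
(near-)interpolating.

## Body frame

The apex (top of the bell on the axial axis) roots every half profile.
It is located by tracking a visible feature near the apex and shifting
the feature's projection along the outline by a constant arclength
offset measured once on the first frame (`locate_apex()`). The
near-apex region deforms very little during swimming, so a least-squares
line through the outline points within ±24% of each half arclength of
the apex gives the body roll $\theta = \arctan m$ (`body_angle()`);
`to_body_frame()` then translates the apex to the origin and rotates by
$-\theta$ (an exact isometry; the convention maps $(1,0)$ under
$\theta = 90^\circ$ to $(0,-1)$).

The ±24% window (`top_fraction = 0.24`) is a compromise: a wider window
admits actively deforming bell regions into the fit, a narrower one
amplifies digitization noise. Note that a least-squares regression line
is exactly rotation-equivariant only for collinear points; for the
gently curved apex region the residual non-equivariance is a few
thousandths of a degree, far below the digitization noise.

## Filtering and resampling

Digitized outlines carry click noise. Each half profile is converted to
polar coordinates about the apex and the radius, as a function of sample
index, is low-pass filtered with a second-order Butterworth filter at
20% of the (index-domain) Nyquist frequency. Polar filtering is used
because the bell is strongly curved — during deep relaxation the margin
rises above the apex, so neither coordinate is single-valued and
filtering x or y directly would distort the shape. Two deliberate
choices:

* The filter is applied forward *and* backward (zero phase). A single
  pass would delay the radius sequence along the arclength and shift
  every landmark fraction towards the margin.
* The filter is implemented with steady-state initial conditions and
  odd-reflection end padding. Plain state-zero filtering corrupts the
  first tens of samples of a short series, which is fatal for profiles
  of ~50–200 points. The apex sample itself (radius zero by
  construction) is pinned, as are both endpoints.

Each filtered half profile is then resampled to `resample_n = 51`
points: a cubic spline in each coordinate, parameterized by cumulative
chordal arclength, is evaluated at the arclength fractions $k/(n-1)$.
This presumes the bell deforms *uniformly along its arclength*, so that
a fixed fraction tracks a material point; it is the same assumption that
underlies comparing node locations across frames. Resampling an
already-uniform profile is a fixed point of this operation. The output
spacings are uniform in the chord-length parameter; in true arclength
they are uniform to $O(h^2)$, which for 51 points on a bell-like curve
means relative spacing deviations of order $10^{-4}$ — below the
digitization noise but not zero, which is why the package's tests
assert uniformity at that level and not at machine precision.

Finally all profiles are normalized by the relaxed half arclength of the
first cycle, taken as the mean of the left and right halves (the two
can differ slightly; the mean avoids preferring a side). The relaxed
instant is identified as the frame of maximum margin-to-margin chord
(maximum bell diameter) between the first two contracted instants —
deliberately *not* maximum arclength, which peaks at contraction
because of the exumbrella pulsation.

## Strategic discretization

The bell is approximated by a small number of straight segments joined
at nodes on the profile. Three node-placement routes are implemented.

**Curvature.** Discrete curvature at each interior sample is the
reciprocal circumradius of the circle through three consecutive points,
$|\kappa| = 4A/(fgh)$, signed by turn direction so peaks (convex) and
valleys (concave) are distinguishable. Averaging $\kappa$ pointwise
across frames and differentiating along arclength, the zero crossings
of $d\bar\kappa/ds$ mark where curvature varies most — candidate nodes
(`curvature_nodes()`). The pointwise across-frame variance (sample
variance, $n-1$ divisor) reports where deformation over *time*
concentrates. Curvature-flat profiles (numerically constant $\bar
\kappa$) yield no candidates rather than noise-driven ones.

**Anatomy.** The bell's functional regions give a fixed landmark set at
0, 40, 64, 88 and 100% of half arclength: apex, coronal joint at the
edge of the passive central disk where the circular muscles start,
the circular-to-radial muscle transition, the flap root where
musculature ends, and the margin (`anatomical_nodes()`).

**Error minimization.** The discrepancy between a profile and a
candidate model is the total unsigned area enclosed between the profile
and the model chords, divided by the profile arclength, making the
error dimensionless on normalized profiles (`profile_model_error()`);
summing over all frames and both sides gives the total error $E$
(`total_error()`). `optimize_nodes()` exhaustively searches interior
node positions on an even percentage grid (default 2%, fine enough to
resolve the anatomical landmark spacing while keeping the search
exhaustive) for the minimum-$E$ model,
with ties broken towards the lexicographically smallest fraction tuple;
`optimize_from_candidates()` performs the same search restricted to the
curvature candidates. The exact normalization of the area error is a
convention of this package (per-profile division by $L_j$); absolute
error values are therefore comparable within this package but not
across differently normalized implementations.

The search precomputes the area contribution of every grid-fraction
pair once per profile, so a four-segment search over the 2% grid
(18 424 interior-node combinations) costs a vectorized sum per
combination. An independent brute-force enumeration over
`total_error()` is kept in the test suite as an oracle.

## Segment kinematics and the Fourier gait model

For each frame of a discrete model, `segment_kinematics()` measures the
chord lengths $l_k(t)$ and deflection angles: $\varphi_1$ is the angle
of segment 1 *below* the body-frame horizontal, and $\varphi_k$ for
$k\ge2$ the signed angle from segment $k{-}1$'s direction to segment
$k$'s. This convention (declared, since inter-segment angle conventions
are rarely stated) makes forward kinematics trivial:
`reconstruct_profile()` walks from the apex adding one deflection per
segment, and extraction/reconstruction invert each other to machine
precision. Angle channels are unwrapped over time.

One cycle is clipped and cyclically shifted so contraction comes first
(`clip_and_shift_cycle()`), tiled nine times, and each channel fitted by
linear least squares on $\{1, \cos n\omega t, \sin n\omega t\}$,
$n = 1..n_F$, $\omega = 2\pi/T$ (`fit_fourier()`, default order 8 for
~27 samples per cycle). Least squares rather than an FFT because the
samples per cycle are few and need not align with the period. Tiling an
exactly periodic signal does not change the coefficients (verified in
the tests); it reproduces the fitting protocol under which the model is
meant to be used — evaluation over many cycles.

`detect_phases()` segments one cycle of the actively driven angle
channel (the circular muscles) into contraction (inward velocity at
least 5% of peak), cruise (speed below 5% of peak — the bell "coasts"
fully contracted) and relaxation (the rest). Velocities are measured on
sample intervals (forward differences, including the wrap-around
interval), so the three phases exactly partition the period and a
plateau-free triangular waveform yields a zero-length cruise; central
differences would instead smear one spurious low-velocity sample around
every extremum. The two duty-cycle conventions — contraction alone, or
contraction plus cruise, over the period — are both reported, matching
the two ways a powered actuator could be driven.

One caveat surfaced by the synthetic swimmer: phase detection is exact
on the driving waveform itself, but a channel *extracted from
fraction-based nodes* can fail to sit perfectly still during cruise
even when its planted waveform does. While the lagging flap still
moves, it redistributes arclength along the profile, so a node pinned
at a fixed arclength fraction wobbles and the extracted angle creeps by
a few degrees per second — enough to clip the detected cruise. This is
a direct consequence of the uniform-deformation assumption behind
fraction-indexed resampling, not a detector bug; segment phases on the
modeled (Fourier) channel or raise `eps` when working with extracted
series.

## Derived quantities

* `node_trajectories()` closes each node's one-cycle path and reports
  its signed shoelace area. Orientation is classified with the phase
  labels: a node whose contraction-phase positions lie farther from the
  apex than its relaxation-phase positions loops "outer on
  contraction" — the drag-efficient pattern of a flapping margin.
* `margin_excursion()` reports the per-axis absolute margin displacement
  between paired relaxed and contracted instants, averaged over sides
  and cycles.
* `subumbrella_volume()` revolves the region bounded by the profile, the
  axis through the apex, and the horizontal line through the profile's
  minimum y. It evaluates $V = |\pi \oint x^2\,dy|$ along the closed
  boundary, which is exact for polyline boundaries (cylinders and cones
  to machine precision) and — unlike disc stacking — remains valid when
  the profile is multi-valued in $y$, as it is when the relaxing bell
  folds over the apex. Convergence on smooth profiles is $O(h^2)$:
  ~0.02% error for a hemisphere at 51 points.

## The synthetic swimmer

No real digitized sequence ships with the package, so every stage is
validated against `synthetic_swimmer` scenes with known ground truth.

`swimmer_spec()` builds a four-segment bell (anatomical fractions
0/40/64/88/100) whose deflection channels follow trapezoidal
contraction–cruise–relaxation waveforms with per-segment amplitude and
lag, plus an antisymmetric triangular "flare" transient for the
actively counter-moving sections. The defaults encode the observed
gait of a ~50 cm animal: period 5.4 s split 2 s contraction / 1 s
cruise / 2.4 s relaxation; circular muscles −42°; central disk +20°
(passively dragged); radial muscles −20° with an 8° counter-flare;
flap +44° net with a large transient flare. Because the generator uses
a single lag per channel while the observed contraction and relaxation
lags differ, the default lags are the per-section means (radial
0.95 s, flap 1.4 s). With these waveforms the generator reproduces,
rather than merely postulates, the qualitative signatures of the real
animal: the exumbrella lengthens ~5% during contraction; the bell
volume dips briefly at contraction onset (the bell first flattens) and
then *grows* through contraction while the diameter shrinks; the margin
traces the largest trajectory loop, outer path on contraction; and the
margin excursion comes out near 0.25/0.6 normalized units in x/y.

Skeleton corners are rounded with circular fillets (default radius 0.04
normalized units) before sampling, because a real bell has no kinks and
the curvature analysis needs smooth extrema to find. Ground truth
(planted channels, skeleton nodes, phase structure) is recorded
alongside the emitted profiles.

`apply_camera()` places the animal in a 640×360 image (140 px per
normalized unit by default), applies roll about the apex image, zoom
and residual drift scale about the frame center, digitization
subsampling and seeded pixel noise, and emits the digitized frames plus
reference and marker tracks. The background reference tracks only the
camera-motion (zoom) component — exactly the situation the two-stage
magnification correction is designed for. The contracted frames listed
in the generated configuration are the last cruise sample of each
cycle, since earlier plateau samples are not geometrically identical
while the lagged channels still move.

What the generator does **not** emulate: out-of-plane rotation
(explicitly out of scope for single-view correction), non-linear
residual drift, left–right asymmetry of a disturbed animal, occlusion
or digitization dropouts, and the 3-D scalloping of the real eight-
segment bell. Passing recovery tests therefore demonstrate correctness
of the algorithms under the stated camera model, not robustness to
every field condition.

## Numerical choices and degenerate inputs

* Scales must be positive; a reference point at the frame center, a
  linear fit implying non-positive arclength, fewer than two contracted
  frames, or a marker far from the outline are hard errors. A missing
  reference track degrades gracefully (unit camera scale, with a
  warning), since the linear-fit stage can still absorb slow drift.
* Collinear triples have zero curvature; coincident points are errors.
  Zero-crossing candidates are interpolated linearly between samples;
  isolated sign flips below 0.1% of the peak derivative are ignored.
* Ties in the node search are broken lexicographically; a zero-length
  chord contributes zero area; fraction grids always include 0 and 100.
* The Fourier design matrix is solved by QR; rank deficiency (too few
  samples for the order) is an error, not a silent least-norm fit.
* All randomness in the generator sits behind one integer seed.

## Problem sizes

The shipped tests and the acceptance script run the full pipeline on
two-cycle scenes of 54 digitized frames (27 samples per 5.4 s cycle at
25 fps digitized every 5 frames, the acquisition geometry the defaults
describe), with 51-point half profiles, ~160-point digitized outlines,
and four-segment searches on the 2% grid. These sizes keep every
recovery property measurable — scale to longer records and finer grids
is linear in frames and combinatorial in interior nodes.
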