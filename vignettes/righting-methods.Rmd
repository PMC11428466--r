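---
title: "Models and methods for analyzing terrestrial self-righting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for analyzing terrestrial self-righting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette explains the physical models behind `righting`, the
assumptions they make, the tunable parameters and why their defaults are
what they are, what the synthetic-trial generator does and does not
emulate, and the numerical choices that matter when reproducing results.

## The measurement model

The pipeline's raw input is a `tracked_trial`: per-frame 3D positions of
named anatomical landmarks in a laboratory frame with Z vertical, sampled
uniformly (1000 fps in the motivating experiments), as produced by
DLT-based multi-camera reconstruction. The canonical schema has 21 names —
cranial, caudal, a dorsal midline point, and coxa / femur–tibia / tarsus
points for legs L1–L3 and R1–R3 — of which the minimal set (cranial,
caudal, dorsum, six tarsi) is required. Missing samples are explicit `NA`s
and are ignored, never interpolated silently.

Tracked coordinates are smoothed by local quadratic regression over a
moving window: 25 ms for body landmarks and 5 ms for the faster legs, both
configurable in milliseconds and converted to samples via the frame rate.
With the robust flag, samples falling more than 6 median absolute
deviations from the local fit get zero weight (bisquare inside the cutoff,
two reweighting iterations), which suppresses isolated tracking gross
errors. Derivatives are the slope of the same local quadratic, so
polynomials up to degree 2 are smoothed and differentiated exactly;
endpoints use one-sided windows. A 2 Hz sine sampled at 1000 fps is
differentiated to better than 0.3% of its peak derivative with the 25 ms
window.

The ground plane is fitted by total least squares to tarsus samples within
0.6 mm of the lowest observed foot height, with two trimming passes
(drop > 2.5 SD, refit) because swing-leg samples can contaminate the band.
Landmarks count as in ground contact when within a tolerance of the plane;
the default tolerance is twice the plane-fit residual SD (about twice the
tracking uncertainty), floored at 0.1 mm for noise-free data.

## Attitude

Attitude is the rotation from an anatomical body frame (origin at the
cranial–caudal midpoint, x cranial, y left-lateral, z dorsal) to the
spatial frame, estimated per frame by solving the absolute-orientation
problem (SVD/Kabsch, no scaling) against a fixed reference configuration.
Computations use scalar-first unit quaternions with hemisphere continuity
enforced along the series; Euler angles are reported in the intrinsic
Tait–Bryan z–y′–x″ (yaw, pitch, roll) convention, with the gimbal-locked
case (|pitch| = 90°) resolved deterministically by setting roll to 0.

The reference configuration is the mean landmark geometry of the first 25
valid frames, expressed in the anatomical frame. The body landmark set is
nearly planar (the dorsal point provides the only strong out-of-plane
lever), so reference noise tilts the recovered dorsoventral axis for the
whole trial; 25 frames = 25 ms of the initial quiescent period keeps that
tilt well under a degree at 0.2 mm tracking noise, where a 5-frame mean
can leave several degrees. The count is an argument (`n_ref`) for data
with shorter quiescence.

Orientation during righting is summarized by `Z_dv`, the Z-component of
the unit dorsal→ventral axis: +1 flat on the back, 0 at the flipping
point, −1 upright with the axis pointing straight down. Angular velocity
comes from the axis–angle decomposition of the relative quaternion between
neighbouring frames; `omega_spin_rp` removes the component along the body
yaw axis, leaving the roll+pitch spin rate that actually reorients the
dorsoventral axis.

## The anchor model (mass properties)

The body (head + thorax + abdomen) is one rigid object whose mass
properties come from exact polyhedral volume integrals of a watertight
triangle mesh at uniform density — not surface sampling — scaled to the
body's mass. Each leg is two thin rods: segment 1 (tibia + tarsus) between
the femur–tibia joint and the tarsus, segment 2 (femur + trochanter +
coxa) between the coxa and the joint, with `I = mL²/12` about transverse
axes and zero axial inertia; rod endpoints are the tracked positions, so
leg configuration is honored frame by frame. Whole-insect COM and the spin
moment of inertia about the instantaneous rotation axis are composed with
the parallel-axis theorem and the tensor quadratic form.

Because growth is isometric in the motivating species, trials are rescaled
to a standardized morphology before analysis: body length 8.9 mm and mass
28.4 mg (`scale_to_standard()`, a uniform coordinate scaling that is
idempotent). The default leg morphometrics table is the package's standard
morphology for that scale: legs carry ~40% of total mass, hindlegs (the
jumping legs) longest and heaviest. The published dissection table resides
in supplementary material that is not machine-readable here, so these
values were chosen once as a plausible set whose splayed reference pose
(legs extended at 45° elevation) puts the legs' share of spin inertia at
70% — the middle of the reported 65–72% range; the share about the roll
axis alone is far higher (~90%) and about the pitch axis far lower
(~47%), so the summary reports the mean over the three principal axes.
Users with real dissection data should supply their own YAML table
(`read_leg_morphometrics()`).

## The inverted-pendulum template

The template treats the insect as a rigid body rotating about a fixed
ground pivot. The pivot is the time-mean position of the most stationary
in-contact landmark over the attempt (body landmarks preferred; the most
stationary in-contact tarsus as fallback), re-estimated per attempt and
held fixed within it. Orbital kinematics divide the smoothed COM speed by
the pivot–COM distance (`omega_orbital = v/d`, guarded below `d` = 1 mm),
the pendulum inertia transfers the spin inertia to the pivot
(`I_pendulum = I_spin + M d²`), and the available kinetic energy is
`KE_avail = ½ I_pendulum ω_orbital²` — the energy in motions that can
raise the COM.

Reaction torque uses `τ_net = I_pendulum α_orbital` and subtracts the
gravity torque. The printed form of the template equation uses the full
pivot–COM distance `d` as the gravity arm, while its accompanying text
defines the arm as the horizontal distance from the pivot to the COM's
ground projection; for a vertical force the horizontal projection is the
physically correct arm, so `r_com` is the default and a `gravity_arm`
switch restores the literal printed form. The gravity arm is unsigned, so
the torque balance is meaningful on the approach to the apex (start to
apex), which is where per-trial summaries evaluate it. Force per leg
divides the net reaction force (`τ_reaction / r_⊥`, with `r_⊥` the mean
in-contact tarsus–pivot distance) by the number of tarsi in contact, and
is also reported in body weights.

A defining template identity — spin and orbital rates equal — holds within
2% on purely rigid simulated pendulums and is deliberately *not* assumed
for real or articulated data: the pipeline reports the measured
`omega_spin_rp : omega_orbital` ratio, which exceeds 1 when leg swings
spin the body faster than the COM orbits.

## Energetics and stability

`PE = M g Z` above the fitted plane, decomposed into body and leg
contributions by component masses. The remaining barrier
`ΔPE(t) = PE_max − PE(t)` uses the maximum over the current attempt, so
failed attempts are self-contained. The righting number
`RN = KE_avail / ΔPE` saturates (reported `NA`, flagged) when ΔPE falls
below 10⁻¹⁰ J rather than blowing up. The apex is the time of maximum
total PE; the flipping point is the first downward zero crossing of
`Z_dv` (linearly interpolated); active overturning is the maximal
contiguous interval containing the flip where |dZ_dv/dt| is at least 50%
of its trial maximum — the published description of that interval is
qualitative, so the 50% threshold is a configurable stand-in chosen to
bracket the flipping point.

The pitch–roll PE landscape rotates the body mesh through Tait–Bryan
(pitch, roll) pairs with yaw fixed at 0 (yaw cannot change COM height for
a point contact), rests it on its lowest vertex, and records
`M_body g Z_com`; the default grid is 1°, and the analysis script uses 2°
(a 180 × 180 grid) to keep runtime in seconds.

The support polygon is the 2D convex hull of in-contact landmarks in
ground-plane coordinates. SM is the signed distance from the COM
projection to the hull boundary (positive strictly inside); ISM is the
boundary distance of the polygon's area centroid; degenerate supports
(point, segment, collinear) have ISM = 0, an undefined ratio, and can
never yield SM > 0. Note one geometric subtlety the simulations expose:
for a caudal-pivot pitch the COM projection reaches the support boundary
essentially *at* the flipping point (the pivot is the hull's forward
vertex), so the SM sign change coincides with the flip to within a few
frames; "negative until upright" should be read with that grain in mind.
Adhesive or clawed feet can stabilize any SM by pulling; SM assumes
pushing contacts only.

## Behavior and coordination

An attempt starts when the dorsum leaves contact tolerance while
overturned (`Z_dv` > 0.9) and ends either in success — all six tarsi in
contact, `Z_dv` < 0, COM speed below 5 mm/s sustained for 100 ms (the
rest-speed threshold operationalizes "came to rest stably"; no published
number exists) — or failure (dorsum recontacts while overturned), with a
30 s give-up horizon. For segmentation only, the tarsus-contact count uses
additionally smoothed (25 ms) foot heights so noise chatter cannot break
the sustained-rest criterion. Method classification is rule-based:
lifted rotating if no body landmark touches the ground during active
overturning; else pitching if the mean rotation axis lies within 30° of
the body lateral axis *and* the pivot sits at the caudal end (1.5 mm
tolerance); else diagonal rotating. The cone and pivot tolerance are
quantitative stand-ins for qualitative mode descriptions and are
arguments.

Leg coordination standardizes each tarsus-height series (body-frame
dorsoventral coordinate, positive ventral per the worked sign convention:
a tarsus raised dorsally above the origin has negative height) to zero
mean over the window from the first analyzed frame to the apex, then
computes the discrete normalized cross-correlation with 1/n normalization
by the series' root-mean-square values — the interpretation under which
any autocorrelation is exactly 1 at zero lag. Peak finding uses local
maxima of the signed value for cross-pairs and of the absolute value at
nonzero lag for autocorrelations (so anti-phase alignments register at
half-period lags), with ties broken toward smaller |lag|. Hindlegs are
excluded from pairwise summaries since they serve mostly static roles.

## The synthetic-trial generator

`simulate_trial()` builds trials under the study conditions: a rigid
flattened body (ellipsoid stand-in with semi-axes 4.45 × 1.8 × 1.1 mm —
half the standardized body length — or any supplied STL mesh), total mass
28.4 mg split between body and the standard leg morphometrics, 1000 fps,
0.2 mm Gaussian landmark noise, and a fixed horizontal rotation axis
through a ground pivot. Dynamics integrate `I φ̈ = τ_gravity(φ) + τ(t)`
with fixed-step classical Runge–Kutta at the frame interval (mechanical
energy conserved to ~10⁻⁶ % over a torque-free fall), with the moment of
inertia of the body plus legs frozen at their initial configuration.

The three righting modes differ in geometry and choreography. Diagonal
rotating pivots on the caudal end with the body yawed 42° so the rotation
axis is oblique to the lateral axis, four feet planted around the COM
projection (statically stable throughout), and the contralateral fore and
mid legs swinging up and over the body in a spatially prescribed arc that
peaks at 68% of the stroke — just after the flip — which is what makes
total PE peak a few milliseconds *after* the flipping point, the ordering
the rigid template cannot produce (a rigid pendulum started supine always
tops out at or before its flip). After the apex the legs brake the fall
viscously, standing in for the corrective recovery motions of real
insects, so the dorsoventral reorientation rate peaks near the flip.
Lifted rotating raises the body 1.5 mm off the ground and rolls it about
the line of three planted ipsilateral feet (a line support: SM can never
be positive until upright). Pitching rotates about the lateral axis on a
caudal pivot with hindleg support. Failed trials release their applied
torque early enough that the work done can never clear the potential
barrier, guaranteeing fall-back; successful strokes release once the work
clears the rigid barrier with a 15% margin and coast over the apex.

What the generator does **not** emulate: contact mechanics and friction
(feet are pinned or prescribed, never slipping or bouncing), leg inertial
back-reaction on the body (legs are kinematically prescribed; their
PE is tracked but the dynamics stay one-dimensional about the fixed
axis), occlusion-driven missing data, and non-Gaussian tracking errors.
Passing the closure tests therefore demonstrates that the *analysis*
recovers the mechanics of an idealized righting motion, not that the
idealization captures every feature of real trials — on real data the
template's own assumptions (fixed pivot, rigid body) are exactly what the
anchor-model comparisons are designed to interrogate.

## Numerical choices and problem sizes

- All internal computation is SI (m, kg, s, J, N·m); unit conversion (mm,
  mg) happens only at the I/O boundary, and mm→m is division by exactly
  1000.
- Metric tables round-trip at full float precision (`%.17g`), with NA/NaN
  as empty cells.
- Quaternion extraction uses Shepperd's largest-pivot method; attitude
  SVD applies the determinant correction for reflections and rejects
  configurations whose second singular value vanishes (collinear
  landmarks).
- The test suite and acceptance script run trials of 370–800 frames
  (0.4–0.8 s), meshes of a few thousand facets, 2°–22.5° landscape grids,
  and 8–20 noise seeds per stochastic check; these sizes were chosen so
  each closure quantity is estimated well inside its tolerance while the
  whole suite completes in a few minutes.

## Known limitations

- The anchor model assumes uniform density for the body mesh and rods for
  the legs; no published density map exists, and the rod simplification's
  COM error is below tracking noise.
- The gravity arm in the torque balance is unsigned, so reaction-torque
  estimates are meaningful from start to apex, not through the fall.
- Attitude quality depends on out-of-plane landmark leverage; with only
  the dorsal point off the body plane, sub-degree accuracy requires the
  reference averaging described above.
- Attempt segmentation thresholds (`Z_dv` > 0.9 overturned, 5 mm/s rest
  speed, 100 ms sustained) are behavioral operationalizations; trials with
  long quiescent pauses spanning the give-up horizon are counted
  conservatively (the attempt in progress is censored).
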