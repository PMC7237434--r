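---
title: "Models and numerical methods in hyolingual"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical methods in hyolingual}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the science and the numerical
choices behind it: the coordinate conventions, the rigid-body and
soft-tissue kinematic measures, the regional tongue-volume model, the
alpha-shape oral volume, the EMG runs-test threshold, the event and
statistics layer, and the synthetic swallow generator that makes the whole
chain testable.

## Coordinate conventions and units

All coordinates are millimetres in a cranial anatomical frame: +X
anteroposterior (positive anterior), +Y superoinferior (positive superior),
+Z mediolateral (positive toward the animal's right); the frame is
right-handed and the palate plane contains the X axis. Published work in
this area fixes the axis *roles* but not their *signs*, so the sign
convention above is a package-level choice used consistently everywhere —
in particular by `sagittal_angle()`, whose convention (anterior = 0°,
superior = 90°, posterior = 180°, inferior = 270°) and by
`gape_pitch_angle()`, which is signed so jaw opening is positive.

`build_anatomical_frame()` fits the palate plane by total least squares
(SVD of the centred landmarks). Two residual ambiguities must be fixed
deterministically for the construction to be equivariant under rigid
transforms of its inputs: the anterior direction comes from ordered midline
landmarks (posterior first), and the superior sign is chosen so that the
first three palate landmarks wind counterclockwise when viewed from above.
Both rules depend only on the landmarks, never on the world frame.

Volumes are computed in mm³ and reported in mL (mm³/1000), matching how
regional tongue volumes are conventionally reported.

Missing marker observations propagate as `NA` through every derived
quantity. Interpolation never happens silently: `interpolate_gaps()` is an
explicit call, linear, restricted to interior gaps of at most 5 frames
(25 ms at 200 Hz), and logs every filled gap.

## Rigid-body kinematics

Pose estimation is the closed-form least-squares (Kabsch/SVD) solution with
a reflection guard forcing `det(R) = +1`; it is deterministic and has no
iteration tolerance. Markers missing in a frame are dropped; fewer than
three usable, non-collinear markers is an error for that frame.

Mandibular pitch is extracted from the mandible-in-cranium rotation by an
intrinsic Z–X–Y Euler decomposition, taking the Z (mediolateral) component.
The decomposition order is not something the source data dictate; the
synthetic generator produces mandible motion with the same convention, so
the choice is closed under test. The gape zero is the frame of minimum gape
in the sequence — an intercuspation proxy, since the true occlusal zero of
a live recording is not observable from markers alone — and is logged.

Velocities are central differences at the native frame rate with one-sided
endpoints: the lowest-bias simple estimator, and the natural reading of a
"first derivative of the length waveform". The zero-velocity band used for
isometry and intercuspal-phase decisions is ±2 SD of the velocity measured
on a static (frozen-specimen style) precision recording; precision across
animals is summarised by the pooled SD, `sqrt(mean(s_k^2))`.

## Muscle and dimension measures

Muscle length is the Euclidean distance between two attachments, each a
marker or a fixed reconstructed point. The sagittal orientation is measured
on the insertion→origin vector projected into the cranial X–Y plane, so a
retracting line of action reads near 180°; the opposite vector convention
would shift every angle by exactly 180°, and the insertion→origin choice is
the one that places the extrinsic retractors in the conventional posterior
band (135°–225°).

Tongue dimensions are axis projections, not Euclidean distances: posterior
width is the |Z| separation of the lateral posterior markers, posterior
depth the |Y| separation of the posterior surface marker and the dorsal
hyoid point, posterior length the |X| separation of the posterior and
middle surface markers. The anterior dimensions use the same projection
scheme (an assumption — the source convention for the anterior tongue is
not documented — flagged here). Tongue-base length is operationalized as
the |X| distance between the midpoint of the two posterolateral markers and
the vallecular marker.

## Regional tongue volume

The tongue is modelled as three primitives delimited by two coronal
cross-sections, each defined by 4 markers:

1. **Ring fit.** A natural cubic spline (`stats::splinefun`,
   `method = "natural"`) is fit per coordinate through the ordered control
   set wrapped for three full loops (13 knots), starting and ending at the
   middle deep marker (middle ring) or the reconstructed dorsal hyoid
   point (posterior ring); only the middle loop is retained. Wrapping
   pushes the natural-spline end conditions two loops away from the
   retained segment; a residual asymmetry of order 10⁻³ of the ring radius
   remains and is accepted (the retained loop is C⁰-closed by
   construction). The spline parameter is cumulative chord length, which is
   shape-preserving for the unevenly spaced marker quadruples.
2. **Matched resampling.** Both rings are resampled at `n_ring = 300`
   points of equal arc length, index 1 at the start control, both loops
   oriented counterclockwise viewed from anterior (+X); a ring arriving
   with opposite handedness is reversed and the reversal logged. The
   correspondence (index k ↔ index k) defines the cylinder side wall. The
   default of 300 matches the spline sampling density; the convergence test
   in the suite shows n = 150 and n = 300 volumes agree within 1%.
3. **Harmonic fill.** Each resampled ring is projected onto the plane of
   its first two principal directions, the enclosed planar domain is
   triangulated, and the surface's x, y, z coordinate functions solve the
   discrete Laplace equation with cotangent weights and the ring as
   Dirichlet data (one sparse symmetric factorization per coordinate
   block, no iterative tolerance). A planar ring therefore fills exactly
   planar (cotangent Laplacians reproduce affine functions), and a
   non-planar ring yields a curved harmonic span whose interior obeys the
   discrete maximum principle coordinate-wise.

   *Mesher.* The planar domain is meshed with concentric copies of the
   boundary loop shrunk toward the 2D centroid (vertex count proportional
   to the scale factor), consecutive loops stitched by arc-length
   parameter, plus a central fan. This structured mesher is valid for
   domains star-shaped about their centroid — which all spline rings
   through 4-marker coronal sections are — and is fully deterministic. A
   conforming-Delaunay mesher would accept more general domains; the
   structured mesh was chosen because it needs no 2D Delaunay machinery,
   produces well-shaped triangles away from the centre, and the harmonic
   solution is mesh-convergent anyway (interior refinement by 4× moves
   enclosed volumes by well under 0.5%, tested). A self-intersecting
   projected boundary is rejected with an error naming the frame.

   Negative cotangent weights from obtuse triangles are kept as-is,
   matching the standard cotangent-Laplacian surface-editing formulation;
   `clamp_cotangent = TRUE` switches to clamped weights for users who want
   a guaranteed M-matrix.
4. **Primitives and volume.** AOT = cone (middle surface → anterior
   marker), POT = deformed cylinder (both surfaces + quad strip between
   matched samples), TB = cone (posterior surface → vallecular marker).
   Face windings are consistent by construction (the fan/strip traverses
   each boundary edge opposite to its base face), the global orientation is
   fixed to outward by the sign of the total signed volume, and each
   closed mesh's volume is the absolute sum of signed tetrahedra about the
   vertex centroid — for a closed mesh the reference point is immaterial
   (verified to 10⁻⁹ over random origins). A missing vallecular marker
   omits the TB mesh (logged); per-frame geometry failures yield `NA`
   volumes and the pipeline continues.

## Oral-cavity volume

The oral cavity is bounded by rigid surfaces (hard palate mucosa, lingual
tooth rows, mandible, anterior hyoid) and a straight mylohyoid raphe from
the inferior hyoid pole to the mandibular symphysis, sampled at 50 points.
Component landmark clouds are posed rigidly per frame and unioned; volume
is the alpha shape with α = 6 (assumed mm, consistent with every other
coordinate in the pipeline): Delaunay tetrahedra whose circumsphere radius
is at most α, volumes summed. Tetrahedra below 10⁻¹² mm³ are excluded
before the circumradius test so that numerically unbounded circumradii of
slivers cannot flip a kept/dropped decision.

The Delaunay backend is an incremental Bowyer–Watson tetrahedralizer with
*exact integer predicates*: inputs are scaled to a 2¹⁸ lattice, perturbed
by ±1 lattice unit of seeded deterministic jitter, snapped to integers, and
orient/insphere tests are evaluated in 128-bit integer arithmetic. This
makes the algorithm robust on the degenerate inputs the pipeline actually
sees (regular grids of bone landmarks, cospherical clusters); exact ties
that survive the jitter trigger a retry with a fresh jitter seed. Volumes
and circumradii are always computed from the original, unperturbed
coordinates, so the jitter affects topology only in exactly-degenerate
(zero-volume) configurations and never the reported volume.

## EMG processing

Conditioning follows the standard chain: zero-phase (forward–backward)
Butterworth filtering — 30 Hz high-pass, optional low-pass in the
1000–3000 Hz range depending on the channel's sampling rate — then
full-wave rectification and RMS integration over non-overlapping 5 ms
windows, which doubles as downsampling to the 200 Hz motion frame rate.
The filter order is 4 (the forward–backward pass doubles the effective
order); window boundaries are defined by time and a partial trailing window
is dropped and logged.

The noise threshold is selected by a runs test: over a grid of 200
candidate thresholds strictly between the envelope minimum and maximum, the
number of runs (maximal same-side blocks) in the ordered envelope is
compared with the number in a seeded random permutation, and the candidate
maximizing (permuted − ordered) is selected; ties go to the lowest such
threshold, the conservative direction for detecting activity. The final
threshold is the mean of 30 replicate selections with fresh permutations,
each replicate's permutation seeded deterministically from the
configuration seed. When a trial contains much more activity than noise,
the optimal threshold creeps upward and cuts into genuine bursts; rather
than automating the fix, the `subset` argument restricts the runs test to a
window in which activity and noise durations are roughly balanced, leaving
the judgement to the analyst. Grid run counts are computed in
O((n + G)·log n) by counting the threshold intervals spanned by consecutive
samples; the test suite pins this fast path against a brute-force
rle-per-threshold oracle on identical permutations.

Activity flags are simply envelope > threshold; bursts are maximal
supra-threshold runs with their onset/offset samples.

## Events

TBR onset is the frame at which the posterior superficial marker is most
anterior before posterior movement begins; offset is the frame at which the
vallecular marker is most posterior after onset, falling back to the
posterior-surface trough (flagged) when no vallecular series exists.
Extrema are located on a moving-average smoothed copy (default window 21
frames, ~105 ms): marker noise at the 0.07 mm precision scale displaces a
raw argmax of these gently curved trajectories by several frames, while the
smoothed argmax stays within ±2 frames; on noiseless data, smoothing with a
symmetric window leaves a locally symmetric extremum exactly in place. The
per-cycle search window is supplied by the caller (from gape-cycle
segmentation): automatic swallow-versus-chew classification is behavioural,
not kinematic, and out of scope. Intercuspal phases are the maximal
intervals (minimum 2 frames) where mandibular pitch velocity stays inside
the precision zero-velocity band. δ-series subtract the value at TBR onset.

## Statistics

One-sample and paired Wilcoxon signed-rank tests use the exact distribution
for n ≤ 25 (ties permitting) and the normal approximation with continuity
correction above; zero differences are dropped (the standard signed-rank
convention), and a comparison whose differences are all zero is reported as
undefined rather than forced to a p-value. Bonferroni correction is applied
as a decision threshold α/m across the m comparisons. Pearson matrices are
pairwise-complete with two-sided t-based p-values; zero-variance columns
yield `NA` with a warning. Cycles are pooled across animals, replicating
the source analysis; a mixed-effects treatment of animal-level clustering
would be the stricter choice and is deliberately not substituted.

## The synthetic swallow generator

`generate_scenario()` emulates the structure the analysis assumes — it is a
kinematic emulation, not a biomechanical simulation. One 1 s swallow gape
cycle at 200 Hz contains: a fast close ending abruptly at intercuspation
(tooth contact), a 0.1 s zero-pitch plateau, a slow open beginning at full
velocity, and a fast open; hyoid protraction/elevation ramps over the TBR
window; a 10-marker tongue constellation with macaque-scale proportions
(posterior coronal ring ≈ 22 × 20 mm, middle ring ≈ 20 × 17 mm) deforming
with midline-dominant retraction; muscle insertion markers constructed so
programmed length changes hold exactly (collinear moves toward/away from a
fixed origin; the hyoglossus insertion sits on the hyoid excursion line so
its shortening equals the excursion magnitude); multichannel EMG as white
noise plus amplitude-modulated burst noise phase-locked to the kinematic
schedule; and bone-landmark clouds for the oral cavity totalling ~6000
points.

Default parameters are the study-condition means: hyoid excursion
4.23/2.13 mm; posterior surface/deep/vallecular retractions
6.25/4.30/4.08 mm; tongue-base length increase 3.61 mm (which fixes the
posterolateral retraction at 4.08 − 3.61 = 0.47 mm); ΔPOT +0.85 mL and
ΔTB +0.65 mL at constant AOT; styloglossus −0.76 mm and palatoglossus
+0.07 mm; marker noise 0.07 mm. Values with no documented counterpart
(posterior deep elevation 2.5 mm, EMG noise σ = 0.1 against burst amplitude
1.0, the baseline marker coordinates) were chosen once as anatomically
plausible and are not tuned thereafter.

Event-defining trajectories need well-defined extrema under noise, so every
retraction follows a cosine ramp preceded by a small anterior drift that
peaks exactly at onset and followed by a small rebound after offset, with
the drift/rebound amplitudes chosen so the curvature matches on both sides
of each extremum (amplitude A(t₁/T)² for a half-window of t₁ = T/2, i.e.
A/4). Locally symmetric extrema are what smoothing-based detection locates
exactly on clean data.

Volume targets cannot be imposed in closed form, so the generator solves
two scalar degrees of freedom against the forward volume model itself (the
same ring/surface/primitive code the pipeline uses, at a coarser interior
resolution for speed): posterior-surface elevation is rooted against the
POT target, then vallecular elevation against the TB target
(`uniroot`, ≤ 50 iterations, brackets −8…16 mm; no sign change is an
error). The achieved deltas, evaluated at the full pipeline resolution, are
recorded in the ground truth; the suite requires them within 2% of the
nominal targets. The middle ring and anterior marker stay fixed, holding
AOT constant by construction.

What the generator does **not** emulate — and what passing closure tests
therefore cannot certify about real recordings: marker tracking dropouts
and occlusions (noise is iid Gaussian, not structured), soft-tissue marker
migration, bolus-dependent cycle variability, EMG crosstalk and motion
artifact, non-rigid hyoid motion, and real anatomical variation between
animals. The closure tests demonstrate that the measurement chain is
correct and self-consistent at the study's noise scale, not that the
biological inferences transfer.

## Problem sizes and determinism

The test suite runs the geometry oracles at 300 ring samples, the
end-to-end closure at one noiseless and one noisy default scenario, the
runs-test calibration over 100 seeded envelopes of 4000 samples, and the
statistics layer at n = 85 cycles — sizes chosen to exercise each method at
its intended operating point while keeping the whole suite fast enough to
run routinely. Every stochastic step (marker noise, EMG noise, permutation
replicates, Delaunay jitter) derives from an explicit integer seed; two
runs with the same seed are identical to the last bit.

## Known limitations

* The regional volume is necessarily smaller than the whole tongue (markers
  sit below the mucosa, and only the inter-ring region is modelled); the
  package reports the modelled region only.
* The structured disk mesher assumes star-shaped projected rings; a
  pathologically folded cross-section would need a constrained mesher.
* TB volume shares its anterior boundary with the hyoid-defined posterior
  ring, so hyoid protraction contributes to TB volume change — an
  interpretation caveat inherited from the measurement definition, not a
  numerical issue.
* The finite enclosing super-tetrahedron of the Delaunay backend can, in
  principle, clip hull slivers with near-infinite circumspheres; such
  slivers carry essentially zero volume, and the hull-limit identity
  (α → ∞ equals the convex-hull volume) is tested to 10⁻⁹.
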