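# hyolingual

Marker-based hyolingual kinematics and regional tongue volumetry for
swallowing analysis.

During swallowing, tongue base retraction (TBR) drives the food bolus out of
the oral cavity into the oropharynx. Testing how TBR is produced — by
extrinsic tongue muscle shortening, by hydrostatic (constant-volume) tongue
deformation, or by a hydraulic linkage in which hyoid protraction and mouth
floor elevation squeeze the tongue base backwards — requires measuring, from
implanted-marker biplanar videoradiography, quantities that no single
off-the-shelf tool provides together:

* **rigid-body bone kinematics** — mandibular pitch (gape) and hyoid
  protraction/elevation from bone-fixed marker clusters, via closed-form
  SVD least-squares registration;
* **extrinsic muscle kinematics** — lengths (Euclidean attachment
  distances), sagittal orientation angles Θ (anterior = 0°, superior = 90°,
  posterior = 180°, inferior = 270°), shortening velocities, and
  concentric/isometric/eccentric/inactive state labels gated by EMG
  activity;
* **regional tongue volumes from 10 implanted markers** — two closed
  natural-spline rings through 4-marker coronal cross-sections (fit with
  three wrapped loops, middle loop retained), each filled with a harmonic
  ("minimal") surface by solving three Poisson equations with cotangent
  Laplacians on a planar triangulation of its principal-plane projection;
  the anterior oral tongue (AOT) is a cone from the middle ring to the
  tongue tip, the posterior oral tongue (POT) a deformed cylinder between
  the rings, and the tongue base (TB) a cone from the posterior ring to the
  vallecular marker, each closed mesh measured as a sum of signed
  tetrahedron volumes;
* **oral-cavity volume** — a 3D alpha shape (circumradius convention,
  α = 6 mm) over several thousand posed bony landmarks bounding the cavity
  (palate, teeth, mandible, hyoid, mylohyoid raphe), built on an exact
  integer-predicate Delaunay tetrahedralization;
* **EMG conditioning and burst detection** — zero-phase 30 Hz high-pass
  Butterworth filtering, full-wave rectification, 5 ms RMS integration to a
  200 Hz envelope, and a noise threshold selected by a runs test that
  maximizes the run-count difference between ordered and permuted
  envelopes, averaged over 30 seeded replicates;
* **event detection and statistics** — TBR onset (most anterior posterior
  superficial marker position) and offset (most posterior vallecular
  position, with a posterior-surface fallback), intercuspal phases from the
  zero-velocity band of a static precision recording, δ-series referenced
  to TBR onset, Wilcoxon signed-rank tests with Bonferroni correction, and
  pairwise-complete Pearson correlation matrices.

Because in vivo recordings of this kind are not freely redistributable, the
package ships a first-class synthetic swallow generator
(`swallow_scenario()` / `generate_scenario()`) whose defaults emulate the
study conditions (200 Hz, one 1 s swallow cycle, hyoid excursion
4.23/2.13 mm, midline retractions 6.25/4.30/4.08 mm, ΔPOT +0.85 mL,
ΔTB +0.65 mL, 0.07 mm marker precision noise, multichannel EMG with
phase-locked bursts) and records the ground truth of every programmed
quantity, so the whole pipeline is testable end to end.

## Worked example

```r
library(hyolingual)

# one synthetic swallow at the study's default conditions (seeded)
gen <- generate_scenario(swallow_scenario(seed = 1))
gen$markers
#> marker_set: 200 frames x 13 markers @ 200 Hz (0.0% missing)
#>   markers: anterior, lateral_right, lateral_left, middle_surface, ...

# tongue base retraction events
ps <- marker_xyz(gen$markers, "posterior_surface")[, 1]
vx <- marker_xyz(gen$markers, "vallecula")[, 1]
ev <- detect_tbr(ps, vx, window = c(20, 195))
str(ev)
#> List of 3
#>  $ onset : int 81
#>  $ offset: int 142
#>  $ method: chr "vallecular"

# hyoid kinematics from the hyoid marker cluster
hp <- pose_series(gen$bone_refs$hyoid, gen$bones$hyoid)
he <- hyoid_excursion(posed_point(hp, colMeans(gen$bone_refs$hyoid)),
                      reference_frame = ev$onset)
round(he[ev$offset, ], 2)
#>     protraction elevation
#> 142        4.14      2.05

# regional tongue volumes at TBR onset and offset (mL)
hd <- posed_point(hp, c(18, -10, 0))   # reconstructed dorsal hyoid point
rv <- regional_volumes(gen$markers, hd, frames = c(ev$onset, ev$offset))
round(unlist(rv[2, 2:4] - rv[1, 2:4]), 3)
#> aot_ml pot_ml  tb_ml
#>  0.026  0.863  0.646
```

TBR spans frames 81–142 (0.40–0.71 s). Between onset and offset the hyoid
protracts 4.14 mm and elevates 2.05 mm; the anterior oral tongue volume is
essentially unchanged while the posterior oral tongue gains 0.86 mL and the
tongue base 0.65 mL — the programmed swallow (4.23/2.13 mm, ~0, +0.85 mL,
+0.65 mL) recovered through the full measurement chain, with the residual
differences at the scale expected from the 0.07 mm marker noise.

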