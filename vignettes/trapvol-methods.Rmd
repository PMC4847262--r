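---
title: "LV volumetry by trapezoidal SAX+LAX fusion: models, phantoms and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{LV volumetry by trapezoidal SAX+LAX fusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trapvol)
```

## The problem

Clinical cardiac MR estimates left-ventricular (LV) volumes from a stack of
9–12 parallel short-axis (SAX) slices, summing one disc per slice (the
modified Simpson method, `msimp_volume()`):

$$ v_i = A_i \,(t + l), \qquad \mathrm{Vol} = \sum_i v_i, $$

with $A_i$ the area enclosed by the myocardial contour of slice $i$, $t$ the
slice thickness and $l$ the inter-slice gap.  When only a few slices are
usable — motion-corrupted slices excluded from analysis, or shortened
protocols for patients who cannot sustain repeated breath-holds — the disc
approximation degrades quickly, because a tall disc of constant area is a
poor model of a tapering ventricle.

`trapvol` implements a fusion model that adds the information of a single
long-axis (LAX) contour, which crosses all slice gaps and the apex, to
recover most of the lost accuracy.

## The trapezoidal fusion model

Adjacent SAX planes cut the LV into *chunks* (`build_chunks()`).  For chunk
$i$ the LAX contour provides:

* the clipped LAX cross-sectional area $A_{LAX}^i$ between the two planes
  (`clip_contour_between_planes()`), and
* the two diameters $d^i_{up}$, $d^i_{low}$ where the LAX contour crosses
  the chunk's bounding planes (`chord_through()`; the outermost crossing
  pair is used when segmentation noise produces extra crossings).

The LAX section is modelled as a trapezoid of equal area; rotating that
trapezoid about the chunk axis and integrating the resulting wedges over a
half-turn gives the chunk volume

$$ V_i \;=\; \frac{0.5\,A_{LAX}^i}{d^i_{up}+d^i_{low}}
   \int_0^{\pi} \Big(\tfrac{d^i_{up}(\theta)+d^i_{low}(\theta)}{2}\Big)^2
   d\theta , $$

where $d(\theta)$ are diameters of the SAX contours through the chunk axis
(`trapezoidal_integral_volume()` evaluates this reference form by the
trapezoid rule).  Observing that the integral is, up to a factor of two,
the area of a SAX contour with the mean diameter, it is approximated by the
mean of the two bounding SAX areas, giving the closed form used in
practice (`trapezoidal_volume()`):

$$ V_i \;\approx\; \frac{A_{LAX}^i}{d^i_{up}+d^i_{low}}
   \big(A_{SAX}^{up,i} + A_{SAX}^{low,i}\big). $$

Two special chunks complete the decomposition:

* **Apical chunk** — below the most apical slice the LAX section is closed
  by a triangle at the apex; setting $d_{low}=0$, $A_{SAX}^{low}=0$ yields
  $V_N = A_{LAX}^N A_{SAX}^{up,N} / (2 d^N_{up})$.  The apex position is
  taken from the LAX contour, which delineates the apex more reliably than
  the partial-volume-blurred apical SAX slices.
* **Basal virtual chunk** — the LAX segments extending above the most
  basal slice define a mirrored chunk ($d_{up}=d_{low}$,
  $A^{up}=A^{low}$).  It is *excluded* from totals by default
  (`include_basal_virtual = FALSE`): no reference method measures that
  region, so including it would break comparability with disc-summation
  ground truths.

**Oblique LAX correction.**  If the LAX plane does not contain the chunk
axis (obliquity $\Phi_i$, the angle between the line joining the two SAX
centroids and the LAX plane), the apparent LAX section is inflated by
$1/\cos\Phi_i$; `correct_lax_area()` deflates it by $\cos\Phi_i$.  The
correction is applied per chunk by default.  It is first-order: it removes
the area inflation but not the chord shortening that grows when the plane
is pivoted far from the axis over a long ventricle, so residuals grow with
tilt times length-to-radius ratio.

**Classical few-slice models** (`classical_volume()`) are provided for the
two-to-three-slice regime: single-plane area–length $8A^2/(3\pi L)$,
biplane area–length $(8/3\pi)A_1A_2/L$, Teichholz $7.0 D^3/(2.4+D)$ (D in
cm), and the hemisphere–cylinder "bullet" $(5/6)AL$.  These formulas come
from the echocardiography literature; they are configuration constants
here, not this package's contribution.

## Coordinates, units and numerical choices

* Right-handed patient coordinates, millimetres everywhere; planes are
  stored as origin plus an orthonormal in-plane frame (DICOM-style without
  binding to DICOM).  Volumes convert to ml only at the reporting boundary.
* Contours are closed simple polygons, orientation normalised CCW on
  construction; non-simple polygons are rejected, not repaired (repair is
  segmentation-tool territory).
* Intersection tolerance: crossings closer than $10^{-6}$ mm merge; a
  vertex exactly on a cutting plane counts once.  Planes within
  $10^{-6}$ rad of parallel do not intersect.
* Slab clipping uses Sutherland–Hodgman.  For non-convex contours whose
  slab section is disconnected the clipped ring contains zero-width
  bridges; areas are therefore measured on the raw ring (bridges cancel in
  the shoelace sum), while the contour-returning API rejects such rings.
* Subset stacks: a retained slice's disc extends to the next retained
  plane; the most apical retained slice uses the mean of the other
  extents.  Slices are always processed in order of axial position.
* Wedge integration uses $n_\theta = 360$ trapezoid panels by default;
  with 96-vertex contours the quadrature error is dominated by polygon
  kinks (relative changes $\sim 10^{-3}$ when doubling $n_\theta$),
  dropping to $<10^{-4}$ at 256 vertices.

## The phantom laboratory

Real validation data (CT-derived heart surfaces, patient MRI) cannot ship
with a package, so `phantom_lab` substitutes parametric LV-like surfaces
with computable ground truth.  All phantoms are star-shaped about their
long axis, so any reslicing plane yields a simple closed contour:

* `ellipsoid` and `cylinder` have closed-form volumes;
* `superellipsoid` (flat-shouldered axial profile) and
  `perturbed-ellipsoid` (low-order angular harmonics, amplitude $\le$ 0.15,
  largest mid-cavity and vanishing at the tips) are voxelized at 0.5 mm
  (`phantom_true_volume()`, accuracy of order the resolution).

`reslice()` cuts SAX planes perpendicular to the long axis (uniform
base-to-apex, a 5 % tip margin for tapering shapes so every slice is a
proper ring; cylinders are cut cap to cap) and one LAX plane at any
rotation about the axis (4CH = 0°, 2CH = 90°) with an optional obliquity
tilt.  Contours are sampled at 96 vertices (SAX) by direct radius
evaluation and 192 vertices (LAX) — exactly from the surface profile when
the plane contains the axis, by bisection ray-casting otherwise.  These
densities keep discretisation error (≈ 0.07 % on areas) far below model
error.

The default study cohort (`phantom_cohort()`) is five perturbed ellipsoids
with transverse semi-axes 17–24 mm, long semi-axis 40–50 mm (cavity
volumes roughly 60–120 ml, LV scale) and harmonic amplitudes 0.02–0.08 —
mild, realistic departures from an ideal ellipsoid.  What these phantoms
do **not** emulate: papillary muscles and trabeculation, a flat truncated
base (real LVs end at the mitral annulus; these phantoms taper at both
tips), wall-motion abnormalities, and segmentation error.  Passing tests
therefore demonstrate correctness of the geometry and the model's
behaviour on smooth star-shaped ventricles, not clinical accuracy.

## Experiments

`run_slice_ablation()` mirrors the slice-count experiment: reslice each
phantom densely (12 slices), retain uniformly covering subsets
(`select_slice_subset()`: keep the most basal and most apical slices, fill
the rest nearest to ideal uniform positions, ties toward the base), and
report mean ± SD percent error per method and slice count.  Both methods
receive the same n SAX slices; the fusion model additionally uses the one
LAX contour (`count` conventions differ in the literature — a LAX slice
can be counted against the slice budget — so the convention is stated
rather than hidden).  On the default cohort the fusion model stays within
about ±1 % down to 4 slices while disc summation degrades to several
percent, and both converge near zero error at 12 slices.

**Breath-hold misregistration** (`apply_breathhold_misregistration()`)
follows the standard contour-level model: every slice (each SAX and the
LAX) is acquired in its own breath-hold and is rigidly translated by an
independent uniform draw, bounded by 18 mm superior–inferior (along the
long axis) and 2.5 mm anterior–posterior (transverse).  Contour shapes and
areas are preserved; only registration degrades.  In the ablation
pipeline, motion is applied to the dense acquired stack, slices whose
plane no longer crosses the LAX contour are excluded
(`drop_chordless_slices()`, the analogue of discarding unusable slices in
practice), and the slice subset is selected from acquired positions.

A caveat this package states openly: with per-slice *independent* draws of
this magnitude the error spread grows strongly (SD of order 10 % at
n = 6), and a negative mean shift of several percent appears on tapering
phantoms.  The shift is structural, not a bug: slice area is a concave
function of axial position, so under symmetric positional scrambling the
expected imaged area satisfies $E[A(z-\delta)] \approx A(z) +
\tfrac{1}{2}A''\,\mathrm{Var}(\delta)$ with $A'' = -2\pi ab/c^2 < 0$ for an
ellipsoid — about −5 % at $\mathrm{Var}(\delta) = 36^2/12$ mm².  A
misregistration simulation whose per-slice displacements are bounded by
18 mm but highly correlated (breath-hold levels reproduced within a few
millimetres, or one level per acquisition) would show noise without this
shift; the per-slice-independent choice is retained here as the documented
worst case.

## Design choices made where the design was open

* **Basal "complete ring" detection**: the first provided SAX contour is
  treated as the most basal usable slice; detecting ring completeness from
  contours alone is not attempted.
* **>2 LAX crossings** (papillary indentations, noise): the outermost pair
  defines the diameter.
* **Misregistered stacks** fail loudly (`decomposition: no LAX chord at
  SAX slice …`) rather than silently extrapolating; the QC helper
  `drop_chordless_slices()` and upstream registration are the explicit
  remedies.
* **Apical obliquity**: the paper-style obliquity is defined between two
  SAX centroids; for the one-contour apical chunk the LAX contour's most
  apical point stands in for the lower centroid.
* **Significance testing**: the evaluation statistics compare error
  magnitudes with a two-sided paired t-test by default (Wilcoxon
  signed-rank available); SDs use the $n-1$ denominator throughout.
* **Myocardial density** 1.05 g/ml for LV mass, configurable; mass is
  computed from end-diastolic epicardial minus endocardial volumes.
* **Problem sizes**: the shipped experiments use 5 phantoms, 12-slice
  dense stacks, 96/192-vertex contours, 0.5 mm voxel oracles and 10 motion
  repetitions — sizes at which discretisation error is negligible against
  model error while a full validation run completes in seconds.

## Interfaces

Contours interchange through a small versioned JSON dialect (schema in
`inst/extdata/contour-schema.json`): per contour an explicit plane frame
plus 2D in-plane points, making plane membership true by construction;
conversion from imaging formats is out of scope.  The command-line wrapper
(`inst/cli/lvvol`, or `lv_cli()` from R) exposes `volume`, `simulate` and
`benchmark` with every model toggle logged, and fixed seeds make all
outputs byte-reproducible.

## Known limitations

* One LAX contour per analysis; multi-LAX fusion and intensity-based
  SAX/LAX registration are out of scope.
* No regional (17-segment) analysis, wall-thickness maps, or right
  ventricle.
* The oblique correction degrades beyond small obliquities on long
  ventricles (see above).
* Phantom realism limits stated above; clinical claims require clinical
  data.
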