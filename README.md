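# trapvol

Left-ventricular (LV) volumetry from a *small* number of segmented cardiac
MR cross-sections, by fusing a stack of parallel short-axis (SAX) contours
with one long-axis (LAX) contour.

## Why

Clinical LV volumes are computed from 9–12 SAX slices with the modified
Simpson rule — one disc per slice, `v_i = A_i (t + l)`.  When slices are
lost to motion artifacts, or acquisitions are shortened for patients who
cannot sustain repeated breath-holds, disc summation degrades badly: a
tall constant-area disc is a poor model of a tapering ventricle.  A single
LAX view crosses every inter-slice gap and the apex, and carries exactly
the shape information the discs are missing.

## The model

Adjacent SAX planes divide the LV into chunks.  For chunk *i* the LAX
contour supplies the clipped cross-sectional area `A_LAX_i` between the
two planes and the diameters `d_up`, `d_low` where it crosses them; the
chunk's LAX section is modelled as an equal-area trapezoid rotated about
the chunk axis, which after integrating the swept wedges and approximating
the mean-diameter section by the mean SAX area gives

    V_i = A_LAX_i * (A_SAX_up + A_SAX_low) / (d_up + d_low)

with an apical specialisation `V_N = A_LAX_N * A_SAX_up / (2 d_up)`
(triangle-closed apex) and a cosine deflation `A_LAX * cos(Phi)` when the
LAX plane is oblique to the chunk axis.  The package also provides the
modified Simpson method, the classical few-slice models (single-plane and
biplane area–length, Teichholz, hemisphere–cylinder), global-function
metrics (EF, SV, LV mass), Bland–Altman agreement statistics, and a
synthetic phantom laboratory (parametric LV-like surfaces with exact or
voxelized ground truth, reslicing at arbitrary LAX orientations,
breath-hold misregistration simulation).

## Worked example

```r
library(trapvol)

spec <- phantom_cohort(1, seed = 8)[[1]]          # an LV-like phantom
#> phantom_spec [perturbed-ellipsoid]: semi-axes (20.3, 19.1, 48.0) mm,
#>   harmonics (k=2: 0.063, k=3: 0.033)
phantom_true_volume(spec)
#> [1] 77.81125

st <- reslice(spec, sax_count = 12)               # 12 SAX + one 4CH LAX
sub <- select_slice_subset(st, 4)                 # keep 4 slices only

trapezoidal_volume(sub)
#> volume_estimate [trapezoidal]: 77.80 ml from 4 SAX slice(s) (4 parts)
msimp_volume(sub)
#> volume_estimate [msimp]: 73.32 ml from 4 SAX slice(s) (4 parts)
```

With only 4 of 12 slices the fusion estimate is 77.80 ml against a ground
truth of 77.81 ml (−0.01 %), while disc summation gives 73.32 ml (−5.8 %).
At the full 12 slices the two agree closely (77.56 ml and 77.90 ml).

Global function from paired-phase volumes:

```r
global_function(120.4, 51.7, epi_edv = 201.3)
#> function_report [unspecified]: EDV 120.4 ml, ESV 51.7 ml, SV 68.7 ml,
#>   EF 57.1%, LVM 84.9 g
```

`SV = EDV − ESV`, `EF = 100·SV/EDV`, and `LVM` is the epicardial minus
endocardial end-diastolic volume times a myocardial density of 1.05 g/ml.

A command-line wrapper ships in `inst/cli/lvvol`:

```sh
lvvol simulate --out phantom.json --seed 7 --shape cylinder --a 20 --c 25
lvvol volume   --in phantom.json --method trapezoidal --n-slices 4
lvvol benchmark --seed 7 --out ablation.csv --ba-out bland-altman.csv
```

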