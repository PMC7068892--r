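---
title: "Phantom-based validation of left-ventricular quantification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phantom-based validation of left-ventricular quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(lvquant)
```

`lvquant` asks a concrete question: when the left ventricle loses a
region of wall motion, how do the volume estimators in routine
small-animal use disagree, and by how much? Answering it against real
animals is expensive and leaves truth unknown; answering it against a
parametric 4D phantom with analytic ground truth makes the error of
every estimator measurable. This vignette documents the phantom, the
estimators, the statistics, and the choices behind the defaults.

## The phantom

### Geometry and kinematics

The healthy endocardium is a truncated semi-ellipsoid of revolution in
cylindrical coordinates around the long axis, apex at `z = 0`, base at
`z = L`:

    r(theta, z, p) = R(p) * sqrt(1 - (1 - z / L(p))^2)

`R(p)` and `L(p)` interpolate between end-diastole (ED) and end-systole
(ES) with a raised-cosine profile over the cycle:
`R(p) = R_ed (1 - s c(p))`, `L(p) = L_ed (1 - l c(p))`, where
`c(p) = (1 - cos(2 pi (p - 1)/n))/2`. No intracycle kinetics beyond the
ED/ES endpoints matter to any quantity the package reports, so the
profile's shape is a convenience: it is smooth, periodic, and puts ED
exactly at phase 1 and peak contraction mid-cycle. The cavity volume of
this shape is `(2/3) pi R^2 L`, which is the closed form every oracle
test is anchored to.

A radial contraction gain ramps in over the basal third (the
hyperdynamic base of the remodelled ventricle), and the epicardium is
derived from the endocardium by local wall-area conservation
(`r_epi^2 - r_endo^2` fixed per column at its ED value), so the wall
thickens exactly where the cavity contracts — which is what makes
radial (thickening) strain well-posed without simulating a tracked
epicardium.

### Infarcts

An infarct is a contiguous sector in `(theta, z)` reaching up from the
apex, with a raised-cosine angular taper (default 15 degrees) so that
emulated contours are kink-free and estimator errors reflect geometry,
not discretisation artifacts. Inside the sector the motion is replaced
by the dysfunction class:

- **akinetic** — the boundary is frozen at its ED position;
- **dyskinetic** — the boundary bulges outward in proportion to the
  contraction profile (default 10% at peak);
- **aneurysmal** — a static outward bulge (default 15%) present at
  every phase.

Ground-truth volume is computed by midpoint quadrature of
`r^2/2` on a 180 x 600 `(theta, z)` grid; for axisymmetric phantoms the
z-integrand is a quadratic polynomial, so the composite-midpoint error
is below `1/(8 n_z^2)` — under 1e-6 relative at the default resolution,
which is the tolerance the test suite enforces. Ground-truth scar
fraction is the sector-weighted share of ED wall volume. Histology
measures scar on stained cross-sectional area rather than wall volume;
at phantom level the two are treated as equivalent, and the package
deliberately exposes only the volume-based definition.

### The cohort generator

The default cohort emulates the published envelope of the 4-week
post-ligation mouse: scar fractions drawn from a truncated normal with
mean 21.5% and SD 16.3% (the printed 4.07% dispersion is a standard
error over 16 hearts; multiplying by sqrt(16) recovers the SD), clipped
to the printed range 4–57%. Anatomy is jittered around R_ed = 2.2 mm,
L_ed = 6.8 mm, wall 0.8 mm — chosen so the truth EDV sits near the
~69 µL cine-CMR reference mean for this model — with remote radial
contraction 0.30 and longitudinal shortening 0.15, which give a healthy
EF near 60% and post-infarct EFs in the mid-40s.

Infarct geometry follows the proximal-ligation pattern: a long
anterolateral wedge growing from the apex. A single severity parameter
`lambda` scales both the apical extent (`1.4 lambda`, capped at 0.78 —
the basal rim stays functional, consistent with the hyperdynamic base,
and a scar frozen basal to the ES annulus would degenerate the
long-axis silhouette) and the angular width (`170 lambda` degrees,
capped at 360); `lambda` is solved per subject by 1-D root finding so
the phantom's true scar fraction matches the drawn target. Scars above
35% are made dyskinetic (large transmural scars bulge), the rest
akinetic. All draws happen inside a seeded stream: the same seed gives
a bit-identical cohort.

What the generator does *not* emulate: image texture and speckle,
respiratory/ECG gating imperfections, papillary muscles and
trabeculation, heart-rate differences between modalities (the in-vivo
CMR sessions ran ~100 bpm slower than echo — a physiological confounder
outside geometric scope), and operator tracing variability beyond the
explicit two-rater noise model. Passing tests therefore demonstrate the
geometric behaviour of the estimators, not their full in-vivo error
budget.

## Acquisition emulation

- **M-mode**: the internal diameter along a beam at fixed elevation and
  azimuth, `r(az) + r(az + 180)` per phase; LVID;d / LVID;s are the
  extremes of the trace. The default elevation is 0.65 L_ed: in a shape
  whose equator sits at the base, the mid-papillary reading level lies
  basal of the geometric midpoint, and this level also reproduces the
  published direction of the M-mode EDV bias (overestimation relative
  to CMR). Beam azimuth is a parameter — no azimuth is
  azimuth-independent once an infarct breaks axisymmetry.
- **Long axis**: the plane through the long axis at a chosen azimuth,
  sampled at `n` stations per side and joined at the apex. Stations are
  placed by a material map: columns inside the infarct keep their ED
  elevation, remote columns follow the global shortening, blended over
  a broad functional border zone (0.25 of the long axis, with a
  monotonicity safeguard). This is the speckle-tracking surrogate that
  makes the segmental strain of a frozen wall vanish instead of
  aliasing the base's descent into fake apical shortening.
- **Short-axis stacks**: slice centres every `step` mm from just below
  the apex to the *maximal* ventricular extent over the cycle, each
  slice a polygon of 360 vertices. Slices basal to the
  current-phase extent yield degenerate zero-area polygons — what a
  contourer produces when a basal slice shows no cavity at ES. (Running
  the stack only to the minimal extent instead would silently discard
  the basal 15–20% of ED volume of a shortening ventricle.) Defaults:
  0.2 mm steps for the 4D protocol; 1 mm thickness, 8 slices for the
  CMR protocol. A named `basal_truncation_z` scenario caps the stack to
  reproduce the "base is hard to visualise" underestimation.

## Estimators and their error budgets

Slice summation `V = sum A_i h_i` converges at second order in the
interior, but the basal endpoint slab contributes up to
`h * A_base / (2 V)` when the ventricular length does not divide the
step: about 5–6% at h = 1 mm on a 6.8 mm ventricle and a fifth of that
at 0.2 mm. The test suite asserts both the 1% (0.2 mm) and the 0.3%
(1 mm on a length the step divides) figures on the static phantom, and
the honest 6% bound on the moving default.

Monoplane Simpson finds the axis from the apex vertex to the midpoint
of the basal chord, then measures perpendicular chords at disk centres;
it is exact for solids of revolution up to disk discretisation (0.5% at
200 disks is enforced), and no accuracy claim is made off-axis — only
the bias-direction property that an out-of-plane akinetic sector makes
it underestimate ESV.

The Teichholz formula is dimensional (its 2.4 mm constant does not
scale), so even its EF is only approximately invariant under anatomical
rescaling; the tests budget 2 percentage points for that, and exact
scale-covariance for every slice- and disk-based estimator when the
acquisition grid scales with the anatomy.

ED and ES are chosen per modality from that modality's own extremes,
the way an operator picks frames; a `truth_phases` switch forces
oracle-aligned phases for convergence tests.

## Wall motion scoring

The three scoring levels sit 1, 3 and 5 mm above the apex (nearest
slice centre, ties toward the apex). Segment boundaries follow the
standard 16-segment layout: apical quadrants centred on the anterior,
lateral, inferior and septal walls; mid and basal sextants in the order
A, AL, IL, I, IS, AS. The auto-scorer grades relative excursion
`q = FE / FE_ref` with thresholds 0.55 (normal) and 0.20
(hypokinetic/akinetic/dyskinetic boundaries), plus a 10% ED-radius
bulge criterion for aneurysm; the reference excursion defaults to the
mean of the best-moving quartile of segments (the remote zone). The
thresholds are package-defined surrogates for visual grading — chosen
so a fully normal phantom scores all 1 and each phantom dysfunction
class maps to its nominal grade — and live in `wmsi_thresholds()`, not
in code.

## Strain

"Peak" strain is the signed extremum of largest magnitude over the
cycle (the sign convention makes contraction negative for longitudinal
and circumferential strain and thickening positive for radial strain).
The six longitudinal segments are equal ED-arc-length intervals tracked
through the material station map. The dyssynchrony index is the SD of
the six segmental peak strains; an SD over segmental time-to-peak would
be an alternative reading of "dyssynchrony", but with a single global
contraction profile all segments peak simultaneously, so peak-strain SD
is the informative choice here.

## Statistics

Bland-Altman differences are percentages of the pairwise mean,
`100 (B - A) / ((A + B)/2)`, test minus reference, with limits of
agreement at bias ± 1.96 SD (sample SD). Published uses of this layout
are inconsistent about the sign of the reported biases; the formula is
authoritative here. ICC is fixed to the two-way random-effects,
absolute-agreement, single-measure form ICC(2,1) =
`(MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))` — the standard
choice for "reliability of single measurements between two raters" —
and negative estimates are reported as computed. Spearman correlation
uses average ranks, a t approximation for n ≥ 10 and exhaustive
permutation below that, and the grading bands assign boundary values to
the higher band (0.5 → moderate, 0.7 → strong, 0.9 → very strong),
since the printed intervals overlap at their edges. The
D'Agostino-Pearson K² test uses the standard skewness and kurtosis
transformations with a chi-square(2) reference and refuses n < 20,
where the moment approximations are unreliable.

One published formula is knowingly corrected: the slice-area "EF"
equation as printed computes `ESV/EDV`, not an ejection fraction;
`EF = 100 (EDV - ESV)/EDV` is used for every modality.

## The in-silico study

`run_study()` chains cohort → emulation → volumetry → wall motion →
strain → statistics, with the emulated 1 mm CMR stack as the
Bland-Altman reference (structurally parallel to an in-vivo design
where CMR is the benchmark; a config switch substitutes truth). The
two-rater ICC simulation applies multiplicative noise
(`v (1 + b_r + cv ε)`, default cv 5%, rater-2 bias +2%) to each
modality's measurements. Problem sizes are n = 32 subjects at 20 phases
with 360-vertex polygons — comfortable desk-scale numbers that keep a
full study run in seconds while leaving slice quantisation, not polygon
resolution, as the dominant error. All tables embed an FNV-1a hash of
the serialised configuration; a rerun under the same master seed writes
byte-identical CSVs.

The qualitative finding the default study reproduces — and the
acceptance suite asserts — is the geometric one: after regional
infarction the Teichholz ESV bias against the CMR reference exceeds 20%
in magnitude and its EF bias is large and negative, while the 0.2 mm
stacked-slice estimator stays within a few percent on both; and the
noise-free WMSI tracks true scar fraction with Spearman rho ≥ 0.9. No
claim is made of reproducing in-vivo bias magnitudes: the animals'
raw data are not available, and the phantom's error budget is
geometric only.

## Known limitations

- The semi-ellipsoid family has its equator at the base; real
  post-infarct ventricles bulge mid-cavity, so the M-mode overestimation
  the phantom produces at the papillary level is smaller than the
  published in-vivo magnitude.
- The scar is transmural by construction; partial-thickness dysfunction
  (hypokinesis grade 2) arises only in blending zones.
- Segmental strain relies on the material station map, which is an
  idealisation of speckle tracking; tangential tissue motion within the
  imaging plane is not represented.
- The permutation Spearman p-value is exhaustive only below n = 10
  (9! evaluations); beyond that the t approximation is used.
- `icc_single()` requires complete tables and does not impute.
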