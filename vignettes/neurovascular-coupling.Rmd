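---
title: "Methods: homotopic connectivity, CBF and their coupling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: homotopic connectivity, CBF and their coupling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nvcoupling)
```

## The model

`nvcoupling` analyzes two co-registered resting-state modalities on one
symmetric voxel grid.

**Homotopic connectivity.** For a voxel $v$ with left–right mirror $m(v)$,
voxel-mirrored homotopic connectivity is

$$\mathrm{VMHC}(v) \;=\; \mathrm{atanh}\!\big(r_{v}\big), \qquad
r_v = \mathrm{corr}\big(x_v(t),\, x_{m(v)}(t)\big),$$

with correlations below a floor $r_0 = 0.2$ set to zero before the Fisher
transform. The floor suppresses weak, noise-driven correlations; floored
voxels *remain in the valid mask* (value 0) rather than being dropped,
because dropping them would change the group-mask composition from subject
to subject. The same value is assigned to $v$ and $m(v)$, so every VMHC
map is exactly mirror-symmetric — an invariant asserted by the test suite
on all outputs. Perfect correlations are clipped at $1 - 10^{-7}$ so the
Fisher transform stays finite (giving $z \approx 8.1$); series with zero
variance make the voxel invalid (NaN). The floor is applied on the $r$
scale, before the transform; the two orders differ only exactly at the
boundary.

**CBF.** Perfusion maps are quantified proportionally from
arterial-spin-labeling difference images,
$\mathrm{CBF} = s\,(\mathrm{control} - \mathrm{label})/\mathrm{PD}$, with a
single configurable scale `cbf_scale` (default 100) standing in for the
full kinetic model, whose acquisition-specific constants (labeling
efficiency, blood T1, post-label delay) are not inputs of this package.
Each map is then standardized by its gray-matter mean, making the
gray-matter mean exactly 1; all downstream group statistics operate on
standardized (and finally z-scored) maps and are invariant to the global
scale, so the proportional simplification does not affect them.

**Coupling.** Two indices quantify neurovascular coupling: (i) the
across-voxel Pearson correlation between a subject's CBF and VMHC maps
over gray matter — one scalar per subject; and (ii) the voxel-wise
CBF/VMHC ratio, the blood supply per unit of homotopic connectivity. The
spatial correlation is computed on the raw maps; being a Pearson
correlation it is invariant to affine rescaling, so z-scored maps give the
same value (asserted by test). The ratio divides the *original* values —
standardized CBF over Fisher-z VMHC, before map z-scoring — and a voxel is
valid only where VMHC exceeds `vmhc_floor` (default 0.05), which excludes
the floored-to-zero voxels from the denominator; without such a floor the
ratio is unbounded. Whether one divides raw-unit or standardized CBF only
changes the ratio map by a global factor, which the subsequent z-scoring
removes; we use standardized CBF as it is the form the pipeline carries.

**Group inference.** Metric maps (VMHC, CBF, CBF/VMHC) are z-scored within
gray matter — population (divide-by-$n$) standard deviation, a fixed
convention so tests are exact; at $10^3$–$10^4$ voxels the $n$ vs $n-1$
difference is negligible — and compared voxel-wise by an OLS GLM with a
group indicator (patient = 1) and nuisance covariates age, sex (F = 1),
education and lesion volume (0 for controls). Lesions enter twice: each
subject's own lesioned voxels are invalid and handled by per-voxel
listwise deletion (a voxel is fitted only if at least 3 subjects per group
remain), and voxels lesioned in more than 50% of the sample are removed
from the analysis mask altogether. The 50% fraction is computed over the
full sample by default — controls contribute empty lesion masks — with a
patients-only denominator available by configuration, since either reading
of "the sample" is defensible; both modes are tested. Voxel-wise p-values
are corrected by Benjamini–Hochberg FDR at $q = 0.05$. ROI analyses
average each metric over atlas regions (valid voxels only) and relate them
to behavior scores by Pearson partial correlation
($t = r\sqrt{(n-2-k)/(1-r^2)}$, $df = n-2-k$), with FDR applied per
metric–score family, not pooled across metrics.

Summary-level helpers reproduce demographics-table statistics from printed
group summaries: a pooled-variance two-sample $t$ from means/SDs/sizes,
and the uncorrected Pearson $\chi^2$ on 2×2 counts (the uncorrected form
is what published sex-distribution statistics conventionally report; the
Yates correction would give a different value).

## Preprocessing

The BOLD stream implements the standard resting-state steps that operate
on an already-registered grid: trimming of leading volumes (default 10, to
magnetization equilibrium) with motion-table rows trimmed consistently and
framewise displacement computed after trimming; Power-style FD,
$\mathrm{FD}_t = \sum_i |\Delta d_{i,t}| + R \sum_j |\Delta \theta_{j,t}|$
with $R = 50$ mm (the conventional sphere radius); nuisance regression on
the Friston-24 set (6 rigid-body parameters, their one-step lags, both
squared) plus optional extra regressors — tissue-signal regressors are
accepted as configuration but not defaulted, since the minimal defensible
nuisance set is the motion expansion; linear detrending followed by an
ideal FFT band-pass at 0.01–0.08 Hz (frequency bins outside the band
zeroed — the simplest filter whose pass-band is exact); and separable
Gaussian smoothing, $\sigma = \mathrm{FWHM}/(2\sqrt{2\ln 2})$ per axis in
mm converted to voxels, with kernels renormalized at volume edges so
constant maps are preserved. Regression precedes filtering, and smoothing
is last, for both modalities.

Two interactions are worth knowing. First, detrend-plus-band-pass is only
*near*-idempotent: a second application re-estimates a small linear trend
on the already-band-limited series; the relative change is at the
$\sqrt{2/d}$ scale for $d$ in-band dimensions (tested to be under 5% at
$T = 1024$). Second, nuisance regression removes up to 25 dimensions from
the series; on short acquisitions this visibly widens the sampling
distribution of the homotopic correlations (fewer effective degrees of
freedom), which is a property of the method, not of the implementation.

## The synthetic cohort

`simulate_cohort()` generates the study conditions the analyses are
modelled on: 19 patients with single left-hemisphere lesions and 22
controls, 180 BOLD volumes at TR = 2 s (the pipeline trims 10), 3 mm
isotropic voxels on a 36×40×36 grid whose left half is large enough to
hold lesions at the reference scale, an ellipsoidal gray-matter
compartment, and a symmetric 8-region atlas.

* **Homotopic correlation** is planted per mirror pair through a shared
  latent factor: $x_L = \sqrt{\rho}\,g + \sqrt{1-\rho}\,e_L$ and
  $x_R = \sqrt{\rho}\,g + \sqrt{1-\rho}\,e_R$ with independent
  unit-variance components, so the expected pair correlation is exactly
  $\rho$. All components are band-limited to the analysis band, so the
  pipeline's filter preserves the planted structure. Truth maps are drawn
  per pair on the Fisher-z scale — group mean 0.53 (controls) / 0.40
  (patients), spatial SD 0.40 clipped to [0.02, 1.8], i.e. correlations
  spanning roughly 0–0.9 as in real VMHC maps — then mapped through tanh.
  Each subject additionally receives a global z offset (SD 0.04 controls /
  0.10 patients, matching the between-subject spread of whole-gray-matter
  VMHC in the reference cohort); without true between-subject variation,
  any brain–behavior effect would ride on measurement noise alone and
  decorrelate as soon as VMHC is re-measured.
* **Lesions** are spheres (radius uniform on 20–26 mm) placed entirely in
  the left half; controls get empty masks. Lesioned voxels carry near-zero
  BOLD signal plus low-amplitude noise (infarct dropout), and the truth
  map of every pair touching the lesion is set to 0 — homotopic
  connectivity collapses when one member is infarcted. The spherical model
  is capped by what fits in the hemisphere (~82 mL), so simulated volumes
  average ~53 mL and cannot reproduce the long upper tail of real lesion
  distributions.
* **CBF** is planted against the subject's own (lesion-aware) truth map:
  $\mathrm{CBF} = \mu + s\,(b\,\tilde z + \sqrt{1-b^2}\,\varepsilon)$ with
  $\tilde z$ the standardized truth, $b$ the group coupling target (0.51
  controls / 0.44 patients) and $\mu$ = 45.8 / 43.8 mL/100 g/min, spatial
  SD 12. The expected across-voxel correlation with the truth equals $b$
  by construction; the *measured* coupling is attenuated a few percent by
  the sampling noise of VMHC at 170 volumes.
* **Motion** traces are Gaussian random walks (steps 0.02 mm / 4×10⁻⁴
  rad, per-subject amplitude factor) calibrated so the cohort mean FD
  lands near 0.096 mm; FD scales exactly linearly with the step sizes.
* **Behavior** (patients only, matching the reference design) is a linear
  function of the subject's measured ROI VMHC plus age and education
  terms plus noise, solved so the expected partial correlation equals
  `behavior_effect_r` (default 0.75), scaled to a 0–100 comprehension
  score and clipped. Patients carry extra ROI-level truth variation
  (z SD 0.15) so that true connectivity differences, not measurement
  noise, carry the effect.

Everything descends from one integer seed; a fixed seed reproduces every
generated artifact bit-exactly (asserted by test).

**What the generator does not emulate:** hemodynamic response functions,
ASL kinetics, spatial autocorrelation beyond the planted pair structure,
anatomically shaped lesions, registration error, or physiological noise.
Passing recovery tests therefore demonstrates that the *estimators and
inference machinery* are correct under the planted model — not that the
pipeline is robust to the artifacts of real acquisitions.

## Numerical and design choices

* Grids must have an even voxel count along the left–right axis; odd
  grids are rejected rather than special-casing a midline plane whose
  voxels would be their own mirrors with $r = 1$. The left–right axis is
  declared per grid (default axis 1, as in MNI orientation), not inferred
  from NIfTI headers.
* Voxel indices are 1-based throughout the R API; the mirror of
  coordinate $i$ is $n + 1 - i$.
* The study-specific symmetric-template step is represented by
  `mirror_average()`; nonlinear registration refinement is upstream of
  this package.
* Degenerate inputs have defined behavior: zero-SD maps z-score to all
  zeros with a warning; zero-variance coupling inputs give NaN with a
  warning; constant covariates are dropped from the design with a
  warning; rank-deficient designs error naming the collinear columns;
  zero pooled variance with equal means gives $t = 0$, with unequal means
  an error.
* Pipeline stages are pure functions of (inputs, config); re-running
  reproduces outputs exactly, which is why no content-hash caching layer
  was added — it would introduce state without changing any result.
* BH-FDR flags are computed via `stats::p.adjust(·, "BH") <= q`, which is
  identical to the step-up rule; the test suite checks this against a
  literal enumeration oracle.

## Problem sizes used for validation

The validation suite runs scaled-down versions of the study conditions,
chosen so each check exercises the full method at desk scale: oracle
equivalence on 4³ grids (tolerance 10⁻¹⁰ against a brute-force voxel
loop); planted-correlation recovery at the study's 170-volume series
length on 10×10×8 grids; coupling recovery over 50 independent 41-subject
cohorts on 14×16×14 grids with lesion radii 5–9 mm (preserving the
lesion-to-hemisphere fraction); 500 null simulations of 200 voxels for
FDR behavior; and behavior-effect recovery at n = 200. On strongly
scaled-down grids the 6 mm smoothing kernel would span a large fraction
of a hemisphere and mix signal across the midline — inflating homotopic
correlations near the mid-plane, a miniature of a real effect that is
modest at full brain size — so scaled validation runs disable smoothing;
the full-size default remains 6 mm.

## Limitations

The generator's planted effects are spatially white given the truth maps,
so cluster structure in the significance maps is not meaningful at small
grid sizes. The proportional CBF quantification cannot produce absolute
perfusion without external calibration. Lesion masking is binary; partial
volume effects at lesion borders are not modelled. The behavior model
links scores to one ROI; distributed effects across regions are not
planted. And the whole pipeline assumes all volumes are already in a
common symmetric space — spatial normalization, lesion in-painting and
segmentation are out of scope.
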