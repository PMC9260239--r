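# nvcoupling

Neurovascular coupling analysis of homotopic functional connectivity for
two-group (stroke patient vs. control) resting-state MRI studies.

## The problem

After a left-hemisphere ischemic stroke, language comprehension deficits
have been linked both to disrupted communication between mirror-symmetric
(homotopic) cortical regions and to disturbed coupling between neural
activity and regional blood supply. Testing such hypotheses requires a
pipeline that combines two imaging modalities on a common voxel grid:

* **VMHC** (voxel-mirrored homotopic connectivity): for every gray-matter
  voxel *v* with left–right mirror *m(v)*, the Pearson correlation of the
  preprocessed BOLD time series, floored at *r* = 0.2 to suppress
  noise-driven correlations and Fisher-transformed,
  *z(v) = atanh(r(v, m(v)))*.
* **CBF** (cerebral blood flow): arterial-spin-labeling perfusion,
  quantified proportionally from control − label difference images and
  standardized by the gray-matter mean.
* **Neurovascular coupling**: the across-voxel Pearson correlation between
  a subject's CBF and VMHC maps over gray matter (one coupling index per
  subject), plus the voxel-wise CBF/VMHC ratio map (blood supply per unit
  of homotopic connectivity).
* **Lesion-aware group inference**: voxel-wise GLM of patient vs. control
  differences controlling age, sex, education and lesion volume, with each
  subject's own lesioned voxels excluded, voxels lesioned in more than half
  the sample removed from the analysis mask, and Benjamini–Hochberg FDR at
  q = 0.05; ROI means and Pearson partial correlations link imaging metrics
  to comprehension scores.

Because the patient MRI data underlying such studies are not public, the
package ships a synthetic-cohort generator (`simulate_cohort()`) that
reproduces the statistical structure of a 19-patient / 22-control study —
planted homotopic correlations, planted CBF–VMHC spatial coupling
(0.44 patients vs. 0.51 controls), left-hemisphere spherical lesions,
motion traces and behavior scores — so every stage of the pipeline can be
validated against known ground truth.

## Worked example

Simulate a small cohort, compute one control subject's VMHC map and
CBF–VMHC coupling, and reproduce the demographics-table statistics shipped
with the package:

```r
library(nvcoupling)

cfg   <- sim_config(shape = c(14, 16, 14), n_timepoints = 170,
                    lesion_radius_mm = c(5, 9), seed = 7)
study <- simulate_cohort(cfg)
gm    <- study$gray_matter

vmhc <- compute_vmhc(study$bold[["con01"]], gm, threshold_r = 0.2)
vmhc
#> <vmhc_map: 1184 valid voxels, threshold r = 0.2, mean z = 0.626>

spatial_coupling(study$cbf[["con01"]], vmhc, gm, subject_id = "con01")
#> <coupling_result con01: spatial r = 0.490 over 1184 voxels>

stats <- cohort_table_stats()
sprintf("sex chi2 = %.3f, age t = %.3f, icv t = %.3f",
        stats$sex$chi2, stats$age$t, stats$icv$t)
#> [1] "sex chi2 = 1.610, age t = 1.379, icv t = 1.777"
```

The VMHC map holds Fisher-z homotopic correlations (this subject's
gray-matter mean is 0.626; the planted control-group level is 0.53 plus a
per-subject offset). The coupling result says this subject's CBF map
correlates at r = 0.49 with their VMHC map across 1184 gray-matter voxels —
recovering the planted control-group coupling of 0.51 up to measurement
attenuation. The demographics statistics reproduce the reference cohort's
printed values (χ²(1) = 1.610 for sex; t(39) = 1.377 and 1.776 for age and
intracranial volume, recomputed from rounded summaries).

The full pipeline — preprocessing (volume trimming, framewise
displacement, Friston-24 regression, 0.01–0.08 Hz band-pass, smoothing),
VMHC, CBF standardization, coupling, voxel-wise lesion-aware GLM with FDR,
ROI tables and behavior correlations — runs as one call:

```r
res <- run_pipeline(pipeline_config(simulation = cfg), out_dir = "results/")
```

A thin command-line wrapper with `simulate | preprocess | vmhc | coupling |
analyze | run` subcommands is in `inst/cli/nvcoupling.R`.

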