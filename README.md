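# wmhbullseye

White matter hyperintensities (WMH) — bright lesions on FLAIR MRI of presumed
vascular origin — impair cognition in ways that depend on *where* they sit.
The classic periventricular/deep dichotomy and plain lobar maps each capture
only half of that geography. The **bullseye parcellation** crosses the two:
every white-matter voxel gets a normalized ventricle-to-cortex distance

```
d(i) = dist_vent(i) / (dist_vent(i) + dist_cortex(i))        in [0, 1]
```

cut into four equidistant concentric layers `[0,.25) [.25,.5) [.5,.75) [.75,1]`,
which are intersected with nine lobar regions (frontal, parietal, temporal,
occipital x left/right, plus a bilateral basal-ganglia region), giving
**36 parcels** that exactly tile the white matter and basal ganglia.

This package implements the full analysis pipeline around that coordinate
system, for neuroimaging researchers who want a tested, reproducible
re-implementation they can run on their own masks — or validate end-to-end
with no data at all:

* **parcellation** — exact spacing-aware Euclidean distance transforms
  (compiled, Felzenszwalb–Huttenlocher), normalized distance, layer
  assignment, lobar intersection with nearest-region gap fill, conservation
  checks; minimal NIfTI-1 I/O.
* **quantify** — per-parcel WMH volumetry (mm³), head-size adjustment
  `WMH_ij * eTIV_mean / eTIV_i`, brain parenchymal fraction
  `BPF = supratentorial / eTIV * 100`, `ln(v + 1)` transform, per-region
  layer proportions and parcel medians.
* **components** — PCA on the 36-parcel correlation matrix, Horn parallel
  analysis (95th percentile of 500 simulated null eigenvalue curves) for
  retention, direct oblimin (quartimin) rotation, pattern/structure loadings,
  component correlations Φ, communalities, regression scores.
* **stats** — standardized cognitive domain composites, mass-univariate
  parcel models with Benjamini–Hochberg FDR (one 36-test family per domain),
  component models with variance inflation factors and 1000-resample
  bootstrap percentile CIs, age-tertile contrasts via a gamma GLM with log
  link, demographic correlations.
* **phantom** — a synthetic brain (nested ellipsoids + lobar wedges) and a
  cohort generator with a known 3-block latent structure, so that every
  stage above is testable against ground truth.

## Worked example

```r
library(wmhbullseye)

pb <- make_phantom_brain(shape = c(96, 96, 96))
bm <- parcellate_phantom(pb)
bm
#> bullseye_map: 96x96x96 grid, spacing 1x1x1 mm
#>   154880 parcellated voxels, 36 distinct parcels

co  <- simulate_cohort(n = 108, seed = 1)
tab <- log_transform(adjust_etiv(parcel_table(co)))
X   <- as.matrix(as.data.frame(tab)[, paste0("p", parcel_codes())])

parallel_analysis(X, n_sim = 500, seed = 1)
#> parallel analysis: retained 3 component(s)
#>   n = 108, p = 36, 500 simulations, 95th percentile
#>   first eigenvalues (observed | null): 11.75|2.49  3.40|2.25  2.81|2.09  1.45|1.97 ...

cm <- fit_components(X, k = 3)
cm
#> component_model: 3 oblimin-rotated principal components (n = 108)
#>   total variance explained (unrotated eigenvalues): 49.9%
#>   per component (unrotated): 32.6%, 9.5%, 7.8%
```

Three correlated components are retained, and their strongest structure
loadings (|loading| > 0.4 via `interpret_loadings(cm)`) recover the
generator's blocks: one temporal/juxtacortical set (`p24 p43 p53 p54 ...`),
one occipital set (`p82 p72 p83 ...`), one fronto-parietal periventricular +
basal-ganglia set (`p92 p32 p12 p42 ...`). Regressing the cognitive domain
scores on the component scores plus covariates (age, sex, education, BPF,
hypertension):

```r
scores <- co[, c("subject_id", "memory", "speed", "reasoning", "vocabulary")]
covs   <- co[, c("subject_id", "age", "sex", "education", "bpf", "hypertension")]
comp   <- data.frame(subject_id = co$subject_id, cm$scores)
res <- fit_component_models(scores, comp, covs, B = 1000, seed = 1)
res[res$domain == "memory" & grepl("^C", res$predictor), ]
#>  domain predictor     beta      t      p  vif bs_lower bs_upper  n
#>  memory        C1 -0.32265 -2.502 0.0146 1.60   -0.553  -0.0996 83
#>  memory        C2  0.00626  0.053 0.9579 1.32   -0.222   0.2241 83
#>  memory        C3 -0.13171 -1.058 0.2936 1.48   -0.349   0.1219 83
```

Here `C1` is the temporal/juxtacortical component; its β of −0.32 (bootstrap
95% CI −0.55 to −0.10, VIF 1.6) recovers the −0.34 effect the generator
injects on episodic memory through that block, while the other components are
null — the pattern the method is designed to expose. (The smaller −0.23
speed-of-processing effect is not always significant at the n ≈ 77
complete-case sample; that is a power statement, not a defect.)

An end-to-end run with all artifact CSVs (loadings, scores, eigenvalues,
associations, age-tertile contrasts, JSON sidecar):

```r
run_demo_pipeline("demo_out", seed = 1)
```

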