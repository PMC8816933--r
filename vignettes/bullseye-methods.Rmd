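---
title: "Methods: bullseye WMH parcellation and latent-component analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bullseye WMH parcellation and latent-component analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wmhbullseye)
```

## The model

White matter hyperintensities (WMH) are treated as a spatial process on the
cerebral white matter whose location carries information about etiology and
cognitive consequences. The bullseye coordinate system assigns every
white-matter (and basal-ganglia) voxel two coordinates:

1. a **normalized ventricle-to-cortex distance**
   \(d_i = D^{vent}_i / (D^{vent}_i + D^{ctx}_i)\), where \(D^{vent}\) and
   \(D^{ctx}\) are Euclidean distances (mm) to the ventricular and cortical
   masks — 0 at the ventricular surface, 1 at the cortex — cut into four
   equidistant layers \([0,.25), [.25,.5), [.5,.75), [.75,1]\);
2. a **lobar region**: frontal, parietal, temporal, occipital per hemisphere,
   plus one bilateral basal-ganglia region (codes 1–9).

Their intersection gives 36 parcels, coded `region*10 + layer` (11–94). The
parcellation is *conservative*: every domain voxel receives exactly one code,
so parcel voxel counts sum to the white-matter + basal-ganglia count. The
downstream analysis is (i) per-parcel volumetry with head-size adjustment and
a log transform, (ii) a PCA of the 36-parcel correlation matrix with Horn
parallel analysis and oblimin rotation to find latent WMH "distribution
types", and (iii) covariate-adjusted linear models linking parcels or
component scores to standardized cognitive domain scores, with BH-FDR and
bootstrap percentile intervals.

## Numerical and design choices

**Distance metric.** Distances are exact Euclidean, computed with the
separable lower-envelope transform, honoring anisotropic voxel spacing in mm
(FLAIR acquisitions often have ~4.5 mm slices). The source convention never
states voxel vs mm units; mm is the choice here because layer boundaries
would otherwise shift with slice thickness. Normalized distance, layers and
parcel codes are invariant to a global rescaling of spacing (ratios cancel);
this is tested.

**Layer boundaries.** Half-open intervals with a closed top layer, so
\(d = 0.25\) is layer 2 and \(d = 1\) is layer 4; every domain voxel gets
exactly one layer.

**Lobar gap fill.** Real lobar projections leave some deep white matter
unlabeled (e.g. corpus callosum). Unlabeled domain voxels take the region of
the nearest labeled voxel in mm; exact ties go to the lowest region code —
deterministic, and required by the conservation invariant. The gap-filled
voxel count is reported on the map object.

**Mask inconsistencies.** Domain voxels inside the ventricle or cortex masks
are excluded; if such overlap exceeds 0.1% of the domain the parcellation
aborts rather than silently reinterpreting inconsistent segmentations.

**Volumetry order.** eTIV adjustment (`v * eTIV_mean / eTIV_i`, with
`eTIV_mean` computed once over the full loaded sample) is applied before the
log transform, and the PCA consumes adjusted, log-transformed volumes. The
natural log with a +1 mm³ offset is used: zeros are frequent in sparse
parcels, the offset is recorded so the transform is invertible, and natural
logs keep regression coefficients interpretable per log-unit. Lesion volume
outside the parcellated domain is always reported as `unassigned`, never
redistributed; above 5% it warns.

**Parallel analysis.** Retention compares observed eigenvalues of the
correlation matrix against the 95th percentile, per eigenvalue position, of
500 simulated iid-normal datasets of the same n × p; components are retained
from the first position until the first non-exceedance. 500/0.95 are the
conventional defaults (the source method cites only the scree-comparison
idea); both are arguments.

**Rotation.** Direct oblimin with γ = 0 (quartimin), no Kaiser
normalization, implemented as oblique gradient projection (tolerance 1e-6 on
the projected gradient, max 1000 iterations, failure is an error with
diagnostics). Each component is sign-flipped so its largest-|loading| entry
is positive. Scores are regression (Thurstone) scores of the standardized
data; a symmetric pseudoinverse is used so duplicated variables degrade
gracefully. Because oblique components overlap, variance explained is
reported both from the unrotated eigenvalues (additive) and as sums of
squared structure loadings (non-additive, labeled as such); total
communality equals the sum of the retained eigenvalues and is unchanged by
rotation — a tested invariant.

**Association models.** Domain scores are re-standardized means of three
z-scored tasks (reverse-scored domains negated first); a domain score is
missing if any of its tasks is missing, and every model is complete-case.
The 36 parcel tests within one cognitive domain form one BH-FDR family (four
families total), matching how per-domain results are displayed in this
literature. Bootstrap intervals use case (subject) resampling — the
conservative default for observational covariate structures — with
rank-deficient resamples redrawn and counted (>10% redraws errors out).
Gamma GLMs (log link, IRLS, Pearson dispersion) compare WMH volumes across
age tertiles, with ties at a tertile cut going to the lower group.

## What the synthetic world is — and is not

`make_phantom_brain()` builds nested ellipsoids (ventricle, white matter,
cortex, intracranial sphere) with eight angular lobar wedges and two
para-ventricular basal-ganglia ellipsoids elongated toward the cortex so
that all nine regions intersect all four layers — the simplest geometry that
populates all 36 parcels. `seed_wmh_lesions()` grows lesions voxel-by-voxel
inside chosen parcels to *exact* target volumes, giving a round-trip oracle
for volumetry: exactness, not realism, is the goal.

`simulate_cohort()` generates log-scale parcel values from a k-factor model
(default k = 3) and exponentiates, so marginal volumes are lognormal — i.e.
right-skewed, as real per-parcel WMH distributions are. The default blocks
mirror the empirically reported aggregation: (1) fronto-parietal +
basal-ganglia periventricular, (2) occipital, (3) temporal + fronto-parietal
juxtacortical; dominant loadings are 0.7, and six peripheral parcels
(temporal layer 1, occipital layer 4, BG layers 3–4) load weakly (0.35),
reproducing the low communalities observed for exactly those parcels.
Factor correlations default to 0.45/0.60/0.45 with the strongest pair being
fronto-parietal–temporal, and are *preserved exactly* under the age and sex
injections: the base-factor correlations are solved so that the population
correlation of the final factor scores equals `factor_corr` (an earlier
draft added injections on top, silently inflating the strongest correlation
to ~0.62). Age correlates 0.41/0.20/0.37 with the three factors and men have
higher occipital scores (+0.36 SD); cognition is linear in factors and
covariates with Gaussian noise (memory loads −0.34 on factor 3, speed −0.23
on factor 1), and ~25–29% of domain scores are set missing per domain to
mimic realistic cognitive-battery attrition. Per-parcel log-median volumes
encode periventricular dominance everywhere except the occipital lobe
(layer 4 dominant); no published quantitative distribution exists, so these
are calibration-free choices fixed once.

The generator does **not** model MRI intensities, lesion texture or
morphology, task-level psychometrics, or nonlinear age effects. A green test
therefore establishes that the *pipeline* recovers known structure from data
with the stated statistical shape — not that any particular clinical result
replicates. Cohort-level figures from the motivating literature (e.g. "65%
of variance explained") depend on a private sample and an unstated variance
convention; the default synthetic cohort yields ~50% by the unrotated-
eigenvalue convention, and no test asserts the literature value.

## Reproducibility

One global integer seed feeds a named-stream RNG (`stream_seed()`): each
stage (phantom, lesions, cohort, parallel-analysis nulls, bootstrap) derives
its own sub-stream, so stages are independently reproducible and library
calls never disturb the caller's RNG state. Identical configuration + seed
gives byte-identical CSV/JSON artifacts; NIfTI outputs contain no
timestamps, so they are byte-identical too.

## Known limitations

* The NIfTI-1 reader/writer is deliberately minimal: 3D volumes, little-
  endian, common datatypes, diagonal-orientation sform; affines are carried
  through but never interpreted (all computation is voxel-space, shapes and
  spacing must agree across a subject's volumes).
* Only direct quartimin (γ = 0) rotation is implemented; other oblimin γ
  values error out explicitly.
* Hemisphere assignment comes from the lobar label volume as provided; the
  package never recomputes a midline.
* With n ≈ 108 and ~27% missingness, the weaker injected effect (speed,
  −0.23) is frequently non-significant in a single cohort draw; detection of
  the stronger memory effect is reliable. Power, not correctness, governs
  these single-draw outcomes.
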