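---
title: "Connectome anomaly mapping: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectome anomaly mapping: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcanomaly)
```

# The problem

Focal brain lesions such as glioblastoma perturb functional connectivity far
beyond their structural boundary, and the perturbation tends to follow the
*functional* organisation of the brain (network co-membership) more than
Euclidean distance. `fcanomaly` quantifies this with a patient-specific,
voxel-wise **anomaly score**: how far a voxel's connectivity profile has
drifted from what a normative control cohort shows at that voxel.

The pipeline, end to end:

1. **Connectome.** For each session, the voxel-by-voxel Pearson correlation
   matrix of the masked BOLD series, Fisher z-transformed
   (`compute_connectome()`). The diagonal is invalid by construction; a
   voxel's *connectivity profile* is its row without the self-entry.
2. **Reference.** The element-wise mean of the control connectomes on the z
   scale (`mean_reference()`).
3. **Similarity.** Per voxel, the cosine similarity between the individual
   profile and the reference profile after discarding negative entries of
   both (`similarity_map()`): 1 = identical positive connectivity pattern,
   0 = none shared.
4. **Baseline and score.** Per voxel, the median and raw MAD of the control
   similarities (`build_baseline()`); the anomaly score is
   `(similarity - median) / MAD` (`anomaly_score()`). Negative scores mean
   deteriorated connectivity; scores below -2.3 are treated as highly
   anomalous throughout.
5. **Tumour exclusion.** All voxels of any tumour tissue class or the
   resection cavity, grown liberally by Gaussian smoothing of the lesion
   mask (`smooth_tumour_mask()`, 3 mm FWHM, keep > 0.05 of peak), are
   removed from the patient *and* every control connectome, and the
   baseline is rebuilt on the reduced voxel set (`patient_anomaly()`).
   Scores therefore never reflect connections into structurally destroyed
   tissue, and each patient gets their own baseline.

Downstream analyses: functional-vs-spatial attribution of anomaly per
tumour voxel (`attribute_patient()`), bi-hemispheric network symmetry
(`network_median_anomaly()`, `symmetry_correlation()`), cerebellar
lesion-network mapping (`lesion_map()`, `lesion_anomaly_overlap()`),
longitudinal trajectories (`align_trajectories()`,
`fit_quadratic_trend()`), and voxel-wise prediction of recurrence location
(`new_tumour_voxels()`, `tumour_vicinity()`, `recurrence_test()`).

# Parameters that matter

| Parameter | Where | Default | Why |
|---|---|---|---|
| correlation clip | `compute_connectome(clip=)` | `1e-6` | keeps `atanh` finite when toy data contain perfect correlations |
| similarity space | `similarity_map(space=)` | `"z"` | profiles are compared as stored (Fisher z); `"r"` back-transforms first |
| MAD consistency | `build_baseline(consistency=)` | off (raw MAD) | scores are in plain MAD units, so the -2.3 threshold is a MAD-unit threshold; the 1.4826 normal-consistency factor is a switch |
| MAD floor | `build_baseline(mad_floor=)` | `1e-6` | zero-dispersion voxels become invalid, never infinite |
| exclusion FWHM | `smooth_tumour_mask(fwhm_mm=)` | 3 mm | liberal masking: at 3 mm spacing a single lesion voxel grows by its 6 face neighbours (kernel ratio 0.0625 > 0.05); the relative threshold 0.05 is exposed |
| anomaly threshold | attribution, overlaps | -2.3 | the "highly anomalous" cut used consistently across analyses |
| attribution subset | `attribute_patient(subset=)` | `"anomalous"` | correlations over highly anomalous voxels; `"all"` uses every valid voxel |
| lesion-map threshold | `lesion_map(threshold=)` | `atanh(0.25)` | a moderate normative-connectivity cut, swept in practice |
| overlap threshold grid | `lesion_anomaly_overlap()` | 1.5, 2, 2.3, 2.6, 3 | a range bracketing -2.3 for threshold-independent concordance |
| vicinity margin | `tumour_vicinity(margin_mm=)` | 10 mm | the 1 cm rim around the prior tumour/resection used as recurrence baseline |
| volume filter | `volume_filter(min_cm3=)` | 3 cm^3 | smaller new-enhancing labels are treated as potential segmentation error |
| permutation budget | `n_perm` everywhere | 10,000 | exhaustive enumeration is used automatically whenever the assignment count fits the budget |

Two conventions worth stating explicitly. *Distance orientation in
attribution:* both predictors are oriented as distances (functional
distance = 1 - |r| of the control-average connectome), so "anomaly follows
X" always means a **positive** Pearson correlation between X-distance and
the anomaly score over the anomalous voxels, and a voxel is labelled by the
larger positive correlation (exact ties and all-negative cases are
`"none"`). *Sessions are indexed*, not dated: 0 = pre-surgery, 1 = post,
2+ = follow-ups; a bi-monthly clinical cadence maps to one index unit.

The vicinity is a *rim*: the prior tumour/resection voxels themselves are
excluded from it, both because their scores are invalid by construction
(they are inside the exclusion mask) and because the comparison of interest
is emerging tumour against structurally intact surroundings.

# The synthetic cohort

Patient resting-state data of this kind are not publicly distributable, so
the package ships a generative stand-in that reproduces exactly the
statistical structure the analyses rely on — and nothing more.

**Phantom.** A rectangular two-compartment brain (`build_phantom()`):
cerebrum and cerebellum blocks, left/right hemispheres mirrored through the
midplane, and the seven canonical resting-state networks (VIS, SM, DAN,
VAN, LIMB, CON, DMN) assigned in *diagonal stripes* (`network = (j + k) mod
7`). Stripes make network membership spatially distributed and
mirror-symmetric, which deliberately dissociates functional proximity from
spatial distance — the estimand of the attribution analysis. Real networks
are patchier; the stripes are the minimal geometry with that property.
The default study phantom has 2,550 voxels at 3 mm spacing; a 728-voxel
"compact" phantom carries the same structure for multi-seed experiments.

**Signal model** (`signal_model()`). Voxel `v` of network `n` with
hemisphere channel `c`:

$$y_v(t) = \lambda\, s_n(t) + \eta\, h_{n,c}(t) + \sigma\, \varepsilon_v(t)$$

with all processes white standard normal. Cerebellar voxels use the
*contralateral* hemisphere channel, giving the crossed cerebro-cerebellar
representation. Same-network, same-channel voxels correlate at
$(\lambda^2+\eta^2)/(\lambda^2+\eta^2+\sigma^2)$, across channels at
$\lambda^2/(\lambda^2+\eta^2+\sigma^2)$. Defaults $\lambda=1, \eta=0.5,
\sigma=1$ give within-network correlations of 0.56 (same channel) and 0.44
(across), in the range seen in denoised voxel-wise resting-state data;
T = 300 volumes for calibration experiments, 150 for the multi-seed
recovery experiments. White signals are intentional: every analysis
consumes correlations only, so temporal autocorrelation would add nuisance
without exercising anything downstream.

**Lesions** (`lesion_spec()`). A lesion scales the *signal* loading of
affected voxels by $a_v = 1-\gamma p_v$ and replaces the removed variance
with fresh voxel noise, so per-voxel variance is preserved and only
connectivity changes. The proximity field $p_v$ is the generative ground
truth the analyses try to recover: network co-membership in functional mode
(optionally restricted to the tumour's hemisphere channel, optionally to
one compartment), $\exp(-d_v/\tau)$ in spatial mode. Generative proximity
is defined by *labels*, not by measured correlation, so recovery tests have
a known estimand. $\gamma = 0$ reproduces the control series bit for bit
under the same seed, which gives common random numbers across effect
sizes.

**Longitudinal schedules** (`longitudinal_schedule()`,
`demo_schedule()`). Ordered sessions pre → post → follow-ups, each with its
own segmentation and lesions. The demo schedule encodes the clinical arc
the analyses target: pre-surgical tumour ($\gamma=0.5$), transiently deeper
perturbation after surgery ($\gamma=0.8$ with the tumour replaced by a
resection cavity), recovery at first follow-up ($\gamma=0.2$), then a
*silent* recurrence: a ~27-voxel site near the cavity perturbed
($\gamma=0.8$, sharply localised) one session before it appears as
enhancing tumour in the segmentation. The site radius (5.3 mm) was chosen
by a power rule: the null AUC of the recurrence test has standard
deviation dominated by network-level noise shared within the site, and the
chosen size keeps twice that spread within the 0.5 +/- 0.15 chance band.
The site volume is far below the 3 cm^3 clinical filter because the whole
phantom is miniature; `run_pipeline()` exposes `min_cm3` so the demo can
state this honestly rather than silently pass the filter.

**What the phantom does not emulate.** Haemodynamics, temporal
autocorrelation, scanner noise, motion, physiological confounds, partial
voluming, registration error, and realistic network geometry. Passing
recovery tests on the phantom therefore shows that the *estimators recover
their estimands* under the assumed signal model — not that the method is
robust to the full noise structure of real fMRI.

# Calibration properties the experiments actually show

Three empirical properties of the score distribution, computed by the test
suite and the acceptance script, deserve emphasis because they are easy to
get wrong when interpreting anomaly maps:

* **The null lower tail is heavy.** Cosine similarity is bounded above by 1
  and estimation noise enters it quadratically (a low-degrees-of-freedom
  quadratic form in the voxel's own series noise), so the across-subject
  similarity distribution is left-skewed. In raw MAD units, lesion-free
  held-out subjects typically show 10-20% of voxels below -2.3 — far more
  than the ~1% a Gaussian intuition would suggest. The -2.3 cut is a
  working threshold for *ranking and contrasting* anomaly, not a calibrated
  false-positive rate; every inferential statement in the package goes
  through permutation tests instead.
* **Out-of-sample scores are shifted.** Control similarities are computed
  against a reference the controls themselves define, so any new subject —
  held-out control or patient — scores systematically lower (roughly
  -0.2 to -0.5 MAD units for whole-map medians under the defaults, with
  subject-level spread of similar size). Comparisons should therefore be
  *within* subject (across locations, thresholds, or sessions), which is
  how every analysis in the package is framed.
* **Bilateral symmetry has a null component.** With any bilateral network
  structure, the estimation noise of same-network correlations is shared
  across hemispheres through the realised network signal, so ipsi- and
  contralateral network medians co-move even in lesion-free subjects and
  the within-network (diagonal) symmetry correlation exceeds the
  cross-network one under the null. The lesioned-cohort recovery shows the
  excess *strengthens* with bilateral lesion propagation; observed symmetry
  should not be read as lesion-driven without that null in mind.

# Numerical and degenerate-input choices

* Correlations are clipped to |r| <= 1 - 1e-6 before `atanh`; averaging is
  done on the z scale (a config switch compares profiles on back-transformed
  r instead).
* All-negative clipped profile rows give an *invalid* similarity (`NA`),
  not 0 — cosine is undefined at the zero vector.
* Baseline voxels with MAD below the floor, or with fewer than 2 valid
  control values, are invalid; scores there are `NA`, never infinite.
* Exact ties in attribution (measure zero) are labelled `"none"` for
  determinism; a constant distance field makes that kind's correlation
  invalid.
* Permutation p-values use the (b+1)/(n+1) convention when sampled and the
  exact exceedance fraction (observed assignment included) when the
  assignment count fits the budget, so p is never 0; the
  contra-vs-ipsi overlap contrast returns p = 1 when the two hemispheres
  are exactly indistinguishable at every threshold instead of erroring.
* The voxel ordering of every masked array is the sorted linear index
  (column-major), so row k of any connectome refers to the same voxel in
  every volume of a study; grids must match bitwise.
* Session seeds of a longitudinal schedule are `seed + session`, keeping
  sessions independent and the whole sequence reproducible from one seed.

# Design decisions that were genuinely open

* **Raw MAD by default.** The score divides by the plain MAD with no
  1.4826 consistency factor, so -2.3 is "2.3 MADs", not "2.3 SDs". The
  factor is available as a switch but changes nothing qualitative: the
  heavy lower tail above is a property of the similarity distribution, not
  of the scaling.
* **Reference averaging on z.** Connectivity is z-transformed and then
  averaged; the alternative order (back-transform, then average) is exposed
  through the similarity-space switch rather than a second reference type.
* **Symmetry correlations across patients.** The symmetry r² is computed
  across patients on network medians (the table is patient-indexed); an
  across-voxel variant within networks would measure within-map texture
  instead of cohort-level symmetry and is not what the summary table
  contains.
* **Crossed-cerebellum experiment uses a compartment-restricted lesion.**
  With an unrestricted bilateral lesion, *secondary* anomaly — the
  similarity drop of unperturbed voxels whose profiles point at perturbed
  ones — saturates both cerebellar hemispheres at every threshold in the
  default grid, hiding the crossed signature. Restricting the perturbation
  to the tumour's hemisphere channel within the cerebellum isolates exactly
  the crossed representation the experiment is about.
* **The recurrence null schedule is fully lesion-free.** A null with
  residual follow-up perturbation (γ = 0.2) is confounded on the phantom:
  the recurrence site shares stripe networks with the residual lesion's
  reach, biasing the null AUC upward. The chance-level comparison uses an
  all-γ=0 schedule; the confounded variant is a property of the striped
  geometry, not of the method.
* **Attribution tumour voxels are enhancing + necrotic only**, the classes
  that define structural tumour presence; oedema and resection take part in
  the exclusion mask but not in per-tumour-voxel attribution.

# Known limitations

* The anomaly score is relative to a *specific* control cohort and
  acquisition; the out-of-sample shift above means absolute score values do
  not transfer across cohorts.
* Functional proximity uses the absolute correlation of the control-average
  connectome; it is a normative quantity and ignores patient-specific
  reorganisation.
* Distances are Euclidean in the common space; no geodesic or white-matter
  distance is offered.
* The phantom's problem sizes (728 and 2,550 voxels, 20-40 controls,
  T = 150-300) were chosen so the full study, tests, and acceptance
  experiments run in minutes on one core; real voxel-wise studies
  (~60,000 voxels) should use the block-streamed connectome path and will
  be dominated by the per-exclusion-set baseline recomputation.
* Recurrence prediction is evaluated against the *next* session's
  segmentation only, and white-matter-dominated recurrence is expected to
  evade a grey-matter connectivity score.
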