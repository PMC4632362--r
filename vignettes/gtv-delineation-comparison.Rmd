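---
title: "Comparing multimodality GTV delineations: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing multimodality GTV delineations: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In head-and-neck radiotherapy planning, the gross tumour volume (GTV) of an
oropharyngeal primary is delineated on whichever imaging is available — CT,
MR, combined CT-MR, or FDG-PET — and different modalities, and different
clinicians on the same modality, produce systematically different contours.
`gtvconcord` implements the quantitative machinery for such a comparison
study: a voxel-mask data model, six pairwise contour-concordance metrics
with their two-stage cohort aggregation, contrast-oriented adaptive
threshold PET auto-segmentation, mixed-effects volume models, and a
synthetic multi-observer study generator used to validate every stage in
the absence of patient imaging data.

## Data model

Masks are 3-D binary arrays on axis-aligned regular grids (`voxel_grid`:
dims, spacing in mm, origin at the centre of the first voxel). The physical
centre of 1-based voxel index $(i,j,k)$ is
$\mathrm{origin} + (\mathrm{index}-1)\cdot\mathrm{spacing}$. Oblique
orientation matrices are rejected at I/O: the analysis never needs them.
Masks compared by any metric must live on compatible grids (equal dims,
spacing and origin within $10^{-6}$ mm); masks delineated in another frame
(e.g. MR) are first resampled onto the common CT/PET frame through a
supplied rigid transform with nearest-neighbour semantics, which preserves
binariness. Resampling direction is fixed as MR $\to$ CT/PET; PET-CT is
acquired inherently co-registered.

## The six concordance metrics

For masks $A$, $B$ with intersection $I = |A \cap B|$ (voxel counts):

* conformity index $\mathrm{CI} = I / |A \cup B|$ (Jaccard). No formula is
  universally attached to the name "conformity index"; the Jaccard form is
  the standard choice that is strictly smaller than DICE whenever overlap
  is imperfect, which matches how the two indices behave in reported
  delineation studies.
* $\mathrm{DICE} = 2I / (|A| + |B|)$; algebraically
  $\mathrm{DICE} = 2\,\mathrm{CI}/(1+\mathrm{CI})$, an identity the test
  suite asserts on every computed pair.
* sensitivity index $= I/|A|$ and inclusion index $= I/|B|$: the
  directional containment fractions. In inter-modality tables the
  sensitivity index is the fraction of the first-named GTV inside the
  second, the inclusion index the fraction of the second inside the first.
* centre-of-gravity distance (CGD): Euclidean distance in mm between the
  unweighted centroids of the two masks' voxel centres.
* mean distance to conformity (MDC): over every voxel in the symmetric
  difference, the Euclidean distance to the nearest true voxel of the
  *other* mask, averaged. It is symmetric by construction and zero iff the
  masks coincide. We define it volumetrically (all non-overlap voxels, not
  only surface voxels); commercial tools do not document their variant, so
  the package states its own definition rather than claiming equivalence.

MDC uses an exact anisotropic 3-D Euclidean distance transform
(Felzenszwalb–Huttenlocher separable parabola envelope, implemented in
C++), validated against a brute-force nearest-neighbour search on random
small masks to $10^{-9}$.

### Aggregation

Inter-observer variability (per modality): all unordered observer pairs
per patient, per-patient metric means, then the cohort mean and SD across
patients — each patient weighted equally regardless of how many observer
pairs it contributed. Only the four symmetric metrics are reported here;
the directional indices are meaningless for unordered pairs.
Inter-modality comparison: for each ordered modality pair, the same
clinician's two masks are compared (pairs involving PET use the single
auto-segmented mask); clinicians missing either modality are skipped, with
no imputation.

## PET auto-segmentation

The contrast-oriented adaptive threshold is
$T = a \cdot \mathrm{mean70} + b \cdot \mathrm{BG}$, where
$\mathrm{mean70}$ is the mean SUV over tumour-ROI voxels at or above 70 %
of the ROI maximum, $\mathrm{BG}$ is the mean SUV of a background region,
and $(a, b)$ are scanner-specific coefficients from phantom calibration
(`calibrate_coefficients` fits them by least squares without intercept).
The comparison is inclusive ($\geq T$), a tie-break fixed by
configuration. The segmentation keeps the largest 26-connected component
by default, suppressing physiologic-uptake satellites; thresholding is
single-pass, not iterated. Background placement is not standardised, so
the package ships a convenience builder (`background_shell`): a shell of
configurable thickness at a configurable distance outside the tumour ROI.
The default coefficients $(a, b) = (0.44, 0.77)$ were produced by the
package's own calibration procedure on noiseless blurred-sphere phantoms
(radii 5–15 mm, tumour:background 4:1 and 8:1, 7 mm FWHM blur); on those
phantoms the calibrated threshold recovers sphere volumes exactly for
radii $\geq$ 6 mm and within one surface-voxel shell at 5 mm.

## Volume statistics

Volumes (cm³) are cube-root transformed before modelling — a volume is a
length cubed, and the transform brings right-skewed volume populations
close to normal; `normality_check` replaces visual Q-Q inspection with
the correlation between ordered sample values and normal quantiles
(default pass cut-off 0.95). The main model is a REML linear mixed model:
fixed effects modality and observer role, random intercepts for patient
and observer. Because PET contributes a single automatic contour per
patient, observer terms are unidentifiable when PET is included, so a
second model with fixed modality and a patient intercept only is fitted
for PET contrasts. Pairwise modality contrasts use Satterthwaite degrees
of freedom with unadjusted p-values, flagged at $\alpha = 0.02$ — the
stricter level compensating for the multiple models; per-patient SD
comparisons use one-way ANOVA with Tukey HSD at 95 % family confidence.
Per-patient SDs use the sample ($n-1$) denominator. Singular fits and
convergence messages are recorded in the result's diagnostics rather than
silently dropped. Unbalanced designs (incomplete MR/CT-MR contouring) are
fitted as-is; mixed models tolerate the missingness.

Two caveats are deliberate documentation rather than bugs. First, the
Tukey stage treats per-patient SDs as independent observations across
modalities, ignoring within-patient correlation. Second, if observer
noise genuinely differs between modalities (it does, by design, in the
generator), the homoscedastic mixed model is misspecified and the modality
contrast is mildly anti-conservative; the type-I calibration check
therefore uses a fully exchangeable null (equal multipliers *and* equal
noise amplitudes).

## The synthetic study generator

The generator (`study_config`, `generate_study`) emulates the structure
of an 11-patient oropharyngeal cohort: five observers (two radiologists,
three oncologists) contouring CT, MR and CT-MR, one auto-segmented PET
contour per patient, and realistic contour incompleteness (defaults: all
CT complete, 4/55 MR and 13/55 CT-MR missing). Everything is a pure
function of (config, seed); sub-streams are derived from patient,
modality and observer identifiers, so regeneration is bit-identical.

Each patient's base tumour is a superposition of 2–4 overlapping
ellipsoids, smoothed and carved to a volume drawn from a log-normal
distribution (median 11.5 cm³, log-SD 0.35 — chosen so cohort means sit
near 12 cm³ and extreme contours span roughly 2–35 cm³). Modality truths
are produced by moving the base surface along its signed distance field
until the volume matches the modality multiplier; defaults
(PET 0.80 < CT 1.00 < MR 1.07 < CT-MR 1.19) are the ratios implied by
reported cohort means, used as generator *targets*, not as claims about
any study's true parameters.

Observer contours follow a **two-scale model**, the central design choice
here. A binary mask on a 2 mm grid cannot express a sub-millimetre radial
offset locally — the smallest local boundary move is one voxel layer — but
its *total volume* can be set to sub-voxel precision by order-statistic
carving. So:

* **volume scale**: an observer's volume is the modality truth plus the
  equivalent-sphere surface area times (role bias + a normal radial error
  with per-modality SD `observer_amp_mm`). Defaults (CT 1.75, CT-MR 1.22,
  MR 0.74 mm; role bias ±0.6 mm) were solved analytically — including the
  small-sample chi bias of the SD estimator — so the expected per-patient
  SD column means land on the 4.47 / 3.71 / 2.49 cm³ reference values.
* **shape scale**: a smooth band-limited random field (Gaussian-smoothed
  white noise, 6 mm correlation length) with per-modality amplitude
  `observer_field_mm` displaces the surface locally; the mask is carved
  from (signed distance − field) at the order statistic matching the
  target volume. Defaults (CT 5, CT-MR 4.5, MR 4.2 mm) were calibrated so
  mean inter-observer DICE sits near 0.56 / 0.67 / 0.69 — the scale seen
  in multimodality delineation studies, with CT the least concordant.

The same radial parameters drive `generate_volume_records`, a fast
record-level generator (no voxelisation) used for statistical simulations
at hundreds of replicates.

One tension is worth recording: with a constant per-patient role offset in
a 2-radiologist + 3-oncologist design, a cohort role gap as large as
reported (≈ 1.5× volumes) would by itself inflate every modality's
per-patient SD beyond the MR reference value. The defaults prioritise the
SD targets (they drive the ANOVA stage) and keep the role effect
directionally correct at a ratio near 1.3.

The PET phantom renders background level plus contrast inside the PET
truth, convolved with an isotropic Gaussian (default FWHM 7 mm, the blur
scale of current PET scanners), plus optional Gaussian noise truncated at
zero. What the generator does **not** emulate: head-and-neck anatomy,
dental artefacts, attenuation/scatter physics, observer "gross error"
outliers, and inter-modality registration error (masks are generated in a
common frame). Tests passing on this generator therefore validate the
pipeline's arithmetic and statistical calibration, not clinical
performance on real images.

## Numerical choices and degenerate inputs

* Signed distances for carving carry a sub-voxel refinement term (a
  smoothed-indicator interpolation) because the voxel-centre EDT is
  quantized in steps of one spacing, which would make sub-voxel volume
  adjustment impossible.
* Empty masks: volumes are 0; all metrics and centroids refuse empty
  inputs with `"empty structure"`. Grid mismatches refuse with
  `"grid mismatch"`.
* Thresholds: `schaefer_threshold` rejects $T \le 0$ or
  $T \ge \mathrm{SUV_{max}}$ as degenerate; segmentation of an empty
  supra-threshold set is an error, not an empty mask.
* Zero-variance samples make the normality statistic undefined and error
  out; an all-equal SD table reports a degenerate ANOVA instead of an F
  statistic.
* Single-patient summaries report SD 0 with `n_patients = 1` rather than
  NA, so report shapes stay stable.

## Problem sizes

Default grids are $64^3$ at 2 mm isotropic — large enough for ~12 cm³
tumours with an 18 mm analysis margin, small enough that a full 11-patient
study (166 masks, ~630 pairwise comparisons) generates and analyses in
about a minute. Statistical calibration suites use the record-level
generator at 200 replicates; the phantom suite uses $48^3$ grids. These
sizes are the package's validation choices; all are configurable.
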