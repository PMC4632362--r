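# gtvconcord

Quantitative comparison of radiotherapy **gross tumour volume (GTV)**
delineations across imaging modalities — CT, MR, combined CT-MR and
FDG-PET — with full accounting for inter-observer variation.

Oropharyngeal primary tumours are notoriously hard to contour: CT soft-tissue
contrast is poor, MR sees the tumour edge better, and PET measures glucose
uptake rather than anatomy. A multimodality delineation study asks several
clinicians to contour the same patients on each modality and then quantifies
(a) how volumes differ by modality and clinician role, and (b) how contour
*positions* differ. `gtvconcord` is a tested, reusable implementation of that
whole analysis for R, driven either by real mask data (NIfTI or JSON masks
plus a CSV manifest) or by its own synthetic study generator.

## What it computes

**Geometry** — binary masks on regular voxel grids; volumes, centroids,
rigid-transform resampling onto a common frame; exact anisotropic 3-D
Euclidean distance transforms (C++).

**Six concordance metrics** for a mask pair A, B with intersection I:

| metric | definition |
|---|---|
| conformity index (CI) | I / \|A ∪ B\| (Jaccard) |
| DICE | 2I / (\|A\| + \|B\|) = 2·CI/(1+CI) |
| sensitivity index | I / \|A\| (fraction of A inside B) |
| inclusion index | I / \|B\| (fraction of B inside A) |
| CGD | distance between centroids (mm) |
| MDC | mean nearest-contour distance over the symmetric difference (mm) |

plus the study-style aggregation: per-patient means over observer pairs
(inter-observer) or same-clinician modality pairs (inter-modality), then
cohort mean (SD) across patients.

**PET auto-segmentation** — the contrast-oriented adaptive threshold
T = a·mean70 + b·BG (mean70 = mean SUV at or above 70 % of the ROI maximum,
BG = background mean), with least-squares phantom calibration of (a, b),
inclusive thresholding, and largest-26-connected-component post-processing.

**Volume statistics** — cube-root transformed REML mixed models
(fixed: modality + observer role; random intercepts: patient, observer;
observer terms dropped when PET's single auto contour is included),
pairwise modality contrasts flagged at α = 0.02, a quantile-correlation
normality check, per-patient × modality SD tables with column means, and
one-way ANOVA + Tukey HSD comparison of inter-observer SDs across
modalities.

**Synthetic studies** — a deterministic generator (11 patients, 2
radiologists + 3 oncologists, configurable modality volume multipliers,
two-scale observer noise, blurred PET phantoms, realistic contour
incompleteness) that gives every pipeline stage a ground truth. See the
methods vignette (`vignettes/gtv-delineation-comparison.Rmd`) for the model
and every default.

## Worked example

```r
library(gtvconcord)

study  <- generate_study(study_config(seed = 42))
report <- run_pipeline(study)   # optionally out_dir = "bundle" to write CSV/JSON
report
```

```
GTV delineation comparison report

Volume summary (cm^3):
  modality mean median mean_sd  max min  n
1       CT 13.2   12.4     5.1 40.7 0.1 55
2       MR 14.2   12.9     2.9 39.6 3.5 51
3     CTMR 16.0   14.6     4.3 50.8 4.9 43
4      PET 10.4    9.4      NA 24.6 5.0 11

Inter-observer SD column means (cm^3):
  CT   MR CTMR
5.14 2.90 4.31

Inter-observer concordance:
       metric comparison mean   sd n_patients
CT.1       ci         CT 0.41 0.09         11
CT.2     dice         CT 0.57 0.10         11
CT.3   cgd_mm         CT 4.63 1.54         11
CT.4   mdc_mm         CT 4.73 1.37         11
MR.1       ci         MR 0.55 0.07         11
MR.2     dice         MR 0.70 0.07         11
...
```

Reading this: the cohort contoured 55 CT, 51 MR and 43 CT-MR GTVs plus one
auto-segmented PET GTV per patient (the generator emulates incomplete
contouring). Mean volumes order PET < CT < MR < CT-MR; CT shows the largest
inter-observer volume SD (5.14 cm³) and the weakest overlap (mean
inter-observer DICE 0.57 vs 0.70 on MR). The mixed-model modality contrasts
are in `report$model_human$contrasts` / `report$model_pet$contrasts`:

```
    contrast estimate     se  df  p_value significant
2  CT - CTMR  -0.1870 0.0553 146 0.000929        TRUE
5   MR - PET   0.2347 0.0900 146 0.010010        TRUE
6 CTMR - PET   0.3181 0.0916 146 0.000675        TRUE
```

i.e. on the cube-root scale CT-MR GTVs are significantly larger than CT, and
PET GTVs significantly smaller than MR and CT-MR, at the α = 0.02 criterion —
the qualitative pattern such a study design is built to detect.

## Command line

A thin CLI over the same functions ships in `inst/cli/gtvpipe.R`:

```sh
Rscript inst/cli/gtvpipe.R run --out bundle --seed 1        # full pipeline
Rscript inst/cli/gtvpipe.R generate --out study --seed 1    # masks + manifest
```
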