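---
title: "Thigh muscle morphometry: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thigh muscle morphometry: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thighmorph)
```

## The measurement model

The package works on per-slice anatomical cross-sectional areas (ACSA) of
the ten thigh muscles that cross the knee: the four knee extensors (VM, VI,
VL, RF) and six knee flexors (BFlh, BFsh, ST, SM, SA, GR). Popliteus and
the gastrocnemii are deliberately outside scope. ACSA on one axial slice is
pixel count times in-plane pixel area; the default geometry is
0.508 × 0.508 mm pixels and 5 mm contiguous slices, and the emulated
segmentation protocol outlines every third slice (`sampling_stride = 3`).

Slice index 0 is the **most distal** slice; all longitudinal positions are
expressed as percent femur length (%FL), distal 0 % to proximal 100 %.
Femur length is the distance between the **centres** of the most proximal
and most distal slices in which femur appears: `(slices spanned − 1) ×
slice pitch`. Whether the underlying anatomical convention uses slice
centres or outer edges is ambiguous at ±1 slice thickness; the
centre-to-centre reading matches "distance between slices" most literally
and is what `measure_femur_length()` implements. A femur confined to one
slice degenerates to 0 mm and warns rather than erroring, because the
failure is in the data, not the request.

ACSAmax is the maximum sampled ACSA of a muscle. Ties are broken toward the
most distal slice — the tie-break only affects the reported argmax slice,
never the value, so any deterministic rule would do; distal was chosen to
match the slice-0-distal orientation. ACSAmax rather than muscle volume or
physiological CSA is the criterion size measure: it is not confounded by
femur length and needs no fibre-angle assumptions.

Labels are taken at face value: no partial-volume or non-contractile-tissue
correction is attempted. Missing inner slices of a muscle (absent on a
sampled slice between occupied ones) are recorded as absent, not zero; the
distribution grid interpolates across them.

## Derived quantities

Per subject: group totals are plain sums of member ACSAmax values; the
KF:KE ratio is the KF total over the KE total; proportional size is each
muscle's ACSAmax as a percent of **that subject's own** group total, so the
proportions in a group always sum to 100 %. Group-level means of the ratio
are means of per-subject ratios, matching the convention that cohort tables
summarize individual values; the ratio of group means coincides only
approximately, and arithmetic identities built on published group means use
ratio-of-means explicitly (as `scripts/acceptance.R` does).

Distribution curves express each profile as %ACSAmax against %FL and
interpolate it on the fixed grid 0, 5, …, 100 %FL. Interpolation is linear:
the minimal assumption, exactly reproducible by a two-point oracle, and
free of overshoot, at the cost of a small downward bias at the peak when no
sample lands on a grid position (bounded by the local slope times the grid
step — the tests assert that bound rather than exact 100 %). There is no
extrapolation: grid positions outside a muscle's measured extent are
absent, a first-class state, so cohort curves start and stop at muscle
boundaries and per-position group sizes shrink accordingly. Muscle samples
lying slightly beyond the femur landmarks are clamped to 0/100 %FL with a
warning — clamping keeps the grid domain fixed without inventing anatomy,
and the alternative (dropping the samples) discards real measurements.

## The statistical battery

* **t-tests**: pooled-variance Student's t by default, Welch by flag. The
  pooled form is the conventional reading of "independent samples t-test"
  and its df convention (n₁+n₂−2) matches the Cohen's *d* pooling below.
* **Cohen's d**: unsigned mean difference over the (n−1)-weighted pooled
  SD — the standard two-sample definition.
* **ANOVAs**: two-way sex × muscle (on ACSAmax and on proportional size)
  and sex × %FL position (per muscle). Muscles and positions are measured
  within subject, so the default design puts subject in the error stratum
  (`aov(value ~ sex * within + Error(subject))`): sex is tested between
  subjects, the within factor and interaction against within-subject
  variation. A purely between-cells variant is available
  (`anova_design = "between"`) for sensitivity analysis, since the original
  analysis structure is not fully specified. Sphericity is not corrected;
  the null simulations in the test suite generate compound-symmetric data,
  where the uncorrected test is exact. A within factor with one level
  degrades to the one-way between-sex ANOVA, whose F equals t².
* **Holm–Bonferroni**: step-down adjustment via `stats::p.adjust`. Families
  follow the analysis question: the ten absolute sizes form one family,
  each muscle group's proportional sizes form their own family, and the 21
  grid positions within one muscle form the family for the region scan.
* **Region scan**: position-wise sex t-tests on %ACSAmax, Holm-adjusted
  within muscle, maximal runs of adjacent significant positions merged into
  intervals. Positions where either sex has fewer than two supported
  subjects are skipped and can never belong to a region. α defaults to
  0.05, configurable.

## The synthetic cohort generator

The generator emulates the statistical structure the analysis assumes, not
images: per-sex per-muscle ACSAmax distributions, smooth longitudinal
shapes, and positive inter-muscle correlation.

* **Size distributions.** Defaults are the reference cohort statistics
  (`reference_cohort_stats()`): 32 males, 34 females, the published
  per-muscle means and SDs in cm².
* **Correlation.** One multiplicative subject-level size factor
  (`size_factor_sd`, default 0.08) is shared across a subject's muscles —
  the simplest mechanism that makes group totals and ratios realistic, as
  no covariance information is published. Its variance is carved out of
  each muscle's total CV (residual CV² = table CV² − size-factor²), so the
  **marginal** means and SDs still reproduce the configured table exactly.
  Because the shared factor cancels in the KF:KE ratio, the size factor
  also tunes the ratio SD; the default brackets the published 0.07–0.08.
  The true inter-muscle correlation is unknown — this parameter is a free,
  documented choice.
* **Shapes.** Each muscle's normalized curve is a unimodal scaled-beta bump
  with onset/offset/peak in %FL and concentration 4, normalized to 1 at the
  peak. The per-muscle supports place extensor bulk near mid-thigh and the
  VM/BFsh bulk distally — illustrative anatomy, not fitted curves.
* **Sampling and noise.** Profiles are the configured ACSAmax times the
  shape, sampled at every third 5-mm slice within the support, plus
  Gaussian measurement noise truncated at 0. The noise SD defaults to
  0.05 cm², in line with the ~0.4 % repeat-measurement variability of
  manual ACSA segmentation. Size draws are truncated at a positivity floor
  (0.1 cm²) by clamping, with a message when triggered — resampling would
  perturb the draw sequence and hence reproducibility.
* **Femur lengths.** Male 450 ± 20 mm, female 420 ± 20 mm — field-typical
  adult values; the source statistics do not publish them.
* **Rasterization.** For validating the mask path, each per-slice area can
  be drawn as a filled disk at 0.508 mm resolution on non-overlapping
  offsets; re-measurement recovers areas within the pixelation bound
  (perimeter × pixel diagonal).

What the generator does **not** emulate: real muscle boundary shapes and
their segmentation ambiguity, acquisition-block stitching, bias fields,
left/right or proximal anatomy beyond a femur landmark pair, and any
between-muscle correlation structure beyond the single shared factor.
Passing tests therefore validate the pipeline's arithmetic and statistical
calibration, not segmentation quality on real images.

## Numerical and edge-case conventions

* Degenerate inputs error early and specifically: all-zero profiles,
  missing group members (named), unknown muscle codes (with the offending
  CSV row), zero KE totals, fewer than two distinct interpolation support
  points, zero-variance equal-mean t-tests.
* Measurement tables serialize doubles at `%.17g`, so write → read → write
  is byte-identical.
* Reporting rounds to 1 dp for cm² and percent and 2 dp for ratios;
  stored values keep full precision.
* All simulation entry points take an explicit integer seed; a cohort is
  byte-reproducible from its seed.

## Problem sizes and what the suite establishes

The test suite runs null calibrations at 10,000 replicates for the t-test
and 5,000 for the ANOVA interaction (both checked against binomial
confidence bands at α = 0.05), 100 replicate cohorts at n = 32/34 for
parameter recovery, and a 300-replicate family-wise error check of the
Holm region scan. These sizes give binomial standard errors a few times
smaller than the tolerances being asserted while keeping a full run in a
few minutes on one core.

One power property deserves explicit statement. At the reference effect
sizes and n = 32/34, the probability that **every** per-muscle sex
comparison reaches p < 0.001 in one cohort is bounded by the weakest
muscle, VL:

```{r power}
# exact noncentral-t power for VL at p < 0.001, pooled design
n1 <- 32; n2 <- 34; df <- n1 + n2 - 2
sp <- sqrt((31 * 3.9^2 + 33 * 5.2^2) / df)
ncp <- (29.2 - 24.5) / (sp * sqrt(1/n1 + 1/n2))
crit <- qt(1 - 0.0005, df)
1 - pt(crit, df, ncp) + pt(-crit, df, ncp)
```

which is about 0.75, so the joint all-ten rate sits near 0.55–0.60 rather
than near 1. A published table in which all ten comparisons show
"< 0.001" is one realized dataset, not a statement of power;
`scripts/acceptance.R` reports the observed joint rate honestly instead of
asserting it high.

## Known limitations

* The ANOVA's sphericity handling and the exact post-hoc family definitions
  of the emulated analysis are conventions chosen here, flagged above;
  the `between` design flag exists precisely to probe that sensitivity.
* Importing spreadsheet supplements of published per-subject data is out of
  scope: their internal layout is not standardized. The canonical CSV is
  the interchange format; any adapter would be written against the actual
  files.
* Mask ingestion assumes one pre-merged label volume; stitching overlapping
  acquisition blocks is out of scope.
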