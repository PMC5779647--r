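# thighmorph

Sex differences in thigh-muscle morphology from MRI segmentations.

`thighmorph` quantifies knee extensor (KE) and knee flexor (KF) muscle
morphology from per-slice segmentations of axial thigh MRI: the maximal
anatomical cross-sectional area (ACSAmax) of each of the ten constituent
muscles, the summed KE and KF group sizes, the KF:KE size ratio (a
muscle-balance index analogous to the hamstrings/quadriceps strength
ratio), each muscle's proportional size within its group, and
femur-length-normalized mass-distribution curves. It then runs the full
sex-comparison battery — independent t-tests, mixed two-way ANOVAs,
Holm–Bonferroni post-hoc correction, Cohen's *d*, and contiguous
significant-region extraction along the femur — and ships a synthetic
cohort generator for validation and power exploration.

It is aimed at researchers in musculoskeletal imaging, sports medicine and
injury epidemiology (ACL injury and hamstring strain risk are the usual
clinical context for the KF:KE balance).

## The quantities

For one subject, with per-slice ACSA `A_m(s)` of muscle *m*:

- `ACSAmax_m = max_s A_m(s)` — the criterion measure of muscle size;
- group totals `KE = Σ_{m∈{VM,VI,VL,RF}} ACSAmax_m` and
  `KF = Σ_{m∈{BFlh,BFsh,ST,SM,SA,GR}} ACSAmax_m`;
- `KF:KE ratio = KF / KE`;
- proportional size `P_m = ACSAmax_m / group_total × 100 %`
  (each muscle against its own subject's group total);
- mass distribution: `A_m` expressed as %ACSAmax against position in
  %femur length (distal 0 % → proximal 100 %), linearly interpolated every
  5 %FL, never extrapolated beyond the muscle's measured extent.

Sex contrasts are reported as the female deficit relative to the male mean,
`(male − female) / male × 100 %`, with pooled-variance t-tests (Welch by
flag), Holm-adjusted p-values per analysis family, and Cohen's *d* with
(n−1)-weighted pooled SD.

## Worked example

```r
library(thighmorph)

# a synthetic cohort drawn from the package's reference statistics:
# 32 males, 34 females, correlated per-muscle ACSAmax, smooth profiles
cohort <- generate_cohort(cohort_spec(), seed = 1)

fit <- thigh_morphometry(cohort)
fit
#> thigh morphometry analysis: 32 male, 34 female subjects
#>   KE_total     male 92.5 +/- 10.0, female 72.6 +/- 7.6  (p = 2.89e-13, d = 2.26)
#>   KF_total     male 55.0 +/- 7.4, female 37.9 +/- 4.2  (p = 2.09e-17, d = 2.86)
#>   KF_KE_ratio  male 0.60 +/- 0.06, female 0.52 +/- 0.05  (p = 5.88e-06, d = 1.22)

round(coef(fit), 3)
#>      male_KE_total    female_KE_total      male_KF_total    female_KF_total
#>             92.476             72.559             55.001             37.894
#>   male_KF_KE_ratio female_KF_KE_ratio
#>              0.596              0.525
```

The males' summed extensor size (92.5 cm²) and the sex gap in the KF:KE
ratio (0.60 vs 0.52) recover the reference cohort values (93.6 cm², 0.59 vs
0.55) within sampling error at these sample sizes. `summary(fit)` prints
the full per-muscle table at display rounding; `plot(fit)` draws the
per-sex mean distribution curves with significant %FL regions shaded;
`simulate(fit)` draws new cohorts from the fitted statistics.

Mask-based inputs work the same way: read a NIfTI label volume plus a YAML
label sidecar with `read_label_volume()`, convert it with
`scan_from_volume()` (ACSA = pixel count × 0.508 × 0.508 mm², every third
5-mm slice), and pass the scans to `thigh_morphometry()` or
`run_pipeline()`, which writes the full CSV report bundle. A thin CLI over
these functions lives at `inst/scripts/thighmorph.R`
(`simulate` / `report` subcommands).

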