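# cestquant

Quantification pipeline for chemical exchange saturation transfer (CEST) MRI
of the brain, written for studies that compare small clinical groups (for
example cognitively impaired patients against matched controls) region by
region.

CEST imaging saturates exchangeable protons (hydroxyl ~1 ppm, amine ~2 ppm,
amide ~3.5 ppm from water) and reads out their dilute pools indirectly through
the water signal. The package takes a multi-offset volume series — 23 offsets
spanning ±6 ppm plus a far off-resonance reference volume (−1560 ppm) — and an
anatomical parcellation, and produces per-region metrics and group statistics
through two complementary quantification routes:

1. **MTR asymmetry.** Per voxel, the Z-spectrum `Z(Δω) = S(Δω)/S0` is
   cubic-spline interpolated (0.01 ppm grid), B0-corrected by moving the
   minimum of the spectrum to 0 ppm, and reduced to
   `MTRasym(Δω) = Z(−Δω) − Z(+Δω)` maps at 1, 2 and 3.5 ppm.
2. **Multi-pool Lorentzian fitting.** Per region, the voxel-corrected spectra
   are averaged (boosting effective SNR by ≈√N) and fit with a six-pool model

   `Z(Δω) = 1 − Σᵢ Aᵢ (Γᵢ/2)² / ((Γᵢ/2)² + (Δω − δᵢ)²)`

   for water, hydroxyl, amine, amide, aliphatic rNOE and the semisolid MT
   background, with bounded nonlinear least squares and pool centers
   constrained to ±0.01 ppm of their prior positions.

Around these sit rigid (6 DOF) motion correction with a mutual-information
registrar and zero-padded slab volumes, FreeSurfer-style ROI management
(bilateral merging, composite AD regions, ventricular exclusion, common-ROI
intersection across subjects), and exact small-sample Mann–Whitney U group
comparisons with report tables.

A seeded synthetic phantom generator (`phantom_spec()`, `generate_cohort()`)
emulates the acquisition geometry (2×2 mm² in-plane, 5 mm slices, 10 slices),
per-tissue pool ground truth, a smooth B0 field, Rician noise and scripted
per-offset motion, so the entire pipeline is testable without patient data.

## Worked example

```r
library(cestquant)

spec   <- phantom_spec()                       # default acquisition + tissue truth
cohort <- generate_cohort(spec, n_per_group = 4, seed = 1)
res    <- run_pipeline(pipeline_config(subjects = cohort, seed = 1))

subset(res$reports$mtrasym$rows,
       metric_name == "mtrasym_3.5" & roi_name == "Cerebral-Cortex",
       select = c(roi_name, u_statistic, p_value, ci_mean, cn_mean))
#>          roi_name u_statistic    p_value     ci_mean     cn_mean
#> 9 Cerebral-Cortex           0 0.02857143 -0.02788561 -0.01882625
```

The row reads as in a clinical report: in the cortical region the mean
3.5 ppm MTR asymmetry of the four CI subjects (−0.028) lies below that of the
four CN subjects (−0.019) with complete separation (`U = 0`), whose exact
two-sided p-value for a 4-vs-4 design is 2/70 ≈ 0.029 — the smallest p this
design can produce. The phantom's configured CI effect (amide and amine
amplitudes −20 %, hydroxyl +20 %) is what the pipeline is recovering here.

Per-region six-pool fits are in `res$per_subject[[id]]$fits`; each carries
fitted pool amplitudes, R², RMSE and residuals. `write_report()` emits the
TSV/JSON tables, `write_asym_maps()` the NIfTI maps.

A thin command-line wrapper ships in `inst/cli/cest-quant`
(`cest-quant phantom|run|fit-roi ...`).

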