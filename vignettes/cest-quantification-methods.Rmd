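---
title: "Quantifying CEST effects: models, corrections and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying CEST effects: models, corrections and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cestquant)
```

## The measurement and its model

Chemical exchange saturation transfer imaging applies off-resonance RF
saturation at a series of frequency offsets and records the attenuated water
signal. Normalizing each offset volume by the far off-resonance reference
(S0, acquired at −1560 ppm where no saturation transfer occurs) gives the
Z-spectrum `Z(Δω) = S(Δω)/S0`. Dilute exchangeable pools — hydroxyl near
+1 ppm, amine/guanidinium near +2 ppm, amide near +3.5 ppm, the relayed NOE
near −3.5 ppm — appear as shallow dips superimposed on the deep direct water
saturation at 0 ppm and the broad semisolid MT background.

The package quantifies these dips along two routes used side by side in
clinical pilot work:

* **MTR asymmetry**, `MTRasym(Δω) = Z(−Δω) − Z(+Δω)`, evaluated voxel-wise at
  1, 2 and 3.5 ppm. It is simple and robust but entangles the upfield pools
  (rNOE, MT asymmetry) with the downfield ones, which is why cortical
  MTR asymmetry at 3.5 ppm is typically *negative* in healthy tissue.
* **Six-pool Lorentzian decomposition** of the region-averaged spectrum,
  `Z = 1 − Σᵢ Lᵢ`, with `Lᵢ(Δω) = Aᵢ (Γᵢ/2)² / ((Γᵢ/2)² + (Δω − δᵢ)²)`.
  This separates direct saturation and MT from the exchange pools at the cost
  of a harder estimation problem.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| saturation axis | 23 offsets on [−6, 6] + ref −1560 | ppm | emulated acquisition |
| dense grid step | 0.01 | ppm | B0 estimate resolution |
| B0 search window | ±1.5 | ppm | excludes the ±3.5 ppm dips, tolerates realistic fields |
| S0 floor | 0.10 × robust max | — | masks non-tissue voxels before division |
| Z clip | 2 | — | guards division blow-ups at the mask edge |
| pool center bounds | prior ± 0.01 | ppm | stabilizes overlapping pools at 3 T spectral resolution |
| amplitude bounds | per pool, e.g. amide [0, 0.3] | — | physiological ranges |
| width bounds | per pool, e.g. water [1.5, 5], MT [15, 60] | ppm | see "Fit conditioning" |
| optimizer | bounded Levenberg–Marquardt, analytic Jacobian, ≤2000 evals, up to 64 deterministic starts | | see below |
| width shrinkage | 0.1 (relative prior sd) | — | empirical-Bayes variance control, see below |
| noise_sigma | 0.005 | fraction of S0 | plausible 3 T magnitude noise |
| B0 field amplitude | 0.3 | ppm | typical shim residue at 3 T |
| group effect (CI) | amide −20 %, amine −20 %, hydroxyl +20 % | | emulated disease contrast |

All pool priors ship as an editable YAML file
(`system.file("extdata", "pool_priors.yaml", package = "cestquant")`); every
bound can be overridden per study.

## B0 correction by the minimum of the Z-spectrum

Each voxel's sampled spectrum is interpolated with an interpolating cubic
spline onto a 0.01 ppm grid; the location of the minimum within ±1.5 ppm is
taken as the voxel's B0 offset, and the spectrum is re-evaluated on the
canonical grid translated by that shift (points leaving the sampled span
become missing rather than extrapolated, and are dropped from downstream
fitting). Ties resolve toward the smaller absolute shift; a flat window
returns 0 with a warning.

Two error sources deserve separate names, because they behave differently:

* **Sampling error.** With 23 samples (≈0.55 ppm spacing), the spline's
  minimum wanders by up to ~0.03–0.05 ppm around the continuous spectrum's
  minimum, depending on where the true shift falls between samples. This is
  intrinsic to minimum-of-Z correction at clinical sampling; the voxel-wise
  B0 map is therefore validated at a 0.05 ppm mean-absolute-error tolerance.
  When the estimator is instead given finely sampled spectra (0.1 ppm), its
  round-trip accuracy is limited only by the dense grid step (0.01 ppm), and
  that is how the estimator itself is validated.
* **Asymmetry bias.** The broad MT background is centered at −2.4 ppm, so the
  true minimum of a multi-pool spectrum sits slightly off 0 (≈+0.02 ppm for
  the default gray-matter truth). Any minimum-finder inherits this bias; it
  is common mode between groups and largely cancels in group contrasts, but
  it is the main reason ROI-fit amplitudes carry a small (≤ ~0.004) bias.

For voxel-wise processing the spline is applied as a precomputed dense-by-knots
linear operator (interpolation is linear in the samples for fixed knots), which
turns per-voxel interpolation into one matrix product per volume.

## Fit conditioning: why the width bounds are tight

With 22–23 usable samples and 18 parameters the six-pool model is nearly
degenerate along directions that trade water/MT width against the small-pool
amplitudes: at the spec's widest bounds the Jacobian's condition number is
~1.5 × 10⁵ and a 10⁻³ systematic distortion of the spectrum (exactly what
residual B0 miscentering produces) moves fitted hydroxyl/amine amplitudes by
~0.01 — comparable to the amplitudes themselves. Constraining widths to
literature-informed 3 T ranges (water [1.5, 5] ppm, hydroxyl [0.6, 2.5],
amine [1.0, 3.5], amide [1.0, 3.5], rNOE [2.0, 5.5], MT [15, 60]) reduces the
subject-to-subject amplitude scatter tenfold while keeping all default tissue
truths strictly inside the bounds. This mirrors the usual practice of tightly
constraining multi-pool fits at 3 T, where spectral resolution cannot support
free broad pools; the wide ranges remain available through the YAML prior for
high-field data.

The optimizer is bounded Levenberg–Marquardt with an analytic Jacobian
(numeric differencing leaves the fit stranded on a plateau about 10⁻⁶ above
the optimum; the analytic gradient reaches machine precision in ~10
iterations). Because overlapping broad pools make the objective multi-modal, fits that do
not reach a numerically zero residual restart from deterministic
low-discrepancy width vectors — each completed by solving the (linear)
amplitude subproblem — keeping the lowest objective found, which is also
guaranteed never to exceed the starting objective. On 200 random in-bounds
truths this multistart recovers every amplitude to machine precision, where a
single cold start strands roughly one fit in ten in a shallow local minimum. Fits are
performed on the corrected *sampled* offsets, never on the dense grid, to
avoid spline-induced residual correlation; a constant spectrum has undefined
R² and is flagged rather than scored.

Even with tight bounds, the maximum-likelihood amplitudes disperse well beyond
the local Cramér–Rao bound at low SNR because the widths absorb noise (the
bound for the hydroxyl amplitude at a 100-voxel average of 0.5 % noise is an
SD of ~0.0016; the raw fit scatters about three times wider). The final
estimate is therefore an empirical-Bayes MAP refit: the residual noise level
is estimated from the unpenalized fit and the widths are given a Gaussian
prior of 10 % relative sd around their starts, scaled by that noise estimate.
The penalty vanishes identically for noise-free data — exact-recovery
behavior is untouched — and halves the small-pool amplitude error at
pilot-study SNR.

## Motion correction

Each offset volume is zero-padded by two slices top and bottom (the
acquisition covers a 5 cm slab; through-plane motion needs headroom),
registered rigidly (6 DOF) to the equally padded reference under a
soft-binned (partial-volume) joint-histogram mutual information, and then
resampled once from the original unpadded data. Design points:

* **Seeding.** The MI surface has a spurious local optimum at exactly
  grid-aligned transforms (zero interpolation blur sharpens the histogram), so
  the optimizer is seeded by a coarse translation grid search plus per-axis
  rotation sweeps before any simplex runs.
* **Blur matching.** Resampling blurs the moving volume while the fixed stays
  sharp; that asymmetry displaces the raw MI optimum by up to ~0.5 mm.
  Refinement therefore runs on both volumes smoothed by σ = 0.7 voxels.
* **Regularization.** Through-plane rotations of a thin smooth slab are
  nearly unidentifiable (MI varies by ~10⁻³ over a degree). A quadratic
  penalty of 10⁻³ per deg² pins those flat directions toward zero motion
  while biasing well-determined parameters by well under a tenth of a voxel.

On phantom data this recovers scripted translations within ~0.15 mm and
in-plane rotations within ~0.4°. Through-plane rotation accuracy is limited by
the slab geometry itself and is not asserted; the same limitation applies to
any registrar given ten smooth slices.

## ROI statistics

Bilateral regions are merged by pooling voxels (the union of the left and
right label sets), so the merged mean equals the voxel-count-weighted mean of
the hemisphere means — and equals the mean over the mask actually used for
spectral averaging. An unweighted mean-of-means alternative would differ for
asymmetric hemispheres; pooling was chosen for that consistency. Composite AD
regions (medial/lateral temporal, lateral/medial parietal) are set unions of
their constituents. Ventricular labels are excluded by default (CSF pulsation
makes their spectra unreliable), and only ROIs present with at least
`min_voxels` voxels in every subject enter the analysis.

Group contrasts use the exact Mann–Whitney U test: `U = min(Uₓ, Uᵧ)` with the
exact two-sided p from the null permutation distribution whenever the samples
are untied and `n + m ≤ 16` (a 4-vs-4 design has 70 assignments; its smallest
two-sided p is 2/70 ≈ 0.029), otherwise a mid-rank normal approximation with
tie and continuity corrections. No multiplicity correction is applied by
default — appropriate for exploratory pilot designs — but Benjamini–Hochberg
adjustment is available, and its flagged set is always a subset of the
uncorrected one. Reports print p to three decimals; JSON keeps full precision.
Because the paper-style tables print the first group's one-sided U (0 or 16
under complete separation), `compare_groups(..., u_convention = "group1")`
reproduces that presentation; the default reports min-U plus a sign column.

## What the phantom emulates — and what it does not

The generator reproduces the acquisition geometry (2×2×5 mm voxels, 10
slices, 23 offsets ±6 ppm, reference at −1560 ppm), per-tissue six-pool
truths, a smooth B0 field (planar gradient plus Gaussian-filtered noise,
bounded at ±0.3 ppm), Rician magnitude noise parameterized as a fraction of
S0, optional scripted per-offset rigid motion, and a multiplicative CI/CN
group effect in the directions reported for cognitive impairment (lower amide
and amine, higher hydroxyl). Water-pool widths follow the direct-saturation
width implied by the stated saturation power (B1rms 1.2 µT ⇒ ≈3 ppm FWHM in
tissue). A two-pool Bloch–McConnell steady-state generator (CW at B1rms)
provides a non-Lorentzian oracle so fit quality is not assessed only against
the fit's own functional form.

It does **not** emulate realistic cortical anatomy (regions are ellipsoids
with FreeSurfer-style ids), partial-volume mixtures, spatially varying
coil sensitivity, physiological drift, or fat contamination (inputs are
assumed water-only). Passing tests therefore demonstrate correctness of the
algorithms under the stated noise/field/motion model, not clinical
performance on patient data.

Problem sizes used in the validation suite are deliberately modest — a
32×32×10 default grid (a scaled-down field of view), 16×16×4 or 12×12×4 grids
for replicated calibration studies, and 50–200 seeded replicates — chosen so
the full suite reruns quickly while keeping every estimate's Monte-Carlo error
well inside the asserted tolerances.

## Numerical conventions and degenerate inputs

* Offsets are processed in sorted order; acquisition order lives only in the
  JSON sidecar.
* Z values are clipped to [0, 2]; voxels with S0 below 10 % of its robust
  maximum (99th percentile) are invalid and propagate as missing, never as 0.
* B0 ties break toward smaller |shift|; flat spectra warn and return 0.
* Samples displaced outside the sampled span by correction are dropped, not
  extrapolated; maps whose corrected support no longer covers ±3.5 ppm are
  marked invalid at that offset.
* An all-zero reference volume, an empty ROI intersection, fewer usable
  samples than parameters, and registration of empty volumes are hard errors;
  a failing subject is flagged and the cohort continues with completers.
* All randomness (phantom fields, noise, cohort seeds) derives from explicit
  integer seeds; helper RNG use is isolated so library calls never perturb a
  caller's RNG stream.

## Known limitations

The 1 ppm (hydroxyl) contrast is intrinsically fragile: in MTR asymmetry the
configured hydroxyl increase is partially cancelled by the amine/amide
decreases acting on the same offset, and in the Lorentzian route the hydroxyl
amplitude sits on the water shoulder where estimation is least conditioned —
in MT-heavy white matter its group direction is below the method's resolving
power at the default effect size, while gray-matter regions recover it. The
minimum-of-Z asymmetry bias (~0.02 ppm) and the 0.55 ppm sampling jointly cap
per-voxel B0 accuracy near 0.03–0.05 ppm. Through-plane rotation recovery is
slab-limited. Exact Mann–Whitney p-values in a 4-vs-4 design are coarse
(multiples of 1/35 and 1/70); the smallest attainable p is 0.029, so "p <
0.05" and "complete separation" coincide for this design.
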