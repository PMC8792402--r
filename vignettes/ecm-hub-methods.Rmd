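---
title: "Methods: eigenvector-centrality hub mapping and its validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: eigenvector-centrality hub mapping and its validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecmhub)
```

## Scope and model

`ecmhub` analyses resting-state fMRI cohorts at the level of ROI time
series.  Everything upstream — realignment, normalisation, ICA denoising,
smoothing — is assumed done; the pipeline starts from a T × N matrix per
participant (T time points, N ROIs) plus a confound table, and ends with
hub sets, null distributions, and correlations between hub centrality and
visual-field scores.

The statistical model has four layers:

1. **Prewhitening.** BOLD noise is temporally autocorrelated; we model it
   as AR(1) per ROI.  Step one regresses the raw series on the six motion
   parameters (plus intercept) and estimates φ from the residuals by the
   lag-1 Yule–Walker ratio, clipped to [−0.99, 0.99].  The raw series are
   whitened by x′ₜ = xₜ₊₁ − φxₜ; step two regresses motion (rows 2..T),
   white-matter and CSF signals out of the whitened data.  Estimating φ on
   motion-filtered residuals avoids attributing motion-induced smoothness
   to the noise process.
2. **Connectivity.** Pearson correlation between ROI pairs, Fisher
   z-transformed.  The per-participant whole-brain summary is the mean
   off-diagonal z; the group comparison uses the difference of group
   medians under label permutation (medians follow the summary the
   analysis is defined on; a means flag exists).
3. **Centrality.** EC is the unit-norm leading eigenvector of
   A = r + 1.  The +1 shift makes A nonnegative, so the Perron–Frobenius
   theorem guarantees a unique nonnegative leading eigenvector for the
   strictly positive matrices that real data produce.  Hubs are ROIs whose
   group-mean EC reaches the 95th percentile across ROIs.
4. **Behavioral coupling.** WorseMD, BIVF and AbsDiffMD summarise per-eye
   total-deviation perimetry; Spearman correlation links them to hub EC.

## Key parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `percentile` (hubs) | 95 | EC percentile | "5% most central" hub convention |
| `n_perm` | 10,000 | permutations | permutation-p resolution ~1e-4 |
| `n_surrogates` | 1,000 | replicates | stable Gaussian fit of the null |
| `n_boot` | 1,000 | replicates | stable EC confidence intervals |
| `tol` (power iteration) | 1e-12 | max-norm | far below any decision threshold |
| AR clip | ±0.99 | — | keeps the whitening filter stable |
| r clip | 1 − 1e-15 | — | keeps atanh finite at |r| = 1 |

The permutation p-value uses the add-one rule, p = (1 + #{|null| ≥
|obs|})/(n_perm + 1): p is never zero and is valid at any n_perm.
Family-wise error across a hub family uses the max-statistic method; the
family is whatever one call tests (the hub set of one scan), deliberately
not all N ROIs.

## Numerical choices

* **Power iteration** starts from the uniform positive vector — inside the
  Perron cone, so convergence is monotone in angle — and stops when
  successive normalised iterates differ by < `tol` in max-norm.  The
  eigenvalue is the Rayleigh quotient.  Tests compare 131 × 131 random
  adjacencies against a dense symmetric eigensolver at 1e-8.
* **Diagonal convention.** The adjacency diagonal is set to 2 (r = 1,
  shifted).  EC(A) = EC(A + cI) exactly, so the convention is immaterial;
  the package asserts this numerically rather than assuming it.
* **Hub threshold.** Linear-interpolation percentile (quantile type 7),
  membership by EC ≥ threshold: ties at the threshold are included rather
  than silently dropped.
* **Whitening edge.** The first time point is dropped (T − 1 rows); at
  T = 260 the information loss is negligible.  A flag enables the
  stationarity-scaled first row √(1 − φ²)·x₁ instead.
* **iAAFT.** Each iteration imposes the original Fourier amplitudes, then
  rank-remaps onto the sorted original values; iteration stops when the
  rank order stabilises (cap 100).  Finishing on the value-remapping step
  makes the surrogate's value multiset *exactly* the original's, while the
  spectrum is approximate (< 5% mean relative periodogram error on AR(1)
  test series).  Surrogates are independent per ROI and participant —
  fresh random phases each — because their purpose is to destroy inter-ROI
  correlation.
* **Bootstrap.** One index vector per participant, applied to all ROI
  columns jointly, preserves the cross-ROI structure the statistic
  depends on.  Simple time-point resampling destroys autocorrelation; a
  moving-block variant (block length ⌈√T⌉) is available by flag.
* **Degenerate inputs.** Zero-variance ROI columns are a hard error in
  connectivity (they have no defined correlation) but a soft φ = 0 with a
  warning in AR estimation; constant series pass through iAAFT unchanged
  with a warning; score correlations with fewer than 4 complete pairs are
  marked not computable.

## Design decisions that were genuinely open

* **Per-ROI vs pooled φ.** The per-ROI estimator is the default (more
  general; ROIs differ in noise spectra); `pooled_phi = TRUE` averages φ
  across ROIs.  Step-two motion regressors re-enter raw (first row
  dropped), not whitened.
* **Group-level EC** is the per-ROI mean over participants of
  per-participant EC vectors, not the EC of the mean adjacency
  (`group_ec` flag switches).  Averaging vectors keeps each participant's
  centrality on the common unit-norm scale.
* **Permutation count** is interpreted per test, not per participant.
* **Hub union rule.** Hubs enter the correlation analysis by fulfilling
  the hub criterion in any group and any scan; a group-difference finding
  is annotated as replicated only when significant in both scans.
* **Eye alignment.** Visual-field maps are stored in visual-field
  coordinates (as on the instrument printout); the two blind-spot points
  (15° temporal, ±3°) are excluded by default.  MD is taken from the
  instrument export when supplied; the fallback `md = mean(td)` is flagged
  in the object, since instrument MD is a weighted, age-corrected summary
  we do not reproduce.  The 24-2/30-2 grids are generated in code from
  their row definitions.

## What the synthetic generator emulates — and what it does not

`sim_config()` defaults encode the study conditions: 131 ROIs in 7
networks, 260 volumes at TR 1.35 s, 24 controls and 20 patients, two scans
per participant, perimetry completed by 17 controls and 19 patients
(effective n = 36).  ROI j of a participant follows

x_j(t) = λ_j·s(t) + γ·c_net(j)(t) + confounds + e_j(t),

with unit-variance AR(1) latents and noise (φ = 0.3), λ_j = 0.9 for the six
planted hubs and 0.3 otherwise (ratio 3), and network loading γ = 0.25.
γ is set by covariance algebra: with γ = 0.25 a planted hub's correlation
with any non-hub (≈ 0.18 across networks) exceeds every non-hub pair's
(≤ ≈ 0.13 within a network), so "hub" is well defined unconditionally,
while larger γ would let within-network cohesion overtake hub coupling.
Patient severity ~ |N(3, 1.5)| attenuates hub loadings by the factor
(1 − 0.1·severity) and simultaneously drives the simulated fields
(td = −softplus(severity ± asymmetry/2 + spatial field), clipped to
[−32, 2] dB), so reduced centrality and worse binocular fields share a
common cause — the direction the analysis is meant to detect.  Two scans
share loadings but not noise, making hub test–retest reproducibility an
emergent, testable property.  `hub_strength = base_strength` is allowed
and yields an exchangeable null in which no ROI is preferred.

Not emulated: hemodynamic response convolution, image-level motion
artifacts, physiological (cardiac/respiratory) aliasing, spatial
autocorrelation between ROIs, non-stationarity, and realistic between-ROI
covariance beyond the low-rank factor structure.  Passing tests therefore
demonstrate that the *pipeline* recovers structure it is designed to
detect under its stated noise model — not that real BOLD data satisfy that
model.

## Validation problem sizes

The test suite and `scripts/acceptance.R` use: 50 random 131 × 131
adjacencies against the dense eigensolver (1e-8); 20 matrices for the
shift/scale invariances (1e-10); 500 null simulations × 1,000 permutations
for test calibration (type-I in [0.03, 0.07]); 200 replicates per
φ ∈ {0.2, 0.4, 0.6} at T = 260 for AR recovery (bias < 0.05, residual
lag-1 autocorrelation < 0.05); 40 AR(1) series for iAAFT spectrum
fidelity; 50 default-scale cohorts for planted-hub recovery (≥ 90%); and
100 cohorts per arm for severity-coupling detection (power ≥ 80% at
coupling 0.1, false positives ≤ 7% at coupling 0).  Pipeline determinism
is checked by byte-comparing the serialised results of two identical runs.
Null-distribution replicate counts in these runs are kept small (they
affect only the smoothness of the fitted Gaussians, not any pass/fail
decision), and the acceptance script scales the coupling arms to 50
cohorts each.

## Known limitations

* The AR(1) noise model ignores higher-order and spatially varying
  autocorrelation (no FILM-style local models).
* Voxel-wise ECM on full volumes is out of scope; the implementation
  operates on ROI-level adjacencies.
* Instrument MD is not recomputed from total deviation; synthetic maps use
  the flagged mean-TD fallback.
* The max-statistic FWE family is caller-defined; results are only as
  interpretable as the declared family.
* Real-data claims require real data: the generator validates the
  machinery, not the biology.
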