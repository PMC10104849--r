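---
title: "Spectral deviation mapping: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral deviation mapping: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specdev)
```

## The Spectral Deviation Index

Resting-state neurophysiological recordings, source-imaged onto a cortical
surface, yield a power spectrum at every vertex. Classical analyses pick a
frequency band in advance and map band-limited power; pathology that
reorganizes the *shape* of the spectrum across several bands at once is then
split across maps and penalized by multiple-comparison corrections. The
Spectral Deviation Index (SDI) instead asks, per patient and per vertex, how
dissimilar the patient's cross-frequency power profile is from each member
of a normative cohort:

1. correlate (Pearson) the patient's per-band power vector at a vertex with
   the corresponding vector of every control participant;
2. take the median of those correlations across controls;
3. variance-stabilize with the Fisher transform (`atanh`) and subtract from
   1:  `SDI = 1 - atanh(median r)`.

A patient whose spectral shape sits in the middle of the normative cloud has
a large median correlation and a strongly negative SDI; `SDI = 1`
corresponds exactly to a median correlation of zero, and larger values mean
greater deviation. The index is sign-invariant with respect to *which* bands
deviate — any reorganization of the profile lowers the correlations — which
is precisely what makes it sensitive to multi-band pathology, and also what
makes the follow-up attribution analyses below necessary.

Assumptions worth stating: subjects must share a vertex space (maps are
projected to a common template upstream); Pearson correlation over a 4-point
band profile is dominated by the highest- and lowest-power bands, so band
definitions matter; and the median over controls makes the reference robust
to outlying control spectra but assumes the control cohort is itself
demographically matched.

### Variants and degenerate cases

* **Band-averaged vs dense.** The default profile is the four canonical
  bands (delta 2–4, theta 5–7, alpha 8–12, beta 15–29 Hz, all edges
  inclusive). `dense_sdi_map()` applies the same recipe over every frequency
  bin in a range (85 bins for 2–30 Hz at 1/3-Hz resolution); the two agree
  in rank ordering across the cortex on smooth cohorts, which the test suite
  checks with Spearman correlations. A 4–7 Hz theta variant found in parts
  of the literature is available via `canonical_bands(theta_lo = 4)`.
* **Raw vs log power.** Correlations are computed on raw power by default;
  `log_power = TRUE` correlates log10 power. Raw power weights the profile
  toward high-power bands, log power treats relative changes symmetrically.
* **Clamping.** Correlations are clamped to ±(1 − 1e−6) before `atanh`, so
  a patient identical to every control yields a large negative but finite
  SDI; clamp events are counted in the output.
* **Zero variance.** A control profile with zero variance has an undefined
  correlation and is excluded from the median (an undefined correlation is
  not evidence of similarity); a zero-variance patient profile produces a
  missing SDI, which propagates with pairwise exclusion.
* **Median convention.** Midpoint interpolation for even control counts;
  output is invariant to control ordering.

## Welch spectra and orientation handling

`welch_psd()` averages Hann-tapered, 50%-overlapping modified periodograms
(one-sided density scaling) within and across epochs; 3-s windows give the
1/3-Hz grid the dense SDI expects. The choice of taper and normalization
follows common practice; a Parseval check against the variance of white
noise is part of the test suite. Unconstrained source orientations are
collapsed with the RMS norm across the three orientation spectra
(`orientation_rms()`).

## Vertex-wise inference: GLM, TFCE, permutation FWE

Maps are related to behaviour with an ordinary least-squares model per
vertex (covariates such as age partialled out), then corrected for multiple
comparisons with Threshold-Free Cluster Enhancement:

`enhanced(v) = Σ_h extent(v, h)^E · h^H · dh`, summed over thresholds
`h = dh, 2dh, … ≤ stat(v)`,

with the conventional exponents E = 1, H = 2. Family-wise error is
controlled by a max-statistic permutation null using the Freedman–Lane
scheme (reduced-model residuals are permuted and re-added to the reduced
fit, so covariate structure is preserved under the null); the smallest
attainable p is `1/(n_perm + 1)`.

Numerical choices:

* `dh` defaults to `max(|t|)/100` of the *observed* map and is reused for
  every permutation, so enhanced values are on one scale. The closed-form
  checks in the tests use `dh = h_max/1000`, where the discrete sum is
  within 1% of the analytic integrals (`h³/3` for an isolated vertex,
  `n·h³/3` for a uniform fully connected graph).
* Two-sided t maps are enhanced separately for each sign on the shared `dh`
  and recombined; the permutation max pools both signs.
* The enhancement sweep is implemented in C++ with an incremental
  union-find over descending thresholds (cost `O(V·levels + E α(V))`), and
  is checked exactly against a brute-force connected-component oracle in R.
* Clusters are connected components of vertices with `p_FWE < α`; each
  cluster's p-value is its smallest vertex p, and its peak vertex carries
  the largest |t| (ties break to the lowest index). A secondary Bonferroni
  correction across models (`bonferroni_secondary()`) is applied when
  several band-wise models test overlapping hypotheses.
* Degenerate fits with zero residual variance are capped at |t| = 1e6 and
  counted rather than propagating infinities.

## Seeded connectivity: orthogonalized AEC

Whole-cortex functional connectivity from a seed vertex uses amplitude
envelope correlations with pairwise leakage removal: per epoch, both signals
are band-passed; each is orthogonalized with respect to the other by
least-squares removal of the partner's band-limited signal (both
directions); Hilbert envelopes of the results are Pearson-correlated; the
two directions are averaged and then averaged across epochs. Orthogonalizing
in both directions and averaging makes the measure symmetric, and zero-lag
linear leakage cancels by construction — identical signals score exactly 0,
and independent signals are unbiased around 0.

Implementation choices: the band-pass is a zero-phase frequency-domain
filter with raised-cosine transitions (0.5 Hz by default), chosen over IIR
designs because narrow low-frequency bands at typical sampling rates make
forward–backward Butterworth filtering numerically fragile; 0.25 s at each
epoch edge is discarded before envelope correlation to absorb filter and
Hilbert transients; envelopes are correlated raw by default with a
log-envelope option. Orientation reduction (e.g., first principal component
of the three source orientations) is assumed done upstream; the module takes
single-orientation epochs.

## Model comparison, mediation, reliability

* **AIC.** `fit_lm()` fixes the Gaussian AIC convention explicitly
  (`n·ln(2π·RSS/n) + n + 2(k+1)`, residual variance counted as a
  parameter — numerically identical to `stats::AIC()` on the same fit), so
  ΔAIC between models on the same cases is convention-independent.
  `|ΔAIC| > 2` is flagged as meaningful. `delta_aic()` refuses to compare
  fits on different complete-case subject sets.
* **Leave-one-band-out attribution.** `loo_band_contribution()` recomputes
  the SDI at a peak vertex once per band with that band excluded, refits
  `outcome ~ SDI + age`, and reports `AIC(leave-one-out) − AIC(full)`.
  A caveat discovered during validation and reproduced reliably in
  simulation: with only four profile points, *every* band carries
  mechanical leverage in the Pearson correlation, so bands that carry no
  deviation still often show ΔAIC > 2 — removing them inflates the
  correlation noise of the recomputed SDI by roughly 4/3 in variance, and
  at n ≈ 60 even a ~0.01–0.03 drop in the outcome correlation converts to
  2–8 AIC units. Driving bands separate clearly from inert ones in rank and
  magnitude, but the inert bands' ΔAIC should not be expected to stay below
  the |2| cut-off; interpretation should lean on the ordering, not the
  absolute threshold.
* **SDI vs band-limited models.** `compare_sdi_vs_bandlimited()` contrasts
  `score ~ SDI + age` against `score ~ delta + theta + alpha + beta + age`
  per parcel; negative ΔAIC favours the more parsimonious SDI model.
* **Mediation.** `mediate()` decomposes a total effect into a direct path
  and an indirect path through a mediator using linear models and a
  non-parametric case-resampling bootstrap (percentile CIs; two-sided
  p = 2·min(P(boot ≤ 0), P(boot ≥ 0))). For linear models
  `total = ADE + ACME` holds exactly on any dataset, which the tests assert
  to 1e−10. Percentile intervals for a product of coefficients are known to
  be conservative when exactly one path is null, so null-calibration
  coverage sits slightly above the nominal 95%.
* **Reliability.** `icc_ck()` implements the two-way random-effects
  consistency ICC for the mean of k raters,
  `(MS_items − MS_error)/MS_items`, with Shrout–Fleiss F-bounds for the
  confidence interval; constant rater offsets do not reduce it.

## Acoustic speech features

The dysarthria-oriented features operate on pulse/formant tables rather than
raw audio (pitch and formant extraction is delegated upstream): local jitter
and shimmer (mean absolute consecutive-cycle difference over the mean,
within voiced segments), pitch SD over voiced cycles, HNR from normalized
autocorrelation peaks (`10·log10(r/(1−r))`), and a vowel-space proxy, the
product of the F1 and F2 inter-quartile ranges. A voice-quality composite is
the first principal component of HNR/jitter/shimmer on the correlation
matrix (the three features have incommensurate units), sign-oriented so
jitter loads positively. Rating tables are aggregated sentences-first, then
raters, with the intermediate patient × rater matrix exposed for the ICC.

## What the synthetic cohorts emulate — and what they do not

`gen_cohort()` draws control spectra as `f^(−χ)` aperiodic backgrounds plus
Gaussian band peaks, with four variability scales chosen to mimic a
demographically matched adult MEG cohort after identical preprocessing:

| parameter | default | role |
|---|---|---|
| `chi_range` | U(1.08, 1.22) | subject-mean aperiodic exponent |
| `chi_spatial_sd` | 0.05 | regional fluctuation of the exponent per vertex |
| `subj_sd` | 0.08 (log) | between-subject band-peak amplitude jitter |
| `vertex_sd` | 0.05 (log) | per-vertex, per-band measurement noise |

The regional exponent term matters: if subject-level spectral shape were a
single global factor shared by every vertex, permutation null maps would be
near-uniform over the cortex and the extent term of TFCE would enhance them
into degenerate whole-surface clusters. Real cortical 1/f slope varies
regionally; modelling that restores spatially local null behaviour.

Patients deviate only inside a target vertex set, where band power is scaled
by `1 + severity · effect_b` with one severity scalar per patient
(N(1, 0.5) truncated to [0, 1.8]; the truncation keeps the multiplicative
form positive). The default effect pattern is a "spectral acceleration" —
power moves out of delta/theta (−0.45, −0.2) into alpha/beta (+0.2, +0.9)
per unit severity. A synthetic impairment rating is
`severity + 0.02·age + N(0, 0.3)`, with age ~ N(66, 8) echoing the
demographics of a late-onset movement-disorder cohort. One non-obvious
property fixed during generator design: a deviation that merely amplifies
the profile's dominant band *increases* patient–control correlations
(stretching a profile along its principal axis raises Pearson r), producing
negative rather than positive SDI contrast; the default pattern weights the
low-power beta band strongly so that deviations genuinely decorrelate.

What the generator does **not** emulate: forward-model field spread and its
distance-dependent leakage, spatially smooth measurement noise, artifact
residuals (cardiac, ocular, movement), medication effects, non-Gaussian
severity distributions, and any nonlinear severity–outcome mapping.
Passing recovery tests on these cohorts therefore demonstrates that the
statistical machinery is correct and calibrated under its own assumptions —
not that effect sizes of real cohorts are attainable.

`gen_coupled_series()` produces band-limited noise carriers whose amplitude
is modulated by `exp(coupling · m(t))` with a shared slow (< 0.6 Hz)
modulator inside coupled pairs; `gen_mediation()` and `gen_ratings()`
produce linear mediation triplets and item × rater tables with known ground
truth.

## Problem sizes used by the test suite

The validation suite runs end-to-end at deliberately chosen scales: SDI
oracle equivalence on 50 random micro-cohorts; localization recovery on 20
cohorts of 60 patients / 60 controls over 2000 lattice vertices with a
50-vertex target patch and 200 permutations; family-wise error calibration
on 500 global-null cohorts (40/40 subjects, 200 vertices, 200
permutations); AEC calibration on 40 seeded runs of 80 epochs; mediation
calibration on 200 null and 100 full-mediation replicates at 500–1000
bootstrap draws. These sizes keep the full suite under ten minutes on one
core while leaving each Monte-Carlo estimate enough replicates to be
meaningful.

## Known limitations

* The SDI depends on the band scheme; four points is the minimum that makes
  a correlation-based profile metric workable, and attribution at that
  resolution is coarse (see the leave-one-band-out caveat above).
* TFCE p-values are exchangeability-based; heavy spatially structured
  confounding that differs between high- and low-outcome subjects is not
  protected against.
* The AEC implementation removes zero-lag leakage only; residual common
  input at non-zero lags is untouched.
* `mediate()` assumes linear, homoscedastic paths and no
  exposure–mediator interaction; sensitivity analysis for sequential
  ignorability is out of scope.
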