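---
title: "NIRS calibration methods in nirbean"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{NIRS calibration methods in nirbean}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirbean)
```

# The problem

Near-infrared reflectance spectroscopy infers the composition of a
ground flour from the overtone and combination absorptions of C–H, O–H
and N–H bonds between 400 and 2490 nm. A NIRS calibration for a trait
(protein %, starch %, phytate %, ...) is a regression of laboratory
reference values on preprocessed log(1/R) spectra. For underutilised
pulses such as rice bean and adzuki bean, a working calibration replaces
assays that cost hours and enzymes with a 90-second scan, which is what
makes germplasm-scale screening feasible.

`nirbean` implements the full calibration loop — preprocessing, modified
PLS regression, factor selection, outlier elimination, validation
statistics, and exhaustive preprocessing search — together with a
synthetic spectra generator so that every stage can be tested against
known ground truth.

# Spectra and conventions

Spectra are absorbance-like values, log10(1/R), on a shared regular
wavelength grid; the default grid (400–2490 nm, 2 nm steps, 1046
points) matches scanning-monochromator instruments. Reflectance is
accepted only at import (`reflectance_to_absorbance()`); everything
downstream works in absorbance.

Repeated scans of one sample are averaged pointwise **in absorbance
space**. Averaging before or after the log transform changes values in
the third decimal for typical reflectances; we fix the absorbance-space
convention because absorbance is the modelled quantity, and document it
here because the choice is not forced by anything upstream.

The calibration/validation split draws a fixed number of validation
samples per crop group uniformly without replacement (default 5 per
crop, i.e. 30 calibration + 10 validation for two groups of 20). With no
crop labels the split is unstratified; the engine is generic even though
the motivating design is stratified.

# Math treatments

A *math treatment* is the recipe `d,g,s1,s2` plus a scatter correction,
applied in this order:

1. **Scatter correction** on the full-length spectrum:
   * **SNV** — per-spectrum standardisation (mean 0, SD 1, n−1
     denominator); removes particle-size scatter; invariant to affine
     transforms of a spectrum.
   * **DT** (detrend) — subtract the least-squares polynomial in
     wavelength, degree 2 by default. Published treatments do not state
     whether the detrend is global or piecewise; we use a single global
     quadratic, the simplest choice consistent with "baseline shift
     correction".
   * **SNV-DT** — SNV then detrend.
   * **MSC / WMSC** — regress each spectrum on a reference spectrum
     (the set mean unless frozen parameters are supplied) and invert
     the fitted offset/slope, x' = (x − a)/b. WMSC uses weighted least
     squares; because no published definition of the weights exists for
     this workflow, we default to the stabilised inverse across-sample
     variance w(λ) = 1/(var(λ) + 1e−6·max var), which down-weights
     wavelengths where chemistry rather than scatter drives variation.
     Uniform weights reduce WMSC to MSC exactly, which the tests use as
     an anchor.
2. **Gap–segment derivative**: moving average of `s1` points, then `d`
   applications of the forward gap difference D_g(x)(i) = x(i+g) − x(i),
   then a moving average of `s2` points. `1` means "no smoothing";
   `0,1,1,1` is the identity.

Three conventions are worth stating because table formats blur them:

* "Binning at intervals of 4, 6, ... 16" is read as the **gap** of the
  gap derivative, not as decimation — decimating would destroy the 2 nm
  grid the models are defined on.
* Compact table strings such as `2,441` and `310,102` parse as
  `2,4,4,1` and `3,10,10,2` (`parse_treatment()`).
* All valid-region operators **truncate** edges rather than padding:
  fabricated boundary values must never feed the regression. The output
  spectra carry their shifted/truncated wavelength axis (a moving
  average is labelled by its window centre, a gap difference by its left
  point).

The derivative and smoothing operators are exactly linear, and a
polynomial of degree < d is annihilated by the d-th gap derivative;
both properties are enforced in the tests.

For MSC/WMSC the reference spectrum (and weights) estimated on the
calibration set are frozen into the fitted model, so validation spectra
are corrected against the *calibration* reference — correcting each set
against its own mean would leak set-level information into the
treatment.

# Modified PLS

`fit_mpls()` is NIPALS PLS1 with one modification: after each factor is
extracted, the spectral residual at every wavelength is divided by the
standard deviation of that wavelength's residuals across samples
(Shenk–Westerhaus residual standardisation). The per-factor scaling
vectors are stored and replayed at prediction time. With
`scale_residuals = FALSE` the code path reduces exactly to PLS1, which
gives a strong three-way oracle: mPLS(scale off) ≡ PLS1 ≡ OLS at full
rank, checked to 1e−6 on random 20 × 15 problems. Wavelengths whose
residual SD underflows (already fitted exactly) keep scale 1 and are
recorded as dropped.

Factor count is chosen from a cross-validated error curve. The CV plan
shuffles the calibration samples once (seeded) and cuts the shuffle into
`n_groups = 5` contiguous blocks; SECV(k) = sqrt(Σ held-out (ŷ−y)² / n)
for k = 1..`max_factors`. The selection rule — the smallest k with
SECV(k) ≤ 1.02 · min SECV — is a parsimony band; the proprietary
software this emulates does not publish its rule, so we chose a simple
auditable one. `max_factors` defaults to 10: with 30 calibration
samples, more latent variables mostly fit noise.

## Outlier elimination

Calibration samples with |CV residual| / SECV > 2.5 are eliminated, in
at most 2 passes and never more than 6 samples in total (the observed
range for this workflow is 0–6 removals, which we enforce as a hard
cap). Two deliberate choices:

* The T statistic is computed against **SECV**, not SEC — the held-out
  residual should be compared with the held-out error scale.
* When SECV < 1e−8 · SD(y) the model is treated as numerically exact
  and nothing is flagged. Without this guard, machine-precision
  residuals on noiseless data have an essentially arbitrary ratio to a
  near-zero SECV and trigger spurious removals.

Validation never removes outliers; all validation statistics are
computed on every held-out sample.

# Statistics

For calibration: SEC = sqrt(Σe²/(n − 1 − k)) (degrees of freedom charged
for k factors and the intercept), SECV as above, RSQ = 1 − SSE/SST
(clamped to [0, 1]). For validation: bias = mean(ŷ − y),
SEP = sqrt(Σ(ŷ−y)²/n) (uncorrected), SEP(C) = sqrt(Σ(ŷ−y−bias)²/(n−1))
(bias-corrected), and the exact decomposition
SEP² = bias² + SEP(C)²·(n−1)/n. Both SEP forms are reported because
published tables are ambiguous about the convention; **RPD is defined
against the uncorrected SEP** (RPD = SD/SEP, SD with n−1), which matches
the large majority of published rows for this workflow. External RSQ is
the squared Pearson correlation of predicted and laboratory values —
the convention behind "high RSQ showing strong correlation" — so it is
invariant to affine recalibration; the 1 − SSE/SST form is exposed as
`mode = "calibration"`. The paired *t*-test is two-sided at the 5% level.
Utility classes: RPD ≥ 3 "high" (quantification), RPD < 2 "poor"
(screening at best), otherwise "screening"; boundaries fall in the
better class.

`reference_validation_examples()` ships the published SEP/SD/RPD rows
for a combined rice bean–adzuki bean flour model *for the traits where
the printed values satisfy RPD = SD/SEP after rounding* (protein,
dietary fiber, starch, phytate, CUPRAC, fat, Fe, red). Three published
rows (sugar, green, blue) are inconsistent with that identity as
printed; the package documents rather than reproduces them.

# Treatment search

`search_best()` evaluates every treatment of a `search_grid()` on one
fixed calibration/validation split (one split per trait run) and ranks
by external RSQ, breaking ties by RPD, then fewer factors, then the
treatment string; `criterion = "rpd"` swaps the first two keys.
Degenerate combinations (e.g. a gap longer than the spectrum) are
recorded as skipped rows with reasons — one bad recipe must not abort an
896-point sweep. The default `smooth1` grid {1, 2, 4, 6} extends the
published {2, 4, 6} with 1 (no smoothing), and the grid is fully
configurable because published winning treatments also use s1 ∈ {7, 10}.

# The synthetic generator

The benchmark datasets stand in for a 40-accession bean collection whose
spectra are not publicly deposited. The generator emulates:

* **Trait distributions** — truncated normals with the published
  mean/SD/range of the 40-accession reference population
  (`table1_distributions()`: protein 22 ± 1.28 [19, 25], starch
  41.1 ± 3.75 [30.7, 47.3], ..., minerals and RGB included). Traits are
  drawn independently by default; real proximates are compositionally
  correlated, but independence keeps recovery tests interpretable, and
  a correlation hook can be added without changing the interface.
* **Spectra** — Beer–Lambert mixing of Gaussian pure-component bands
  placed at the seven major bean-flour peaks (1194, 1499, 1730, 1964,
  2124, 2310, 2345 nm; moisture peaking at 1964 nm, the O–H first
  overtone). Band-to-constituent amplitudes are simulator parameters:
  published spectra give peak positions, not pure spectra, so recovery
  properties — not resemblance to any particular instrument trace —
  are what the generator is calibrated for. Traits with no NIR-active
  bonds in free form (minerals, colour channels) get **no** spectral
  signal, mirroring the poor absorption of minerals in the NIR region;
  a search over such a trait should and does fail (RPD < 2).
* **Scatter and noise** — per sample, x = b·(baseline + mixture) + a + ε
  with b ~ lognormal(0, σ_b), a ~ N(0, σ_a), white ε per point, and a
  fixed gentle polynomial baseline. This is exactly the affine
  per-sample model that SNV/MSC assume, so the correctors can be tested
  as exact inverses of the corruption.

Preset noise levels (chosen once, as study conditions): `clean` is
noise- and scatter-free; `scattered` has σ_b = 0.1, σ_a = 0.02 and no
white noise; `paper_like` has σ_b = 0.08, σ_a = 0.01 and white noise
σ_n = 3e−5 AU — the noise floor of a research scanning monochromator
after 32-scan averaging (single-scan RMS noise of roughly 150–200 µAU
divided by √32); `noisy` keeps a deliberately degraded 5e−4 AU for
stress tests. All presets have 40 samples in two pseudo-crop groups of
20, the second group's spectrally active trait means shifted by +0.3 SD
to mimic between-crop composition differences.

What passing tests on this generator do **not** show: robustness to
nonlinear scatter (the generator's scatter is exactly affine),
wavelength-calibration drift, correlated constituent variation, or real
band shapes. They do show that the pipeline's algebra — preprocessing,
mPLS, statistics, search, outlier loop — is correct and that the
workflow recovers what is recoverable under its own assumptions.

# Numerical choices

* SD uses the n−1 denominator everywhere.
* NIPALS stops with an error when the remaining covariance norm or a
  score norm falls below 1e−12 ("n_factors too large"); during a grid
  search such failures become skipped rows.
* MSC/WMSC reject fits with |slope| ≤ 1e−8, naming the sample.
* SNV rejects constant spectra; detrend requires degree < n.
* The SECV ≥ 1e−8·SD(y) guard in the outlier loop (above).
* Ties in factor selection resolve to the smaller k; ties in search
  ranking resolve by RPD, then fewer factors, then the treatment
  string, making the ranking a total order.
* All randomness (splits, CV plans, simulator draws) flows through
  explicit integer seeds via an internal scoped-RNG helper; no function
  disturbs the caller's random stream, and every pipeline output is
  bit-reproducible given its seeds.

Problem sizes in the shipped tests were chosen to keep the full suite
fast while still exercising every code path end to end: the benchmark
datasets use the 40-sample design throughout; oracle comparisons run on
20 × 15 to 30 × 60 problems; the acceptance-style search sweeps a
reduced 8-treatment grid (derivatives {1, 2}, gaps {4, 6},
s1 ∈ {1, 4}, SNV-DT and WMSC) rather than all 896 combinations.

# Limitations

* mPLS is implemented as the residual-standardisation variant; the
  proprietary implementation it emulates is not published, so
  factor-by-factor numerical identity with it cannot be claimed — the
  PLS1 reduction switch keeps the choice testable.
* PLS2 (simultaneous multi-trait), variable selection (iPLS) and neural
  models are out of scope, as are JCAMP-DX/ISI binary formats and
  instrument control.
* The RPD utility thresholds (2, 3) are field conventions, not
  statistical guarantees; with 10 validation samples the sampling
  variance of RPD is substantial.
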