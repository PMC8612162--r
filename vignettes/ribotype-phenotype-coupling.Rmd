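---
title: "Coupling ribotypic and phenotypic traits in ciliated protists: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupling ribotypic and phenotypic traits in ciliated protists: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribotraits)
```

This vignette is the package's account of the science it implements: the
models, their assumptions, the tunable parameters, the numerical
choices, and what the synthetic-data validation does and does not show.

## The biological problem

Per-cell 18S rDNA and rRNA copy numbers of protists vary over orders of
magnitude with cell size, growth phase, and encystment, which
complicates every rDNA/rRNA-based inference about abundance, biomass,
activity and diversity. In ciliates the transcriptionally active rDNA
resides in the polyploid macronucleus; through the life cycle (lag, log,
plateau, unstable cyst, resting cyst) cell volume (CV), macronuclear
volume (MV) and both copy numbers decline together — except in resting
cysts, which keep roughly half or more of their rDNA but lose 2–4 orders
of magnitude of rRNA. That asymmetry is what the framework exploits.

## Geometry

Fixed cells and their macronuclei are treated as prolate spheroids,
`V = (π/6)·L·W²` with the length as the major axis and the width as both
minor axes (`spheroid_volume()`); for cross-species comparisons sizes are
expressed as the equivalent spherical diameter, `ESD = (6V/π)^(1/3)`
(`esd_from_volume()`). The two are exact inverses for globular cells,
and the identity `CV = (π/6)·ESD³` underlies the algebraic fit
transforms below. The nucleocytoplasmic ratio MV/CV (`nc_ratio()`) falls
in the 1–8% band for these species; values ≥ 1 are flagged rather than
rejected, since they can only arise from measurement error.

Maximum growth rate is the steepest sliding-window OLS slope of
ln(abundance) versus time (`max_growth_rate()`), in d⁻¹. The window
default is 3 consecutive sampling points: daily sampling of cultures
that leave log phase within a few days leaves little data per window,
and 3 points is the smallest window that still averages over counting
noise. The exact windowing behind the published rates is not restated in
the source; the sliding-window rule is this package's choice and is
configurable.

## Allometric fits and their exact transforms

All scaling relations are ordinary least squares on log10–log10 axes
(`fit_power_law()`), matching how the published fits were made; no
errors-in-variables correction is applied, and p-values are the standard
slope t-tests without multiplicity adjustment. `allometry_registry()`
stores the published coefficients *verbatim* rather than re-deriving
them. Three exact transforms connect the parameterizations:

- `cv_fit_to_esd_fit()`: substituting `CV = (π/6)·ESD³` triples the
  slope and shifts the intercept by `slope · log10(π/6)`. The constant
  `log10(π/6) ≈ −0.27875` is kept at full precision. Note the published
  ESD-basis intercepts were obtained by independent refits and printed
  rounded (0.396 where the exact transform of the CV fit gives 0.3984;
  3.43 vs 3.4275): the registry keeps the printed values, and the tests
  treat the difference as rounding, not error.
- `percell_to_population()`: an idealized population of `N` identical
  cells has total copy number `N ×` the per-cell value, i.e. the same
  power law plus `log10(N)`.
- `ratio_fit()`: subtracting two fits with a common predictor gives the
  power law of their ratio; for two population-level fits the `log10(N)`
  terms cancel, which is why the rRNA:rDNA ratio of a vegetative
  population depends on cell size alone.

Composing the transforms reproduces published derived quantities: the
ratio of the population rRNA and rDNA relations gives slope
0.33 = 2.61 − 2.28 and intercept 3.034 = 3.43 − 0.396, whose antilog is
the constant 1081; composing MV ∝ CV^0.83 with the ESD conversion
predicts MV/CV ∝ ESD^−0.51, within 0.02 of the independently fitted
−0.522.

## The resting-cyst estimator

For a vegetative population the total rRNA:rDNA ratio is
`10^3.034 · ESD^0.33` (`expected_ratio()`). Resting cysts contribute
rDNA but essentially no rRNA (0.02–0.5% of a vegetative cell's
content), so with a cyst share `f` of the rDNA pool the measured ratio
shrinks by the factor `(1 − f)`, giving

```
cyst% = 1 − (rRNA_total / rDNA_total) / (10^3.034 · ESD^0.33)
```

implemented in `cyst_fraction()`. Design notes:

- The printed intermediate form of this derivation carries a sign
  inconsistency in its trailing term (`… − 0.33 log10(ESD) + 3.034`
  would not reduce to the division form unless the last term is
  negative); the implementation follows the final division form and
  documents the discrepancy rather than resolving it.
- The baseline coefficients are injectable, so species- or
  taxon-specific recalibrations slot in; defaults are the
  Colpoda-derived constants.
- Estimates outside [0, 1] — expected under measurement noise — are
  clamped, flagged, and the raw value retained, rather than erroring.
- ESD is the vegetative-cell ESD, not a pool-weighted mixture; for the
  mixed populations the generator builds, cysts and vegetative cells
  share a size, and real applications should supply the vegetative
  cell size the baseline was calibrated on.
- If the cysts' own rRNA contribution is known it may be supplied as
  `rrna_rc` and is subtracted before the ratio is formed; at the
  measured suppression levels it shifts the estimate by < 0.5%.

`cyst_fraction_ci()` provides a percentile bootstrap over replicate
pools. Percentile intervals from few replicates undercover; the
validation uses 12 replicates, and applications with the conventional
3 biological replicates should read the interval as descriptive.

## Growth-rate models

`fit_growth_model()` fits `log10(r) = a·t + b·log10(x) + c` with no
interaction term (none is published). The design matrix must have full
rank — a constant predictor or temperature column errors out rather
than silently dropping a term. `compare_models()` ranks fits by R² and
refuses to compare fits carrying different response data. The published
ranking (rDNA 0.89 > ratio 0.76 > rRNA 0.34 > CV 0.33) is stored in
`growth_registry()`; the source text prints n = 11 in one place for the
rDNA model while its table prints n = 12, and the registry records 12.
The 12-point synthetic design (4 temperature levels 16–28 °C crossed
with predictor decades 10³–10⁵) mirrors the structure, not the values,
of the real 4-species data set, which is not printed per point.

## Single-cell variant analysis

`pairwise_identity()` uses global end-to-end alignment with unit
match/mismatch/gap scores (via Biostrings); identity is matches over
alignment columns, with terminal-gap columns excluded and each internal
gap position counting as one non-matching column. Clustering
(`greedy_cluster()`) is deterministic abundance-sorted greedy centroid
assignment: variants in descending read count (ties broken
lexicographically) join the first centroid at or above the threshold or
found a new cluster. The published analysis used an established greedy
clustering tool; this reimplementation is deterministic and
order-invariant by construction but is not guaranteed to agree with
that tool exactly at boundary identities. At threshold 1.00 clusters
are exact-sequence groups.

The threshold grid is fixed at 0.01 steps over [0.89, 1.00]. The
*leveling threshold* is the largest cutoff at which a cell's pool
collapses to a single OTU, and the maximum intragenomic divergence is
estimated as `(1 − leveling) − residual_error_rate`
(`corrected_divergence()`), floored at zero, with the residual error
taken from clone-library controls (1% for the two soil species, 0 for
the marine ones). Rarefied richness subsamples reads *without*
replacement (100 repetitions, seeded); whether the published per-1,600
read counts used replacement or how many repetitions is not stated, so
these defaults are flagged assumptions. ASV-to-OTU lumping happens
within each cell's pool.

## Synthetic-data generators

The generators define the validation conditions and are deliberately
simple, seeded, and exactly documented:

- `gen_cells()`: per-stage log-normal CV around the profiles'
  stage means, with MV, rDNA and rRNA placed on the generating power
  laws under multiplicative log-normal noise (default log10 SD 0.25,
  which reproduces the R² ≈ 0.8–0.9 range of the real fits). Stage
  means for the two Colpoda-like profiles encode the printed per-stage
  values where available (e.g. lag-phase 2.14×10⁵ μm³ and cyst
  2.0×10⁴ μm³ for the large species; cyst 2.0×10³ μm³ for the small
  one) and the printed reduction percentages elsewhere. Copy-number
  dispersions are not published; the defaults are assumptions exposed
  as parameters.
- Cyst rRNA suppression is parameterized *relative to the size-expected
  vegetative rRNA at the cyst's own CV*: 9.8×10⁻³ (small species) and
  1.2×10⁻³ (large species) reproduce the measured cyst rRNA contents
  (3.4×10⁴ and 3.1×10⁴ copies) and hence the observed ~300–4200×
  log-phase:cyst contrasts.
- `gen_population()` builds mixed populations on the *printed*
  ESD-basis coefficients (2.28/0.396 and 2.61/3.43), so the vegetative
  ratio is `10^3.034` exactly and the zero-noise estimator sweep
  recovers the true fraction to within `f ×` suppression — the exact
  algebraic bias of ignoring cyst rRNA.
- `gen_variant_pool()` mutates evenly spaced template positions
  (cyclic base replacement), so substitutions stay isolated, the
  optimal alignment stays ungapped, and the realised divergence is
  exactly `k/L`; a divergence of 11% on a 373-nt template yields
  identity 0.8901, which levels precisely at the 0.89 grid point.
  Spurious error reads are singletons carrying one random substitution.
  Templates are random sequences under a fixed seed; no real 18S
  sequence is required or included.
- `gen_dilution_series()` produces
  `CT = intercept − log10(copies)/log10(1 + E)` plus Gaussian noise,
  by default in triplicate reactions per dilution point, as the assays
  are conventionally run.

Validation problem sizes were fixed at design time: 100 replicates of
n = 200 for exponent recovery (with the predictor spanning the
cross-taxon cell-volume range, log10 CV ∈ [1.3, 5.3], over which the
unified rRNA scaling is claimed — a 2-decade single-species range would
roughly double the slope standard error), 100 seeded dilution series
for the efficiency window, and 200-cell populations for the estimator
sweep. A pre-test power analysis (slope SE =
`0.25/(sd(log10 x)·√200)` ≈ 0.019) puts the per-replicate probability
of landing within ±0.05 of the true exponent near 0.99.

## What the synthetic validation does not show

The generators emulate the *statistical structure* the analysis
assumes: power-law coupling with log-normal scatter, a clean cystic
rRNA collapse, isolated substitutions in denoised variants. Real data
add features deliberately not modelled — chimeras and indel errors,
taxon-dependent rDNA:CV relations (the marine spirotrichs carry 30–80×
more rDNA than similarly sized colpodids, so the Colpoda baselines do
not transfer across distant taxa), unstable cysts that sit off the
vegetative rRNA trend, and qPCR inhibition. Passing tests therefore
demonstrate correctness of the computations and internal consistency of
the framework, not field-readiness of the default calibrations; the
estimator's baseline must be recalibrated per taxon before use on
environmental samples.

## Numerical conventions

Volumes in μm³, lengths and ESD in μm, rates in d⁻¹, temperatures in
°C; no unit autodetection. All seeded functions restore the caller's
RNG state. Identity comparisons against clustering thresholds use a
1e-12 tolerance so grid-point identities (e.g. 0.92 exactly) cluster
stably. Negative rRNA-by-subtraction results clamp to zero with a
warning, and replicate CTs may be averaged before curve inversion
(default: fit all points; the efficiency is computed from the pooled
fit, as per-plate efficiencies are not separately published).
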