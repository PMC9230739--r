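---
title: "Methods: ATR-IR multivariate calibration with chemocal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ATR-IR multivariate calibration with chemocal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemocal)
```

## Scope and assumptions

`chemocal` builds univariate-response PLSR calibrations that predict the
content of one active ingredient (mg per dosage unit) from ATR-IR absorbance
spectra. The modelling assumptions are the standard ones for solid-sample
vibrational calibration:

- absorbance is, after pretreatment, approximately linear in the analyte's
  mass fraction at the probed surface (Beer–Lambert in the thin effective
  ATR layer);
- all spectra in one analysis share a single instrument grid — the package
  refuses to combine differing grids rather than interpolate silently;
- the dominant nuisance effects are multiplicative scatter (contact/particle
  effects), slow baseline drift, and additive detector noise — exactly the
  effects the pretreatment menu targets.

## Pretreatment operators

**SNV** maps each spectrum to zero mean and unit standard deviation using
the sample (n − 1) convention, the behavior of common chemometrics software;
switching to the population convention would be a one-line change and only
rescales every spectrum by the same factor. SNV removes per-spectrum
multiplicative scatter and offset exactly: `snv(a*x + b) = sign(a) * snv(x)`.

**Area normalization** divides by the sum of absolute intensities. This is a
discrete proxy for total band area; on the (effectively uniform) grids used
here the omitted spacing factor is a constant that cancels after mean
centering in the regression, so a trapezoidal integral would change nothing
downstream.

**Savitzky–Golay derivatives** fit a local least-squares polynomial in a
centered odd window and differentiate it. Two choices matter:

- Derivatives are scaled by the grid spacing, so results are true
  d/d(cm⁻¹) values and are grid-independent.
- Edges are handled by re-evaluating the first/last full-window polynomial
  at the off-center positions rather than truncating, so the matrix width
  never changes and interval bookkeeping never shifts across pipeline steps.

Pipelines compose left-to-right: `"area_norm+snv"` area-normalizes first.
Published pretreatment labels of the form "A + B" do not state an order;
left-to-right application is this package's convention and any other order
can be written explicitly. Where a second-derivative configuration appears
without stated polynomial/window parameters, the defaults polynomial 2,
window 11 are used (the most common choice in the field) — this is a
documented assumption, not a fitted value.

## Sample selection

`kennard_stone()` implements greedy max–min selection on Euclidean
distances: extreme pair first, then repeatedly the sample farthest from the
selected set. Ties break to the lowest row index, making the algorithm
fully deterministic without a seed. `ks_split_by_stratum()` applies it
independently within each strength level, because a balanced per-strength
calibration design (e.g. exactly 24 of 30 per strength) is only guaranteed
by per-stratum application; a single global pass is also exposed as
`kennard_stone()` for users who want it. Distances are computed on the raw
absorbances (optionally restricted to the model's wavenumber intervals),
not on pretreated data: selection happens once per study, before any
model-specific pretreatment is chosen.

## PLSR engine

NIPALS with deflation of both X and y; X is column-mean-centered and y
centered, with **no variance scaling** — variance handling is the
pretreatment's job, and unscaled centering is the standard choice for
spectral PLSR. With a univariate response the inner NIPALS iteration is
stationary after one pass; the iteration guard (tolerance 1e-12, cap 500)
exists for degenerate inputs. If deflation exhausts the data's rank before
the requested factor count, a rank error is raised rather than returning
near-zero noise factors.

Cross-validation is leave-one-out for n ≤ 100 and 10 seeded random segments
otherwise; each fold is fitted once at the maximum factor count and
truncated regression vectors give predictions at every smaller count. The
default selection rule is the RMSECV minimum (lowest count on ties); a
parsimonious rule (smallest count within a stated relative tolerance of the
minimum) is available. Published factor counts for the built-in
configurations are carried as `pinned_factors` so a screening table can be
reproduced with fixed complexity, but by default factor counts are treated
as data-dependent outcomes and re-derived.

Models serialize to JSON with all numeric payloads as C99 hexadecimal
floats: decimal JSON loses the last bits of a double, and the contract here
is that a reloaded model re-predicts *bit-identically*.

## Evaluation

RMSEP is `sqrt(mean((pred - ref)^2))` — the only reading of the usual
formula that keeps units consistent — and bias is the signed mean error;
`rmsep²  = bias² + population-variance(residuals)` is enforced as a test
invariant. `r2_model()` is 1 − SS_res/SS_tot and is reported raw (it can be
negative for a model worse than the mean); only the squared-correlation
variants are bounded to [0, 1].

The method-comparison test is a two-sided paired t-test by default (the
conventional choice when a comparison is reported only as "no significant
difference at 95% confidence"), with a sign-flip permutation alternative for
non-normal differences. Heteroscedasticity — in practice judged visually
from residual plots — is quantified as the Spearman correlation between
|residual| and reference value with a one-sided permutation p-value: an
increasing-spread alternative is the phenomenon of interest.

## Model screening and ranking

`builtin_grid()` enumerates the 13 tablet and 11 granule interval ×
pretreatment configurations of the standard screening design.
`select_best()` ranks successful rows by a composite rank-sum: descending
ranks on R²(model) and R²(Pearson) plus ascending ranks on RMSEP and |bias|,
each weighted. The published narrative selection among such screens
emphasizes accuracy (|bias|) over the last digit of precision, so the
default doubles the bias weight; with equal weights the ranking flips to the
lowest-RMSEP candidate. Both behaviors are exposed, documented, and tested
on a printed screening report used as a fixture. Ties go to fewer latent
factors, then the lower config id.

## The synthetic generator

No public instrument data accompanies this workflow, so the package ships a
generator that produces data with the statistical structure the analysis
assumes. Per sample:

1. Component mass fractions come from the formulation series (active 4–30 mg
   in a 132 mg unit; lactose compensates, other excipients constant), so
   absorbance is exactly affine in the active's mass fraction when all
   disturbances are off.
2. Each component contributes a sum of Lorentzian bands (Lorentzian being
   the typical mid-IR line shape). The active's bands sit at its
   characteristic positions (~1700, 2900, 1640, 1600, 1100, 880 cm⁻¹); the
   excipient libraries use generic carbohydrate/stearate features that
   deliberately overlap the active's fingerprint region, reproducing the
   real difficulty of low-dose ATR-IR assay.
3. Disturbances: per-sample multiplicative scatter (sd 0.05), linear
   baseline (offset sd 0.02 a.u., slope sd 1e-5 a.u./cm⁻¹), additive noise
   (sd 0.002 a.u.), all typical magnitudes for a DTGS ATR accessory on a
   400–4000 cm⁻¹ grid at 2 cm⁻¹ spacing.
4. The **only** modelled tablet/granule difference is `tablet_surface_sd`
   (default 0.03, granules 0): a multiplicative jitter on the per-sample
   surface mass fractions. An intact compact can present one component at
   its surface in greater proportion than the bulk mass ratio, while ground
   granules present a homogenized surface. Because the jitter is relative,
   its absolute effect grows with strength, which is what makes tablet
   validation residuals heteroscedastic while granule residuals stay
   near-homoscedastic — the package's tests verify exactly this contrast.
5. Reference values emulate a validated HPLC assay: truth × recovery
   (default 1.015, the midpoint of a 100.0–102.9% recovery range) × (1 + ε)
   with ε Gaussian at RSD 0.0126.

The granule strength series defaults to the same seven formulations as
tablets, since those define the available compositions.

What the generator does **not** emulate: ATR penetration-depth wavelength
dependence, instrument line-shape convolution, atmospheric CO₂/H₂O lines,
Mie scattering, or any unit-scale difference between tablet and granule
reference values. Passing tests on synthetic data therefore demonstrate the
pipeline's correctness and its qualitative mechanisms (scatter correction
helps; surface jitter produces heteroscedasticity), not the numerical
performance to expect on any particular instrument.

## Numerical and design choices

- Interval bounds are inclusive at both ends, matching the conventional
  "500–1700, 2500–4000 cm⁻¹" notation without endpoint gaps.
- Grids are stored ascending; writers may emit descending instrument order,
  readers normalize.
- SG filters require an evenly spaced grid (1e-6 relative tolerance) and a
  window no larger than the spectrum.
- Both 400–4000 and 400–3700 cm⁻¹ working ranges are supported; neither is
  hard-coded (the built-in grids simply use each form's conventional range).
- Degenerate inputs fail loudly with classed conditions
  (`chemocal_degenerate_error`, `chemocal_rank_error`, ...), and pipeline
  errors name the offending sample.
- One master seed fans out to per-stage child seeds via a fixed affine map
  (`child_seed()`), so spectra and reference noise can be regenerated
  independently; all child seeds stay below 2³¹.
- HPLC back-calculation flags out-of-range concentrations instead of
  rejecting them: a fixed dilution scheme applied across a 4–30 mg series
  necessarily leaves some strengths outside a 10–30 µg/mL validated range,
  and silently rejecting them would be worse than flagging.

## Problem sizes in the test-suite

The suite exercises the full default study sizes (210 tablet / 70 granule
spectra, 1801 grid points) for the bookkeeping and regime checks, and uses
20–40 seed replicates for the stochastic property checks (parameter
recovery, scatter-correction contrast, heteroscedasticity contrast, test
level), which is enough to separate the designed effects from seed noise
while keeping a full run around a minute. Oracle comparisons (Kennard–Stone
vs exhaustive greedy, full-rank PLSR vs OLS) run on 200 random small
instances each.

## Known limitations

- Single-analyte (univariate-y) PLSR only; no SIMPLS/kernel variants and no
  coefficient uncertainty intervals.
- No MSC, detrending, OSC or wavelet pretreatments (not part of this
  workflow's menu).
- The JCAMP-DX reader covers uncompressed AFFN XYDATA/XYPOINTS only;
  SQZ/DIF/DUP-compressed files are rejected with a format error.
- No automated wavelength-interval optimization: the screening grid encodes
  intervals chosen by a spectroscopist.
- Published cross-validation metrics from commercial software cannot be
  reproduced exactly without the original instrument data and knowledge of
  that software's segmentation; the package's CV scheme is documented above
  instead.
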