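---
title: "Single-marker quantification: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-marker quantification: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qamskit)
library(dplyr)
```

## The measurement model

qamskit targets a common situation in natural-product quality control: a
chromatographic assay separates a panel of structurally related compounds
(here nine prenylated flavonoids of *Psoralea corylifolia* seed, detected by
UV at 250 nm), but authentic standards for routine calibration exist only for
a subset. The package implements two quantification routes over the same peak
tables and compares them.

**External standard (ES).** Each analyte $i$ gets a linear calibration
$A = b_i W + a_i$ of peak area on standard concentration $W$ (µg/mL),
fitted by ordinary least squares. Sample areas invert through the analyte's
own line, and the prep arithmetic converts extract concentration to seed
content:

$$\text{content (mg/g)} = W \,(\text{µg/mL}) \times \frac{V\,(\text{mL})}{m\,(\text{g}) \times 1000},$$

with the assay default $m = 0.1$ g of powdered seed made up to $V = 10$ mL.

**Single marker (QAMS).** One marker compound $k$ (neobavaisoflavone:
commercially available, consistently abundant) is calibrated normally. For
each other analyte $m$, a relative correction factor

$$f_{m} = \frac{W_k\,A_m}{W_m\,A_k}$$

is measured from standard mixtures in which marker and analyte are injected
*in the same run*, then averaged over conditions (injection volumes 1–20 µL;
optionally instruments × columns). In samples, the marker concentration
$W_k$ comes from its own curve and the analyte follows by the unique
rearrangement

$$W_m = \frac{W_k\,A_m}{\bar f_m\,A_k}.$$

Both routes are judged per (sample, analyte) cell by the accuracy
$100 \cdot w_{\text{QAMS}} / w_{\text{ES}}$.

### Assumptions the factor rests on

* Detector response is linear in concentration over the working range, and
  areas scale linearly with injection volume.
* $f$ is a property of the compound pair and the detection wavelength, not of
  the individual run: the RSD of $f$ across injection volumes (2–4% for this
  panel) and its spread across systems (2–7%) are the empirical checks.
* Marker and analyte areas are taken from the same run, so common
  multiplicative disturbances (injection volume error, detector gain drift)
  cancel exactly — `compute_rcf()` is invariant to a common rescaling of both
  areas or both concentrations, and the package tests enforce this.

### The intercept caveat

$f$ is a ratio of *single-point* response factors $A/W$. When a calibration
line has a nonzero intercept, $A/W = b + a/W$ depends on $W$, so $f$ measured
at the standard-mix concentration differs slightly from the ratio that would
be exact at the sample concentration. With the panel's published calibration
parameters the intercepts are 4–5 orders of magnitude below the working-range
response, which bounds the induced bias at roughly 0.01–0.03% of content —
invisible next to injection noise. The consequence for testing is precise,
though: the noiseless QAMS-vs-ES identity is *exactly* 100% only when
intercepts vanish. The test suite therefore checks exactness (to 1e-6
percentage points) on a zero-intercept study and separately bounds the
intercept-induced deviation (< 0.1 percentage points) under the published
intercepts. This is a real property of single-marker methods, not an artifact
of the implementation.

## Calibration, LOD and LOQ

`fit_calibration()` uses unweighted OLS (nothing in the assay suggests 1/x
weighting), $R^2$ as the squared Pearson correlation, and the residual
standard deviation $s$ with an $n-2$ denominator. Detection and
quantification limits follow the 3σ/S and 10σ/S convention,

$$\mathrm{LOD} = 3s/b, \qquad \mathrm{LOQ} = 10s/b,$$

so LOQ/LOD is 10/3 by construction — the convention the panel's published
LOD/LOQ pairs are consistent with (e.g. 8.718/2.615 = 3.334). The σ source
(residual SD rather than blank SD or S/N = 3) is a package choice; only the
10:3 ratio is externally constrained. Concentrations above the fitted range
are extrapolated but flagged `above_range` rather than rejected, since the
published per-analyte ranges were evidently applied loosely; concentrations
below LOQ are kept (clamped at zero for blanks) and flagged `below_loq`,
and report writers render such cells as an em dash.

## What the synthetic study emulates

`study_truth()` fixes the study conditions; `generate_study()` draws the
data. Defaults are the conditions of the reference assay:

| parameter | default | why |
|---|---|---|
| panel response (slope, intercept) | published calibration parameters | simulation truth with realistic magnitudes |
| per-sample true contents | the thirteen published batch contents; dashed cells as true zeros | realistic content ranges and blank structure |
| prep | 0.1 g / 10 mL | the assay's prep rule |
| injection volumes | 1, 2, 4, 6, 10, 16, 20 µL (reference 10 µL) | the seven volumes of the published f table |
| area noise | multiplicative lognormal, CV 2% | percent-scale RSDs match the published precision table better than additive noise |
| replicates | 3 per run | as in the published f determination |
| calibration | 6 levels, geometric spacing across each range | level count unpublished; 6 is standard practice |
| between-day shift | CV 1.5% | reproduces interday > intraday ordering |
| prep-to-prep effect | CV 1% | repeatability slightly above pure injection noise |
| system gains | CV 1% per analyte on non-reference systems | makes f differ across instrument × column, as observed |

Recovery spikes sample S7 at 100% of native content (spike level
unpublished; 100% is the usual choice) using a 0.5 g / 50 mL prep — the
published recovery used 0.5 g of sample, and keeping the assay's
mass:volume ratio keeps spiked extracts inside the calibration ranges.

Peaks, when a full trace is wanted, are plain Gaussians: the assay's
quantities of interest are areas, every peak is baseline-separated in the
reference method, and a Gaussian has a closed-form area
(`true_amount × height_scale`) that anchors integration tests to an
independent quadrature oracle. `integrate_peaks()` subtracts a local linear
baseline through the window endpoints and integrates by the trapezoid rule;
negative integrals (noisy blanks) clip to zero with a flag.

**What the simulator does not model** — and therefore what passing tests do
*not* demonstrate about real data: peak tailing and co-elution interference,
detector saturation, injection-volume nonlinearity (the real per-volume f
values drift systematically from 1 to 20 µL; the simulator's do not),
gradient retention shifts, extraction-efficiency differences, and
between-batch matrix effects. The published f table is therefore kept as a
fixture for the summary statistics rather than regenerated.

A deliberate consequence: with ideal linear responses, the simulated $f$
equals the slope ratio $b_m/b_k$ (e.g. ≈ 0.34 for bavachin against
neobavaisoflavone), while the published table prints 2.92 for that pair —
closer to the reciprocal. Neither orientation of the defining formula
reproduces every published column from the published slopes; the package
follows the formula as defined, treats the published per-volume values as
authoritative inputs for the summary statistics, and leaves the discrepancy
unreconciled, as reconciling it would require the unpublished raw areas.

Similarly, the published QAMS and ES content tables label a few columns
inconsistently: pairing their cells by numerical agreement (printed accuracy
= printed ratio) works for 58 of 68 cells; `qams_reference()` marks the
remainder `consistent = FALSE` and the package uses only consistent cells as
numeric fixtures. The accuracy extremes over the consistent cells, 92.89%
and 109.5%, match the reported headline band.

## Validation battery conventions

* RSD is always $100 \cdot \mathrm{sd}/\mathrm{mean}$ with the sample SD.
* Intraday precision: RSD of day-1 replicate injections (six in the
  reference design). Interday: RSD of all replicates pooled across days —
  the published report is ambiguous between pooled RSD and RSD of day means;
  pooled is the stricter and more common convention and is the only one
  implemented.
* Recovery uses the marginal formula
  $100\,(\text{measured} - \text{base})/\text{spiked}$ through the full
  quantification path.
* Stability is the RSD over the 0–24 h timepoint series.

## Numerical choices and degenerate inputs

* Exact fits report residual SD 0 and LOD = LOQ = 0 without warnings.
* `snr()` returns `Inf` with a warning on a zero-variance noise region.
* Replicate areas are averaged before curve inversion (kept symmetric
  between the ES and QAMS routes).
* Fewer than 3 calibration levels, zero concentration variance, missing
  curves, missing marker peaks, non-positive factor inputs and out-of-grid
  integration windows all fail fast with messages naming the offending
  analyte, sample or window.
* All randomness flows through a single seed per study; a fixed seed gives a
  bit-identical bundle.

## Problem sizes used in the checks

The test suite and the acceptance script run entirely on synthetic studies at
the default scale (13 samples × 9 analytes × 3 replicates, 7 volumes): a
noiseless study for the exact identities, 200 seeds at 2% noise for the
accuracy-coverage property (the observed coverage of the 92–108% band is
≈ 99.9%, comfortably above the 95% requirement), 100 replicates for the
noise-CV calibration of the generator, and 50 seeds for integration
unbiasedness. These sizes give Monte-Carlo standard errors well below the
margins being asserted while keeping a full run in well under a minute.

## Known limitations

* Single-wavelength, single-detector model; no UV spectra, so analyte
  identity is taken from the peak table rather than confirmed spectrally.
* The correction factor is assumed transferable across systems after the
  robustness check; systematic detector nonlinearity between systems would
  bias QAMS in ways the ES route would not detect.
* Contents are not moisture-corrected and extraction efficiency is taken as
  1 (the recovery arm measures the combined effect rather than correcting
  for it).
* Corylin and bavachalcone are excluded from the single-marker route by
  default — their separation and abundance are too poor for a stable factor
  in the reference assay — but `estimate_rcf(exclude = character())`
  re-enables them for exploratory use.
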