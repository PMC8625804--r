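---
title: "HRM variant scanning: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{HRM variant scanning: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrmscan)
```

## The screening model

High-resolution melting compares the shape of a sample's
fluorescence-vs-temperature curve against curves from wildtype controls.
`hrmscan` treats this as a band-exceedance test on normalized curves:

1. **Derivatives.** Each curve is smoothed with a Savitzky–Golay filter
   and the local polynomial's analytic first derivative gives the
   negative derivative plot −dF/dT (`smooth_derivatives()`). Melting
   transitions are peaks of this curve.
2. **Domain detection** (`find_domains()`). A domain is a peak of
   −dF/dT whose height and topographic prominence both reach
   `domain_threshold` (default 0.10) times the curve's global −dF/dT
   maximum. Boundaries are the derivative valley shared with an
   adjacent domain or, on outer flanks, the first return of −dF/dT
   below the threshold. The melting region extends `region_pad`
   (default 2 °C) past each boundary.
3. **Normalization** (`normalize_domain()`). Two least-squares baseline
   lines through the leading and trailing `baseline_frac` (default
   10 %) of the region map fluorescence to `(F − L)/(U − L)`, followed
   by an affine rescale that pins the leading-window mean at exactly 1
   and the trailing-window mean at exactly 0. Linear baselines absorb
   affine backgrounds exactly, which the tests exploit.
4. **Reference band and call** (`build_reference()`,
   `difference_curve()`, `classify_sample()`). Controls are collapsed
   into a per-temperature median and SD. A sample is *variant* when its
   standardized deviation |z| exceeds `k` (default 2) for at least `m`
   (default 10) consecutive grid points — a sustained excursion of
   about 0.4 °C at the default 0.04 °C spacing, which single-point
   noise cannot produce.
5. **Two-step, stratified orchestration** (`analyze_experiment()`).
   The whole amplicon is analysed first as one region, then every
   domain separately; domains are detected once, on the median control
   curve, so all samples share identical scopes. With
   `stratify_by_sex`, test samples are compared against same-sex
   control bands; with `combine_preparations`, the mixed (artificial
   heterozygote) and unmixed preparations of one individual are
   OR-combined, since either may show the clearer deviation.

The assumptions are those of HRM itself: curves are densely and
uniformly sampled (the default grid emulates 25 readings/°C), controls
are genuinely wildtype for the amplicon, and a variant changes curve
shape somewhere within at least one melting region.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `window` | 61 | grid points (≈ 2.4 °C) | Savitzky–Golay window |
| `polyorder` | 3 | — | local polynomial order |
| `domain_threshold` | 0.10 | fraction of max −dF/dT | minimum peak height *and* prominence |
| `region_pad` | 2.0 | °C | melting-region extension per side |
| `min_domain_width` | 0.5 | °C | narrower domains merge into a neighbour |
| `baseline_frac` | 0.10 | fraction of region | baseline window size (≥ 5 points) |
| `k` | 2.0 | SD multiples | band half-width |
| `m` | 10 | grid points | minimum excursion run |

**Why a 61-point window.** The variance of a Savitzky–Golay derivative
estimate grows steeply as the window shrinks, and the domain threshold
is a *derivative-scale* quantity: if the derivative's noise excursions
approach `domain_threshold × max(−dF/dT)`, spurious peaks appear on the
transition flanks no matter how peaks are scanned. At the default grid
(0.04 °C) and realistic instrument noise (0.5–1 % of the melt
amplitude), sub-degree windows put the derivative noise *above* the
10 % threshold, so the default window is 61 points (≈ 2.4 °C). That
window still resolves transitions separated by ≥ 4 °C and, being
symmetric, does not bias the peak location of a symmetric transition —
the suite checks exact noise-free Tm recovery for logistic slopes
0.5–2 °C. Narrow, closely spaced domains need a smaller window plus a
correspondingly cleaner signal (e.g. averaged replicates); both are
configurable.

**Prominence, not just height.** Height alone cannot separate a real
shoulder domain from a noise wiggle riding a flank at the same
absolute level. Topographic prominence (height above the higher of the
two saddles separating a peak from higher ground) is the standard peak
salience measure; applying the same 0.10 relative threshold to both
keeps a single tunable.

**k and m.** On normalized curves, per-point noise is roughly
independent across the grid, so the probability that pure noise exceeds
2 SD for 10 consecutive points is negligible; systematic shape changes
(a shifted transition) easily persist that long. Raising `k` or `m`
can only make calls more conservative — a monotonicity the tests
assert.

## Numerical choices and degenerate inputs

* **SD floor.** Baseline windows have near-zero control SD *by
  construction* (both ends are pinned), so z = d/sd would manufacture
  calls there. The per-point SD is floored at the 10th percentile of
  the region's SD values and at 1e-6 absolute.
* **Median centre.** The reference centre is the per-point median of
  controls (a single outlying control then shifts the centre by at most
  one rank); the mean is available via `center = "mean"`.
* **Ties and plateaus.** Peaks are *strict* local maxima; exact
  plateaus (measure-zero on real data) yield no peak at the plateau's
  interior.
* **Flat curves** produce a `NoDomainsFound` warning and an empty
  domain list, not an error; the whole-amplicon scope still runs.
* **Degenerate baselines** (U ≤ L somewhere in a region) abort that
  region's normalization; `analyze_experiment()` records the skipped
  (sample, scope) pair with a warning instead of failing the run.
* **Thin strata.** Under sex stratification, fewer than 2 same-sex
  controls triggers a logged fallback to the unstratified band.
* **Interpolation** onto the common grid is linear with no
  extrapolation (spans are intersected); at 0.04 °C spacing the linear
  error is negligible and affine curves are reproduced exactly.
* **Duplicate temperatures** within a curve are an error (a malformed
  export), never averaged.

## The simulator: what it does and does not emulate

`simulate_melt_curve()` models melting as a weighted sum of two-state
(logistic) transitions over a background `(b0 + b1·(T − lo))·exp(−b2·(T
− lo))` plus i.i.d. Gaussian noise, on a 65–95 °C grid at 0.04 °C.
Defaults: amplitude 1000 RFU, background (100, −1, 0), noise 5 RFU
(0.5 % of amplitude — a realistic post-PCR noise floor), one transition
at 80 °C with slope 1 °C. Heterozygotes
(`simulate_heterozygote()`) are duplex mixtures: wildtype homoduplex,
variant homoduplex (default −0.3 °C, the small full-match shift of a
substitution), and heteroduplex (default −2 °C, mid-range of published
heteroduplex destabilization), with equimolar-mix fractions
(0.25, 0.25, 0.5).

This emulates the features the analysis consumes — multi-domain
sigmoidal shape, background decay, instrument noise, heteroduplex
depression — and deliberately omits: sequence thermodynamics
(nearest-neighbour Tm prediction), dye redistribution/saturation
chemistry, temperature-calibration drift between wells, and correlated
(smooth) instrument noise. Passing tests therefore demonstrate the
*algorithm's* correctness and its sensitivity under idealized noise;
they do not certify performance on any particular instrument, where
well-to-well calibration error is often the limiting factor and may
require the sex-stratified analysis and replicate controls.

## Problem sizes

The acceptance benchmark simulates 20 cohorts of 16 controls + 50
variants (66 curves of 751 points each) with heteroduplex shifts drawn
uniformly from −3 to −1 °C, and reports the mean sensitivity of the
end-to-end pipeline at its defaults. Property suites use 100 random
multi-transition layouts for the peak-set oracle, 30 seeds per slope
for noisy Tm recovery, and 6 cohorts of 15 wildtype test samples for
the specificity guard.

## Known limitations

* Binary calls only: no genotype clustering, allele-fraction
  estimation, or p-values — positives go to sequencing.
* Domains are detected on the median control curve; a variant creating
  an *extra* domain absent from controls is only caught through the
  whole-amplicon scope and the per-sample domain tally diagnostic.
* Very close domains (< ~4 °C) merge at the default window; resolving
  them trades noise robustness for resolution via `window`.
* The reference band needs ≥ 2 (recommended ≥ 3, ideally more)
  controls per stratum; bands from few controls under-estimate the SD
  and can inflate calls.
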