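# hrmscan

Variant scanning from high-resolution melting (HRM) curves, with
melting-domain analysis for long amplicons.

## The problem

HRM is a closed-tube, post-PCR screening technique: an amplicon is slowly
heated in the presence of a saturating DNA dye while fluorescence is
recorded (typically 25 readings/°C). Any sequence change — especially a
heterozygous one, where mismatched heteroduplexes melt one to a few
degrees lower than homoduplexes — alters the shape of the melt curve.
Screening amplicons this way, and sequencing only the positives, is far
cheaper than sequencing every exon, which matters for genetic diagnosis
of inherited bleeding disorders (hemophilia A/B, von Willebrand disease)
in settings where systematic Sanger sequencing is not accessible.

Two things make naive melt-curve comparison unreliable:

* **Long amplicons (> 300 bp) melt in several domains.** Each
  helix-to-coil transition appears as its own peak in the negative
  derivative −dF/dT, and a variant may perturb only one of them. The
  whole-amplicon comparison dilutes that signal.
* **Hemizygous males form no heteroduplexes.** Mixing the sample with
  wildtype DNA creates an *artificial heterozygote*; sometimes the
  unmixed preparation is the more discriminating one, so both should be
  analysed and combined.

`hrmscan` implements the full screening pipeline: Savitzky–Golay
derivatives, automatic melting-domain detection, per-domain
normalization, comparison against a median ± k·SD control band, binary
variant/normal calling with sex stratification and mixed/unmixed
preparation combination — plus a synthetic melt-curve simulator with
known ground truth so every stage is testable without instrument data.

## Method

For each well, fluorescence F(T) is smoothed by a Savitzky–Golay filter
and its analytic derivative gives the negative derivative curve
−dF/dT. Melting domains are peaks of −dF/dT: strict local maxima whose
height *and* topographic prominence reach a fraction (default 0.10) of
the global maximum; smaller excursions are noise. Domain boundaries are
the derivative valley between adjacent peaks, or where the derivative
returns below the threshold on the outer flanks. Each domain's *melting
region* extends 2 °C beyond its boundaries; its Tm is the peak
temperature.

Within a region, the curve is normalized by two-baseline background
subtraction: least-squares lines U(T) and L(T) through the leading and
trailing 10 % of the region define

    F_norm(T) = (F(T) − L(T)) / (U(T) − L(T)) ∈ [0, 1],

which absorbs affine backgrounds exactly. Control wells are collapsed
into a per-temperature **median** (robust to an outlying control) and
standard deviation; a sample's difference curve d(T) = F_norm(T) −
median(T) is standardized to z(T) = d(T)/max(sd(T), floor). The sample is
called **variant** when |z| > k for at least m consecutive grid points
(defaults k = 2, m = 10 ≈ 0.4 °C) in any analysis scope — the whole
amplicon first, then every domain — in any preparation of the
individual. Calls are screening results and need confirmation by
sequencing.

The simulator models melting as weighted two-state (logistic)
transitions over a linear/exponential background with Gaussian noise;
heterozygotes are duplex mixtures (wildtype homoduplex, variant
homoduplex shifted ~−0.3 °C, heteroduplex shifted −1 to −3 °C).

## Worked example

```r
library(hrmscan)

cohort <- simulate_cohort(n_controls = 8, n_variants = 2, seed = 42,
                          n_wildtype_tests = 1)
fit <- analyze_experiment(cohort$set)
fit
#> HRM variant-scanning analysis: 3 samples vs 8 controls, 1 domain(s)
#>   band: centre median +/- 2.0 sd, run >= 10 points
#>   calls: 2 variant, 1 normal
#> Screening result only: variant calls require confirmation by sequencing.

summary(fit)$domains
#>  index    tm peak_height_rel region_start region_end
#>      1 79.92               1        74.24      85.76

calls_table(fit)
#>  sample_id amplicon_id    call supporting_scopes
#>        W01    amplicon  normal
#>        V01    amplicon variant amplicon,domain_1
#>        V02    amplicon variant amplicon,domain_1

evaluate_detection(fit, cohort$truth)
#> <detection_metrics> TP 2  FN 0  TN 1  FP 0
#>   sensitivity: 1.000   specificity: 1.000
```

The simulated wildtype Tm is 80 °C; the pipeline detects one melting
domain at 79.92 °C and flags both heterozygous samples (in the
whole-amplicon and the domain scope) while the wildtype test sample
stays inside the control band. `plot(fit, scope = "domain_1")` draws the
standard three-panel display (normalized melt curves, negative
derivative, difference plot with the grey ±k·sd band).

File-based workflows use `read_melt_export()` (wide or long CSV/TSV plus
a metadata table) and `run_analyze()`, which writes `calls.tsv` and
`summary.json`. A thin command-line front end lives in
`inst/cli/hrm.R` (`analyze`, `simulate`, `benchmark` subcommands).

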