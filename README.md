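# pairqpcr

Pairwise-efficiency estimation for real-time PCR dilution series.

## The problem

Relative quantification by qPCR stands or falls with the amplification
efficiency *E* — the per-cycle fractional increase of product, with
*E* = 1 meaning perfect doubling. The standard way to measure it is the
calibration (standard) curve: regress the quantification cycle Cq on
log10 concentration across a dilution series and take
*E* = 10^(−1/slope) − 1. That squeezes one *E* out of six wells, so the
estimate is noisy and practitioners run triplicate curves to stabilise
it.

`pairqpcr` implements a combinatorial alternative that extracts far
more information from the *same* wells. Under the classical kinetic
model *F_i* = (*F*₀ / *b*^*D*) (1 + *E*)^*i* — fluorescence *F* at
cycle *i*, dilution step *D* at base *b* — any two fluorescence
readings inside the exponential phase imply an efficiency:

```
E_ij = b^[ (log_b F_j − log_b F_i + (D2 − D1)) / (j − i) ] − 1
```

Enumerating every valid pair across (and within) the curves of one
six-well dilution set yields hundreds of per-pair *E* values instead of
one. Their distribution is diagnosed (skewness, bias-corrected excess
kurtosis, chi-square goodness of fit against a normal at 0.05-wide
bins), low-frequency histogram bins are excluded as outliers, and the
retained values are averaged into the set-level efficiency.

Around the estimator the package provides the full workflow:

- **Window diagnostics** — early-cycle noise profiling, a
  studentized-residual "first outlier" takeoff detector, the First
  Derivative Maximum, per-cycle efficiency scans under candidate *F*₀,
  and a Monte-Carlo grid search over RFU boundary pairs.
- **Baseline** — the classical calibration-curve fit, per set.
- **Precision harness** — resampling of replicate dilution sets
  (samplings of 3 from the replicate pool, means compared by SD), the
  standard way to compare estimator precision.
- **Quantification** — back-calculated initial fluorescence
  *F*₀ = *F_i*/(1+*E*)^*i*, efficiency-corrected expression ratios
  (1+*E*)^ΔCq, maximal replicate-ratio error, and a dilution-ratio
  accuracy table against known folds.
- **Simulator** — a seeded synthetic-plate generator (exponential
  growth, logistic saturation, Gaussian reading noise, threshold Cq
  calls) that emulates a 16-replica six-step two-fold dilution
  experiment, so everything is testable without instrument data.

Functions take and return tibbles and chain with the pipe; fitted
objects have `tidy()`/`glance()` methods and `autoplot()` figures.

## Worked example

```r
library(pairqpcr)

plate <- simulate_plate(seed = 1)   # 16 x 6-step two-fold sets, E = 0.8
set_efficiency(plate, "A1-6", window = c(20, 180))
#> <efficiency_estimate> pairwise, set A1-6
#>   E = 0.7913 (raw 0.78433; 14 of 235 pairs excluded)

cmp <- run_full_comparison(plate, seed = 1)
cmp$precision[, 1:6]
#> # A tibble: 2 x 6
#>   method           sd e_max e_min  range  mean
#>   <chr>         <dbl> <dbl> <dbl>  <dbl> <dbl>
#> 1 calibration 0.0151  0.842 0.763 0.0790 0.802
#> 2 pairwise    0.00704 0.811 0.776 0.0344 0.793
```

The six-well set A1-6 produced 235 valid reading pairs in the 20–180
RFU window; the frequency rule dropped 14 of them and the retained mean
recovers the generating efficiency 0.8 to within 0.01. The comparison
table is the headline result: both estimators are unbiased
(mean *E* ≈ 0.80), but resampling triplicates of the 16 replicate sets
shows the pairwise estimator at roughly half the standard deviation
(0.007 vs 0.015) and less than half the max–min spread of the
calibration curve.

A thin command-line wrapper over the same functions ships in
`inst/cli/pairqpcr` (subcommands `simulate`, `estimate`, `calibrate`,
`noise`, `boundaries`, `precision`, `quantify`, `compare`; plain CSV in
and out, explicit `--seed` everywhere).

## Package layout

- `R/` — plate containers and CSV readers, the simulator, window
  diagnostics, the pairwise estimator, the calibration baseline, the
  precision harness, quantification, the comparison workflow, plots.
- `tests/testthat/` — unit and property tests per module plus
  end-to-end acceptance checks.
- `vignettes/pairwise-efficiency.Rmd` — the methods vignette: model,
  assumptions, parameter choices, and what the synthetic validation
  does and does not show.
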