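---
title: "Pairwise efficiency estimation for qPCR dilution series: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pairwise efficiency estimation for qPCR dilution series: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairqpcr)
```

## The model and its assumptions

Everything in this package rests on the classical kinetic description
of PCR: before saturation, the product — and with it the
baseline-subtracted fluorescence $F$ — grows geometrically,

$$F_i = \frac{F_0}{b^{D}}\,(1+E)^i,$$

where $i$ counts completed cycles, $E$ is the amplification efficiency
($E = 1$ is perfect doubling), $b$ is the dilution base (2 for
two-fold series), $D$ the integer dilution step of the well
($D = 0$ undiluted), and $F_0$ the fluorescence-equivalent of the
undiluted starting template. The assumptions inherited from the
calibration-curve tradition are: identical kinetics across the
dilutions of one set, constant and maximal $E$ before saturation, and
fluorescence proportional to product.

Solving the model for two readings of the same dilution set — cycles
$i$ and $j$ on steps $D_1$ and $D_2$, same curve or not — eliminates
$F_0$ and gives a per-pair efficiency,

$$E_{i,j} = b^{\frac{\log_b F_j - \log_b F_i + (D_2 - D_1)}{j-i}} - 1 .$$

The estimator enumerates every unordered pair of readings inside the
exponential-phase window, excluding only pairs that share a cycle
number (the exponent would divide by zero); same-curve pairs
($D_1 = D_2$) are legitimate instances of the formula and are kept. A
six-well set with about four in-window readings per curve yields on
the order of 200–260 pairs, which is what turns a six-well assay into
a sample large enough for distributional statistics. A
`cross_well_only` flag exists for sensitivity analysis, because
same-curve pairs are the one enumeration choice a user might
reasonably contest.

Note an equivalence worth keeping in mind: under this sign convention,
multiplying every reading of a curve by $b$ describes the same sample
relabelled one step *less* dilute ($D - 1$); the package's property
suite checks that cross-curve pair values are invariant under exactly
that relabelling.

## Outlier exclusion

The per-pair values are binned at width 0.05 (half-open intervals
$[k\cdot 0.05, (k+1)\cdot 0.05)$ anchored at 0). Their distribution is
summarised by the adjusted Fisher–Pearson skewness and bias-corrected
excess kurtosis — the spreadsheet conventions, so values are
comparable with what a bench scientist computes in Excel — and by a
Pearson chi-square goodness-of-fit against a normal with the sample
mean and sd. The chi-square statistic sums over bins whose expected
count reaches 5, with degrees of freedom (number of such bins) − 3;
tail mass beyond the outermost bins is folded in so expected counts
total $n$. The test needs at least 50 values; the textbook validity
note that no more than 20% of bins should fall under an expected count
of 5 is reported as an annotation, not enforced as a gate, since the
same threshold already drives the exclusion rule itself.

Exclusion is non-parametric and frequency-based, which matters because
the pair distributions are typically skewed and leptokurtic, so
sigma-rules calibrated on normality would be wrong. Starting at the
modal bin and scanning outward, the first bin below the mode with a
count under 5 fixes the low cutoff at that bin's *upper* edge; the
first such bin above the mode fixes the high cutoff at its *lower*
edge; values beyond the cutoffs are dropped and the set-level
efficiency is the plain arithmetic mean of the rest. If every bin is
sparse the data are left untouched with a warning — exclusion needs a
populated mode to scan from. Values exactly on a cutoff are retained
(the cutoffs are the edges of the first *unreliable* bins).

## Choosing the analysis window

The window $[lower, upper]$ in RFU decides which readings count as
"exponential phase". Its default, 20–180 RFU for two-fold series read
on a plate whose curves saturate around 2000 RFU, is bracketed from
three directions, each with its own function:

- **Below by noise.** `noise_profile()` pools early-cycle readings;
  with reading noise of sd 3 RFU the pool spans roughly ±10 RFU, and
  `clamp_window()` warns and raises any lower bound that dips into the
  observed noise band. A reading inside the noise band would enter the
  logarithm with arbitrary relative error.
- **Below by takeoff.** `first_outlier_cycle()` flags the first cycle
  rising significantly above a linear background fit (studentized
  prediction residual against the one-sided $t$ quantile, default
  $\alpha = 0.01$, background of at least 4 cycles). One extra
  requirement is ours: the *next* cycle's residual against the same
  fit must confirm the flag. A single-look rule at $\alpha = 0.01$
  scanned over ~25 candidate cycles would false-flag roughly a fifth
  of pure-noise series; amplification, unlike a noise spike, is
  sustained, and the confirmation step brings the per-series
  false-detection rate under 5% (checked by simulation in the test
  suite).
- **Above by saturation.** `fdm_cycle()` returns the cycle of steepest
  rise — the centered difference $(F_{c+1}-F_{c-1})/2$ on raw
  readings, ties to the earliest cycle, no smoothing (any smoother
  would add a parameter the data do not demand). Past the FDM the
  efficiency is visibly declining, so the upper bound belongs below
  the FDM fluorescence.

Within those brackets, `boundary_grid_search()` picks empirically: for
each candidate window it computes all per-set pairwise efficiencies
and scores the window by the Monte-Carlo SD of resampled triplicates,
re-using the same seed — hence the identical samplings — for every
candidate so windows differ only in the thing being tested. Windows
leaving any set with fewer than two admitted readings are reported
infeasible rather than erroring, so a coarse grid over a new
instrument's range is safe to run. Membership is a closed interval on
both edges; readings with $F \le 0$ are inadmissible regardless.

## The calibration baseline and the precision harness

The baseline is the classical fit of Cq on $\log_{10}$ concentration
with $E = 10^{-1/slope} - 1$, always on the decimal log regardless of
$b$ (the $\log_b$ parameterisation gives the identical $E$ by change
of base, and one code path avoids divergence). When the layout has no
concentrations they derive as $b^{-D}$; the slope is scale-invariant,
so the arbitrary unit is harmless.

Precision is compared by the resampling scheme standard in this field:
each "sampling" draws 3 *distinct* replicate sets from the pool
(without replacement within a sampling — a wet-lab triplicate has
three different replicas), averages their efficiencies, and the SD
over 100 sampling means is the precision. Samplings are independent of
one another. The defaults 100 and 3 are the conventional choices; the
SD uses the $n-1$ denominator. The harness's own correctness anchor is
exact: the test suite enumerates all $\binom{16}{3} = 560$ triplicates
and checks the Monte-Carlo SD converges to the closed-form sampling SD
at $10^4$ samplings.

## Quantification

With a set-level $E$ in hand, each in-window reading back-casts the
initial fluorescence $F_0 = F_i/(1+E)^i$, and the per-well $F_0$ is
the arithmetic mean over its in-window readings (the model makes every
reading an equally valid estimator, and averaging over the window is
the option with no tuning knob). $F_0$ is linear in the starting
amount, so ratios of $F_0$ are concentration ratios, with no
fractional-cycle construct involved. The Cq route uses the
efficiency-corrected ratio $(1+E)^{\Delta Cq}$; the base is the
amplification factor $1+E$ because $E$ here is fractional.

Two accuracy-flavoured analyses build on this. The maximal-error
analysis takes replicate wells holding identical template — where the
true ratio is exactly 1 — and reports the worst observed ratio: the
extreme Cq pair through the Pfaffl formula at the maximal per-set
efficiency (the exponentiation makes error grow with $E$, so this is
the worst case), against $\max F_0 / \min F_0$ over the same wells.
The dilution-accuracy table uses the known fold-dilutions between
groups of sets as an external standard: expected folds (2, 8, 32 on
the default plate) against observed F0-fold and Cq-fold per group.
Errors follow the convention
$100\,(\text{observed}-\text{expected})/\text{observed}$ — the
convention under which the table's printed errors are reproducible
from its printed folds — and the per-method average is the mean
absolute error over the non-reference groups.

## What the simulator emulates, and what it does not

`simulate_plate()` exists so that every claim above is testable
without an instrument. Its defaults are fixed to the study design the
package targets, and were chosen once, from the experiment's stated
conditions, not adjusted afterwards:

| parameter | default | why |
|---|---|---|
| `e_true` | 0.8 | a realistic efficiency for a well-behaved assay |
| `f0` | 0.004 RFU | undiluted starting fluorescence implied by back-calculation on such assays |
| `base`, `steps`, `n_sets` | 2, 0–5, 16 | 16 replicas of a six-step two-fold series |
| `n_cycles` | 33 | the run length of the emulated protocol |
| `plateau` | 2000 RFU | saturation ceiling; thresholds up to ~230 RFU stay in the lower curve |
| `noise_sd` | 3 RFU | additive Gaussian reading noise spanning ≈ ±10 RFU at ±3σ |
| `set_offsets` | 0,0,1,1,3,3,5,5 ×2 | start amounts 100/50/12.5/3.125 ng across row pairs, giving known folds 2/8/32 |

Saturation is logistic: each cycle's increment is damped by
$(1 - F/\text{plateau})$. That is the simplest smooth monotone damping
that produces the observed shape — efficiency roughly stable early,
then declining — and with `plateau = Inf` the curve is exactly the
closed form, which is what the $10^{-12}$-level exactness tests use.
Cq calls interpolate log-linearly between the flanking cycles, exact
for pure exponentials; a vendor's interpolation rule is undocumented,
and on noiseless curves the two agree anyway. Wells that never cross
the threshold return `NA` with a warning rather than an error, because
on real plates the most dilute wells sometimes do exactly that.

Two honest limitations. First, logistic damping has no perfectly flat
efficiency phase — $E$ declines (slowly) from the first cycle — so
in-window pairwise estimates on the default plate carry a small
downward bias, under 0.01 at the default window, visible in the
parameter-recovery tests. Second, the noise model is purely additive
and well-independent. Real plates add well-to-well systematic
variation (pipetting, optics, position), which is precisely the
variation that makes single-curve calibration fits erratic in
practice. Consequently the simulation reproduces the *precision*
advantage of the pairwise estimator (it shows up robustly in the
Monte-Carlo comparison) but does not reproduce the large
accuracy-table gap between the methods that real data can show: on
synthetic plates both arms land within ~15% average fold error and
neither dominates. Passing tests here validate the machinery and the
precision claim, not every magnitude a real instrument would produce.
An optional per-well log-normal `f0_jitter_sd` exists for users who
want to layer pipetting error on top; it is off by default because no
principled magnitude for it was available.

## Numerical and interface choices

- Cycle numbering is 1-based; the exponent $i$ counts completed
  cycles.
- Histogram bins are anchored at 0, not at the sample minimum, so two
  sets' bins align and the cutoffs land on round efficiencies.
- Ties in the modal bin and in the FDM go to the earliest
  bin/cycle.
- All randomness is scoped: functions taking a `seed` restore the
  caller's RNG state on exit, and identical inputs plus seed give
  bit-identical output (plates, samplings, grid searches, written
  reports).
- Readers reject, rather than repair, malformed inputs: duplicate
  (well, cycle) rows, cycle gaps, non-numeric fluorescence, repeated
  dilution steps within a set, negative or NaN Cq values.
- The native format is long CSV (`well,cycle,rfu`; layout
  `well,set_id,dilution_step,concentration`; `well,cq`), readable and
  diffable; vendor exports convert to it trivially.
- Test and validation problem sizes — 200 resampled six-sets for
  recovery, 50 plates for the precision comparison, 200 random
  instances for the pair-count oracle, $10^4$ samplings for the
  convergence check — were sized to give stable medians and
  proportions for the properties being checked.

## Known limitations

- The estimator inherits the constant-efficiency assumption; on
  chemistry with strong cycle-dependent efficiency the window must be
  narrow, and the estimate is window-conditional.
- The first-outlier detector assumes an approximately linear
  background; strongly drifting baselines should be handled upstream.
- Plates whose wells differ in cycle count are rejected by design; the
  container insists on rectangular runs.
- The accuracy table needs layout concentrations spanning more than
  one start amount; on a plate of identical replicas it has no groups
  to compare and says so.
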