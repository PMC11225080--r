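---
title: "Methods: from oxygen traces to thermal optima and safety margins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from oxygen traces to thermal optima and safety margins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermoscope)
```

This vignette is the package's own account of the science it implements: the
measurement model, the estimators and their assumptions, the parameters that
matter, the numerical choices, and the limits of what the synthetic-data
tests can show about real data.

## The measurement model

Intermittent-flow respirometry alternates *seals* — the chamber is closed and
the animal draws down dissolved oxygen — with *flushes* that restore
saturation. During a seal, oxygen (tracked as percent air saturation) falls
approximately linearly over the 15-minute window, so the uptake rate is
recovered from an ordinary least-squares slope:

$$\dot{M}\mathrm{O}_2 \;=\; -\frac{\text{slope}}{100}\; C_s(T, P)\; V
\quad [\mathrm{mg\,O_2\,min^{-1}}],$$

where the slope is in %-saturation min⁻¹, $C_s(T,P)$ is the air-saturated
oxygen concentration of fresh water (mg L⁻¹), and $V$ the chamber water
volume (L). $C_s$ uses the Benson–Krause relation with the standard vapour
pressure and pressure-factor corrections — the relation behind the widely
used USGS solubility tables, which the unit tests check against (10.08 mg L⁻¹
at 15 °C and 1 atm, etc.). Barometric pressure defaults to 101.325 kPa and is
exposed as a parameter because high-elevation sites sit well below one
atmosphere; the conversion is linear in $C_s V$, so a site-pressure
correction rescales all rates of a trial by a common factor and leaves
factorial scope, optimum locations, and breadths unchanged.

The default protocol mirrors a typical overnight design: 15-minute seals,
3-minute flushes, recording from 7 p.m. to 9 a.m. (46 seals), then a
36-minute exhaustive chase spanning two further flush/seal cycles. Seals are
trimmed by `trim_seconds = 60` at the start to discard flush-mixing carryover
(standard practice; the value is configurable), then split into equal,
non-overlapping sub-windows — two per overnight seal, five per chase seal,
matching the number of usable slope measurements each seal type supports.

## Rate estimators and the quality filter

Per animal: **RMR** is the mean of all overnight rates at or below the lower
10% quantile (linear-interpolation quantile, R type 7; the "at or below"
comparison is non-strict) of the quality-filtered pool — spontaneous activity
inflates some overnight slopes, and the lower-decile mean rejects those.
**MMR** is the highest quality-filtered rate measured during the chase
cycles. **AS** = MMR − RMR and **FAS** = MMR / RMR hold exactly by
construction. Sub-windows with oxygen *increasing* (negative uptake) are kept
in the slope table but flagged, and the estimators drop them.

The quality filter keeps slopes with a coefficient of determination above
0.90. Both a sub-window and a whole-seal $R^2$ are computed, and **the filter
defaults to the seal-level statistic**. The reason is quantitative. The
population $R^2$ of a regression with slope $b$ over a window with time
spread $\mathrm{sd}(t)$ and per-sample noise $\sigma$ is
$b^2\mathrm{var}(t)/(b^2\mathrm{var}(t)+\sigma^2)$ — independent of the
sampling rate. At the cold end of a trial grid (resting uptake ≈ 9 × 10⁻⁴
mg min⁻¹ at 8 °C in a 133-ml chamber) the seal slope is only ≈ 0.057 % min⁻¹.
With 0.05 %-saturation sample noise, a 7-minute sub-window then has a
population $R^2$ of ≈ 0.84 and a 2.8-minute chase sub-window ≈ 0.81: an
honest resting decline *cannot* clear a 0.90 sub-window threshold, and the
only sub-windows that do are the activity-burst ones — the filter would
invert its purpose and the trial would be unusable. The full trimmed
14-minute seal has population $R^2 ≈ 0.96$ and passes. With seal-scope
filtering the lower-decile estimator recovers a known cold-trial resting rate
to within 5% at that noise level (measured −4.3% without activity bursts,
−3.4% with them), which is the behaviour the filter is meant to deliver.
`r2_scope = "sub_window"` remains available for data clean enough to support
it.

Background (blank) respiration is interpolated linearly between the pre- and
post-trial blanks, but is treated as zero unless a blank exceeds the
detection threshold (default 0 — i.e., no adjustment when no background is
detected).

## Thermal performance curves

Each metabolic variable is modelled against test temperature with a catalog
of six forms: `a + bX`, `a + bX + cX²`, `a + bX^1.5 + cX²`,
`a + bX²·ln X + cX³`, the log-polynomial
`a + b(ln X)² + c·ln X + d·ln X/X`, and the double-exponential
`exp(ρX) − exp(ρ·t_max − (t_max − X)/δ)`. **All logarithms are natural
logarithms** — the bundled reference coefficients are only consistent with
that convention, which the tests verify against the published point
predictions.

Fitting minimizes RSS by Levenberg–Marquardt iteration (`minpack.lm::nlsLM`),
from data-driven starts: the five forms linear in their coefficients get
exact OLS starts from their basis expansion, the double-exponential gets a
heuristic (log-slope of the rising limb, `t_max` just above the warmest
observation). Ten multiplicatively jittered restarts (each parameter × U[0.5,
2], seeded) guard against local minima; fits that overflow or fail to
converge are dropped, and a form is only reported if at least one start
converges. Convergence tolerances are `ftol = ptol = 1e-12`.

Model selection uses Gaussian-likelihood AIC, $n\ln(2\pi\,\mathrm{RSS}/n) +
n + 2(k+1)$, counting the error variance as a parameter — the same convention
as `stats::AIC`, which a test cross-checks. Among fits within 2 AIC units of
the minimum, the fewest-parameter model wins; ties break by lower AIC, then
catalog order. Only AIC *differences* ever matter, and a test verifies
selection is invariant to a constant shift. Fit quality is summarized as the
adjusted r² of the linear regression of observed on fitted values.

Near its peak the double-exponential is a difference of two large, nearly
equal exponentials (both ≈ 40.5 for the bundled coefficients at 24.8 °C,
difference ≈ 7 × 10⁻³). It is evaluated as
$e^{s_2}\,\mathrm{expm1}(s_1 - s_2)$, which keeps full relative precision in
the difference rather than subtracting two ~40s in floating point.

## Optima and breadth

Predictions are evaluated on a dense grid (0.01 °C steps) over the span of
test temperatures, 7.8–30.1 °C by default; the reference analysis never
extrapolates beyond the tested range, and the domain is configurable. Topt is
the grid argmax (exact ties break toward the cooler temperature); Topt90 and
Topt80 are the maximal *contiguous* interval containing the peak where the
prediction stays at or above 90% / 80% of the peak value. If the threshold
set is disconnected — possible for wiggly log-polynomials — the component
containing the peak is reported and the number of other components is
attached as an attribute rather than silently merged. Temperatures are
reported to 0.1 °C (the customary precision for these quantities); the grid
itself is 0.01 °C, and a refinement test checks that halving the step moves
Topt by less than one step.

**How precisely can an optimum be located?** Less precisely than intuition
suggests. For the bundled warm-site aerobic-scope curve the region within 10%
of the peak spans 8 °C, and realistic residual scatter (RSE ≈ 0.00083 against
a peak of 0.0039) puts the sampling standard deviation of the fitted Topt
near 1 °C at n = 44 — both by the delta method applied to the `nlsLM`
coefficient covariance and by direct simulation. Recovery of Topt to ±0.5 °C
is therefore *not* a property this design can promise (the suite carries a
calibration check at that strength, and it documents exactly this limit);
breadth intervals (Topt90/Topt80 endpoints) are the more stable summaries.
The 2-unit parsimony rule adds a further caveat: at this noise level a
3-parameter quadratic is often competitive with the 4-parameter generating
form, and its vertex sits systematically warmer for this asymmetric curve.

## Habitat thermal regime metrics

Hourly logger series collapse to per-calendar-date mean/min/max (UTC dates;
partial days are flagged, not extrapolated). From the daily table:
7DADMean/Max/Min are 7-day moving averages using only windows fully contained
in the period (25 windows in a 31-day month), and the period summary is the
mean of the window values; the diel range is the mean of daily max − min.
**Cumulative degree days are the plain sum of daily means over the period,
and degree hours the plain sum of hourly readings** (°C·days, °C·hours): a
31-day month averaging 17 °C accumulates ≈ 529 degree days and ≈ 12 700
degree hours. A literal "days × sum" product would be ~31-fold larger and
inconsistent with how these metrics are conventionally reported; the sums are
the definition used here. On a constant series CDH = 24 × CDD exactly, which
is a test invariant.

Threshold exposure counts, for a reference interval such as a population's
Topt90 range, the days whose daily mean/min/max fall below, within (inclusive
bounds), and above the interval — these partition the period, another test
invariant — plus the hourly readings above the upper bound and within the
interval. Winter metrics bound the freezing season by the first sub-freezing
daily minimum after 1 September and the last before 1 June; a site that never
freezes falls back to a fixed 11 November–16 April window, and the counts of
days with min ≤ 0 °C and max ≤ 0 °C plus the February minimum are reported.

Thermal safety margins subtract a habitat maximum estimate from the
population's Topt90 upper limit: TSM_Max uses the August hourly maximum,
TSM_7DADMax the August mean 7DADMax. Negative values mean the habitat already
exceeds the optimum breadth.

## The synthetic-data generator

The generator exists so every stage is testable against known truth. Traces:
within-seal decline is *linear* in saturation at the slope implied by the
true rate through the inverse of the conversion above — consistent with the
slope-based analysis (no exponential washout is simulated, and flush
hydrodynamics are not modelled; flush samples are excluded from analysis
anyway). Overnight uptake sits at the resting truth, transiently elevated by
Poisson-placed activity bursts (multiplicative 1.5–3 × RMR for 1–5 minutes,
capped at the maximum truth) — these produce the high-slope outliers the
lower-decile estimator must reject. Chase-phase uptake equals the maximum
truth. Gaussian iid noise (default 0.05 %-saturation per sample, a free
parameter since real optode noise magnitude is instrument-specific) is added
per sample and clamped to [0, 100 + 3σ]. With zero noise the full chain
returns the generating rates to 10⁻⁹ relative — the round-trip test.

Cohorts assign one animal per test temperature across 7.8–30.1 °C and draw
per-animal true rates from the bundled population curves plus Gaussian
scatter at each curve's residual standard error; chamber volumes (129–137 ml)
and dry masses (0.034–0.311 g) are drawn uniformly over the observed ranges.
Habitat series are annual mean + seasonal sinusoid + diel sinusoid + noise,
optionally clipped at a freezing floor; the two presets are tuned to land
near the two reference sites' August means, diel ranges, and winter
behaviour (a diel half-amplitude of 5.3 °C reproduces the ~10.6 °C observed
daily max−min; the warm site's floor of −0.1 °C rides the freezing point all
winter while the dam-stabilized preset never freezes).

What the generator does **not** emulate — and hence what passing tests do not
show about real data: optode drift and autocorrelated sensor noise,
temperature fluctuation within a trial, background microbial respiration,
diurnal metabolic rhythms, mass–rate covariance (true rates are drawn
independently of mass), and non-sinusoidal weather events in habitat series.

## Allometry

Mass effects are screened, not modelled: `allometric_scan()` rescales RMR and
MMR by mass⁻ᵇ for b on a grid over [0, 1], refits the aerobic-scope response,
and reports the drift of the optimum breadth. At b = 0 the identity holds
exactly, and with equal masses any b is a common rescaling that cannot move
the optimum. With *random* masses spanning the full observed 9-fold range,
dividing mass-independent synthetic rates by mass¹ injects ~64% multiplicative
scatter and the refitted range wanders by several degrees — so the stability
conclusion is meaningful for real data (where rates co-vary with mass, so the
division removes variance rather than adding it) and is exercised in tests
with a modest mass spread, where the adjustment approximates a common
rescaling.

## Problem sizes and runtime choices

The test suite uses trace sampling intervals of 5–10 s (the generator's 1 s
default matches continuous optode logging; the coarser test cadence leaves
≥ 28 samples per sub-window and does not change population R², which is
sampling-rate-free), cohorts of 12–44 animals, 40–100 simulation seeds for
calibration checks, and single-month habitat series — sizes chosen so the
whole suite runs in well under a minute while every estimator is exercised at
the reference design's geometry. The acceptance script is deterministic model
evaluation on 0.01 °C grids and runs in seconds.

## Known limitations

* Optimum *location* is weakly identified at realistic scatter (see above);
  prefer breadth intervals for cross-population comparisons.
* The lower-decile RMR rule is mildly conservative: with iid noise and no
  activity it sits 2–4% below the true resting rate; MMR, as a maximum over
  noisy estimates, sits a few percent high.
* Daily statistics use calendar dates in the logger's (UTC) clock; no
  partial-day extrapolation or time-zone shifting is attempted.
* Degree-hours above a threshold count readings, not exceedance-weighted
  magnitudes.
* No uncertainty bands are produced for Topt or breadth endpoints, and no
  mixed-effects (year, individual) structure is modelled; years are pooled
  within population as in the reference analysis.
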