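---
title: "Estimating dormancy break dates and agroclimatic requirements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating dormancy break dates and agroclimatic requirements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chillreq)
```

## The problem

Temperate fruit trees release winter endodormancy only after accumulating
a cultivar-specific amount of chill (the chilling requirement, CR) and
then flower after accumulating a cultivar-specific amount of heat (the
heat requirement, HR). Neither the transition date nor the requirements
can be observed directly in the field, so they are estimated — from
forcing trials on cut shoots, from long series of bloom dates and
temperatures, or from developmental biomarkers. `chillreq` implements the
whole chain: chill/heat accumulation models, four break-date estimators,
the requirements pipeline with classification bands, and Bland–Altman
agreement analysis between methods, together with a synthetic generator
that makes every stage testable against a known ground truth.

All computations run on hourly temperature series (°C, local standard
time, no DST shifts). The dormancy season spans September 1 to April 30;
day-of-season indices anchor October 1 as day 1, which puts April 30 at
day 212 in seasons whose February has 28 days. In leap seasons
February 29 keeps its own index (April 30 = 213): estimators report
calendar dates, so comparability across seasons is unaffected and no real
day of weather is dropped.

## Accumulation models

**Dynamic chill portions.** Chill accumulation is modelled as a two-step
process. An intermediate product $x$ relaxes each hour toward a
temperature-dependent equilibrium $x_s(T) = (a_0/a_1)\,e^{(E_1-E_0)/T}$
at rate $k_1(T) = a_1 e^{-E_1/T}$ ($T$ in Kelvin):
$x \leftarrow x_s - (x_s - x)\,e^{-k_1}$. Cold hours raise $x$; warm
hours pull it back down. When $x$ reaches the critical level 1, the
fraction $\xi(T) = s/(1+s)$ with
$s = \exp\!\big(\mathrm{slp}\cdot\mathrm{tetmlt}\,(T-\mathrm{tetmlt})/T\big)$
converts irreversibly into chill portions (CP) and leaves the pool.
Portions can never be destroyed, so cumulative CP is non-decreasing —
warm spells cost only the intermediate pool. The constants
(`dynamic_params()`: slp 1.6, tetmlt 277 K, $E_0$ 4153.5, $E_1$ 12888.8,
$a_0$ 1.395·10⁵, $a_1$ 2.567·10¹⁸, Kelvin offset 273) are the canonical
published values, frozen in one place for bit-reproducibility. The
recursion is sequential by nature and is implemented in C++; the test
suite holds it to an independent straight-line R transcription at 10⁻⁹ on
a thousand random series, and checks invariance to splitting a series
into chunks with carried state.

**Utah chill units.** Stepwise hourly weights: 0 up to 1.4 °C, 0.5 to
2.4 °C, 1 to 9.1 °C, 0.5 to 12.4 °C, 0 to 15.9 °C, −0.5 to 18 °C, −1
above. The often-quoted "chill between 1.5 and 12.4 °C" is the positive
band of this table; the negative bands matter because the Utah
convention starts counting at the day when the running cumulative CU
reaches its minimum (`utah_start_date()`, ties broken toward the latest
such day, restart at zero from the following hour).

**Weinberger chilling hours.** One hour strictly below 7.2 °C (45 °F)
counts one CH, from the first qualifying autumn hour.

**Growing degree hours.** Heat is the capped-linear form
$\max(0, \min(T, 25) - 4.5)$ °C·h. A plain count of hours above 4.5 °C
would saturate near 24 per day and could never reach the thousands of
units per forcing period that requirement studies report; the linear
degree-hour form with the standard 25 °C cap is therefore used.

## Break-date estimators

**Forcing test.** Shoots collected weekly are held 8 days in a warm
chamber; endodormancy is considered overcome at the first collection
whose mean chamber bud weight reaches 1.30 × the mean field weight
(inclusive, means of the 10-bud samples). If no collection qualifies the
estimator returns a `not_released` sentinel rather than a date.

**Correlation model.** For each grid day $d$ (1…212) the daily mean
temperatures are averaged over a 15-day window and correlated across
years with the bloom day-of-season. Warm weather while chill is limiting
delays bloom (positive correlation); warm weather during forcing advances
it (negative). Significance uses the two-sided critical value
$r^* = t_{1-\alpha/2,\,n-2}\big/\sqrt{t^2_{1-\alpha/2,\,n-2} + n - 2}$
(0.553 for 13 years at α = 0.05). The transition period runs from the
last day with $r \ge r^*$ to the first later day with $r \le -r^*$; the
break is its mid-point, rounded half-up. The window is centred
($d-7 \dots d+7$, truncated at the grid edges); window length and α are
arguments. Profiles with a zero-variance response are returned as
all-zero with a flag, and a missing transition yields an `undetermined`
sentinel with a diagnostic rather than a guess.

**PLS phase delineation.** Bloom day-of-season is regressed by NIPALS
partial least squares (2 components by default) on the seasons × days
matrix of daily CP gains, and separately on daily GDH gains, both centred
and scaled per column (zero-variance days get coefficient 0, VIP 0).
Daily rates are smoothed beforehand with a centred 11-day running mean
(configurable; 1 disables), standard practice in PLS phenology because
single-day rates are noisy. Days whose higher accumulation rate advances
bloom show negative coefficients; variable importance in projection above
0.8 marks them reliable. The chilling phase is the longest such run in
the chill model, tolerating up to 5 interior non-qualifying days
(phases in published analyses are contiguous *trends*, not strict runs);
its last day is the break date. The forcing phase is delineated the same
way in the heat model among runs starting after the chilling phase, and
the day gap between the phases is reported as the transition length.

**Biomarker pass-through.** Externally observed break dates (one per
season) are taken as-is; the per-cultivar date is their mean on the
day-of-season ordinal, rounded half-up. Dates are averaged on ordinals
rather than raw `Date`s so that seasons from different calendar years are
commensurable.

## Requirements, summaries and agreement

CR is the model's cumulative value at 24:00 of the break date, counted
from the model-specific start (Dynamic: September 1 — appropriate for
climates where no chill occurs earlier, configurable; Utah: the
maximum-negative-effect restart; Weinberger: the first sub-7.2 °C hour).
HR is GDH over the closed day span from the break date to F50. Methods
that date the break per season (forcing, biomarker) get per-season
CR/HR, then mean ± sample SD (n − 1) and cv = 100·SD/mean. Methods that
produce a single day-of-season (correlation, PLS) apply that fixed
calendar day in every season; the reported SD/cv describe the spread of
the accumulations to that fixed date across seasons — the only
construction under which a single-date method has a defined SD. A single
season reports SD 0 with an explicit flag; a zero mean makes cv `NA`
rather than infinite.

Classification follows the published integer bands. Because printed
integer bands leave real-valued gaps, bands are closed half-open at the
upper printed bound (CR medium = [56, 66); the HR gap (3900, 3901) closes
upward into medium). CR values below 50 CP are flagged `below_range`
instead of being silently binned. These rules reproduce the published
memberships of all 20 reference cultivars exactly (checked in the test
suite from the shipped `published_requirements()` tables).

Bland–Altman agreement uses differences of per-cultivar CP values:
bias = mean difference, limits of agreement = bias ± 1.96·SD (sample SD;
the 1.96 multiplier is the fixed normal quantile, not re-derived from
t), points exactly on a limit count as inside (conservative toward
agreement), and two methods agree when at least 95 % of cultivars fall
inside. All six unordered pairs of the four methods are enumerated by
`compare_methods()`.

## The synthetic generator

`gen_weather()` builds each season's hourly series as

> seasonal sinusoid + per-season mean shift + diurnal sinusoid +
> daily-step AR(1) anomaly,

with defaults describing a dry inland Mediterranean climate: annual mean
15 °C, seasonal half-range 9.5 °C with the coldest day near January 15,
diurnal half-range 5 °C peaking at 14:00, AR(1) coefficient 0.8 per day
with innovation SD 1.5 °C (stationary SD 2.5 °C, decorrelation ≈ 4.5
days — synoptic weather-regime persistence; the anomaly is held constant
within a day), and an interannual shift SD of 0.8 °C. Under these
defaults season totals reach roughly 90–115 CP by the end of March, the
range long-term records from such climates show. All draws derive from
one master seed through fixed per-season/per-cultivar stream offsets, so
identical configurations are bit-identical and adding cultivars never
perturbs existing ones.

`gen_bloom_records()` embodies the sequential dormancy model as ground
truth: the true break is the first hour at which Dynamic CP (from
September 1) reaches CR\*; true F50 is the first later hour at which GDH
reaches HR\*; observed F50 adds rounded Gaussian day noise (default SD
2 days). Seasons where either requirement is unreachable are flagged
`no_bloom`. `gen_bud_weight_trials()` and `gen_biomarker_dates()`
generate forcing-trial and biomarker observations consistent with that
truth (chamber/field weight ratios around 1.10 before and 1.45 after the
break, clipped to the correct side of the 1.30 criterion; biomarker
dates jittered ±2 days).

What the generator does *not* emulate: month-scale and teleconnection
driven climate anomalies (its memory is ≈ 4.5 days plus a season-wide
shift), weather-station artefacts (gaps, sensor drift — gap handling is
exercised with constructed files instead), any biological deviation from
the sequential model (chill–heat overlap, partial chill compensation,
frost damage), and calibration to any particular station's record.
Passing tests on synthetic data therefore demonstrate correctness of the
estimators' mechanics under the stated model, not their field validity.

## The recovery experiment and its interpretation

`recovery_experiment()` simulates independent cultivars (CR\* uniform in
45–85 CP, HR\* in 3500–5500 GDH, 20 seasons each), runs the correlation
and PLS estimators on the observable records only, and scores the break
date against the mean truth break (±10 days) and the implied CR against
CR\* (±8 CP). The test suite and `scripts/acceptance.R` run it at 100
cultivars and report the recovery rates.

The experiment is informative precisely because its result is sobering:
under the sequential ground-truth model the recovery rates are far below
what one might hope (the acceptance run reports them; they are near
zero for the correlation method). The cause is structural, not numeric.
In the sequential model a season whose break comes $\Delta$ days late
starts forcing $\Delta$ days later into a warming spring, so the bloom
date moves by only about
$\Delta \cdot r_{\mathrm{GDH}}(\text{break}) / r_{\mathrm{GDH}}(\text{bloom})$
— with a January break (~60 GDH·day⁻¹) and a March bloom
(~180 GDH·day⁻¹) roughly 90 % of any break-date shift is absorbed before
it reaches the bloom record. Bloom variance is then dominated by spring
forcing anomalies, the chilling-side correlations rarely reach the
critical value (0.44 at 20 seasons), and no estimator that sees only
bloom dates and temperatures can locate the break precisely. Real
multi-decade records evidently carry a stronger chilling signal than
this idealised truth model produces — real dormancy does not hand over
from chill to heat at a single hour, and real climate anomalies persist
on longer scales. The estimators themselves are exact: each is verified
against constructed profiles and independent transcriptions at 10⁻⁹.

## Numerical and design choices

* Missing weather: gaps ≤ 6 h may be filled linearly
  (`fill_policy = "linear_fill_max6h"`); longer gaps are errors, never
  silently bridged.
* Daily-only records: `interpolate_hourly()` places the minimum at 05:00
  and maximum at 14:00, rises on a quarter sine and decays linearly to
  the next dawn; daily extremes are reproduced exactly at the anchors.
* Tie-breaks are documented and tested: mid-point and date means round
  half-up; the Utah start takes the latest minimum; phase runs prefer
  the later of equal spans.
* Thresholds are inclusive where the criterion says "reaches": the
  forcing 30 % criterion, VIP > 0.8 (strict), CP conversion at pool ≥ 1,
  Weinberger strictly below 7.2 °C.
* Degenerate inputs return flagged sentinels (`not_released`,
  `undetermined`, `no_bloom`, cv `NA`) rather than fabricated values.
* Problem sizes in the shipped tests (series up to 2000 h for oracle
  sweeps, 100 × 20-season recovery, 10⁴-pair Bland–Altman check) keep the
  full suite in the minutes range while leaving every statistical check
  adequately powered.

## Limitations

Beyond the generator's idealisations above: the correlation and PLS
methods intrinsically need long series (≥ 11 seasons enforced); the
season grid treats hourly records as local standard time and leaves DST
artefacts to the gap policy; the Utah start rule makes CU requirements
sensitive to warm autumns in a way CP/CH are not; and classification
bands are specific to the published apricot reference set — they are
reported alongside, not instead of, the continuous values.
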