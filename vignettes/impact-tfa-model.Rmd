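---
title: "Modelling CHD gains from trans-fat reduction: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling CHD gains from trans-fat reduction: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(impacttfa)
library(dplyr)
```

## The model

`impacttfa` implements a stratified counterfactual (comparative risk
assessment) model of coronary heart disease (CHD) outcomes under reductions
in dietary trans fatty acid (TFA) intake. The population is divided into 70
strata: seven ten-year age bands (25–34 … 85+) × two sexes × five
socio-economic circumstance (SEC) quintiles derived from area deprivation
scores. Throughout the package quintile 1 is the most affluent and quintile
5 the most deprived; this orientation matches the survey evidence that
deprived groups consume more trans fat, and it is deliberately explicit in
every schema because published tables often leave it ambiguous.

Three outcome measures are computed per stratum and year:

* **Deaths prevented or postponed (DPP).** For stratum $s$ with quintile
  $q(s)$,
  $$\mathrm{DPP}_s = D_s \cdot \min\{\Delta_{q(s)} \, m_{a(s),g(s)},\, 1\},$$
  where $D_s$ is the expected number of CHD deaths under no change in
  intake, $\Delta_q$ is the quintile's intake reduction in percent of daily
  energy, and $m_{a,g}$ is the mortality-reduction factor per 1% of daily
  energy for age band $a$ and sex $g$. The dose response is linear — a
  0.5% reduction yields exactly half the effect of a 1% reduction — with a
  cap at 1 (a scenario cannot prevent more deaths than are expected).

* **Life-years gained (LYG).** Each prevented death is weighted by the
  median survival of the CHD-state subgroup in which it was averted
  (diagnosed CHD, undiagnosed CHD, free of CHD):
  $$\mathrm{LYG}_s = \mathrm{DPP}_s \sum_k w_{a(s),k}\, S_k(s).$$
  Undiagnosed-CHD survival is always the midpoint of the diagnosed and
  no-CHD medians. The per-quintile life-expectancy (LE) index — anchored at
  exactly 1.0 for quintile 3 — rescales the undiagnosed and no-CHD
  survivals; diagnosed-CHD survival is *not* SEC-indexed, because no
  deprivation-stratified survival data exist for diagnosed patients. This
  is conservative: it probably understates the true survival gradient.

* **Admissions avoided.** The same stratum-level mortality-reduction
  fraction is applied to baseline incident admissions for acute myocardial
  infarction (AMI), unstable angina (UA) and heart failure (HF). Only
  these incident groups are modelled; community-prevalence groups are out
  of scope because case fatality is held constant, so within each stratum
  the avoided counts preserve the baseline AMI:UA:HF ratios exactly.

Inequality is summarised on *rates*, not crude counts: quintile populations
differ strongly at old ages (shorter life expectancy thins the deprived
quintiles), so `compute_rate_index()` divides each quintile's outcome total
by its population, within any requested age–sex group, and indexes on
quintile 3 (≡ 1.0).

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| population-average effect | 0.12 | fraction per 1% TFA energy | meta-analytic estimate that 1% of daily energy from TFA raises CHD mortality ~12% |
| effect bounds | 80% / 120% of mean | — | the sensitivity envelope used for all uncertainty propagation |
| equal-scenario baseline intake | 1.3 | % daily energy | UK population mean from low-income diet survey data |
| unequal baseline intake | 0.75 / 0.87 / 1.0 / 1.25 / 1.5 | % daily energy, q1…q5 | survey gradient: deprived quintiles consume more TFA |
| PSA draws | 5,000 | — | default; 10,000 with 5/95 centiles equally supported |
| PSA percentiles | 2.5 / 97.5 | — | 95% interval |

The age/sex effect table is *parametric*: the exact stratified factors used
in published work live in supplementary material that is not distributed,
so the default table spreads the 12% population-average anchor across age
bands with a configurable attenuation schedule (identical for both sexes by
default), calibrated so that the population-weighted mean is exactly the
anchor. Any externally estimated table matching the schema overrides it.
The attenuation mirrors the age gradient observed for cholesterol-mediated
CHD mortality effects: relative effects shrink with age. The 85+ band —
never covered by trial or cohort estimates — is extrapolated by continuing
the geometric attenuation ratio, $m_{85+} = m_{75–84}^2 / m_{65–74}$; a
linear continuation is available behind a flag for audit.

### Apportioning prevented deaths over CHD states

No published source states how DPPs split across the diagnosed /
undiagnosed / no-CHD subgroups, yet the split drives LYG. Rather than bury
an assumption, `default_subgroup_shares()` is an explicit, documented input:
the diagnosed share rises with age (0.30 → 0.65) as prevalent disease
accumulates, the undiagnosed share is roughly flat (~0.25), the remainder
are event deaths in people without recognised CHD. Every LYG result should
be read conditional on this input, and sensitivity explored by supplying
alternatives.

## Uncertainty propagation

`run_psa()` re-evaluates the pipeline over seeded Monte Carlo parameter
draws and summarises each output cell by empirical percentiles (type-7
linear interpolation between order statistics — the estimator is stated
exactly because spreadsheet tools differ). Two design choices deserve
explanation:

* **Shared effect factor (default).** The uncertain quantity behind the
  effect table is a single pooled estimate; the age/sex gradient is a
  deterministic transformation of it. The default therefore draws one
  scale factor per iteration, applied to the whole table
  (`effect_draw = "shared"`). This makes total DPP exactly linear in the
  drawn factor, so with uniform bounds $(0.8m, 1.2m)$ the 2.5th percentile
  of total DPP sits at $0.81m$ in closed form — a property the test suite
  exploits. Cell-wise independent draws (`effect_draw = "cellwise"`) are
  available where one prefers to treat each cell as its own parameter;
  they give narrower totals because independent cell errors partially
  cancel.

* **Families.** Effect factors default to a truncated normal (mean at the
  point, sd = (high − low)/(2 × 1.96), resampled below 0); survival to a
  uniform on the 80%/120% envelope. Both respect the printed bounds; the
  per-class family is configurable because the original distribution list
  is not available. Setting bounds to `c(1, 1)` makes a class degenerate,
  which collapses intervals onto the point estimates — a useful audit.

Draw streams are indexed by (seed, draw id, parameter class) through a
Lehmer-style mix, so the same (seed, draw id) pair always reproduces the
identical draw, reruns are bit-identical, and adding a parameter class does
not shift existing streams.

## What the synthetic generator emulates — and what it does not

Real inputs to this kind of model (national mortality registers, hospital
episode statistics, survival follow-up studies) are restricted, so
`synthetic_spec()` + `generate_*()` create baselines with the *statistical
structure* the method assumes:

* CHD death rates doubling every 7 years of age, a male excess of 1.8, and
  a log-linear deprivation gradient reaching 1.5 between quintiles 5 and 1;
* an adult population of 35 million with a plausible age pyramid, mild
  female excess at old ages, and thinner deprived quintiles above 75;
* 32,000 expected CHD deaths per year, of the order of an
  England-and-Wales forecast year, apportioned to strata by largest
  remainder so stratum counts are integers summing exactly to the total;
* admissions at 0.65 (AMI), 2.9 (UA) and 0.75 (HF) per death — about
  140,000 incident admissions — with AMI/UA peaking in middle age and HF
  in old age;
* median survival declining with age from 9 (diagnosed) and 15 (no CHD)
  years at 65–74, undiagnosed at the midpoint, and an LE index running
  linearly 1.08 → 0.92 across quintiles.

Generation is deterministic given the spec: fixtures do not carry sampling
noise, so stochastic variation is attributable solely to the PSA. These
magnitudes are *illustrative*. Passing tests demonstrate that the
machinery is correct (linearity, conservation, anchoring, oracle
equivalence, seeded reproducibility), not that any particular published
total is reproduced: real registry data have cohort effects, non-monotone
quintile patterns, readmissions and coding artefacts that the generator
deliberately omits.

## Numerical choices

* **Rounding** is presentation-only: totals are displayed to the nearest
  100 (nearest 1,000 above 10,000) in `value_display` columns, while all
  machine output keeps full precision.
* **Largest-remainder apportionment** breaks ties by first occurrence in
  stratum-grid order, making generation deterministic.
* **Degenerate inputs**: a zero-reduction scenario produces valid all-zero
  artefacts; the rate index is reported as `NA` (not an error) in exported
  tables when the quintile-3 anchor rate is zero, and
  `compute_rate_index()` itself refuses the undefined division.
* **Caps**: the scaled mortality-reduction fraction is capped at 1, so
  implausibly large doses cannot prevent more deaths than expected.
* The middle coarse reporting band is 55–74 inclusive; published table
  headers sometimes print "55–75" for the same rows.

## Problem sizes used by the test suite

The shipped tests run the full 70-stratum pipeline throughout; oracle
equivalence is checked on 1,000 randomly generated cases against an
independently coded brute-force implementation, and the Monte Carlo
closed-form check uses 50,000 draws. These sizes were chosen as the
smallest that make the stochastic assertions sharp.

## Known limitations

* The effect of intake *increases* is out of scope, as are substitution
  effects of replacement fats and any separate treatment of ruminant TFA.
* Case fatality and community prevalence are held constant; there is no
  prevalence feedback or readmission model, so admissions gains are likely
  conservative.
* The default effect table is a calibrated construction, not an estimated
  dataset; conclusions about age structure of gains should come from an
  externally supplied table.
* The subgroup apportionment of DPPs is an assumption surfaced as an
  input, not an estimate.

## A minimal run

```{r example}
spec <- synthetic_spec(seed = 1)
baseline <- generate_baseline(spec)

imp <- estimate_impact(
  baseline = baseline,
  scenario = uniform_reduction_scenario(1.0),
  admissions = generate_admissions(spec, baseline),
  survival = generate_survival(spec),
  psa = psa_config(n_draws = 1000, seed = 1)
)
glance(imp)
imp$totals
compute_rate_index(tidy(imp), baseline, metric = "dpp")
```
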