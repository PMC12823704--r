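---
title: "Modelling the benefits and costs of statin primary prevention"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the benefits and costs of statin primary prevention}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(statinCEA)
```

## The model

statinCEA implements an annual-cycle Markov cohort state-transition model of
lifelong statin therapy for the primary prevention of atherosclerotic
cardiovascular disease (ASCVD), evaluated for the adult population between
ages 25 and 99. A cohort enters event-free at a chosen treatment start age
and is propagated one year at a time through seven states: four living
(event-free; history of at least one coronary event, CHD; history of at
least one cerebrovascular event, CVE; history of at least one of each) and
three absorbing dead states split by cause (fatal CHD, fatal CVE,
other-cause death). Age 99 is the final modelled cycle.

Five event types drive the transitions, with annual probabilities per sex
and age: non-fatal CHD, non-fatal CVE, fatal CHD, fatal CVE, and death from
any other cause. They are derived from a cause-of-death life table as

$$p^{fat}_{chd} = q \cdot f_{chd}, \qquad
  p^{fat}_{cve} = q \cdot f_{cve}, \qquad
  p^{oth} = q - p^{fat}_{chd} - p^{fat}_{cve},$$

where $q$ is the annual all-cause death probability and $f_{chd}, f_{cve}$
are the fractions of deaths attributed to coronary and cerebrovascular
disease. Non-fatal probabilities are imputed with fixed non-fatal:fatal
ratios, 2.89 for coronary and 3.31 for cerebrovascular events. The three
fatal probabilities partition $q$ exactly, which the tests verify to
machine precision.

### Within-cycle composition

The three death causes compete additively within a cycle. Conditional on
surviving the cycle, non-fatal CHD and CVE occur as independent events, so
both can coincide within one year; a simultaneous pair is the only route
into the combined-history state. Independence is the minimal assumption
given that coincidence must be possible but no dependence structure is
specified. A person who dies in a cycle is counted as the death only: the
survivor-conditional construction makes non-fatal events survivor-only by
definition, so no non-fatal event cost is accrued in a death cycle.

A history of disease modifies subsequent risk once, never compounded: after
a coronary event both coronary probabilities are multiplied by
$c_1 = 1.444$; after a cerebrovascular event the cerebrovascular ones by
$c_2 = 2.666$; after both, both multipliers apply. Transitions between the
two event families are excluded, so a person with only a coronary history
has zero cerebrovascular risk and vice versa — a deliberate simplification
inherited from the model's source assumptions, not an epidemiological
claim. Recurrent non-fatal events leave the state unchanged (only the
existence of a history matters for risk) but are still counted as incident
events, and by default accrue the event cost at every occurrence;
`cost_params(recurrent_costs = FALSE)` switches to first-events-only, since
either accrual convention is defensible.

### Risk calibration

The model is anchored to the 10-year risk scale used by clinical treatment
thresholds (the combined endpoint of the Pooled Cohort Equations: non-fatal
myocardial infarction, CHD death, or any stroke). `calibrate_risk()` finds
the single scalar $k$ multiplying all four cardiovascular probabilities at
every age at or above the start age such that an untreated, event-free
cohort's cumulative probability of a *first* combined-endpoint event within
ten one-year cycles — with competing other-cause death — equals the target.
The cumulative risk is strictly increasing in $k$, so bracketed bisection on
$[10^{-6}, 10^3]$ has a unique solution; iteration stops when the achieved
risk is within $10^{-8}$ of the target. Probabilities, not hazards, are
scaled, because the model is specified in annual probabilities; scaled
values are clamped during bracketing, and the final calibrated set raises
an error if any probability would exceed 1. Whether the original analysis
scaled fatal and non-fatal components jointly is not documented; the single
joint scalar is the minimal identifiable choice.

Treatment multiplies the four cardiovascular probabilities by $1 - rrr$
with $rrr = 0.30$ in every age, sex and risk stratum; other-cause death is
untouched; adherence is perfect; treatment is lifelong from the start age.

### Two calibration targets for a scenario cell

A scenario cell (threshold $\tau$, start age $a$) can be calibrated two
ways. The default, `calibrate_to = "mean_risk"`, targets the mean 10-year
risk of the whole treated stratum (everyone above $\tau$), because a
population-level table row treats the entire stratum, not marginal persons
at the threshold. `calibrate_to = "threshold"` targets $\tau$ itself, which
compares *like cohorts* across start ages: the same 10-year risk evaluated
at different ages. The qualitative orderings expected of the model — NNT
falling with threshold and rising with start age, QALY gain falling with
start age, ICER falling with threshold — are asserted in the point-risk
mode. In stratum-mean mode the mean treated risk itself rises with the
start age, which partially offsets the competing-risk effect; with a steep
external risk gradient the age orderings can invert, which is a property of
the inputs, not of the engine.

## Economic valuation

All conventions are end-of-cycle: a cycle's QALYs and statin cost are
credited according to the state occupied at its end, so the death cycle
contributes neither (the fatal event's direct cost is accrued in that
cycle); there is no half-cycle correction. Discounting starts at treatment
start, $d(t) = 1.03^{-t}$ with $t = 0$ for the first cycle.

* **QALYs** — sum over cycles of the discount factor times
  occupancy-weighted utilities: 1.0 event-free, 0.9648 after CHD, 0.8835
  after CVE, 0.8524 after both.
* **Life expectancy** — undiscounted, unweighted expected life-years; a
  demographic quantity, deliberately not discounted.
* **Statin cost** — 100 EUR per year alive, discounted.
* **Event costs** — expected incident events times direct unit costs
  (fatal CHD 10,671 EUR; non-fatal CHD 20,215 EUR; fatal CVE 11,874 EUR;
  non-fatal CVE 24,044 EUR), discounted.
* **ICER** — discounted statin cost of the treated arm divided by the
  incremental discounted QALYs; by the published definition the numerator
  is gross, with avoided event costs reported separately
  (`icer(..., net = TRUE)` nets them out).
* **NNT** — inverse of the absolute reduction in the cumulative
  probability of a first combined-endpoint event over five cycles,
  competing mortality included in both arms; five years matches the typical
  duration of the randomised statin trials.

Because everything is truncated at age 99 and utilities multiply living
years, QALYs can never exceed life-years, and setting the discount rate to
zero with unit weights makes the two coincide exactly — both are identity
tests in the suite.

## Uncertainty: microsimulation bootstrap

Point estimates come from the deterministic cohort expectation, which is
exact for this model (verified against exhaustive path enumeration on a
three-cycle toy at $10^{-12}$). Confidence intervals come from a paired
microsimulation: 20,000 individual life courses per arm sampled from the
same cycle structure, with utility weights drawn once per iteration from
their published 95% CIs (normal on the weight scale, sd = CI width / 3.92,
truncated to $[0,1]$) and shared between the arms of an iteration, while
event randomness is independent between arms. Both sources of uncertainty
are switchable (`sample_utilities`). The reported interval is a percentile
bootstrap (1,000 resamples) of the *mean* per-iteration gain — the
quantity the tables report — rather than the spread of individual gains,
which is orders of magnitude wider. Cross-sex intervals combine the two
sexes' per-iteration outcomes with the population sex weights before
resampling.

## Population aggregation

Per-sex outcomes are combined with the population's sex proportions: at the
treatment start age for single-cohort quantities (NNT, QALYs, ICER), and
per year of life for population-level life-expectancy gains. The treated
share of the population and the stratum's mean risk come either from a
parametric risk distribution (below) or are supplied directly as published
reference values (`german_reference_grid()`, shipped in `extdata`). The
annual budget is the undiscounted steady state, share × population basis ×
100 EUR; the population basis is an explicit argument because published
shares refer to the adult population while published budgets use the total
population (83.2 million for Germany 2022).

Population life-expectancy gains recognise that treating "everyone above
$\tau$ from age $a$" treats mostly older, higher-risk people: for every age
$x \ge a$ a cohort is calibrated to the conditional mean risk above $\tau$
at that age, and its life-expectancy gain is weighted by the number of
qualifying persons at $x$. The total-population gain scales the treated
gain by the treated share, untreated persons contributing zero — hence it
is always the smaller of the two, and both are smaller than the gain of an
individual who starts at $a$ and is followed to 99.

## Synthetic data: what it emulates and what it does not

The pipeline must run end-to-end without the national inputs it was
designed for (cause-of-death life tables and a risk-factor survey), so two
generators provide stand-ins; they are study conditions, not fixtures, and
are themselves tested.

**Mortality.** `synthetic_life_table()` draws the all-cause probability
from a Gompertz–Makeham form $q(x) = \min(1, a + s \, b \, e^{cx})$ with a
per-sex scale $s$, and logistic, mildly age-increasing cause-of-death
fractions. Defaults: $a = 2.2 \times 10^{-3}$, $b = 3 \times 10^{-5}$,
$c = 0.082$, female scale 0.6; CHD fraction asymptotes 0.21 (men) / 0.19
(women) and cerebrovascular 0.10 / 0.105, midpoint age 10, slope 0.06.
Relative to a real national life table the senescent slope is flatter and
young-adult mortality higher. This compression is deliberate: calibrating a
25-year-old cohort to stratum risks above 10% multiplies cardiovascular
probabilities by factors near ten, and with a realistically steep mortality
curve the scaled non-fatal probabilities at the oldest ages would exceed 1
(the calibration design scales probabilities uniformly above the start
age). The chosen defaults keep every default grid cell feasible with
headroom while preserving the structure that matters to the model:
monotone-increasing mortality, a female advantage, rising cause fractions,
and a 40-year-old's combined 10-year risk in the low single digits so that
all three thresholds (7.5/10/15%) are exercisable. Consequently, absolute
outputs under synthetic mortality are internally consistent but not
nationally calibrated — passing tests demonstrate the correctness of the
machinery, not German point estimates.

**Population.** `synthetic_population()` carries a fixed entering cohort
(51% male at age 25) through the life table's survival, giving a female
excess at high ages and an adult total near 62 million.

**Risk.** `risk_distribution()` models the 10-year combined-endpoint risk
per sex and age as log-normal with a log-median rising linearly in age
(slope 0.028 per year, saturating at 85; medians at 40 of 4.0% for men and
2.8% for women; log-sd 0.35), upper-truncated at 1 with closed-form tail
probabilities and conditional means. It is a stand-in for applying a risk
equation to a risk-factor survey: smooth, unimodal, with no risk-factor
structure, cohort effects, or threshold clustering of real populations.

## Numerical choices and degenerate inputs

* Calibration: bisection, absolute risk tolerance $10^{-8}$, bracket
  $[10^{-6}, 10^3]$, hard error if unreachable or if a calibrated
  probability exceeds 1 in an occupied state.
* State propagation: plain matrix recursion; occupancy conservation is
  asserted at $10^{-12}$ per cycle.
* An ICER with non-positive QALY gain is `NA` with a warning, never a
  number; an NNT with non-positive risk reduction is `Inf`; an empty
  treated stratum gives share 0 and an `NA` mean risk; table cells that a
  strict-parity run cannot support are `NA` with a reason code, never 0.
* All randomness (microsimulation, utility draws, bootstrap) is governed
  by explicit integer seeds; repeated runs are bit-identical.

## Problem sizes

The deterministic grid (3 thresholds × 5 start ages, both sexes, with
per-age life-expectancy curves per threshold) runs in a few seconds; the
microsimulation uses 20,000 iterations per arm as its reference size, which
the test suite also exercises (agreement with the expectation within three
Monte-Carlo standard errors) alongside smaller sizes for interval
behaviour.

## Known limitations

The model inherits its source assumptions: no transitions between event
families, a single lifelong relative risk reduction with perfect adherence
and no disutility, direct costs only, no secular mortality trends, no
statin side effects, and truncation at 99 which compresses life-expectancy
gains for young cohorts. The single-scalar probability calibration is one
of several conventions compatible with "calibrated to a 10-year risk"; an
age-varying or hazard-scale calibration would change old-age event loads
and therefore NNT and life-expectancy patterns. Published reference values
can be reproduced in structure (shares, mean risks, budgets) and order of
magnitude, but value-level parity would require the unpublished national
cause-of-death tables.
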