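---
title: "Projecting diabetes prevention from population increases in walking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Projecting diabetes prevention from population increases in walking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(walkdiab)
```

`walkdiab` projects how many type 2 diabetes cases, and how much attributable
health-care spending, a population would avert if defined target groups
walked more each week. This vignette is the package's account of the model,
its assumptions, the tunable parameters, the synthetic data it is exercised
on, and the numerical choices made where conventions had to be fixed.

## The risk engine

Ten-year risk per respondent uses the Weibull survival model in its
proportional-hazards form: cumulative hazard $H(t) = t^{\rho} e^{\eta}$, so

$$\mathrm{risk}(t) = 1 - \exp\!\left(-t^{\rho} e^{\eta}\right),$$

with a sex-specific shape $\rho > 0$ and linear predictor
$\eta = \beta_0 + \sum_j \beta_j (x_j - c_j)$ over self-reported risk factors
(age, sex, BMI, ethnicity, education, immigrant status, prior hypertension,
prior heart disease, household income quintile, smoking). This is the model
family used by population risk tools such as DPoRT. Two conventions had to
be fixed:

* **Parameterization.** "Weibull" admits several equivalent forms
  (accelerated-failure-time with $(\mu, \sigma)$, shape/scale, hazard-based).
  We fix the proportional-hazards form $H(t) = t^{\rho} e^{\eta}$ because it
  is invertible to all the others: a published coefficient set in an AFT
  form with intercept $\mu$ and scale $\sigma$ maps to
  $\rho = 1/\sigma,\ \eta = -\mu/\sigma$, and each slope to
  $\beta_j^{\mathrm{PH}} = -\beta_j^{\mathrm{AFT}}/\sigma$. The coefficient
  schema records a `schema_version` so transcriptions can document the
  transform they applied.
* **Centering.** Coefficients apply to $(x_j - c_j)$, with the centering
  constants $c_j$ part of the configuration. Centering is how such tools are
  adjusted across populations with different baseline risk-factor means; a
  constant of 0 recovers uncentered behaviour.

The shipped coefficient file is a **synthetic example** — plausible effect
directions and a realistic overall risk level, but not an estimate of any
published algorithm (whose values are restricted to appendices or licences
and are consumed here as user configuration).

Eligibility mirrors the two-stage design of population-risk analyses: risk
is computed for all respondents aged 20+ without prior diabetes and with
complete risk-factor data (the share excluded for missingness is logged,
since survey analyses report it); the analysis set is then further
restricted to ages 20–64 and region residency. Records excluded at stage
two still carry a risk, which matters when a user wants province-wide risk
but regional aggregates. Complete-case analysis only; no imputation.

## Activity metrics

Respondents report weekly minutes of active transportation, leisure
activity and other activity (all moderate intensity, 3 MET/min) and how
many of those minutes were vigorous (6 MET/min). Because vigorous minutes
are a subset of the three category totals, moderate minutes are total minus
vigorous — otherwise vigorous time would be double-counted:

$$\mathrm{MET\text{-}min/week} = 3\,( \mathrm{total} - \mathrm{vigorous}) + 6\,\mathrm{vigorous}.$$

Categories follow the survey convention exactly: sedentary (0), somewhat
active (1–449), moderately active (450–899), active (≥ 900 MET-min/week).
Daily step counts from active transportation use the equivalence of
moderate walking to 100 steps/min: steps/day = weekly transport minutes
× 100 / 7. Steps are kept unrounded internally; the reporting helper rounds
to the nearest ten below 150 min/week and to the nearest hundred at 150,
matching how such equivalences are quoted (360 steps at 25 min, 2100 at
150).

**Weighted quartiles.** Low physical activity is defined by quartiles of
weekly MET-minutes. Whether published analyses weight this split is rarely
stated; both are supported and the survey-weighted split is the default
(consistent with every other estimate being weighted). The quantile
convention is the lower weighted quantile of the empirical weighted
distribution (the smallest observed value whose cumulative weight share
reaches 0.25/0.50/0.75), elements at or below a cut point fall in the lower
quartile, and tied values always share a quartile — a tie group is never
split. Quartile assignment is invariant to uniform weight rescaling.

## Scenarios

The anchor effect is a meta-analytic 26% relative risk reduction at 11.25
MET-h/week of activity — 150 min/week of moderate walking. Reductions for
smaller increments are linearized on the natural log scale,
$RR(m) = \exp(\log(1-0.26)\, m/150)$, which makes $RR$ multiplicative in
minutes: $RR(a)RR(b) = RR(a+b)$. Exact RR values are used in computation;
whole-percent reductions (5/10/14/18/26) are display-only, because
propagating rounded effects would introduce avoidable error. Extrapolation
beyond 150 min/week is refused unless explicitly enabled: the anchor says
nothing about the dose–response shape beyond the guideline level.

Target groups: (1) weighted activity quartiles 1–2; (2) under 1000 daily
steps from active transport, zero included, 1000.0 excluded (the group is
"between 0 and 999 steps"); (3) no active transport at all. The
quartile-3–4 exclusion applies in *all* scenarios — it is the shared
coverage rule, not a scenario-1 special case — so the three target sets are
nested (3 ⊆ 2 ⊆ 1), which forces the ordering of projected benefits at any
common increment.

Risks of targeted respondents are multiplied by RR directly (a risk ratio),
because the reduction is applied to the estimated risk, not to the hazard.
A hazard-ratio variant, $\mathrm{risk}' = 1-(1-\mathrm{risk})^{RR}$, is
available behind `mode = "hazard"` for sensitivity analysis; at risks below
15% the two differ by well under a percentage point of risk.

For costing, scenario-adjusted annual incidence scales *every* yearly
increment $F(y)-F(y-1)$ by the member's RR. This is the only choice
consistent with scaling the ten-year risk by RR (the increments still
telescope to $RR \times \mathrm{risk}_{10}$); re-solving the Weibull with a
shifted hazard would instead change the *timing* of cases, which the
risk-ratio formulation does not claim to do.

## Attributable costs

The cost calculator is deterministic expected-value accounting
(spreadsheet-style, no stochastic deaths): the cohort diagnosed in year $d$
contributes, in calendar year $y \ge d$,
$\mathrm{cases}_d \times S(y-d+1) \times c(y-d+1)$, where $c(k)$ is the
sex-specific per-patient excess cost at follow-up year $k$ and
$S(k) = \prod_{j<k}(1-m_j)$ is survival to the start of year $k$. Fixed
conventions, each tested:

* costs accrue to survivors at the *start* of a follow-up year; mortality
  applies between years (so $S(1)=1$ always);
* excess costs are stored for follow-up years 1–8 only; years 9–10 resolve
  to the year-8 value by rule (costing studies follow patients eight
  years);
* accrual is truncated at the 10-year horizon — a cohort diagnosed in year
  10 contributes one follow-up year. Following every cohort a full ten
  years (running past the projection window) is the natural alternative;
  truncation is the default because the projection reports costs *within*
  the window, and the alternative is reachable by raising `horizon_years`
  for the cost stage alone;
* no discounting or inflation adjustment by default (`discount_rate = 0`),
  matching how such projections are reported in constant dollars.

Costs are linear in case counts, nondecreasing in every cost entry and
nonincreasing in every mortality entry; savings are exact
baseline-minus-scenario totals. The shipped schedule is a synthetic
example with the qualitative cost shape (expensive diagnosis year, dip,
rise with duration); real schedules are configuration.

## The synthetic population

The generator emulates a survey cohort of 5,160 records representing
3,857,703 adults aged 20–64, with weighted marginals matching the published
cohort distribution: sex (47.9% male), age bands 20–44/45–64, income
quintiles, BMI bands, weekly activity categories (17.5% sedentary … 42.9%
active), active-transport minute bands (46.2% at 0 min) and daily step
bands. Printed survey tables need not total 100% (missing observations,
rounding); each marginal is rescaled to sum to one, which shifts targets by
at most a few tenths of a point.

Structure beyond the marginals is deliberately minimal:

* **Transport minutes and step bands are one variable.** Since steps/day is
  a strictly increasing function of weekly transport minutes, both band
  systems pin the same minute-scale CDF at their own edges. Merging the two
  edge sets yields refined minute intervals whose probabilities must all be
  non-negative — otherwise the configured pair of maps is impossible and
  generation refuses with an error naming the pair. Minutes are drawn
  uniformly within each refined interval; the open-ended top band is capped
  at 600 min/week (≈ 1.4 h/day of active transport, a realistic upper bound
  for commuters) and the cap must exceed 350 so the ≥5000-step band is
  reachable.
* **Activity categories are consistent with minutes by construction.**
  Categories are allocated by weighted quota with records ordered by
  descending transport minutes, so the respondents who walk most get the
  most active categories and a category's MET range can always accommodate
  the MET-minutes its transport alone implies; leisure/other/vigorous
  minutes are then drawn to land total MET-minutes inside the assigned
  band. A vigorous share of up to 25% of activity time is allowed where the
  MET target permits.
* **Everything else is independent.** Published tables give marginals, not
  a joint distribution; any correlation structure we invented would be
  untestable. Categorical characteristics are assigned by randomized
  weighted quota rather than independent multinomial draws: quotas
  reproduce every configured weighted share up to a single record's weight,
  so calibration holds at any seed and sample size, while assignments
  remain random and independent across characteristics.
* **Weights** are log-normal (sdlog 0.5, a right-skew typical of design
  weights) rescaled to the target population total exactly. Ethnicity,
  education, immigrant status, smoking, hypertension and heart disease have
  no published cohort marginals; their defaults
  (`default_prevalences()`) are free parameters chosen as plausible values
  for a large diverse urban adult population, documented as such, and only
  there to exercise the risk engine.
* A configurable `missing_share` (default 0) blanks one randomly chosen
  risk factor per affected record, mimicking the few-percent item
  non-response that drives complete-case exclusion.

What passing tests on this population do **not** show: behaviour under real
joint risk-factor correlations (age × BMI × activity, income × ethnicity),
complex survey design effects (clustering, stratification, bootstrap
replicate weights), or the accuracy of any particular coefficient set. They
do show that the machinery — weighting, eligibility, risk aggregation,
scenario algebra, cost accounting — is correct, calibrated and
deterministic.

## Numerical choices

* Rounding is half-away-from-zero and confined to the presentation layer
  (`render_table3()`); all stored results are full precision. Rounded delta
  rows can therefore disagree with differences of rounded absolute rows by
  one unit in the last place; a `check_rounding` mode warns when they
  disagree by more.
* Degenerate inputs fail with typed conditions: configuration errors
  (impossible marginals, malformed coefficient or cost files), validation
  errors (out-of-range arguments), degenerate-data errors (empty
  populations, zero total weight).
* Category boundaries are closed exactly as printed: 449 is somewhat
  active, 450 and 899 moderately active, 900 active; a quartile cut point
  belongs to the lower quartile.
* Determinism: the same configuration and seed reproduce byte-identical
  populations and outputs; the generator restores the caller's RNG state.

## Problem sizes used by the test suite

Chosen to make the checks sharp at desk scale: marginal calibration on
5,000 records (quota assignment makes the 2-percentage-point tolerance
conservative); Monte-Carlo verification of the risk engine against
simulated Weibull event times at $n = 10^6$ per parameter pair (ten random
pairs, three-standard-error bands); maximum-likelihood parameter recovery
at $n = 50{,}000$ within 5%; cost-calculator equality against brute-force
enumeration on 20 random instances; full-pipeline identity and ordering
checks on the 5,160-record default cohort.

## Known limitations

No behaviour-change uptake model (scenarios assume full compliance of the
target group); a single log-linear dose–response anchored at one point; no
population growth or demographic change over the horizon; no productivity
or informal-care costs; synthetic defaults stand in for restricted
coefficient sets, cost schedules and microdata, so absolute projections
from the defaults are illustrative, not estimates for any real
jurisdiction.
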