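---
title: "Methods: linked-mortality simulation, weighting, and doubly truncated estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linked-mortality simulation, weighting, and doubly truncated estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mortlink)
```

## The estimation problem

Census-linked death registers contain one record per *death*, never per
survivor, and only for deaths inside a calendar window. A register with
high coverage 1975–2005 observes a person born in 1905 only if they died
between ages 70 and 100 (and the file universe additionally caps ages at
65–100). Occurrence–exposure rates and standard survival tools are
unavailable; naive regression of age at death on covariates is biased
toward zero because both early and late deaths are cut off.

`mortlink` treats this as a doubly truncated likelihood problem. Deaths
follow a Gompertz proportional-hazards law

$$h_i(x) = a\,e^{bx}\,e^{\beta Z_i},$$

so survival is \(S_i(x) = \exp\{-(a e^{\beta Z_i}/b)(e^{bx}-1)\}\). Each
observed death age \(x_i\) carries its own truncation bounds
\(x_i^l \le x_i < x_i^r\), and the likelihood is the product of densities
normalized to the observable window:

$$L(\theta) = \prod_i \frac{f(x_i\mid\theta)}
  {F(x_i^r\mid\theta) - F(x_i^l\mid\theta)}.$$

`fit_gompertz_trunc()` maximizes this over \((\log a, \log b, \beta)\)
(the log scale enforces positivity without constraints) by BFGS followed
by damped Newton polishing; the convergence flag requires a per-record
gradient max-norm below `1e-6`. Standard errors come from the inverse of
the finite-difference observed information of the total log-likelihood.
Initial values: \(b_0 = 0.1\); \(a_0 = b_0 e^{-b_0 \bar x}\), which
places the Gompertz modal age at the mean observed death age;
\(\beta_0 = 0\).

### Truncation-window convention

Windows derive per birth cohort from the register's high-coverage years
\([w_1, w_2]\) and the file's age universe:
\(x^l = \max(65,\; w_1 - \text{birth year})\) and
\(x^r = \min(w_2 + 1 - \text{birth year},\; 100)\), half-open
\([x^l, x^r)\). The cap at 100 mirrors the weighting universe (deaths at
65–100): without it the likelihood would claim ages the file never
contains, slightly biasing the slope for the oldest cohorts. Setting
`max_age = Inf` restores the uncapped convention.

Integer register ages are converted to continuous ages by the midpoint
convention \(x = \text{age} + 0.5\) (switchable to uniform jitter, or
`"none"` when ages are already continuous). The denominator is computed
in log space as
\(\log S(x^l) + \log(-\text{expm1}(\log S(x^r) - \log S(x^l)))\), which
is stable both for tiny windows and for parameter values visited by the
optimizer where the window mass underflows; the optimizer wrapper maps
non-finite trial values to a large penalty rather than aborting.

### The naive comparison and attenuation

`ols_age_at_death()` fits
\(\text{age at death}_i = \beta_0 + \gamma_t + \beta Z_i + \epsilon_i\)
with birth-year fixed effects \(\gamma_t\) — essential because earlier
cohorts are mechanically observed dying older. The test suite
demonstrates on every seeded replicate that the truncated-sample OLS
coefficient is strictly smaller in magnitude than the all-deaths OLS
coefficient, and that the truncated MLE hazard ratio is closer to truth
than the OLS-implied one (`ols_implied_hr()` uses
\(\mathrm{HR} \approx e^{-b\,\beta_{\text{years}}}\), the first-order
Gompertz shift identity).

### Rate and hazard-ratio utilities

`extinct_cohort_rates()` reconstructs survivors from deaths alone:
\(N(a) = \sum_{a' \ge a} D(a') + \text{tail}\), with
\(q(a) = D(a)/N(a)\) pinned by tests against the closed-form Gompertz
conditional probability, and \(m(a) = D(a)/(N(a) - D(a)/2)\) reported as
the central-rate analogue (informational; only \(q\) is asserted). The
`tail_completion` argument stands in for external completion of
non-extinct cohorts; parsing real exposure files is out of scope.

`annualize_hr()` converts a two-group contrast into a per-year hazard
ratio, \((hr_{\text{high}}/hr_{\text{low}})^{1/\text{gap}}\).
`hr_to_e_gain()` converts a hazard ratio into a difference in remaining
life expectancy at age 35 by quadrature of
\(e(35) = \int_0^\infty e^{-\mathrm{hr}\,H(35, 35+t)}\,dt\) under the
default \(a = 3.34\times10^{-5}, b = 0.1\). The hazard is scaled above
the evaluation age only; published conversions of this kind do not fully
specify cohort composition or whether fitted parameters enter, so the
package documents this single convention and does not treat external
e(35) figures as targets.

## The synthetic world

The generator's defaults state one world, used by every test:

* Birth cohorts 1900–1920, birth month uniform; census day April 1, 1940
  with completed-years ages (a person born in April has not had their
  1940 birthday).
* Race White/Black/Other at 89.9/9.6/0.5% — the 1940 male census
  distribution; sex 50/50; 49 birth-state levels (48 contiguous states +
  DC, uniform by default) plus "abroad" at 7%, of whom 85% arrived before
  census day (only those can appear in the census file).
* Education 0–21 years with category masses ≈ 65% below high-school
  completion, 27% high school/some college, 4% bachelor's, 2% advanced.
* Mortality: Gompertz \(a = 3.34\times10^{-5}, b = 0.1\) — the standard
  conversion parameters for these cohorts — with a default education
  effect of \(e^\beta = 0.96\) per schooling year, sampled by inverse
  CDF: \(T = \tfrac1b \log(1 + bE/(a e^{\beta Z}))\), \(E\sim\)Exp(1).
* Registers: DMF-like (window 1975–2005; no sex, birthplace or father's
  surname) and Numident-like (1988–2005; all three), inclusion 0.96
  inside the window. Coverage outside the window "drops dramatically" in
  the real systems without a published figure; `p_out = 0.05` is a free
  configuration parameter.
* Noise: name typos resample to fresh unused keys (unmatchable by
  construction), nickname swaps are recoverable through the equivalence
  table, full-key collisions copy another decedent's keys (the
  false-match channel), and register birth years are misstated by
  −2…+2 with 12% total mass. Middle initials are missing for 30% of
  register and 70% of census records.

Dates are held at month resolution; the months-lived encoding makes the
register's month-arithmetic age equal \(\lfloor T\rfloor\) exactly when
noise is off, so age misstatement is the only discretization channel.
Names are opaque pool keys: linkage behavior depends only on the
equality/collision structure, which the pools control exactly — there is
no phonetics, household structure, sub-state geography or migration. A
green test therefore establishes the *logic* of the chain (key handling,
exclusion rules, weighting arithmetic, likelihood correctness), not
robustness to real transcription behavior.

Every operation draws from a labeled substream of one global seed
(`with_substream()`), so stages are independently reproducible and rerun
byte-identically.

## Linkage conventions

The match requires exact equality of standardized first and last keys
(plus birth state for Numident-like registers) with implied-1940-age
bands of 0, 1, 2 years. The *strict* conservative reading is
implemented: a record with two same-key candidates within the maximum
band is excluded even when one candidate is exactly right — false-match
minimization is prioritized over match rate, which collapses the banded
iteration into a single unique-in-both-directions pass with the band
recorded per pair.

Women: marital status on census day decides the rule — ever-married
women match on their (married) census surname; never-married women match
their census surname against the register's father's-surname field.
Widowed and divorced women are treated as ever-married by default (the
source procedure is silent; `widowed_use_father` switches this). Women
who (re)marry after census day carry an unmatchable surname and are an
accepted recall loss; the tests verify female recall sits below male
recall while precision stays at 1 absent collisions. Middle initials are
never a match field; among matched pairs with initials on both sides,
the disagreement rate is an upper bound on the false-match rate, and the
tests verify the bound under 10% injected false matches.

"Standardized" is implemented as trim/lower-case plus an explicit
nickname-equivalence table supplied as data; no phonetic algorithm is
assumed since the source does not name one.

## Weighting conventions

Cell weights are the ratio of reference to linked deaths in
(death year, age, sex, race, birth state) cells over the universe:
native-born, died 65–100, death year inside the register window. Race is
collapsed to White/Black/Other before weighting. Fallbacks, in order:
pre-cutoff deaths (birth state unavailable in the reference data before
1979) take the cutoff-year weight of their age/race/birthplace stratum
(sex deliberately excluded, as the source sentence reads; switchable);
the foreign-born take the mean weight of already-weighted native
decedents sharing year, age, race and sex; remaining records take the
same-stratum native mean; the final fallback is weight 1. The donor pool
is "already-weighted native decedents" — including pre-cutoff-weighted
ones — because the rule speaks of decedents' weights, not Eq.-1 cells.

Raking is classical IPF over year, age, sex, race and birthplace
margins, tolerance \(10^{-6}\) relative, at most 100 cycles, then
trimming clamps to \([1, 5\times\text{mean unadjusted weight}]\) with
the ceiling anchored once to the pre-raking weights; rake and trim
alternate up to 10 rounds. Margins are restricted to the register's
attainable universe (male-only for the DMF-like file, post-cutoff years,
native-born). Non-convergence is a reported state, not an error: with a
floor of 1, exact calibration is infeasible whenever the unconstrained
IPF solution dips below 1 (fully-matched singleton cells), which happens
on noisy sparse runs; diagnostics expose the rounds, per-margin errors,
weighted-coverage ratio, and the share of weight-1 fallback records.

Scale matters for the fallback rules: they presuppose the cell density
of national data. At the bundled 5,000-person demo scale, pre-1979 and
donor strata are mostly empty and the weight-1 share is several percent;
at a ~100,000-person world it falls below 1%, which is where the suite
asserts it. Variance estimation for weighted estimators and any
Hispanic-origin adjustment are out of scope.

## Pipeline and interchange

All interchange is headered CSV (flat person-level files); the public
layouts are exactly `histid, byear, bmonth, dyear, dmonth, death_age,
weight` for the DMF-like file, plus `sex, race_first, race_last, bpl,
socstate, age_first_application, zip_residence` for the Numident-like
file (unmodelled fields emitted empty). The emitted person-level files
are restricted to in-window deaths at ages 65–100 — the weightable
universe — so every published record carries a meaningful weight. The
configuration is a single JSON document (JSON rather than YAML because
the target environment ships no YAML parser for R; the schema is
otherwise as designed), hashed into the run manifest together with the
seed and per-stage row counts. Stages resume from on-disk intermediates
and rerun byte-identically under a fixed seed.

## Known limitations

* The generator has no infant/child mortality hump and no
  period shocks; the Gompertz law holds exactly, so goodness-of-fit of
  the *model family* is untested by construction.
* Name noise is structural, not lexical; linkage error rates do not
  transfer to real string data.
* The rake-trim fixed point with a floor of 1 need not exist on sparse
  noisy samples (reported, see above).
* External reference figures from restricted real data (match rates,
  coverage percentages, published hazard ratios and e(35) columns) are
  structural analogues only; no test asserts them numerically.
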