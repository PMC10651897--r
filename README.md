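# mortlink

Old-age mortality research increasingly relies on linking historical
census microdata to administrative death registers. The resulting files
are "deaths without denominators": every record is a death, observed only
inside a calendar window (a *doubly truncated* sample), linked by noisy
name keys, and selectively covered by period, age, sex, race and
birthplace. `mortlink` rebuilds that entire computational chain as a
tested, reusable R package:

1. **Synthetic data** — a 1940-style census-day population (birth cohorts
   1900–1920, sex, race, birth state, education, marital status, opaque
   name keys) with mortality simulated from a Gompertz
   proportional-hazards law, plus DMF-like (1975–2005, no sex/birthplace)
   and Numident-like (1988–2005, with sex, birthplace and father's
   surname) death registers, a complete vital-statistics-style reference
   tabulation, and configurable linkage noise.
2. **Record linkage** — the conservative deterministic (ABE-style) match:
   exact agreement on standardized first/last name keys (plus birth state
   when available), age bands of 0/1/2 years, and the rule that any record
   with a second same-key candidate is excluded entirely. Women are
   linked with maiden-name handling: ever-married women by their married
   surname, never-married women via the register's father's-surname
   field. Evaluation reports precision/recall against simulation truth,
   representativeness tables, and the middle-initial diagnostic (initials
   are never a match field, so their disagreement rate bounds the
   false-match rate from above).
3. **Weighting** — post-stratification weights
   W(y,a,s,r,b) = deaths in the reference cell / deaths in the linked
   cell, fallback rules for pre-cutoff years, the foreign-born and
   unweightable strata, then iterative raking (IPF) to population
   marginals with trimming to [1, 5 × mean unadjusted weight].
4. **Mortality models** — the doubly truncated Gompertz
   proportional-hazards likelihood

   L(θ) = ∏ᵢ f(xᵢ | θ) / (F(xᵢʳ | θ) − F(xᵢˡ | θ)),
   hᵢ(x) = a e^{bx} e^{βZᵢ},

   maximized over (log a, log b, β) with observed-information standard
   errors; naive OLS on age at death with cohort fixed effects (which is
   *attenuated* under truncation — demonstrated, not just asserted);
   extinct-cohort age-specific mortality rates q(a) = D(a)/N(a) with
   N(a) = Σ_{a′≥a} D(a′); and hazard-ratio utilities (annualization,
   conversion to remaining-life-expectancy differences at age 35).
5. **Pipeline** — a config-driven `generate → link → weight → estimate →
   report` runner with CSV interchange, per-stage resume, a JSON run
   manifest, and a CLI (`inst/cli/mortlink.R`).

## Worked example

Generate a 42,000-person world, link men to a DMF-like register, and fit
the truncated Gompertz model to the linked deaths:

```r
library(mortlink)
spec <- population_spec(cohort_sizes = 2000L, seed = 99L)
pop  <- generate_population(spec)
pop  <- simulate_mortality(pop, gompertz_params(a = 3.34e-5, b = 0.1),
                           effect = c(education_years = log(0.96)),
                           seed = 99L)
census <- build_census_file(pop)
nn  <- make_nickname_table(2000L)
reg <- build_death_register(pop, register_spec("dmf-like"),
                            noise_spec(), nn, seed = 99L)
res <- abe_conservative_match(census[sex == "male"], reg$register,
                              nicknames = nn)
evaluate_linkage(res, reg$truth, census[sex == "male"],
                 reg$register)$summary
#> match_rate  precision     recall
#>      0.663      1.000      0.899

linked <- merge(res$pairs, reg$register, by = "row_id")
linked <- merge(linked, census[, .(histid, education_years)],
                by = "histid")
linked <- linked[dyear >= 1975 & dyear <= 2005 &
                   death_age >= 65 & death_age <= 100]
samp <- truncated_sample(linked, window = c(1975, 2005),
                         covariates = "education_years")
fit_gompertz_trunc(samp)
#> Truncated Gompertz PH fit (n = 12915)
#>   a = 4.43e-05 (log-scale SE 0.12)
#>   b = 0.09692 (log-scale SE 0.0155)
#>   education_years: beta = -0.0431, HR = 0.9578 (SE 0.0030)
#>   log-likelihood: -41996.48
```

The match rate of 66% reflects the conservative exclusion of every
ambiguous key at this small name-pool size; precision is 1.0 because
ambiguity is discarded rather than guessed. The fitted hazard ratio per
year of schooling (0.958, truth 0.96) is recovered despite the sample
containing only deaths at ages 65–100 inside 1975–2005 — the situation
in which OLS on age at death is biased toward zero. Converting:

```r
hr_to_e_gain(0.9578)           # 0.412 years of e(35) per schooling year
annualize_hr(0.748, 1.178, 8)  # 0.9448 per-year HR from a group contrast
```

The full pipeline, end to end:

```r
run_pipeline(default_config(seed = 1, n_per_cohort = 1000L), "out/")
```

or from the shell:

```sh
Rscript inst/cli/mortlink.R run-all --seed 1 --outdir out
```

## Documentation

The methods vignette (`vignettes/linked-mortality-methods.Rmd`) describes
the models, the weighting and linkage conventions, what the synthetic
generator does and does not emulate, and the numerical choices.
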