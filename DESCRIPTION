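Package: mortlink
Title: Simulated Census-Mortality Linkage, Post-Stratification Weights, and
    Truncated Gompertz Estimation
Version: 0.1.0
Authors@R:
    person("Morten", "Linke", email = "mortlink@example.org",
           role = c("aut", "cre"))
Description: A reproducible pipeline for studying old-age mortality from
    linked census and death-register microdata when only deaths -- not
    survivors -- are observed.  Generates a synthetic 1940-style census-day
    population with Gompertz proportional-hazards mortality, emits
    DMF-like and Numident-like death registers with realistic linkage
    noise, links them back to the census with a conservative deterministic
    (exact-key, small age band) algorithm including maiden-name handling
    for women, constructs NCHS-style post-stratification weights with
    fallback rules, raking ratio calibration and weight trimming, and
    estimates mortality differentials by maximum likelihood under doubly
    truncated death observation, alongside extinct-cohort age-specific
    rates and naive OLS comparisons that demonstrate attenuation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
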