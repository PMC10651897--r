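#' Specification of the simulated census-day population
#'
#' Describes the world the generator draws: birth cohorts, cohort sizes,
#' categorical covariate distributions, name-key pool sizes and the global
#' seed. Defaults encode the stated study conditions: cohorts 1900-1920, a
#' White/Black/Other race split of 89.9/9.6/0.5 percent, birth states over
#' the 48 contiguous states + DC plus an "abroad" level, integer education
#' 0-21 years, and four marital-status levels.
#'
#' @param cohort_range inclusive birth-year interval, e.g. `c(1900, 1920)`.
#' @param cohort_sizes persons per birth year; recycled across cohorts.
#' @param p_sex named probabilities over `c("male", "female")`.
#' @param p_race named probabilities over `c("White", "Black", "Other")`.
#' @param p_bstate named probabilities over the 49 state levels plus
#'   `"abroad"`; default splits `1 - p_abroad` uniformly over states.
#' @param p_abroad share foreign-born used to build the default `p_bstate`.
#' @param p_education probabilities over integer years 0:21.
#' @param p_marital named probabilities over
#'   `c("never", "married", "widowed", "divorced")` (status on census day).
#' @param n_first,n_last sizes of the first-name and surname key pools.
#' @param p_immigrated_before_census probability a foreign-born person
#'   arrived before census day (only those appear in the census file).
#' @param p_marry_after_census probability a woman (re)marries after census
#'   day and carries a new surname on her death record.
#' @param seed integer global seed.
#' @return object of class `population_spec`.
#' @export
population_spec <- function(cohort_range = c(1900L, 1920L),
                            cohort_sizes = 1000L,
                            p_sex = c(male = 0.5, female = 0.5),
                            p_race = c(White = 0.899, Black = 0.096,
                                       Other = 0.005),
                            p_bstate = NULL,
                            p_abroad = 0.07,
                            p_education = default_education_probs(),
                            p_marital = c(never = 0.32, married = 0.60,
                                          widowed = 0.05, divorced = 0.03),
                            n_first = 2000L, n_last = 4000L,
                            p_immigrated_before_census = 0.85,
                            p_marry_after_census = 0.20,
                            seed = 1L) {
  if (length(cohort_range) != 2L || cohort_range[1] > cohort_range[2]) {
    config_error("cohort_range", "must be an ordered year interval")
  }
  cohorts <- seq.int(cohort_range[1], cohort_range[2])
  sizes <- rep_len(as.integer(cohort_sizes), length(cohorts))
  if (any(sizes <= 0)) config_error("cohort_sizes", "must all be > 0")
  if (is.null(p_bstate)) {
    st <- state_regions()$bstate
    p_bstate <- c(setNames(rep((1 - p_abroad) / length(st), length(st)), st),
                  abroad = p_abroad)
  }
  check_prob_vec(p_sex, "p_sex")
  check_prob_vec(p_race, "p_race")
  check_prob_vec(p_bstate, "p_bstate")
  check_prob_vec(p_education, "p_education")
  check_prob_vec(p_marital, "p_marital")
  if (length(p_education) != 22L) {
    config_error("p_education", "must have 22 entries (years 0..21)")
  }
  if (n_first < 1L || n_last < 1L) {
    config_error("name pools", "must be non-empty")
  }
  for (nm in c("p_immigrated_before_census", "p_marry_after_census")) {
    v <- get(nm)
    if (!is.finite(v) || v < 0 || v > 1) config_error(nm, "must be in [0,1]")
  }
  structure(list(
    cohorts = cohorts, cohort_sizes = sizes,
    p_sex = p_sex, p_race = p_race, p_bstate = p_bstate,
    p_education = p_education, p_marital = p_marital,
    n_first = as.integer(n_first), n_last = as.integer(n_last),
    p_immigrated_before_census = p_immigrated_before_census,
    p_marry_after_census = p_marry_after_census,
    seed = as.integer(seed)
  ), class = "population_spec")
}

#' Default education-years distribution
#'
#' A discrete distribution over 0:21 whose category masses roughly follow
#' the 1940 male population: about 65% below 12 completed years, 27% with
#' high school or some college (12-15), 4% with 16 (bachelor's) and 2%
#' with 17+ (advanced).
#'
#' @return numeric vector of length 22 summing to 1.
#' @export
default_education_probs <- function() {
  w <- c(
    0.020, 0.015, 0.020, 0.030, 0.045, 0.055, 0.070, 0.110, 0.200, 0.045,
    0.035, 0.030,                         # years 0-11: ~0.675
    0.170, 0.020, 0.030, 0.045,           # 12-15: ~0.265
    0.041,                                # 16
    0.010, 0.005, 0.002, 0.001, 0.001     # 17-21: ~0.019
  )
  w / sum(w)
}

#' Generate the census-day population
#'
#' Draws one row per simulated person with identity keys, demographic
#' covariates and name keys. Surname logic: every person carries a family
#' surname (the father's). Men and never-married women report it in the
#' census; ever-married women report a married surname. Women flagged as
#' marrying after census day carry yet another surname on their death
#' record, which is what breaks own-surname linkage for them.
#'
#' @param spec a [population_spec()].
#' @return data.table, one row per person (no death information yet).
#' @export
generate_population <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  n <- sum(spec$cohort_sizes)
  first_pool <- sprintf("f%05d", seq_len(spec$n_first))
  last_pool <- sprintf("l%05d", seq_len(spec$n_last))
  with_substream(spec$seed, "population", {
    pop <- data.table(
      histid = sprintf("P%08d", seq_len(n)),
      byear = rep(spec$cohorts, spec$cohort_sizes),
      bmonth = sample.int(12L, n, replace = TRUE),
      sex = sample(names(spec$p_sex), n, TRUE, prob = spec$p_sex),
      race = sample(names(spec$p_race), n, TRUE, prob = spec$p_race),
      bstate = sample(names(spec$p_bstate), n, TRUE, prob = spec$p_bstate),
      education_years = sample(0:21, n, TRUE, prob = spec$p_education),
      marital_status = sample(names(spec$p_marital), n, TRUE,
                              prob = spec$p_marital),
      first_key = sample(first_pool, n, TRUE),
      family_key = sample(last_pool, n, TRUE),
      middle_initial = sample(LETTERS, n, TRUE)
    )
    ever_married_woman <- pop$sex == "female" &
      pop$marital_status != "never"
    # census surname: family name unless an ever-married woman
    pop[, last_key := family_key]
    pop[ever_married_woman,
        last_key := sample(last_pool, sum(ever_married_woman), TRUE)]
    pop[, father_last_key := family_key]
    pop[, marry_after_census := sex == "female" &
          runif(n) < spec$p_marry_after_census]
    pop[, register_last_key := last_key]
    pop[marry_after_census == TRUE,
        register_last_key := sample(last_pool, sum(marry_after_census), TRUE)]
    pop[, immigrated_before_census := bstate != "abroad" |
          runif(n) < spec$p_immigrated_before_census]
    pop[]
  })
}

#' Simulate Gompertz proportional-hazards mortality for a population
#'
#' Draws each person's exact death age from the proportional-hazards
#' Gompertz law by inverse-CDF sampling and derives the month-resolution
#' death date from the birth date. The continuous truth
#' (`true_death_age`) is retained alongside the integer register view.
#'
#' @param pop population table from [generate_population()].
#' @param params [gompertz_params()] baseline hazard.
#' @param effect named numeric vector of log hazard ratios per unit of the
#'   named covariate columns (e.g. `c(education_years = log(0.96))`); may
#'   be `NULL` for no covariate effect.
#' @param seed substream seed; defaults to hashing the population size.
#' @return `pop` with columns `true_death_age`, `true_dyear`, `true_dmonth`.
#' @export
simulate_mortality <- function(pop, params, effect = NULL, seed = 1L) {
  stopifnot(inherits(params, "gompertz_params"))
  pop <- copy(as.data.table(pop))
  bz <- linear_predictor(pop, effect)
  with_substream(seed, "mortality", {
    t_death <- rgompertz(nrow(pop), params, bz)
    # months lived, so register month arithmetic recovers floor(T) exactly
    m <- month_index(pop$byear, pop$bmonth) + as.integer(floor(12 * t_death))
    pop[, true_death_age := t_death]
    pop[, true_dyear := m %/% 12L]
    pop[, true_dmonth := (m %% 12L) + 1L]
    pop[]
  })
}

# beta'Z from named effect vector over columns of dt
linear_predictor <- function(dt, effect) {
  if (is.null(effect) || length(effect) == 0L) return(0)
  miss <- setdiff(names(effect), names(dt))
  if (length(miss)) {
    config_error("effect", paste("names absent from table:",
                                 paste(miss, collapse = ", ")))
  }
  if (any(!is.finite(effect))) config_error("effect", "must be finite")
  z <- as.matrix(dt[, names(effect), with = FALSE])
  drop(z %*% effect)
}

#' Build the census-day file
#'
#' Keeps exactly the persons alive on census day (and, for the
#' foreign-born, present in the country by then), with age recorded in
#' completed years as of census day. The file carries histid and all
#' covariates but no death information.
#'
#' @param pop population with simulated mortality.
#' @param census_day `c(year, month)`; the canonical day is April 1, so a
#'   person born in the census month has not yet had their birthday.
#' @return data.table census file.
#' @export
build_census_file <- function(pop, census_day = c(1940L, 4L)) {
  pop <- as.data.table(pop)
  if (!"true_dyear" %in% names(pop)) {
    stop("population has no simulated mortality; run simulate_mortality()",
         call. = FALSE)
  }
  cy <- census_day[1]; cm <- census_day[2]
  if (any(pop$byear * 12L + pop$bmonth > cy * 12L + cm)) {
    stop("census day precedes some birth dates", call. = FALSE)
  }
  census_idx <- month_index(cy, cm)
  alive <- month_index(pop$true_dyear, pop$true_dmonth) >= census_idx
  cen <- pop[alive & immigrated_before_census == TRUE]
  cen[, census_age := cy - byear - as.integer(bmonth >= cm)]
  drop <- intersect(c("true_death_age", "true_dyear", "true_dmonth",
                      "register_last_key", "marry_after_census"),
                    names(cen))
  cen[, (drop) := NULL]
  cen[]
}

#' Death-register specification
#'
#' @param kind `"numident-like"` (has sex, birthplace, father's surname;
#'   high coverage 1988-2005) or `"dmf-like"` (neither sex nor birthplace;
#'   high coverage 1975-2005).
#' @param window inclusive calendar-year interval of high coverage.
#' @param p_in,p_out inclusion probability for deaths inside / outside the
#'   window; must satisfy `0 <= p_out < p_in <= 1`.
#' @return object of class `register_spec`.
#' @export
register_spec <- function(kind = c("numident-like", "dmf-like"),
                          window = NULL, p_in = 0.96, p_out = 0.05) {
  kind <- match.arg(kind)
  if (is.null(window)) {
    window <- if (kind == "dmf-like") c(1975L, 2005L) else c(1988L, 2005L)
  }
  if (length(window) != 2L || window[1] > window[2]) {
    config_error("window", "must be an ordered year interval")
  }
  if (!(p_out >= 0 && p_out < p_in && p_in <= 1)) {
    config_error("p_in/p_out", "must satisfy 0 <= p_out < p_in <= 1")
  }
  structure(list(kind = kind, window = as.integer(window),
                 p_in = p_in, p_out = p_out),
            class = "register_spec")
}

#' Linkage-noise specification
#'
#' All rates in `[0, 1]`. `age_misstatement_dist` is a distribution over
#' birth-year shifts -2..+2 applied to the register's birth year.
#' `name_typo_rate` resamples a key to a fresh unused key (an unmatchable
#' error); `nickname_swap_rate` replaces a first-name key by its nickname
#' variant (recoverable by standardization); `duplicate_key_rate` copies
#' another decedent's full key set (a collision, the source of false
#' matches).
#'
#' @param name_typo_rate,nickname_swap_rate,duplicate_key_rate rates.
#' @param age_misstatement_dist named probabilities over `-2:2`.
#' @param mi_missing_register,mi_missing_census probability the middle
#'   initial is missing on each source.
#' @return object of class `noise_spec`.
#' @export
noise_spec <- function(name_typo_rate = 0.05,
                       nickname_swap_rate = 0.10,
                       duplicate_key_rate = 0.002,
                       age_misstatement_dist = c(`-2` = 0.01, `-1` = 0.05,
                                                 `0` = 0.88, `1` = 0.05,
                                                 `2` = 0.01),
                       mi_missing_register = 0.3,
                       mi_missing_census = 0.7) {
  for (nm in c("name_typo_rate", "nickname_swap_rate", "duplicate_key_rate",
               "mi_missing_register", "mi_missing_census")) {
    v <- get(nm)
    if (!is.finite(v) || v < 0 || v > 1) config_error(nm, "must be in [0,1]")
  }
  check_prob_vec(age_misstatement_dist, "age_misstatement_dist")
  if (!identical(names(age_misstatement_dist),
                 as.character(-2:2))) {
    config_error("age_misstatement_dist", "must be named over -2..2")
  }
  structure(list(name_typo_rate = name_typo_rate,
                 nickname_swap_rate = nickname_swap_rate,
                 duplicate_key_rate = duplicate_key_rate,
                 age_misstatement_dist = age_misstatement_dist,
                 mi_missing_register = mi_missing_register,
                 mi_missing_census = mi_missing_census),
            class = "noise_spec")
}

#' Zero-noise specification (convenience for tests and oracles)
#' @export
noise_none <- function() {
  noise_spec(name_typo_rate = 0, nickname_swap_rate = 0,
             duplicate_key_rate = 0,
             age_misstatement_dist = c(`-2` = 0, `-1` = 0, `0` = 1,
                                       `1` = 0, `2` = 0),
             mi_missing_register = 0, mi_missing_census = 0)
}

#' Nickname-equivalence table for the first-name pool
#'
#' A fraction of pool keys get a variant key (`<key>n`) that standardizes
#' back to the canonical key; used by both the register noise process and
#' [standardize_name()].
#'
#' @param n_first first-name pool size.
#' @param frac fraction of keys with a nickname variant.
#' @return data.table with columns `variant`, `canonical`.
#' @export
make_nickname_table <- function(n_first = 2000L, frac = 0.3) {
  k <- sprintf("f%05d", seq_len(max(1L, round(n_first * frac))))
  data.table(variant = paste0(k, "n"), canonical = k)
}

#' Build a death register from the simulated population
#'
#' Every decedent enters independently with probability `p_in` if the death
#' year lies in the high-coverage window, else `p_out`. Emitted fields
#' depend on the register kind; name keys and the register birth year are
#' perturbed per the noise spec. The register carries no histid; the truth
#' map (`row_id` to `histid`) is returned separately and is for evaluation
#' only.
#'
#' @param pop population with simulated mortality.
#' @param spec [register_spec()].
#' @param noise [noise_spec()].
#' @param nicknames nickname table from [make_nickname_table()] (used for
#'   nickname swaps); `NULL` disables swaps even if the rate is positive.
#' @param seed substream seed.
#' @return list with `register` (data.table) and `truth` (data.table
#'   `row_id`, `histid`).
#' @export
build_death_register <- function(pop, spec, noise = noise_none(),
                                 nicknames = NULL, seed = 1L) {
  stopifnot(inherits(spec, "register_spec"), inherits(noise, "noise_spec"))
  pop <- as.data.table(pop)
  label <- paste0("register-", spec$kind)
  with_substream(seed, label, {
    in_win <- pop$true_dyear >= spec$window[1] &
      pop$true_dyear <= spec$window[2]
    keep <- runif(nrow(pop)) < ifelse(in_win, spec$p_in, spec$p_out)
    reg <- pop[keep, .(
      histid, byear, bmonth,
      dyear = true_dyear, dmonth = true_dmonth,
      sex, bstate, first_key,
      last_key = register_last_key,
      father_last_key, middle_initial
    )]
    n <- nrow(reg)
    reg[, row_id := sprintf("R%08d", seq_len(n))]
    truth <- reg[, .(row_id, histid)]
    reg[, histid := NULL]

    # birth-year misstatement shifts the register's implied ages
    shift <- sample(-2:2, n, TRUE, prob = noise$age_misstatement_dist)
    reg[, byear := byear + shift]
    reg[, death_age := completed_years(month_index(byear, bmonth),
                                       month_index(dyear, dmonth))]

    # nickname swap: recoverable through standardization
    if (!is.null(nicknames) && noise$nickname_swap_rate > 0) {
      swap <- runif(n) < noise$nickname_swap_rate
      idx <- match(reg$first_key, nicknames$canonical)
      doit <- swap & !is.na(idx)
      reg[doit, first_key := nicknames$variant[idx[doit]]]
    }
    # typo: fresh unused key, guaranteed unmatchable
    for (col in c("first_key", "last_key")) {
      typo <- runif(n) < noise$name_typo_rate
      if (any(typo)) {
        reg[typo, (col) := paste0(reg[[col]][typo], "#", which(typo))]
      }
    }
    # collision: copy another decedent's full key set
    if (noise$duplicate_key_rate > 0 && n > 1L) {
      dup <- which(runif(n) < noise$duplicate_key_rate)
      if (length(dup)) {
        src <- sapply(dup, function(i) {
          j <- sample.int(n, 1L)
          if (j == i) j <- (i %% n) + 1L
          j
        })
        reg[dup, c("first_key", "last_key", "father_last_key", "bstate") :=
              reg[src, .(first_key, last_key, father_last_key, bstate)]]
      }
    }
    miss <- runif(n) < noise$mi_missing_register
    reg[miss, middle_initial := NA_character_]

    if (spec$kind == "dmf-like") {
      reg[, c("sex", "bstate", "father_last_key") := NULL]
    }
    setcolorder(reg, "row_id")
    list(register = reg[], truth = truth)
  })
}

#' Complete reference tabulation of deaths (vital-statistics analogue)
#'
#' Tabulates the population's true deaths by the requested cell dimensions
#' over a span of death years, emulating a complete national tabulation.
#' Optionally suppresses birth state before a cutoff year (collapsing those
#' cells) and inflates foreign-born cells by an entrant share, emulating
#' post-census immigrant deaths present in national data but impossible in
#' the census-linked sample.
#'
#' @param pop population with simulated mortality.
#' @param dims subset of `c("dyear", "death_age", "sex", "race", "bstate")`.
#' @param years inclusive death-year interval to cover.
#' @param suppress_bstate_before year before which `bstate` is recorded as
#'   NA (cells collapsed); `NULL` for never.
#' @param entrant_inflation nonnegative share added to foreign-born cells.
#' @return data.table with the dims plus `n_deaths`.
#' @export
build_reference_totals <- function(pop,
                                   dims = c("dyear", "death_age", "sex",
                                            "race", "bstate"),
                                   years,
                                   suppress_bstate_before = NULL,
                                   entrant_inflation = 0) {
  allowed <- c("dyear", "death_age", "sex", "race", "bstate")
  if (!all(dims %in% allowed)) {
    config_error("dims", paste("must be a subset of",
                               paste(allowed, collapse = ", ")))
  }
  pop <- as.data.table(pop)
  d <- pop[true_dyear >= years[1] & true_dyear <= years[2],
           .(dyear = true_dyear,
             death_age = floor(true_death_age),
             sex, race, bstate)]
  if (!is.null(suppress_bstate_before) && "bstate" %in% dims) {
    d[dyear < suppress_bstate_before, bstate := NA_character_]
  }
  tot <- d[, .(n_deaths = .N), by = dims]
  if (entrant_inflation > 0 && "bstate" %in% dims) {
    tot[bstate == "abroad",
        n_deaths := as.integer(round(n_deaths * (1 + entrant_inflation)))]
  }
  setorderv(tot, dims)
  tot[]
}
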