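# Shared fixtures and independent oracles for the test suite.

std_params <- function() gompertz_params(a = 3.34e-5, b = 0.1)

# closed-form Gompertz survival, written independently of the package path
oracle_surv <- function(x, a, b, bz = 0) {
  exp(-(a * exp(bz) / b) * (exp(b * x) - 1))
}
oracle_cdf <- function(x, a, b, bz = 0) 1 - oracle_surv(x, a, b, bz)

# naive per-record truncated log-likelihood (direct CDF calls, plain loop)
oracle_trunc_loglik <- function(theta, x, x_l, x_r, Z = NULL) {
  a <- exp(theta[1]); b <- exp(theta[2])
  total <- 0
  for (i in seq_along(x)) {
    bz <- if (is.null(Z)) 0 else sum(Z[i, ] * theta[-(1:2)])
    f <- a * exp(b * x[i] + bz) * oracle_surv(x[i], a, b, bz)
    mass <- oracle_cdf(x_r[i], a, b, bz) - oracle_cdf(x_l[i], a, b, bz)
    total <- total + log(f) - log(mass)
  }
  total
}

# exponential integral E1 via its own defining integral
oracle_E1 <- function(c) {
  stats::integrate(function(u) exp(-u) / u, c, Inf, rel.tol = 1e-12)$value
}

# brute-force IPF fixed point on an r x c table of weights
oracle_ipf_2way <- function(w, rows, cols, row_targets, col_targets,
                            iters = 10000) {
  for (k in seq_len(iters)) {
    rt <- tapply(w, rows, sum)
    w <- w * (row_targets / rt)[rows]
    ct <- tapply(w, cols, sum)
    w <- w * (col_targets / ct)[cols]
  }
  as.numeric(w)
}

binom_3sd <- function(p, n) 3 * sqrt(p * (1 - p) / n)

# small population with mortality simulated under the standard conditions
make_small_world <- function(n_per_cohort = 200L, seed = 42L, ...) {
  spec <- population_spec(cohort_sizes = n_per_cohort, seed = seed, ...)
  pop <- generate_population(spec)
  simulate_mortality(pop, std_params(),
                     c(education_years = log(0.96)), seed = seed)
}

# population whose match keys are unique by construction (for linkage
# guarantees); men only avoids the surname-change channel
make_unique_key_world <- function(n_per_cohort = 100L, seed = 7L) {
  pop <- make_small_world(n_per_cohort, seed = seed)
  n <- nrow(pop)
  pop[, first_key := sprintf("u%06d", seq_len(n))]
  pop[, last_key := sprintf("v%06d", seq_len(n))]
  pop[, family_key := last_key]
  pop[, father_last_key := last_key]
  pop[, register_last_key := last_key]
  pop
}

# direct simulation of a doubly-truncated education-mortality study:
# cohorts 1900-1920, deaths observable at ages [65, 100) inside a
# calendar window; returns a continuous-age truncated_sample
simulate_trunc_study <- function(n, seed, window = c(1975L, 2005L),
                                 beta = log(0.96), min_age = 65) {
  set.seed(seed)
  byear <- sample(1900:1920, n, replace = TRUE)
  edu <- sample(0:21, n, replace = TRUE, prob = default_education_probs())
  t_death <- rgompertz(n, std_params(), bz = beta * edu)
  dyear_cont <- byear + t_death
  obs <- t_death >= min_age & t_death < 100 &
    dyear_cont >= window[1] & dyear_cont < window[2] + 1
  dt <- data.table::data.table(
    byear = byear, death_age = t_death, education_years = edu)[obs]
  list(
    sample = truncated_sample(dt, window, min_age = min_age,
                              covariates = "education_years",
                              jitter = "none"),
    all_deaths = data.table::data.table(byear = byear, death_age = t_death,
                                        education_years = edu)
  )
}
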