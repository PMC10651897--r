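#' Gompertz proportional-hazards parameters
#'
#' The Gompertz law h(x) = a e^{bx} with a proportional covariate multiplier
#' e^{bz}: h_i(x) = a e^{bx} e^{bz_i}. `a` is the hazard level at age 0 (per
#' year), `b` the log-hazard slope per year of age. Defaults are the standard
#' conversion values for US male cohorts of the early 20th century
#' (a = 3.34e-5, b = 0.1).
#'
#' @param a hazard at age 0, per year; must be > 0.
#' @param b log-hazard slope per year of age; must be > 0.
#' @return an object of class `gompertz_params`.
#' @export
gompertz_params <- function(a = 3.34e-5, b = 0.1) {
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a) || a <= 0) {
    config_error("a", "must be a positive finite scalar")
  }
  if (!is.numeric(b) || length(b) != 1L || !is.finite(b) || b <= 0) {
    config_error("b", "must be a positive finite scalar")
  }
  structure(list(a = a, b = b), class = "gompertz_params")
}

#' @export
print.gompertz_params <- function(x, ...) {
  cat(sprintf("Gompertz hazard h(x) = a*exp(b*x): a = %g, b = %g\n",
              x$a, x$b))
  invisible(x)
}

#' Gompertz proportional-hazards distribution functions
#'
#' Evaluates hazard, cumulative hazard, survival, density and CDF of the
#' Gompertz proportional-hazards model at ages `age`, with covariate linear
#' predictor `bz` (log hazard ratio; scalar or vector recycled against age).
#'
#' @param params [gompertz_params()].
#' @param bz linear predictor beta'Z (log hazard ratio), default 0.
#' @param age vector of ages (years, >= 0).
#' @return list with vectors `hazard`, `cumhaz`, `surv`, `dens`, `cdf`.
#' @examples
#' gompertz_functions(gompertz_params(), bz = 0, age = c(0, 35, 70))
#' @export
gompertz_functions <- function(params, bz = 0, age) {
  stopifnot(inherits(params, "gompertz_params"))
  if (any(age < 0)) stop("ages must be nonnegative", call. = FALSE)
  h <- params$a * exp(params$b * age + bz)
  H <- gompertz_cumhaz(age, params$a, params$b, bz)
  S <- exp(-H)
  list(hazard = h, cumhaz = H, surv = S, dens = h * S, cdf = -expm1(-H))
}

# H(x) = (a e^{bz} / b) (e^{bx} - 1), vectorized
gompertz_cumhaz <- function(age, a, b, bz = 0) {
  (a * exp(bz) / b) * expm1(b * age)
}

# log S(x) = -H(x)
gompertz_logsurv <- function(age, a, b, bz = 0) {
  -gompertz_cumhaz(age, a, b, bz)
}

gompertz_logdens <- function(age, a, b, bz = 0) {
  log(a) + bz + b * age - gompertz_cumhaz(age, a, b, bz)
}

#' Sample Gompertz proportional-hazards death ages
#'
#' Inverse-CDF sampling: with E ~ Exp(1),
#' T = (1/b) log(1 + b E / (a e^{bz})).
#'
#' @param n number of draws.
#' @param params [gompertz_params()].
#' @param bz linear predictor per draw (scalar or length-n vector).
#' @return numeric vector of exact (continuous) ages at death.
#' @export
rgompertz <- function(n, params, bz = 0) {
  stopifnot(inherits(params, "gompertz_params"))
  e <- rexp(n)
  log1p(params$b * e / (params$a * exp(bz))) / params$b
}

#' Remaining life expectancy at an age under a hazard multiplier
#'
#' e(x) = integral over t >= 0 of exp(-hr * H(x, x + t)) dt, where
#' H(x, x + t) is the baseline Gompertz cumulative hazard between x and
#' x + t. The multiplier `hr` scales the hazard above age `x` only.
#'
#' @param age age x at which remaining expectancy is evaluated.
#' @param params [gompertz_params()].
#' @param hr hazard ratio applied above `age` (> 0), default 1.
#' @param rel_tol quadrature relative tolerance.
#' @return remaining life expectancy in years.
#' @export
gompertz_e_remaining <- function(age, params, hr = 1, rel_tol = 1e-8) {
  stopifnot(inherits(params, "gompertz_params"))
  if (!is.finite(hr) || hr <= 0) stop("hr must be > 0", call. = FALSE)
  a <- params$a; b <- params$b
  # H(x, x+t) = (a e^{bx} / b) (e^{bt} - 1)
  cc <- a * exp(b * age) / b
  f <- function(t) exp(-hr * cc * expm1(b * t))
  integrate(f, 0, Inf, rel.tol = rel_tol)$value
}
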