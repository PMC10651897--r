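#' @importFrom data.table data.table as.data.table setDT setnames := .N .SD
#'   copy rbindlist fread fwrite setorder setorderv setcolorder setkeyv set
#' @importFrom stats optim optimHess runif rexp lm coef setNames integrate
#'   pnorm qnorm sd
#' @importFrom utils head modifyList packageVersion
NULL

# data.table NSE variables, silences R CMD check
utils::globalVariables(c(
  ".", "histid", "row_id", "byear", "bmonth", "dyear", "dmonth",
  "death_age", "weight", "n_deaths", "n_sample", "n_target", "bstate",
  "race", "sex", "marital_status", "education_years", "first_key",
  "last_key", "father_last_key", "middle_initial", "true_dyear",
  "true_dmonth", "true_death_age", "census_age", "reg_census_age",
  "in_window", "included", "band", "reason", "weight_src", "in_universe",
  "first_std", "last_std", "match_key", "n_cand", "cand_c", "cand_r",
  "immigrated_before_census", "register_last_key", "family_key",
  "marry_after_census", "cohort", "age", "deaths", "survivors",
  "q_a", "m_a", "w0", "level", "i.weight", "N", "edu_cat", "region",
  "stratum", "dimension", "age_c", "age_r", "histid_true", "mi_c", "mi_r",
  "pct_weighted", "pct_census", "difference", "count_matched",
  "pct_unweighted", "adj", "s", "log_m", "metric", "value", "term",
  "natural", "variant", "canonical"
))

#' Evaluate an expression under a temporary RNG state
#'
#' Saves and restores `.Random.seed`, so library code never perturbs the
#' caller's random stream. `label` maps a single global seed to independent
#' per-stage substreams.
#'
#' @param seed integer scalar, the global seed.
#' @param label character scalar naming the substream (stage name).
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_substream <- function(seed, label, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, label))
  expr
}

#' Derive a deterministic substream seed from (seed, label)
#'
#' djb2-style string hash folded with the seed, reduced mod 2^31 - 1 so the
#' result is always a valid 32-bit R integer.
#'
#' @keywords internal
substream_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  h <- 5381
  for (ch in utf8ToInt(label)) h <- (h * 33 + ch) %% 2147483647
  as.integer((h + (abs(seed) %% 2147483647) * 48271) %% 2147483647)
}

#' Stop with a configuration error naming the offending field
#' @keywords internal
config_error <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg),
       call. = FALSE)
}

check_prob_vec <- function(p, field, tol = 1e-9) {
  if (any(!is.finite(p)) || any(p < 0)) {
    config_error(field, "must be finite and nonnegative")
  }
  if (abs(sum(p) - 1) > tol) {
    config_error(field, sprintf("must sum to 1 (got %.12f)", sum(p)))
  }
  invisible(p)
}

# months-since-year-0 encoding used for all date arithmetic; month in 1..12
month_index <- function(year, month) year * 12L + (month - 1L)

# completed years lived between two month indices
completed_years <- function(from_idx, to_idx) (to_idx - from_idx) %/% 12L

#' Contiguous US states + DC with census divisions
#'
#' 49 birth-state levels used by the generator and the representativeness
#' tables, plus the census division ("region") each belongs to. AK/HI are
#' excluded; an extra "abroad" level marks the foreign-born.
#'
#' @return data.table with columns `bstate`, `region`.
#' @export
state_regions <- function() {
  keep <- !(datasets::state.abb %in% c("AK", "HI"))
  dt <- data.table(
    bstate = c(datasets::state.abb[keep], "DC"),
    region = c(as.character(datasets::state.division[keep]),
               "South Atlantic")
  )
  setorder(dt, bstate)
  dt[]
}
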