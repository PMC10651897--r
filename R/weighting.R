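#' Post-stratification cell weights (ratio of reference to sample deaths)
#'
#' For every linked death inside the weighting universe (native-born, died
#' at ages `age_range`, death year inside `year_range`), assigns
#' W = n_target / n_sample for its (year, age, sex, race, birth state)
#' cell, where n_target comes from the reference totals and n_sample from
#' the linked file itself. Records outside the universe, or in cells absent
#' from the reference totals, are flagged unweighted (`NA`) for the
#' fallback rules.
#'
#' @param linked data.table of linked deaths carrying the cell dimensions.
#' @param totals reference totals with the same dimensions + `n_deaths`.
#' @param dims cell dimensions, default
#'   `c("dyear", "death_age", "sex", "race", "bstate")`.
#' @param age_range inclusive age-at-death universe, default `c(65, 100)`.
#' @param year_range inclusive death-year universe (the register's
#'   high-coverage window).
#' @return list: `linked` (copy with `weight`, `weight_src`,
#'   `in_universe`), `cells` (data.table of populated cells with
#'   `n_target`, `n_sample`, `weight`).
#' @export
compute_cell_weights <- function(linked, totals,
                                 dims = c("dyear", "death_age", "sex",
                                          "race", "bstate"),
                                 age_range = c(65L, 100L),
                                 year_range) {
  linked <- copy(as.data.table(linked))
  totals <- as.data.table(totals)
  for (nm in dims) {
    if (!nm %in% names(linked)) {
      stop(sprintf("linked table lacks dimension '%s'", nm), call. = FALSE)
    }
    if (!nm %in% names(totals)) {
      stop(sprintf("totals table lacks dimension '%s'", nm), call. = FALSE)
    }
  }
  linked[, in_universe :=
           (!"bstate" %in% dims | bstate != "abroad") &
           death_age >= age_range[1] & death_age <= age_range[2] &
           dyear >= year_range[1] & dyear <= year_range[2]]
  samp <- linked[in_universe == TRUE, .(n_sample = .N), by = dims]
  cells <- merge(samp, totals[, c(dims, "n_deaths"), with = FALSE],
                 by = dims, all.x = TRUE)
  setnames(cells, "n_deaths", "n_target")
  cells[, weight := ifelse(!is.na(n_target) & n_sample > 0,
                           n_target / n_sample, NA_real_)]
  linked[, weight := NA_real_]
  linked[, weight_src := NA_character_]
  linked[cells, on = dims, weight := i.weight]
  linked[in_universe == FALSE, weight := NA_real_]
  linked[!is.na(weight), weight_src := "cell"]
  list(linked = linked[], cells = cells[])
}

#' Fallback weights for records the cell rule cannot cover
#'
#' Applies, in order: (i) deaths in years before the birth-state-available
#' cutoff get the cutoff-year weight of their (age, race, birthplace)
#' stratum (averaged over sex); (ii) the foreign-born get the mean weight
#' of native-born decedents sharing death year, age, race and sex; (iii)
#' any record still unweighted gets the mean weight of native-born
#' decedents sharing age, year, sex and race; (iv) remaining records get
#' weight 1. Every record ends with a positive weight.
#'
#' @param linked output `linked` of [compute_cell_weights()].
#' @param cells output `cells` of [compute_cell_weights()].
#' @param bstate_cutoff first death year with birth state available in the
#'   reference totals (`NULL` disables rule i).
#' @param precutoff_include_sex include sex in the rule-(i) strata; the
#'   canonical reading excludes it. Default FALSE.
#' @return copy of `linked` with completed `weight` and `weight_src` in
#'   `cell`, `pre-cutoff`, `foreign-born`, `mean-aysr`, `unit`.
#' @export
assign_fallback_weights <- function(linked, cells, bstate_cutoff = NULL,
                                    precutoff_include_sex = FALSE) {
  linked <- copy(as.data.table(linked))
  cells <- as.data.table(cells)

  fill_from <- function(idx, lookup, by_cols, src) {
    if (!length(idx)) return(invisible())
    w <- lookup[linked[idx], on = by_cols, w0]
    got <- idx[!is.na(w)]
    linked[got, weight := w[!is.na(w)]]
    linked[got, weight_src := src]
  }

  if (!is.null(bstate_cutoff)) {
    by_i <- c("death_age", "race", "bstate")
    if (precutoff_include_sex) by_i <- c(by_i, "sex")
    ref <- cells[dyear == bstate_cutoff & !is.na(weight),
                 .(w0 = mean(weight)), by = by_i]
    fill_from(which(is.na(linked$weight) & linked$dyear < bstate_cutoff),
              ref, by_i, "pre-cutoff")
  }

  # mean weight of already-weighted native-born decedents by
  # (dyear, death_age, sex, race); donors include pre-cutoff-weighted
  # records, since the rule speaks of decedents' weights, not Eq.-1 cells
  by_n <- c("dyear", "death_age", "sex", "race")
  native_donors <- function() {
    linked[!is.na(weight) & bstate != "abroad",
           .(w0 = mean(weight)), by = .(dyear, death_age, sex, race)]
  }
  fill_from(which(is.na(linked$weight) & linked$bstate == "abroad"),
            native_donors(), by_n, "foreign-born")
  fill_from(which(is.na(linked$weight)), native_donors(), by_n,
            "mean-aysr")
  linked[is.na(weight), `:=`(weight = 1, weight_src = "unit")]
  linked[]
}

#' Margin specification for raking
#'
#' @param dimension column name the margin constrains.
#' @param targets named numeric vector of population totals per level.
#' @param tolerance maximum relative error accepted for the margin.
#' @return object of class `margin_spec`.
#' @export
margin_spec <- function(dimension, targets, tolerance = 1e-6) {
  if (any(!is.finite(targets)) || any(targets < 0)) {
    config_error("targets", "must be finite and nonnegative")
  }
  if (is.null(names(targets))) config_error("targets", "must be named")
  structure(list(dimension = dimension, targets = targets,
                 tolerance = tolerance), class = "margin_spec")
}

#' Marginal targets derived from a reference-totals table
#'
#' @param totals reference totals (`n_deaths` plus dimension columns).
#' @param dims dimensions to build margins for.
#' @param tolerance per-margin relative tolerance.
#' @return list of [margin_spec()].
#' @export
margins_from_totals <- function(totals, dims, tolerance = 1e-6) {
  totals <- as.data.table(totals)
  lapply(dims, function(dm) {
    m <- totals[!is.na(get(dm)) & get(dm) != "",
                .(n = sum(n_deaths)), by = dm]
    margin_spec(dm, setNames(m$n, as.character(m[[dm]])), tolerance)
  })
}

max_margin_rel_err <- function(dt, margins, weight_col = "weight") {
  vapply(margins, function(mg) {
    cur <- dt[, .(s = sum(get(weight_col))), by = c(mg$dimension)]
    lev <- as.character(cur[[mg$dimension]])
    tgt <- mg$targets[lev]
    if (any(is.na(tgt))) {
      stop(sprintf("sample level absent from margin '%s' targets",
                   mg$dimension), call. = FALSE)
    }
    max(abs(cur$s - tgt) / pmax(tgt, .Machine$double.eps))
  }, numeric(1))
}

#' Rake weights to marginal population totals (IPF)
#'
#' Classical raking ratio estimation: cycle through the margins in order,
#' multiplying each record's weight by target/current for its level, until
#' every margin's maximum relative error is within its tolerance or
#' `max_iter` cycles are exhausted.
#'
#' @param dt data.table with a weight column and the margin dimensions.
#' @param margins list of [margin_spec()].
#' @param max_iter maximum IPF cycles (default 100).
#' @param weight_col name of the weight column.
#' @return list: `weights` (calibrated vector, row order of `dt`),
#'   `converged`, `iterations`, `max_rel_err` (named per margin).
#' @export
rake <- function(dt, margins, max_iter = 100L, weight_col = "weight") {
  dt <- copy(as.data.table(dt))
  stopifnot(length(margins) > 0L)
  for (mg in margins) {
    lev_s <- unique(as.character(dt[[mg$dimension]]))
    bad <- lev_s[!is.na(match(lev_s, names(mg$targets))) &
                   mg$targets[lev_s] == 0]
    bad <- c(bad, lev_s[is.na(match(lev_s, names(mg$targets)))])
    if (length(bad)) {
      stop(sprintf(
        "infeasible margin '%s': sample level(s) %s have no positive target",
        mg$dimension, paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  tols <- vapply(margins, `[[`, numeric(1), "tolerance")
  err <- max_margin_rel_err(dt, margins, weight_col)
  it <- 0L
  while (any(err > tols) && it < max_iter) {
    it <- it + 1L
    for (mg in margins) {
      cur <- dt[, .(s = sum(get(weight_col))), by = c(mg$dimension)]
      cur[, adj := mg$targets[as.character(get(mg$dimension))] / s]
      fac <- cur[dt, on = mg$dimension, adj]
      data.table::set(dt, j = weight_col, value = dt[[weight_col]] * fac)
    }
    err <- max_margin_rel_err(dt, margins, weight_col)
  }
  list(weights = dt[[weight_col]], converged = all(err <= tols),
       iterations = it,
       max_rel_err = setNames(err, vapply(margins, `[[`, character(1),
                                          "dimension")))
}

#' Trim weights into a floor/ceiling band
#'
#' The canonical band is a floor of 1 and a ceiling of five times the mean
#' unadjusted (pre-raking) weight; the ceiling is computed once from the
#' unadjusted weights and held fixed across rake-trim rounds.
#'
#' @param weights numeric weights.
#' @param floor lower bound, default 1.
#' @param ceiling upper bound; default `5 * mean(unadjusted)`.
#' @param unadjusted the pre-raking weights the ceiling anchors to
#'   (required when `ceiling` is NULL).
#' @return clamped weights.
#' @export
trim_weights <- function(weights, floor = 1, ceiling = NULL,
                         unadjusted = NULL) {
  if (is.null(ceiling)) {
    if (is.null(unadjusted) || !length(unadjusted) ||
        mean(unadjusted) <= 0) {
      stop("ceiling requires positive unadjusted weights", call. = FALSE)
    }
    ceiling <- 5 * mean(unadjusted)
  }
  pmin(pmax(weights, floor), ceiling)
}

#' Iterative rake-then-trim calibration
#'
#' Alternates raking and trimming until, in one round, no weight is
#' clamped and every margin is within tolerance, or `max_rounds` is
#' reached (reported, not an error). Records outside `calibrate` (e.g.
#' pre-cutoff years, the foreign-born) are trimmed but never raked.
#'
#' @param linked weighted linked table (after fallback rules).
#' @param margins list of [margin_spec()] for the calibratable subset.
#' @param calibrate logical vector marking records subject to raking;
#'   default all.
#' @param floor,ceiling trim band; `ceiling = NULL` anchors to
#'   `5 * mean` of the current (unadjusted) weights of the calibratable
#'   subset.
#' @param max_rounds maximum rake-trim rounds (default 10).
#' @param max_iter IPF cycles per rake call.
#' @return list: `linked` (copy with final `weight`), `diagnostics`
#'   (coverage ratio, share of raw weights above the ceiling, rounds, IPF
#'   iterations, per-margin max relative error, `converged`).
#' @export
rake_trim_iterate <- function(linked, margins, calibrate = NULL,
                              floor = 1, ceiling = NULL,
                              max_rounds = 10L, max_iter = 100L) {
  linked <- copy(as.data.table(linked))
  if (is.null(calibrate)) calibrate <- rep(TRUE, nrow(linked))
  unadj <- linked$weight[calibrate]
  if (is.null(ceiling)) ceiling <- 5 * mean(unadj)
  share_above <- mean(unadj > ceiling)
  tols <- vapply(margins, `[[`, numeric(1), "tolerance")

  sub <- linked[calibrate]
  rounds <- 0L; ipf_total <- 0L; converged <- FALSE
  err <- rep(Inf, length(margins))
  while (rounds < max_rounds) {
    rounds <- rounds + 1L
    rk <- rake(sub, margins, max_iter = max_iter)
    ipf_total <- ipf_total + rk$iterations
    trimmed <- trim_weights(rk$weights, floor, ceiling)
    clamped <- any(abs(trimmed - rk$weights) >
                     1e-12 * pmax(1, abs(rk$weights)))
    sub[, weight := trimmed]
    err <- max_margin_rel_err(sub, margins)
    if (!clamped && all(err <= tols)) { converged <- TRUE; break }
  }
  linked[calibrate, weight := sub$weight]
  # records never raked are still trimmed into the band
  linked[!calibrate, weight := trim_weights(weight, floor, ceiling)]
  target_total <- sum(margins[[1]]$targets)
  diagnostics <- list(
    coverage_ratio = sum(sub$weight) / target_total,
    share_above_ceiling = share_above,
    rounds = rounds, ipf_iterations = ipf_total,
    max_rel_err = setNames(err, vapply(margins, `[[`, character(1),
                                       "dimension")),
    converged = converged, ceiling = ceiling
  )
  list(linked = linked[], diagnostics = diagnostics)
}
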