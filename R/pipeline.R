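#' Default pipeline configuration
#'
#' A single nested list (JSON-serializable) holding every stage's
#' parameters: population spec, both register specs, noise, weighting
#' universe and thresholds, estimation options and the global seed. All
#' randomness in the pipeline derives from `seed` via labeled substreams.
#'
#' @param seed global integer seed.
#' @param n_per_cohort persons per birth cohort.
#' @return nested configuration list.
#' @export
default_config <- function(seed = 1L, n_per_cohort = 1000L) {
  list(
    seed = as.integer(seed),
    population = list(
      cohort_range = c(1900L, 1920L),
      n_per_cohort = as.integer(n_per_cohort),
      p_abroad = 0.07,
      p_immigrated_before_census = 0.85,
      p_marry_after_census = 0.20,
      n_first = 2000L, n_last = 4000L
    ),
    mortality = list(a = 3.34e-5, b = 0.1,
                     effect = list(education_years = log(0.96))),
    census_day = c(1940L, 4L),
    registers = list(
      dmf = list(kind = "dmf-like", window = c(1975L, 2005L),
                 p_in = 0.96, p_out = 0.05),
      numident = list(kind = "numident-like", window = c(1988L, 2005L),
                      p_in = 0.96, p_out = 0.05)
    ),
    noise = list(name_typo_rate = 0.05, nickname_swap_rate = 0.10,
                 duplicate_key_rate = 0.002,
                 age_misstatement = c(0.01, 0.05, 0.88, 0.05, 0.01),
                 mi_missing_register = 0.3, mi_missing_census = 0.7),
    weighting = list(age_range = c(65L, 100L),
                     bstate_cutoff = 1979L,
                     rake_tol = 1e-6, max_ipf_iter = 100L,
                     max_rounds = 10L),
    estimation = list(covariates = "education_years", min_age = 65,
                      jitter = "midpoint", use_weights = FALSE),
    log_level = "info"
  )
}

#' Read / write a pipeline configuration (JSON)
#'
#' @param path file path.
#' @return configuration list.
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  modifyList(default_config(), cfg)
}

#' @rdname read_config
#' @param config configuration list.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

config_hash <- function(config) {
  # polynomial rolling hash over the canonical JSON encoding
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  h <- 5381
  for (ch in utf8ToInt(as.character(s))) h <- (h * 33 + ch) %% 2147483647
  sprintf("%08x", as.integer(h))
}

noise_from_config <- function(nz) {
  noise_spec(
    name_typo_rate = nz$name_typo_rate,
    nickname_swap_rate = nz$nickname_swap_rate,
    duplicate_key_rate = nz$duplicate_key_rate,
    age_misstatement_dist = setNames(nz$age_misstatement,
                                     as.character(-2:2)),
    mi_missing_register = nz$mi_missing_register,
    mi_missing_census = nz$mi_missing_census
  )
}

plog <- function(level, cfg, fmt, ...) {
  if (identical(cfg$log_level, "quiet")) return(invisible())
  message(sprintf("[%s] %s", level, sprintf(fmt, ...)))
}

#' Run the full pipeline: generate, link, weight, estimate, report
#'
#' Executes the stages in order, writing every intermediate as a headered
#' CSV under `outdir` so any suffix of the stage list can be resumed from
#' disk. Returns a run manifest with the config hash, seed and per-stage
#' row counts.
#'
#' Files written: `population.csv`, `census.csv`, `register_{dmf,numident}.csv`,
#' `truth_{dmf,numident}.csv`, `totals_{dmf,numident}.csv`,
#' `crosswalk_{dmf,numident}.csv`, `linked_{dmf,numident}.csv` (the public
#' person-level layouts, with a `weight` column), `weight_cells_*.csv`,
#' `weight_diagnostics_*.csv`, `fit_*.csv`, `cohort_rates_*.csv`,
#' `evaluation_*.csv`, `manifest.json`.
#'
#' @param config configuration list (see [default_config()]).
#' @param outdir output directory (created if needed).
#' @param stages subset of
#'   `c("generate", "link", "weight", "estimate", "report")`, in order;
#'   earlier stages are read back from `outdir` when skipped.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config = default_config(), outdir,
                         stages = c("generate", "link", "weight",
                                    "estimate", "report")) {
  all_stages <- c("generate", "link", "weight", "estimate", "report")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  pth <- function(...) file.path(outdir, paste0(...))
  counts <- list()
  nicknames <- make_nickname_table(config$population$n_first)
  seed <- config$seed

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  if ("generate" %in% stages) run_stage("generate", {
    pc <- config$population
    spec <- population_spec(
      cohort_range = pc$cohort_range, cohort_sizes = pc$n_per_cohort,
      p_abroad = pc$p_abroad,
      p_immigrated_before_census = pc$p_immigrated_before_census,
      p_marry_after_census = pc$p_marry_after_census,
      n_first = pc$n_first, n_last = pc$n_last, seed = seed)
    pop <- generate_population(spec)
    params <- gompertz_params(config$mortality$a, config$mortality$b)
    eff <- unlist(config$mortality$effect)
    pop <- simulate_mortality(pop, params, eff, seed = seed)
    census <- build_census_file(pop, config$census_day)
    mi_miss <- with_substream(seed, "census-mi",
      runif(nrow(census)) < config$noise$mi_missing_census)
    census[mi_miss, middle_initial := NA_character_]
    fwrite(pop, pth("population.csv"))
    fwrite(census, pth("census.csv"))
    nz <- noise_from_config(config$noise)
    for (rg in names(config$registers)) {
      rc <- config$registers[[rg]]
      rs <- register_spec(rc$kind, rc$window, rc$p_in, rc$p_out)
      out <- build_death_register(pop, rs, nz, nicknames, seed = seed)
      fwrite(out$register, pth("register_", rg, ".csv"))
      fwrite(out$truth, pth("truth_", rg, ".csv"))
      tot <- build_reference_totals(
        pop, years = rc$window,
        suppress_bstate_before =
          if (rg == "dmf") config$weighting$bstate_cutoff else NULL)
      fwrite(tot, pth("totals_", rg, ".csv"))
    }
    plog("info", config, "generate: population %d, census %d",
         nrow(pop), nrow(census))
  })
  counts$population <- nrow(fread(pth("population.csv")))
  census <- fread(pth("census.csv"))
  counts$census <- nrow(census)

  if ("link" %in% stages) run_stage("link", {
    for (rg in names(config$registers)) {
      reg <- fread(pth("register_", rg, ".csv"))
      kind <- config$registers[[rg]]$kind
      use_bs <- kind == "numident-like"
      men <- census[sex == "male"]
      reg_men <- if ("sex" %in% names(reg)) reg[sex == "male"] else reg
      res <- abe_conservative_match(men, reg_men, use_birth_state = use_bs,
                                    nicknames = nicknames,
                                    census_day = config$census_day)
      if (kind == "numident-like") {
        resw <- match_women(census, reg, use_birth_state = use_bs,
                            nicknames = nicknames,
                            census_day = config$census_day)
        resw$pairs <- resw$pairs[!row_id %in% res$pairs$row_id]
        res$pairs <- rbindlist(list(res$pairs, resw$pairs))
      }
      fwrite(res$pairs, pth("crosswalk_", rg, ".csv"))
      fwrite(res$unmatched_census, pth("exclusions_", rg, ".csv"))
      plog("info", config, "link %s: %d pairs", rg, nrow(res$pairs))
    }
  })

  if ("weight" %in% stages) run_stage("weight", {
    for (rg in names(config$registers)) {
      reg <- fread(pth("register_", rg, ".csv"))
      cw <- fread(pth("crosswalk_", rg, ".csv"))
      tot <- fread(pth("totals_", rg, ".csv"))
      kind <- config$registers[[rg]]$kind
      window <- config$registers[[rg]]$window
      linked <- build_linked_table(cw, reg, census, kind)
      wc <- config$weighting
      # the public file universe: deaths inside the high-coverage window
      # and within the weightable age span
      linked <- linked[dyear >= window[1] & dyear <= window[2] &
                         death_age >= wc$age_range[1] &
                         death_age <= wc$age_range[2]]
      cutoff <- if (rg == "dmf") wc$bstate_cutoff else NULL
      res <- compute_cell_weights(linked, tot,
                                  age_range = wc$age_range,
                                  year_range = window)
      linked <- assign_fallback_weights(res$linked, res$cells,
                                        bstate_cutoff = cutoff)
      calib <- linked$in_universe &
        (is.null(cutoff) | linked$dyear >= (cutoff %||% -Inf)) &
        linked$weight_src %in% c("cell", "mean-aysr")
      # margin universe: native-born, weightable ages, post-cutoff years,
      # and only the sexes the register's sample can contain
      mt <- tot[!is.na(bstate) & bstate != "" & bstate != "abroad" &
                  n_deaths > 0]
      mt <- mt[death_age >= wc$age_range[1] &
                 death_age <= wc$age_range[2]]
      if (kind == "dmf-like") mt <- mt[sex == "male"]
      if (!is.null(cutoff)) mt <- mt[dyear >= cutoff]
      margins <- margins_from_totals(
        mt, dims = c("dyear", "death_age", "sex", "race", "bstate"),
        tolerance = wc$rake_tol)
      # records whose (noisy) margin levels have no population target are
      # not calibratable; they keep their fallback weight, trimmed only
      for (mg in margins) {
        calib <- calib &
          as.character(linked[[mg$dimension]]) %in% names(mg$targets)
      }
      rt <- rake_trim_iterate(linked, margins, calibrate = calib,
                              max_rounds = wc$max_rounds,
                              max_iter = wc$max_ipf_iter)
      linked <- rt$linked
      fwrite(public_layout(linked, kind), pth("linked_", rg, ".csv"))
      fwrite(res$cells, pth("weight_cells_", rg, ".csv"))
      dg <- rt$diagnostics
      fwrite(data.table(metric = c("coverage_ratio",
                                   "share_above_ceiling", "rounds",
                                   "ipf_iterations", "converged",
                                   "ceiling", "share_unit_weight"),
                        value = c(dg$coverage_ratio,
                                  dg$share_above_ceiling, dg$rounds,
                                  dg$ipf_iterations,
                                  as.numeric(dg$converged), dg$ceiling,
                                  mean(linked$weight_src == "unit"))),
             pth("weight_diagnostics_", rg, ".csv"))
      plog("info", config, "weight %s: %d linked, coverage %.4f",
           rg, nrow(linked), dg$coverage_ratio)
    }
  })

  if ("estimate" %in% stages) run_stage("estimate", {
    for (rg in names(config$registers)) {
      linked <- fread(pth("linked_", rg, ".csv"))
      full <- merge_on_histid(linked, census)
      es <- config$estimation
      window <- config$registers[[rg]]$window
      samp <- truncated_sample(full, window, min_age = es$min_age,
                               covariates = es$covariates,
                               jitter = es$jitter,
                               weight_col =
                                 if (isTRUE(es$use_weights)) "weight"
                                 else NULL)
      fit <- fit_gompertz_trunc(samp)
      fwrite(data.table(
        term = names(fit$theta), estimate = fit$theta, se = fit$se,
        natural = c(fit$a_hat, fit$b_hat, unname(fit$hr)),
        loglik = fit$loglik, converged = fit$converged),
        pth("fit_", rg, ".csv"))
      rates <- extinct_cohort_rates(cohort_death_counts(full))
      rates[, log_m := ifelse(is.na(m_a) | m_a <= 0, NA_real_,
                              log(m_a))]
      fwrite(rates, pth("cohort_rates_", rg, ".csv"))
      plog("info", config, "estimate %s: b = %.4f, HR = %.4f",
           rg, fit$b_hat, if (length(fit$hr)) fit$hr[1] else NA)
    }
  })

  if ("report" %in% stages) run_stage("report", {
    for (rg in names(config$registers)) {
      reg <- fread(pth("register_", rg, ".csv"))
      cw <- fread(pth("crosswalk_", rg, ".csv"))
      truth <- fread(pth("truth_", rg, ".csv"))
      linked <- fread(pth("linked_", rg, ".csv"))
      res <- structure(list(pairs = cw,
                            unmatched_census = data.table(),
                            unmatched_register = data.table(),
                            counts = c(n_census = nrow(census),
                                       n_register = nrow(reg),
                                       n_matched = nrow(cw))),
                       class = "match_result")
      wts <- setNames(linked$weight, linked$histid)
      ev <- evaluate_linkage(res, truth, census, reg, weights = wts)
      fwrite(ev$representativeness, pth("evaluation_", rg, ".csv"))
      fwrite(data.table(metric = c(names(ev$summary), "mi_n_both",
                                   "mi_agreement"),
                        value = c(unname(ev$summary),
                                  ev$middle_initial$n_both,
                                  ev$middle_initial$agreement)),
             pth("evaluation_summary_", rg, ".csv"))
      plog("info", config, "report %s: match rate %.3f, precision %.3f",
           rg, ev$summary["match_rate"], ev$summary["precision"])
    }
  })

  for (rg in names(config$registers)) {
    f <- pth("crosswalk_", rg, ".csv")
    if (file.exists(f)) counts[[paste0("matched_", rg)]] <- nrow(fread(f))
    f <- pth("register_", rg, ".csv")
    if (file.exists(f)) counts[[paste0("register_", rg)]] <- nrow(fread(f))
  }
  manifest <- list(
    config_hash = config_hash(config), seed = config$seed,
    counts = counts,
    version = as.character(packageVersion("mortlink")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# assemble the person-level linked table used for weighting
build_linked_table <- function(crosswalk, register, census, kind) {
  linked <- merge(as.data.table(crosswalk)[, .(histid, row_id)],
                  as.data.table(register), by = "row_id")
  cen_cols <- c("histid", "race", "education_years", "marital_status")
  if (kind == "dmf-like") cen_cols <- c(cen_cols, "sex", "bstate")
  linked <- merge(linked, as.data.table(census)[, cen_cols, with = FALSE],
                  by = "histid")
  linked
}

# emit the public person-level CSV layout for each register kind
public_layout <- function(linked, kind) {
  linked <- as.data.table(linked)
  base <- linked[, .(histid, byear, bmonth, dyear, dmonth, death_age,
                     weight)]
  if (kind == "dmf-like") return(base)
  ext <- linked[, .(sex, race_first = race, race_last = race,
                    bpl = bstate, socstate = NA_character_,
                    age_first_application = NA_integer_,
                    zip_residence = NA_character_)]
  cbind(base, ext)
}

#' Inner join of a linked mortality file with the census on histid
#'
#' Duplicated histids on either side are an integrity error (named in the
#' message); histids that do not resolve produce a warning with the count.
#'
#' @param x linked (register-side) table with `histid`.
#' @param census census table with `histid`.
#' @return data.table inner join.
#' @export
merge_on_histid <- function(x, census) {
  x <- as.data.table(x); census <- as.data.table(census)
  dup_x <- unique(x$histid[duplicated(x$histid)])
  if (length(dup_x)) {
    stop(sprintf("duplicated histid(s) in linked table: %s",
                 paste(head(dup_x, 5), collapse = ", ")), call. = FALSE)
  }
  dup_c <- unique(census$histid[duplicated(census$histid)])
  if (length(dup_c)) {
    stop(sprintf("duplicated histid(s) in census table: %s",
                 paste(head(dup_c, 5), collapse = ", ")), call. = FALSE)
  }
  out <- merge(x, census, by = "histid", suffixes = c("", "_census"))
  n_lost <- nrow(x) - nrow(out)
  if (n_lost > 0) {
    warning(sprintf("%d histid(s) did not resolve in the census", n_lost),
            call. = FALSE)
  }
  out
}

#' Write a small bundled demo fixture
#'
#' Runs the full pipeline on a ~5,000-person population under a frozen
#' seed, producing a complete set of stage outputs (including the truth
#' maps) that the test suite and examples use.
#'
#' @param dir output directory.
#' @param seed frozen seed, default 1940.
#' @return the run manifest, invisibly.
#' @export
make_demo_fixture <- function(dir = tempfile("mortlink-demo-"),
                              seed = 1940L) {
  cfg <- default_config(seed = seed, n_per_cohort = 238L)
  cfg$log_level <- "quiet"
  manifest <- run_pipeline(cfg, dir)
  invisible(manifest)
}
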