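# minimal linked/totals fixtures built in code
mk_linked <- function(n, dyear = 1990L, death_age = 75L, sex = "male",
                      race = "White", bstate = "CA") {
  data.table::data.table(histid = sprintf("h%04d", seq_len(n)),
                         dyear = dyear, death_age = death_age,
                         sex = sex, race = race, bstate = bstate)
}

test_that("cell weight is the target/sample ratio; exact conservation", {
  linked <- mk_linked(20L)
  totals <- data.table::data.table(dyear = 1990L, death_age = 75L,
                                   sex = "male", race = "White",
                                   bstate = "CA", n_deaths = 100L)
  res <- compute_cell_weights(linked, totals, year_range = c(1988L, 2005L))
  expect_true(all(res$linked$weight == 5.0))
  expect_equal(sum(res$linked$weight), 100)     # weighted = target

  # n_sample = n_target in every cell: weights all 1
  totals2 <- data.table::copy(totals)[, n_deaths := 20L]
  res2 <- compute_cell_weights(linked, totals2,
                               year_range = c(1988L, 2005L))
  expect_true(all(res2$linked$weight == 1.0))
})

test_that("universe filtering and empty cells flag rather than error", {
  linked <- rbind(mk_linked(5L),
                  mk_linked(2L, death_age = 50L),      # below age range
                  mk_linked(2L, dyear = 1980L),        # outside window
                  mk_linked(2L, bstate = "abroad"))    # foreign-born
  totals <- data.table::data.table(dyear = 1990L, death_age = 75L,
                                   sex = "male", race = "White",
                                   bstate = "CA", n_deaths = 10L)
  res <- compute_cell_weights(linked, totals, year_range = c(1988L, 2005L))
  expect_equal(sum(res$linked$in_universe), 5L)
  expect_equal(sum(is.na(res$linked$weight)), 6L)
})

test_that("fallback rules fill every record with a positive weight", {
  # cell-weighted natives + one foreign-born + one unweightable stratum
  linked <- rbind(mk_linked(4L),
                  mk_linked(1L, bstate = "abroad"),
                  mk_linked(1L, race = "Other", bstate = "ZZ"))
  totals <- data.table::data.table(dyear = 1990L, death_age = 75L,
                                   sex = "male", race = "White",
                                   bstate = "CA", n_deaths = 10L)
  res <- compute_cell_weights(linked, totals, year_range = c(1988L, 2005L))
  out <- assign_fallback_weights(res$linked, res$cells)
  expect_true(all(out$weight > 0))
  # foreign-born: mean weight of native-born in same (y, a, r, s) = 2.5
  expect_equal(out[bstate == "abroad"]$weight, 2.5)
  expect_equal(out[bstate == "abroad"]$weight_src, "foreign-born")
  # no same-cell natives for race Other: falls through to weight 1
  expect_equal(out[race == "Other"]$weight, 1)
  expect_equal(out[race == "Other"]$weight_src, "unit")
})

test_that("pre-cutoff years inherit the cutoff-year stratum weight", {
  linked <- rbind(mk_linked(4L, dyear = 1979L),
                  mk_linked(3L, dyear = 1976L))
  totals <- data.table::data.table(dyear = 1979L, death_age = 75L,
                                   sex = "male", race = "White",
                                   bstate = "CA", n_deaths = 12L)
  res <- compute_cell_weights(linked, totals, year_range = c(1975L, 2005L))
  out <- assign_fallback_weights(res$linked, res$cells,
                                 bstate_cutoff = 1979L)
  expect_equal(unique(out[dyear == 1976L]$weight), 3)  # 12/4 from 1979
  expect_equal(unique(out[dyear == 1976L]$weight_src), "pre-cutoff")
})

test_that("raking: trivial cases and the 2x2 IPF fixed-point oracle", {
  dt <- data.table::data.table(
    row = c("a", "a", "b", "b"), col = c("x", "y", "x", "y"), weight = 1)
  margins <- list(margin_spec("row", c(a = 30, b = 70)),
                  margin_spec("col", c(x = 40, y = 60)))
  rk <- rake(dt, margins)
  expect_true(rk$converged)
  oracle <- oracle_ipf_2way(rep(1, 4), dt$row, dt$col,
                            c(a = 30, b = 70), c(x = 40, y = 60))
  expect_equal(rk$weights, unname(oracle), tolerance = 1e-8)

  # margins already satisfied: weights unchanged, zero iterations
  dt2 <- data.table::data.table(g = c("a", "b"), weight = c(3, 7))
  rk2 <- rake(dt2, list(margin_spec("g", c(a = 3, b = 7))))
  expect_identical(rk2$iterations, 0L)
  expect_equal(rk2$weights, c(3, 7))

  # single margin calibrates exactly in one pass
  dt3 <- data.table::data.table(g = c("a", "a", "b"), weight = 1)
  rk3 <- rake(dt3, list(margin_spec("g", c(a = 10, b = 5))))
  expect_equal(rk3$weights, c(5, 5, 5))
  expect_lte(rk3$iterations, 1L)

  # zero-target level present in the sample is infeasible
  expect_error(rake(dt3, list(margin_spec("g", c(a = 10, b = 0)))),
               "infeasible margin")
})

test_that("trimming clamps into [floor, 5 x mean unadjusted]", {
  expect_equal(trim_weights(0.4, ceiling = 10), 1.0)
  expect_equal(trim_weights(11, unadjusted = c(2, 2)), 10)   # 5 * 2
  w <- c(1.2, 3, 9.9)
  expect_equal(trim_weights(w, unadjusted = c(2, 2)), w)     # inside band
  expect_error(trim_weights(1), "unadjusted")
})

test_that("rake-trim iteration converges and reports diagnostics", {
  set.seed(41)
  n <- 400L
  dt <- data.table::data.table(
    g = sample(c("a", "b"), n, TRUE), h = sample(c("x", "y"), n, TRUE),
    weight = 1 + rexp(n, 2))
  # inflate ~2% of weights beyond the eventual ceiling
  dt$weight[sample(n, 8)] <- 6 * mean(dt$weight) * 5 / 5
  tg <- sum(dt$weight) * c(a = 0.45, b = 0.55)
  th <- sum(dt$weight) * c(x = 0.5, y = 0.5)
  margins <- list(margin_spec("g", tg), margin_spec("h", th))
  res <- rake_trim_iterate(dt, margins)
  expect_true(res$diagnostics$converged)
  expect_true(all(res$linked$weight >= 1 - 1e-12))
  expect_true(all(res$linked$weight <= res$diagnostics$ceiling + 1e-12))
  expect_true(all(res$diagnostics$max_rel_err <= 1e-6))

  # idempotence: re-running changes no weight beyond tolerance
  res2 <- rake_trim_iterate(res$linked, margins,
                            ceiling = res$diagnostics$ceiling)
  expect_equal(res2$linked$weight, res$linked$weight, tolerance = 1e-5)

  # infeasible: a singleton level whose target needs w > ceiling
  dt_bad <- data.table::data.table(g = c("a", rep("b", 99)), weight = 1)
  m_bad <- list(margin_spec("g", c(a = 1000, b = 99)))
  res_bad <- rake_trim_iterate(dt_bad, m_bad, ceiling = 5)
  expect_false(res_bad$diagnostics$converged)
  expect_equal(res_bad$diagnostics$rounds, 10L)
})

test_that("margins_from_totals reproduces the marginal sums", {
  tot <- data.table::data.table(
    dyear = c(1990L, 1990L, 1991L), race = c("White", "Black", "White"),
    n_deaths = c(10L, 5L, 7L))
  mg <- margins_from_totals(tot, c("dyear", "race"))
  expect_equal(mg[[1]]$targets, c(`1990` = 15, `1991` = 7))
  expect_equal(mg[[2]]$targets, c(White = 17, Black = 5))
})
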