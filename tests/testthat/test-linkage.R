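tiny_census <- function(...) {
  data.table::data.table(...)
}

test_that("standardize_name is idempotent and honors nickname classes", {
  nn <- make_nickname_table(100L)
  keys <- c(nn$variant[1:5], nn$canonical[6:10], "zz001", "  F00001N ")
  once <- standardize_name(keys, nn)
  expect_identical(standardize_name(once, nn), once)
  # variant and canonical collapse to one class
  expect_identical(standardize_name(nn$variant[1], nn),
                   standardize_name(nn$canonical[1], nn))
  # distinct classes stay distinct
  expect_false(standardize_name(nn$canonical[1], nn) ==
                 standardize_name(nn$canonical[2], nn))
})

test_that("unique pair matches at band 0; ambiguity excludes conservatively", {
  cen <- tiny_census(histid = "A", first_key = "f1", last_key = "l1",
                     census_age = 30L)
  reg <- tiny_census(row_id = "R1", first_key = "f1", last_key = "l1",
                     byear = 1910L, bmonth = 1L)  # implied age 30
  res <- abe_conservative_match(cen, reg)
  expect_equal(nrow(res$pairs), 1L)
  expect_equal(res$pairs$band, 0L)

  # two register candidates 1 year apart: census record excluded entirely
  reg2 <- tiny_census(row_id = c("R1", "R2"), first_key = "f1",
                      last_key = "l1", byear = c(1910L, 1911L),
                      bmonth = 1L)
  res2 <- abe_conservative_match(cen, reg2)
  expect_equal(nrow(res2$pairs), 0L)
  expect_equal(res2$unmatched_census$reason, "ambiguous-register")

  # strict conservative rule: a nearer candidate does not rescue the record
  res3 <- abe_conservative_match(cen, reg2, max_band = 2L)
  expect_equal(nrow(res3$pairs), 0L)
  # but tightening the band below the second candidate's distance does
  res4 <- abe_conservative_match(cen, reg2, max_band = 0L)
  expect_equal(nrow(res4$pairs), 1L)
})

test_that("age flexibility uses the implied register age and band labels", {
  cen <- tiny_census(histid = c("A", "B"),
                     first_key = c("f1", "f2"), last_key = "l1",
                     census_age = c(30L, 40L))
  # R1 implies census age 29 (born June 1910): band 1 for A
  reg <- tiny_census(row_id = c("R1", "R2"),
                     first_key = c("f1", "f2"), last_key = "l1",
                     byear = c(1910L, 1898L), bmonth = c(6L, 1L))
  res <- abe_conservative_match(cen, reg)
  expect_equal(nrow(res$pairs), 2L)
  expect_equal(sort(res$pairs$band), c(1L, 2L))
  # at max_band 0 neither pair survives
  res0 <- abe_conservative_match(cen, reg, max_band = 0L)
  expect_equal(nrow(res0$pairs), 0L)
})

test_that("noise-free unique keys give precision = recall = 1", {
  pop <- make_unique_key_world(150L)
  cen <- build_census_file(pop)
  men <- cen[sex == "male"]
  out <- build_death_register(pop, register_spec("dmf-like"),
                              noise_none(), seed = 5L)
  res <- abe_conservative_match(men, out$register)
  ev <- evaluate_linkage(res, out$truth, men, out$register)
  expect_equal(unname(ev$summary["precision"]), 1.0)
  expect_equal(unname(ev$summary["recall"]), 1.0)
})

test_that("band monotonicity: match count never falls as max_band loosens", {
  pop <- make_unique_key_world(120L, seed = 13L)
  cen <- build_census_file(pop)[sex == "male"]
  out <- build_death_register(pop, register_spec("dmf-like"),
                              noise_none(), seed = 6L)
  counts <- vapply(0:2, function(b) {
    nrow(abe_conservative_match(cen, out$register, max_band = b)$pairs)
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("one-to-one: no census or register row appears twice", {
  pop <- make_small_world(300L, seed = 17L)   # realistic noisy keys
  cen <- build_census_file(pop)[sex == "male"]
  nn <- make_nickname_table(2000L)
  out <- build_death_register(pop, register_spec("dmf-like"),
                              noise_spec(), nn, seed = 7L)
  res <- abe_conservative_match(cen, out$register, nicknames = nn)
  expect_false(anyDuplicated(res$pairs$histid) > 0)
  expect_false(anyDuplicated(res$pairs$row_id) > 0)
})

test_that("women: surname rules, post-census marriages, DMF unsupported", {
  # never-married woman matched through the father's-surname proxy
  cen <- tiny_census(histid = "W1", sex = "female",
                     marital_status = "never", first_key = "f1",
                     last_key = "fam1", census_age = 30L, bstate = "CA")
  reg <- tiny_census(row_id = "R1", sex = "female", first_key = "f1",
                     last_key = "mar9", father_last_key = "fam1",
                     byear = 1910L, bmonth = 1L, bstate = "CA")
  res <- match_women(cen, reg)
  expect_equal(res$pairs$histid, "W1")

  # ever-married woman whose register surname changed again: unmatched
  cen2 <- tiny_census(histid = "W2", sex = "female",
                      marital_status = "married", first_key = "f2",
                      last_key = "mar1", census_age = 35L, bstate = "NY")
  reg2 <- tiny_census(row_id = "R2", sex = "female", first_key = "f2",
                      last_key = "mar2", father_last_key = "fam2",
                      byear = 1905L, bmonth = 1L, bstate = "NY")
  res2 <- match_women(cen2, reg2)
  expect_equal(nrow(res2$pairs), 0L)

  dmf <- tiny_census(row_id = "R3", first_key = "f1", last_key = "l1",
                     byear = 1910L, bmonth = 1L)
  expect_error(match_women(cen, dmf), "unsupported")
})

test_that("post-1940 marriages depress female recall, not precision", {
  spec <- population_spec(cohort_sizes = 250L, seed = 23L,
                          p_marry_after_census = 0.30,
                          n_first = 50000L, n_last = 100000L)
  pop <- generate_population(spec)
  # force unique keys so the only failure channel is the surname change
  n <- nrow(pop)
  pop[, first_key := sprintf("u%06d", seq_len(n))]
  pop <- simulate_mortality(pop, std_params(), NULL, seed = 23L)
  cen <- build_census_file(pop)
  out <- build_death_register(pop, register_spec("numident-like"),
                              noise_none(), seed = 23L)
  reg <- out$register

  res_m <- abe_conservative_match(cen[sex == "male"],
                                  reg[sex == "male"],
                                  use_birth_state = TRUE)
  res_w <- match_women(cen, reg, use_birth_state = TRUE)
  ev_m <- evaluate_linkage(res_m, out$truth, cen[sex == "male"], reg)
  ev_w <- evaluate_linkage(res_w, out$truth, cen[sex == "female"], reg)
  expect_equal(unname(ev_m$summary["precision"]), 1.0)
  expect_equal(unname(ev_w$summary["precision"]), 1.0)
  expect_lt(ev_w$summary["recall"], ev_m$summary["recall"])
})

test_that("middle-initial diagnostic: clean matches agree fully; injected
           false matches bound the false-match rate", {
  pop <- make_unique_key_world(400L, seed = 29L)
  cen <- build_census_file(pop)[sex == "male"]
  out <- build_death_register(pop, register_spec("dmf-like"),
                              noise_none(), seed = 8L)
  res <- abe_conservative_match(cen, out$register)
  ev <- evaluate_linkage(res, out$truth, cen, out$register)
  expect_equal(ev$middle_initial$agreement, 1.0)

  # inject 10% false matches with uniform random initials
  set.seed(30)
  pairs <- res$pairs
  nfm <- round(0.10 * nrow(pairs))
  flip <- sample(nrow(pairs), nfm)
  pairs$histid[flip] <- sample(setdiff(cen$histid, pairs$histid), nfm)
  reg_noisy <- data.table::copy(out$register)
  reg_noisy[, middle_initial := sample(LETTERS, .N, TRUE)]
  cen_noisy <- data.table::copy(cen)
  cen_noisy[, middle_initial := sample(LETTERS, .N, TRUE)]
  res_f <- res; res_f$pairs <- pairs
  ev_f <- evaluate_linkage(res_f, out$truth, cen_noisy, reg_noisy)
  fm_rate <- nfm / nrow(pairs)
  disagreement <- 1 - ev_f$middle_initial$agreement
  mc_sd <- sqrt(fm_rate * (1 - fm_rate) / ev_f$middle_initial$n_both)
  expect_gte(disagreement, fm_rate - 3 * mc_sd)
})

test_that("representativeness: equal match probability leaves strata balanced", {
  pop <- make_small_world(500L, seed = 31L)
  cen <- build_census_file(pop)
  set.seed(32)
  matched <- sample(cen$histid, round(0.4 * nrow(cen)))
  tab <- evaluate_linkage(
    structure(list(pairs = data.table::data.table(histid = matched,
                                                  row_id = matched,
                                                  band = 0L),
                   unmatched_census = data.table::data.table(),
                   unmatched_register = data.table::data.table(),
                   counts = c(n_census = nrow(cen),
                              n_register = length(matched),
                              n_matched = length(matched))),
              class = "match_result"),
    truth = data.table::data.table(row_id = matched, histid = matched),
    census = cen,
    register = data.table::data.table(row_id = matched,
                                      middle_initial = NA_character_)
  )$representativeness
  n_m <- length(matched)
  # each stratum share among matched within 3 multinomial SD of census share
  ok <- abs(tab$pct_unweighted - tab$pct_census) / 100 <=
    3 * sqrt(pmax(tab$pct_census / 100 * (1 - tab$pct_census / 100), 1e-9)
             / n_m)
  expect_true(all(ok))
})
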