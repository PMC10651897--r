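#' Standardize a name key
#'
#' Deterministic, idempotent canonicalization: trim, lower-case, then map
#' through an explicit nickname-equivalence table (variant -> canonical).
#' Keys absent from the table are returned unchanged.
#'
#' @param raw character vector of raw keys.
#' @param nicknames optional data.table/data.frame with columns `variant`,
#'   `canonical`.
#' @return character vector of canonical keys.
#' @examples
#' nn <- data.frame(variant = "f00001n", canonical = "f00001")
#' standardize_name(c("F00001N", "f00002"), nn)
#' @export
standardize_name <- function(raw, nicknames = NULL) {
  out <- tolower(trimws(raw))
  if (!is.null(nicknames)) {
    idx <- match(out, tolower(nicknames$variant))
    hit <- !is.na(idx)
    out[hit] <- tolower(nicknames$canonical[idx[hit]])
  }
  out
}

# register's implied completed age on census day, from its birth date
implied_census_age <- function(byear, bmonth, census_day = c(1940L, 4L)) {
  census_day[1] - byear - as.integer(bmonth >= census_day[2])
}

#' Conservative deterministic record linkage (ABE-style)
#'
#' Links census to register records requiring exact agreement on the
#' standardized first and last name keys (plus birth state when
#' `use_birth_state`), with the implied 1940 ages differing by at most
#' `max_band` years. The conservative rule: any record -- on either side --
#' with two or more same-key candidates within `max_band` years is excluded
#' entirely, even when one candidate is closer in age; a pair is accepted
#' only when each member is the other's unique candidate. Accepted pairs
#' are labeled with the age band actually used (0, 1 or 2).
#'
#' @param census data.table with `histid`, `first_key`, `last_key`,
#'   `census_age` and (if used) `bstate`.
#' @param register data.table with `row_id`, `first_key`, `last_key`,
#'   `byear`, `bmonth` and (if used) `bstate`.
#' @param use_birth_state include birth state in the exact key (only
#'   possible for Numident-like registers).
#' @param max_band maximum age discrepancy in years (default 2).
#' @param nicknames nickname table passed to [standardize_name()].
#' @param census_day `c(year, month)` for implied-age arithmetic.
#' @return object of class `match_result`: list with `pairs`
#'   (`histid`, `row_id`, `band`), `unmatched_census` and
#'   `unmatched_register` (ids with reason codes `no-candidate`,
#'   `ambiguous-register`, `ambiguous-census`), and summary `counts`.
#' @export
abe_conservative_match <- function(census, register,
                                   use_birth_state = FALSE, max_band = 2L,
                                   nicknames = NULL,
                                   census_day = c(1940L, 4L)) {
  census <- as.data.table(census)
  register <- as.data.table(register)
  need_c <- c("histid", "first_key", "last_key", "census_age")
  need_r <- c("row_id", "first_key", "last_key", "byear", "bmonth")
  if (use_birth_state) {
    need_c <- c(need_c, "bstate"); need_r <- c(need_r, "bstate")
  }
  for (nm in need_c) if (!nm %in% names(census)) {
    stop(sprintf("census table lacks key column '%s'", nm), call. = FALSE)
  }
  for (nm in need_r) if (!nm %in% names(register)) {
    stop(sprintf("register table lacks key column '%s'", nm), call. = FALSE)
  }

  cc <- census[, .(histid,
                   key = make_match_key(census, use_birth_state, nicknames),
                   age = census_age)]
  rr <- register[, .(row_id,
                     key = make_match_key(register, use_birth_state,
                                          nicknames),
                     age = implied_census_age(byear, bmonth, census_day))]

  cand <- merge(cc, rr, by = "key", allow.cartesian = TRUE,
                suffixes = c("_c", "_r"))
  cand <- cand[abs(age_c - age_r) <= max_band]
  cand[, band := abs(age_c - age_r)]
  cand[, cand_c := .N, by = histid]   # register candidates per census rec
  cand[, cand_r := .N, by = row_id]   # census candidates per register rec

  pairs <- cand[cand_c == 1L & cand_r == 1L, .(histid, row_id, band)]

  amb_c <- unique(cand[cand_c > 1L, histid])
  amb_r <- unique(cand[cand_r > 1L, row_id])
  # census records whose unique candidate was itself ambiguous
  amb_via_r <- setdiff(unique(cand[cand_c == 1L & cand_r > 1L, histid]),
                       pairs$histid)
  amb_via_c <- setdiff(unique(cand[cand_r == 1L & cand_c > 1L, row_id]),
                       pairs$row_id)

  un_c <- data.table(histid = setdiff(census$histid, pairs$histid))
  un_c[, reason := "no-candidate"]
  un_c[histid %in% amb_via_r, reason := "ambiguous-census"]
  un_c[histid %in% amb_c, reason := "ambiguous-register"]
  un_r <- data.table(row_id = setdiff(register$row_id, pairs$row_id))
  un_r[, reason := "no-candidate"]
  un_r[row_id %in% amb_via_c, reason := "ambiguous-register"]
  un_r[row_id %in% amb_r, reason := "ambiguous-census"]

  structure(list(
    pairs = pairs,
    unmatched_census = un_c,
    unmatched_register = un_r,
    counts = c(n_census = nrow(census), n_register = nrow(register),
               n_matched = nrow(pairs))
  ), class = "match_result")
}

make_match_key <- function(dt, use_birth_state, nicknames) {
  k <- paste(standardize_name(dt$first_key, nicknames),
             standardize_name(dt$last_key, nicknames), sep = "|")
  if (use_birth_state) k <- paste(k, dt$bstate, sep = "|")
  k
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("match_result: %d census x %d register -> %d pairs\n",
              x$counts["n_census"], x$counts["n_register"],
              x$counts["n_matched"]))
  invisible(x)
}

#' Link women via maiden-name handling (Numident-like registers only)
#'
#' Women changing surnames at marriage break own-surname linkage. For
#' ever-married women (census marital status), the census surname is a
#' married name present on both sides, so the ordinary match applies. For
#' never-married women, the census surname is the father's, matched against
#' the register's father's-surname field. Women marrying (again) after
#' census day carry an unmatched surname and are an accepted loss.
#' DMF-like registers lack the father's-surname field, so linking women to
#' them is unsupported.
#'
#' @param census census table (women are selected internally by `sex`).
#' @param register a Numident-like register containing `father_last_key`
#'   and `sex`.
#' @param use_birth_state,max_band,nicknames,census_day as in
#'   [abe_conservative_match()].
#' @param widowed_use_father treat widowed/divorced women as never-married
#'   (father's-surname rule) instead of ever-married; default FALSE.
#' @return `match_result` for the census women.
#' @export
match_women <- function(census, register, use_birth_state = TRUE,
                        max_band = 2L, nicknames = NULL,
                        census_day = c(1940L, 4L),
                        widowed_use_father = FALSE) {
  census <- as.data.table(census)
  register <- as.data.table(register)
  if (!"father_last_key" %in% names(register)) {
    stop("register is not Numident-like (no father's surname field); ",
         "linking women to a DMF-like register is unsupported",
         call. = FALSE)
  }
  women <- census[sex == "female"]
  reg_w <- if ("sex" %in% names(register)) register[sex == "female"]
           else register
  never_set <- if (widowed_use_father) c("never", "widowed", "divorced")
               else "never"
  never <- women[marital_status %in% never_set]
  ever <- women[!marital_status %in% never_set]

  res_ever <- abe_conservative_match(ever, reg_w, use_birth_state,
                                     max_band, nicknames, census_day)
  reg_left <- reg_w[!row_id %in% res_ever$pairs$row_id]
  # father's surname stands in for the register surname
  reg_father <- copy(reg_left)[, last_key := father_last_key]
  res_never <- abe_conservative_match(never, reg_father, use_birth_state,
                                      max_band, nicknames, census_day)

  pairs <- rbindlist(list(res_ever$pairs, res_never$pairs))
  un_c <- rbindlist(list(res_ever$unmatched_census,
                         res_never$unmatched_census))
  un_r <- res_never$unmatched_register
  structure(list(
    pairs = pairs, unmatched_census = un_c, unmatched_register = un_r,
    counts = c(n_census = nrow(women), n_register = nrow(reg_w),
               n_matched = nrow(pairs))
  ), class = "match_result")
}

#' Evaluate a linkage against simulation truth
#'
#' Computes the match rate, precision and recall (restricted to the
#' census-and-register universe), a representativeness table comparing
#' matched shares with full-census shares by education, race, marital
#' status and region of birth, and the middle-initial diagnostic: among
#' pairs with a middle initial on both sides, the agreement share. Since
#' initials are never a match field, the disagreement rate upper-bounds the
#' false-match rate.
#'
#' @param result a `match_result`.
#' @param truth truth map `row_id` -> `histid` from the generator.
#' @param census the census table.
#' @param register the register table (for middle initials).
#' @param weights optional named vector of person weights (names = histid)
#'   for the weighted representativeness column.
#' @return list with `summary` (match_rate, precision, recall),
#'   `representativeness` (data.table), `middle_initial` (list with
#'   `n_both`, `agreement`).
#' @export
evaluate_linkage <- function(result, truth, census, register,
                             weights = NULL) {
  stopifnot(inherits(result, "match_result"))
  truth <- as.data.table(truth)
  census <- as.data.table(census)
  register <- as.data.table(register)
  if (anyDuplicated(truth$row_id)) {
    stop("truth map is not injective over register rows", call. = FALSE)
  }
  if (!all(result$pairs$row_id %in% truth$row_id)) {
    stop("truth map inconsistent: matched register rows missing from it",
         call. = FALSE)
  }
  pairs <- merge(result$pairs, truth, by = "row_id",
                 suffixes = c("", "_true"))
  n_match <- nrow(pairs)
  tp <- sum(pairs$histid == pairs$histid_true)
  # linkable universe: true pairs whose census member is in the census file
  universe <- truth[histid %in% census$histid]
  summary <- c(
    match_rate = n_match / nrow(census),
    precision = if (n_match) tp / n_match else NA_real_,
    recall = if (nrow(universe)) tp / nrow(universe) else NA_real_
  )

  rep_tab <- representativeness_table(census, pairs$histid, weights)

  mi <- merge(pairs[, .(row_id, histid)],
              census[, .(histid, mi_c = middle_initial)], by = "histid")
  mi <- merge(mi, register[, .(row_id, mi_r = middle_initial)],
              by = "row_id")
  both <- !is.na(mi$mi_c) & !is.na(mi$mi_r)
  middle_initial <- list(
    n_both = sum(both),
    agreement = if (any(both)) mean(mi$mi_c[both] == mi$mi_r[both])
                else NA_real_
  )
  list(summary = summary, representativeness = rep_tab,
       middle_initial = middle_initial)
}

# stratum shares among matched vs full census, by standard dimensions
representativeness_table <- function(census, matched_ids, weights = NULL) {
  cen <- copy(as.data.table(census))
  cen[, edu_cat := cut(education_years, c(-Inf, 11, 15, 16, Inf),
                       labels = c("<High School", "HS or some college",
                                  "Bachelor's", "Advanced"))]
  reg_map <- state_regions()
  cen[, region := reg_map$region[match(bstate, reg_map$bstate)]]
  cen[is.na(region), region := "Abroad"]
  matched <- cen[histid %in% matched_ids]
  w <- if (is.null(weights)) rep(1, nrow(matched))
       else unname(weights[matched$histid])
  out <- list()
  for (dm in c("edu_cat", "race", "marital_status", "region")) {
    lev <- sort(unique(cen[[dm]]))
    cm <- matched[[dm]]
    tab <- data.table(
      dimension = dm, stratum = as.character(lev),
      count_matched = as.integer(table(factor(cm, levels = lev))),
      pct_unweighted = 100 * as.numeric(table(factor(cm, levels = lev))) /
        max(1L, nrow(matched)),
      pct_weighted = 100 * vapply(lev, function(l) {
        sum(w[cm == l]) / max(sum(w), .Machine$double.eps)
      }, numeric(1)),
      pct_census = 100 * as.numeric(
        table(factor(cen[[dm]], levels = lev))) / nrow(cen)
    )
    out[[dm]] <- tab
  }
  tab <- rbindlist(out)
  tab[, difference := pct_weighted - pct_census]
  tab[]
}
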