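# Sequential nested-trial construction: per-fiscal-year eligibility
# screening, arm assignment, covariate extraction, outcome ascertainment and
# expansion into discrete person-periods.

#' Screen one fiscal year for trial eligibility
#'
#' Returns the persons who, at the fiscal-year start (April 1), satisfy all
#' eligibility criteria, with their assigned arm: `SHC` if a checkup record
#' exists in that fiscal year, `non-SHC` otherwise. The prior-checkup and
#' prevalent-disease screens search the entire observable pre-entry history;
#' the lookback window governs only enrollment continuity, the visit-count
#' criterion and the resource-use exclusion.
#'
#' @param db a `claims_db`.
#' @param fy fiscal year to screen.
#' @param criteria an [eligibility_criteria()] object.
#' @return a `data.table` with columns `person_id`, `arm` and `age_at_entry`,
#'   plus an `attrition` attribute counting persons dropped by each rule.
#' @export
screen_fiscal_year <- function(db, fy, criteria = eligibility_criteria()) {
  stopifnot(inherits(db, "claims_db"), inherits(criteria, "eligibility_criteria"))
  fs <- fy_start_date(fy)
  p <- db$persons
  if (!nrow(p)) {
    out <- data.table(person_id = integer(), arm = character(),
                      age_at_entry = integer())
    setattr(out, "attrition", integer())
    return(out)
  }
  age <- age_in_years(p$birth_date, fs)
  ok_age <- age >= criteria$age_min & age <= criteria$age_max
  ok_enroll <- p$enroll_start <= (fs - criteria$lookback_days) &
    p$enroll_end >= fs

  lb_lo <- fs - criteria$lookback_days
  use <- db$claims[kind %chin% c("outpatient_visit", "hospitalization") &
                     date >= lb_lo & date < fs, .N, by = person_id]
  n_use <- integer(nrow(p))
  n_use[match(use$person_id, p$person_id)] <- use$N
  ok_visits <- n_use >= criteria$min_visits_in_lookback

  ok_checkup <- rep(TRUE, nrow(p))
  if (criteria$require_no_prior_checkup && nrow(db$checkups)) {
    prior <- unique(db$checkups[date < fs, person_id])
    ok_checkup[p$person_id %in% prior] <- FALSE
  }

  ok_excl <- rep(TRUE, nrow(p))
  for (ex in criteria$exclusion_code_sets) {
    dx_ids <- unique(db$claims[kind == "diagnosis" & date < fs &
                                 code_matches(code, ex$diagnosis), person_id])
    rx_ids <- unique(db$claims[kind == "dispensing" & date < fs &
                                 code_matches(code, ex$drugs), person_id])
    ok_excl[p$person_id %in% intersect(dx_ids, rx_ids)] <- FALSE
  }

  cand <- ok_age & ok_enroll & ok_visits & ok_checkup & ok_excl
  ok_resource <- rep(TRUE, nrow(p))
  if (any(cand) && criteria$resource_use_exclusion_percentile < 100) {
    # inverse-ECDF quantile: only persons strictly above the empirical
    # percentile value are dropped
    thr <- quantile(n_use[cand],
                    criteria$resource_use_exclusion_percentile / 100,
                    type = 1, names = FALSE)
    ok_resource <- n_use <= thr
  }
  keep <- cand & ok_resource

  out <- data.table(person_id = p$person_id[keep],
                    arm = "non-SHC",
                    age_at_entry = age[keep])
  fy_val <- as.integer(fy)  # plain vector: avoids data.table NSE capture
  shc_ids <- if (nrow(db$checkups))
    unique(db$checkups$person_id[db$checkups$fy == fy_val]) else integer(0)
  out[person_id %in% shc_ids, arm := "SHC"]
  setattr(out, "attrition", c(
    age = sum(!ok_age), enrollment = sum(ok_age & !ok_enroll),
    visits = sum(ok_age & ok_enroll & !ok_visits),
    prior_checkup = sum(ok_age & ok_enroll & ok_visits & !ok_checkup),
    prevalent_disease = sum(ok_age & ok_enroll & ok_visits & ok_checkup &
                              !ok_excl),
    resource_use = sum(cand & !ok_resource)))
  out[]
}

#' Build the sequential nested cohort
#'
#' Screens every fiscal year in `fy_range` with [screen_fiscal_year()] and
#' stacks the results as trial entries. Under the default criteria a person
#' contributes a non-SHC entry in every year they qualify and a single SHC
#' entry in the year of their first checkup (later years fail the
#' no-prior-checkup screen). Entry date is the fiscal-year start.
#'
#' @param db a `claims_db`.
#' @param fy_range integer vector of fiscal years to screen.
#' @param criteria an [eligibility_criteria()] object.
#' @return a `data.table` of trial entries (`entry_id`, `person_id`,
#'   `trial_fy`, `arm`, `entry_date`, `age_at_entry`), with attributes
#'   `n_unique_persons` and `mean_entries_per_person`.
#' @export
build_sequential_cohort <- function(db, fy_range,
                                    criteria = eligibility_criteria()) {
  if (!length(fy_range))
    stop("build_sequential_cohort: `fy_range` is empty", call. = FALSE)
  parts <- lapply(sort(unique(as.integer(fy_range))), function(y) {
    s <- screen_fiscal_year(db, y, criteria)
    s[, trial_fy := y]
    s[, entry_date := rep(fy_start_date(y), .N)]
    s
  })
  entries <- rbindlist(parts, use.names = TRUE)
  if (!nrow(entries)) {
    entries <- data.table(entry_id = integer(), person_id = integer(),
                          trial_fy = integer(), arm = character(),
                          entry_date = as.Date(character()),
                          age_at_entry = integer())
    setattr(entries, "n_unique_persons", 0L)
    setattr(entries, "mean_entries_per_person", NA_real_)
    return(entries)
  }
  setorder(entries, trial_fy, person_id)
  entries[, entry_id := .I]
  setcolorder(entries, c("entry_id", "person_id", "trial_fy", "arm",
                         "entry_date", "age_at_entry"))
  setattr(entries, "n_unique_persons", uniqueN(entries$person_id))
  setattr(entries, "mean_entries_per_person",
          nrow(entries) / uniqueN(entries$person_id))
  entries[]
}

#' Baseline covariates for trial entries
#'
#' One row per entry: age at entry, sex, employment, fiscal year of entry,
#' hospitalization count in the preceding 12 months (categories 0 / 1 / 2+),
#' health-care visit count in the preceding 12 months (categories 1-2 / 3-5 /
#' 6-11 / 12+), and a binary indicator (`hx_<code>`) for every 3-digit ICD-10
#' diagnosis family recorded strictly before entry. Indicator columns are
#' dropped when their cohort prevalence falls below `prevalence_floor` or
#' when they belong to the families excluded from the weight model: the
#' prevalent-disease code sets (E10/E14, I10-I15), pregnancy (O) and
#' perinatal (P) chapters. Absence of a code is treated as absence of the
#' condition.
#'
#' @param db a `claims_db`.
#' @param entries output of [build_sequential_cohort()].
#' @param prevalence_floor minimum cohort prevalence for an indicator column
#'   (default 0.0001, i.e. 0.01 percent).
#' @param lookback_days window for the visit / hospitalization counts.
#' @return a `data.table` keyed by `entry_id`, with attribute
#'   `dropped_codes`.
#' @export
baseline_covariates <- function(db, entries, prevalence_floor = 0.0001,
                                lookback_days = 365L) {
  stopifnot(all(entries$person_id %in% db$persons$person_id))
  cov <- entries[, .(entry_id, person_id, trial_fy, arm, entry_date,
                     age = age_at_entry)]
  cov <- db$persons[, .(person_id, female, employed)][cov, on = "person_id"]

  counts <- function(kinds) {
    cl <- db$claims[kind %chin% kinds, .(person_id, date)]
    j <- cl[cov[, .(entry_id, person_id, lo = entry_date - lookback_days,
                    hi = entry_date)],
            on = .(person_id, date >= lo, date < hi), .N, by = .EACHI]
    j$N
  }
  cov[, n_visits := counts("outpatient_visit")]
  cov[, n_hosp := counts("hospitalization")]
  cov[, hosp_cat := cut(n_hosp, c(-Inf, 0, 1, Inf), labels = c("0", "1", "2+"))]
  cov[, visit_cat := cut(pmax(n_visits, 1L), c(0, 2, 5, 11, Inf),
                         labels = c("1-2", "3-5", "6-11", "12+"))]

  dx <- db$claims[kind == "diagnosis" & nchar(code) >= 3L,
                  .(person_id, date, code3 = substr(code, 1L, 3L))]
  drop_fam <- function(x) x %in% c("E10", "E14", paste0("I1", 0:5)) |
    startsWith(x, "O") | startsWith(x, "P")
  dx <- dx[!drop_fam(code3)]
  first_dx <- if (nrow(dx))
    dx[, .(first_date = min(date)), by = .(person_id, code3)]
  else data.table(person_id = integer(), code3 = character(),
                  first_date = as.Date(character()))
  hits <- first_dx[cov[, .(entry_id, person_id, entry_date)],
                   on = .(person_id, first_date < entry_date),
                   .(entry_id = i.entry_id, code3 = x.code3), nomatch = NULL]
  dropped <- character(0)
  if (nrow(hits)) {
    prev <- hits[, .(n = uniqueN(entry_id)), by = code3]
    keep_codes <- prev[n / nrow(cov) >= prevalence_floor, code3]
    dropped <- setdiff(prev$code3, keep_codes)
    hits <- hits[code3 %chin% keep_codes]
  }
  if (nrow(hits)) {
    wide <- dcast(unique(hits), entry_id ~ code3, fun.aggregate = length,
                  value.var = "code3")
    setnames(wide, setdiff(names(wide), "entry_id"),
             paste0("hx_", setdiff(names(wide), "entry_id")))
    cov <- wide[cov, on = "entry_id"]
    for (cl in grep("^hx_", names(cov), value = TRUE))
      set(cov, which(is.na(cov[[cl]])), cl, 0L)
  }
  setcolorder(cov, c("entry_id", "person_id", "trial_fy", "arm", "entry_date",
                     "age", "female", "employed", "hosp_cat", "visit_cat"))
  setkey(cov, entry_id)
  setattr(cov, "dropped_codes", dropped)
  cov[]
}

# Vectorized outcome ascertainment: earliest qualifying date >= from_date per
# query row. Used by find_first_outcome() and expand_person_periods().
first_outcome_dates <- function(db, person_ids, from_dates, outdef) {
  stopifnot(inherits(outdef, "outcome_definition"))
  if (!is.null(outdef$components)) {
    comp <- lapply(outdef$components, function(d)
      first_outcome_dates(db, person_ids, from_dates, d))
    return(do.call(pmin, c(comp, list(na.rm = TRUE))))
  }
  dx <- db$claims[kind == "diagnosis" &
                    code_matches(code, outdef$diagnosis_codes),
                  .(person_id, date)]
  if (outdef$require_drug && nrow(dx)) {
    rx <- db$claims[kind == "dispensing" &
                      code_matches(code, outdef$drug_codes),
                    .(person_id, date, rx_date = date)]
    setkey(rx, person_id, date)
    m <- rx[dx, on = .(person_id, date), roll = "nearest"]
    dx <- m[!is.na(rx_date) &
              abs(as.numeric(rx_date - date)) <= outdef$conjunction_window_days,
            .(person_id, date)]
  }
  if (!nrow(dx))
    return(as.Date(rep(NA_integer_, length(person_ids)), origin = "1970-01-01"))
  setkey(dx, person_id, date)
  q <- data.table(person_id = person_ids, from = from_dates)
  dx[q, on = .(person_id, date >= from), mult = "first", x.date]
}

#' First qualifying outcome date for one person
#'
#' Earliest date on or after `from_date` at which a diagnosis code in the
#' outcome definition is recorded and — when the definition requires it — a
#' listed medication is dispensed within the conjunction window of that
#' diagnosis. For the composite outcome, the earliest over its components.
#'
#' @param db a `claims_db`.
#' @param person_id a single person identifier.
#' @param from_date earliest date considered.
#' @param outdef an [outcome_definition()].
#' @return a `Date`, or `NA` if no qualifying outcome exists.
#' @export
find_first_outcome <- function(db, person_id, from_date,
                               outdef = outcome_definition("composite")) {
  stopifnot(length(person_id) == 1L, length(from_date) == 1L)
  first_outcome_dates(db, person_id, as.Date(from_date), outdef)
}

#' Expand trial entries into discrete person-periods
#'
#' Each entry becomes consecutive intervals `[entry + (k-1)Δ, entry + kΔ)`
#' until the earliest of: the outcome (event = 1 in the interval containing
#' the event date), disenrollment or the administrative end (censored = 1),
#' or the follow-up horizon (censored = 1 in the last interval). Also carries
#' `still_in_non_shc_protocol` (flips to 0 in the interval of a non-SHC
#' entry's first checkup, for censoring-weight analyses) and
#' `cumulative_shc_sessions` (checkups since entry through the end of
#' interval k; fixed at 0 for the non-SHC arm, for the dose analysis).
#'
#' @param entries output of [build_sequential_cohort()].
#' @param db a `claims_db`.
#' @param outdef an [outcome_definition()].
#' @param interval `"year"` (default) or `"month"`.
#' @param horizon_years follow-up horizon (default 10).
#' @param admin_end_date administrative censoring date; defaults to the last
#'   enrollment end in `db`.
#' @return a `data.table` of person-periods: `entry_id`, `person_id`,
#'   `trial_fy`, `arm`, `treated` (0/1), `k`, `event`, `censored`,
#'   `still_in_non_shc_protocol`, `cumulative_shc_sessions`.
#' @export
expand_person_periods <- function(entries, db,
                                  outdef = outcome_definition("composite"),
                                  interval = c("year", "month"),
                                  horizon_years = 10L,
                                  admin_end_date = NULL) {
  interval <- match.arg(interval)
  delta <- if (interval == "year") 365.25 else 365.25 / 12
  k_max <- as.integer(round(horizon_years * 365.25 / delta))
  admin_end_date <- as.Date(admin_end_date %||% max(db$persons$enroll_end))
  if (any(entries$entry_date > admin_end_date))
    stop("expand_person_periods: entry after the administrative end",
         call. = FALSE)

  e <- entries[, .(entry_id, person_id, trial_fy, arm, entry_date)]
  e <- db$persons[, .(person_id, enroll_end)][e, on = "person_id"]
  ev_date <- first_outcome_dates(db, e$person_id, e$entry_date, outdef)
  t_ev <- as.numeric(ev_date - e$entry_date) / delta
  t_cens <- as.numeric(pmin(e$enroll_end, admin_end_date) -
                         e$entry_date + 1) / delta
  k_ev <- floor(t_ev) + 1
  k_cens <- pmin(ceiling(t_cens), k_max)
  has_event <- !is.na(k_ev) & k_ev <= k_cens
  n_per <- ifelse(has_event, k_ev, k_cens)

  pp <- e[rep(seq_len(.N), n_per),
          .(entry_id, person_id, trial_fy, arm)]
  pp[, k := sequence(n_per)]
  last <- cumsum(n_per)
  pp[, event := 0L]; pp[, censored := 0L]
  pp[last[has_event], event := 1L]
  pp[last[!has_event], censored := 1L]
  pp[, treated := as.integer(arm == "SHC")]

  # deviations from the non-SHC protocol and cumulative checkup dose
  pp[, still_in_non_shc_protocol := 1L]
  pp[, cumulative_shc_sessions := 0L]
  if (nrow(db$checkups)) {
    ck <- db$checkups[, .(person_id, date)]
    non <- e[arm == "non-SHC", .(entry_id, person_id, entry_date)]
    if (nrow(non)) {
      setkey(ck, person_id, date)
      fdev <- ck[non, on = .(person_id, date >= entry_date), mult = "first",
                 .(entry_id = i.entry_id, k_dev = floor(
                   as.numeric(x.date - i.entry_date) / delta) + 1)]
      fdev <- fdev[!is.na(k_dev)]
      if (nrow(fdev)) {
        pp[fdev, on = .(entry_id, k >= k_dev), still_in_non_shc_protocol := 0L]
      }
    }
    shc_pp <- pp[arm == "SHC", .(entry_id, person_id, k)]
    if (nrow(shc_pp)) {
      shc_pp[e, on = "entry_id", entry_date := i.entry_date]
      shc_pp[, hi := entry_date + k * delta]
      cnt <- ck[shc_pp, on = .(person_id, date >= entry_date, date < hi),
                .N, by = .EACHI]
      pp[arm == "SHC", cumulative_shc_sessions := cnt$N]
    }
  }
  pp[]
}
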