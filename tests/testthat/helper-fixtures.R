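library(data.table)

# Assemble a claims_db from partial tables, filling schema defaults.
make_db <- function(persons, claims = NULL, checkups = NULL) {
  persons <- copy(as.data.table(persons))
  for (cl in c("birth_date", "enroll_start", "enroll_end"))
    set(persons, j = cl, value = as.Date(persons[[cl]]))
  if (!"female" %in% names(persons)) set(persons, j = "female", value = 0L)
  if (!"employed" %in% names(persons)) set(persons, j = "employed", value = 0L)
  empty <- seqtte:::empty_claims_db()
  claims <- if (is.null(claims)) empty$claims else {
    claims <- copy(as.data.table(claims))
    set(claims, j = "date", value = as.Date(claims$date))
    if (!"code" %in% names(claims)) set(claims, j = "code", value = "")
    claims
  }
  checkups <- if (is.null(checkups)) empty$checkups else {
    checkups <- copy(as.data.table(checkups))
    set(checkups, j = "date", value = as.Date(checkups$date))
    for (cl in c("bmi", "waist_cm", "sbp_mmhg", "hba1c_pct"))
      if (!cl %in% names(checkups)) set(checkups, j = cl, value = NA_real_)
    if (!"smoker" %in% names(checkups))
      set(checkups, j = "smoker", value = NA_integer_)
    if (!"fy" %in% names(checkups))
      set(checkups, j = "fy", value = fiscal_year(checkups$date))
    checkups
  }
  structure(list(persons = persons, claims = claims, checkups = checkups),
            class = "claims_db")
}

# Six hand-traceable persons screened for fiscal year 2015:
#  1: age 45, enrolled with lookback and visits        -> eligible, non-SHC
#  2: age 39                                           -> fails age minimum
#  3: age 50, I10 diagnosis + C03 dispensing pre-entry -> prevalent exclusion
#  4: age 60, prior checkup (FY2014)                   -> prior-checkup rule
#  5: age 70, checkup inside FY2015                    -> eligible, SHC
#  6: age 50, enrolled only from 2015-01-01            -> lookback fails
screening_fixture <- function() {
  persons <- data.table(
    person_id = 1:6,
    birth_date = as.Date(c("1970-01-15", "1976-02-01", "1965-03-10",
                           "1955-05-20", "1944-12-01", "1965-07-07")),
    enroll_start = as.Date(c("2013-01-01", "2013-01-01", "2013-01-01",
                             "2013-01-01", "2013-06-01", "2015-01-01")),
    enroll_end = as.Date(rep("2019-12-31", 6)))
  claims <- data.table(
    person_id = c(1L, 1L, 2L, 3L, 3L, 3L, 4L, 5L, 6L),
    date = as.Date(c("2014-06-01", "2014-10-01", "2014-06-15", "2014-07-01",
                     "2014-08-01", "2014-09-01", "2014-11-02", "2014-09-09",
                     "2015-02-01")),
    kind = c("outpatient_visit", "outpatient_visit", "outpatient_visit",
             "outpatient_visit", "diagnosis", "dispensing",
             "outpatient_visit", "outpatient_visit", "outpatient_visit"),
    code = c("", "", "", "", "I10", "C03", "", "", ""))
  checkups <- data.table(
    person_id = c(4L, 5L),
    date = as.Date(c("2014-07-10", "2015-06-20")),
    fy = c(2014L, 2015L))
  make_db(persons, claims, checkups)
}

# Small default-structure simulation shared across tests (cached).
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_persons = 4000, seed = 420)
      cache <<- list(cfg = cfg, db = generate_population(cfg))
    }
    cache
  }
})
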