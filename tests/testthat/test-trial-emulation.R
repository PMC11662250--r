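test_that("fiscal-year helpers implement the April-March convention", {
  expect_equal(fy_start_date(2015), as.Date("2015-04-01"))
  expect_equal(fy_end_date(2015), as.Date("2016-03-31"))
  expect_equal(fiscal_year(as.Date(c("2015-04-01", "2016-03-31",
                                     "2016-04-01"))),
               c(2015, 2015, 2016))
})

test_that("screening reproduces the hand-traced eligible set and arms", {
  db <- screening_fixture()
  s <- screen_fiscal_year(db, 2015)
  expect_equal(sort(s$person_id), c(1L, 5L))
  expect_equal(s[person_id == 1, arm], "non-SHC")
  expect_equal(s[person_id == 5, arm], "SHC")
  expect_equal(s[person_id == 1, age_at_entry], 45L)
  expect_equal(s[person_id == 5, age_at_entry], 70L)
  att <- attr(s, "attrition")
  expect_equal(unname(att[c("age", "prevalent_disease", "prior_checkup")]),
               c(1, 1, 1))
  expect_equal(nrow(db$persons) - sum(att), nrow(s))
})

test_that("exclusion needs the code AND drug conjunction; age band is inclusive", {
  db <- screening_fixture()
  # strip person 3's dispensing: the diagnosis alone must not exclude
  db$claims <- db$claims[!(person_id == 3 & kind == "dispensing")]
  s <- screen_fiscal_year(db, 2015)
  expect_true(3L %in% s$person_id)
  # relax the age minimum: the 39-year-old enters
  s2 <- screen_fiscal_year(db, 2015, eligibility_criteria(age_min = 39))
  expect_true(2L %in% s2$person_id)
})

test_that("sequential cohort gives yearly non-SHC entries and one SHC entry", {
  persons <- data.table(
    person_id = 1:2,
    birth_date = as.Date(c("1965-01-01", "1960-01-01")),
    enroll_start = as.Date("2011-06-01"),
    enroll_end = as.Date("2019-12-31"))
  visits <- CJ(person_id = 1:2, yr = 2012:2018)
  visits <- visits[, .(person_id, date = as.Date(paste0(yr, "-10-15")),
                       kind = "outpatient_visit", code = "")]
  checkups <- data.table(person_id = 1:2,
                         date = as.Date(c("2016-05-05", "2013-07-01")),
                         fy = c(2016L, 2013L))
  db <- make_db(persons, visits, checkups)
  entries <- build_sequential_cohort(db, 2013:2017)
  e1 <- entries[person_id == 1]
  expect_equal(e1[arm == "non-SHC", sort(trial_fy)], 2013:2015)
  expect_equal(e1[arm == "SHC", trial_fy], 2016L)
  # person 2's first observable eligible year is their checkup year
  e2 <- entries[person_id == 2]
  expect_equal(nrow(e2), 1L)
  expect_equal(e2$arm, "SHC")
  expect_equal(e2$trial_fy, 2013L)
  expect_equal(attr(entries, "n_unique_persons"), 2L)
})

test_that("tightening criteria never adds entries", {
  db <- shared_sim()$db
  base <- build_sequential_cohort(db, 2012:2014)
  tight <- build_sequential_cohort(db, 2012:2014,
                                   eligibility_criteria(age_max = 69,
                                                        min_visits_in_lookback = 2))
  expect_lte(nrow(tight), nrow(base))
  expect_true(all(tight[, paste(person_id, trial_fy)] %in%
                    base[, paste(person_id, trial_fy)]))
})

test_that("baseline covariates encode the printed count categories", {
  persons <- data.table(person_id = 1L, birth_date = as.Date("1970-01-01"),
                        enroll_start = as.Date("2013-01-01"),
                        enroll_end = as.Date("2019-12-31"))
  visits <- data.table(person_id = 1L,
                       date = as.Date("2014-04-01") - c(30, 60, 90, 120),
                       kind = "outpatient_visit", code = "")
  db <- make_db(persons, visits)
  entries <- build_sequential_cohort(db, 2014)
  cov <- baseline_covariates(db, entries)
  expect_equal(as.character(cov$hosp_cat), "0")
  expect_equal(as.character(cov$visit_cat), "3-5")
})

test_that("history indicators obey the prevalence floor and family exclusions", {
  n <- 40L
  persons <- data.table(person_id = seq_len(n),
                        birth_date = as.Date("1970-01-01"),
                        enroll_start = as.Date("2013-01-01"),
                        enroll_end = as.Date("2019-12-31"))
  claims <- rbind(
    data.table(person_id = seq_len(n), date = as.Date("2013-12-01"),
               kind = "outpatient_visit", code = ""),
    data.table(person_id = 1:20, date = as.Date("2013-06-01"),
               kind = "diagnosis", code = "J30"),
    data.table(person_id = 1L, date = as.Date("2013-06-01"),
               kind = "diagnosis", code = "K29"),   # 1/40 < floor 0.1
    data.table(person_id = 1:20, date = as.Date("2013-06-01"),
               kind = "diagnosis", code = "O80"),   # pregnancy chapter
    data.table(person_id = 1:20, date = as.Date("2013-06-01"),
               kind = "diagnosis", code = "I10"))   # exclusion family
  db <- make_db(persons, claims)
  entries <- build_sequential_cohort(db, 2014)
  cov <- baseline_covariates(db, entries, prevalence_floor = 0.1)
  expect_true("hx_J30" %in% names(cov))
  expect_false(any(c("hx_K29", "hx_O80", "hx_I10") %in% names(cov)))
  expect_true("K29" %in% attr(cov, "dropped_codes"))
  expect_equal(cov[person_id == 1, hx_J30], 1L)
  expect_equal(cov[person_id == 30, hx_J30], 0L)
})

test_that("outcome ascertainment applies the code-drug conjunction window", {
  persons <- data.table(person_id = 1:3, birth_date = as.Date("1970-01-01"),
                        enroll_start = as.Date("2010-01-01"),
                        enroll_end = as.Date("2019-12-31"))
  claims <- data.table(
    person_id = c(1L, 1L, 2L, 3L, 3L, 3L, 3L),
    date = as.Date(c("2015-05-01", "2015-05-11",   # E11 + A10 within 10 d
                     "2015-05-01",                  # I10, never any drug
                     "2016-02-01", "2016-02-20",    # hypertension event d1
                     "2017-06-01", "2017-06-05")),  # diabetes event d2 > d1
    kind = c("diagnosis", "dispensing", "diagnosis",
             "diagnosis", "dispensing", "diagnosis", "dispensing"),
    code = c("E11", "A10", "I10", "I10", "C03", "E11", "A10"))
  db <- make_db(persons, claims)
  dm <- outcome_definition("diabetes")
  expect_equal(find_first_outcome(db, 1L, as.Date("2015-01-01"), dm),
               as.Date("2015-05-01"))
  ht <- outcome_definition("hypertension")
  expect_true(is.na(find_first_outcome(db, 2L, as.Date("2015-01-01"), ht)))
  comp <- outcome_definition("composite")
  expect_equal(find_first_outcome(db, 3L, as.Date("2015-01-01"), comp),
               as.Date("2016-02-01"))
  # outside the conjunction window the pair no longer qualifies
  dm30 <- outcome_definition("diabetes", conjunction_window_days = 5)
  expect_equal(find_first_outcome(db, 1L, as.Date("2015-01-01"), dm30),
               as.Date(NA))
})

test_that("period expansion follows the interval arithmetic", {
  persons <- data.table(person_id = 1:3, birth_date = as.Date("1970-01-01"),
                        enroll_start = as.Date("2009-01-01"),
                        enroll_end = as.Date(c("2025-12-31", "2015-10-01",
                                               "2025-12-31")))
  visits <- data.table(person_id = rep(1:3, each = 2),
                       date = rep(as.Date(c("2014-06-01", "2014-12-01")), 3),
                       kind = "outpatient_visit", code = "")
  # person 1: event 2.5 years after the 2015-04-01 entry
  ev <- data.table(person_id = c(1L, 1L), date = as.Date("2017-10-01"),
                   kind = c("diagnosis", "dispensing"), code = c("E11", "A10"))
  db <- make_db(persons, rbind(visits, ev))
  entries <- build_sequential_cohort(db, 2015)
  pp <- expand_person_periods(entries, db,
                              admin_end_date = as.Date("2026-03-31"))
  p1 <- pp[person_id == 1][order(k)]
  expect_equal(p1$k, 1:3)
  expect_equal(p1$event, c(0L, 0L, 1L))
  expect_equal(p1$censored, c(0L, 0L, 0L))
  # person 2: disenrolls half a year in, no event
  p2 <- pp[person_id == 2]
  expect_equal(nrow(p2), 1L)
  expect_equal(p2$event, 0L)
  expect_equal(p2$censored, 1L)
  # person 3: full observation, horizon-censored at 10 annual periods
  p3 <- pp[person_id == 3][order(k)]
  expect_equal(nrow(p3), 10L)
  expect_equal(p3$event, rep(0L, 10))
  expect_equal(p3$censored, c(rep(0L, 9), 1L))
})

test_that("periods are gap-free with at most one event per entry", {
  db <- shared_sim()$db
  entries <- build_sequential_cohort(db, 2011:2014)
  pp <- expand_person_periods(entries, db)
  chk <- pp[, .(gapfree = identical(sort(k), seq_len(.N)),
                n_event = sum(event), n_cens = sum(censored),
                last_only = all(which(event == 1 | censored == 1) == .N)),
            by = entry_id]
  expect_true(all(chk$gapfree))
  expect_true(all(chk$n_event <= 1))
  expect_true(all(chk$n_event + chk$n_cens <= 1))
  expect_true(all(chk$last_only | (chk$n_event + chk$n_cens == 0)))
  expect_lte(max(pp$k), 10)
  expect_true(all(pp$event %in% 0:1 & pp$censored %in% 0:1))
  expect_true(all(pp[event == 1, censored] == 0))
})

test_that("annual and monthly expansions agree on event placement", {
  persons <- data.table(person_id = 1L, birth_date = as.Date("1970-01-01"),
                        enroll_start = as.Date("2013-01-01"),
                        enroll_end = as.Date("2025-12-31"))
  claims <- rbind(
    data.table(person_id = 1L, date = as.Date("2014-10-01"),
               kind = "outpatient_visit", code = ""),
    data.table(person_id = 1L, date = as.Date("2016-06-01"),
               kind = c("diagnosis", "dispensing"), code = c("E11", "A10")))
  db <- make_db(persons, claims)
  entries <- build_sequential_cohort(db, 2015)
  ann <- expand_person_periods(entries, db,
                               admin_end_date = as.Date("2026-03-31"))
  mon <- expand_person_periods(entries, db, interval = "month",
                               admin_end_date = as.Date("2026-03-31"))
  k_ann <- ann[event == 1, k]
  k_mon <- mon[event == 1, k]
  expect_length(k_ann, 1L)
  expect_length(k_mon, 1L)
  expect_equal(k_ann, ceiling(k_mon / 12))
  # non-SHC protocol flag flips in the interval of the first checkup
  db$checkups <- data.table(person_id = 1L, date = as.Date("2017-08-01"),
                            fy = 2017L, bmi = NA_real_, waist_cm = NA_real_,
                            sbp_mmhg = NA_real_, hba1c_pct = NA_real_,
                            smoker = NA_integer_)
  db$claims <- db$claims[kind != "diagnosis" & kind != "dispensing"]
  entries2 <- build_sequential_cohort(db, 2015)
  pp2 <- expand_person_periods(entries2, db,
                               admin_end_date = as.Date("2026-03-31"))
  expect_equal(pp2[order(k), still_in_non_shc_protocol][1:4],
               c(1L, 1L, 0L, 0L))
})

test_that("cumulative checkup sessions accrue only in the SHC arm", {
  persons <- data.table(person_id = 1L, birth_date = as.Date("1970-01-01"),
                        enroll_start = as.Date("2013-01-01"),
                        enroll_end = as.Date("2025-12-31"))
  claims <- data.table(person_id = 1L, date = as.Date("2014-10-01"),
                       kind = "outpatient_visit", code = "")
  checkups <- data.table(person_id = 1L,
                         date = as.Date(c("2015-07-01", "2016-07-01",
                                          "2018-07-01")),
                         fy = c(2015L, 2016L, 2018L))
  db <- make_db(persons, claims, checkups)
  entries <- build_sequential_cohort(db, 2015)
  expect_equal(entries$arm, "SHC")
  pp <- expand_person_periods(entries, db,
                              admin_end_date = as.Date("2026-03-31"))
  expect_equal(pp[order(k), cumulative_shc_sessions],
               c(1L, 2L, 2L, 3L, rep(3L, 6)))
})
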