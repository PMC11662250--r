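# Eligibility criteria and outcome definitions. ICD-10 / ATC codes are
# matched by prefix: a listed code matches any recorded code that starts
# with it ("C07" matches "C07AB02"), so 3-digit families cover their
# subdivisions.

#' Eligibility criteria for the sequential nested trials
#'
#' Encodes the per-fiscal-year screening rules: age band at entry, minimum
#' continuous-enrollment lookback, minimum health-care use in the lookback
#' window, no prior checkup, no prevalent disease (diagnosis code plus
#' matching medication dispensing anywhere in the observable pre-entry
#' history), and exclusion of extreme resource users.
#'
#' @param age_min,age_max age band in completed years at the fiscal-year
#'   start (default 40-74; one sensitivity analysis caps at 69).
#' @param lookback_days required continuous enrollment before entry.
#' @param min_visits_in_lookback minimum number of outpatient-visit or
#'   hospitalization records inside the lookback window.
#' @param require_no_prior_checkup drop persons with any checkup record
#'   before the fiscal-year start (one sensitivity analysis relaxes this).
#' @param exclusion_code_sets named list of prevalent-disease rules; each
#'   element has `diagnosis` (ICD-10 prefixes) and `drugs` (ATC prefixes),
#'   both of which must be present in the pre-entry history. Defaults:
#'   diabetes E10/E14 with any A10 dispensing; hypertension I10-I15 with any
#'   C02/C03/C07-C09 dispensing.
#' @param resource_use_exclusion_percentile persons at or above this
#'   percentile of lookback-window outpatient + hospitalization record counts
#'   (computed on the otherwise-eligible screened population) are excluded;
#'   a proxy for institutionalized individuals.
#' @return an object of class `eligibility_criteria`.
#' @export
eligibility_criteria <- function(age_min = 40L, age_max = 74L,
                                 lookback_days = 365L,
                                 min_visits_in_lookback = 1L,
                                 require_no_prior_checkup = TRUE,
                                 exclusion_code_sets = default_exclusions(),
                                 resource_use_exclusion_percentile = 99.99) {
  if (age_min > age_max)
    stop("eligibility_criteria: `age_min` must be <= `age_max`", call. = FALSE)
  if (lookback_days < 1L)
    stop("eligibility_criteria: `lookback_days` must be >= 1", call. = FALSE)
  structure(list(age_min = as.integer(age_min), age_max = as.integer(age_max),
                 lookback_days = as.integer(lookback_days),
                 min_visits_in_lookback = as.integer(min_visits_in_lookback),
                 require_no_prior_checkup = isTRUE(require_no_prior_checkup),
                 exclusion_code_sets = exclusion_code_sets,
                 resource_use_exclusion_percentile =
                   resource_use_exclusion_percentile),
            class = "eligibility_criteria")
}

#' @rdname eligibility_criteria
#' @export
default_exclusions <- function() {
  list(
    diabetes = list(diagnosis = c("E10", "E14"), drugs = "A10"),
    hypertension = list(diagnosis = paste0("I1", 0:5),
                        drugs = c("C02", "C03", "C07", "C08", "C09"))
  )
}

#' Outcome definitions
#'
#' Each outcome is an earliest date on which a listed diagnosis code is
#' recorded with (when `require_drug`) a listed medication dispensed within
#' `conjunction_window_days` of it. The composite outcome is the earliest of
#' its diabetes and hypertension components, each with its own drug class, so
#' a diabetes code never pairs with an antihypertensive.
#'
#' Defaults follow the claims-based definitions: diabetes E11/E14 with A10;
#' hypertension I10-I13 plus I15 with C02/C03/C07-C09 (`hypertension_extra`
#' lets you use the alternative printed fifth code instead); negative-control
#' depression F32/F34/F35 with no drug requirement.
#'
#' @param name one of `"composite"`, `"diabetes"`, `"hypertension"`,
#'   `"negative_control"`.
#' @param conjunction_window_days half-width of the window pairing diagnosis
#'   and dispensing dates (default 90).
#' @param hypertension_extra the fifth hypertension code family (default
#'   `"I15"`; set `"E15"` to reproduce the alternative coding).
#' @return an object of class `outcome_definition`; for the composite, a
#'   list of component definitions under `$components`.
#' @examples
#' outcome_definition("diabetes")$diagnosis_codes
#' @export
outcome_definition <- function(name = c("composite", "diabetes",
                                        "hypertension", "negative_control"),
                               conjunction_window_days = 90L,
                               hypertension_extra = "I15") {
  name <- match.arg(name)
  make <- function(nm, dx, rx, need_drug) {
    structure(list(name = nm, diagnosis_codes = dx, drug_codes = rx,
                   require_drug = need_drug,
                   conjunction_window_days = as.integer(conjunction_window_days)),
              class = "outcome_definition")
  }
  dm <- make("diabetes", c("E11", "E14"), "A10", TRUE)
  ht <- make("hypertension", c("I10", "I11", "I12", "I13", hypertension_extra),
             c("C02", "C03", "C07", "C08", "C09"), TRUE)
  nc <- make("negative_control", c("F32", "F34", "F35"), character(0), FALSE)
  switch(name,
         diabetes = dm,
         hypertension = ht,
         negative_control = nc,
         composite = {
           out <- make("composite", c(dm$diagnosis_codes, ht$diagnosis_codes),
                       c(dm$drug_codes, ht$drug_codes), TRUE)
           out$components <- list(dm, ht)
           out
         })
}

# TRUE for recorded codes starting with any of the listed prefixes.
code_matches <- function(codes, prefixes) {
  if (!length(prefixes)) return(rep(FALSE, length(codes)))
  hit <- rep(FALSE, length(codes))
  for (p in prefixes) hit <- hit | startsWith(codes, p)
  hit
}
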