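# Configuration for the synthetic claims-database generator.

#' Default confounder specification
#'
#' Five baseline factors drive both checkup uptake and chronic-disease onset,
#' echoing the kind of imbalance seen between checkup participants and
#' non-participants in employee-insurance claims (participants more often
#' employed and male, slightly older within the eligible band, with more
#' metabolic-risk coding). Each element gives the factor's distribution and
#' its additive effects (log-odds scale) on the uptake, composite-outcome and
#' negative-control logits. Factors carrying a `code` are surfaced in the
#' claims as a 3-digit ICD-10 diagnosis recorded at enrollment start, so the
#' propensity model can observe them.
#'
#' @return a list of confounder descriptors, one per factor.
#' @export
default_confounders <- function() {
  list(
    list(name = "female",   dist = "builtin",
         beta_uptake = -0.8, beta_outcome = -0.4, beta_nc = 0.5),
    list(name = "employed", dist = "builtin",
         beta_uptake = 0.9,  beta_outcome = 0.5,  beta_nc = -0.2),
    list(name = "age_std",  dist = "age",
         beta_uptake = 0.25, beta_outcome = 0.7,  beta_nc = 0.1),
    list(name = "metabolic_history", dist = "bernoulli", par = 0.30,
         beta_uptake = 0.4,  beta_outcome = 0.9,  beta_nc = 0.3,
         code = "E66"),
    list(name = "mental_history", dist = "bernoulli", par = 0.15,
         beta_uptake = -0.4, beta_outcome = 0.2,  beta_nc = 0.8,
         code = "F41"),
    # preventive-care-seeking: the dominant, fully observed uptake driver
    # (annual-examination coding); no direct effect on either outcome, so
    # participators exhaust early without distorting hazards
    list(name = "preventive_care", dist = "bernoulli", par = 0.35,
         beta_uptake = 3.0,  beta_outcome = 0,    beta_nc = 0,
         code = "Z00")
  )
}

#' Default background diagnosis-code pool
#'
#' Benign 3-digit ICD-10 codes written into the claims history with
#' person-level propensities tied to the confounders, so the high-dimensional
#' part of the propensity model has genuine signal rather than pure noise.
#' `base_logit` is the per-fiscal-year recording log-odds for a reference
#' person; the `load_*` columns tilt it by the named confounder.
#'
#' @return a `data.frame`, one row per code.
#' @export
default_code_pool <- function() {
  data.frame(
    code = c("J30", "J06", "H52", "K29", "M54", "J02", "L20", "H10",
             "K02", "N39", "R51", "J45", "B35", "H66", "K59", "M25"),
    base_logit = c(-0.4, -0.5, -0.6, -1.6, -1.4, -1.8, -2.2, -2.0,
                   -2.2, -2.6, -2.4, -2.6, -3.0, -3.0, -2.8, -2.6),
    load_female = c(0.1, 0.1, 0.0, 0.1, 0.0, 0.2, 0.1, 0.0,
                    0.0, 0.6, 0.3, 0.0, -0.2, 0.0, 0.3, 0.0),
    load_employed = c(0.0, -0.1, 0.1, 0.1, 0.1, -0.1, 0.0, 0.0,
                      0.0, -0.1, 0.0, 0.0, 0.1, -0.1, 0.0, 0.0),
    load_metabolic = c(0.0, 0.0, 0.1, 0.3, 0.2, 0.0, 0.0, 0.0,
                       0.2, 0.1, 0.0, 0.1, 0.1, 0.0, 0.2, 0.3),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration
#'
#' Assembles and validates the parameters of the synthetic claims generator.
#' Defaults describe a moderately confounded employee-insurance population:
#' annual checkup uptake driven by employment, sex, age and coded history;
#' chronic-disease (diabetes/hypertension-style) onset as a yearly Bernoulli
#' hazard on the logit scale with a protective checkup effect; a depression-
#' style negative-control outcome with the same confounder structure but no
#' treatment effect; and geometric disenrollment.
#'
#' @param n_persons number of insured persons to simulate.
#' @param fy_start,fy_end first and last fiscal year of checkup availability
#'   (labelled by the calendar year of April 1).
#' @param admin_end_fy administrative end of observation; records stop at
#'   March 31 of `admin_end_fy + 1`.
#' @param age_range_at_entry integer interval of ages (years) at the start of
#'   `fy_start`.
#' @param sex_female_prob,employed_prob marginal probabilities of female sex
#'   and of being the insured employee (vs dependent).
#' @param confounder_spec list of confounder descriptors; see
#'   [default_confounders()].
#' @param unmeasured_effect_uptake,unmeasured_effect_outcome log-odds effects
#'   of a standard-normal latent health-seeking factor on uptake and on both
#'   outcome hazards; 0 (default) disables unmeasured confounding.
#' @param baseline_annual_outcome_hazard reference yearly probability of
#'   composite-outcome onset.
#' @param log_hr_treatment true conditional effect of checkup participation
#'   on the composite-outcome hazard, log-odds scale; the hazard switches to
#'   the treated logit from the fiscal year of first checkup onward.
#' @param baseline_annual_nc_hazard reference yearly probability of the
#'   negative-control outcome (never affected by treatment).
#' @param annual_disenroll_prob yearly probability of leaving the insurer.
#' @param uptake_intercept log-odds of a first checkup in an eligible
#'   fiscal year for a reference person. The default confounder spec puts
#'   most uptake heterogeneity on the observed preventive-care indicator, so
#'   likely participators take up within their first eligible years and the
#'   residual crossover among non-SHC entrants stays small, keeping the
#'   trial-entry contrast close to the always-versus-never oracle contrast.
#' @param uptake_repeat_prob probability of attending again in each year
#'   after the first checkup (drives the dose analysis only; the outcome
#'   hazard uses the persistent first-checkup switch).
#' @param prevalent_fraction fraction of persons with prevalent disease
#'   (diagnosis plus medication) coded shortly after enrollment start; these
#'   exercise the baseline exclusion rules.
#' @param visit_rate_log mean log yearly outpatient-visit rate.
#' @param hosp_rate yearly hospitalization rate (Poisson).
#' @param code_pool background diagnosis-code pool; see [default_code_pool()].
#' @param seed integer seed; the generator is fully deterministic given the
#'   configuration and seed.
#' @return an object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_persons = 100, seed = 7)
#' cfg$log_hr_treatment
#' @export
sim_config <- function(n_persons = 10000L,
                       fy_start = 2010L,
                       fy_end = 2017L,
                       admin_end_fy = 2019L,
                       age_range_at_entry = c(40L, 70L),
                       sex_female_prob = 0.70,
                       employed_prob = 0.35,
                       confounder_spec = default_confounders(),
                       unmeasured_effect_uptake = 0,
                       unmeasured_effect_outcome = 0,
                       baseline_annual_outcome_hazard = 0.015,
                       log_hr_treatment = log(0.9),
                       baseline_annual_nc_hazard = 0.008,
                       annual_disenroll_prob = 0.05,
                       uptake_intercept = -3.4,
                       uptake_repeat_prob = 0.8,
                       prevalent_fraction = 0.05,
                       visit_rate_log = 1.2,
                       hosp_rate = 0.08,
                       code_pool = default_code_pool(),
                       seed = 1L) {
  cfg <- list(
    n_persons = as.integer(n_persons), fy_start = as.integer(fy_start),
    fy_end = as.integer(fy_end), admin_end_fy = as.integer(admin_end_fy),
    age_range_at_entry = as.integer(age_range_at_entry),
    sex_female_prob = sex_female_prob, employed_prob = employed_prob,
    confounder_spec = confounder_spec,
    unmeasured_effect_uptake = unmeasured_effect_uptake,
    unmeasured_effect_outcome = unmeasured_effect_outcome,
    baseline_annual_outcome_hazard = baseline_annual_outcome_hazard,
    log_hr_treatment = log_hr_treatment,
    baseline_annual_nc_hazard = baseline_annual_nc_hazard,
    annual_disenroll_prob = annual_disenroll_prob,
    uptake_intercept = uptake_intercept,
    uptake_repeat_prob = uptake_repeat_prob,
    prevalent_fraction = prevalent_fraction,
    visit_rate_log = visit_rate_log, hosp_rate = hosp_rate,
    code_pool = code_pool, seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  chk_prob <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || any(is.na(v)) || any(v < 0) || any(v > 1))
      stop("sim_config: `", field, "` must be a probability in [0, 1]",
           call. = FALSE)
  }
  for (f in c("sex_female_prob", "employed_prob",
              "baseline_annual_outcome_hazard", "baseline_annual_nc_hazard",
              "annual_disenroll_prob",
              "uptake_repeat_prob", "prevalent_fraction"))
    chk_prob(f)
  if (cfg$n_persons < 0L)
    stop("sim_config: `n_persons` must be >= 0", call. = FALSE)
  if (!(cfg$fy_start <= cfg$fy_end))
    stop("sim_config: `fy_start` must be <= `fy_end`", call. = FALSE)
  if (!(cfg$fy_end <= cfg$admin_end_fy))
    stop("sim_config: `fy_end` must be <= `admin_end_fy`", call. = FALSE)
  if (cfg$age_range_at_entry[1] > cfg$age_range_at_entry[2])
    stop("sim_config: `age_range_at_entry` is an inverted interval",
         call. = FALSE)
  invisible(cfg)
}

# Draw the person-level confounder matrix (columns in spec order) plus the
# latent health-seeking factor. `age_std` is (age at fy_start - midpoint)/10.
draw_confounders <- function(cfg, n, age0, female, employed) {
  spec <- cfg$confounder_spec
  out <- matrix(0, nrow = n, ncol = length(spec),
                dimnames = list(NULL, vapply(spec, `[[`, "", "name")))
  mid <- mean(cfg$age_range_at_entry)
  for (j in seq_along(spec)) {
    s <- spec[[j]]
    out[, j] <- switch(s$dist,
      builtin = switch(s$name,
        female = as.numeric(female),
        employed = as.numeric(employed),
        stop("sim_config: unknown builtin confounder `", s$name, "`",
             call. = FALSE)),
      age = (age0 - mid) / 10,
      bernoulli = rbinom(n, 1L, s$par),
      normal = rnorm(n, s$par[1], s$par[2]),
      stop("sim_config: unknown confounder distribution `", s$dist, "`",
           call. = FALSE))
  }
  out
}

confounder_effects <- function(cfg, which = c("uptake", "outcome", "nc")) {
  which <- match.arg(which)
  field <- paste0("beta_", switch(which, uptake = "uptake",
                                  outcome = "outcome", nc = "nc"))
  vapply(cfg$confounder_spec, function(s) s[[field]] %||% 0, numeric(1))
}
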