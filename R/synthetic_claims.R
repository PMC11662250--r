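# Synthetic claims database: persons / claims / checkups tables with
# confounded checkup uptake, discrete-time outcome hazards with a known
# treatment effect, a null-effect negative-control outcome, and geometric
# disenrollment. Everything is generated at day resolution inside Japanese
# fiscal years (April 1 - March 31).

empty_claims_db <- function() {
  structure(list(
    persons = data.table(person_id = integer(), birth_date = as.Date(character()),
                         female = integer(), employed = integer(),
                         enroll_start = as.Date(character()),
                         enroll_end = as.Date(character())),
    claims = data.table(person_id = integer(), date = as.Date(character()),
                        kind = character(), code = character()),
    checkups = data.table(person_id = integer(), date = as.Date(character()),
                          fy = integer(), bmi = numeric(), waist_cm = numeric(),
                          sbp_mmhg = numeric(), hba1c_pct = numeric(),
                          smoker = integer())
  ), class = "claims_db")
}

#' Generate a synthetic claims database
#'
#' Simulates an employee-insurance population with the structure the
#' emulation pipeline assumes: enrollment spans; yearly outpatient visits and
#' occasional hospitalizations; background 3-digit ICD-10 diagnosis codes
#' whose recording propensities are tied to the confounders; annual checkup
#' participation decided by a logistic model on the confounders (plus an
#' optional latent health-seeking factor); composite chronic-disease onset as
#' a yearly Bernoulli hazard whose logit switches to the treated value from
#' the fiscal year of first checkup onward; a negative-control outcome
#' simulated identically but with zero treatment effect; and prevalent cases
#' coded at enrollment to exercise the baseline exclusions. Onset is recorded
#' as a diagnosis code and a matching drug dispensing on the same date, so
#' the code-plus-medication outcome definition fires unambiguously.
#'
#' The generator is fully deterministic given `cfg` (including its seed); all
#' dated records fall inside the person's enrollment span.
#'
#' @param cfg a [sim_config()] object.
#' @return an object of class `claims_db`: a list of three `data.table`s,
#'   `persons` (person_id, birth_date, female, employed, enroll_start,
#'   enroll_end), `claims` (person_id, date, kind in diagnosis / dispensing /
#'   outpatient_visit / hospitalization, code) and `checkups` (person_id,
#'   date, fy, measurements with realistic missingness).
#' @examples
#' db <- generate_population(sim_config(n_persons = 200, seed = 42))
#' sapply(db, nrow)
#' @export
generate_population <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  n <- cfg$n_persons
  if (n == 0L) return(empty_claims_db())

  sim_start <- fy_start_date(cfg$fy_start)
  admin_end <- fy_end_date(cfg$admin_end_fy)

  # ---- persons ----
  age0 <- sample(seq(cfg$age_range_at_entry[1], cfg$age_range_at_entry[2]),
                 n, replace = TRUE)
  birth_date <- sim_start - round(age0 * 365.25 + runif(n, 0, 364))
  female <- rbinom(n, 1L, cfg$sex_female_prob)
  employed <- rbinom(n, 1L, cfg$employed_prob)
  conf <- draw_confounders(cfg, n, age0, female, employed)
  u_latent <- rnorm(n)

  span_years <- cfg$fy_end - cfg$fy_start
  enroll_start <- sim_start +
    round(runif(n, -1095, 365 * max(span_years - 1, 0)))
  if (cfg$annual_disenroll_prob > 0) {
    dis_years <- rgeom(n, cfg$annual_disenroll_prob) + runif(n)
    enroll_end <- pmin(enroll_start + round(dis_years * 365.25), admin_end)
  } else {
    enroll_end <- rep(admin_end, n)
  }
  enroll_end <- pmax(enroll_end, enroll_start + 1L)

  persons <- data.table(person_id = seq_len(n), birth_date = birth_date,
                        female = female, employed = employed,
                        enroll_start = enroll_start, enroll_end = enroll_end)

  beta_u <- confounder_effects(cfg, "uptake")
  beta_y <- confounder_effects(cfg, "outcome")
  beta_n <- confounder_effects(cfg, "nc")
  lp_uptake <- drop(conf %*% beta_u) + cfg$unmeasured_effect_uptake * u_latent
  lp_outcome <- drop(conf %*% beta_y) + cfg$unmeasured_effect_outcome * u_latent
  lp_nc <- drop(conf %*% beta_n) + cfg$unmeasured_effect_outcome * u_latent
  # sicker people visit a bit more; gives the visit-count covariate signal
  visit_lam <- exp(cfg$visit_rate_log + 0.12 * scale_clamp(lp_outcome))

  claims_parts <- list()
  part <- function(pid, date, kind, code) {
    data.table(person_id = pid, date = date, kind = kind, code = code)
  }

  # ---- confounder marker codes, recorded once at enrollment start ----
  for (s in cfg$confounder_spec) {
    if (!is.null(s$code)) {
      has <- which(conf[, s$name] == 1)
      if (length(has))
        claims_parts[[length(claims_parts) + 1L]] <-
          part(has, enroll_start[has], "diagnosis", s$code)
    }
  }

  # ---- prevalent disease (diagnosis + matching drug at enrollment) ----
  prevalent <- rep(FALSE, n)
  n_prev <- round(cfg$prevalent_fraction * n)
  if (n_prev > 0) {
    ids <- sample(n, n_prev)
    prevalent[ids] <- TRUE
    d <- pmin(enroll_start[ids] + 14L, enroll_end[ids])
    is_dm <- rbinom(n_prev, 1L, 0.4) == 1L
    dx <- ifelse(is_dm, "E14", "I10")
    rx <- ifelse(is_dm, "A10", "C09")
    claims_parts[[length(claims_parts) + 1L]] <- part(ids, d, "diagnosis", dx)
    claims_parts[[length(claims_parts) + 1L]] <- part(ids, d, "dispensing", rx)
  }

  # ---- fiscal-year loop: visits, codes, checkups, outcome onset ----
  pool <- cfg$code_pool
  load_mat <- code_pool_loads(pool, conf)  # n x n_codes logit tilts
  first_fy <- fiscal_year(min(enroll_start))
  first_checkup_fy <- rep(NA_integer_, n)
  onset_done <- prevalent  # prevalent cases carry no incident onset
  nc_done <- rep(FALSE, n)
  h0_logit <- qlogis(cfg$baseline_annual_outcome_hazard)
  h0_nc_logit <- qlogis(cfg$baseline_annual_nc_hazard)
  checkup_parts <- list()

  for (fy in seq(first_fy, cfg$admin_end_fy)) {
    fs <- fy_start_date(fy); fe <- fy_end_date(fy)
    w_lo <- pmax(enroll_start, fs); w_hi <- pmin(enroll_end, fe)
    active <- which(w_lo <= w_hi)
    if (!length(active)) next
    frac <- as.numeric(w_hi[active] - w_lo[active] + 1) / 365

    rdate <- function(idx_local) {
      a <- active[idx_local]
      w_lo[a] + round(runif(length(a)) *
                        as.numeric(w_hi[a] - w_lo[a]))
    }

    # outpatient visits and hospitalizations
    nv <- rpois(length(active), visit_lam[active] * frac)
    iv <- rep(seq_along(active), nv)
    if (length(iv))
      claims_parts[[length(claims_parts) + 1L]] <-
        part(active[iv], rdate(iv), "outpatient_visit", "")
    nh <- rpois(length(active), cfg$hosp_rate * frac)
    ih <- rep(seq_along(active), nh)
    if (length(ih))
      claims_parts[[length(claims_parts) + 1L]] <-
        part(active[ih], rdate(ih), "hospitalization", "")

    # background diagnosis codes
    for (j in seq_len(nrow(pool))) {
      p <- plogis(pool$base_logit[j] + load_mat[active, j]) * pmin(frac, 1)
      hit <- which(rbinom(length(active), 1L, p) == 1L)
      if (length(hit))
        claims_parts[[length(claims_parts) + 1L]] <-
          part(active[hit], rdate(hit), "diagnosis", pool$code[j])
    }

    # checkup uptake (program years only; must be enrolled at FY start)
    if (fy >= cfg$fy_start && fy <= cfg$fy_end) {
      age_fy <- age0 + (fy - cfg$fy_start)
      elig <- which(enroll_start <= fs & enroll_end >= fs &
                      age_fy >= 40L & age_fy <= 74L)
      if (length(elig)) {
        repeating <- !is.na(first_checkup_fy[elig])
        p_take <- ifelse(repeating, cfg$uptake_repeat_prob,
                         plogis(cfg$uptake_intercept + lp_uptake[elig]))
        takes <- elig[rbinom(length(elig), 1L, p_take) == 1L]
        if (length(takes)) {
          newly <- takes[is.na(first_checkup_fy[takes])]
          first_checkup_fy[newly] <- fy
          cd <- fs + round(runif(length(takes)) *
                             as.numeric(pmin(enroll_end[takes], fe) - fs))
          checkup_parts[[length(checkup_parts) + 1L]] <-
            checkup_measurements(takes, cd, fy, conf, female, age0)
        }
      }
    }

    # composite-outcome onset (yearly Bernoulli hazard, treated switch)
    at_risk <- active[!onset_done[active]]
    if (length(at_risk)) {
      treated <- !is.na(first_checkup_fy[at_risk]) &
        first_checkup_fy[at_risk] <= fy
      p_ev <- plogis(h0_logit + lp_outcome[at_risk] +
                       cfg$log_hr_treatment * treated) *
        pmin(as.numeric(w_hi[at_risk] - w_lo[at_risk] + 1) / 365, 1)
      ev <- at_risk[rbinom(length(at_risk), 1L, p_ev) == 1L]
      if (length(ev)) {
        onset_done[ev] <- TRUE
        d <- w_lo[ev] + round(runif(length(ev)) * as.numeric(w_hi[ev] - w_lo[ev]))
        is_dm <- rbinom(length(ev), 1L, 0.35) == 1L
        claims_parts[[length(claims_parts) + 1L]] <-
          part(ev, d, "diagnosis", ifelse(is_dm, "E14", "I10"))
        claims_parts[[length(claims_parts) + 1L]] <-
          part(ev, d, "dispensing", ifelse(is_dm, "A10", "C09"))
      }
    }

    # negative-control onset: same confounder structure, zero treatment effect
    nc_risk <- active[!nc_done[active]]
    if (length(nc_risk)) {
      p_nc <- plogis(h0_nc_logit + lp_nc[nc_risk]) *
        pmin(as.numeric(w_hi[nc_risk] - w_lo[nc_risk] + 1) / 365, 1)
      ev <- nc_risk[rbinom(length(nc_risk), 1L, p_nc) == 1L]
      if (length(ev)) {
        nc_done[ev] <- TRUE
        d <- w_lo[ev] + round(runif(length(ev)) * as.numeric(w_hi[ev] - w_lo[ev]))
        claims_parts[[length(claims_parts) + 1L]] <-
          part(ev, d, "diagnosis", "F32")
      }
    }
  }

  claims <- rbindlist(claims_parts)
  setorder(claims, person_id, date, kind, code)
  checkups <- if (length(checkup_parts)) rbindlist(checkup_parts)
              else empty_claims_db()$checkups
  setorder(checkups, person_id, fy)
  structure(list(persons = persons, claims = claims, checkups = checkups),
            class = "claims_db")
}

# clamp-and-center a linear predictor so rate tilts stay moderate
scale_clamp <- function(x) pmin(pmax(x - mean(x), -2), 2)

code_pool_loads <- function(pool, conf) {
  n <- nrow(conf)
  get <- function(nm) if (nm %in% colnames(conf)) conf[, nm] else numeric(n)
  fem <- get("female"); emp <- get("employed"); met <- get("metabolic_history")
  sapply(seq_len(nrow(pool)), function(j)
    pool$load_female[j] * fem + pool$load_employed[j] * emp +
      pool$load_metabolic[j] * met)
}

checkup_measurements <- function(ids, dates, fy, conf, female, age0) {
  m <- length(ids)
  met <- if ("metabolic_history" %in% colnames(conf))
    conf[ids, "metabolic_history"] else numeric(m)
  bmi <- rnorm(m, 21.5 + 2.8 * met + 0.8 * (1 - female[ids]), 2.8)
  waist <- rnorm(m, 72 + 2.6 * (bmi - 21.5) + 4.5 * (1 - female[ids]), 4)
  sbp <- rnorm(m, 112 + 1.4 * (bmi - 21.5) + 0.45 * (age0[ids] - 55) +
                 3.5 * (1 - female[ids]), 11)
  hba1c <- rnorm(m, 5.38 + 0.1 * met + 0.006 * (age0[ids] - 55), 0.22)
  smoker <- rbinom(m, 1L, plogis(-2.4 + 1.6 * (1 - female[ids])))
  miss <- function(x, p) { x[runif(m) < p] <- NA; x }
  data.table(person_id = ids, date = dates, fy = fy,
             bmi = round(miss(bmi, 0.0004), 1),
             waist_cm = round(miss(waist, 0.005), 1),
             sbp_mmhg = round(miss(sbp, 0.002)),
             hba1c_pct = round(miss(hba1c, 0.127), 1),
             smoker = miss(smoker, 0.019))
}

#' Monte-Carlo ground truth for the simulated treatment effect
#'
#' Simulates both potential-outcome trajectories for `n_mc` persons drawn
#' from the configured confounder distribution — checkup from the first
#' eligible fiscal year versus never — and returns the discrete-time marginal
#' hazard ratio implied by the two counterfactual incidence curves. Because
#' each person's yearly hazard is deterministic given their covariates, the
#' per-person survival curves are computed in closed form and only the
#' covariate draw is Monte Carlo; the marginal HR is the treatment
#' coefficient of a pooled logistic fit (treatment + interval indicators) to
#' the aggregated counterfactual risk sets. The Monte-Carlo standard error
#' comes from splitting the draw into `n_groups` independent blocks.
#'
#' @param cfg a [sim_config()] object; only the confounder distribution and
#'   hazard parameters are used (enrollment and uptake play no role in the
#'   counterfactual contrast).
#' @param n_mc number of Monte-Carlo persons (>= 1000).
#' @param seed integer seed for the covariate draw.
#' @param horizon_years follow-up length of the counterfactual curves.
#' @param n_groups number of blocks used for the Monte-Carlo standard error.
#' @return a list of class `ground_truth`: `true_conditional_hr`,
#'   `true_marginal_hr`, `mc_se` (on the log-HR scale it is `mc_se_log`),
#'   and `true_10y_risk_by_arm` (treated, untreated).
#' @examples
#' gt <- ground_truth(sim_config(n_persons = 0), n_mc = 2000, seed = 1)
#' gt$true_marginal_hr
#' @export
ground_truth <- function(cfg, n_mc = 100000L, seed = 1L,
                         horizon_years = 10L, n_groups = 20L) {
  validate_sim_config(cfg)
  if (n_mc < 1000L) stop("ground_truth: `n_mc` must be >= 1000", call. = FALSE)
  set.seed(seed)
  n <- as.integer(n_mc)
  age0 <- sample(seq(cfg$age_range_at_entry[1], cfg$age_range_at_entry[2]),
                 n, replace = TRUE)
  female <- rbinom(n, 1L, cfg$sex_female_prob)
  employed <- rbinom(n, 1L, cfg$employed_prob)
  conf <- draw_confounders(cfg, n, age0, female, employed)
  u_latent <- rnorm(n)
  lp <- drop(conf %*% confounder_effects(cfg, "outcome")) +
    cfg$unmeasured_effect_outcome * u_latent
  h0 <- qlogis(cfg$baseline_annual_outcome_hazard)
  lam1 <- plogis(h0 + lp + cfg$log_hr_treatment)  # treated from year 1
  lam0 <- plogis(h0 + lp)                         # never treated

  fit_hr <- function(idx) {
    K <- horizon_years
    s1 <- outer(1 - lam1[idx], 0:K, `^`)  # survival through k columns 0..K
    s0 <- outer(1 - lam0[idx], 0:K, `^`)
    n1 <- colSums(s1)[1:K]; e1 <- colSums(s1[, 1:K, drop = FALSE] * lam1[idx])
    n0 <- colSums(s0)[1:K]; e0 <- colSums(s0[, 1:K, drop = FALSE] * lam0[idx])
    X <- cbind(1, a = rep(c(1, 0), each = K),
               stats::model.matrix(~ factor(rep(1:K, 2)))[, -1])
    colnames(X)[1] <- "(Intercept)"
    fit <- wlogit(X, c(e1 / n1, e0 / n0), w = c(n1, n0))
    list(log_hr = unname(fit$coef[2]),
         risk = c(treated = 1 - mean(s1[, K + 1]),
                  untreated = 1 - mean(s0[, K + 1])))
  }

  all_fit <- fit_hr(seq_len(n))
  grp <- rep_len(seq_len(n_groups), n)
  grp_log <- vapply(seq_len(n_groups),
                    function(g) fit_hr(which(grp == g))$log_hr, numeric(1))
  mc_se_log <- sd(grp_log) / sqrt(n_groups)
  structure(list(
    true_conditional_hr = exp(cfg$log_hr_treatment),
    true_marginal_hr = exp(all_fit$log_hr),
    mc_se_log = mc_se_log,
    mc_se = exp(all_fit$log_hr) * mc_se_log,
    true_10y_risk_by_arm = all_fit$risk
  ), class = "ground_truth")
}

#' Write / read a claims database as CSV files
#'
#' Writes `persons.csv`, `claims.csv` and `checkups.csv` (UTF-8, header row,
#' ISO-8601 dates) to a directory, and reads them back.
#'
#' @param db a `claims_db` object.
#' @param dir directory path (created if needed).
#' @return `write_claims_db` returns `dir` invisibly; `read_claims_db`
#'   returns a `claims_db`.
#' @export
write_claims_db <- function(db, dir) {
  stopifnot(inherits(db, "claims_db"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fwrite(db$persons, file.path(dir, "persons.csv"))
  fwrite(db$claims, file.path(dir, "claims.csv"))
  fwrite(db$checkups, file.path(dir, "checkups.csv"))
  invisible(dir)
}

#' @rdname write_claims_db
#' @export
read_claims_db <- function(dir) {
  pick <- function(f) fread(file.path(dir, f))
  persons <- pick("persons.csv")
  for (cl in c("birth_date", "enroll_start", "enroll_end"))
    persons[[cl]] <- as.Date(persons[[cl]])
  claims <- pick("claims.csv")
  claims[, date := as.Date(date)]
  claims[, code := as.character(code)]
  claims[is.na(code), code := ""]
  checkups <- pick("checkups.csv")
  if (nrow(checkups)) checkups[, date := as.Date(date)]
  structure(list(persons = persons, claims = claims, checkups = checkups),
            class = "claims_db")
}
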