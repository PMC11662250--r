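# Pipeline orchestration from a single config list, plus the descriptive
# baseline table.

#' Run the full emulation pipeline from a configuration
#'
#' Executes simulate-or-load, cohort construction, weighting, estimation
#' and (optionally) the negative-control bias audit, from one config list
#' with defaults for every key. Unknown keys are rejected. When `out_dir`
#' is set, writes `results.json`, `curves.csv`, `balance.csv`,
#' `baseline_table.csv` and `weights.csv`.
#'
#' Config keys (defaults in parentheses): `db` (a `claims_db`), `db_dir`
#' (directory of CSVs; one of the two is required unless `sim` is given),
#' `sim` (a [sim_config()] to generate from), `fy_range` (derived from the
#' database checkup years), `entry_fy_max` (`NULL`), `age_max` (74),
#' `lookback_days` (365), `allow_prior_other_checkups` (`FALSE`),
#' `interval` (`"year"`), `outcome` (`"composite"`), `horizon_years` (10),
#' `prevalence_floor` (1e-4), `truncate_pct` (`NULL`), `per_protocol`
#' (`FALSE`), `interaction` (`FALSE`), `dose` (`FALSE`), `n_boot` (0 = no
#' bootstrap), `bias_audit` (`FALSE`), `seed` (1), `out_dir` (`NULL`).
#'
#' @param config a named list of config keys.
#' @return a list of class `emulation_results`: the estimate, balance
#'   report, baseline table, attrition log, bootstrap and bias-audit
#'   components where requested, and the fully resolved config.
#' @export
run_emulation <- function(config = list()) {
  defaults <- list(db = NULL, db_dir = NULL, sim = NULL, fy_range = NULL,
                   entry_fy_max = NULL, age_max = 74L, lookback_days = 365L,
                   allow_prior_other_checkups = FALSE, interval = "year",
                   outcome = "composite", horizon_years = 10L,
                   prevalence_floor = 0.0001, truncate_pct = NULL,
                   per_protocol = FALSE, interaction = FALSE, dose = FALSE,
                   n_boot = 0L, bias_audit = FALSE, seed = 1L,
                   out_dir = NULL)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("run_emulation: unknown config key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  cfg <- utils::modifyList(defaults, config)

  db <- cfg$db
  if (is.null(db) && !is.null(cfg$db_dir)) db <- read_claims_db(cfg$db_dir)
  if (is.null(db) && !is.null(cfg$sim)) db <- generate_population(cfg$sim)
  if (is.null(db))
    stop("run_emulation: supply one of `db`, `db_dir`, `sim`", call. = FALSE)

  fy_range <- cfg$fy_range
  if (is.null(fy_range)) {
    if (!nrow(db$checkups))
      stop("run_emulation: `fy_range` required when the database has no ",
           "checkups", call. = FALSE)
    fy_range <- seq(min(db$checkups$fy), max(db$checkups$fy))
  }
  if (!is.null(cfg$entry_fy_max)) fy_range <- fy_range[fy_range <= cfg$entry_fy_max]

  criteria <- eligibility_criteria(
    age_max = cfg$age_max, lookback_days = cfg$lookback_days,
    require_no_prior_checkup = !cfg$allow_prior_other_checkups)
  outdef <- outcome_definition(cfg$outcome)

  design <- emulation_design(db, fy_range, criteria, outdef,
                             interval = cfg$interval,
                             horizon_years = cfg$horizon_years,
                             prevalence_floor = cfg$prevalence_floor)
  est <- fit_ipw_hazard(design, truncate_pct = cfg$truncate_pct,
                        per_protocol = cfg$per_protocol,
                        interaction = cfg$interaction, dose = cfg$dose)
  bal <- balance_report(design$covariates, weights = est$weights)
  btab <- baseline_table(design$entries, db)
  boot <- NULL
  if (cfg$n_boot > 0L) {
    boot <- bootstrap_cis(design, n_reps = cfg$n_boot, seed = cfg$seed,
                          truncate_pct = cfg$truncate_pct,
                          per_protocol = cfg$per_protocol)
    est$hr_ci <- boot$hr_ci
    est$rd_ci <- boot$rd_ci
  }
  audit <- NULL
  if (isTRUE(cfg$bias_audit)) {
    nc_design <- emulation_design(db, fy_range, criteria,
                                  outdef = outcome_definition("negative_control"),
                                  interval = cfg$interval,
                                  horizon_years = cfg$horizon_years,
                                  prevalence_floor = cfg$prevalence_floor)
    nc <- fit_ipw_hazard(nc_design)
    if (cfg$n_boot > 0L) {
      nc_boot <- bootstrap_cis(nc_design, n_reps = cfg$n_boot,
                               seed = cfg$seed)
      nc$hr_ci <- nc_boot$hr_ci
    }
    audit <- bias_audit(est$hr_point, est$hr_ci, nc$hr_point, nc$hr_ci)
    audit$nc_estimate <- nc
  }
  attrition <- c(n_persons = nrow(db$persons),
                 n_entries = nrow(design$entries),
                 n_unique_entered = attr(design$entries, "n_unique_persons"),
                 n_periods = nrow(design$periods),
                 n_events = sum(design$periods$event))
  # echo the effective config, minus data objects and machine-local paths
  out <- structure(list(estimate = est, balance = bal, baseline = btab,
                        bootstrap = boot, bias_audit = audit,
                        attrition = attrition, design = design,
                        config = cfg[setdiff(names(cfg),
                                             c("db", "sim", "db_dir",
                                               "out_dir"))]),
                   class = "emulation_results")
  if (!is.null(cfg$out_dir)) write_results(out, cfg$out_dir)
  out
}

write_results <- function(res, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  est <- res$estimate
  payload <- list(
    hr = est$hr_point, hr_ci = est$hr_ci,
    rd_at_horizon = est$rd_at_horizon, rd_ci = est$rd_ci,
    crude_hr = est$crude_hr,
    dose_hr_per_session = est$dose_hr_per_session,
    weight_summary = as.list(est$weights$summary),
    balanced = attr(res$balance, "balanced"),
    attrition = as.list(res$attrition),
    config = res$config)
  if (!is.null(res$bias_audit))
    payload$bias_audit <- res$bias_audit[c("hr_negative_control",
                                           "hr_calibrated", "rr_approx",
                                           "e_value_point",
                                           "e_value_ci_bound")]
  jsonlite::write_json(payload, file.path(dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  if (!is.null(est$curves)) fwrite(est$curves, file.path(dir, "curves.csv"))
  fwrite(res$balance, file.path(dir, "balance.csv"))
  fwrite(res$baseline$by_arm, file.path(dir, "baseline_table.csv"))
  fwrite(data.table(entry_id = res$design$entries$entry_id,
                    ps = est$weights$ps, sw = est$weights$sw),
         file.path(dir, "weights.csv"))
  invisible(dir)
}

#' Descriptive baseline table
#'
#' Per-arm summaries of the entry cohort: size, age and entry-year medians
#' with IQRs, sex and employment percentages, the most common preexisting
#' 3-digit diagnosis families, and — for the SHC arm, whose checkup record
#' carries measurements — BMI, waist circumference (with sex-specific
#' obesity thresholds of 85 cm for males and 90 cm for females), systolic
#' blood pressure, hemoglobin A1c and smoking, each with its missingness
#' percentage. Medians and IQRs use linear-interpolation quantiles.
#'
#' @param entries output of [build_sequential_cohort()].
#' @param db a `claims_db`.
#' @param top_n number of preexisting-illness rows.
#' @return a list of class `baseline_table`: `by_arm` (long table of
#'   statistics), `smd` (named vector for the shared covariates), and
#'   `shc_measures` (measurement summaries with missingness).
#' @export
baseline_table <- function(entries, db, top_n = 3L) {
  e <- db$persons[, .(person_id, female, employed)][entries, on = "person_id"]
  arms <- c("SHC", "non-SHC")
  stat_rows <- list()
  add <- function(variable, values) {
    stat_rows[[length(stat_rows) + 1L]] <<-
      data.table(variable = variable, arm = arms, value = values)
  }
  fmt_miqr <- function(x) {
    q <- median_iqr(x)
    if (is.na(q[1])) return(NA_character_)
    sprintf("%.1f (%.1f-%.1f)", q[1], q[2], q[3])
  }
  n_by <- vapply(arms, function(a) sum(e$arm == a), numeric(1))
  add("n", as.character(n_by))
  add("age_median_iqr",
      vapply(arms, function(a) fmt_miqr(e[arm == a, age_at_entry]),
             character(1)))
  add("female_pct",
      vapply(arms, function(a)
        sprintf("%.1f", 100 * mean(e[arm == a, female])), character(1)))
  add("entry_fy_median_iqr",
      vapply(arms, function(a) fmt_miqr(e[arm == a, trial_fy]), character(1)))
  add("employed_pct",
      vapply(arms, function(a)
        sprintf("%.1f", 100 * mean(e[arm == a, employed])), character(1)))

  # most common preexisting 3-digit diagnosis families (pre-entry history)
  dx <- db$claims[kind == "diagnosis" & nchar(code) >= 3L,
                  .(person_id, date, code3 = substr(code, 1L, 3L))]
  hits <- unique(dx[e[, .(entry_id, person_id, entry_date, arm)],
                    on = .(person_id, date < entry_date),
                    .(entry_id = i.entry_id, arm = i.arm, code3 = x.code3),
                    nomatch = NULL, allow.cartesian = TRUE])
  if (nrow(hits)) {
    top <- hits[, .N, by = code3][order(-N)][seq_len(min(top_n, .N)), code3]
    for (cd in top)
      add(paste0("preexisting_", cd, "_pct"),
          vapply(arms, function(a) sprintf(
            "%.1f", 100 * uniqueN(hits[arm == a & code3 == cd, entry_id]) /
              max(n_by[[a]], 1L)), character(1)))
  }

  safe_smd <- function(x) {
    if (length(unique(e$arm)) < 2L) return(NA_real_)
    smd(x, e$arm)
  }
  smds <- c(
    age = safe_smd(e$age_at_entry),
    female = safe_smd(e$female),
    employed = safe_smd(e$employed),
    entry_fy = safe_smd(as.numeric(e$trial_fy)))

  # SHC-arm checkup measurements (the record that defines the arm)
  shc <- e[arm == "SHC", .(entry_id, person_id, trial_fy, female)]
  meas <- db$checkups[shc, on = c(person_id = "person_id", fy = "trial_fy"),
                      mult = "first", nomatch = NULL]
  shc_measures <- NULL
  if (nrow(meas)) {
    one <- function(x, label, pct_above = NA_real_) {
      q <- median_iqr(x)
      data.table(measure = label, median = q[1], q1 = q[2], q3 = q[3],
                 pct_above_threshold = pct_above,
                 missing_pct = 100 * mean(is.na(x)))
    }
    waist_thr <- ifelse(meas$female == 1L, 90, 85)
    shc_measures <- rbind(
      one(meas$bmi, "bmi", 100 * mean(meas$bmi >= 25, na.rm = TRUE)),
      one(meas$waist_cm, "waist_cm",
          100 * mean(meas$waist_cm >= waist_thr, na.rm = TRUE)),
      one(meas$sbp_mmhg, "sbp_mmhg"),
      one(meas$hba1c_pct, "hba1c_pct"),
      one(meas$smoker, "smoker_pct",
          100 * mean(meas$smoker, na.rm = TRUE)))
  }
  structure(list(by_arm = rbindlist(stat_rows), smd = smds,
                 shc_measures = shc_measures),
            class = "baseline_table")
}
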