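# End-to-end estimation: a prebuilt "design" (entries, covariates,
# person-periods) plus a fit function that accepts person-level draw counts,
# so the nonparametric bootstrap re-runs propensity fitting, weight
# computation and the hazard model per replicate without re-screening the
# claims tables. Frequency-weighted refits are likelihood-identical to
# duplicating resampled persons' rows; covariate selection (the prevalence
# floor) and the resource-use percentile are design steps fixed at the
# original sample.

#' Build the estimation design from a claims database
#'
#' Runs cohort construction, covariate extraction and person-period
#' expansion once, returning everything [fit_ipw_hazard()] and
#' [bootstrap_cis()] need.
#'
#' @param db a `claims_db`.
#' @param fy_range fiscal years screened for entry.
#' @param criteria an [eligibility_criteria()] object.
#' @param outdef an [outcome_definition()] (for the negative-control
#'   outcome, persons with a pre-entry negative-control diagnosis are
#'   additionally excluded at each entry).
#' @param interval `"year"` or `"month"`.
#' @param horizon_years follow-up horizon.
#' @param prevalence_floor minimum prevalence for history indicators.
#' @param admin_end_date administrative censoring date.
#' @return a list of class `emulation_design` with `entries`, `covariates`,
#'   `periods`, and the settings used.
#' @export
emulation_design <- function(db, fy_range,
                             criteria = eligibility_criteria(),
                             outdef = outcome_definition("composite"),
                             interval = "year", horizon_years = 10L,
                             prevalence_floor = 0.0001,
                             admin_end_date = NULL) {
  entries <- build_sequential_cohort(db, fy_range, criteria)
  if (!nrow(entries))
    stop("emulation_design: no eligible entries in the given years",
         call. = FALSE)
  if (identical(outdef$name, "negative_control")) {
    prev_nc <- first_outcome_dates(db, entries$person_id,
                                   rep(as.Date("1900-01-01"), nrow(entries)),
                                   outdef)
    entries <- entries[is.na(prev_nc) | prev_nc >= entry_date]
    entries[, entry_id := .I]
  }
  covariates <- baseline_covariates(db, entries,
                                    prevalence_floor = prevalence_floor)
  periods <- expand_person_periods(entries, db, outdef, interval = interval,
                                   horizon_years = horizon_years,
                                   admin_end_date = admin_end_date)
  structure(list(entries = entries, covariates = covariates,
                 periods = periods, interval = interval,
                 horizon_years = horizon_years, outdef = outdef),
            class = "emulation_design")
}

#' Fit the IPW-adjusted hazard model on a design
#'
#' Fits the propensity model, computes stabilized weights, fits the weighted
#' pooled logistic hazard model, and returns the adjusted hazard ratio,
#' standardized cumulative-incidence curves, the risk difference at the
#' horizon and the crude comparator. `draws` supplies per-person bootstrap
#' frequency counts (the full pipeline from the propensity fit onward is
#' re-run under them).
#'
#' @param design an [emulation_design()].
#' @param draws optional named-by-nothing integer vector of per-person draw
#'   counts aligned with `unique(design$entries$person_id)`, or a
#'   `data.table(person_id, draw)`.
#' @param spline a [spline_spec()].
#' @param truncate_pct optional weight-truncation percentile.
#' @param per_protocol apply inverse-probability-of-censoring weights and
#'   drop periods after a non-SHC entry's first checkup.
#' @param interaction,dose passed to [fit_pooled_logistic()].
#' @param with_crude also fit the unweighted model (skipped inside the
#'   bootstrap loop unless requested).
#' @return a list of class `estimate_result`: `hr_point`, `rd_at_horizon`,
#'   `curves`, `crude_hr`, `dose_hr_per_session` (when `dose`), the fitted
#'   models and the weight summary.
#' @export
fit_ipw_hazard <- function(design, draws = NULL, spline = spline_spec(),
                           truncate_pct = NULL, per_protocol = FALSE,
                           interaction = FALSE, dose = FALSE,
                           with_crude = TRUE) {
  entries <- design$entries
  base_w <- NULL
  if (!is.null(draws)) {
    if (is.data.frame(draws)) {
      base_w <- draws$draw[match(entries$person_id, draws$person_id)]
      base_w[is.na(base_w)] <- 0
    } else base_w <- draws
    stopifnot(length(base_w) == nrow(entries))
  }
  ps <- fit_propensity(design$covariates, base_weights = base_w)
  wset <- stabilized_weights(ps, entries, base_weights = base_w,
                             truncate_pct = truncate_pct)
  ipcw <- NULL
  if (per_protocol)
    ipcw <- ipcw_weights(design$periods, design$covariates)
  w <- period_weights(design$periods, entries, wset, ipcw = ipcw,
                      base_weights = base_w)
  model <- fit_pooled_logistic(design$periods, weights = w, spline = spline,
                               interaction = interaction, dose = dose)
  K <- min(model$k_max,
           if (design$interval == "year") design$horizon_years
           else design$horizon_years * 12L)
  out <- list(
    hr_point = if (interaction) NA_real_ else hazard_ratio(model),
    rd_at_horizon = if (dose) NA_real_ else risk_difference(model, K),
    curves = if (dose) NULL else rbind(
      cbind(arm = 1L, cumulative_incidence(model, 1, K)),
      cbind(arm = 0L, cumulative_incidence(model, 0, K))),
    dose_hr_per_session = if (dose) unname(exp(model$coefficients["dose"]))
                          else NULL,
    model = model, propensity = ps, weights = wset,
    horizon = K
  )
  if (with_crude && is.null(draws)) {
    cr <- crude_estimates(design$periods, spline = spline)
    out$crude_hr <- cr$hr
    out$crude_rd_at_horizon <- risk_difference(cr$model, min(K, cr$model$k_max))
    out$crude_curves <- rbind(
      cbind(arm = 1L, cumulative_incidence(cr$model, 1, min(K, cr$model$k_max))),
      cbind(arm = 0L, cumulative_incidence(cr$model, 0, min(K, cr$model$k_max))))
  }
  class(out) <- "estimate_result"
  out
}

#' @export
print.estimate_result <- function(x, ...) {
  cat("IPW-adjusted HR:", format(x$hr_point, digits = 4))
  if (!is.null(x$hr_ci))
    cat("  (95% CI ", format(x$hr_ci[1], digits = 4), "-",
        format(x$hr_ci[2], digits = 4), ")", sep = "")
  cat("\nRisk difference at horizon:",
      format(100 * x$rd_at_horizon, digits = 3), "%\n")
  if (!is.null(x$crude_hr))
    cat("Crude HR:", format(x$crude_hr, digits = 4), "\n")
  invisible(x)
}

#' Person-level nonparametric bootstrap confidence intervals
#'
#' Resamples unique persons with replacement (all of a person's entries and
#' periods move together, since persons appear in several nested trials and
#' periods are serially dependent) and re-runs the pipeline from the
#' propensity fit onward per replicate. Percentile 2.5/97.5 intervals for
#' the hazard ratio and the risk difference at the horizon. Replicates that
#' fail (e.g. separation) are skipped and counted; more than 10% failures is
#' an error.
#'
#' @param design an [emulation_design()].
#' @param n_reps number of replicates (>= 2; 1000 for the main analysis,
#'   200 where the computational burden is high).
#' @param seed integer seed.
#' @param ... passed to [fit_ipw_hazard()] (spline, truncation, switches).
#' @return a list of class `bootstrap_ci`: `hr_ci`, `rd_ci`, the replicate
#'   draws (`hr`, `rd`), and `n_failed`.
#' @export
bootstrap_cis <- function(design, n_reps = 200L, seed = 1L, ...) {
  if (n_reps < 2L) stop("bootstrap_cis: `n_reps` must be >= 2", call. = FALSE)
  set.seed(seed)
  persons <- unique(design$entries$person_id)
  hr <- rd <- rep(NA_real_, n_reps)
  for (r in seq_len(n_reps)) {
    idx <- sample.int(length(persons), replace = TRUE)
    cnt <- tabulate(idx, nbins = length(persons))
    dr <- data.table(person_id = persons, draw = cnt)
    res <- tryCatch(
      fit_ipw_hazard(design, draws = dr, with_crude = FALSE, ...),
      error = function(e) NULL)
    if (!is.null(res)) { hr[r] <- res$hr_point; rd[r] <- res$rd_at_horizon }
  }
  n_failed <- sum(is.na(hr))
  if (n_failed > 0.1 * n_reps)
    stop("bootstrap_cis: ", n_failed, " of ", n_reps,
         " replicates failed", call. = FALSE)
  structure(list(
    hr_ci = quantile(hr, c(0.025, 0.975), na.rm = TRUE, type = 7,
                     names = FALSE),
    rd_ci = quantile(rd, c(0.025, 0.975), na.rm = TRUE, type = 7,
                     names = FALSE),
    hr = hr, rd = rd, n_failed = n_failed, n_reps = n_reps
  ), class = "bootstrap_ci")
}
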