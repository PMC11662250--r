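# Weighted pooled logistic discrete-time hazard model, hazard ratios,
# standardized cumulative incidence, and crude comparators. Because the
# outcome model contains only treatment and functions of interval index,
# person-periods are aggregated to unique design cells before fitting, so
# fits cost the same at 10^3 or 10^7 periods.

#' Restricted cubic spline specification for the time-in-study basis
#'
#' The discrete-time hazard is modelled with a natural (restricted) cubic
#' spline of the interval index, knots placed at quantiles of the observed
#' person-period interval distribution (defaults 5/35/65/95 percent, four
#' knots giving three basis columns). With too few distinct intervals the
#' basis degrades gracefully to linear, then to intercept-only.
#'
#' @param n_knots number of knots (>= 3 for a cubic basis).
#' @param knot_quantiles quantile positions of the knots, in (0, 1).
#' @return an object of class `spline_spec`.
#' @export
spline_spec <- function(n_knots = 4L,
                        knot_quantiles = c(0.05, 0.35, 0.65, 0.95)) {
  if (length(knot_quantiles) != n_knots)
    stop("spline_spec: `knot_quantiles` must have length `n_knots`",
         call. = FALSE)
  if (is.unsorted(knot_quantiles, strictly = TRUE))
    stop("spline_spec: knot quantiles must be strictly increasing",
         call. = FALSE)
  structure(list(n_knots = as.integer(n_knots),
                 knot_quantiles = knot_quantiles),
            class = "spline_spec")
}

# Evaluate the spline basis at `k`, with knots from the reference
# distribution `ref` (defaults to `k` itself). Returns a matrix with zero or
# more columns named time1, time2, ...
spline_basis <- function(k, spec = spline_spec(), ref = k,
                         knots = NULL) {
  if (is.null(knots)) {
    knots <- unique(quantile(ref, spec$knot_quantiles, type = 7,
                             names = FALSE))
  }
  if (length(unique(k)) < 2L && length(knots) < 3L)
    return(structure(matrix(numeric(0), nrow = length(k), ncol = 0L),
                     knots = knots))
  if (length(knots) < 3L) {
    b <- matrix(as.numeric(k), ncol = 1L)
  } else {
    b <- splines::ns(k, knots = knots[2:(length(knots) - 1L)],
                     Boundary.knots = knots[c(1L, length(knots))])
    b <- unclass(b)[, , drop = FALSE]
  }
  colnames(b) <- paste0("time", seq_len(ncol(b)))
  attr(b, "knots") <- knots
  b
}

#' Fit the weighted pooled logistic discrete-time hazard model
#'
#' Solves the weighted logistic score equations for the event indicator on
#' treatment, a restricted cubic spline of interval index and, optionally, a
#' treatment-by-interval interaction (linear in interval) or the cumulative
#' checkup-dose covariate. `exp(coefficient of treatment)` is the
#' discrete-time hazard (odds) ratio, the standard hazard-ratio
#' approximation when per-interval risks are small.
#'
#' @param person_periods output of [expand_person_periods()].
#' @param weights per-period positive weights (e.g. stabilized IPW expanded
#'   to periods, times bootstrap draw counts); `NULL` for unweighted.
#' @param spline a [spline_spec()].
#' @param interaction add a treatment-by-interval (linear) interaction.
#' @param dose add `cumulative_shc_sessions` as a time-dependent covariate.
#' @param adjust_fy include trial-fiscal-year main effects (default TRUE
#'   when `person_periods` spans several entry years). The stabilized
#'   weights' numerator conditions on entry year, so entry year must appear
#'   in the outcome model; otherwise drifting arm shares and risk mix across
#'   years confound the pooled contrast. Cumulative incidence is then
#'   standardized over the weighted entry-year mix.
#' @return an object of class `hazard_model`: named coefficients
#'   (`(Intercept)`, `treated`, `time*`, optionally `treated_x_k`, `dose`,
#'   `fy*`), the spline knots, the entry-year standardization weights, fit
#'   diagnostics, and the number of person-periods.
#' @export
fit_pooled_logistic <- function(person_periods, weights = NULL,
                                spline = spline_spec(),
                                interaction = FALSE, dose = FALSE,
                                adjust_fy = TRUE) {
  pp <- person_periods
  w <- weights %||% rep(1, nrow(pp))
  stopifnot(length(w) == nrow(pp))
  ok <- !is.na(w) & w > 0
  pp <- pp[ok]; w <- w[ok]
  ev_tot <- sum(w * pp$event)
  if (ev_tot <= 0 || ev_tot >= sum(w))
    stop("fit_pooled_logistic: all-event or no-event input", call. = FALSE)

  knots <- unique(quantile(pp$k, spline$knot_quantiles, type = 7,
                           names = FALSE))
  use_fy <- adjust_fy && "trial_fy" %in% names(pp) &&
    length(unique(pp$trial_fy)) > 1L
  cell_vars <- c("treated", "k", if (dose) "cumulative_shc_sessions",
                 if (use_fy) "trial_fy")
  pp <- pp[, c(cell_vars, "event"), with = FALSE]
  pp[, row_weight := w]  # materialize: j-expressions must see a column
  cells <- pp[, .(w = sum(row_weight), wev = sum(row_weight * event)),
              by = cell_vars]
  S <- spline_basis(cells$k, spline, knots = knots)
  X <- cbind(`(Intercept)` = 1, treated = cells$treated, S)
  if (interaction) X <- cbind(X, treated_x_k = cells$treated * cells$k)
  if (dose) X <- cbind(X, dose = cells$cumulative_shc_sessions)
  fy_levels <- NULL; fy_shares <- NULL
  if (use_fy) {
    fy_levels <- sort(unique(cells$trial_fy))
    F <- stats::model.matrix(~ factor(trial_fy, levels = fy_levels),
                             data = cells)[, -1, drop = FALSE]
    colnames(F) <- paste0("fy", fy_levels[-1])
    X <- cbind(X, F)
    # standardization mix: weighted entry share per year (interval 1)
    first <- cells[k == min(k), .(w = sum(w)), by = trial_fy]
    fy_shares <- setNames(first$w / sum(first$w),
                          as.character(first$trial_fy))
    fy_shares <- fy_shares[as.character(fy_levels)]
  }
  fit <- wlogit(X, cells$wev / cells$w, w = cells$w)
  coefs <- setNames(rep(NA_real_, ncol(X)), colnames(X))
  coefs[fit$coef_names] <- fit$coef
  structure(list(coefficients = coefs, dropped = fit$dropped, knots = knots,
                 spline = spline, interaction = interaction, dose = dose,
                 fy_levels = fy_levels, fy_shares = fy_shares,
                 deviance = fit$deviance, converged = fit$converged,
                 iterations = fit$iterations,
                 n_periods = nrow(pp), k_max = max(pp$k)),
            class = "hazard_model")
}

#' @export
print.hazard_model <- function(x, ...) {
  cat("Pooled logistic hazard model on", x$n_periods, "person-periods\n")
  if (!x$interaction)
    cat("  HR (treated):", format(exp(x$coefficients["treated"])), "\n")
  invisible(x)
}

#' Hazard ratio from a fitted model
#'
#' For the constant-HR model, `exp(coefficient of treatment)`. For a model
#' with the treatment-by-interval interaction, supply `at` to get the HR as
#' a function of interval; querying a single HR from an interaction model is
#' a contract error.
#'
#' @param model a [fit_pooled_logistic()] object.
#' @param at interval indices at which to evaluate the HR (interaction
#'   models only).
#' @return a positive scalar, or a named vector over `at`.
#' @export
hazard_ratio <- function(model, at = NULL) {
  stopifnot(inherits(model, "hazard_model"))
  bA <- model$coefficients["treated"]
  if (!model$interaction) {
    if (!is.null(at))
      warning("hazard_ratio: `at` ignored for a constant-HR model")
    return(unname(exp(bA)))
  }
  if (is.null(at))
    stop("hazard_ratio: interaction model fitted; supply `at` to get HR(k)",
         call. = FALSE)
  setNames(exp(bA + model$coefficients["treated_x_k"] * at),
           paste0("k=", at))
}

#' Standardized cumulative incidence from the fitted hazard model
#'
#' `CI_a(K) = 1 - prod_{k=1..K} (1 - lambda(k; a))` with `lambda` the fitted
#' per-interval hazard under treatment `a`. With only treatment and time in
#' the weighted model this is the IPW-standardized curve.
#'
#' @param model a [fit_pooled_logistic()] object (no dose term).
#' @param arm 0 or 1.
#' @param horizon number of intervals (must not exceed the fitted range).
#' @return a `data.table` with columns `k`, `hazard`, `cuminc`.
#' @export
cumulative_incidence <- function(model, arm, horizon = model$k_max) {
  stopifnot(inherits(model, "hazard_model"), arm %in% c(0, 1))
  if (model$dose)
    stop("cumulative_incidence: not defined for the dose model", call. = FALSE)
  if (horizon > model$k_max)
    stop("cumulative_incidence: horizon ", horizon,
         " beyond fitted range (", model$k_max, ")", call. = FALSE)
  k <- seq_len(horizon)
  S <- spline_basis(k, model$spline, knots = model$knots)
  eta <- model$coefficients["(Intercept)"] +
    model$coefficients["treated"] * arm +
    drop(S %*% model$coefficients[colnames(S)])
  if (model$interaction)
    eta <- eta + model$coefficients["treated_x_k"] * arm * k
  if (is.null(model$fy_levels)) {
    lam <- plogis(eta)
    return(data.table(k = k, hazard = lam, cuminc = 1 - cumprod(1 - lam)))
  }
  # standardize over the weighted entry-year mix
  fy_coef <- c(0, model$coefficients[paste0("fy", model$fy_levels[-1])])
  cuminc <- hazard <- rep(0, horizon)
  for (j in seq_along(model$fy_levels)) {
    lam_j <- plogis(eta + fy_coef[j])
    cuminc <- cuminc + model$fy_shares[j] * (1 - cumprod(1 - lam_j))
    hazard <- hazard + model$fy_shares[j] * lam_j
  }
  data.table(k = k, hazard = hazard, cuminc = cuminc)
}

#' Risk difference at the horizon
#'
#' Treated-minus-untreated difference in model-based cumulative incidence.
#'
#' @inheritParams cumulative_incidence
#' @return a scalar in `[-1, 1]`.
#' @export
risk_difference <- function(model, horizon = model$k_max) {
  cumulative_incidence(model, 1, horizon)$cuminc[horizon] -
    cumulative_incidence(model, 0, horizon)$cuminc[horizon]
}

#' Crude (unweighted) estimates
#'
#' The default crude comparator is the unweighted pooled logistic analogue
#' of the main model. When the `survival` package is available,
#' `crude_cox_hr()` also provides the continuous-time proportional-hazards
#' estimate on entry-level follow-up (interval-valued times; Efron ties),
#' which the pooled-logistic HR approaches in the rare-event limit.
#'
#' @param person_periods output of [expand_person_periods()].
#' @param spline a [spline_spec()].
#' @return `crude_estimates`: a list with `hr` and the fitted model;
#'   `crude_cox_hr`: a positive scalar.
#' @export
crude_estimates <- function(person_periods, spline = spline_spec()) {
  # univariable analogue: treatment and time only, no entry-year adjustment
  m <- fit_pooled_logistic(person_periods, weights = NULL, spline = spline,
                           adjust_fy = FALSE)
  list(hr = hazard_ratio(m), model = m)
}

#' @rdname crude_estimates
#' @export
crude_cox_hr <- function(person_periods) {
  if (!requireNamespace("survival", quietly = TRUE))
    stop("crude_cox_hr: the `survival` package is not available",
         call. = FALSE)
  el <- person_periods[, .(time = max(k), event = max(event),
                           treated = treated[1]), by = entry_id]
  fit <- survival::coxph(survival::Surv(time, event) ~ treated, data = el)
  unname(exp(stats::coef(fit)))
}

#' Expand entry-level weights to person-periods
#'
#' Utility joining a [stabilized_weights()] set (entry-level) and optional
#' per-period censoring weights into the per-period weight vector expected
#' by [fit_pooled_logistic()].
#'
#' @param person_periods output of [expand_person_periods()].
#' @param entries the entry/covariate table the weights align with.
#' @param wset a [stabilized_weights()] object (or `NULL`).
#' @param ipcw an [ipcw_weights()] object (or `NULL`).
#' @param base_weights optional entry-level frequency weights.
#' @return a numeric vector, one element per person-period (NA where the
#'   per-protocol analysis censors the row).
#' @export
period_weights <- function(person_periods, entries, wset = NULL,
                           ipcw = NULL, base_weights = NULL) {
  sw_entry <- (if (is.null(wset)) rep(1, nrow(entries)) else wset$sw) *
    (base_weights %||% rep(1, nrow(entries)))
  w <- sw_entry[match(person_periods$entry_id, entries$entry_id)]
  if (!is.null(ipcw)) w <- w * ipcw$cw
  w
}
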