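# Propensity model, stabilized inverse-probability-of-treatment weights,
# per-protocol censoring weights, and covariate-balance diagnostics.

# Design matrix for the propensity / censoring models: age, sex, employment,
# fiscal year of entry (categorical), hospitalization and visit categories,
# and every hx_* history indicator present in the covariate table.
covariate_model_matrix <- function(cov) {
  hx <- grep("^hx_", names(cov), value = TRUE)
  terms <- c("age", "female", "employed",
             if (length(unique(cov$trial_fy)) > 1L) "factor(trial_fy)",
             if (length(levels(droplevels(cov$hosp_cat))) > 1L) "hosp_cat",
             if (length(levels(droplevels(cov$visit_cat))) > 1L) "visit_cat",
             hx)
  f <- stats::as.formula(paste("~", paste(terms, collapse = " + ")))
  stats::model.matrix(f, data = cov)
}

#' Fit the propensity model for checkup participation
#'
#' Maximum-likelihood logistic regression of arm assignment on the baseline
#' covariates, pooled across trials with the fiscal year of entry as a
#' covariate. Constant and collinear columns are dropped (reported in the
#' diagnostics), and fitted probabilities outside `[1e-8, 1 - 1e-8]` raise a
#' separation flag.
#'
#' @param covariates a [baseline_covariates()] table (or any data.frame with
#'   the same columns).
#' @param arm arm labels; defaults to `covariates$arm`. `"SHC"` is the
#'   treated level.
#' @param base_weights optional nonnegative per-entry frequency weights
#'   (used by the person-level bootstrap).
#' @return an object of class `propensity_model`: coefficients, fitted
#'   probabilities, and convergence / separation diagnostics.
#' @export
fit_propensity <- function(covariates, arm = NULL, base_weights = NULL) {
  arm <- arm %||% covariates$arm
  a <- as.integer(arm == "SHC")
  tab <- table(factor(a, levels = 0:1))
  if (any(tab == 0L))
    stop("fit_propensity: need entries in both arms (SHC = ", tab["1"],
         ", non-SHC = ", tab["0"], ")", call. = FALSE)
  X <- covariate_model_matrix(covariates)
  fit <- wlogit(X, a, w = base_weights)
  structure(list(
    coefficients = setNames(fit$coef, fit$coef_names),
    dropped_columns = fit$dropped,
    fitted = fit$fitted,
    iterations = fit$iterations,
    converged = fit$converged,
    max_score = fit$max_score,
    separation = fit$separation,
    arm = a
  ), class = "propensity_model")
}

#' @export
print.propensity_model <- function(x, ...) {
  cat("Propensity model:", length(x$coefficients), "coefficients,",
      x$iterations, "IRLS iterations",
      if (x$separation) "(separation flagged)" else "", "\n")
  invisible(x)
}

#' Stabilized inverse-probability-of-treatment weights
#'
#' For entry i with arm a and covariates L, `sw_i = P(A = a | trial year) /
#' P(A = a | L)`: the numerator is the (weighted) arm fraction within the
#' entry's fiscal year, the denominator the fitted propensity `e(L)` or
#' `1 - e(L)`. Stabilization keeps the weight mean near 1 within each
#' arm-by-year stratum; optional symmetric percentile truncation is
#' available but off by default.
#'
#' @param model a [fit_propensity()] object fitted on these entries.
#' @param entries the covariate/entry table the model was fitted on (needs
#'   `trial_fy`).
#' @param base_weights optional frequency weights (bootstrap draws).
#' @param truncate_pct optional percentile `p` in (0, 50); weights are capped
#'   at their `p` and `100 - p` percentiles.
#' @return a list of class `weight_set`: `sw`, `ps`, and a `summary` table.
#' @export
stabilized_weights <- function(model, entries, base_weights = NULL,
                               truncate_pct = NULL) {
  stopifnot(inherits(model, "propensity_model"))
  a <- model$arm
  ps <- model$fitted
  if (any((a == 1L & ps <= 0) | (a == 0L & ps >= 1)))
    stop("stabilized_weights: fitted probability of 0/1 for an observed arm ",
         "(separation)", call. = FALSE)
  bw <- base_weights %||% rep(1, length(a))
  num1 <- stats::ave(a * bw, entries$trial_fy, FUN = sum) /
    stats::ave(bw, entries$trial_fy, FUN = sum)
  num <- ifelse(a == 1L, num1, 1 - num1)
  den <- ifelse(a == 1L, ps, 1 - ps)
  sw <- num / den
  if (!is.null(truncate_pct)) {
    bounds <- quantile(sw, c(truncate_pct, 100 - truncate_pct) / 100,
                       type = 7, names = FALSE)
    sw <- pmin(pmax(sw, bounds[1]), bounds[2])
  }
  structure(list(
    sw = sw, ps = ps,
    summary = c(mean = mean(sw), max = max(sw),
                quantile(sw, c(0.01, 0.5, 0.99), names = TRUE))
  ), class = "weight_set")
}

#' Standardized mean difference
#'
#' `smd_from_props(p1, p0)` evaluates the binary-covariate formula
#' `|p1 - p0| / sqrt((p1(1-p1) + p0(1-p0)) / 2)` from two group proportions;
#' `smd_from_moments(m1, v1, m0, v0)` the continuous analogue
#' `|m1 - m0| / sqrt((v1 + v0)/2)`; and `smd(x, group, weights)` computes
#' either from microdata (binary when `x` takes only values 0/1), optionally
#' weighted. All return the absolute value; a zero pooled variance with a
#' nonzero difference returns `Inf` with a warning.
#'
#' @param p1,p0 group proportions in `[0, 1]`.
#' @param m1,m0 group means; `v1,v0` group variances.
#' @param x a numeric vector; `group` a two-level grouping (the treated /
#'   first level is whichever sorts last, but the result is symmetric).
#' @param weights optional nonnegative weights.
#' @return a nonnegative scalar.
#' @examples
#' smd_from_props(0.627, 0.820)  # 0.44 to 2 dp
#' smd_from_props(0.580, 0.262)  # 0.68 to 2 dp
#' @export
smd_from_props <- function(p1, p0) {
  stopifnot(p1 >= 0, p1 <= 1, p0 >= 0, p0 <= 1)
  smd_from_moments(p1, p1 * (1 - p1), p0, p0 * (1 - p0))
}

#' @rdname smd_from_props
#' @export
smd_from_moments <- function(m1, v1, m0, v0) {
  pooled <- (v1 + v0) / 2
  if (pooled <= 0) {
    if (abs(m1 - m0) < .Machine$double.eps^0.5) return(0)
    warning("smd: zero pooled variance with nonzero difference; returning Inf")
    return(Inf)
  }
  abs(m1 - m0) / sqrt(pooled)
}

#' @rdname smd_from_props
#' @export
smd <- function(x, group, weights = NULL) {
  g <- as.integer(factor(group))
  stopifnot(length(unique(g[!is.na(g)])) == 2L)
  w <- weights %||% rep(1, length(x))
  mom <- function(lvl) {
    i <- which(g == lvl & !is.na(x))
    m <- weighted.mean(x[i], w[i])
    v <- sum(w[i] * (x[i] - m)^2) / sum(w[i])
    c(m, v)
  }
  a <- mom(2L); b <- mom(1L)
  is_binary <- all(x %in% c(0, 1, NA))
  if (is_binary) smd_from_props(a[1], b[1]) else
    smd_from_moments(a[1], a[2], b[1], b[2])
}

#' Covariate balance before and after weighting
#'
#' Expands the covariates into the propensity design matrix (dropping the
#' intercept) and reports the unweighted and weighted absolute standardized
#' mean difference between arms for every column, flagging any weighted
#' |SMD| at or above 0.1.
#'
#' @param covariates a [baseline_covariates()] table.
#' @param arm arm labels; defaults to `covariates$arm`.
#' @param weights a [stabilized_weights()] object or a numeric vector.
#' @return a `data.table` (covariate, smd_unweighted, smd_weighted, flag)
#'   with attribute `balanced` (TRUE when all weighted |SMD| < 0.1).
#' @export
balance_report <- function(covariates, arm = NULL, weights = NULL) {
  arm <- arm %||% covariates$arm
  sw <- if (inherits(weights, "weight_set")) weights$sw else
    weights %||% rep(1, length(arm))
  X <- covariate_model_matrix(covariates)[, -1, drop = FALSE]
  res <- data.table(
    covariate = colnames(X),
    smd_unweighted = apply(X, 2, smd, group = arm),
    smd_weighted = apply(X, 2, smd, group = arm, weights = sw))
  res[, flag := smd_weighted >= 0.1]
  setattr(res, "balanced", all(res$smd_weighted < 0.1))
  res[]
}

#' Inverse-probability-of-censoring weights for the per-protocol analysis
#'
#' Non-SHC entries are artificially censored at the interval of their first
#' checkup. A pooled logistic model for remaining uncensored per interval —
#' on the baseline covariates and a restricted cubic spline of interval
#' index — gives conditional uncensoring probabilities; the per-period
#' weight is the stabilized cumulative product, with the numerator from an
#' intercept-plus-spline-only model. SHC-arm periods get weight 1. Periods
#' from the deviation interval onward receive `NA` (they are excluded from
#' the per-protocol fit).
#'
#' @param person_periods output of [expand_person_periods()] (must carry
#'   `still_in_non_shc_protocol`).
#' @param covariates the [baseline_covariates()] table for the same entries.
#' @param spline a [spline_spec()].
#' @return a list of class `ipcw_set`: `cw` (per-period weight aligned with
#'   `person_periods` rows), plus both fitted models' diagnostics.
#' @export
ipcw_weights <- function(person_periods, covariates,
                         spline = spline_spec()) {
  pp <- person_periods
  stopifnot("still_in_non_shc_protocol" %in% names(pp))
  cw <- rep(1, nrow(pp))
  non_idx <- which(pp$arm == "non-SHC")
  if (!length(non_idx) || all(pp$still_in_non_shc_protocol[non_idx] == 1L)) {
    message("ipcw_weights: no artificial censoring events; all weights 1")
    return(structure(list(cw = cw, denominator_model = NULL,
                          numerator_model = NULL), class = "ipcw_set"))
  }
  non <- pp[non_idx, .(entry_id, k, still_in_non_shc_protocol)]
  # at risk of censoring at interval k: no deviation before k
  first_dev <- non[still_in_non_shc_protocol == 0L, .(k_dev = min(k)),
                   by = entry_id]
  non[, k_dev := first_dev[non, on = "entry_id", x.k_dev]]
  at_risk <- is.na(non$k_dev) | non$k <= non$k_dev
  y_uncens <- as.numeric(is.na(non$k_dev) | non$k < non$k_dev)

  Xc <- covariate_model_matrix(covariates)
  rows <- match(non$entry_id, covariates$entry_id)
  S <- spline_basis(non$k, spline, pp$k)
  Xden <- cbind(Xc[rows, , drop = FALSE], S)
  den_fit <- wlogit(Xden[at_risk, , drop = FALSE], y_uncens[at_risk])
  num_fit <- wlogit(cbind(1, S)[at_risk, , drop = FALSE], y_uncens[at_risk])

  p_den <- p_num <- rep(NA_real_, nrow(non))
  p_den[at_risk] <- den_fit$fitted
  p_num[at_risk] <- num_fit$fitted
  ratio <- ifelse(at_risk, p_num / p_den, NA_real_)
  non[, w := ratio]
  non[, cw := cumprod(ifelse(is.na(w), 1, w)), by = entry_id]
  w_out <- ifelse(non$still_in_non_shc_protocol == 1L, non$cw, NA_real_)
  cw[non_idx] <- w_out
  structure(list(cw = cw,
                 denominator_model = den_fit[c("iterations", "converged",
                                               "separation")],
                 numerator_model = num_fit[c("iterations", "converged")]),
            class = "ipcw_set")
}
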