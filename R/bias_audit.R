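# Negative-control outcome run, bias-calibrated hazard ratio, HR-to-RR
# conversion for common (non-rare) outcomes, and E-values.

#' Bias-calibrated hazard ratio
#'
#' Divides the primary HR by the negative-control HR on the log scale. With
#' both 95% CIs supplied, each standard error is recovered as
#' `(log(upper) - log(lower)) / (2 * 1.96)` and the calibrated interval is
#' `log(point) +/- 1.96 * sqrt(SE_p^2 + SE_nc^2)` (independent-variance
#' combination).
#'
#' @param hr_primary,hr_nc positive hazard ratios.
#' @param ci_primary,ci_nc optional length-2 intervals containing their
#'   points.
#' @return a list with `hr` and (when both CIs are given) `ci`.
#' @examples
#' calibrate_hr(0.90, hr_nc = 1.05)$hr  # 0.857..., i.e. 0.86 at 2 dp
#' @export
calibrate_hr <- function(hr_primary, ci_primary = NULL, hr_nc,
                         ci_nc = NULL) {
  if (hr_primary <= 0 || hr_nc <= 0)
    stop("calibrate_hr: hazard ratios must be positive", call. = FALSE)
  chk_ci <- function(ci, point, nm) {
    if (is.null(ci)) return(invisible())
    if (length(ci) != 2L || any(ci <= 0) || ci[1] > ci[2])
      stop("calibrate_hr: `", nm, "` must be a positive interval",
           call. = FALSE)
    if (ci[1] > point || ci[2] < point)
      warning("calibrate_hr: `", nm, "` does not contain its point ",
              "estimate; the interval width is still used for the SE",
              call. = FALSE)
  }
  chk_ci(ci_primary, hr_primary, "ci_primary")
  chk_ci(ci_nc, hr_nc, "ci_nc")
  point <- hr_primary / hr_nc
  out <- list(hr = point)
  if (!is.null(ci_primary) && !is.null(ci_nc)) {
    se_p <- (log(ci_primary[2]) - log(ci_primary[1])) / (2 * 1.96)
    se_nc <- (log(ci_nc[2]) - log(ci_nc[1])) / (2 * 1.96)
    half <- 1.96 * sqrt(se_p^2 + se_nc^2)
    out$ci <- exp(log(point) + c(-1, 1) * half)
  }
  out
}

#' Approximate risk ratio for a common outcome
#'
#' The square-root conversion `RR = (1 - 0.5^sqrt(HR)) / (1 -
#' 0.5^sqrt(1/HR))`, appropriate when the outcome is not rare; it compresses
#' the HR toward 1, fixes 1, and maps reciprocal HRs to reciprocal RRs.
#'
#' @param hr a positive hazard ratio.
#' @return a positive risk ratio.
#' @export
hr_to_rr_common <- function(hr) {
  if (any(hr <= 0)) stop("hr_to_rr_common: `hr` must be positive",
                         call. = FALSE)
  (1 - 0.5^sqrt(hr)) / (1 - 0.5^sqrt(1 / hr))
}

#' E-value for an observed risk ratio
#'
#' The minimum strength of association, on the risk-ratio scale, that an
#' unmeasured confounder would need with both exposure and outcome to fully
#' explain away the observed association: with `RR* = max(rr, 1/rr)`,
#' `E = RR* + sqrt(RR* (RR* - 1))`. `e_value_ci_bound()` applies the formula
#' to the confidence limit closest to the null, returning `Inf` when the
#' interval crosses 1 (no finite confounder strength is excluded).
#'
#' @param rr a positive risk ratio.
#' @param ci a length-2 risk-ratio confidence interval.
#' @return a value >= 1 (`e_value`), or >= 1 / `Inf` (`e_value_ci_bound`).
#' @examples
#' e_value(2)  # 2 + sqrt(2) = 3.414
#' @export
e_value <- function(rr) {
  if (any(rr <= 0)) stop("e_value: `rr` must be positive", call. = FALSE)
  rr_star <- pmax(rr, 1 / rr)
  rr_star + sqrt(rr_star * (rr_star - 1))
}

#' @rdname e_value
#' @export
e_value_ci_bound <- function(ci) {
  stopifnot(length(ci) == 2L)
  if (any(ci <= 0)) stop("e_value_ci_bound: limits must be positive",
                         call. = FALSE)
  if (ci[1] <= 1 && ci[2] >= 1) return(Inf)
  e_value(ci[which.min(abs(log(ci)))])
}

#' Re-run the pipeline with the negative-control outcome
#'
#' Builds a fresh design with the depression-style negative-control outcome
#' (drug conjunction off, prevalent negative-control cases excluded at
#' entry) and fits the IPW-adjusted model. A non-null negative-control HR
#' signals residual bias from selection or unmeasured confounding.
#'
#' @param db a `claims_db`.
#' @param fy_range fiscal years screened for entry.
#' @param criteria an [eligibility_criteria()].
#' @param ... passed to [emulation_design()] / [fit_ipw_hazard()].
#' @return an `estimate_result` (see [fit_ipw_hazard()]).
#' @export
negative_control_run <- function(db, fy_range,
                                 criteria = eligibility_criteria(), ...) {
  design <- emulation_design(db, fy_range, criteria,
                             outdef = outcome_definition("negative_control"),
                             ...)
  fit_ipw_hazard(design)
}

#' Assemble the bias audit
#'
#' Combines a primary and a negative-control estimate into the calibrated
#' HR, the common-outcome risk-ratio approximation, and point and
#' confidence-bound E-values.
#'
#' @param hr_primary,ci_primary primary HR and its 95% CI.
#' @param hr_nc,ci_nc negative-control HR and its 95% CI.
#' @param outcome_rare use the rare-outcome shortcut (RR = HR) instead of
#'   the square-root conversion; default FALSE, matching a common composite
#'   outcome.
#' @return a list of class `bias_audit_result`: `hr_negative_control`,
#'   `hr_calibrated` (with CI when both CIs are supplied), `rr_approx`,
#'   `e_value_point`, `e_value_ci_bound`.
#' @export
bias_audit <- function(hr_primary, ci_primary = NULL, hr_nc, ci_nc = NULL,
                       outcome_rare = FALSE) {
  cal <- calibrate_hr(hr_primary, ci_primary, hr_nc, ci_nc)
  to_rr <- if (outcome_rare) identity else hr_to_rr_common
  rr <- to_rr(cal$hr)
  ev_ci <- if (!is.null(cal$ci)) e_value_ci_bound(to_rr(cal$ci)) else NA_real_
  structure(list(
    hr_negative_control = hr_nc, nc_ci = ci_nc,
    hr_calibrated = cal$hr, hr_calibrated_ci = cal$ci,
    rr_approx = rr,
    e_value_point = e_value(rr),
    e_value_ci_bound = ev_ci
  ), class = "bias_audit_result")
}

#' @export
print.bias_audit_result <- function(x, ...) {
  cat("Negative-control HR:", format(x$hr_negative_control, digits = 4), "\n")
  cat("Bias-calibrated HR:", format(x$hr_calibrated, digits = 4))
  if (!is.null(x$hr_calibrated_ci))
    cat("  (95% CI ", format(x$hr_calibrated_ci[1], digits = 4), "-",
        format(x$hr_calibrated_ci[2], digits = 4), ")", sep = "")
  cat("\nApproximate RR:", format(x$rr_approx, digits = 4),
      "  E-value:", format(x$e_value_point, digits = 4), "\n")
  invisible(x)
}
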