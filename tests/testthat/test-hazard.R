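# Build person-period tables with exact cell counts, so closed-form
# expectations hold without simulation error.
exact_periods <- function(n_by_arm, K, events_by_arm_k, fy = 2015L) {
  rows <- list()
  id <- 0L
  for (a in seq_along(n_by_arm)) {
    arm <- names(n_by_arm)[a]
    treated <- as.integer(arm == "SHC")
    # persons who reach each k: those with later events or never
    ev_k <- events_by_arm_k[[a]]
    n <- n_by_arm[[a]]
    # construct individual event times so each cell has its exact count
    times <- rep(Inf, n)
    at_risk <- seq_len(n)
    for (k in seq_len(K)) {
      ev <- head(at_risk, ev_k[k])
      times[ev] <- k
      at_risk <- setdiff(at_risk, ev)
    }
    for (i in seq_len(n)) {
      id <- id + 1L
      last <- min(times[i], K)
      rows[[id]] <- data.table(
        entry_id = id, person_id = id, trial_fy = fy, arm = arm,
        treated = treated, k = seq_len(last),
        event = as.integer(seq_len(last) == times[i]),
        censored = as.integer(seq_len(last) == K & times[i] > K),
        still_in_non_shc_protocol = 1L, cumulative_shc_sessions = 0L)
    }
  }
  rbindlist(rows)
}

test_that("intercept-only fit returns the weighted event fraction", {
  pp <- data.table(entry_id = 1:100, person_id = 1:100, trial_fy = 2015L,
                   arm = "non-SHC", treated = 0L, k = 1L,
                   event = rep(c(1L, 0L), c(20, 80)),
                   censored = rep(c(0L, 1L), c(20, 80)),
                   still_in_non_shc_protocol = 1L,
                   cumulative_shc_sessions = 0L)
  w <- rep(c(2, 1), c(50, 50))
  m <- fit_pooled_logistic(pp, weights = w)
  frac <- sum(w * pp$event) / sum(w)
  expect_equal(plogis(m$coefficients[["(Intercept)"]]), frac,
               tolerance = 1e-8)
})

test_that("two constant-hazard arms recover the exact odds ratio", {
  # h1 = 0.02, h0 = 0.025 represented exactly through fractional weights:
  # per (arm, k) one event row with mass n_k h and one survivor row with
  # mass n_k (1 - h), n_k the geometric risk set
  K <- 4
  mk_cells <- function(arm, treated, h, n0) {
    rbindlist(lapply(seq_len(K), function(k) {
      nk <- n0 * (1 - h)^(k - 1)
      data.table(entry_id = 0L, person_id = 0L, trial_fy = 2015L, arm = arm,
                 treated = treated, k = k, event = c(1L, 0L),
                 censored = 0L, still_in_non_shc_protocol = 1L,
                 cumulative_shc_sessions = 0L, w = nk * c(h, 1 - h))
    }))
  }
  pp <- rbind(mk_cells("SHC", 1L, 0.02, 4000),
              mk_cells("non-SHC", 0L, 0.025, 4000))
  m <- fit_pooled_logistic(pp, weights = pp$w)
  expect_equal(hazard_ratio(m),
               (0.02 / 0.98) / (0.025 / 0.975), tolerance = 1e-6)
})

test_that("integer weights are equivalent to duplicated rows", {
  sim <- shared_sim()
  design <- emulation_design(sim$db, 2012:2013)
  pp <- design$periods
  set.seed(99)
  w <- sample(1:3, nrow(pp), replace = TRUE)
  m1 <- fit_pooled_logistic(pp, weights = w)
  pp_dup <- pp[rep(seq_len(.N), w)]
  m2 <- fit_pooled_logistic(pp_dup)
  expect_equal(m1$coefficients, m2$coefficients, tolerance = 1e-8)
})

test_that("hazard_ratio transforms the treatment coefficient", {
  base <- list(coefficients = c(`(Intercept)` = -3, treated = 0),
               interaction = FALSE)
  class(base) <- "hazard_model"
  expect_equal(hazard_ratio(base), 1)
  base$coefficients["treated"] <- log(0.9)
  expect_equal(hazard_ratio(base), 0.9)
  inter <- base
  inter$interaction <- TRUE
  inter$coefficients <- c(inter$coefficients, treated_x_k = 0.05)
  expect_error(hazard_ratio(inter), "interaction")
  hrk <- hazard_ratio(inter, at = c(1, 2))
  expect_equal(unname(hrk), 0.9 * exp(0.05 * c(1, 2)))
})

test_that("cumulative incidence matches the constant-hazard closed form", {
  m <- structure(list(
    coefficients = c(`(Intercept)` = qlogis(0.1), treated = 0, time1 = 0),
    knots = c(1, 10), spline = spline_spec(), interaction = FALSE,
    dose = FALSE, fy_levels = NULL, k_max = 10L), class = "hazard_model")
  ci <- cumulative_incidence(m, arm = 0, horizon = 10)
  expect_equal(ci$cuminc[10], 1 - 0.9^10, tolerance = 1e-12)
  expect_equal(ci$hazard, rep(0.1, 10))
  expect_equal(risk_difference(m, 10), 0)
  expect_error(cumulative_incidence(m, 0, horizon = 11), "beyond")
  # monotone and bounded
  expect_true(all(diff(ci$cuminc) > 0))
  expect_true(all(ci$cuminc >= 0 & ci$cuminc <= 1))
})

test_that("fitted curves stay monotone and bounded on simulated data", {
  sim <- shared_sim()
  design <- emulation_design(sim$db, 2011:2014)
  est <- fit_ipw_hazard(design)
  for (a in 0:1) {
    cv <- est$curves[arm == a]
    expect_true(all(diff(cv$cuminc) >= 0))
    expect_true(all(cv$cuminc >= 0 & cv$cuminc <= 1))
  }
  expect_equal(est$rd_at_horizon,
               est$curves[arm == 1, max(cuminc)] -
                 est$curves[arm == 0, max(cuminc)])
})

test_that("curves track the empirical cumulative incidence without censoring", {
  # unconfounded, no disenrollment, single entry year: the model-based curve
  # should match the nonparametric event fraction
  conf0 <- lapply(default_confounders(), function(s) {
    s$beta_uptake <- 0; s$beta_outcome <- 0; s$beta_nc <- 0; s
  })
  cfg <- sim_config(n_persons = 8000, fy_start = 2010, fy_end = 2010,
                    admin_end_fy = 2019, annual_disenroll_prob = 0,
                    prevalent_fraction = 0, confounder_spec = conf0,
                    uptake_intercept = -0.5, seed = 303)
  db <- generate_population(cfg)
  design <- emulation_design(db, 2010, horizon_years = 9L)
  est <- fit_ipw_hazard(design)
  pp <- design$periods
  emp <- pp[, .(events = sum(event), n1 = sum(k == 1)), by = treated]
  for (a in 0:1) {
    emp_ci <- emp[treated == a, events / n1]
    mod_ci <- est$curves[arm == a, max(cuminc)]
    expect_lt(abs(mod_ci - emp_ci), 2.5 * sqrt(emp_ci * (1 - emp_ci) /
                                                 emp[treated == a, n1]))
  }
})

test_that("pooled-logistic crude HR approaches the Cox estimate for rare events", {
  skip_if_not_installed("survival")
  sim <- shared_sim()
  design <- emulation_design(sim$db, 2011:2015)
  cr <- crude_estimates(design$periods)
  cox <- crude_cox_hr(design$periods)
  expect_lt(abs(log(cr$hr) - log(cox)), log(1.02))
})

test_that("bootstrap intervals are deterministic given the seed", {
  cfg <- sim_config(n_persons = 1500, seed = 12)
  db <- generate_population(cfg)
  design <- emulation_design(db, 2011:2014)
  b1 <- bootstrap_cis(design, n_reps = 15, seed = 4)
  b2 <- bootstrap_cis(design, n_reps = 15, seed = 4)
  expect_identical(b1$hr_ci, b2$hr_ci)
  expect_identical(b1$rd_ci, b2$rd_ci)
  b3 <- bootstrap_cis(design, n_reps = 15, seed = 5)
  expect_false(identical(b1$hr_ci, b3$hr_ci))
  expect_true(b1$hr_ci[1] <= b1$hr_ci[2])
  expect_equal(b1$n_failed, 0)
})

test_that("dose model reports a per-session hazard ratio", {
  sim <- shared_sim()
  design <- emulation_design(sim$db, 2011:2014)
  est <- fit_ipw_hazard(design, dose = TRUE)
  expect_true(is.finite(est$dose_hr_per_session))
  expect_gt(est$dose_hr_per_session, 0)
  expect_error(cumulative_incidence(est$model, 1), "dose")
})

test_that("interaction model exposes a time-varying hazard ratio", {
  sim <- shared_sim()
  design <- emulation_design(sim$db, 2011:2014)
  est <- fit_ipw_hazard(design, interaction = TRUE)
  hrk <- hazard_ratio(est$model, at = 1:5)
  expect_length(hrk, 5)
  expect_true(all(is.finite(hrk) & hrk > 0))
})
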