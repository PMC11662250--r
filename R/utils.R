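# Fiscal-year conventions: Japanese fiscal year y runs April 1 of calendar
# year y through March 31 of y+1. All dates are `Date` (day resolution),
# intervals half-open [start, end).

#' Fiscal-year date helpers
#'
#' `fy_start_date(fy)` returns April 1 of fiscal year `fy`; `fy_end_date(fy)`
#' returns the last covered day, March 31 of `fy + 1`; `fiscal_year(date)`
#' maps a date to the fiscal year containing it.
#'
#' @param fy integer fiscal year(s), labelled by the calendar year of April 1.
#' @param date a `Date` vector.
#' @return `Date` or integer vector, matching the input length.
#' @examples
#' fy_start_date(2015)          # "2015-04-01"
#' fiscal_year(as.Date("2016-03-31"))  # 2015
#' @export
fy_start_date <- function(fy) as.Date(paste0(as.integer(fy), "-04-01"))

#' @rdname fy_start_date
#' @export
fy_end_date <- function(fy) fy_start_date(as.integer(fy) + 1L) - 1L

#' @rdname fy_start_date
#' @export
fiscal_year <- function(date) {
  date <- as.Date(date)
  data.table::year(date) - (data.table::month(date) < 4L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Age in completed years at `at` for birth date `birth`.
age_in_years <- function(birth, at) {
  yb <- data.table::year(birth); ya <- data.table::year(at)
  mb <- data.table::month(birth) * 100L + data.table::mday(birth)
  ma <- data.table::month(at) * 100L + data.table::mday(at)
  ya - yb - (ma < mb)
}

# --- weighted logistic regression ------------------------------------------
#
# IRLS fit of a binomial logit model; `y` may be an event fraction in [0, 1]
# with prior weight `w` (so aggregated person-period cells fit the same
# likelihood as row-level data). Rank-deficient columns are dropped (pivoted
# QR), mirroring glm's aliasing behaviour; a small ridge is applied only if
# the weighted information matrix is numerically singular.
wlogit <- function(X, y, w = NULL, max_iter = 100L, tol = 1e-10) {
  X <- as.matrix(X)
  if (is.null(w)) w <- rep(1, length(y))
  stopifnot(nrow(X) == length(y), length(w) == length(y))
  X_all <- X
  keep_rows <- which(w > 0)
  if (length(keep_rows) < nrow(X)) {
    X <- X[keep_rows, , drop = FALSE]; y <- y[keep_rows]; w <- w[keep_rows]
  }

  qx <- qr(X * sqrt(w))
  dropped <- character(0)
  if (qx$rank < ncol(X)) {
    use <- sort(qx$pivot[seq_len(qx$rank)])
    dropped <- colnames(X)[setdiff(seq_len(ncol(X)), use)]
    X <- X[, use, drop = FALSE]
  }

  p <- ncol(X)
  beta <- numeric(p)
  if (all(X[, 1L] == 1)) {
    mu0 <- min(max(weighted.mean(y, w), 1e-8), 1 - 1e-8)
    beta[1L] <- qlogis(mu0)
  }
  dev_fun <- function(mu) {
    mu <- pmin(pmax(mu, 1e-15), 1 - 1e-15)
    -2 * sum(w * (y * log(mu) + (1 - y) * log1p(-mu)))
  }
  eta <- drop(X %*% beta)
  dev <- dev_fun(plogis(eta))
  converged <- FALSE
  it <- 0L
  max_score <- Inf
  while (it < max_iter) {
    it <- it + 1L
    mu <- plogis(eta)
    mu_c <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
    score <- drop(crossprod(X, w * (y - mu)))
    info <- crossprod(X, X * (w * mu_c * (1 - mu_c)))
    step <- tryCatch(solve(info, score), error = function(e) NULL)
    if (is.null(step)) {
      diag(info) <- diag(info) + 1e-8 * max(diag(info), 1)
      step <- solve(info, score)
    }
    # step-halving keeps the deviance monotone under quasi-separation
    lambda <- 1
    repeat {
      beta_new <- beta + lambda * step
      eta_new <- drop(X %*% beta_new)
      dev_new <- dev_fun(plogis(eta_new))
      if (is.finite(dev_new) && dev_new <= dev + 1e-8) break
      lambda <- lambda / 2
      if (lambda < 1e-10) { beta_new <- beta; eta_new <- eta; dev_new <- dev; break }
    }
    delta <- abs(dev - dev_new)
    beta <- beta_new; eta <- eta_new; dev <- dev_new
    max_score <- max(abs(score))
    if (delta < tol * (abs(dev) + 0.1)) { converged <- TRUE; break }
  }
  mu <- plogis(eta)
  # predictions for every input row, including zero-weight ones
  fitted_all <- if (length(keep_rows) < nrow(X_all)) {
    use_cols <- match(colnames(X), colnames(X_all))
    plogis(drop(X_all[, use_cols, drop = FALSE] %*% beta))
  } else mu
  list(coef = beta, coef_names = colnames(X), dropped = dropped,
       fitted = fitted_all, deviance = dev, iterations = it,
       converged = converged, max_score = max_score,
       separation = any(mu < 1e-8 | mu > 1 - 1e-8))
}

# Linear-interpolation quantiles (stats type 7), the package-wide convention
# for medians and IQRs.
median_iqr <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(c(median = NA_real_, q1 = NA_real_, q3 = NA_real_))
  q <- quantile(x, c(0.5, 0.25, 0.75), names = FALSE, type = 7)
  c(median = q[1], q1 = q[2], q3 = q[3])
}
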