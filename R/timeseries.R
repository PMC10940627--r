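# ARIMA detrending and residual cross-correlation ----------------------------
#
# Environmental series (temperature, CO2) and disparity medians sampled on a
# uniform 10-Ma grid are strongly autocorrelated; correlating them raw would
# be spurious. Each series is therefore reduced to the residuals of an
# ARIMA(p,d,q) fit — the order chosen by AICc over a small grid for the
# driver, then imposed on the response — and the residual series are
# compared by normalised cross-correlation.
#
# Differencing is applied explicitly: the series is differenced d times and
# an ARMA(p,q) with mean is fitted to the result (stats::arima, CSS-ML), so
# residuals have length n - d and a (0,1,0) fit leaves the first differences
# minus their mean.

arima_aicc <- function(fit, n) {
  k <- length(fit$coef) + 1 # + sigma^2
  aicc <- -2 * fit$loglik + 2 * k + if (n - k - 1 > 0) 2 * k * (k + 1) / (n - k - 1) else Inf
  aicc
}

fit_arma_once <- function(y, p, q) {
  suppressWarnings(
    stats::arima(y, order = c(p, 0L, q), include.mean = TRUE, method = "CSS-ML")
  )
}

#' Fit an ARIMA model with fixed order
#'
#' @param x Numeric series on a uniform grid, no gaps.
#' @param order Integer vector `c(p, d, q)`.
#' @return Object of class `arima_fit`: `order`, `coefficients`,
#'   `residuals` (length `length(x) - d`), `loglik`, `AICc`.
#' @export
fit_arima_fixed <- function(x, order) {
  x <- as.numeric(x)
  if (length(order) != 3L || any(order < 0)) stop("'order' must be c(p, d, q) >= 0")
  p <- order[1]; d <- order[2]; q <- order[3]
  if (length(x) - d < max(8L, p + q + 2L)) stop("series too short for this order")
  if (stats::sd(x) == 0) {
    if (p == 0 && d == 0 && q == 0)
      return(structure(list(order = c(0L, 0L, 0L),
                            coefficients = c(intercept = x[1]),
                            residuals = rep(0, length(x)),
                            loglik = NA_real_, AICc = NA_real_),
                       class = "arima_fit"))
    stop("constant series: only order (0,0,0) is identifiable")
  }
  y <- if (d > 0) diff(x, differences = d) else x
  fit <- tryCatch(fit_arma_once(y, p, q),
                  error = function(e) stop("ARIMA fit failed for order (",
                                           paste(order, collapse = ","), "): ",
                                           conditionMessage(e), call. = FALSE))
  if (p > 0 && any(Mod(polyroot(c(1, -fit$coef[seq_len(p)]))) < 1 + 1e-8))
    stop("non-stationary AR fit for order (", paste(order, collapse = ","), ")")
  structure(list(order = as.integer(order),
                 coefficients = fit$coef,
                 residuals = as.numeric(stats::residuals(fit)),
                 loglik = fit$loglik,
                 AICc = arima_aicc(fit, length(y))),
            class = "arima_fit")
}

#' Select and fit an ARIMA model by AICc grid search
#'
#' Fits every order with `p` in 0..3, `d` in 0..2, `q` in 0..3 (orders whose
#' estimation fails are skipped) and keeps the smallest-AICc fit. A constant
#' series yields the mean-only (0,0,0) model with zero residuals.
#'
#' @param x Numeric series, length >= 8, on a uniform grid with no gaps.
#' @param max_p,max_d,max_q Grid limits.
#' @return An `arima_fit` (see [fit_arima_fixed()]).
#' @export
fit_arima_auto <- function(x, max_p = 3L, max_d = 2L, max_q = 3L) {
  x <- as.numeric(x)
  if (length(x) < 8L) stop("series too short (need >= 8 points)")
  if (anyNA(x)) stop("series has gaps")
  if (stats::sd(x) == 0) return(fit_arima_fixed(x, c(0L, 0L, 0L)))
  best <- NULL
  for (d in 0:max_d) for (p in 0:max_p) for (q in 0:max_q) {
    cand <- tryCatch(fit_arima_fixed(x, c(p, d, q)), error = function(e) NULL)
    if (is.null(cand) || !is.finite(cand$AICc)) next
    if (is.null(best) || cand$AICc < best$AICc) best <- cand
  }
  if (is.null(best)) stop("no ARIMA order could be fitted")
  best
}

#' @export
print.arima_fit <- function(x, ...) {
  cat("arima_fit: order (", paste(x$order, collapse = ","), "), AICc ",
      format(x$AICc, digits = 6), "\n", sep = "")
  invisible(x)
}

#' Residual cross-correlation
#'
#' Normalised cross-correlation between two residual series at lags
#' `-max_lag .. +max_lag` (via `stats::ccf`); the value at lag `l` is the
#' correlation between `a` at time `t + l` and `b` at time `t`.
#'
#' @param resid_a,resid_b Equal-length numeric series (length >= 3) with
#'   positive variance.
#' @param max_lag Maximum lag in grid steps (default 5).
#' @return Data frame with `lag` and `r`; the maximum `|r|` and its lag are
#'   attached as attributes `max_r` and `max_lag_at`.
#' @export
cross_correlate <- function(resid_a, resid_b, max_lag = 5L) {
  a <- as.numeric(resid_a); b <- as.numeric(resid_b)
  if (length(a) != length(b)) stop("series lengths differ")
  if (length(a) < 3L) stop("series too short")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) stop("zero-variance input")
  cc <- stats::ccf(a, b, lag.max = max_lag, plot = FALSE)
  out <- data.frame(lag = as.integer(cc$lag), r = as.numeric(cc$acf))
  i <- which.max(abs(out$r))
  attr(out, "max_r") <- out$r[i]
  attr(out, "max_lag_at") <- out$lag[i]
  out
}

#' Read an environmental time series
#'
#' Two-column CSV (`age`, `value`), e.g. temperature or CO2 on a 10-Ma grid.
#' Rows are returned sorted from oldest to youngest.
#'
#' @param path CSV path.
#' @return Data frame with `age` (Ma) and `value`.
#' @export
read_series_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(df)[1:2] <- c("age", "value")
  df[order(-df$age), , drop = FALSE]
}

#' Correlate disparity medians with an environmental driver
#'
#' Detrends the driver by [fit_arima_auto()], imposes the selected order on
#' the response via [fit_arima_fixed()], and cross-correlates the residuals.
#' Both series must sit on the same uniform age grid.
#'
#' @param driver,response Numeric series, oldest first, equal length.
#' @param max_lag Maximum lag for [cross_correlate()].
#' @return List with `driver_fit`, `response_fit`, `ccf` (data frame),
#'   `max_r`, `max_lag_at`.
#' @export
correlate_disparity_series <- function(driver, response, max_lag = 5L) {
  dfit <- fit_arima_auto(driver)
  rfit <- fit_arima_fixed(response, dfit$order)
  cc <- cross_correlate(dfit$residuals, rfit$residuals, max_lag = max_lag)
  list(driver_fit = dfit, response_fit = rfit, ccf = cc,
       max_r = attr(cc, "max_r"), max_lag_at = attr(cc, "max_lag_at"))
}
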