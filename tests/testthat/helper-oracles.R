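# Independent oracles and small fixture builders shared across tests.

# Closed-form simple linear regression: slope/intercept/r2 from raw sums,
# independent of lm().
ols_oracle <- function(x, y) {
  n <- length(x)
  xbar <- sum(x) / n
  ybar <- sum(y) / n
  sxx <- sum((x - xbar)^2)
  sxy <- sum((x - xbar) * (y - ybar))
  slope <- sxy / sxx
  intercept <- ybar - slope * xbar
  resid <- y - intercept - slope * x
  sst <- sum((y - ybar)^2)
  r2 <- if (sst == 0) 1 else 1 - sum(resid^2) / sst
  list(slope = slope, intercept = intercept, r2 = r2)
}

# Brute-force rolling percentile: explicit sort-and-interpolate (quantile
# type 7 arithmetic written out), truncated centered windows.
rolling_percentile_oracle <- function(x, percentile, window) {
  n <- length(x)
  left <- (window - 1) %/% 2
  right <- window - 1 - left
  p <- percentile / 100
  out <- numeric(n)
  for (i in seq_len(n)) {
    w <- sort(x[max(1, i - left):min(n, i + right)])
    m <- length(w)
    h <- (m - 1) * p + 1
    lo <- floor(h)
    hi <- ceiling(h)
    out[i] <- w[lo] + (h - lo) * (w[hi] - w[lo])
  }
  out
}

# A concentration time series that decays as a clean power law after an
# addition: baseline c0 up to t_add, then c_peak * (tau / dt)^k.
make_power_trace <- function(k, c0 = 0.005, c_peak = 0.05, t_add = 3 * 3600,
                             duration = 12 * 3600, dt = 60) {
  times <- seq(0, duration, by = dt)
  cc <- rep(c0, length(times))
  tau <- times - t_add
  post <- tau > 0
  cc[post] <- pmax(c0, c_peak * (tau[post] / dt)^k)
  time_series(times, cc, "concentration")
}

conc_record <- function(ts, t_add = 3 * 3600, salt = "KNO3", ...) {
  experiment_record(ts, salt, addition_time = t_add, ...)
}
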