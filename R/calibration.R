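# Sensor calibration models.
#
# The impedance channel is non-specific: each salt gets its own calibration,
# a straight line in log10(Z) vs log10(c) fitted over the user-chosen linear
# range. pH (potentiometric) and H2O2 (amperometric) channels are plain
# linear maps output = gain * input + offset.

#' Fit a per-salt impedance calibration curve
#'
#' Ordinary least squares of `log10(Z)` on `log10(c)` over the supplied
#' calibration points. The fit uses every supplied point: restricting to the
#' sensor's linear range is done by the user's choice of points, since no
#' automatic breakpoint rule is imposed. The validity range is the span of
#' the supplied concentrations.
#'
#' @param points A data.frame (or list) with columns/fields `c` (mol/L) and
#'   `Z` (ohm); all entries must be strictly positive.
#' @param salt_name Salt identifier the curve is keyed by.
#' @return An object of class `calibration_curve` with fields `salt_name`,
#'   `slope` (d log10 Z / d log10 c, negative for conductive salts),
#'   `intercept` (log10 ohm at 1 mol/L), `valid_c_range`, `fit_r2`,
#'   `n_points`.
#' @examples
#' pts <- data.frame(c = 10^seq(-4, -1), Z = 10^(5 - 0.5 * seq(-4, -1)))
#' fit_impedance_calibration(pts, "KCl")
#' @export
fit_impedance_calibration <- function(points, salt_name) {
  cc <- as.numeric(points$c)
  Z <- as.numeric(points$Z)
  if (length(cc) != length(Z)) {
    stop("calibration points need matching c and Z vectors", call. = FALSE)
  }
  if (length(cc) < 2L) {
    stop("need at least 2 calibration points", call. = FALSE)
  }
  if (any(!is.finite(cc)) || any(!is.finite(Z)) || any(cc <= 0) || any(Z <= 0)) {
    stop("all calibration concentrations and impedances must be positive and finite",
         call. = FALSE)
  }
  lx <- log10(cc)
  ly <- log10(Z)
  if (stats::sd(lx) == 0) {
    stop("singular calibration fit: all concentrations identical", call. = FALSE)
  }
  fit <- stats::lm(ly ~ lx)
  co <- unname(stats::coef(fit))
  ssr <- sum(stats::residuals(fit)^2)
  sst <- sum((ly - mean(ly))^2)
  r2 <- if (sst == 0) 1 else 1 - ssr / sst
  structure(
    list(salt_name = salt_name, slope = co[2L], intercept = co[1L],
         valid_c_range = range(cc), fit_r2 = r2, n_points = length(cc)),
    class = "calibration_curve"
  )
}

#' Construct a calibration curve from known coefficients
#'
#' Used by the simulator and when loading persisted calibration tables.
#'
#' @inheritParams fit_impedance_calibration
#' @param slope,intercept Line coefficients in log10 space.
#' @param valid_c_range Length-2 numeric, mol/L.
#' @param fit_r2,n_points Fit diagnostics (optional).
#' @return A `calibration_curve`.
#' @export
calibration_curve <- function(salt_name, slope, intercept,
                              valid_c_range = c(1e-8, 0.1),
                              fit_r2 = NA_real_, n_points = 2L) {
  stopifnot(is.finite(slope), is.finite(intercept),
            length(valid_c_range) == 2L, valid_c_range[1L] < valid_c_range[2L],
            n_points >= 2L)
  structure(
    list(salt_name = salt_name, slope = slope, intercept = intercept,
         valid_c_range = as.numeric(valid_c_range), fit_r2 = fit_r2,
         n_points = as.integer(n_points)),
    class = "calibration_curve"
  )
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "<calibration_curve> %s: log10(Z) = %.4f %+.4f log10(c), c in [%.3g, %.3g] M (r2 = %.4f, n = %d)\n",
    x$salt_name, x$intercept, x$slope, x$valid_c_range[1L],
    x$valid_c_range[2L], x$fit_r2, x$n_points))
  invisible(x)
}

#' Forward impedance from concentration
#'
#' Evaluates the calibration line: `Z = 10^(intercept + slope * log10(c))`.
#'
#' @param curve A `calibration_curve`.
#' @param c_molar Concentration(s) in mol/L, positive.
#' @return Impedance in ohm.
#' @export
impedance_from_concentration <- function(curve, c_molar) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (any(c_molar <= 0)) stop("concentration must be positive", call. = FALSE)
  10^(curve$intercept + curve$slope * log10(c_molar))
}

#' Invert a calibration curve: concentration from impedance
#'
#' `c = 10^((log10(Z) - intercept) / slope)`. Values falling outside the
#' curve's validity range are still returned but flagged as extrapolated.
#'
#' @param curve A `calibration_curve`.
#' @param Z Impedance(s) in ohm, positive.
#' @return A list with `c` (mol/L) and logical `extrapolated` (per element).
#' @export
concentration_from_impedance <- function(curve, Z) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (any(Z <= 0)) stop("impedance must be positive", call. = FALSE)
  if (curve$slope == 0) {
    stop("cannot invert a calibration curve with zero slope", call. = FALSE)
  }
  cc <- 10^((log10(Z) - curve$intercept) / curve$slope)
  list(c = cc,
       extrapolated = cc < curve$valid_c_range[1L] | cc > curve$valid_c_range[2L])
}

#' Linear sensor calibration (pH, H2O2)
#'
#' `output = gain * input + offset`. For the potentiometric pH electrode the
#' input is pH and the output is potential in volts (gain near the Nernst
#' slope, about -0.059 V per pH unit at room temperature); for the
#' amperometric H2O2 sensor the input is concentration in mol/L and the
#' output current in amperes.
#'
#' @param gain Output unit per input unit; must be nonzero.
#' @param offset Output unit at zero input.
#' @param valid_input_range Length-2 numeric range of inputs the sensor was
#'   characterized over.
#' @return An object of class `linear_sensor_cal`.
#' @export
linear_sensor_cal <- function(gain, offset, valid_input_range = c(-Inf, Inf)) {
  if (!is.finite(gain) || gain == 0) {
    stop("sensor gain must be finite and nonzero", call. = FALSE)
  }
  stopifnot(length(valid_input_range) == 2L,
            valid_input_range[1L] < valid_input_range[2L])
  structure(list(gain = gain, offset = as.numeric(offset),
                 valid_input_range = as.numeric(valid_input_range)),
            class = "linear_sensor_cal")
}

invert_linear_cal <- function(cal, output) {
  x <- (output - cal$offset) / cal$gain
  list(value = x,
       out_of_range = x < cal$valid_input_range[1L] |
         x > cal$valid_input_range[2L])
}

#' pH from electrode potential
#'
#' @param cal A [linear_sensor_cal()] with gain in V per pH unit.
#' @param E Open-circuit potential(s) in volts.
#' @return List with `ph` and logical `out_of_range`.
#' @export
ph_from_potential <- function(cal, E) {
  stopifnot(inherits(cal, "linear_sensor_cal"))
  r <- invert_linear_cal(cal, E)
  list(ph = r$value, out_of_range = r$out_of_range)
}

#' H2O2 concentration from sensor current
#'
#' @param cal A [linear_sensor_cal()] with gain in A per mol/L.
#' @param I Amperometric current(s) in amperes.
#' @return List with `c` (mol/L) and logical `out_of_range`.
#' @export
h2o2_from_current <- function(cal, I) {
  stopifnot(inherits(cal, "linear_sensor_cal"))
  r <- invert_linear_cal(cal, I)
  list(c = r$value, out_of_range = r$out_of_range)
}

#' Write / read a calibration table
#'
#' Persists per-salt calibration curves as delimited text with columns
#' `salt_name, slope, intercept, c_min, c_max, r2, n_points`.
#'
#' @param curves A list of `calibration_curve` objects.
#' @param path Output CSV path.
#' @return `path` invisibly (`write_calibration_table`); a named list of
#'   curves (`read_calibration_table`).
#' @export
write_calibration_table <- function(curves, path) {
  if (inherits(curves, "calibration_curve")) curves <- list(curves)
  df <- do.call(rbind, lapply(curves, function(cv) {
    data.frame(salt_name = cv$salt_name, slope = cv$slope,
               intercept = cv$intercept, c_min = cv$valid_c_range[1L],
               c_max = cv$valid_c_range[2L], r2 = cv$fit_r2,
               n_points = cv$n_points)
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_calibration_table
#' @export
read_calibration_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  curves <- lapply(seq_len(nrow(df)), function(i) {
    calibration_curve(df$salt_name[i], df$slope[i], df$intercept[i],
                      c(df$c_min[i], df$c_max[i]), df$r2[i], df$n_points[i])
  })
  names(curves) <- df$salt_name
  curves
}
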