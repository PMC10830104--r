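#' Sensor channel units
#'
#' Maps a channel kind to the unit its samples are stored in. Raw channels
#' (impedance, pH potential, H2O2 current) carry instrument units; derived
#' channels carry chemical units.
#'
#' @format Named character vector.
#' @keywords internal
CHANNEL_UNITS <- c(
  impedance          = "ohm",
  ph_potential       = "volt",
  h2o2_current       = "ampere",
  concentration      = "mol/L",
  ph                 = "pH",
  h2o2_concentration = "mol/L"
)

#' Construct a sensor time series
#'
#' A `time_series` holds one sensor channel: elapsed times in seconds from the
#' start of the recording and the signal values in the channel's unit. Times
#' must be non-negative and strictly increasing; wall-clock time is never
#' stored because every downstream quantity (baseline window, fit window,
#' addition time) is elapsed-time based.
#'
#' @param times Numeric vector, seconds from recording start, strictly
#'   increasing, non-negative.
#' @param values Numeric vector, same length as `times`.
#' @param channel_kind One of `"impedance"`, `"ph_potential"`,
#'   `"h2o2_current"`, `"concentration"`, `"ph"`, `"h2o2_concentration"`.
#' @return An object of class `time_series` with fields `times`, `values`,
#'   `channel_kind`, `unit`.
#' @examples
#' ts <- time_series(c(0, 1, 2), c(100e3, 101e3, 102e3), "impedance")
#' ts$unit
#' @export
time_series <- function(times, values, channel_kind) {
  channel_kind <- match.arg(channel_kind, names(CHANNEL_UNITS))
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) != length(values)) {
    stop("`times` and `values` must have the same length", call. = FALSE)
  }
  if (length(times) == 0L) {
    stop("a time series needs at least one sample", call. = FALSE)
  }
  if (anyNA(times) || anyNA(values)) {
    stop("NA values are not allowed in a time series", call. = FALSE)
  }
  if (times[1L] < 0) {
    stop("times must be non-negative seconds from recording start",
         call. = FALSE)
  }
  if (length(times) > 1L && any(diff(times) <= 0)) {
    bad <- which(diff(times) <= 0)[1L] + 1L
    stop(sprintf("times must be strictly increasing (violated at sample %d)",
                 bad), call. = FALSE)
  }
  structure(
    list(times = times, values = values, channel_kind = channel_kind,
         unit = unname(CHANNEL_UNITS[channel_kind])),
    class = "time_series"
  )
}

#' @export
print.time_series <- function(x, ...) {
  cat(sprintf("<time_series> %s [%s], %d samples, t = %.1f..%.1f s\n",
              x$channel_kind, x$unit, length(x$times),
              x$times[1L], x$times[length(x$times)]))
  invisible(x)
}

#' @export
length.time_series <- function(x) length(x$times)

#' Construct an uptake experiment record
#'
#' Bundles one sensor trace with the metadata of an uptake experiment: which
#' salt was added, when and how much, and whether the trace is a plant-free
#' control (paper substrate only). Controls are used to measure the slow
#' electrode-wetting drift that the normalized uptake ratio divides out.
#'
#' @param trace A [time_series()].
#' @param salt_name Salt identifier, e.g. `"KNO3"`.
#' @param addition_time Seconds at which salt solution was added, or `NULL`
#'   for runs without an addition. Must lie inside the trace's time span.
#' @param addition_volume_ul Added volume in microlitres (default 30).
#' @param addition_concentration Concentration of the added solution in mol/L.
#' @param is_control `TRUE` for plant-free paper controls.
#' @param n_plants Number of seedlings on the paper disc (0 for controls).
#' @param plant_age_days Age of the seedlings in days.
#' @return An object of class `experiment_record`.
#' @export
experiment_record <- function(trace, salt_name,
                              addition_time = NULL,
                              addition_volume_ul = 30,
                              addition_concentration = 0.1,
                              is_control = FALSE,
                              n_plants = if (is_control) 0L else 30L,
                              plant_age_days = 9L) {
  if (!inherits(trace, "time_series")) {
    stop("`trace` must be a time_series", call. = FALSE)
  }
  if (!is.character(salt_name) || length(salt_name) != 1L || !nzchar(salt_name)) {
    stop("`salt_name` must be a non-empty string", call. = FALSE)
  }
  if (!is.null(addition_time)) {
    addition_time <- as.numeric(addition_time)
    tspan <- range(trace$times)
    if (addition_time < tspan[1L] || addition_time > tspan[2L]) {
      stop(sprintf(
        "addition_time %.1f s lies outside the trace span [%.1f, %.1f] s",
        addition_time, tspan[1L], tspan[2L]), call. = FALSE)
    }
  }
  is_control <- isTRUE(is_control)
  n_plants <- as.integer(n_plants)
  if (is_control && n_plants != 0L) {
    stop("a plant-free control must have n_plants = 0", call. = FALSE)
  }
  if (n_plants < 0L) stop("n_plants must be non-negative", call. = FALSE)
  structure(
    list(trace = trace, salt_name = salt_name, addition_time = addition_time,
         addition_volume_ul = as.numeric(addition_volume_ul),
         addition_concentration = as.numeric(addition_concentration),
         is_control = is_control, n_plants = n_plants,
         plant_age_days = as.integer(plant_age_days)),
    class = "experiment_record"
  )
}

#' @export
print.experiment_record <- function(x, ...) {
  cat(sprintf(
    "<experiment_record> salt = %s, %s, n_plants = %d, addition at %s\n",
    x$salt_name, if (x$is_control) "control (no plants)" else "plant run",
    x$n_plants,
    if (is.null(x$addition_time)) "none" else sprintf("%.0f s", x$addition_time)))
  print(x$trace)
  invisible(x)
}
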