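# Core uptake computation: after a salt addition the root system draws ions
# back out of the paper disc and the measured concentration decays from its
# peak toward the pre-addition baseline. That decay is summarized by fitting
# c = B * tau^k (tau = time since addition) over the window from the peak to
# the point where the trace re-meets the baseline within a 5% tolerance; k is
# the uptake rate and is normalized by the mean k of plant-free controls.

#' Pipeline configuration for uptake estimation
#'
#' Collects the tunable constants of the uptake pipeline. The defaults are
#' the standard protocol values: 2 h baseline window, 5% baseline tolerance,
#' rolling median (50th percentile) smoothing for peak detection only, fit on
#' the unsmoothed concentrations.
#'
#' @param baseline_hours Baseline averaging window, hours.
#' @param tolerance Relative tolerance for re-meeting the baseline (0.05 =
#'   5%).
#' @param smoothing A [smoothing_spec()] applied before peak detection
#'   (default: rolling median over 100 points, the display smoothing used
#'   for uptake traces), or `NULL` for none. Detection smoothing never mixes
#'   pre- and post-addition samples in one window.
#' @param peak_tolerance Relative tolerance for the noise-robust peak rule
#'   of [find_post_addition_peak()]; defaults to the baseline tolerance.
#' @param fit_on_smoothed Fit the power law on the smoothed series instead of
#'   the raw conversion (default `FALSE`).
#' @param control_epsilon Controls with |mean k| below this are treated as
#'   zero for normalization (undefined ratio).
#' @return A list of class `uptake_config`.
#' @export
uptake_config <- function(baseline_hours = 2, tolerance = 0.05,
                          smoothing = smoothing_spec(50, 100L),
                          fit_on_smoothed = FALSE, peak_tolerance = tolerance,
                          control_epsilon = 1e-9) {
  stopifnot(baseline_hours > 0, tolerance >= 0, peak_tolerance >= 0,
            is.null(smoothing) || inherits(smoothing, "smoothing_spec"))
  structure(list(baseline_hours = baseline_hours, tolerance = tolerance,
                 smoothing = smoothing,
                 fit_on_smoothed = isTRUE(fit_on_smoothed),
                 peak_tolerance = peak_tolerance,
                 control_epsilon = control_epsilon),
            class = "uptake_config")
}

# Detection smoothing that respects the addition discontinuity: the pre- and
# post-addition segments are filtered separately so no window mixes baseline
# samples with post-addition samples (a straddling median dips artificially
# right after the step).
smooth_around_addition <- function(conc, t_add, spec) {
  post <- conc$times > t_add
  v <- conc$values
  if (any(!post)) {
    pre_ts <- time_series(conc$times[!post], v[!post], conc$channel_kind)
    v[!post] <- percentile_filter(pre_ts, spec)$values
  }
  if (any(post)) {
    post_ts <- time_series(conc$times[post], v[post], conc$channel_kind)
    v[post] <- percentile_filter(post_ts, spec)$values
  }
  time_series(conc$times, v, conc$channel_kind)
}

#' Find the power-law fit window
#'
#' Scans the concentrations after the peak for the first sample at or below
#' `baseline * (1 + tolerance)`; the fit runs from the peak up to that
#' sample. The tolerance is applied one-sided from above because additions
#' raise the concentration and the decay approaches the baseline from above.
#' If the trace never re-meets the baseline the window extends to the last
#' sample and `reached_baseline` is `FALSE`.
#'
#' @param conc A concentration [time_series()].
#' @param t_peak Peak time in seconds (within the trace).
#' @param baseline Pre-addition baseline concentration, > 0.
#' @param tolerance Relative tolerance, default 0.05.
#' @return List with `t_end` and logical `reached_baseline`.
#' @export
find_fit_window <- function(conc, t_peak, baseline, tolerance = 0.05) {
  stopifnot(inherits(conc, "time_series"), baseline > 0)
  n <- length(conc$times)
  if (t_peak >= conc$times[n]) {
    stop("peak at the last sample: no post-peak window to fit", call. = FALSE)
  }
  after <- which(conc$times > t_peak)
  hit <- after[conc$values[after] <= baseline * (1 + tolerance)]
  if (length(hit) == 0L) {
    list(t_end = conc$times[n], reached_baseline = FALSE)
  } else {
    list(t_end = conc$times[hit[1L]], reached_baseline = TRUE)
  }
}

#' Fit the power-law decay c = B * tau^k
#'
#' Ordinary least squares of `log10(c)` on `log10(t - t_origin)` over samples
#' in `[t_start, t_end]`. The returned `k` is the slope (signed; negative for
#' decaying traces) and `B = 10^intercept` in mol/L at tau = 1 s.
#'
#' @param conc A concentration [time_series()].
#' @param t_start,t_end Window bounds in seconds (inclusive).
#' @param t_origin Time origin of the power law; all window samples must have
#'   `t > t_origin`. The physically distinguished choice is the addition
#'   time.
#' @return List with `B`, `k`, `r2`, `n` (samples used).
#' @export
fit_power_law <- function(conc, t_start, t_end, t_origin) {
  stopifnot(inherits(conc, "time_series"), t_start < t_end)
  sel <- conc$times >= t_start & conc$times <= t_end
  tt <- conc$times[sel]
  cc <- conc$values[sel]
  if (length(tt) < 3L) {
    stop("fewer than 3 samples in the fit window", call. = FALSE)
  }
  if (any(cc <= 0)) {
    stop("non-positive concentration in the fit window", call. = FALSE)
  }
  tau <- tt - t_origin
  if (any(tau <= 0)) {
    stop("all window samples must lie strictly after the time origin",
         call. = FALSE)
  }
  lx <- log10(tau)
  ly <- log10(cc)
  fit <- stats::lm(ly ~ lx)
  co <- unname(stats::coef(fit))
  sst <- sum((ly - mean(ly))^2)
  r2 <- if (sst == 0) 1 else 1 - sum(stats::residuals(fit)^2) / sst
  list(B = 10^co[1L], k = co[2L], r2 = r2, n = length(tt))
}

#' Estimate the uptake rate of one experiment
#'
#' Runs the full single-trace pipeline: convert impedance to concentration
#' through the salt's calibration curve, average the first
#' `baseline_hours` as the baseline, locate the post-addition peak
#' (optionally on a smoothed copy), determine the fit window by the
#' baseline-tolerance rule, and fit `c = B * tau^k` with the addition time as
#' origin. Traces whose concentration never rises above the baseline or never
#' decreases after the addition get `zero_uptake = TRUE` and `k_uptake = 0`.
#'
#' @param record An [experiment_record()] with an impedance or concentration
#'   trace and a recorded `addition_time`.
#' @param curve The salt's [calibration_curve()]; may be omitted when the
#'   trace is already a concentration channel.
#' @param config An [uptake_config()].
#' @return An object of class `uptake_result`: fields `B`, `k_uptake`,
#'   `t_fit_start`, `t_fit_end`, `baseline`, `reached_baseline`,
#'   `zero_uptake`, `fit_r2`, `n_fit`, `extrapolated_fraction`.
#' @export
compute_uptake <- function(record, curve = NULL, config = uptake_config()) {
  stopifnot(inherits(record, "experiment_record"),
            inherits(config, "uptake_config"))
  if (is.null(record$addition_time)) {
    stop("record has no addition_time: cannot estimate uptake", call. = FALSE)
  }
  t_add <- record$addition_time
  trace <- record$trace
  extrap_frac <- 0
  if (trace$channel_kind == "impedance") {
    stopifnot(inherits(curve, "calibration_curve"))
    conv <- concentration_from_impedance(curve, trace$values)
    extrap_frac <- mean(conv$extrapolated)
    conc <- time_series(trace$times, conv$c, "concentration")
  } else if (trace$channel_kind == "concentration") {
    conc <- trace
  } else {
    stop("uptake estimation needs an impedance or concentration trace",
         call. = FALSE)
  }
  baseline <- estimate_baseline(conc, config$baseline_hours)
  detect <- if (!is.null(config$smoothing)) {
    smooth_around_addition(conc, t_add, config$smoothing)
  } else conc
  fit_series <- if (config$fit_on_smoothed) detect else conc
  # no-peak decision on the raw conversion (did the addition raise the
  # concentration at all?); peak location on the smoothed series with the
  # noise-robust earliest-attainment rule
  raw_peak <- find_post_addition_peak(conc, t_add, baseline = baseline)
  peak <- find_post_addition_peak(detect, t_add, baseline = NULL,
                                  tolerance = config$peak_tolerance)
  peak$no_peak <- raw_peak$no_peak
  if (peak$no_peak) peak$t_peak <- NA_real_

  zero_result <- function() {
    structure(list(B = NA_real_, k_uptake = 0, t_fit_start = NA_real_,
                   t_fit_end = NA_real_, baseline = baseline,
                   reached_baseline = NA, zero_uptake = TRUE,
                   fit_r2 = NA_real_, n_fit = 0L,
                   extrapolated_fraction = extrap_frac),
              class = "uptake_result")
  }
  if (peak$no_peak) return(zero_result())
  post <- which(conc$times >= t_add)
  if (length(post) >= 2L && all(diff(conc$values[post]) >= 0)) {
    # concentration never decreases after the addition -> no uptake
    return(zero_result())
  }
  if (peak$t_peak >= conc$times[length(conc$times)]) {
    # peak sits on the last sample: no decay transient recorded
    return(zero_result())
  }
  # the decay origin is the addition: the fit cannot start before the first
  # sample strictly after it (tau > 0), even if heavy smoothing flattens the
  # detected peak onto the addition instant
  t_start <- max(peak$t_peak, min(conc$times[conc$times > t_add]))
  win <- find_fit_window(fit_series, t_start, baseline,
                         tolerance = config$tolerance)
  fit <- fit_power_law(fit_series, t_start, win$t_end, t_origin = t_add)
  structure(list(B = fit$B, k_uptake = fit$k, t_fit_start = t_start,
                 t_fit_end = win$t_end, baseline = baseline,
                 reached_baseline = win$reached_baseline, zero_uptake = FALSE,
                 fit_r2 = fit$r2, n_fit = fit$n,
                 extrapolated_fraction = extrap_frac),
            class = "uptake_result")
}

#' @export
print.uptake_result <- function(x, ...) {
  if (x$zero_uptake) {
    cat("<uptake_result> zero uptake (no decaying post-addition transient)\n")
  } else {
    cat(sprintf(
      "<uptake_result> k = %.5f, B = %.4g, window [%.0f, %.0f] s, baseline %.4g M, reached_baseline = %s\n",
      x$k_uptake, x$B, x$t_fit_start, x$t_fit_end, x$baseline,
      x$reached_baseline))
  }
  invisible(x)
}

#' Normalize an uptake rate against plant-free controls
#'
#' The ratio `k_uptake / mean(k_control)` puts different salts on a common
#' footing: control traces (no plants) capture the slow impedance drift from
#' electrode wetting and evaporation, and their apparent k serves as the
#' denominator. Ratios at or below 1 indicate net zero or negative uptake.
#'
#' @param k_uptake Fitted exponent of one plant experiment (signed).
#' @param control_results List of `uptake_result` objects (or a numeric
#'   vector of control k values) from plant-free runs; at least one.
#' @param epsilon Controls mean below this magnitude make the ratio
#'   undefined (flagged, not infinite).
#' @return List of class `normalized_uptake` with `ratio`, `k_control_mean`,
#'   `n_controls`, `undefined`.
#' @export
normalize_uptake <- function(k_uptake, control_results, epsilon = 1e-9) {
  ks <- if (is.numeric(control_results)) {
    control_results
  } else {
    vapply(control_results, function(r) r$k_uptake, numeric(1L))
  }
  if (length(ks) == 0L) {
    stop("need at least one control result to normalize", call. = FALSE)
  }
  km <- mean(ks)
  if (abs(km) < epsilon) {
    return(structure(list(ratio = NA_real_, k_control_mean = km,
                          n_controls = length(ks), undefined = TRUE),
                     class = "normalized_uptake"))
  }
  structure(list(ratio = k_uptake / km, k_control_mean = km,
                 n_controls = length(ks), undefined = FALSE),
            class = "normalized_uptake")
}

#' Batch uptake run over a manifest
#'
#' Processes every trace listed in a manifest with the identical pipeline
#' (controls included: their apparent k captures the drift), then normalizes
#' each plant run by the mean control k of the same salt, falling back to the
#' pooled controls when a salt has none.
#'
#' @param manifest Data.frame from [read_manifest()] or a manifest CSV path.
#' @param curves Named list of [calibration_curve()] objects keyed by salt.
#' @param config An [uptake_config()].
#' @return Data.frame with one row per experiment: `path`, `salt_name`,
#'   `role`, `k`, `B`, `baseline`, `reached_baseline`, `zero_uptake`,
#'   `ratio`, `ratio_undefined`.
#' @export
run_uptake_batch <- function(manifest, curves, config = uptake_config()) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  if (is.null(manifest$resolved_path)) manifest$resolved_path <- manifest$path
  if (inherits(curves, "calibration_curve")) {
    curves <- stats::setNames(list(curves), curves$salt_name)
  }
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    rec <- read_trace(manifest$resolved_path[i])
    curve <- curves[[manifest$salt_name[i]]]
    if (is.null(curve) && rec$trace$channel_kind == "impedance") {
      stop(sprintf("no calibration curve for salt '%s'",
                   manifest$salt_name[i]), call. = FALSE)
    }
    res <- compute_uptake(rec, curve, config)
    data.frame(path = manifest$path[i], salt_name = manifest$salt_name[i],
               role = manifest$role[i], k = res$k_uptake, B = res$B,
               baseline = res$baseline,
               reached_baseline = isTRUE(res$reached_baseline),
               zero_uptake = res$zero_uptake)
  })
  df <- do.call(rbind, rows)
  df$ratio <- NA_real_
  df$ratio_undefined <- NA
  ctrl <- df[df$role == "control", , drop = FALSE]
  for (i in which(df$role == "plant")) {
    ks <- ctrl$k[ctrl$salt_name == df$salt_name[i]]
    if (length(ks) == 0L) ks <- ctrl$k
    if (length(ks) == 0L) next      # no controls at all: leave NA
    nu <- normalize_uptake(df$k[i], ks)
    df$ratio[i] <- nu$ratio
    df$ratio_undefined[i] <- nu$undefined
  }
  df
}
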