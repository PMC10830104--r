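# Synthetic sensor-trace generator. Emulates the phenomenology the uptake
# pipeline assumes: a flat pre-addition baseline (>= 3 h), a step increase in
# concentration when salt solution is added, a power-law decay c = B*tau^k
# back toward baseline for plant runs, a slow upward impedance drift for
# plant-free controls (electrode wetting), and multiplicative lognormal
# measurement noise on the impedance channel. All randomness flows from the
# spec's single seed.

#' Default synthetic calibration curve
#'
#' A representative per-salt impedance calibration: slope -0.5 in log-log
#' space, 10 kilo-ohm at 1 mol/L, valid from 1 uM to 0.1 M. Synthetic; used
#' by the generator whenever no fitted curve is supplied.
#'
#' @param salt_name Salt name to key the curve by.
#' @return A [calibration_curve()].
#' @export
default_calibration_curve <- function(salt_name = "synthetic") {
  calibration_curve(salt_name, slope = -0.5, intercept = 4,
                    valid_c_range = c(1e-6, 0.1), fit_r2 = 1, n_points = 15L)
}

#' Synthetic trace specification
#'
#' Parameters of one generated uptake experiment. Defaults follow the
#' standard protocol and the observed instrument behavior: addition after a
#' 3 h rest, 24 h total recording, ~0.1 kilo-ohm/hour control drift,
#' multiplicative impedance noise of 0.5%.
#'
#' @param salt_name Salt identifier.
#' @param calibration A [calibration_curve()] for the forward map.
#' @param c0 Pre-addition concentration, mol/L.
#' @param t_add Addition time in seconds (`NULL` for no-addition runs).
#' @param c_peak Concentration immediately after the addition, mol/L; must
#'   exceed `c0` for addition runs.
#' @param k_true Power-law exponent of the decay (0 for no uptake).
#' @param drift_rate Impedance drift in ohm/hour (default 100, i.e. ~0.1
#'   kilo-ohm/hour).
#' @param noise_sd Relative (lognormal sigma) multiplicative noise on the
#'   impedance, default 0.005.
#' @param duration_s Total recording length, seconds.
#' @param dt_s Sampling interval, seconds.
#' @param is_control Plant-free control flag.
#' @param n_plants Seedling count for plant runs.
#' @param seed Integer seed for the noise stream.
#' @return A list of class `trace_spec`.
#' @export
trace_spec <- function(salt_name = "synthetic",
                       calibration = default_calibration_curve(salt_name),
                       c0 = 0.005, t_add = 3 * 3600, c_peak = 0.05,
                       k_true = -0.4, drift_rate = 100, noise_sd = 0.005,
                       duration_s = 24 * 3600, dt_s = 60,
                       is_control = FALSE,
                       n_plants = if (is_control) 0L else 30L, seed = 1L) {
  stopifnot(inherits(calibration, "calibration_curve"),
            c0 > 0, dt_s > 0, duration_s > dt_s, noise_sd >= 0)
  if (!is.null(t_add)) {
    if (duration_s <= t_add) {
      stop("duration_s must exceed t_add", call. = FALSE)
    }
    if (c_peak <= c0) {
      stop("c_peak must exceed c0 for an addition run", call. = FALSE)
    }
  }
  structure(list(salt_name = salt_name, calibration = calibration, c0 = c0,
                 t_add = t_add, c_peak = c_peak, k_true = k_true,
                 drift_rate = drift_rate, noise_sd = noise_sd,
                 duration_s = duration_s, dt_s = dt_s,
                 is_control = isTRUE(is_control),
                 n_plants = as.integer(n_plants), seed = as.integer(seed)),
            class = "trace_spec")
}

#' Generate a synthetic impedance trace
#'
#' Builds the concentration profile (baseline, step, clamped power-law decay
#' anchored so that the first sample after the addition sits at `c_peak`),
#' maps it through the calibration curve, adds the linear impedance drift and
#' seeded multiplicative lognormal noise, and wraps the result as an
#' impedance-channel [experiment_record()].
#'
#' The power law is evaluated for `t - t_add > 0` only: the decay's time
#' origin is the addition itself, so a sample falling exactly on the
#' addition instant still belongs to the pre-addition plateau.
#'
#' @param spec A [trace_spec()].
#' @return An [experiment_record()]; the true concentration profile is
#'   attached as attribute `"c_true"`.
#' @export
generate_trace <- function(spec) {
  stopifnot(inherits(spec, "trace_spec"))
  times <- seq(0, spec$duration_s, by = spec$dt_s)
  cc <- rep(spec$c0, length(times))
  if (!is.null(spec$t_add)) {
    tau <- times - spec$t_add
    post <- tau > 0
    dt_ref <- min(tau[post])    # anchors c(first post-addition sample) = c_peak
    cc[post] <- pmax(spec$c0,
                     spec$c_peak * (tau[post] / dt_ref)^spec$k_true)
  }
  Z <- impedance_from_concentration(spec$calibration, cc) +
    spec$drift_rate * times / 3600
  if (spec$noise_sd > 0) {
    Z <- with_seed(spec$seed,
                   Z * exp(stats::rnorm(length(Z), 0, spec$noise_sd)))
  }
  rec <- experiment_record(
    trace = time_series(times, Z, "impedance"),
    salt_name = spec$salt_name,
    addition_time = spec$t_add,
    addition_concentration = 0.1,
    is_control = spec$is_control,
    n_plants = spec$n_plants)
  attr(rec, "c_true") <- cc
  rec
}

#' Blocker-experiment ratio presets
#'
#' Normalized uptake ratios of the calcium-nitrate uptake experiments under
#' channel-blocker pretreatments, used as simulation targets: untreated 6.1;
#' deionized water 5.8 (4.5 h) and 6.0 (24 h is NaCl below); NaCl 6.0
#' (4.5 h) and 4.7 (24 h); the calcium-channel blocker LaCl3 4.0 (4.5 h) and
#' 3.1 (24 h).
#'
#' @return Named numeric vector of target ratios.
#' @export
blocker_presets <- function() {
  c(untreated = 6.1, water_4p5h = 5.8, NaCl_4p5h = 6.0,
    LaCl3_4p5h = 4.0, NaCl_24h = 4.7, LaCl3_24h = 3.1)
}

#' Generate a cohort of plant and control traces
#'
#' For each entry of `target_ratios` the generator first measures, by
#' running the uptake pipeline on a noiseless control trace, the apparent
#' drift-equivalent exponent `k_control`; the plant runs are then generated
#' with `k_true = target_ratio * k_control` so that the full pipeline's
#' normalized ratio closes the loop on the requested target. Plant traces
#' carry the drift-equivalent decay inside `k_true` (their `drift_rate` is
#' zero); control traces carry the drift in impedance space. Trace files, a
#' manifest and a ground-truth sidecar are written under `dir`.
#'
#' @param target_ratios Named numeric vector of target normalized ratios
#'   (default [blocker_presets()]); names are used as salt identifiers.
#' @param n_plant_reps,n_control_reps Replicates per condition (controls
#'   must be >= 1).
#' @param dir Output directory (created if missing).
#' @param curve Calibration curve shared by the cohort.
#' @param noise_sd Relative impedance noise (0 for noiseless cohorts).
#' @param drift_rate Control drift, ohm/hour.
#' @param seed Master seed; every trace gets an independent derived seed.
#' @return List with `manifest` (path), `ground_truth` (data.frame: salt,
#'   k_true, target_ratio), `calibration` (path to the persisted table).
#' @export
generate_cohort <- function(target_ratios = blocker_presets(),
                            n_plant_reps = 3L, n_control_reps = 3L,
                            dir = tempfile("cohort"),
                            curve = default_calibration_curve(),
                            noise_sd = 0.005, drift_rate = 100, seed = 1L) {
  if (length(target_ratios) == 0L) stop("empty target ratio set", call. = FALSE)
  if (is.null(names(target_ratios)) || any(!nzchar(names(target_ratios)))) {
    stop("target_ratios must be named", call. = FALSE)
  }
  if (n_control_reps < 1L) {
    stop("normalization needs at least one control replicate", call. = FALSE)
  }
  if (n_plant_reps < 1L) stop("need at least one plant replicate", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  # drift-equivalent control exponent, measured once on a noiseless control
  ref_spec <- trace_spec(salt_name = "ref", calibration = curve, k_true = 0,
                         drift_rate = drift_rate, noise_sd = 0,
                         is_control = TRUE, seed = 0L)
  k_control_ref <- compute_uptake(generate_trace(ref_spec), curve)$k_uptake
  if (abs(k_control_ref) < 1e-12) {
    stop("unreachable target ratio: control drift-equivalent k is ~0",
         call. = FALSE)
  }

  n_traces <- length(target_ratios) * (n_plant_reps + n_control_reps)
  seeds <- with_seed(seed, sample.int(.Machine$integer.max, n_traces))
  si <- 0L
  rows <- list()
  gt <- list()
  for (salt in names(target_ratios)) {
    ratio <- target_ratios[[salt]]
    k_true <- ratio * k_control_ref
    gt[[salt]] <- data.frame(salt_name = salt, k_true = k_true,
                             k_control_ref = k_control_ref,
                             target_ratio = ratio)
    for (r in seq_len(n_plant_reps)) {
      si <- si + 1L
      sp <- trace_spec(salt_name = salt, calibration = curve,
                       k_true = k_true, drift_rate = 0, noise_sd = noise_sd,
                       seed = seeds[si])
      fn <- sprintf("%s_plant_%02d.csv", gsub("[^A-Za-z0-9]", "_", salt), r)
      write_trace(generate_trace(sp), file.path(dir, fn))
      rows[[length(rows) + 1L]] <- data.frame(path = fn, salt_name = salt,
                                              role = "plant")
    }
    for (r in seq_len(n_control_reps)) {
      si <- si + 1L
      sp <- trace_spec(salt_name = salt, calibration = curve, k_true = 0,
                       drift_rate = drift_rate, noise_sd = noise_sd,
                       is_control = TRUE, seed = seeds[si])
      fn <- sprintf("%s_control_%02d.csv", gsub("[^A-Za-z0-9]", "_", salt), r)
      write_trace(generate_trace(sp), file.path(dir, fn))
      rows[[length(rows) + 1L]] <- data.frame(path = fn, salt_name = salt,
                                              role = "control")
    }
  }
  manifest_path <- file.path(dir, "manifest.csv")
  utils::write.csv(do.call(rbind, rows), manifest_path, row.names = FALSE,
                   quote = FALSE)
  gt_df <- do.call(rbind, gt)
  rownames(gt_df) <- NULL
  gt_path <- file.path(dir, "ground_truth.csv")
  utils::write.csv(gt_df, gt_path, row.names = FALSE, quote = FALSE)
  cal_path <- file.path(dir, "calibration.csv")
  curves <- lapply(names(target_ratios), function(s) {
    cv <- curve; cv$salt_name <- s; cv
  })
  write_calibration_table(curves, cal_path)
  list(manifest = manifest_path, ground_truth = gt_df,
       ground_truth_path = gt_path, calibration = cal_path, dir = dir)
}

#' Generate a synthetic salt-uptake classification dataset
#'
#' Draws salts (with replacement, mimicking replicated experiments) from the
#' bundled panel and assigns each a latent normalized uptake ratio from a
#' class-conditional model: salts with nutrient or sodium cations get high
#' ratios, heavy-metal salts low ones, with the separation scaled by
#' `class_signal_strength` (0 = no association between descriptors and
#' ratio). Labels are produced by [bin_uptake()].
#'
#' @param n_salts Number of samples (>= n_ranges).
#' @param class_signal_strength Non-negative separation multiplier
#'   (default 1; 0 gives a permutation null).
#' @param n_ranges Number of uptake classes, 2-6.
#' @param noise_sd SD of the Gaussian noise on the latent ratio.
#' @param seed Integer seed.
#' @return List with `features` (numeric matrix), `labels` (integer vector),
#'   `ratios`, `salt_names`.
#' @export
generate_ml_dataset <- function(n_salts, class_signal_strength = 1,
                                n_ranges = 2L, noise_sd = 0.5, seed = 1L) {
  if (class_signal_strength < 0) {
    stop("class_signal_strength must be non-negative", call. = FALSE)
  }
  if (n_salts < n_ranges) stop("need n_salts >= n_ranges", call. = FALSE)
  effects <- c(heavy_metal = -0.5, sodium = 2, macronutrient = 2.5,
               secondary_nutrient = 3)
  panel <- salt_panel()
  feats_panel <- build_feature_table(panel)
  with_seed(seed, {
    pick <- sample.int(length(panel), n_salts, replace = TRUE)
    feats <- feats_panel[pick, , drop = FALSE]
    eff <- effects[feats$cation_nutrient_class]
    ratios <- 1 + class_signal_strength * unname(eff) +
      stats::rnorm(n_salts, 0, noise_sd)
    labels <- bin_uptake(ratios, n_ranges)
    list(features = feature_matrix(feats), labels = labels, ratios = ratios,
         salt_names = feats$salt_name)
  })
}
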