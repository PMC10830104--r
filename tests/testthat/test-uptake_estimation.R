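test_that("fit window ends at the first baseline-tolerance crossing", {
  tt <- seq(0, 10) * 600
  cc <- c(1, 1, 1, 5, 3, 2, 1.5, 1.04, 0.9, 0.9, 0.9)
  ts <- time_series(tt, cc, "concentration")
  w <- find_fit_window(ts, t_peak = 1800, baseline = 1, tolerance = 0.05)
  expect_equal(w$t_end, 7 * 600)      # first sample at/below 1.05
  expect_true(w$reached_baseline)
  # never re-meets the baseline: window runs to the end
  cc2 <- c(1, 1, 1, 5, 4, 3.5, 3, 2.8, 2.6, 2.5, 2.4)
  w2 <- find_fit_window(time_series(tt, cc2, "concentration"), 1800, 1)
  expect_equal(w2$t_end, 6000)
  expect_false(w2$reached_baseline)
  expect_error(find_fit_window(ts, t_peak = 6000, baseline = 1),
               "last sample")
})

test_that("power-law fit recovers exact and noisy parameters", {
  tau <- seq(60, 7200, by = 60)
  ts <- time_series(tau + 1000, 2 * tau^(-0.3), "concentration")
  f <- fit_power_law(ts, min(ts$times), max(ts$times), t_origin = 1000)
  expect_equal(f$k, -0.3, tolerance = 1e-10)
  expect_equal(f$B, 2, tolerance = 1e-9)
  expect_equal(f$r2, 1, tolerance = 1e-12)
  # 1% multiplicative noise: equals the closed-form OLS oracle on logs
  set.seed(11)
  noisy <- 2 * tau^(-0.3) * exp(rnorm(length(tau), 0, 0.01))
  tsn <- time_series(tau + 1000, noisy, "concentration")
  fn <- fit_power_law(tsn, min(tsn$times), max(tsn$times), t_origin = 1000)
  o <- ols_oracle(log10(tau), log10(noisy))
  expect_equal(fn$k, o$slope, tolerance = 1e-10)
  expect_equal(fn$B, 10^o$intercept, tolerance = 1e-8)
  # constant series: flat limit
  tsc <- time_series(tau, rep(0.02, length(tau)), "concentration")
  fc <- fit_power_law(tsc, 60, 7200, t_origin = 0)
  expect_equal(fc$k, 0, tolerance = 1e-12)
  expect_equal(fc$B, 0.02, tolerance = 1e-12)
})

test_that("power-law fit rejects invalid windows", {
  tau <- c(60, 120, 180)
  ts <- time_series(tau, c(1, 2, 3) * 1e-3, "concentration")
  expect_error(fit_power_law(ts, 60, 120, 0), "fewer than 3")
  ts2 <- time_series(tau, c(1e-3, -1e-3, 2e-3), "concentration")
  expect_error(fit_power_law(ts2, 60, 180, 0), "non-positive")
  expect_error(fit_power_law(ts, 60, 180, 100), "after the time origin")
})

test_that("compute_uptake recovers the generator's exponent on clean traces", {
  sp <- trace_spec(k_true = -0.4, drift_rate = 0, noise_sd = 0)
  res <- compute_uptake(generate_trace(sp), sp$calibration)
  expect_false(res$zero_uptake)
  expect_equal(res$k_uptake, -0.4, tolerance = 1e-6)
  expect_equal(res$baseline, 0.005, tolerance = 1e-9)
})

test_that("non-decreasing post-addition traces are zero uptake", {
  tt <- seq(0, 8 * 3600, by = 600)
  cc <- ifelse(tt <= 3 * 3600, 1e-3, 1e-3 + (tt - 3 * 3600) * 1e-9)
  rec <- conc_record(time_series(tt, cc, "concentration"))
  res <- compute_uptake(rec)
  expect_true(res$zero_uptake)
  expect_identical(res$k_uptake, 0)
})

test_that("compute_uptake requires an addition time", {
  tt <- seq(0, 8 * 3600, by = 600)
  rec <- experiment_record(time_series(tt, rep(1e-3, length(tt)),
                                       "concentration"), "KCl")
  expect_error(compute_uptake(rec), "no addition_time")
})

test_that("scaling concentrations scales B and leaves k unchanged", {
  ts <- make_power_trace(-0.35)
  rec1 <- conc_record(ts)
  rec2 <- conc_record(time_series(ts$times, 7 * ts$values, "concentration"))
  r1 <- compute_uptake(rec1)
  r2 <- compute_uptake(rec2)
  expect_equal(r2$k_uptake, r1$k_uptake, tolerance = 1e-9)
  expect_equal(r2$B, 7 * r1$B, tolerance = 1e-6)
})

test_that("compute_uptake equals the manual composition of its stages", {
  sp <- trace_spec(k_true = -0.25, drift_rate = 50, noise_sd = 0.004, seed = 9)
  rec <- generate_trace(sp)
  cfg <- uptake_config(smoothing = NULL)
  res <- compute_uptake(rec, sp$calibration, cfg)
  conc <- time_series(rec$trace$times,
                      concentration_from_impedance(sp$calibration,
                                                   rec$trace$values)$c,
                      "concentration")
  base <- estimate_baseline(conc, 2)
  pk <- find_post_addition_peak(conc, rec$addition_time, baseline = base,
                                tolerance = cfg$peak_tolerance)
  t_start <- max(pk$t_peak,
                 min(conc$times[conc$times > rec$addition_time]))
  win <- find_fit_window(conc, t_start, base, tolerance = 0.05)
  fit <- fit_power_law(conc, t_start, win$t_end,
                       t_origin = rec$addition_time)
  expect_equal(res$k_uptake, fit$k, tolerance = 1e-12)
  expect_equal(res$B, fit$B, tolerance = 1e-10)
  expect_equal(res$t_fit_end, win$t_end)
  expect_equal(res$baseline, base)
})

test_that("normalization divides by the mean control exponent", {
  expect_equal(normalize_uptake(-0.05, c(-0.05))$ratio, 1)
  nu <- normalize_uptake(-0.31, c(-0.04, -0.06))
  expect_equal(nu$ratio, 6.2, tolerance = 1e-12)
  expect_identical(nu$n_controls, 2L)
  und <- normalize_uptake(-0.3, c(-0.01, 0.01))
  expect_true(und$undefined)
  expect_true(is.na(und$ratio))
  expect_error(normalize_uptake(-0.3, numeric(0)), "at least one control")
})

test_that("batch runner normalizes per salt with pooled fallback", {
  d <- withr::local_tempdir()
  co <- generate_cohort(target_ratios = c(saltA = 3), n_plant_reps = 2,
                        n_control_reps = 2, dir = d, noise_sd = 0, seed = 5)
  res <- run_uptake_batch(co$manifest, read_calibration_table(co$calibration))
  expect_identical(nrow(res), 4L)
  plant <- res[res$role == "plant", ]
  expect_true(all(abs(plant$ratio - 3) < 0.05))
  expect_true(all(is.na(res$ratio[res$role == "control"])))
})
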