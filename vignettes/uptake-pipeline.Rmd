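---
title: "From impedance traces to ion-uptake phenotypes"
author: "rhizosense"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From impedance traces to ion-uptake phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhizosense)
```

## The measurement and the model

Seedlings grown on a wetted paper disc sit on a screen-printed electrode
pair; the impedance magnitude at a fixed excitation frequency tracks the
ionic strength of the disc. Adding a small volume of salt solution steps
the local concentration up; as the roots take the ions back up, the
concentration relaxes toward its pre-addition baseline. The package
summarizes that relaxation with a power law

$$c(t) = B\,\tau^{k}, \qquad \tau = t - t_\mathrm{add},$$

whose exponent $k_\mathrm{uptake}$ (negative for decaying traces) is the
uptake phenotype. Because every recording also shows a slow impedance rise
unrelated to the plants (electrode wetting and evaporation, on the order of
0.1 kilo-ohm per hour), plant-free control discs are processed with the
identical pipeline and the reported quantity is the **normalized uptake
ratio** $k_\mathrm{uptake}/\bar k_\mathrm{control}$. Ratios at or below 1
mean no net uptake.

The chain for one experiment is:

1. **Calibration.** Per salt, an ordinary least-squares line of
   $\log_{10} Z$ on $\log_{10} c$ fitted to calibration points
   (`fit_impedance_calibration()`); the fit is inverted to convert the
   recorded impedance trace to concentration. The fit deliberately uses all
   supplied points: restricting to the sensor's linear range is the user's
   choice of points, because no robust automatic breakpoint rule exists for
   these sensors. pH and H2O2 channels use plain linear maps
   (`ph_from_potential()`, `h2o2_from_current()`).
2. **Baseline.** The mean concentration over the first 2 hours of the
   recording (`estimate_baseline()`), before any addition.
3. **Peak.** The post-addition concentration maximum
   (`find_post_addition_peak()`). If the concentration never exceeds the
   baseline, or never decreases after the addition, the uptake is set to
   zero.
4. **Fit window.** From the peak to the first sample at or below
   `baseline * 1.05` — the 5% tolerance; if the trace never re-meets the
   baseline, to the end of the recording (`find_fit_window()`).
5. **Fit.** OLS of $\log_{10} c$ on $\log_{10}\tau$ over the window
   (`fit_power_law()`), with the addition time as the origin of $\tau$.
6. **Normalization.** Division by the mean control exponent
   (`normalize_uptake()`), with an explicit undefined flag when the control
   mean is numerically zero.

## Numerical and design choices

**Time origin.** $c = B\tau^k$ is origin-sensitive and the origin is not
derivable from the data; the addition instant is the only physically
distinguished time, so $\tau = t - t_\mathrm{add}$. This is configurable in
`fit_power_law()`.

**Baseline-meeting rule.** "Meets the baseline within 5%" is evaluated on
the measured (optionally smoothed) concentration, one-sided from above
(additions raise the concentration, the decay approaches the baseline from
above). The alternative — iterating until the *fitted curve* crosses the
baseline — would require a fixed-point iteration with no clear convergence
guarantee, and is not used.

**Log-space fitting.** The fit is linear OLS on logged data rather than
nonlinear least squares in linear space: it is deterministic, needs no
starting values, and weights the relative (multiplicative) errors that
electrochemical noise actually produces.

**Smoothing.** The rolling percentile filter (`percentile_filter()`,
default 50th percentile) mirrors the display smoothing used for such
traces; windows are counted in samples, centered, and truncated at the
series edges so the output length equals the input. Peak *detection* runs
on a smoothed copy by default (100-point median), but the power-law fit
runs on the unsmoothed conversion: smoothing flattens fast transients and
would bias $k$ for quickly decaying salts. Detection smoothing never mixes
pre- and post-addition samples in one window — a median window straddling
the step dips artificially and mislocates the peak.

**Peak location under noise.** The literal argmax of a noisy plateau is the
largest noise excursion and is biased late; since the control's log-log
slope is strongly window-start dependent, that bias propagates into the
normalization denominator. The pipeline therefore takes the *earliest*
sample whose smoothed value is within the tolerance (default: the same 5%)
of the post-addition maximum. On noiseless decaying traces this coincides
exactly with the argmax; `find_post_addition_peak(..., tolerance = 0)`
restores the strict argmax.

**Degenerate traces.** A peak on the last sample leaves no transient to
fit and is treated as zero uptake, as is any trace whose post-addition
concentration never decreases. Fits require at least three samples and
strictly positive concentrations.

## What the synthetic generator emulates — and what it does not

`generate_trace()` builds: a flat baseline at `c0` for at least 3 hours; a
step to `c_peak` at the addition; a decay
$c = c_\mathrm{peak}(\tau/\tau_1)^{k_\mathrm{true}}$ anchored so the first
post-addition sample sits at the peak (avoiding the $\tau = 0$
singularity), clamped from below at `c0`; a linear impedance drift
(default 100 ohm/hour, the observed control drift); and multiplicative
lognormal noise on the impedance (default 0.5%, a plausible placeholder —
the true instrument noise and sampling rate are not published, so both are
explicit parameters). Defaults use a 24 h recording sampled every 60 s
with the addition at 3 h, and a representative calibration line (slope
−0.5, 10 kilo-ohm at 1 mol/L).

`generate_cohort()` closes the loop on target normalized ratios, using the
printed channel-blocker experiment values (untreated 6.1; water 5.8; NaCl
6.0 at 4.5 h and 4.7 at 24 h; LaCl3 4.0 at 4.5 h and 3.1 at 24 h) as
presets: it first measures the drift-equivalent control exponent
$k_\mathrm{control}$ by running the full pipeline on a noiseless control
trace, then sets each plant run's $k_\mathrm{true}$ to
$\mathrm{target} \times k_\mathrm{control}$. Plant traces carry that
drift-equivalent decay inside $k_\mathrm{true}$ and no separate impedance
drift — if they carried both, the measured ratio would sit near
target + 1 rather than the target. Controls carry the drift in impedance
space, where the electrode physics puts it.

What the generator does **not** emulate: dissolution/mixing kinetics at
the addition (the step is instantaneous), electrode polarization and
double-layer dynamics, temperature or humidity excursions, multi-salt
interference, and pH/H2O2 plant dynamics (those channels are exercised
only through their linear calibrations). Passing tests on synthetic data
therefore demonstrate the correctness and stability of the *estimators*,
not the biological validity of the power-law model for any particular
organism.

`generate_ml_dataset()` draws salts with replacement from the bundled
29-salt panel and assigns latent ratios from class-conditional normals
whose means follow the observed pattern — nutrient-cation and sodium salts
high, heavy-metal salts at or below 1 — with a separation multiplier
(`class_signal_strength`, 0 = permutation null) and Gaussian noise
(sd 0.5). The descriptors are real ion properties (charge, mass,
periodic-table group, nutrient class); only the ratios are synthetic.

## Group statistics

`one_way_anova()` is the classical fixed-effects F test computed through a
standard linear-model fit; `tukey_kramer()` performs all pairwise
comparisons with the Kramer unequal-$n$ standard error
$\sqrt{\mathrm{MSE}/2\,(1/n_i + 1/n_j)}$ and studentized-range p-values
from base R's `ptukey` (numerical, so any number of groups works). The
compact letter display uses the standard insert-and-absorb algorithm, with
letters ordered by descending group mean. The simulated type-I error of
the ANOVA at $\alpha = 0.05$ is checked against [0.045, 0.055] over 10,000
null replicates in the test suite.

## The uptake classifier

`crossval_classify()` trains a gradient-boosted tree ensemble (depth 3,
100 rounds, learning rate 0.3, single-threaded for bit-reproducibility —
the reference work names no hyperparameters, so these shallow-tree
defaults are documented and overridable) under 5-fold cross-validation,
stratified when every class has at least five members. Ratios are binned
by `bin_uptake()`: two ranges split at ratio 1 (uptake vs no uptake); for
3–6 ranges the first boundary stays at 1 and the rest divide (1, max]
equally — the reference work does not state its boundaries, so this fixed
deterministic rule is used, with a configurable override. F1 is the
positive-class $2PR/(P+R)$ for binary problems and the macro average
otherwise (the averaging convention is likewise unstated and documented
here as an assumption), then averaged over folds.

## Problem sizes and reproducibility

The test suite and acceptance script use 24 h traces at 60 s sampling,
200 Monte-Carlo replicates for noise studies, cohorts of 3 plant + 3
control replicates per condition, 10,000 ANOVA null replicates, and
120-sample classification datasets over 20 seeds — sizes at which every
reported Monte-Carlo margin is stable. All randomness flows from explicit
seeds through an RNG-state-preserving wrapper; generating data never
perturbs the caller's RNG stream.

## Known limitations

* The power law is a phenomenological summary, not a transport model;
  $k$ values from different window lengths are comparable only through
  control normalization.
* Automatic linear-range selection for calibrations is out of scope; the
  user picks the points.
* `k_uptake` is stored signed (negative for decay); the normalized ratio
  is positive when plant and control decays share sign. Magnitude-only
  reporting would hide sign inversions, so it is not done.
* With very fast decays (a transient shorter than the smoothing window)
  the smoothed detection series flattens; the pipeline guards this by
  clamping the fit start to the first post-addition sample, but fewer than
  three in-window samples still abort the fit, by design.

## A worked example

```{r example, eval = FALSE}
dir <- tempfile()
cohort <- generate_cohort(dir = dir, seed = 1)        # blocker presets
curves <- read_calibration_table(cohort$calibration)
results <- run_uptake_batch(cohort$manifest, curves)
aggregate(ratio ~ salt_name, results[results$role == "plant", ], mean)
```
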