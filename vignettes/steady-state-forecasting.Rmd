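---
title: "Modelling and forecasting adsorptive gas-sensor transients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and forecasting adsorptive gas-sensor transients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sensecast)
```

## The problem

Metal-oxide-semiconductor (MOS) gas sensors are the workhorse of low-cost
electronic noses for breath analysis: adsorbing volatile organic compounds
change the conductance of a heated oxide film. Their drawback is a settling
time of a minute or more, while a complete breathing cycle lasts a few
seconds. If the steady-state reading could be forecast from the first ~10 s
of the transient, breath-by-breath analysis would become possible without
bagging and storing breath samples.

`sensecast` implements that forecasting pipeline: a physically motivated
response-model family, signal conditioning for raw acquisition channels,
multi-start nonlinear least-squares (NLLSQ) fitting, a synthetic exposure
generator with split-then-augment dataset construction, two small MLP
forecasters, and outlier-robust evaluation.

## The response-model family

Ideal monolayer (Langmuir) adsorption gives fractional site occupancy
$\theta$ obeying
$$\dot\theta = k_{ad}(1-\theta) - k_d\,\theta,$$
whose solution approaches its steady state as a single exponential with
rate $k_{ad}+k_d$ (`langmuir_occupancy()`). Real films add surface
heterogeneity, multi-layer effects and pore diffusion; the phenomenological
fix is a Kohlrausch *stretched* exponential $e^{-(t/\tau)^\beta}$. A second,
faster exponential term absorbs the initial transient caused by gas
diffusing into the sensing chamber. The resulting reference model is
$$x(t) = a_1 e^{-(t/\tau_1)^\beta} + a_2 e^{-t/\tau_2} + o ,$$
whose limit at infinite time — the forecasting target $t_\infty$ — is the
offset $o$ exactly (`steady_state_value()`).

Four nested candidates are kept (`table_forms()`): first- or second-order,
with or without the stretch. Higher orders and per-term delays are
representable (`model_form(3, ...)`, `delayed = TRUE`) purely so that their
over-parameterisation can be demonstrated: on second-order data an
order-3 fit yields amplitude confidence intervals spanning zero or no
meaningful RMSE improvement, and that is how the family size was frozen.

## Signal pipeline

Raw channels are converted to engineering units (12-bit ADC counts to
volts; divider voltage to chemiresistor resistance, sensor on the high
side; shunt-amplifier voltage to electrochemical current with the 100 Ω /
gain-225 chain), median-filtered with a 3-sample window (150 ms at the
20 Hz sampling rate — far below the sensor dynamics, so only isolated
glitches are touched), and windowed to the 85 s exposure starting where the
airflow channel first exceeds 0.2 slm. Conventions the hardware does not
dictate are fixed and documented: replicate padding in the median filter
(length-preserving), strict `>` with first-crossing tie-break at the onset,
1-based sample indexing with half-open windows, and the divider topology
(which only flips a monotone transform).

## Fitting

`fit_response()` runs Levenberg–Marquardt with box bounds and analytic
Jacobians. The initial guess is data-driven: offset from the mean of the
last 5 % of the fitted span, total amplitude from the first sample, time
constant from a log-linear fit of the decay, $\beta_0 = 0.9$; `n_starts`
(default 8) jittered copies (±50 %, seeded) guard against local minima, and
`compare_forms()` additionally warm-starts each richer form from the
embedded solution of its nested simpler forms, which enforces the nesting
inequality in practice. Bounds: $\tau \in [0.05, 500]$ s,
$\beta \in [0.1, 1.5]$, amplitudes and offset unbounded (an electrochemical
channel may rise). Convergence requires a solver success code *and* a small
projected gradient; because an absolute gradient threshold is meaningless
across signal scales, the check is relative,
$\|g_{proj}\| \le \sqrt{tol}\,(1 + SS)$ with `tolerance = 1e-8`, and
components pressing against an active bound are excluded. A fit that
converges nowhere is returned flagged, never silently.

Goodness of fit is RMSE over all samples of the curve, plus NRMSE
(normalised by the measured signal range) for cross-sensor comparability.
Fitting on a truncated horizon `tn` and scoring on the full curve
(`truncation_study()`, horizons 85/40/20/10 s) quantifies how plain
curve-fitting degrades into extrapolation: in-sample residuals stay small
while the full-curve error grows monotonically as the horizon shrinks.

A numerical caveat worth knowing: truncated stretched-exponential fits are
badly conditioned even without noise — many parameter sets reproduce the
first 10 s to residuals below 1e-3 of range while disagreeing wildly at
infinite time. The default 8 starts are enough for full-span fits; reaching
the zero-residual basin of a noiseless 10 s fit can take a multi-start an
order of magnitude denser.

## Synthetic exposures

`generate_dataset()` emulates the acquisition: coefficients drawn uniformly
per archetype, a constant pre-onset baseline at the model's $t=0$ value, a
step in the companion airflow channel, additive white Gaussian measurement
noise after the onset, and windowing through the very same onset-detection
path real recordings would take. Archetype intervals are implementer-chosen
to be realistic for such hardware, not measured values: the MOS-like
presets decay over tens of seconds ($\tau_1 \in [15,45]$ or $[25,60]$ s,
$\beta \in [0.5,1.0]$, fast term $\tau_2$ of a few seconds), the
electrochemical preset settles within ~10 s and rises (negative
amplitudes). Noise is 1 % of trace range (0.5 % electrochemical), chosen to
land full-span NRMSE of the reference fit near 0.01 — the level a low-cost
bench setup typically achieves.

The dataset protocol is split-then-augment: 25 exposures, an 80–20 split
(20 train / 5 test), then 4 children per exposure — 125 rows total — by
$x' = s_a (x - o) + s_o\, o + \varepsilon$ with
$s_a \sim U(0.8, 1.2)$, $s_o \sim U(0.9, 1.1)$ and
$\sigma_\varepsilon = 0.005$ of range (the scaling ranges are stand-ins;
no published values exist). Decomposing at the *stored offset* rather than
the last sample makes the transform exact on the model family, so child
targets are the parent's with $a_i s_a$ and $o\, s_o$. Children inherit the
parent's split, which is precisely what keeps train and test stratified and
leakage-free. Every stage takes a seed and is bit-reproducible.

What the generator deliberately does not emulate: sensor drift, humidity
and temperature sensitivity, gas-mixture cross-sensitivity, the recovery
(purge) phase, and cyclical breathing airflow. Passing tests on this data
therefore demonstrate the pipeline's correctness and the forecasters'
behaviour *under the model's own assumptions*, not performance on real
breath data.

## The two MLP forecasters

Both networks see the first 200 post-onset samples (10 s at 20 Hz) and
share a 200–50–24 leaky-ReLU trunk (slope 0.01, configurable); the output
layer is 6 linear units predicting the coefficient vector
$(a_1, \tau_1, \beta, a_2, \tau_2, o)$ — the forecast is then the predicted
$o$, the exact limit, with evaluation at a finite time exposed as an option
— or 1 unit predicting the final value directly. Inputs are divided by the
maximum training-set onset value; each target column by its training-set
maximum; factors are stored with the model and reused on test data.

Training is minibatch Adam, learning rate 2e-4, batch 16, 100 epochs, MSE
on scaled targets (the loss is not stated anywhere authoritative; MSE is
the standard regression choice), seeded Glorot-uniform initialisation,
per-epoch reshuffling, no early stopping and no schedule. At ~11 k weights
this trains in seconds on one CPU; `cross_validate()` reports per-fold
training losses over 5 seeded folds of the training portion. Synthetic
datasets use generator ground truth as coefficient targets; for real data
the targets would come from full-span reference-model fits.

## Evaluation

`ground_truth_final_value()` defaults to the model-free tail mean (final
1 s of the 85 s window); the fitted-offset alternative exists because an
operational definition of "true final value" is otherwise missing.
`error_metrics()` reports MAE/MAPE and their geometric counterparts
GMAE/GMAPE; the geometric mean suppresses the few catastrophic forecasts
that otherwise dominate, and zero errors are floored at 1e-12 inside the
logs (flagged via an attribute) rather than dropped. Samples with APE above
3× the method median are flagged as outliers, never removed.

On the 125-row synthetic dataset, both networks typically achieve GMAPE in
the 6–17 % range at the 10 s window against 12–33 % for NLLSQ
extrapolation, and the test suite pins one such realisation. The margin is
smaller than on real data, and on occasional realisations a lucky NLLSQ
run is competitive: synthetic traces come from exactly the family NLLSQ
fits, so extrapolation is far better-behaved here than under real-world
model misspecification. The qualitative ordering — learned forecasters
beat naive curve extrapolation at short windows — is the robust finding.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use 20–25 exposures per
experiment, 4 augmentation children, full 85 s / 20 Hz geometry, 8 fitting
starts (4 where many fits are averaged), and 100-epoch training — the full
study geometry, sized to run in minutes on one CPU. Degenerate inputs are
handled explicitly: constant traces fit to their level with near-zero
amplitude but have undefined NRMSE (an error, not an NA), non-positive
scaling maxima fall back to absolute values with a warning, and a
non-converged fit refuses to extrapolate.
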