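---
title: "Modelling finger-skin temperature recovery as a feedback control system"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling finger-skin temperature recovery as a feedback control system}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermofit)
```

## The model and its assumptions

After an isometric handgrip exercise, the skin temperature over a finger
joint first drifts passively (often undershooting below the post-exercise
value) and then actively re-warms toward its basal level. `thermofit`
abstracts the many physiological processes behind this as a "black-box"
second-order, time-invariant feedback loop with two hierarchical units: a
supervisor that decides *when* active recovery starts, and an executor — a
first-order plant driven by an integral controller — that carries it out.

All dynamics run in *deviation coordinates*: the modelled signal is
$\tilde y(t) = y(t) - y_0$, where $y_0$ is the temperature at the end of the
exercise, and the reference is $r = T - y_0$ with $T$ the time-averaged
baseline (basal) temperature. This reconciles the zero-initial-condition
assumption of the transfer-function analysis with the physical fact that the
recording starts at $y_0$, and it makes the disturbance parameter a
deviation-scale quantity. Absolute temperatures are restored only at the
I/O boundary (`to_absolute()` / `deviation_transform()`).

The switched dynamics are:

* **open loop**, $t < LT$: $\dot{\tilde y} = a\,(d - \tilde y)$ with
  $\tilde y(0) = 0$, hence $\tilde y(t) = d\,(1 - e^{-a t})$. The constant
  $d$ is the uncontrolled heat exchange with the environment; a negative $d$
  produces the characteristic undershoot.
* **closed loop**, $t \ge LT$: $\dot{\tilde y} = a\,(m + d - \tilde y)$,
  $\dot m = K\,(r - \tilde y)$, with the integrator reset at the switch,
  $m(LT) = 0$. Integral action guarantees $\tilde y \to r$ (zero
  steady-state error) whenever $K > 0$, which is the control-theoretic
  reading of homeostasis.

The plant has unit static gain (its input gain equals its pole $a$);
allowing separate gains would make the parameterisation degenerate. The
disturbance drives the plant through the same path in both regimes — the
supervisor gates only the controller.

**Units.** Everything is in sample units: one sample is 10 s at the 0.1 Hz
acquisition rate. Thus a lag of $LT = 6$ is one minute, and a pole of
$a = 0.1$/sample corresponds to a 100 s time constant. The search bounds
($LT \le 22$ samples, i.e. within the 30-sample recovery window) are only
consistent with this choice.

## Simulation: exact closed form

Both regimes are linear and time-invariant, so the package evaluates the
trajectory in exact closed form instead of calling a numerical ODE solver:
the closed-loop phase is the matrix exponential of the $2\times2$ system in
its equilibrium-shifted coordinates, implemented with overflow-safe
overdamped / underdamped / critically-damped branches. This is exact at
every sample, roughly two orders of magnitude faster than adaptive
integration (the estimation chain evaluates the simulator thousands of
times per curve), and free of solver tolerances. The lag time is treated as
continuous — the closed-loop phase starts from the open-loop solution
evaluated *exactly* at $t = LT$ — so estimated lags are not quantised to
the sampling grid.

The test suite validates the closed form against an independent brute-force
discretisation: fixed-step classical RK4 starting at 1/100 of the sample
spacing and halving the step until self-convergence. Over the stable part
of the search box the two agree to better than $10^{-9}$ °C; unstable
parameter sets ($K < 0$, admitted by the search space) grow exponentially
and are compared at relative tolerance, since absolute agreement on
trajectories of magnitude $10^{13}$ is beyond double precision for any
method.

## Preprocessing

Raw exports (CSV, one temperature column per region at 0.1 Hz) are
validated for uniform sampling and plausibility (15–42 °C; out-of-window
samples are masked and linearly interpolated, with a series rejected above
10% missing). Smoothing is a centred moving average of span 5 with
symmetrically shrinking edge windows (widths 1, 3, 5 …), the common default
of thermal-analysis platforms: it passes affine signals unchanged and never
widens the value range. Smoothing is applied to the full recording *before*
the baseline/recovery split, so the boundary samples share windows — the
order in which the original analysis states it. The basal temperature is
the baseline mean; $y_0$ is the first recovery sample, not an extrapolation
into the unrecorded exercise gap.

Smoothing has a cost that matters for interpretation: a span-5 average
attenuates dynamics on the scale of a few samples. On the fast
no-undershoot regime ($a = 0.8$, $K = 1.5$) it biases the fitted gain from
1.5 to about 0.49 even without noise. The pipeline keeps smoothing because
the estimation is defined on the filtered signal, but the estimator's own
noise-robustness properties are stated on unsmoothed input, and the bias is
one reason cohort-level contrasts shrink through the full pipeline (see
below).

## Parameter estimation

Estimation minimises the mean-squared criterion
$f = \frac{1}{N_E}\sum_i (y^*_i - y^e_i)^2$ (units °C²). The $1/N_E$
normalisation is chosen so the exclusion threshold $f > 1$ — about 1 °C RMS
misfit — is independent of curve length; the threshold comparison is strict,
so a fit at exactly 1 is retained. $T$ and $y_0$ are measured quantities
and are never fitted.

Three stages:

1. **Graphical initialisation** — classical step-response identification:
   the lag is the turning point before the sustained rise (detected as the
   last sample before the slope first exceeds 5% of its peak); $d_0$ is the
   value there (the open-loop asymptote estimate); $a_0$ is the reciprocal
   of the time to cover 63% ($1 - e^{-1}$) of the remaining distance to the
   final value; and the whole-loop static gain (final value over $r$) maps
   to the controller gain via $K_0 = \text{gain} \times a_0$, the
   dimensional bridge implied by the unit-gain plant. Flat curves fall back
   to the search-space centre with a warning; estimates are clipped into
   the box.
2. **Nelder–Mead refinement** of the four-vector, unconstrained in the
   classical sense but with out-of-box proposals evaluated at their clipped
   point plus a quadratic penalty ($10^3 \times$ squared violation), and
   the incumbent clipped on return. Deterministic; 500 iterations,
   relative tolerance $10^{-10}$.
3. **Bounded nonlinear least squares** — Levenberg–Marquardt on the
   residual vector with box constraints (`minpack.lm::nls.lm`; cost
   tolerance $10^{-10}$, parameter tolerance $10^{-8}$, 200 iterations).

The chain guarantees monotone refinement (a later stage never returns a
worse incumbent than an earlier one; the better point is kept in the rare
degenerate corner), and the final parameters always lie inside the search
box.

**Identifiability.** Noiseless curves from the physiologically occupied
sub-box ($LT \le 15$, $a \le 2$, $|d| \le 1$, $0 < K \le 3$) are recovered
with median error at machine precision. The full search box is *not*
identifiable from a 30-sample window: poles and gains with
$\sqrt{aK} \gtrsim 3$/sample put the closed-loop natural frequency beyond
the Nyquist limit of the grid, and lags near the window end leave no
closed-loop samples. Under measurement noise there is also a known
$LT$–$d$ ridge: a shallow undershoot is almost equally well explained by a
shorter lag with a deeper disturbance, so $LT$ and $d$ have heavier-tailed
errors than $a$ and $K$. These are properties of the model-plus-protocol,
not of the optimiser.

## The synthetic cohort generator

The generator is the package's stand-in for the (undeposited) clinical
recordings and defines the conditions under which every downstream stage is
tested: 11 PsA and 9 HC subjects × 14 regions — 154 + 126 = 280 curves — at
0.1 Hz with 9 baseline and 30 recovery samples. Per (group, region), the
four parameters are drawn from independent normal distributions with the
group-average means and SDs of the packaged table, truncated to the search
box by resampling (100 attempts, then clipping). Normality is the minimal
assumption given that only means and SDs are reported; several SDs exceed
their means, so truncation is load-bearing. Per subject, the basal
temperature is drawn from N(30, 1) °C and the reference from N(0.8, 0.3) °C
truncated positive; measurement noise is iid Gaussian with SD 0.04 °C, the
thermal resolution of research-grade cameras. All randomness flows from one
master seed through an explicit splitting scheme; the caller's RNG state is
never touched.

What the generator does *not* emulate — and hence what passing tests do not
establish about real data: inter-region correlation within a hand (regions
are independent here), skewed or heavy-tailed parameter populations (the
real fitted distributions reject normality), physiological coupling between
parameters, and physical plausibility of the tail draws — a negative-$K$
draw (admitted by the table's negative group means) yields an unstable loop
whose "temperature" can leave the 15–42 °C window within the 5-minute
recording. Such recordings are rejected on re-ingestion by the plausibility
mask, and their fits are typically removed by the $f > 1$ exclusion — the
synthetic analogue of the original analysis excluding 13% / 4% of curves.

One consequence deserves emphasis. The cohort-level discrimination
property (pooled rank-sum tests flagging $d$ and/or $K$ in at least 80% of
seeded replicates) is *not met* by these generative conditions: even with
perfect parameter recovery, drawing 154/126 truncated-normal parameter sets
from the tabulated means and SDs yields a union power of about 0.79, and
the full pipeline (smoothing bias plus the exclusion rule preferentially
removing fast-dynamics and unstable draws, which carry much of the group
contrast) lands near 0.5. The corresponding acceptance test is left
failing deliberately: the tabulated means/SDs under a normal generative
model reconstruct a weaker group separation than the original skewed data
exhibited.

## Statistical conventions

* Group comparisons report the rank sum of the PsA group with midranks
  under ties. When the smaller group has fewer than 10 observations the
  p value is exact — computed from the tie-aware permutation distribution
  via a counting dynamic programme (validated against full enumeration) —
  and no z statistic is reported; otherwise the tie-corrected normal
  approximation is used and z is reported. Two-sided throughout;
  $\alpha = 0.05$; no multiple-testing correction, matching the original
  analysis.
* Classification is binary logistic regression of group on
  $(LT, a, d, K)$ with HC as reference (a two-class "multinomial" model
  reduces to exactly this). Perfect separation is detected and flagged
  rather than silently diverging; Wald statistics are $\beta/SE$ and odds
  ratios $e^\beta$.
* The ROC sweeps every distinct fitted probability; the cutoff maximises
  Youden's $J$, with ties broken toward higher sensitivity and then toward
  the higher threshold (in a perfectly separated cohort the returned
  cutoff keeps every positive). Records exactly at the cutoff are
  predicted PsA. The AUC is the area under the empirical ROC polygon,
  which equals the Mann–Whitney exceedance probability with ties counted
  half (asserted in the tests, cross-checked against pROC). Confusion
  matrices are row-normalised percentages; classification is in-sample, as
  in the original region-based analysis.

## Problem sizes and runtimes

The test suite and acceptance checks are sized for a single CPU: 100
parameter draws for the simulator-equivalence and integral-control checks,
200 replicates per regime for noisy recovery, 200 noiseless draws for the
recovery property, exhaustive rank-sum enumeration up to group sizes of 7,
and 20 seeded default cohorts (5 600 curve fits) for the end-to-end
discrimination property. The full analysis workflow (280 curves,
generation through classification) completes in about two minutes.

## Known limitations

* The model is a deliberate abstraction: no bioheat physics, no modelling
  of the exercise period itself ($t = 0$ is the end of exercise), step-like
  reference semantics, and a single switch time.
* The identifiable region of the search box is much smaller than the box
  itself (Nyquist and window-length limits above); fitted parameters near
  the bounds should be read as censored values, not point estimates.
* The generator's independence assumptions understate the structure of
  real cohorts; classification results on synthetic data (often perfectly
  separated at per-region sample sizes of 9–11 per group) are demonstrations
  of the machinery, not effect-size claims.
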