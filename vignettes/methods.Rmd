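---
title: "Methods: models, defaults and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, defaults and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the mathematical models behind each module, why the
defaults are what they are, and the numerical decisions that affect
results. Code chunks are illustrative and not evaluated at build time.

## 1. Balloon design model

A balloon of volume $V$ filled with a gas mixture of density
$\rho_\mathrm{balloon}$ in air of density $\rho_\mathrm{air}$ produces a
net buoyant force

$$F = (\rho_\mathrm{air} - \rho_\mathrm{balloon})\, g\, V .$$

Mixture density is the volume-fraction-weighted mean of component
densities. Defaults are $\rho_\mathrm{air} = 1.204$ and
$\rho_\mathrm{He} = 0.1664$ kg·m⁻³ (20 °C at sea level); both are plain
arguments, so other temperatures are a parameter change, not a code
change. With the default 15 L, 80/20 helium–air balloon this gives an
equivalent lift mass of 12.45 g; subtracting the 3 g envelope and 2 g
rigging leaves a payload capacity of 7.45 g. `required_volume()` inverts
the payload equation in closed form and raises an error when the gas is
not lighter than air (no volume is feasible).

**Tether geometry.** The cord is modeled as a taut straight line: with
anchor height $h$ and lateral offset $d$ the balloon-side end drops by
$\sqrt{h^2 + d^2} - h$. A catenary correction is deliberately omitted —
with ~0.07 N of tension from the net lift and a light cord, sag is
negligible at these scales, and the straight-cord model already matches
the published 1.34 cm worked example for $h = 1.2$ m, $d = 18$ cm.

**Inertial audit.** Buoyancy cancels weight, not inertia:
`inertial_force(0.006, 1.5)` reports the 9 mN needed to accelerate the
counterbalanced 6 g at a typical locomotor 1.5 m·s⁻².

## 2. Kinematics

Trajectories are confidence-filtered (points below `confidence_floor =
0.6` are replaced by linear interpolation in time), converted to cm via
`px_per_cm`, and lightly smoothed with a centered moving average
(`smooth_window = 5` frames; at 30 frames/s this is a 167 ms window, short
relative to locomotor dynamics but enough to suppress single-frame tracker
jitter).

- **Path length** is the sum of Euclidean steps, reported in meters.
- **Total turning angle** is the sum of absolute heading changes between
  consecutive displacement vectors. Heading is undefined for near-zero
  steps, so steps shorter than `min_step_cm = 0.2` are merged into their
  neighbors before computing angles (at 30 frames/s, 0.2 cm per frame is
  6 cm/s of apparent speed — genuine walking steps survive, sub-pixel
  jitter does not). This guard is applied to the turning total only; the
  instantaneous kinematic series keeps every frame so that velocity
  statistics are unbiased.
- **Kinematic series**: speeds live on step midpoints; angular velocity is
  the wrapped heading difference over the midpoint interval, and the two
  accelerations are first differences of the velocities. The first
  angular-velocity sample and the first acceleration samples are `NA` by
  construction rather than zero-padded.
- **Segmentation**: frames with speed ≥ `v_threshold = 2` cm/s are walking
  (the conventional open-field threshold, comfortably between tracker
  noise and the ~4–7 cm/s walking speeds here). Runs shorter than
  `min_bout_s = 0.5` s are merged shortest-first into their neighbors, so
  single-frame threshold chatter does not fragment bouts.
- **Session summary**: distance, turning, walking fraction, and
  time-weighted means of walking-bout speed and absolute angular velocity.

## 3. Calcium transients and the fluorescence rate

Input is a ΔF/F matrix (neurons × frames, default 3 frames/s, 167 s = 500
frames, as produced by upstream segmentation). Per neuron:

1. **Baseline** is the 20th percentile of the trace — robust to activity
   occupying a minority of the session.
2. **Noise** is estimated from successive differences,
   $\hat\sigma = \mathrm{mad}(\Delta F_t)/\sqrt{2}$, which is insensitive
   to the slow transient envelope. If the trace is too quiet for that
   estimator it falls back to the MAD of below-baseline samples, then the
   global MAD, then a small constant; a perfectly flat trace yields no
   transients and a warning.
3. **Transients** are maximal runs above `baseline + 3·σ̂`. Onset and
   offset are linearly interpolated at the threshold crossings — this is
   what makes the area second-order accurate in the frame interval rather
   than first-order. Runs shorter than `min_duration_s = 0.66` (two frames
   at 3 frames/s) are discarded as noise spikes.
4. **Valley splitting**: within a run, interior local minima that dip
   below `split_dip_frac = 0.5` of the smaller flanking peak (measured
   from baseline) split the run, deepest first, recursively. Without this,
   Poisson-overlapping events merge into one long transient and the rate
   statistic acquires a heavy tail; `split_dip_frac = 0` disables it.
5. **Rate**: each transient's *fluorescence rate* is its
   baseline-subtracted trapezoidal area divided by its duration; a
   neuron's overall rate is the unweighted mean over its transients
   (`NA` with zero transients).

**Classification.** With overall rates $r_p$ (probe only), $r_{bw}$
(balloon + weight), $r_w$ (weight) and relative tolerance
$\tau = 0.20$, a neuron is

- *suppressed* iff $|r_{bw} - r_p| < \tau r_p$ and
  $r_p - r_w > \tau r_p$ and $r_{bw} - r_w > \tau r_{bw}$;
- *enhanced* with the two weight inequalities mirrored;
- *unclassified* otherwise (including any missing rate).

Inequalities are strict, so exact 20% ties are unclassified; the two
labels are mutually exclusive by construction ($r_w$ cannot be both more
than 20% below and more than 20% above $r_p$). The rule is invariant to
common rescaling of the three rates.

## 4. Mixed-model inference

Each behavioral response is modeled as

$$y_{ij} = \mu + \beta_{\mathrm{condition}(j)} + b_i + \varepsilon_{ij},
\qquad b_i \sim N(0, \sigma_a^2),$$

fit by REML (`lmerTest::lmer`). The condition fixed effect is tested with
a Satterthwaite-denominator F; in the balanced 5-animal × 3-condition
design this reproduces the classical randomized-block (repeated-measures
ANOVA) test with denominator df $(k-1)(n-1) = 8$ exactly. The animal
random effect is tested by a likelihood-ratio test of the ML refit against
the condition-only linear model ($\chi^2_1$); when the fitted
between-animal variance is zero (a singular fit) the random-effect p-value
is reported as 1 and the fixed-effect F equals the one-way ANOVA F — a
property the test suite asserts. Pairwise condition contrasts come from
`emmeans` marginal means with Bonferroni adjustment
($p_\mathrm{adj} = \min(1, 3p)$, three comparisons).

## 5. Synthetic generator: calibration and limitations

**Trajectories** follow a two-state (walk/rest) continuous-time Markov
chain sampled at 30 frames/s: transition probabilities
$1 - e^{-\text{rate}\,\Delta t}$, walking speed Gaussian truncated at zero,
heading a random walk with variance `heading_diffusion`·Δt, positions
reflected into a 25.4 cm (10″) square arena, 167 s sessions. Defaults were
calibrated once, analytically, to the published condition means — expected
distance equals (stationary walking fraction) × duration × mean speed:

| condition      | walk/rest rate (s⁻¹) | speed (cm/s) | expected distance |
|----------------|----------------------|--------------|-------------------|
| probe only     | 0.20 / 0.20          | 6.7 ± 2.0    | ≈ 5.6 m           |
| balloon+weight | 0.20 / 0.20          | 6.7 ± 2.0    | ≈ 5.6 m           |
| weight         | 0.12 / 0.22          | 4.2 ± 1.5    | ≈ 2.5 m           |

so the weight condition covers ≈ 0.44 of the control distance. Each
animal gets a log-normal speed multiplier (SD 0.08 on the log scale,
shared across conditions) so the animal random intercept in the mixed
model is estimable rather than identically zero.

**Known limitation — turning angle.** Wall reflections in a small arena
impose a geometric floor on total heading change, so absolute turning
totals run above the published values (~1.4×) even though the
weight-to-control *ratio* (≈ 0.5) matches. `heading_diffusion = 0.01`
rad²/s was chosen to match that ratio; treat absolute turning totals from
the generator as internally consistent rather than literally calibrated.

**Calcium traces**: per neuron a homogeneous Poisson train (baseline 0.12
events/s) of double-exponential kernels (0.1 s rise, 1.0 s decay,
GCaMP6m-scale), unit peak, log-normal amplitudes (median 0.8 ΔF/F), white
noise SD 0.05 (signal-to-noise ~16, typical of fiberscope ΔF/F output). Of
124 neurons, 25 are planted weight-suppressed and 15 weight-enhanced:
under the weight condition their event rate *and* amplitude are scaled by
0.5 or 1.5 (a "50% change"). Under the other two conditions all neurons
are statistically identical, so any classifier call there is a false
positive. At these defaults the classifier recovers planted neurons with
sensitivity ≈ 0.95 at a false-positive rate ≈ 0.01.

**Determinism.** Every generator takes an explicit seed; cohort-level
functions fan a master seed out into per-session seeds through a fixed
splitting rule, so entire cohorts, pipeline outputs, and the acceptance
JSON are reproducible bit-for-bit.

## 6. Numerical choices

- Trapezoidal integration with interpolated endpoints for transient areas:
  exact for piecewise-linear signals between crossings, $O(\Delta t^2)$
  otherwise (the test suite checks the convergence rate on triangular
  pulses).
- Angles are accumulated from `atan2` differences wrapped to
  $(-\pi, \pi]$, never from arccosines, avoiding catastrophic cancellation
  for near-straight steps.
- The moving-average smoother uses a cumulative-sum formulation with
  edge-shrinking windows (no zero padding), so endpoints are unbiased.
- p-values are never multiplied beyond 1; Bonferroni is applied to the
  three pairwise contrasts only, not the omnibus test.
- Seeds are kept below $2^{31}$ so they are valid R integer seeds on all
  platforms.

## 7. Problem sizes and runtime

Chosen so the full suite runs on one CPU in minutes: sessions are 167 s at
30 frames/s (~5,000 tracking frames) and 500 imaging frames at 3 frames/s;
cohorts are 5 animals × 3 conditions; the default neuron population is
124. One full pipeline run (15 sessions + one imaged experiment) takes
~15 s; one mixed-model cohort replicate ~0.5 s; the acceptance script
(~100 model replicates plus 3 classifier experiments) about a minute.
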