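---
title: "Dissecting fast and slow processes in saccadic adaptation: methods and design choices"
author: "saccadapt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting fast and slow processes in saccadic adaptation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saccadapt)
```

# The scientific problem

Saccadic adaptation is the gradual recalibration of saccade amplitude that
occurs when the target is systematically displaced while the eye is in
flight (saccadic suppression hides the jump). In a *global* adaptation
paradigm the eye travels a closed path — here a clockwise hexagon with
10 dva between neighbouring targets — so every one of the six saccade
directions adapts. Displacing the target 3.3 dva forward along the saccade
trajectory drives gain-up adaptation, displacing it 2.5 dva backward drives
gain-down adaptation; the asymmetric magnitudes make the *relative*
post-displacement gains symmetric (13.3/10 vs 7.5/10, i.e. perturbations
+0.33 and −0.25 in relative-gain units).

The question the workflow addresses is how two qualitatively different
learning processes contribute to this adaptation for two kinds of saccades:
*reactive* saccades (a single target steps to the next vertex, latencies
near 200 ms) and *scanning* saccades (all six targets stay visible and the
next one is selected voluntarily, latencies near 300 ms). A session has
four blocks — 48 baseline trials, two 96-trial adaptation blocks of
opposite gain direction, 48 baseline trials — and each participant
completes the full factorial of saccade type by block order.

# The dual-state decomposition

The core model is the two-process (multi-rate) state-space model of motor
adaptation. On trial $i$, with error $\varepsilon(i)$:

$$x_f(i) = \alpha_f\,\varepsilon(i) + \beta_f\,x_f(i-1), \qquad
  x_s(i) = \alpha_s\,\varepsilon(i) + \beta_s\,x_s(i-1),$$
$$a(i) = \gamma_f\,x_f(i) + \gamma_s\,x_s(i).$$

The fast process learns quickly and forgets quickly
($\alpha_f > \alpha_s$, $\beta_f < \beta_s$) and is commonly linked to
explicit learning; the slow process is the implicit complement. The
learning and retention rates are fixed at the canonical values
$\alpha_f = 0.21$, $\beta_f = 0.59$, $\alpha_s = 0.02$,
$\beta_s = 0.992$; only the two process gains $\gamma_f, \gamma_s \ge 0$
are estimated. Fixing the rates deliberately trades flexibility in the
shape of each individual process for stability of the quantities of
interest: free 6-parameter fits let learning rates, retention rates and
gains trade off against each other, whereas with fixed rates the two gains
reweight two fixed basis shapes and are well identified (the package
reports the condition number of that basis via
`dual_state_identifiability()`; it is ≈ 6 for a 96-trial constant
perturbation, comfortably identifiable). A free-rate fit is not part of the
analysis surface.

All adaptation quantities are expressed in relative-gain deviation units
(baseline gain = 1), so the perturbation schedule is $p(i) = -0.25$ or
$+0.33$ during adaptation blocks and 0 at baseline.

**Error signal.** The model needs an error term and there are two
defensible definitions. The default is *closed-loop*,
$\varepsilon(i) = p(i) - a(i-1)$: the model corrects its own output, which
is the canonical multi-rate formulation and keeps simulation
self-contained. The alternative, *observed-error* mode
($\varepsilon(i) = p(i) - (g_{obs}(i-1) - 1)$, with a fall-back to the
model output on rejected trials), is available through
`error_mode = "observed"` in both the simulator and the fitter, since
measured behaviour arguably drives the real error signal. The choice
matters little for fitting (noiseless traces coincide), but closed-loop is
the default because it makes the generative model independent of
measurement noise.

**Summary quantities.** The *slow ratio*
$\gamma_s / (\gamma_f + \gamma_s)$ expresses the slow process's share of
total fitted gain (0.5 = equal contributions). Fits are per participant
and condition; ratios are averaged over the two gain directions within a
participant before any group statistics, and condition contrasts are
one-sample t-tests of the ratio against 0.5 and paired t-tests of the
reactive−scanning gain difference per process.

# Exponential timescale and the paired bootstrap

A complementary, model-light description of the first adaptation block is
the exponential $f(t) = 1 - \alpha\,(1 - e^{-t/\beta})$, which starts at 1
and approaches $1-\alpha$; $\alpha$ is the adaptation magnitude (negative
for gain-up) and $\beta$ the timescale in trials, deliberately decoupled
from magnitude. An algebraic variant that instead approaches $\alpha$
exists in the literature; it is available as `form = "printed"` but the
default follows the asymptote-at-$1-\alpha$ convention, which is the
stated interpretation of $\alpha$ as a magnitude.

Because $\alpha$ enters linearly given $\beta$, the fit profiles $\alpha$
out in closed form and searches $\beta$ on a log-spaced 40-point grid over
$(10^{-2}, 10N]$ refined by golden-section search to an SSE tolerance near
1e-10. This replaces multi-start gradient descent with a deterministic
search of the same space: self-consistency tests recover noiseless
parameters to $|\Delta\alpha| < 10^{-6}$, $|\Delta\beta| < 10^{-4}$. The
`converged` flag is honest: it is `FALSE` when the optimum sits on the
search boundary or when the data are constant, in which case $\beta$ is
unidentifiable and returned as `NA`.

Condition comparisons use a paired participant bootstrap: in each fold,
participants are resampled with replacement, the *same* resample is
applied to every condition, each condition's resampled series are averaged
and fitted, and per-fold parameter differences are collected. The
two-tailed p is twice the smaller of the fractions of differences below
and above zero, floored at $2/n_{folds}$ (ties count half to each side, so
literally identical conditions give p = 1). Final inference uses
$10^5$ folds; the bundled analyses and tests use 1000–2000 folds, which
changes p-value granularity but not the procedure. Calibration simulations
(500 null cohorts of 12 participants, 1000 folds) put the false-positive
rate at the 0.05 level near 0.09–0.10: with 12 participants this
percentile-type bootstrap is mildly anticonservative, a known property of
the procedure rather than of its implementation, and worth remembering
when reading p-values close to threshold.

# Saccade detection and kinematics

Detection uses the median-based velocity-threshold algorithm. Velocities
come from a five-sample moving-window differentiator
$v(i) = \frac{p(i+2)+p(i+1)-p(i-1)-p(i-2)}{6\,\Delta t}$ (edge samples
take the nearest interior value), and the threshold per component is
$\eta = \lambda\,\sigma$ with the robust spread
$\sigma = \sqrt{\operatorname{med}(v^2) - \operatorname{med}(v)^2}$, which
ignores the saccades themselves. Samples with
$(v_x/\eta_x)^2 + (v_y/\eta_y)^2 > 1$ are saccade candidates; maximal runs
separated by less than the merge gap are merged and runs shorter than the
minimum duration are dropped. The parameters $\lambda = 6$, minimum
duration 6 ms and merge gap 20 ms are standard for this algorithm family
and are arguments, not constants. Runs never extend across invalid
(blink) samples, and traces whose robust spread is zero raise an error
rather than silently returning nothing. A brute-force scan of the same
inequality is kept in the test suite as an oracle; the production
implementation must match its event boundaries exactly. One caveat
discovered by property testing: because thresholds are re-estimated per
component, rotating a trace can move a threshold crossing by one sample,
so rotation invariance holds for event counts and durations to ±1 sample,
not exactly.

Latency is onset minus flash onset (the go signal in both saccade-type
conditions, for comparability); negative latencies are kept but flagged
anticipatory.

# Quality control and normalisation

Trials are rejected, in this order, when (1) they contain a blink,
(2) the saccade amplitude is below 3 dva, (3) the amplitude is more than 3
two-sided median absolute deviations from its block's median, or (4) the
saccade start point is more than 1.5 dva from the pre-saccadic target. The
first failing rule is recorded as the reason, per-reason counts are
reported, and rejected trials stay in the table as `NA` gains — nothing is
dropped silently. The MAD is used raw (unscaled); a `mad_constant`
argument provides the 1.4826 normal-consistency factor if wanted. When a
block's MAD is zero (more than half its amplitudes identical) the rule
degenerates to rejecting any deviation from the median, which is the
behaviour that makes a lone wild amplitude in an otherwise constant block
an outlier; blocks contributing fewer than four amplitudes skip the rule
with a warning. The block statistics are computed over trials surviving
rules 1–2, which makes rejection idempotent. "Block" here means
experimental block within a session, not the whole session.

Amplitudes become gains by dividing by the median amplitude of the valid
first-block trials *of the same hexagon direction*, so direction-specific
amplitude differences cancel; peak velocity and duration are normalised
identically by their own baseline medians. Time-courses are smoothed with
a centered 6-trial running average (the hexagonal period), computed over
valid trials only, shrinking at edges, and never crossing a block
boundary. Block-transition scores are the mean gain of the first 6 trials
of the incoming block minus the mean of the last 6 of the outgoing block,
over valid trials among those six; a participant with no valid trial in
either window is excluded from that statistic rather than imputed.

# The synthetic cohort: what it emulates and what it does not

Every stage is testable without any recorded eye data because the
generator produces the full study from the protocol up:

* **Gain dynamics** follow the dual-state model (closed loop) with
  additive i.i.d. Gaussian observation noise, default `noise_sd = 0.05`
  gain units — typical trial-to-trial saccade-gain variability.
* **Condition means for the process gains** are the package's calibration:
  reactive $(\gamma_f, \gamma_s) = (0.522, 0.630)$ and scanning
  $(0.256, 0.762)$, with between-participant sd 0.15. These were
  back-solved from the group-level pattern the workflow is designed to
  detect — reactive adaptation split roughly equally between processes,
  scanning adaptation dominated by the slow process, overall adaptation
  comparable — and reproduce that pattern's contrasts (slow difference
  ≈ 0.13, fast difference ≈ 0.27) exactly at the means.
* **Latencies** are Gaussian with condition means 193 ms (reactive) and
  307 ms (scanning), trial sd 30 ms, between-participant sd 15 ms,
  truncated at 80 ms.
* **Kinematics** split the relative amplitude $rel = A/A_0$ into peak
  velocity $\propto rel^{w}$ and duration $\propto rel^{1-w}$, consistent
  with the minimum-jerk relation $A = \tfrac{8}{15} V D$. Gain-down blocks
  use $w = 0.8$ (velocity-driven), gain-up $w = 0.5$ (balanced), baseline
  $w = 0.69$ (the local main-sequence slope at 10 dva), reflecting the
  standard finding that amplitude reductions are carried mainly by peak
  velocity.
* **Gaze traces** (optional) fixate until the latency, then execute a
  minimum-jerk saccade whose peak velocity follows the main sequence
  $V(A) = V_{max}(1 - e^{-A/c})$ with $V_{max} = 500$ °/s, $c = 14$° —
  standard oculomotor values, fully configurable — plus positional noise
  and optional blinks (runs of invalid samples). Sampling is 1 kHz.
* **Awareness** responses are Bernoulli draws whose logit follows the
  residual displacement $|p(i) - a(i-1)|$ scaled to dva, with a larger
  slope for backward (fovea-crossing) jumps than forward ones and a logit
  bonus in scanning sessions (more visual references); baseline blocks
  fall back to a 2% false-alarm rate, and 2% of probes go unanswered.

What the generator does *not* emulate — and therefore what green tests do
not certify about recorded data: main-sequence variability and
fatigue-related drift, saccade curvature, post-saccadic oscillations and
corrective saccades, pupil-size artefacts, calibration drift, and any
dependence of the error signal on where the eye actually landed within a
trial. Gaussian observation noise also has heavier-than-real tails at the
3-MAD boundary, so a few percent of clean synthetic trials are rejected by
the MAD rule, exactly as real sessions lose trials to it.

Recovered slow ratios on synthetic cohorts run slightly below the
generating means (attenuation from noise in the fast gain, whose basis
trace carries less signal than the slow one under a constant
perturbation); the contrast directions and significance pattern are
robust. A recovery study across the $\gamma$ grid (both gain directions,
96 trials, noise 0.05) puts the mean absolute error near 0.11 for the
fast gain and 0.07 for the slow gain — close to the Cramér–Rao limit of
this design, so more precise per-participant gains require longer blocks
or less noisy saccades, not a better optimiser.

# Numerical and degenerate-input choices

* Dual-state gain fits: bounded L-BFGS from five starts, followed by
  projected Gauss-Newton polishing (central differences, step $10^{-6}$);
  noiseless data are recovered to $10^{-6}$. Invalid trials are excluded
  from the loss while the recursion advances on every trial. Fewer than 10
  valid trials, or an all-zero perturbation schedule, is an error.
* Exponential fits: deterministic profiled search (above); at least 5
  finite points required; constant series return $\alpha = 0$, `NA`
  timescale, flagged.
* t-tests: zero-variance input errors unless every value equals the null
  exactly, in which case $t = 0$, $p = 1$, $d = 0$ (the defensible reading
  of a degenerate but perfectly null sample). Paired designs use the sd of
  differences for Cohen's d. Repeated-measures ANOVAs are delegated to
  `stats::aov` with partial $\eta^2$ computed per error stratum — routine
  statistics are not re-derived.
* All randomness flows through explicit integer seeds and a local RNG
  scope (`.Random.seed` is saved and restored), so no exported function
  perturbs the caller's random stream and identical seeds give
  bit-identical output.

# Problem sizes used in the bundled analyses

The packaged scripts and tests run at desk scale, chosen as the sizes at
which every qualitative conclusion stabilises: cohorts of 12 participants
(the study's size), 2000 bootstrap folds for the bundled analyses versus
$10^5$ for final inference, 100 replicates per grid point for the recovery
study, 500 null cohorts at 1000 folds for calibration, and 200 random
traces for detector/oracle agreement. The `analysis/` directory holds the
numbered drivers (simulate → detect → preprocess → fit → report) that
produce `results/`; `scripts/acceptance.R` reruns the full pipeline from a
single seed and writes the headline numbers as JSON.

# Known limitations

* The pipeline consumes plain tabular gaze and trial data; proprietary
  eye-tracker formats must be converted upstream.
* Online (experiment-time) saccade detection is represented only as a
  protocol parameter (1.5 dva poll threshold); solely offline detection is
  implemented.
* The bootstrap's mild anticonservativeness at n = 12 (above) is inherent
  to the prescribed procedure.
* Error-clamp trials, microsaccade/drift classification, binocular data
  and Bayesian reanalyses are out of scope.
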