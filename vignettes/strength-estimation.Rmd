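---
title: "Estimating lower-limb strength from exoskeleton resistance-exercise performance"
author: "exostrength"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating lower-limb strength from exoskeleton resistance-exercise performance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exostrength)
```

## The problem

Hip-joint exoskeletons that apply resistance torque during squats, knee-ups
and reverse lunges record a joint-torque signal whose peaks mark each
repetition. Together with surface EMG (sEMG) from the thigh muscles, that
performance record carries information about the wearer's baseline
lower-limb strength - the quantity a gym would otherwise measure with
vertical-jump mats, 1RM machines and dynamometers. `exostrength` implements
the full analysis chain from raw signals to a validated regression model of
strength, plus a synthetic-data generator that stands in for a real
30-participant cohort so that every stage is testable end to end.

The chain is:

1. **simulate** - a cohort with a latent strength factor, muscle
   parameters, and per-session torque/sEMG signal bundles;
2. **extract** - filtering, MVIC normalization, repetition-peak detection;
3. **metrics** - 27 per-participant performance metrics;
4. **model** - statistically screened multivariable OLS with effect size
   and power;
5. **validate** - bootstrap resampling with proportional Gaussian noise.

The numbered scripts under `analysis/` drive these stages in order and
write their tables under `results/`; every computation they perform lives
in the package and is unit-tested.

## The composite strength target

Each participant's baseline strength is summarized by muscle parameters:
vertical jump height VJ (cm, best of three), 1RM leg extension + leg curl
normalized to body weight, RM(LE+LC,Weight) (kg/kg), and isometric
extension + curl normalized to body weight, ISO(LE+LC,Weight) (N/kg).
Weight normalization makes participants of different size comparable. The
model target is the composite

$$\mathrm{TP} = z(\mathrm{VJ}) + z(\mathrm{RM_{LE+LC}/W}) + z(\mathrm{ISO_{LE+LC}/W}),$$

the sum of cohort z-scores (sample SD, denominator $n-1$; the convention is
not dictated by the construction, so we state it). By construction TP has
cohort mean 0, and rescaling any raw variable by a positive constant leaves
it unchanged. `fit_standardizer()` records the cohort moments;
`read_standardizer()` freezes them so TP becomes a pure function of a
participant - the property the bootstrap validation depends on. Whether
z-scores should be formed within sex strata instead of the full cohort is a
genuinely open choice; we standardize over the full cohort, which keeps the
composite interpretable as "strength relative to this population".

## Signal processing

Raw sEMG (2000 Hz) passes through a mains notch and a 20-500 Hz band-pass.
Both are Butterworth IIR designs applied forward-backward
(`signal::filtfilt`), so the chain is zero-phase and burst centers do not
shift: a band-stop of width $f_0/Q$ ($Q = 30$, order 2) and a 4th-order
band-pass. The literature names the filter types but rarely the order or
realization; forward-backward 4th-order is the common default and the tests
pin the contract that matters (>= 20 dB at the mains line, passband
preserved within 5-10%, linearity). A separate high-pass for mechanical
artifact would be redundant with the 20 Hz low edge and is deliberately
omitted. The mains frequency defaults to 60 Hz and is configurable to
50 Hz.

Amplitude is measured as a moving-RMS envelope (`rectified_envelope()`,
default window 0.1 s, reflect-padded so length is preserved). "Amplitude"
could equally mean mean-rectified value; RMS matches how MVIC references
are usually taken and is the configurable default. MVIC normalization is
the affine map

$$\mathrm{MVIC}(x) = \frac{x - \mathrm{sEMG}_{rest}}{\mathrm{sEMG}_{max} - \mathrm{sEMG}_{rest}},$$

with the per-channel maximum taken over maximal-contraction reference
recordings and rest as a robust (median) envelope level.

Repetition peaks are local maxima gated at 30% of the 95th-percentile
amplitude with a minimum inter-peak distance of half the expected
repetition interval (metronome target in the constant condition, nominal
free pace otherwise), ties broken to the earlier sample. The distance
constraint is what rejects the secondary extension-phase torque peak within
each cycle. An empty result is a warning, not an error: zero detected
repetitions is a meaningful outcome downstream.

## Performance metrics

For each exercise (squat, knee-up, lunge) and condition (max-effort 45/60 s
bouts; metronome-paced 60/132/48 RPM bouts of 90/180/120 s):

* **NR** - repetition count;
* **IS** - initial speed, the mean over the first 10 (squat, lunge) or 30
  (knee-up) intervals, reported in repetitions per 10 s (60 RPM = 10 per
  10 s). This unit makes the squat-only regression coefficients coherent
  (mean squat IS around 8.5 per 10 s);
* **CZ** (constant condition only) - repetitions inside the constant-speed
  zone. An interval deviates when it differs from the target by more than
  10% (`rel_tol`); the zone ends at the first run of 3 (`persistence`)
  consecutive deviating intervals. The threshold and persistence are not
  quantified in the source protocols; 10%/3 are conservative defaults,
  exposed as arguments, and the implementation is verified against a
  brute-force window-scan oracle. An optional minimum-zone-duration check
  (default off) covers the alternative reading that the zone is only
  evaluated after a fixed time mark;
* **sEMG amp / iEMG** - RMS amplitude and trapezoidal iEMG over the final
  10 s minus the initial 10 s of the MVIC-normalized envelope, averaged
  across the 8 channels (unweighted; per-channel values are available from
  `semg_amplitude_delta()`/`iemg_delta()` directly). Positive values mean
  more activation late in the bout.

One protocol note: descriptions of the lunge constant-speed bout disagree
between 120 s and 180 s in the source material; the procedural value 120 s
is used. The lunge IS window is likewise stated once as 10 and once as 30
repetitions; 10 (the metric-definition value) wins and both are
configurable.

## The synthetic-data generator

The generator emulates exactly the statistical structure the analysis
assumes, not biomechanics - no musculoskeletal model, no kinematics:

* a standard-normal latent strength $s$ per participant; demographics from
  the study population (weight $66.43 \pm 9.8$ kg, height
  $170.93 \pm 8.5$ cm, age $26.1 \pm 2.8$ y, 19:11 male:female);
* muscle parameters linear in $s$ with Gaussian noise (defaults in
  `default_muscle_loadings()`: e.g. VJ $= 38 + 6s \pm 2$ cm, chosen to give
  realistic adult ranges and a strong but imperfect latent-composite
  correlation). Draws that come out non-positive are rejection-resampled
  up to 100 times, then clipped at 1% of the intercept - this preserves
  the configured moments almost everywhere;
* torque: one positive raised-cosine flexion lobe and one negative
  extension lobe per cycle (peak 8 Nm, under the 10 Nm device ceiling);
  the repetition interval is defined flexion-peak to flexion-peak;
* sEMG: per-repetition Gaussian-windowed bursts of band-limited
  (20-450 Hz) carrier noise, amplitude drifting by `emg_amp_drift`
  (default +30%) from first to last repetition - amplitude *rise* is the
  classic sub-maximal fatigue signature, but only the magnitude of the
  change is ever used downstream, so the sign is configurable - plus a
  mains sinusoid (60 Hz, amplitude 0.05 a.u.) and white noise
  (SD 0.02 a.u.);
* fatigue: intervals hold the paced value until onset (default 40 s,
  shifted +5 s per latent SD so stronger participants fatigue later), then
  lengthen by 3% per repetition with 2% multiplicative noise. These
  dynamics are not printed anywhere in the source material; the defaults
  are calibration choices that produce constant-then-variable speed zones
  of realistic proportions and live in the config, never hard-coded.

Determinism: a master seed fans out to per-stage and per-participant child
seeds via a stable string hash (`child_seed()`), so cohorts and sessions
are bit-identical under a fixed seed and each pipeline stage is
reproducible in isolation. With noise and mains amplitude at zero,
peak detection recovers planted repetition times to within one sample -
the ground-truth fidelity contract the oracle tests rely on.

**Calibration.** The free-pace squat speed is
$8.47 + 1.959\,s + \varepsilon$, $\varepsilon \sim N(0, 0.4027^2)$ reps per
10 s. The split of the total speed SD (2.0) was chosen once so that
$\mathrm{corr}(\text{speed}, s) \times \mathrm{corr}(s, \mathrm{TP}) =
0.873$ under the default loadings, where $\mathrm{corr}(s, \mathrm{TP}) =
0.891$ was evaluated numerically at large $n$ (the body-weight division
makes the composite slightly nonlinear in $s$, so a pure closed form is
exact only at fixed weight - the test suite checks that case against its
closed form). The population correlation between measured squat initial
speed and TP on an $n = 5000$ cohort lands within $\pm 0.02$ of 0.873.

**The reduced squat-only model.** The regression-recovery checks use
`squat_only_config()`/`simulate_squat_cohort()`: speed
$x \sim N(8.47, 2.0^2)$ and $\mathrm{TP} = 0.659\,x - 5.58 +
N(0, 0.7363^2)$, the residual SD fixed by requiring the standardized
coefficient (= correlation) to be 0.873. This implies a closed-form slope
SE of $0.7363/(2\sqrt{29}) = 0.068$ at $n = 30$. The full signal-level
generator cannot simultaneously satisfy this slope and correlation: a
z-score sum of three positively correlated components has SD at least
$\sqrt 3$, while slope/beta coherence forces SD(TP) = 1.51. The two
generators therefore serve different purposes - the signal-level one for
the pipeline's structure and the reduced one for quantitative parameter
recovery - and both are exported, documented API.

What passing tests on synthetic data do *not* show: that real torque
traces have raised-cosine lobes, that real fatigue is geometric, or that a
real cohort's metric correlations match. They show the pipeline is
internally correct: filters meet their specs, detection recovers known
truth, metrics equal their oracles, and the regression recovers planted
parameters at the planted effect size.

## Statistical pipeline

Variable screening (`select_variables()`) mirrors standard practice for
small-cohort regression:

1. drop metrics rejecting Shapiro-Wilk normality at $\alpha = 0.05$ (one
   source passage prints 0.005, but the accompanying tables annotate 0.05;
   0.05 is adopted and configurable);
2. drop metrics whose single-predictor fit on the target fails residual
   normality (Shapiro-Wilk) or homoscedasticity. Homoscedasticity is
   assessed by the Breusch-Pagan test at $\alpha = 0.05$ - a reproducible
   substitute for the visual residual/QQ inspection this screening is
   usually done by;
3. cluster survivors on $d = 1 - |r|$ (average linkage - no linkage is
   canonical here, and average is the least order-sensitive default), cut
   at $|r| = 0.7$, and keep per cluster the metric most correlated with
   the target (alphabetical tie-break). Every drop is logged with its
   reason in an audit table.

`fit_ols()` wraps `stats::lm` and reports the conventional table: B, SE,
standardized beta $= B\,\mathrm{sd}(x)/\mathrm{sd}(y)$, multiple R,
adjusted $R^2$, Cohen's $f^2 = R^2/(1-R^2)$ and post-hoc power from the
noncentral F distribution with $u = p$, $v = n - p - 1$ and noncentrality
$\lambda = f^2 n$ (the G*Power convention; at effect sizes above 3 every
convention yields power indistinguishable from 1). For a single predictor
$|\beta| = |r| = R$ exactly, an identity the tests assert to 1e-10.
Degenerate inputs fail loudly: rank-deficient designs name the collinear
columns, and fits with $n \le p + 1$ are refused. Missing cells are
handled by listwise deletion within each fit.

`bootstrap_validate()` probes robustness: resample participants with
replacement to 100 or 300 rows, add independent Gaussian noise with SD
equal to 10% or 30% of each column's original SD to every predictor and
every raw composite component, recompute TP with the *frozen* original
standardizer, refit, and average R and adjusted $R^2$ over 200 repeats;
optionally sex (male 1 / female 0) and age join the predictors. "x%
Gaussian noise" is not a standard definition - SD-proportional additive
noise per column is our reading, noise is added after resampling, and the
composite components (not the composite itself) receive it so the frozen
standardizer stays meaningful. Because of that ambiguity only the
qualitative pattern - mean R non-increasing in the noise fraction - is
asserted, not specific bootstrapped R values. A closed-form check anchors
the implementation: with one predictor and noise fraction $q$ on both
variables, the correlation attenuates by $1/\sqrt{(1+q^2)(1+q^2)}$.

## Problem sizes and numerical choices

The test suite runs the signal-level generator at cohort sizes 2-30 (and
cheap, signal-free repetition planting at 5000 for the calibration
check), the reduced model at up to $10^5$, and 1000 repeated $n = 30$
cohorts for slope recovery; these sizes give Monte-Carlo error well below
the asserted tolerances while keeping the default suite around two
minutes. The full 30-participant, 180-session workflow in `analysis/`
takes a few minutes, dominated by 2000 Hz session synthesis and
filtering.

Numerical conventions worth stating: envelope edge handling is reflect
padding; peak ties break to the earlier sample; Cohen's $f^2$ is guarded
against $R^2 = 1$; correlation matrices use pairwise-complete observations
with a minimum of 3 pairs per cell; and published adjusted-$R^2$ values
are not always consistent with the standard correction
$1 - (1-R^2)(n-1)/(n-p-1)$ applied to the published R at the published n
(e.g. R = 0.873, p = 1, n = 30 gives 0.754, not the printed 0.721); the
standard formula is implemented and the discrepancy simply noted.

## Known limitations

* The generator's fatigue and noise parameters are calibration choices,
  not estimates from data; only the latent-strength/speed/composite
  correlation structure is quantitatively calibrated.
* Metrics aggregate the 8 sEMG channels with an unweighted mean;
  left/right asymmetry and per-muscle modeling are out of scope.
* The screening pipeline is a faithful but necessarily specific reading of
  "statistical validation": other defensible orderings (e.g. screening on
  multivariable rather than single-predictor residuals) would select
  different survivor sets on some cohorts.
* No claim is made about real-participant physiology; with real data in
  the documented formats the same functions apply unchanged.
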