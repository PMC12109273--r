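---
title: "Methods: Hilbert-regression tracking error for GVS pursuit experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Hilbert-regression tracking error for GVS pursuit experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gvstrack)
```

## The experiment this package analyses

Galvanic vestibular stimulation (GVS) delivers a small current over the
vestibular apparatus through mastoid electrodes (the *two-pole*
configuration) or mastoids plus temples (*three-pole*). In the design this
package targets, each participant performs a visuomotor pursuit task — keep
a cursor inside a target ring that moves along an invisible Lissajous curve
(X 0.075 Hz, Y 0.1 Hz, 60 Hz display) while the cursor is additionally
perturbed by a smaller, faster Lissajous curve (X 0.14 Hz, Y 0.21 Hz) —
once per stimulus per electrode configuration. The stimulus bank holds eight
amplitude-modulated (AM) waveforms, written as envelope/carrier pairs in Hz
(GVS1 [10, 30] through GVS8 [30, 110]), plus a sham (zero-current) control.
Trials last 45 s; stimulation is subthreshold, at 90% of the sensory
threshold found by an ascending staircase (0.1 mA base and steps),
determined separately per configuration.

The scientific questions are: does any stimulus or electrode configuration
lower tracking error relative to sham, and how much more is gained by
choosing each participant's best (stimulus, configuration) pair — the
*individualised stimulus*?

## The tracking-error statistic

The cursor path mixes the deterministic task structure with the
participant's tracking error. Per axis, the pipeline regresses the cursor
coordinate on an intercept, the target Lissajous component, the cursor
perturbation component, and the Hilbert quadrature of each (X cursor on X
regressors only, Y on Y only). The residuals ErrX and ErrY are combined
pointwise,

$$ErrR_i = \sqrt{ErrX_i^2 + ErrY_i^2},$$

and averaged within consecutive *sub-trials* whose duration is one quarter
of the target's Y period — 2.5 s at 0.1 Hz, so a 45 s trial yields 18
sub-trial means. Sub-trials are the repeated-measures unit everywhere
downstream; a trailing partial segment is discarded (45 s divides evenly,
so this matters only for non-standard timelines).

Why the quadratures: a sinusoid delayed by any lag is an exact linear
combination of itself and its Hilbert quadrature, so the regression absorbs
each participant's visuomotor delay without estimating it. The quadrature is
computed by the FFT analytic-signal construction on the full trial *before*
segmentation, confining edge effects to the trial ends rather than every
segment boundary. Including the perturbation curve in the design is a
choice: the perturbation is a known deterministic nuisance injected by the
task, and removing it isolates participant error. The narrower design
(target only) is available via `trial_errors(regressor_set = "target_only")`
for sensitivity analyses. An intercept is always included; it is harmless
when the curves are zero-mean and necessary when they are not. Collinear
design columns are dropped with a warning rather than failing, since exact
collinearity can only arise from degenerate configured trajectories.

## Comparison metrics

With $\overline{ErrR}$ the per-condition mean over sub-trials:

* **Configuration difference**: $\Delta Err$ is the mean over paired
  sub-trials of (two-pole − three-pole) error; negative favours two-pole.
* **Individualised stimulus**: the non-sham (stimulus, configuration) cell
  minimising a participant's mean error. Exact ties (measure-zero on real
  data) break deterministically: bank order GVS1–GVS8, then two-pole first.
* **Improvement over sham**:
  $PI_{GVS} = 100\,(\overline{ErrR}_{SHAM} - \overline{ErrR}_{GVS}) / \overline{ErrR}_{GVS}$,
  with both errors averaged across the two configurations; replicate sham
  trials are pooled first.
* **Improvement of the individualised stimulus**:
  $PI_{Ind} = 100\,(\overline{ErrR}_{GVS} - \overline{ErrR}_{Ind}) / \overline{ErrR}_{Ind}$.
  The denominator is the individualised cell's own (single-configuration)
  error by default. The alternative reading — averaging the chosen
  stimulus's error across both configurations — is available with
  `improvement_table(individualised = "cross_config")`; the default is
  preferred because the individualised choice names one configuration, and
  averaging in the unchosen configuration dilutes precisely the effect the
  selection is meant to capture.

`improvement_table()` reports both percentages per stimulus, averaged across
participants; its SHAM row reads as the improvement of individualised
stimulation over sham, and 0 (sham against itself).

## Statistical layer

Sub-trial means within a trial are not independent samples, so
configuration contrasts use a linear mixed-effects model,
`mean_err ~ configuration + (1 | participant) + (1 | subtrial_index)`
(crossed random intercepts), fitted by REML with lme4. The p-value is the
large-sample normal approximation of the fixed-effect coefficient — with
thousands of sub-trial observations per contrast the normal and
Satterthwaite answers coincide to the digits reported. A positive estimate
means the three-pole configuration had larger error. Singular fits (common
when the sub-trial variance component is truly zero) fall back to the
participant-only random intercept with a warning; single-participant scopes
drop the participant term instead. The eight per-stimulus contrasts form one
family and are Benjamini–Hochberg adjusted together; sham-versus-
individualised per-participant means are compared with the exact paired
Wilcoxon signed-rank test (exact null for up to 25 non-zero pairs, normal
approximation with continuity correction beyond). Error bars on pooled
medians use a seeded bootstrap (default 1000 resamples) of the median.

## The synthetic-data generator

Human recordings are replaced by a generative stand-in:

$$cursor(t) = gain \cdot target(t - lag) + perturbation(t) + \varepsilon(t),$$

with $\varepsilon$ zero-mean Gaussian noise low-pass filtered by a
first-order recursion at the participant's motor-noise bandwidth and scaled
to standard deviation `base_noise_sd × multiplier(stimulus, configuration)`.
The *effect map* of multipliers is the planted ground truth: stimuli act
only through it, not through any biomechanical transduction of the
waveform, because the analysis measures effects on error magnitude only.

Defaults, chosen once as the conditions the simulator emulates:

* 10 participants × 2 configurations × (8 GVS + sham), 45 s at 60 Hz.
* Effect multipliers `1/(1 + PI/100)` for planted over-sham improvements of
  12, 19, 13, 23, 7, 4, 21, 25 percent for GVS1…GVS8 (GVS8 best overall at
  0.8), identical in both configurations.
* Per-participant heterogeneity: each non-sham cell is multiplied by a
  lognormal(0, 0.1) draw, so realised optima differ across participants and
  individualised selection has something real to find; this magnitude
  yields individualised-over-sham improvements in the tens of percent.
* Participant parameters: gain ~ lognormal(0, 0.05); visuomotor lag ~
  U(0.12, 0.25) s; baseline noise SD ~ lognormal(log 0.15, 0.25) screen
  units (the target amplitude is 1); noise bandwidth 2 Hz, so residuals are
  smooth and autocorrelated as real motor error is.
* Reproducibility: every participant consumes an RNG substream derived from
  the cohort seed, so extending a cohort leaves existing participants'
  data bit-identical.

What the generator does **not** emulate: tremor spectra or any
disease-specific kinematics, nonlinear or time-varying tracking strategies,
learning or fatigue across trials, and any direct effect of the stimulus
waveform on the cursor. Passing tests therefore demonstrate that the
pipeline recovers planted effects of the assumed form from band-limited
Gaussian error — not that GVS affects human tracking.

## Numerical choices and degenerate inputs

* AM waveform: suppressed-carrier product of sines
  $s(t) = A\,\sin(2\pi f_e t)\sin(2\pi f_c t)$, with an optional modulation
  depth $m$ giving $A((1-m) + m\sin(2\pi f_e t))\sin(2\pi f_c t)$. Default
  synthesis at 600 Hz; synthesis below twice the carrier frequency warns
  about aliasing instead of failing, since a 60 Hz device-rate mode is
  legitimate for timing studies but corrupt for spectral ones.
* Lissajous amplitudes/phases are configurable and default to unit target
  amplitude, 0.25 perturbation ratio, zero phases; the error statistic is
  invariant to them by construction (the regression removes the curves).
* The trailing-partial-segment floor rule, the edge-hold lag shift, and the
  exact rescaling of filtered noise to its target SD are each asserted by
  tests at their boundary cases.
* Tables round-trip through CSV at shortest-round-trip double precision, so
  a written cohort re-read from disk reproduces the analysis bit for bit.

## Problem sizes used by the test suite

Unit tests run on 10–15 s timelines (4–6 sub-trials). The end-to-end
property checks run at the native design: sub-trial structure on 45 s/60 Hz
trials; the regression oracle on 100 random instances up to length 2700;
individualised-stimulus recovery on 100 cohorts of 10 participants with a
planted 1.3× multiplier contrast; and the type-I calibration of the
configuration contrast on 500 null cohorts, where the rejection rate at
$\alpha = 0.05$ must lie in [0.03, 0.07].

## Known limitations

* The normal-approximation p-value is anti-conservative for very small
  cohorts (2–3 participants); at the design's 10 participants and 18
  sub-trials the Monte-Carlo calibration is nominal.
* `PI_{Ind}` computed on the same data used to select the individualised
  stimulus is optimistically biased (winner's curse); the package
  implements the estimator as defined and leaves cross-validated selection
  out of scope.
* The 60 Hz stimulus device rate is below Nyquist for carriers above 30 Hz;
  the package warns rather than resolving what hardware upsampling may have
  done.
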