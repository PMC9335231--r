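---
title: "Detecting and validating sleep BOLD oscillations with sleepbold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and validating sleep BOLD oscillations with sleepbold}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sleepbold)
```

## The analysis model

During NREM sleep, the regional BOLD signal acquires two oscillatory
components riding on its scale-free aperiodic background: an infra-slow
oscillation below 0.1 Hz (typically 0.04–0.07 Hz), most prominent in
intermediate (N2) sleep, and a faster oscillation above 0.1 Hz (typically
0.15–0.18 Hz), most prominent in deep (N3) sleep. Their power time
courses behave as hemodynamic signatures of sleep spindle and slow-wave
activity respectively.

`sleepbold` quantifies these phenomena with one fixed windowing contract
shared by every time course in the analysis: **sliding Hamming windows of
104 s (50 volumes at TR = 2.08 s), advanced by one volume (2.08 s)**.
Each window is demeaned, tapered with
$w[n] = 0.54 - 0.46\cos(2\pi n/(N-1))$, and its one-sided
magnitude-squared spectrum is normalised by the squared taper sum, so a
unit-amplitude sinusoid at a bin frequency contributes band power 0.5
regardless of the taper. The frequency grid is $k/104$ Hz,
$k = 1, \dots, 25$ (the DC bin is excluded; the Nyquist frequency is
0.2404 Hz). This amplitude calibration is what all gain and percent-change
recovery checks rest on; a frequency-domain/time-domain Parseval identity
for it is asserted in the test suite.

The aperiodic trend is removed by a robust (Huber-weighted IRLS) line fit
of $\log_{10}$ power against $\log_{10}$ frequency over 0.01–0.22 Hz,
excluding the two oscillation search ranges so genuine peaks cannot drag
the trend. Peaks are the maxima of the fit residual within each search
range, accepted when they exceed 2 robust SDs (MAD) of the fit-range
residuals. These constants are explicit arguments because the analysis
the package reproduces does not pin them down; the search ranges default
to 0.03–0.08 Hz (low) and 0.13–0.19 Hz (high). The high range stops at
0.19 Hz rather than the Nyquist so that at least 10 spectral bins remain
for the aperiodic fit on the 1/104-Hz grid — it still brackets the
0.15–0.18 Hz band where the fast oscillation lives.

Windows are assigned the sleep stage covering the majority of their 50
volumes; windows without an 80% single-stage majority are labelled
`transition` and excluded from stage averages and stage-restricted
correlations (they remain available to the lag analysis). The percent
power change from wake to sleep is
$100\,(\bar P_{\text{sleep}} - \bar P_{\text{wake}})/\bar P_{\text{wake}}$
per region and band.

## EEG events and multimodal coupling

Spindles are detected by an amplitude-threshold rule in the sigma band
(11–16 Hz, zero-phase 4th-order Butterworth): moving-RMS envelope
(0.2-s kernel), events where the envelope exceeds 3× its channel median,
boundaries extended down to 1.25× the median, durations restricted to
0.5–3 s, events closer than 0.3 s merged. Slow waves are detected by
zero-crossing segmentation of the delta band (0.5–4 Hz): negative
half-waves of 0.25–1 s whose trough falls below −3.75 MAD of the filtered
trace (an absolute microvolt threshold can be supplied for calibrated
data); the event spans the full trough-to-trough cycle. All thresholds
are relative by default, making detection invariant to amplitude
rescaling.

Event activity is integrated as seconds of event time per 2.08-s bin
(matching the fMRI sampling), then aggregated as a Hamming-weighted
average over the same 104-s windows as the spectrogram, so that BOLD
power and EEG activity traces share window centers exactly. Correlations
between them are computed per region and run, across stages (all clean
windows) or within one stage; group inference Fisher-transforms one
coefficient per (region, run) entry and applies a one-sample (or paired)
t-test. Because adjacent windows overlap by 98%, per-entry p-values are
also reported with a Bartlett effective-sample-size correction, as a
diagnostic only. No hemodynamic-delay shift is applied between EEG- and
BOLD-derived traces: the 104-s smoothing dwarfs the ~5-s hemodynamic
delay (a `shift` can be emulated by offsetting window centers for
sensitivity analyses).

The broadband amplitude trace (windowed, taper-normalised SD) is the
control pairing: the claim under test is that the *frequency content*,
not the overall amplitude, carries the event information.

## Lag maps at wake–sleep transitions

The falling-asleep segment runs from the last sustained wake epoch before
the first sustained NREM run to the first sustained N2/N3 epoch (waking:
symmetric), padded by 120 s. Within the segment, per-region band-power
traces are baseline-subtracted (mean wake-window power) so the rising or
falling edge dominates, and every region pair is cross-correlated over
integer window shifts up to ±60 s, with parabolic interpolation through
the peak. The cross-correlation uses the *biased* normalisation (divide
by the full segment length rather than the shrinking overlap): on
step-like onset traces the per-overlap correlation develops spurious
maxima at the search boundary that can exceed the true peak, while the
biased form tapers them away. A region's lag is the mean of its row of
the pairwise lag matrix over reliable pairs (lag projection), zero-
centred; positive values lead. Boundary peaks are flagged unreliable and
excluded. A single 104-s-smoothed transition contains only ~6 independent
samples, so single-run maps are noisy; group maps are obtained by
averaging per-run maps across recordings, which is also how the
recovery checks evaluate them (20 seeded runs).

## Physiological confounds

RETROICOR-style nuisance regressors are built from the raw traces:
cardiac and respiratory phase (sin/cos, Fourier orders 1–2; cardiac
phase linear between pulse peaks, respiratory phase by the
amplitude-histogram method signed with the derivative), beat-wise rates
interpolated linearly to volume midpoints, respiratory volume (6-s
windowed SD) and depth (cycle peak-to-trough). Peak picking uses
refractory periods of 0.35 s (cardiac) and 1.5 s (respiration).
"Volume" and "depth" are both reported because the literature's
definitions differ; the output headers name them explicitly. Regression
removes an intercept, a linear drift, and the regressors by least
squares; residuals are orthogonal to the design and the operation is
idempotent. Aliasing of periodic physiology into the slow fMRI band is
computed by folding: a 1-Hz pulse sampled at TR = 2.08 s aliases to
0.0385 Hz — inside the infra-slow band, which is why the confound
analysis matters. Band-limited physiological power uses the same
104-s/2.08-s window contract at each series' own sampling rate (the raw
respiratory and cardiac bands lie above the BOLD Nyquist, so they cannot
be evaluated at the volume rate).

## What the synthetic generator emulates

`simulate_recording()` produces BOLD, EEG, a hypnogram, and physiology
with the statistical structure the analysis assumes, under one seed
(identical configurations are bitwise-reproducible):

* **Hypnogram**: W → N1 → N2 → N3 → N2 → W in 30-s epochs with
  configurable dwell times (defaults proportion a 60-min run as
  10:5:12.5:15:7.5:10 min), giving exactly one falling-asleep and one
  waking transition.
* **BOLD**: per region, 1/f spectrally-shaped Gaussian background (exact
  frequency-domain shaping, exponent 1) plus two sinusoids at per-region
  frequencies drawn from 0.04–0.07 and 0.15–0.18 Hz. Stage gains ramp
  with a 20-s half-cosine (shorter than one analysis window, avoiding
  spectral splatter) and are delayed per region by configurable onset and
  offset lags. Default squared gains are profiled — low-frequency: 3.0
  (N1), 4.6 (N2), 2.2 (N3); high-frequency: 2.0, 3.0, 4.67 — so each
  band's duration-weighted sleep/wake power ratio is 3.5 under the
  default hypnogram, i.e. a wake→sleep power increase in the 200–300%
  range once in-band background power dilutes it. A flat gain profile
  would meet the power-step calibration too, but would erase the
  band-to-event specificity that the coupling analysis must detect.
* **EEG** (250 Hz): pink background plus spindle bursts (11–16 Hz,
  0.5–2 s, Tukey(0.25) taper so onsets wax quickly; amplitude 5× the
  sigma-band background RMS) and biphasic slow waves (one 0.8–1.5 s
  cycle, negative phase first, trough 6× the delta-band background RMS).
  Event onsets are an inhomogeneous Poisson process — stage base rate
  times an infra-slow sinusoidal envelope of depth 0.8 at the mean
  injected oscillation frequency, normalised to mean 1 so stage rates are
  preserved in expectation — realised by thinning. Default base rates:
  spindles 2/min in N2 (1/min in N1 and N3), slow waves 7/min in N3
  (3/min in N2, 1/min in N1), zero in wake. The slow-wave amplitude of
  6× delta RMS is what a relative-threshold detector needs against a
  pink background whose own delta half-waves exceed 2 robust SDs about
  13% of the time; weaker waves are not separable by any threshold that
  also keeps the false-positive rate under 20%. The stated event
  periodicities and envelope frequencies are deliberately decoupled
  (2/min ≠ 0.04–0.07 Hz): the envelope frequency follows the injected
  BOLD oscillation, the base rate the literature's densities, and both
  are independent configuration keys.
* **Physiology** (50 Hz): respiration as a sinusoid with band-limited
  (0.04–0.4 Hz) random-walk fluctuations of instantaneous rate (±8%)
  and depth (±20%) around 0.25 Hz; cardiac pulse as a peaked
  raised-cosine waveform with ±5% rate fluctuation around 1 Hz.
  Physiology is generated independently of the BOLD oscillations, which
  is exactly the null the confound analysis must reproduce.
* An optional slow multiplicative amplitude envelope (`bold_amp_mod`,
  0.005–0.03 Hz, drawn independently per region) supports the
  amplitude-control null analysis: with stage-flat gains and this
  envelope active, broadband amplitude varies while carrying no event
  information.

What the generator does **not** emulate — hemodynamic response
convolution, head motion, scanner drift, MR artifacts in EEG, REM sleep,
non-sinusoidal oscillation waveforms, spatial correlation between
regions beyond the shared hypnogram — bounds what passing tests show:
they demonstrate that the analysis recovers known structure under its
own assumptions at realistic SNR, not that it is robust to every
artifact of real recordings.

## Numerical choices and degenerate inputs

* Stage averages, correlations, transitions and lag maps return
  *absent-with-reason* objects (`available = FALSE` plus a message)
  rather than silent zeros when stages are missing, windows too few
  (default minimum 30), variance zero, or lag peaks sit on the search
  boundary.
* Bands narrower than one spectral bin fall back to the nearest bin with
  a warning. Non-positive spectral values are dropped (and counted) from
  the log-log aperiodic fit.
* Rank-deficient nuisance designs drop collinear columns and name them.
* Intervals are half-open `[start, end)`; all times are seconds from
  recording start; windows are identified by their center time.

## Problem sizes in the validation suite

The recovery checks run the generator at its default study conditions: a
60-min recording, 12 regions, TR 2.08 s, EEG at 250 Hz. Spectral-peak
placement uses one run; the percent-change bracket averages 10 runs; the
event-density check 3 runs; the coupling-specificity analysis 12 runs
plus 6 amplitude-null runs; lag recovery averages 20 runs with injected
0/10/20-s onset lags in three region groups. These sizes give stable
group-level statistics while keeping the whole suite runnable on a
laptop in a few minutes.
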