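---
title: "Measuring zebrafish ECG intervals: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring zebrafish ECG intervals: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zfecg)
```

## The measurement problem

Adult zebrafish are a practical model for cardiac drug screening: a
single-lead needle ECG shows distinct P waves, QRS complexes and T waves, and
the standard clinical intervals (PR, QRS, QT, RR) respond to β-agonists,
calcium- and sodium-channel blockers and QT-prolonging antiarrhythmics much
as they do in humans.  The recordings are, however, small in amplitude
(R ≈ 1 mV at the electrode), fast (resting heart rate ≈ 148 bpm, so a full
cardiac cycle lasts ≈ 400 ms), and contaminated by gill-movement artifact,
AC-line pickup and baseline wander.  `zfecg` implements the measurement
pipeline for such recordings and pairs it with a synthetic generator whose
ground-truth channel makes every stage testable without animals.

The pipeline, exposed as the single fitting function `ecg_analyze()`, is:

1. **Polarity correction** — electrode reversal inverts the trace; if the top
   decile of |amplitude| is predominantly negative the trace is negated
   (`auto_polarity()`), and a tie (all-zero input) is left alone.
2. **Zero-phase FIR band-pass, 3–45 Hz** — a windowed-sinc (Hamming) design
   of order `3·fs / f_low` (600 taps at 600 samples/s), applied by centred
   convolution with reflected edge padding.  Symmetric taps plus centred
   application give exactly zero phase, so fiducial latencies survive
   filtering; the taps are mean-corrected so the DC gain is exactly zero.
   The stopband rejects the 60 Hz line by more than 40 dB
   (`fir_bandpass_response()` evaluates the designed response).
3. **R-peak detection** — an adaptive-threshold peak picker in the
   Pan–Tompkins/Hamilton family: squared first derivative, short moving
   average (25 ms), candidate local maxima accepted above a running
   signal-peak fraction (`threshold_frac`, default 0.4), a 150 ms refractory
   period, optional search-back in long gaps at half threshold, and final
   refinement to the raw-trace maximum within ±20 ms.
4. **Segmentation and template averaging** — fixed windows around each R
   peak, each smoothed with a centred moving average of
   `template_smooth_n = 10` samples and averaged pointwise into the
   recording's reference wave (`average_template()`).  At 600 samples/s a
   10-sample boxcar has a spectral null exactly at 60 Hz, which is why a
   window of about 10 is the natural choice at this sampling rate.
5. **Delineation** — on the template, QRS onset/end are found where the
   magnitude falls below 5% of the R amplitude moving outward from R; the P
   peak is the pre-QRS maximum within 150 ms of R with onset/end at 10% of
   the P amplitude; the T end is where the post-QRS deflection decays below
   10% of the T amplitude.  QT is measured from QRS onset (onset of
   ventricular depolarisation) to T end (end of repolarisation).  A wave
   whose amplitude is below 5% of R is reported absent, never fabricated.
6. **Per-beat refinement** — template fiducials are projected onto each beat
   and refined within ±10 ms (peaks to the local maximum, bounds to the
   nearest threshold crossing on the lightly smoothed beat), so a noisy beat
   cannot move a fiducial across waves.
7. **Intervals and summaries** — per-beat RR, HR = 60000/RR, PR, QRS, QT and
   Fridericia-corrected QTc; recording summaries are means with sample
   standard deviations.

## Numerical choices that matter

Three accuracy problems dominate threshold-based delineation on this kind of
signal, and the package's solutions are worth recording.

**Baseline reference.**  A 10% threshold crossing is meaningless unless the
iso-electric level is known.  A global running-median baseline fails here: at
148 bpm the P–QRS–T complex occupies roughly two-thirds of the cycle, so any
median window either tracks the waves or the wander.  Instead each beat's
baseline is taken as the median of its own TP segment — the quiet zone just
before the P wave, located from the template fiducials — which is the
standard clinical reference and is exactly zero on clean data.  The T end is
additionally re-referenced to the iso-electric segment just *after* the T
wave when the beat window reaches that far, because on the shallow T tail
(≈ 0.003 mV/ms at the 10% point) even a few microvolts of residual offset
translate into milliseconds.

**AC-line residue in averages.**  Line pickup is only partially incoherent
with the beat times, so averaging a few hundred beats leaves a small 60 Hz
ripple in the mean beat that biases shallow threshold crossings outward.
Measurement windows are therefore cleaned by least-squares projection onto
sine/cosine at the line frequency (`detector_config(line_hz = )`); the beat
waveform itself has negligible energy at 60 Hz (the QRS spectrum at 60 Hz is
below 0.5% of its peak), so the projection strips the line without phase
distortion.  This mirrors, in exact form, what the classic
moving-average-of-N≈10 smoothing achieves approximately.

**Smoothing bias of the template.**  The 10-sample moving average widens
every wave slightly (a Gaussian flank of sd σ becomes sd
√(σ² + w²/12)), pushing 5%/10% crossings outward by 1–3 ms.  The template is
therefore used for *anchoring* (and reported as the reference wave), while
the anchors themselves are re-delineated on the plain, unsmoothed mean beat
before per-beat refinement.

Other conventions: sample indices are 0-based; durations use the half-open
convention `(end − onset)·1000 / fs`; voltages are millivolts internally
(readers convert a microvolt header); a time column always wins over a
declared rate, and a disagreement beyond 0.1% is an error because a wrong
acquisition rate corrupts every downstream interval.  The per-beat template
window (default ±200 ms) is widened automatically to about half the median
RR (capped at 500 ms) so that a drug-prolonged QT — 481 ms under amiodarone
— still falls inside the window; without this, T waves of slow long-QT
rhythms would be truncated.  Degenerate inputs degrade gracefully: a flat
record yields an empty detection and an `n_beats = 0` summary rather than an
error.

## Heart-rate correction

QTc uses Fridericia's formula, `QTc = QT / RR^(1/3)` with RR in seconds —
the correction recommended for drug-safety work — applied per beat with that
beat's own preceding RR; the summary QTc is the mean of per-beat QTc values,
not the correction of the means.  The choice of RR units is fixed by the
formula's fixed point (QTc = QT at RR = 1 s) and checked by exact identities
in the tests (`qtc_fridericia(480, 1000) = 480`, `qtc_fridericia(300, 125) =
600`).  Bazett's `QT / √RR` is provided as a labelled alternative
(`qtc_bazett()`) but is never the default.

## Drug-effect analysis

`compare_pre_post()` works on per-subject means in paired order: fold change
is the per-subject ratio averaged arithmetically across subjects (matching
the fold-change convention of dose–response work), percent change is the
per-subject percent averaged the same way, and the paired Student t is
computed from its formula with the two-sided p-value via the regularised
incomplete beta function (`pbeta`), cross-checked against `t.test` in the
suite.  When the paired differences have zero variance the statistic is
undefined and a `no_variance` flag is reported instead of a number.
`dose_response()` tabulates mean ± sd of folds against log10 dose without
fitting a curve.

Atrioventricular block is graded with explicit, configurable rules:
*first-degree* when mean PR exceeds the baseline mean by more than three
baseline standard deviations with every P conducted; *high-degree* when the
dropped-QRS ratio (P events without a following QRS over all P events)
exceeds 5%.  The thresholds are package-defined operating points, not
literature constants.  Non-conducted P waves are located by scanning R–R
gaps longer than 1.6× the median RR at the expected beat positions for a
P-like deflection above half the typical P amplitude (`find_p_events()`).

## The synthetic generator

`render_record()` turns a `scenario_spec()` into a record plus ground truth.
Beats are sums of parameterised Gaussians: P and T waves whose "width" is
defined as the full width at the 10% delineation threshold, and a triphasic
QRS whose R flank reaches 5% of its amplitude exactly at the programmed QRS
bounds — so the generator's truth fiducials are analytically placed at the
same landmarks the delineator estimates.  The P is positioned so that
QRS onset − P onset equals the programmed PR, and the T so that its 10% decay
point sits at QRS onset + QT.  Rhythm is a piecewise time-course
(`pw_profile()`: constant, step and ramp segments) with Gaussian RR jitter;
per-beat intervals are read from the time-courses at each beat time, and
infeasible programmes (PR + QT ≥ RR) are rejected by validation, never
clipped.  Acquisition is emulated at 600 samples/s with a zero-phase 80 Hz
digital low-pass, matching the recording kit the package targets.

Noise reproduces the field's dominant artifacts: AC-line pickup (60 Hz,
0.05 mV), gill-movement artifact as amplitude-modulated 1–3 Hz bursts
(Poisson rate 0.5/s, raised-cosine envelopes, 0.1 mV peak), slow baseline
wander (0.2 Hz, 0.1 mV) and white sensor noise (0.02 mV sd).  Within-recording
RR jitter defaults to 5 ms — sinus variability large enough to decorrelate
line phase across beats, small against the ≈ 130 ms feasibility slack of the
baseline rhythm.  All stochastic draws flow from the single scenario seed in
a fixed order, so identical scenarios render bit-identical records; polarity
−1 negates the complete trace (lead reversal), which makes the polarity
linearity property exact.

The scenario presets encode the studied conditions: baseline (HR 148 bpm,
PR 62 ms, QRS 44 ms, QT 215 ms), a separate constant-RR 469 ms scenario (the
cohort-mean RR and cohort-mean HR come from averaging across fish, so the
two are deliberately exposed as distinct scenarios rather than reconciled),
MS-222 bradycardia (108 → 89 → 64 bpm over ten minutes), an isoproterenol
dose ladder (heart-rate folds 1.04–1.25 for 0.5–10 µM, pre-rate 124 bpm),
verapamil (155 → 116 bpm within a minute, 88 bpm by five minutes),
amiodarone (HR 60, QT 481, QRS 79, PR 103), quinidine (HR 166 → 92, QT 200 →
303) and veratridine (PR 58 → 85 ms, dropped-QRS available via
`dropped_qrs_prob` for high-degree block).

**What the generator does not emulate.**  Wave shapes are smooth Gaussians:
real zebrafish QRS complexes are sharper and asymmetric, T waves can be
biphasic, and morphology drifts with anaesthesia depth.  Gill artifact is
band-limited noise, not the quasi-periodic, movement-locked waveform of a
real fish; perfusion pulse is not modelled separately; electrode motion,
contact loss and ectopic beats are absent.  Passing the recovery tests
therefore demonstrates that the measurement chain is unbiased under the
stated morphology and noise model — it does not certify performance on real
recordings with pathological morphology, and the threshold fractions may
need retuning for waveforms far from the defaults.

## Problem sizes and verification

The package chooses deliberately small but sufficient problem sizes:
property and unit tests run on 10–60 s renders (≈ 25–150 beats); the
recovery checks use ten 120 s recordings per scenario (≈ 290 beats each at
baseline), six paired subjects for the isoproterenol fold, and 1000
replicates of n = 10 for the type-I-error calibration of the paired t-test.
Detection is validated against the simulator's truth channel (sensitivity
and positive predictivity 1.0 on clean renders, ≥ 0.99 at preset noise), and
interval recovery against the programmed generative parameters (HR within
±2 bpm, PR/QRS within ±4 ms, QT within ±5–6 ms).  `scripts/acceptance.R`
re-runs the same recoveries end to end and writes the recovered values as
JSON.

## Known limitations

Template averaging assumes a single dominant beat morphology; runs with
frequent ectopy or alternans need multi-template clustering, which is out of
scope.  The orphan-P search assumes P waves keep their sinus timing during
blocked conduction.  Heart-rate-variability metrics beyond the RR summary,
torsade-de-pointes morphology detection and multi-lead support are
deliberately not provided.
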