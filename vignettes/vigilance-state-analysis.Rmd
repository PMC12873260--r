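---
title: "Vigilance-state analysis: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vigilance-state analysis: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(vigilstate)
```

`vigilstate` analyses rodent sleep recordings in which cortical slow waves,
neuronal OFF periods and pupil-linked arousal can dissociate from
behavioural state. This vignette is the package's own account of the
methods: what each stage computes, which conventions were fixed where
several were defensible, and what the synthetic generator does and does not
emulate.

## Time and epoch conventions

Time is measured in seconds from recording start; sample `i` of a signal at
rate `fs` sits at `(i-1)/fs`. Scoring epochs are half-open intervals
`[4k, 4(k+1))`, 0-based in all on-disk formats (so "epoch 450" starts at
1800 s). All signal analysis assumes the 256 Hz rate produced by
`preprocess()`.

## Acquisition preprocessing

Recordings arrive at their acquisition rate (typically 305 Hz) and are
band-passed with zero-phase Chebyshev type II filters — 0.5–120 Hz for
EEG/LFP, 10–45 Hz for EMG — then resampled to 256 Hz by rational polyphase
resampling. The type II family is used throughout because it is the one
design whose stopband edges the slow-wave stage fully specifies; using it
for the prefilter keeps the pipeline on a single filter family. The
prefilter's transition bands are a package choice (stopband edges at half
the lower passband edge and 1.5× the upper edge, capped inside Nyquist),
with 40 dB stopband attenuation per pass and the minimum order meeting
those edges, computed from the analog prototype with bilinear prewarping. All
filters run as cascaded second-order sections forward and backward
(squared-magnitude response, zero phase): direct transfer-function filtering
of a 0.5 Hz edge at 256 Hz is numerically unreliable, sections are not.

## Epoch scoring

Each 4-s epoch yields: EMG RMS; the frontal slow-wave-activity (SWA)
envelope amplitude (`sqrt(2)` × RMS of the 0.5–4 Hz filtered signal);
occipital theta (7–12.5 Hz) and delta (0.5–4 Hz) band powers; and their
ratio, the *theta dominance*. Classification applies the field's rules with
a fixed precedence:

1. **WAKE** if EMG RMS is above the waking threshold — EMG outranks the
   EEG, so drug-induced wake slow waves still score as wake;
2. otherwise **REM** if EMG is low and theta dominance ≥ 1.5;
3. otherwise **NREM** (low-EMG epochs with high-amplitude frontal slow
   activity meet the classical criterion; remaining low/intermediate-EMG
   epochs default to NREM, the closest operational reading of "mixed
   frequencies of lower amplitude").

**Threshold calibration.** The waking/sleeping EMG boundary is found per
recording by a two-class variance split (Otsu's criterion) on log epoch EMG
RMS, with `emg_hi`/`emg_lo` placed 2% above and below it. A
percentile-based rule (60th/40th percentile) was considered first but
rejected: its thresholds track state *occupancy*, not the separation
between EMG clusters, so any recording that is unusually sleep- or
wake-heavy pushes the cutoff inside a cluster and misclassifies a large
fraction of epochs. The variance split depends only on the clusters
themselves and behaves identically on 30-minute and 24-hour recordings.
`theta_dominance_min = 1.5` is a fixed, documented default; visual scoring
criteria carry no numbers, so any constant here is a convention.

**Micro-arousals.** Runs of 1–4 waking epochs flanked by sleep (NREM or REM
on the left, NREM on the right) are relabelled `MICRO_AROUSAL`; runs of five
or more stay wake. The rule is re-applied until a fixpoint, with
micro-arousal epochs counting as waking when run lengths are measured, so a
relabelling can never strand an inconsistent run. Only
WAKE ↔ MICRO_AROUSAL transitions ever occur, and the fixpoint is reached in
at most `n` passes.

**Artefacts.** An epoch is flagged per derivation when the robust z-score
(median/MAD) of its peak amplitude exceeds 8, or when it contains a run of
five identical extreme samples (saturation). Flags exclude epochs from
spectral averages but never alter state labels.

## Spectra and the aperiodic slope

Per-epoch spectra use a periodic Hann window on 1024-sample epochs: 0.25 Hz
bins, 481 bins exported over 0–120 Hz. Power is scaled by the window's
energy so that the one-sided band sum of a sinusoid equals its variance;
band edges are inclusive on both sides (0.5 and 4.0 both belong to SWA).
Two theta definitions circulate (7–12.5 Hz for scoring, 6–9 Hz in aperiodic
contexts); the scoring definition is the package default, and every band is
an argument.

The aperiodic slope is an ordinary least-squares line through log10(power)
versus frequency over 20–120 Hz — linear–log space, implemented exactly as
stated even though a 1/f^χ background is a line in log–log space, not
linear–log. Because of that mismatch the default fit cannot return χ;
`fit_spectral_slope(..., log_freq = TRUE)` switches the regressor to
log10(frequency), and `-slope` then estimates the exponent (recovered
within a few percent on synthetic 1/f signals). The linear–log default is
kept deliberately: it is the convention the slope values are meant to be
comparable to.

## Phase–amplitude coupling

`modulation_index()` implements the Tort entropy index with the toolbox
conventions: third-order Butterworth zero-phase band-passing, analytic
signal phase and envelope, 18 phase bins, and
MI = (log N − H(P))/log N ∈ [0, 1]. MI is invariant to amplitude scaling,
≈ 0 for phase-independent amplitude, and exactly 1 when all amplitude mass
falls in one bin. The comodulogram grid spans phase centres 1.5–10.5 Hz and
amplitude centres up to 100.5 Hz; grid steps and bandwidths are arguments,
since the only fixed quantities are the grid's extremes.

## Slow waves and OFF periods

The LFP is filtered to 0.5–4 Hz (stopband edges 0.2/8 Hz, 40 dB, minimum
order, zero phase). A wave is a maximal run of strictly positive filtered
samples bounded by zero crossings, accepted only when the excursions on
*both* sides dip below zero; onset/offset are the bounding crossings, the
amplitude is the positive peak. Duration is therefore the positive
excursion's span (zero crossing to zero crossing), not trough-to-trough,
and amplitude is the peak, not peak-to-trough — both conventions are
documented here because the opposite readings are also seen in the
literature. The detector is verified against a brute-force segment-scan
oracle on a thousand random filtered signals.

All detected waves feed the amplitude/duration distributions; only waves
whose amplitude strictly exceeds the mean + 2 × (population) SD across all
detected waves feed the multi-unit analysis. Peri-event profiles align
spikes to wave peaks in 10 ms bins over ±500 ms; the trough is the
minimum-rate bin (ties broken toward zero lag, since an OFF period flattens
the whole trough at zero), and the trough width is the contiguous span
below half the baseline rate (mean rate beyond ±300 ms).

## Pupillometry

Diameter is the mean of the north–south and east–west keypoint distances,
accepted only when all four likelihoods are ≥ 0.99 — the strictest reading
of the confidence cut, applied per point, which preserves the geometry of
the estimate. Missing stays missing by default; optional linear
interpolation across gaps ≤ 1 s exists but is off, since no interpolation
rule is part of the method. Time courses are per-bin means as percent of a
baseline window, so a peak of 175% is a +75% dilation. Frame timestamps
come from the nominal frame rate; units are pixels unless a calibration is
supplied — all reported quantities are percent-of-baseline and unit-free.

## Endpoints

Architecture endpoints are exact epoch arithmetic (4 s per epoch;
micro-arousals counted separately). REM latency runs from the injection to
the first REM epoch starting at or after it. A NREM *episode* — undefined
in the source conventions — defaults to ≥ 15 consecutive NREM epochs
(1 min) tolerating one interruption, the conventional rodent criterion, and
is configurable. SWA dynamics are reported per NREM epoch from the first
post-injection episode onset, as percent of the recording's mean NREM SWA
unless a baseline-day reference is supplied.

Condition contrasts compare within-subject mean spectra bin by bin with
paired two-sided t-tests, uncorrected, mirroring the per-frequency post-hoc
lines drawn under spectra; maximal significant runs are reported, and a
sign-flip permutation option exists for small samples. Mixed-effects
modelling of the original cohorts is out of scope. Under the null the
per-bin false-positive rate is the nominal α (checked over 200 simulated
studies).

## The synthetic generator

`synth_config()` defines the study conditions: a semi-Markov hypnogram
(exponential bouts, means 200/280/80 s for wake/NREM/REM, REM entered only
from NREM), 1/f^χ backgrounds (χ = 2) with per-epoch state oscillations
(NREM delta 60 µV frontal, REM theta 40 µV occipital, active-wake occipital
theta 30 µV), EMG white noise graded 40/15/8 µV RMS, NREM LFP slow waves at
6/min with lognormal amplitudes (median 250 µV) and 100–200 ms spike-free
OFF periods centred on each positive peak (depth-electrode polarity), and
Poisson multi-unit firing at 30 Hz elsewhere. The drug window adds discrete
wake slow waves scaled so the frontal 0.5–4 Hz power gain equals
`drug_swa_gain` (default 2), multiplies occipital theta by
`drug_theta_gain` (default 0.4), leaves the EMG untouched, and dilates the
pupil by a raised-cosine transient peaking at +75% for 720 s. None of the
per-state magnitudes are measured values — the source reports no µV
figures — they are plausibility choices fixed once; effect *directions* are
the emulated science.

What the generator does **not** emulate: spindles and ripples, real EMG
spectra, slow homeostatic SWA trends across the day, per-neuron spiking
structure, eye blinks, or video artefacts. Passing tests therefore
demonstrate that the pipeline recovers known structure of this statistical
form — state-dependent band power, silence-coupled waves, keypoint
geometry — not that it handles every pathology of in-vivo data.

## Numerical choices and degenerate inputs

- Filter orders come from the closed-form Chebyshev bound with bilinear
  prewarping; all filtering is zero-phase second-order sections.
- The 1/f background is flat below 0.5 Hz so variance stays finite; the
  synthesized exponent is exact in expectation, which is what makes the
  log–log fit a genuine recovery test.
- Degenerate cases are errors, not guesses: empty channel lists, unsorted
  spikes, unknown state labels, bands outside 0–120 Hz, non-positive power
  under a log, fewer than 2 waves for the amplitude criterion, fewer than 3
  pairs for a correlation, a baseline window with no valid pupil frames.
- Detection ties: a wave's peak is the first maximal sample; the OFF trough
  is the zero-rate bin nearest zero lag; equal wave amplitudes give SD 0 and
  an empty high-amplitude subset (strict inequality).
- Problem sizes in the test suite (a 24-h scored study, 1000 oracle
  comparisons, 200 null studies, 100 coupling-depth runs) were chosen as the
  smallest sizes at which the checked statistics are stable.

## Known limitations

Scoring calibration assumes both waking and sleeping epochs exist in the
recording; a recording spent entirely in one state gives an arbitrary EMG
split (as any per-recording calibration must). EDF output quantizes to 16
bits over a per-channel range padded 5%, so round trips are exact only to
one quantization step. The pose-CSV reader accepts the DeepLabCut dialect
only. Pupil-frame alignment to EEG time uses the nominal frame rate with an
optional constant offset; variable camera clocks are not modelled.
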