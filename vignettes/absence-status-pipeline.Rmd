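---
title: "Quantifying drug-induced absence status epilepticus in rodent EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying drug-induced absence status epilepticus in rodent EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swdquant)
```

## The problem

Rat strains with genetic absence epilepsy (GAERS, WAG/Rij) express
spontaneous spike-and-wave discharges (SWDs): rhythmic sharp-spike plus
slow-wave complexes, classically at a 7--11 Hz fundamental, lasting a few
seconds to tens of seconds. Central activation of the alpha-2a adrenergic
receptor (e.g. with dexmedetomidine, DEX) converts this activity into an
absence-status-epilepticus-like state: an initial continuous discharge a
few minutes after injection, a long block of sedation sleep, and then a
second period of status events that can run continuously for many minutes,
with a slowed spike-and-wave fundamental (5--6 Hz).

`swdquant` packages the quantification of such sessions end to end:
discharge detection, status classification, phase segmentation, sleep
scoring, multitaper spectra and interhemispheric coherence, and the
nonparametric group statistics — plus a ground-truth-annotated simulator,
since every stage must be testable without animal recordings.

## The synthetic session generator

`generate_dex_session()` is phenomenological: it reproduces the *signal
statistics* that the downstream estimators consume, not thalamocortical
biophysics.

* **Background**: band-limited (1--40 Hz) pink noise, RMS `sigma_uv`
  (default 20 µV). The reference "background amplitude" of a Gaussian
  background is its 95th-percentile rectified level, `1.96 * sigma`.
* **Discharges**: a non-sinusoidal cycle — a narrow positive spike
  (Gaussian, about a fifth of the cycle) followed by a slow half-wave —
  synthesised with a phase accumulator so the requested fundamental falls
  exactly on the analysis grid, with 5% per-cycle amplitude jitter. The
  cycle shape makes harmonics at 2x and 3x the fundamental appear as
  separate spectral peaks. Trains are band-limited to 1--40 Hz at
  synthesis (emulating the acquisition filter of the amplifier) and
  rescaled so the median per-cycle peak equals
  `amplitude_ratio * 1.96 * sigma_uv`; the default ratio 2.5 sits above
  the detector's 2.0 threshold by the same margin a clearly
  supra-threshold discharge would in chart review. Per-cycle peaks
  jitter symmetrically (5--6%) in baseline and initial-status
  discharges; second-period cycles instead jitter *upward only*
  (half-Gaussian, scale 0.25) — a right-skewed peak distribution with
  occasional high-voltage spikes that gives the post-sleep state the
  highest peak-voltage variance, as the variance test expects, without
  ever dropping a cycle below its nominal amplitude.
* **Sedation sleep**: delta-dominant noise (1--4 Hz band carrying ~80% of
  the power) with spindle-like 12.5--15 Hz transients at a configurable
  density, total RMS 25 µV — above wake background, but deliberately
  below the 2x discharge threshold.
* **Timeline**: a 40-min baseline with spontaneous 5--20 s discharges at
  6 Hz; injection; one initial status event with onset ~N(2.74, 1.19) min
  truncated to 1--5 min and duration ~N(128, 38.9) s truncated to 60--240
  s; sedation sleep; a second period of status events whose durations fall
  in the 1--2 / 2--5 / >5 min bins with 70:17:14 weights; a trailing
  baseline. The >5-min bin is an exponential excess over 300 s (mean
  227 s, capped at 26 min), chosen so the grand mean of second-period
  durations is 170.1 s under the default weights. Discharge fundamentals
  slow across phases: 6 Hz baseline, 5.9 Hz initial status, 5 Hz
  post-sleep, and the post-sleep spike is widened (harmonic attenuation),
  reproducing the blunted 2f/3f harmonics of the post-sleep state.

Two sampling details matter for parameter recovery and are easy to get
wrong. First, truncating a normal to a physiological range shifts its
mean; the generator solves for the untruncated mean that leaves the
*truncated* mean on target (`tnorm_mean_adjust()`). Second, sleep must
start after the initial status ends; drawing the latency independently
and rejecting inconsistent draws would inflate its mean by about a
minute. Instead sleep onset is modelled as *initial-status end plus a
positive gamma-distributed gap* whose two moments are matched so that the
latency (sleep start minus injection) has exactly the configured mean and
SD. Across 500 sampled timelines all recovered means sit within sampling
error of their targets.

Per-animal SDs are recovered from cohort-level SEMs as `SEM * sqrt(n)`
with n = 8, the standard conversion. Sampling rate defaults to 200 Hz:
any rate above twice the 40-Hz analysis edge works, and 200 Hz keeps a
comfortable margin for the spike's sharp rise.

What the generator does *not* emulate: movement and electrode artifacts,
drifting background amplitude, wake/sleep microstructure, imperfect
bilateral synchrony of discharge onset, and biological correlations
between timeline quantities beyond the sleep-follows-status constraint.
Tests passing on synthetic sessions therefore validate the estimators
under clean, stationary conditions; on real recordings the robust
background estimate helps, but artifact periods still need manual
exclusion.

## Discharge detection

`detect_swds()` implements the classical criteria — amplitude at least
twice background, spike-and-wave rhythm, duration over 1 s, merging of
discharges separated by less than 1 s — as a reproducible operator:

1. **Background amplitude** (`estimate_background_amplitude()`): the 40th
   percentile across 0.5-s windows of the within-window 95th percentile
   of the rectified signal, computed on the pre-injection segment when the
   injection time is known. The within-window 95th percentile is a
   peak-equivalent level for both noise-like (`~1.96 sigma`) and
   oscillatory (`~amplitude`) backgrounds. The cross-window quantile
   trades two failure modes: a median breaks down once discharges occupy
   half the record, while a very low quantile underestimates the
   background enough for rare noise excursions to cross the 2x threshold;
   the 40th percentile stays correct up to ~60% discharge density while
   keeping the threshold essentially at the median level.
2. **Envelope**: per 0.5-s window (step 0.25 s), the mean of the top 3%
   of rectified samples. A percentile-style envelope at, say, the 95th
   percentile systematically underestimates the peak of a spike train
   whose spike occupies ~10% of the cycle, which would push a discharge
   generated at 2.5x background below a 2.0x threshold; the top-3% mean
   tracks the per-cycle peak for both morphologies.
3. **Candidates** are runs of windows with envelope at or above
   `2.0 x background`; boundaries are placed at window centres
   (quantisation 0.25 s).
4. **Merge, duration, rhythm**: candidates separated by less than 1 s are
   merged; events must then exceed 1 s; finally at least 60% of an
   event's windows must have their dominant frequency (zero-padded
   windowed periodogram argmax) inside the SWD band.

The canonical band is 7--11 Hz (`detection_config()`); the
injection-session entry points use `dex_detection_config()` with a
4--12 Hz band because the drug-slowed fundamentals (5--6 Hz) fall below
the canonical band — a detector that enforced 7--11 Hz strictly would
reject the very events this model produces. The detector is invariant to
rescaling the whole signal, never emits events under the minimum
duration, and on generator output with the default 2.5 amplitude ratio
recovers injected events with recall and precision 1.0 at 80%
interval-overlap matching.

Per-cycle **peak voltages** are extracted by slicing each event into
cycles of the event's dominant frequency and taking each cycle's maximum;
their variance is the statistic behind `peak_voltage_variance_test()`.

## Status classification, sleep, phases

A discharge of 60 s or more is an **absence-status event**
(`classify_status()`), binned left-closed into 1--2, 2--5 and >5 min
(`B1`/`B2`/`B3`); "over 1 min" is implemented as `>= 60 s` and the
boundary cases are measure-zero for the generator. **Sedation sleep**
(`detect_sleep()`) is scored as maximal intervals of at least 60 s in
which at least 80% of sliding 10-s windows (step 1 s) have more than 45%
of their 1--40 Hz power in the delta band and no detected discharge
overlaps; brief spindle interruptions up to 10 s are absorbed. Window
centres define the boundaries, which keeps the boundary error near the
step size (empirically under 5 s for a clean transition). The 0.45
threshold separates the generator's sleep (delta fraction ~0.85) from
wake pink background (~0.38) with a wide margin on 10-s windows.

`segment_session()` then splits a session at the first sleep interval:
status events between injection and sleep are the *initial status*,
status events after sleep ends the *second period*; latencies are
reported in minutes after injection. Sleep offset is scored
independently of the first second-period event rather than defined by
it; the two agree to within seconds on generator output. A session with
no post-injection status (the pretreatment-suppressed outcome) yields
empty phases and `NA` latencies, flagged, not an error.

## Spectra, coherence, and group statistics

`multitaper_psd()` estimates an **amplitude-convention** spectrum (RMS
across DPSS tapers of the tapered Fourier amplitude, linear in the
signal) on the 1..40 Hz grid from 5-s epochs; `select_epochs()` provides
the `first5` / `mid5` / `last5` epochs of an event, requiring 20 s of
event by default. The taper bandwidth parameter is "2 Hz" read as *total*
bandwidth (half-bandwidth W = 1 Hz, time-bandwidth NW = 5, K = 9 tapers).
The wider reading (W = 2 Hz, K = 19) is selectable via
`bandwidth_convention = "half"`, but its spectral window spans +/- 2 Hz
and flattens a line's neighbourhood so much that harmonic peaks land off
the 1-Hz grid (a 7-Hz train's harmonics appear at 15/20 rather than
14/21); peak frequencies quoted on a 1-Hz grid require a concentration
bandwidth no wider than the grid step, hence the default.

`mt_coherence()` is the amplitude-weighted phase coherence
`|<A_l A_r e^{i dphi}>| / sqrt(<A_l^2><A_r^2>)` averaged across tapers
within the epoch (no sub-windowing: one 5-s epoch is the analysis unit).
It is bounded in [0, 1] and identically 1 for identical channels; with
K = 9 tapers its independence floor is about `1/sqrt(K) ~ 0.33`.

`find_spectral_peaks()` returns grid frequencies strictly greater than
both neighbours with power above a relative floor (default 10% of the
spectrum maximum), ascending; the "first peak" of a spectrum is the first
element. `compare_psd_groups()` runs a two-sided Mann-Whitney U test per
frequency and applies Benjamini-Hochberg control across the 40
frequencies at q = 0.01. With the exact test, the smallest two-sided
p-value at n = 6 + 6 is ~0.0022, so isolated single-frequency effects
cannot survive q = 0.01 at that sample size — only effects spread over
many frequencies (or larger groups) can; the power simulations in the
test suite use n = 8 for this reason.

`peak_voltage_variance_test()` defaults to Bartlett's homogeneity test,
whose statistic is chi-square with k - 1 = 2 degrees of freedom for the
three event types; the Brown-Forsythe variant is available for
heavy-tailed peak distributions. Per-animal p-values are FDR-corrected
across animals with `fdr_correct()`.

## Numerical choices

* All filtering is zero-phase via an FFT mask with raised-cosine
  transitions (unit in-band gain, no group delay to shift event
  boundaries); FFT lengths are padded to 2-3-5-smooth sizes.
* DPSS tapers come from the classical symmetric tridiagonal eigenproblem
  and are cached per (length, NW, K).
* Intervals are half-open `[start, end)` in seconds from record start,
  double precision; duration bins are left-closed.
* Ties in the windowed dominant frequency argmax resolve to the lowest
  frequency; spectra with plateaus yield no peak at the plateau (strict
  inequality), which the K = 9 taper choice makes a non-issue on
  generator output.
* Degenerate inputs: zero-duration segments return empty vectors; records
  shorter than one analysis window, background estimation on under 10 s,
  epochs from events shorter than the minimum, and fewer than 2
  observations per comparison group raise explicit errors.

## Problem sizes in the validation suite

The test suite and the acceptance script validate parameter recovery on
ensembles of 50 full sessions (about two hours of simulated signal each
at 200 Hz), which a single core processes in a few minutes; the
generator-closure checks use 150--500 timeline draws, and the Monte-Carlo
calibration of the variance test uses 1000 replicates at n = 50 per
group. These sizes put Monte-Carlo standard errors well below the
tolerances being checked while keeping a full run inexpensive.

## Known limitations

* The generator's clean stationarity overstates detector performance
  relative to artifact-laden recordings (see above).
* Sleep scoring knows a single sedation-sleep state; no NREM/REM staging.
* The in-band rule widened to 4--12 Hz for injection sessions would also
  accept theta-band oscillations of comparable amplitude; on real data
  the amplitude criterion carries more of the discrimination burden.
* EDF support covers the subset of the format the package writes
  (16-bit, two signals, 1-s records); it is not a general EDF+ reader.
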