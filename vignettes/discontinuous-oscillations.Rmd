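---
title: "Quantifying discontinuous oscillations in the neonatal prefrontal-hippocampal network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying discontinuous oscillations in the neonatal prefrontal-hippocampal network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neodev)
library(tibble)
```

## The analysis problem

In the first postnatal week, the rodent prelimbic cortex (PL) and hippocampal
CA1 (HP) do not oscillate continuously. Their local field potential (LFP)
alternates between "silent" stretches and discrete bouts of coordinated
oscillatory discharge — *active periods*. Most physiologically meaningful
quantities at this age (band power, cross-regional coupling) are only defined
*within* those bouts, so the analysis chain is: detect the bouts, summarize
their features, estimate spectra and coupling inside them, reduce everything
to one row of features per animal, and compare groups of animals with
nonparametric tests.

`neodev` implements that chain end to end, together with synthetic-data
generators that produce recordings, spike trains, behavior logs, and whole
cohorts *with ground truth*, so every stage is testable without access to any
particular laboratory's recordings.

## Active-period detection

The detector mirrors standard practice for discontinuous neonatal LFP:

1. band-pass 4–20 Hz (zero-phase Butterworth, order 3 per pass) and
   downsample to 100 Hz;
2. z-score per channel over the whole recording (relative mode);
3. form an envelope with a 500 ms boxcar;
4. hysteresis threshold: maximal runs of envelope samples strictly above the
   *lower* threshold (2 SD, or 50 µV in absolute mode) are kept when they
   contain at least one sample strictly above the *upper* threshold (4 SD /
   100 µV);
5. merge periods separated by less than 1 s; then discard periods shorter
   than 300 ms (in that order — the order is observable and tested);
6. report per period the maximum absolute amplitude of the raw-scale trace
   band-passed to 4–100 Hz, and per recording the mean amplitude, mean
   duration, periods per minute, and fraction of time active.

**Envelope choice.** A "boxcar square filter" admits two readings: rectify
then average, or square, average, and take the root (an RMS envelope). We use
the RMS envelope as the default (`square_boxcar_sqrt`), with rectification
behind a switch. The RMS reading is self-consistent with the absolute
thresholds: a 150 µV oscillation has an RMS envelope of
$150/\sqrt{2} \approx 106$ µV, above the 100 µV seed threshold, whereas its
rectified mean ($2/\pi \cdot 150 \approx 95$ µV) would sit *below* the seed
threshold and a textbook 150 µV burst would never be detected in absolute
mode.

**Relative vs absolute thresholds.** Relative (SD-based) thresholds are the
default because they are invariant to gain differences between animals —
detection output is provably identical for `x` and `a*x` — at the cost of a
self-normalization: long or frequent bursts inflate the recording SD and so
raise the effective threshold. With the burst statistics we simulate
(≈2.5 % duty cycle) this costs little sensitivity; analyses of recordings
with much denser bursting should prefer absolute mode.

## Spectra, coherence, and coupling

**Welch PSD.** Non-overlapping windows (1 s default, i.e. 1 Hz resolution),
Hann taper, one-sided normalization such that the integrated PSD equals the
mean square of the signal (checked against Parseval in the tests).
`psd_over_periods()` draws whole windows only from inside detected periods,
skips periods shorter than one window (and counts them), and averages window
periodograms. Band powers (theta 4–12, beta 12–30, gamma 30–40 Hz) are
trapezoidal integrals with interpolated band edges, so adjacent bands add
exactly.

**Imaginary coherence.** $C_{XY}(f) = |\mathrm{Im}(P_{XY} / \sqrt{P_{XX}
P_{YY}})|$ from the same Welch machinery. Because only the imaginary part is
kept, any zero-lag mixture of a common source (the volume-conduction
confound) scores ~0; a quadrature pair scores ~1 at the carrier.

**Phase-amplitude coupling.** For each (phase frequency $f_p$, amplitude
frequency $f_a$) cell: band-pass both signals, take the phase of the HP
signal and the amplitude envelope of the PL signal from the analytic signal,
bin amplitude by phase into 18 bins, and compute the Kullback–Leibler
modulation index $MI = (\log N + \sum p \log p)/\log N \in [0, 1]$ (a
mean-vector-length estimator is available via `method = "mvl"`).

The amplitude filter bandwidth is the one genuinely consequential estimator
choice. Amplitude modulation at $f_p$ of a carrier at $f_a$ lives in
sidebands at $f_a \pm f_p$: an amplitude band narrower than $2 f_p$ removes
the modulation it is supposed to measure, and we verified that a fixed
±2 Hz band makes the modulation index flat in the injected coupling depth.
The default grid therefore uses adaptive amplitude bands of
$f_a \pm (f_p + 4)$ Hz (centers 13–47 Hz in 2 Hz steps, clipped below
Nyquist), the bandwidth rule recommended for KL-MI estimators; the extra
4 Hz margin keeps the sidebands away from the filter roll-off so that
neighboring cells are penalized by admitted noise rather than rewarded by
sideband attenuation. Fixed-width grids remain available by passing
`halfwidth_hz` explicitly. One caveat: for a noiseless sinusoidal phase
signal, adjacent phase cells carry nearly the same phase estimate (the
filter's amplitude response does not perturb the phase of a single
sinusoid), so peak localization along the phase axis is only meaningful for
signals with a realistic noise background.

## Spiking and information measures

Multi-unit activity is detected on the 500–5000 Hz band (clipped to
$0.45 f_s$ with a warning at low sampling rates) as local minima exceeding
5 SD of the filtered trace with topographic prominence (computed on the
negated trace) greater than half the peak magnitude, at most one detection
per 1 ms refractory window. Both criteria are relative, making detection
scale-free. Band-pass filtering any transient produces opposite-polarity
rebound lobes of roughly a third of the peak; the 5 SD threshold, referenced
to the filtered-trace SD, is what keeps those rebounds sub-threshold at
physiological spike rates, and the test fixtures inject in-band templates at
a realistic ~40 Hz multi-unit rate for exactly that reason.

Spike trains are binned at 50 ms and summed across a region's electrodes.
Entropy and mutual information are plug-in (maximum-likelihood) estimates on
the empirical distribution of binned counts, in bits by default. Plug-in MI
is biased upward by roughly $(|X||Y|-|X|-|Y|+1)/(2N\ln 2)$ bits; at 36,000
bins (a 30 min recording) this is below 0.001 bits and we treat it as
negligible rather than applying bias corrections. Reported log-MI values in
figures are a plotting transform, not part of the estimator.

## Behavioral scores

All scores are exact arithmetic on event logs: interaction bouts from
head-point zone entries with the climbing exclusion (head and
center-of-gravity both inside the object zone does not count), the
discrimination ratio $(novel - familiar)/(novel + familiar)$ (undefined, not
zero, when both are zero), triplet-based Y-maze metrics (spontaneous
alternation, alternate-arm return, same-arm return, each divided by $n-2$
triplets), the marble-burying index as the mean across observers per
timepoint, 8-zone open-field occupancy with path length and velocity, and
scan-sampling nest occupancy percentages.

The triplet definitions make the three Y-maze categories disjoint by
construction (the residual case first = second ≠ third belongs to none), a
property the tests assert on random sequences.

## Group statistics

The battery is rank-based throughout: two-sided Mann–Whitney U (exact by
full enumeration of rank assignments when $n_x + n_y \le 16$ and tie-free;
otherwise normal approximation with tie and continuity corrections),
Kruskal–Wallis with tie-corrected H and Dunn's pairwise z tests (Bonferroni
by default, Holm by flag), and Friedman with within-block midranks and
Dunn's post hoc. `run_cohort()` picks the test automatically: two groups →
Mann–Whitney, three or more → Kruskal–Wallis + Dunn.

**Outlier rule.** Values strictly above the 90th or strictly below the 10th
percentile (linear-interpolation percentiles, `quantile()` type 7) are
excluded before testing. We apply the rule to the *pooled* feature values,
not per group: per-group trimming removes each group's overlapping extremes
and thereby amplifies chance separation — in null simulations at $n = 12$
per group it nearly quadruples the Mann–Whitney false-positive rate (~18 %
vs the nominal 5 %), while pooled trimming measures at ~4 %. The per-sample
rule itself (`exclude_outliers()`) retains the strict-inequality semantics.

## The synthetic-data generators

`gen_lfp()` emulates what the analysis assumes about neonatal LFP: a $1/f$
pink background (15 µV SD default) with Tukey-tapered (α = 0.25) sinusoidal
bursts at annotated times. Defaults — 10 Hz bursts of 200 µV at 1.5 per
minute with lognormal durations around 1 s, shared between PL and HP — were
chosen once as realistic neonatal values: bursts an order of magnitude above
the background, a few per minute, ~2.5 % duty cycle. Burst onsets are
stratified into equal slots with ≥1.5 s separation so ground truth never
interacts with the 1 s merge rule. Cross-regional coupling is injected by
adding a continuous phase rhythm to HP and a carrier on PL whose envelope is
$(1 + d\cos\varphi)/2$ at depth $d$.

`gen_coupled_spike_trains()` produces two Poisson trains whose dependence is
a binomial thinning of the first train's realized counts, so both marginal
rates stay fixed while MI rises monotonically with the coupling parameter
(and equals $H(A)$ exactly at coupling 1). `gen_behavior()` assigns bouts to
the novel object with probability $(1 + preference)/2$, making the expected
discrimination ratio equal the preference. `gen_cohort()` applies per-group
multipliers (amplitude, rate, coupling depth, preference) on top of
per-animal lognormal amplitude variability (cv 15 %), with per-animal seeds
derived deterministically from a master seed.

What the generators do **not** emulate: non-sinusoidal burst morphology
(spindle shape, nested gamma), non-stationary background, movement and
electrical artifacts, electrode drift, volume conduction between regions,
and state transitions. Passing tests therefore demonstrate that the
*estimators and statistics* behave correctly under the assumed signal model,
not that the detector is robust to every artifact of real recordings.

## Numerical choices and degenerate inputs

* Filters: zero-phase forward–backward Butterworth, order 3 per pass, with
  reflect padding of three periods of the lowest passed frequency; bands
  must satisfy $0 \le f_{lo} < f_{hi} < f_s/2$, and a band with
  $f_{lo} > 0$ has the channel mean removed first so constant signals map
  exactly to zero.
* Downsampling uses a zero-phase frequency-domain low-pass, flat to
  $0.4 f_{target}$ and zero from $0.5 f_{target}$, then integer decimation
  (or linear interpolation for non-integer ratios).
* Thresholds are strict inequalities; ties at exactly a threshold do not
  seed or extend periods.
* Zero-variance channels are errors (never silently skipped) for z-scoring,
  relative-mode detection, and MUA detection.
* Empty period lists yield rate 0 and fraction 0 but *missing* amplitude and
  duration.
* Welch windows that do not fit are an error for whole signals and a counted
  skip for periods.
* All generators are pure functions of spec + seed; per-animal seeds are
  derived with 32-bit-safe integer arithmetic.

## Problem sizes used in the shipped checks

The shipped tests and the acceptance script run, among other things: one
30-minute, 100 Hz two-channel recording with 20 injected bursts for detector
recall/precision; 100 seeds × 4 coupling depths (60 s each) for PAC
monotonicity; a 10 s, 25 kHz trace with 400 injected spikes for MUA recall;
2000 replicates per test for type-I error at $n = 12$ per group; and
100 power, 100–200 null, and 30 rescue cohorts of 24–36 animals with
60-second recordings each for the end-to-end parameter-recovery checks.
Sixty-second recordings keep cohort simulations light; the detector and all
downstream estimators are duration-agnostic, and the single-animal checks
use the full 30-minute length.

## Known limitations

* Published neonatal PAC analyses rarely print their estimator in full; the
  KL modulation index is one standard choice, the mean vector length the
  other, and the package's checks target ordering and peak placement, which
  both satisfy.
* Plug-in entropy/MI carry small positive bias; bias-corrected estimators
  are out of scope.
* The Friedman branch requires complete blocks; unbalanced repeated designs
  are rejected.
* Absolute-threshold detection requires µV units end to end; the reader
  refuses files without unit metadata rather than guessing.
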