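---
title: "Methods: ECG-augmented SOBI for neonatal cardiac-artifact removal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ECG-augmented SOBI for neonatal cardiac-artifact removal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cardsobi)
```

## The model

A neonatal EEG segment is modeled as an instantaneous linear mixture of
sources: low-frequency brain activity, an electrical cardiac leak that is a
scaled copy of the ECG waveform on every affected electrode (zero delay,
QRS-locked), and a pulsatile artifact — the vascular pulse conducted through
the open anterior fontanelle — whose waveform is a slow rise-and-decay
delayed 150–350 ms after each R peak and whose topography peaks
fronto-centrally (Fz/Cz). Because mixing is instantaneous and sources have
distinct temporal autocorrelation structure, second-order blind
identification (SOBI) applies: after whitening, the lagged covariance
matrices of the mixture are jointly diagonalizable by one orthogonal matrix,
and sources are identified up to permutation, sign and scale.

The central design idea is to make the cardiac subspace explicit: the
normalized recorded ECG (`nECG`) and a synthesized Artificial Pulse Signal
(`nAPS`) are appended to the 19 EEG channels before decomposition (group
G1, 21 signals; G2 drops the APS; G3 is EEG-only). These auxiliary rows are
nearly clean realizations of the two artifact sources, which anchors two of
the recovered components onto the cardiac time courses instead of letting
that variance smear across many components.

Assumptions worth stating explicitly:

* the ECG channel is present, of usable quality, and synchronized with the
  EEG — every stage (APS, normalization, classification delays, varRPP)
  hangs off the detected R peaks;
* artifacts are spatially stationary over the analyzed segment (fixed
  mixing columns), which is why 5-minute segments are the intended unit of
  analysis;
* the decomposition is square and full-rank: a constant or duplicated
  channel is a hard error, never a silent dimension reduction.

## Stage-by-stage choices

**Band-pass filter.** Windowed-sinc FIR, Hamming window, 0.5–45 Hz. The
order follows a transition bandwidth of `min(low, 2)` Hz at the low edge
(1691 taps at 256 Hz), and the symmetric kernel is applied twice after
mirror padding by one filter length — the forward–backward equivalent, so
the filter is exactly zero-phase. Zero phase matters downstream: the
ECC/PCC decision uses peak delays of ±20 ms and 150–350 ms, which a causal
filter's group delay would corrupt.

**R-peak detection.** The method that consumes the R peaks does not depend
on how they were found, so a standard derivative-energy scheme is used:
5–40 Hz band-pass of an ECG copy, squared first difference, adaptive
threshold at 0.4 × the local 2-s maximum, 200 ms refractory period, then
refinement to the raw-ECG extremum within ±40 ms. It is exact to ±1 sample
on synthetic ECGs down to 15 dB SNR (tested), which is all the pipeline
needs. Rates outside 0.5–5 Hz are flagged as warnings in the returned
object rather than errors, since the bound is physiological, not numerical.

**Heart-rate frequency.** Defined as `fs / median(RR)` — robust to missed
beats. One subtlety: at 2.4 Hz and 256 Hz sampling, the median R-R interval
is quantized to whole samples, so this estimate moves in ≈ 0.02 Hz steps,
while the spectral metrics (APICs, varPSDhr) read a single 0.01 Hz PSD bin.
The pipeline therefore refines the metric frequency to the ECG PSD argmax
within ±0.1 Hz of the R-R estimate, so the bin interrogated is the actual
cardiac spectral line. Without this refinement the single-bin metrics
fluctuate strongly from segment to segment for reasons unrelated to
separation quality.

**APS template.** Per beat, a linear saw-tooth ramp from 0 to 1 over
`rise_fraction = 0.35` of the local R-R interval, then a raised-cosine
decay back to 0; the sampled maximum is placed exactly
`round(delay · fs / 1000)` samples after the R peak (delay default 250 ms).
Each instance spans the local R-R interval, so instances tile the beat grid
without additive overlap (overlapping tails are resolved by a pointwise
maximum). The template is injectable (`pulse_template()`) because only the
qualitative shape — high amplitude, slow progression, single maximum — is
constrained by the physiology.

**Amplitude normalization.** `signal × MAmpEEG / AmpSignal`, with
peak-to-peak amplitudes taken literally as max − min over the whole
segment, one scalar per segment. An optional robust mode uses the
0.5th–99.5th percentile spread to resist single-sample spikes; it is off by
default to keep the literal definition. The operation is idempotent and
forces the output peak-to-peak to equal the mean EEG peak-to-peak exactly.

**SOBI.** Lags 1–100 samples (≈ 4–390 ms at 256 Hz) span cardiac
timescales; the set is configurable. Whitening uses the symmetric
eigendecomposition of the zero-lag covariance with an absolute eigenvalue
floor of 1e-12 × trace; below-floor eigenvalues raise the rank-deficiency
error naming the offending rows. Joint diagonalization runs cyclic Givens
sweeps with the closed-form per-pair angle, stopping when every rotation
sine in a sweep falls below 1e-8 (max 100 sweeps). On real-size problems
(21 × 100 matrices) the sweep limit is often reached while the rotations
hover around 1e-4 — brain sources with nearly identical 1/f spectra make
some angles ill-determined — so the result is returned with a convergence
flag; the cardiac components, whose spectra are distinct, are unaffected.
Sources are ordered by descending power fraction at the heart-rate
frequency (cardiac components first, deterministic output), and each
source's sign is fixed so its best correlation with an input row is
positive. Sources carry unit variance; scale lives in the mixing matrix.

**Welch PSD.** 100-s Hamming windows with 50% overlap give the 0.01 Hz
native resolution at 256 Hz; shorter signals fall back to the largest
power-of-two window with the FFT zero-padded onto the same 0.01 Hz grid.
Estimates are one-sided densities restricted to 0.5–45 Hz.

**Classification cascade.** For each target artifact (ECG features → ECC,
APS features → PCC): (i) artefactual if one of {PSD correlation,
time-course correlation} exceeds 0.9 and the other exceeds 0.75;
(ii) otherwise if the PSD correlation exceeds 0.9 and the median per-beat
peak delay matches the physiology (|delay| ≤ 20 ms for ECC; 150–350 ms for
PCC); (iii) otherwise NCC. Correlations are absolute values (ICA sign is
arbitrary), making labels sign- and scale-invariant. Two published readings
of the correlation rule exist; the default implements the stricter
symmetric one, and `literal_text_rule = TRUE` switches to the more
permissive variant (both correlations > 0.75). The delay "equal to 0" for
ECC is given a ±20 ms tolerance: exact zero is unattainable at 256 Hz
sampling with finite QRS width, and 20 ms stays far below the 150 ms PCC
lower bound, so the branches cannot overlap. The per-beat IC peak is the
maximum of |IC| within [R, R + 0.9·RR]; the median delay is defined only
when at least half the beat windows are usable. If both the ECC and PCC
branches fire, the larger PSD correlation wins (ties to ECC). For G2/G3
decompositions the APS is not a SOBI input, but the classifier still
synthesizes it from the R peaks (flagged in the output), so pulsatile
components remain detectable in every group mode.

**Metrics.** "Power at the heart-rate frequency" is the PSD value at the
single nearest 0.01 Hz bin — the literal reading — with an optional
band-integral mode (±0.05 Hz) available for drifting rhythms. "Total
power" is the sum of squared mean-removed samples. The CC threshold uses a
strict inequality (APICs > 1%). varRPP and SPV/varPSDhr average over the
EEG channels only (auxiliary rows never enter any metric); a channel subset
can be supplied when only part of the montage is affected. Percentage
variations are reported unclamped — negative values mean power increased.

**Validation scores.** ECC and PCC merge into one cardiac-related class
before counting. The sensitivity is the corrected form
`(TPR − FPR)/(1 − FPR)`, which reduces to ordinary recall when FP = 0; the
pathological negative case (TPR < FPR) is flagged with a warning and
reported as-is. Scores are stored at full precision; rounding is a display
concern (2 decimals for group comparisons, 3 where finer print is needed).

## The synthetic generator

`generate_recording()` emulates a contaminated 5-minute neonatal segment:
19 channels at 256 Hz; 17 brain sources of 1/f-shaped Gaussian noise
band-limited to 0.5–8 Hz, mixed by a random full-rank matrix to ≈ 20 µV
RMS per channel; an ECG at millivolt scale with Gaussian-second-derivative
QRS complexes (≈ 80 ms support, so the waveform maximum coincides with the
R sample) and a low T wave, beating at 2.4 Hz with 3% R-R jitter; an
electrical leak (the ECG waveform scaled per channel, visible tens-of-µV R
spikes, strongest temporally/frontally); a pulse train delayed 250 ± 20 ms
per beat, present on all channels through volume conduction but 2–3×
stronger fronto-centrally; and white sensor noise at 20 dB SNR. Seventeen
brain sources plus the two artifact sources keep the 19-channel mixture
square and full-rank. The optional seizure mode replaces one brain source
with an amplitude-modulated 1–3 Hz burst train (10-s on/off cycles), so the
source count — and hence the rank structure — is unchanged. All randomness
flows from a single seed and the global RNG state is restored on exit.

What the generator does **not** emulate: realistic head-model topographies
(weights are fixed gain vectors, not a forward solution), electrode
artifacts (pops, movement, ocular/muscle activity), amplitude
nonstationarity, heart-rate drift over minutes, and ectopic beats. Passing
tests on this generator therefore demonstrates that the pipeline removes
what its model says cardiac interference is; performance on real recordings
additionally depends on those unmodeled features, most of all on ECG
quality.

One accounting subtlety in ground-truth scoring: in G1/G2 groups the
auxiliary nECG/nAPS rows themselves emerge as independent components and
are labeled ECC/PCC — correctly, since they are cardiac signals. In
artifact-free simulations these components carry no EEG projection
(removing them changes the reconstructed EEG by ≈ nothing), so
`score_against_truth()` counts false alarms only on brain-only ICs:
components matching neither a planted artifact source nor an auxiliary
input.

## Problem sizes in the test suite

Unit tests run on 20–60 s segments with lag sets 1:15–1:50 to keep
turnaround fast; the acceptance-level study uses the full default
conditions (300 s, 19 channels, lags 1:100) across 20 contaminated seeds
(G1 and G3) plus artifact-free counterparts, and `scripts/acceptance.R`
repeats that study with seeds derived from its `--seed` argument. SOBI
oracle checks use 3–10-channel planted problems where the answer is known
by construction.

## Known limitations

* Exact component-level agreement with any other SOBI implementation is
  not expected: the lag set, convergence tolerance and sweep order all
  influence the rotation within the degenerate brain subspace.
* The single-bin spectral metrics assume a stable heart rate over the
  segment; for drifting rhythms use the band-integral mode.
* The classifier's thresholds (0.9/0.75, 20 ms, 150–350 ms) are fixed
  clinical-heuristic constants, deliberately not fitted to data; the
  config file exposes them all.
* EDF support covers the common 16-bit single-rate case (one data record
  per second, identical sampling rate across signals); mixed-rate or
  EDF+ annotation records are out of scope.
* No treatment of non-cardiac artifact classes; an IC contaminated by both
  cardiac and ocular activity is removed wholesale if it passes the
  cascade.
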