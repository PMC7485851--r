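---
title: "AUREA: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{AUREA: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aurea)
```

## The classification model

AUREA treats breathing-pattern scoring as a per-sample decision problem on
two uncalibrated belt signals (ribcage RCG, abdomen ABD, typically 50 Hz).
It makes no assumption of sinusoidal breaths, constant rate or constant
amplitude; everything is built from sliding rectangular windows that
advance one sample at a time, so every sample of the record receives a
label and the output is a pattern sequence (PSEQ) aligned with the input.

The assumptions that *are* made:

- a respiratory pause is a stretch where both belts' excursions collapse to
  a small fraction of their recent baseline (the AASM-style amplitude
  rule), so *normalized variance* discriminates it;
- movement produces broadband stochastic power below ~0.5 Hz with amplitude
  larger than breathing, so power that survives a comb filter notched at
  the modal respiratory frequency (*nonperiodic power*) discriminates it;
- breathing itself is quasi-periodic, so after smoothing and binarising
  each channel, the high-pass-filtered sum and difference of the two
  binary signals carry the synchronous (`b+`) and paradoxical (`b-`)
  oscillation power;
- pattern prevalences are heavily unbalanced (synchronous breathing
  dominates), which is why the k-means decision boundaries are re-anchored
  by cluster size (see below).

Classification is a fixed-order cascade PAU → MVT → SYB → ASB of binary
detectors.  Pause is tested first because during a pause the signal power
is so low that every other metric becomes noise-dominated; movement is
tested second because its low-frequency power would bias the synchrony
detectors.  Samples rejected by all four detectors are UNK.

## Analysis windows and tunable parameters

All widths are seconds unless stated; widths convert to the nearest odd
sample count (rounding up when even) so centred windows have an integral
half-width.  Defaults follow the published AUREA configuration for 50 Hz
infant recordings.

| parameter | default | role |
|-----------|---------|------|
| `nLF`, `nDTPauMvt` | 5 | detrend window for the PAU/MVT chains; removes mean and drift |
| `nDTSybAsb` | 2 | detrend window for the SYB/ASB chain |
| `nV` | 1 | variance window; short so brief pauses register quickly |
| `nQV` | 120 | trailing window for the variance-normalising quantile |
| `nMA` | 1.42 | comb-filter window; first null at fs/N ≈ 0.70 Hz (42 breaths/min, the modal infant rate) |
| `nRMS` | 5 | RMS window on the comb-filtered signal |
| `nQRMS` | 600 | trailing window for the RMS-normalising quantile |
| `nSMO` | 0.42 | pre-binarisation smoothing; rejects sensor noise without blurring breaths |
| `nB` | 2 | power window for SUM/DIF (≈1.4 breath cycles) |
| `nBPhase` | 101 samples | phase moving-average window |
| `qVar`, `qRMS` | 0.5 | normalising quantiles; the median is a robust "recent normal breathing" reference because SYB occupies >60% of the time.  The RMS quantile is not pinned down by the published description; the median is adopted by analogy and both are configurable. |
| `hpCutoff` | 0.5 Hz | high-pass on SUM/DIF; pause/movement power lives below ~0.4 Hz |

`trainAurea()` additionally takes a seed (k-means++ initialisation,
best-of-10 restarts — the published description is silent on
initialisation, so a reproducible scheme was chosen and recorded in the
model) and `includeInvalid` (whether samples with incomplete normalisation
windows join the training pool; default off).

## Numerical and interpretation choices

- **Window edges.** Centred windows shrink symmetrically at the record
  edges; trailing quantile windows expand from the start.  Output length
  therefore always equals input length, which the sample-wise PSEQ
  contract requires.  `validMask` marks samples whose longest window
  (the 600 s trailing quantile) is fully supported; classification labels
  every sample regardless, but training excludes unsupported samples by
  default and evaluation summaries in this package are reported on the
  supported region.
- **Epsilon floor.** The denominators (and numerators) of both log-ratio
  metrics are floored at 1e-12 in squared-signal units, so an all-zero
  calibration stretch yields a large negative but finite metric rather
  than -Inf.  Scale invariance is exact away from the floor; at samples
  whose windowed power sits below it (in practice only edge samples whose
  shrunken window leaves an exact-zero residual) the floor breaks the
  ratio property, which the test suite documents explicitly.
- **Binarisation baseline.** The published description compares the
  smoothed signal against the low-frequency baseline even though the
  smoothed signal is built from the already-detrended series; this package
  binarises as *smoothed detrended signal > 0*, which is the same
  comparison expressed once, and ties (exactly zero) map to 0.
- **SUM/DIF operands.** The sum and difference are formed from the
  *binary* channels: only then does the documented limiting behaviour hold
  (synchronous: SUM oscillates 0–1 while DIF ≡ 0; paradoxical: SUM ≡ 0.5
  while DIF oscillates).
- **High-pass filter.** An 825-tap linear-phase FIR (Hamming window,
  design cutoff just below 0.5 Hz) applied as a single centred
  convolution with mirrored edges: symmetric taps give exactly zero phase
  without forward–backward filtering, preserving the temporal alignment of
  `b+`/`b-` with the PSEQ.  Measured response: ≈ −2.6 dB at 0.5 Hz and
  < −55 dB at 0.3 Hz.
- **Respiratory frequency.** The published description names a
  zero-crossing demodulation without a formula.  Here, consecutive
  transitions of the binary signal delimit half-periods and every sample
  between transitions k and k+1 receives `1/(2·Δt)`; samples outside the
  first/last transition carry the nearest defined value, and a series with
  fewer than two transitions is NaN everywhere (NaNs are excluded from
  summaries, never imputed).  Frequency and phase are descriptive outputs;
  only the six metrics feed the cascade.  The single `fResp`/`phi` series
  are computed from the 2 s-detrend-chain binaries, frequency from the
  abdomen channel (the channel used for the published feature
  distributions).
- **Boundary adjustment.** Applied once after k-means convergence, using
  the converged cluster sizes; each training stage then removes the
  samples its *adjusted* boundary assigns to the target, so training
  reductions mirror classification exactly.  Points exactly on the
  hyperplane go to the anti-class (strict inequality).
- **Index orientation.** The published performance tables normalise
  "precision" over the reference row and "recall" over the predicted
  column of the confusion matrix, the transpose of textbook usage.  The
  default `orientation = "published"` reproduces those tables;
  `orientation = "conventional"` gives the standard definitions.  One
  published table entry (UNKNOWN precision) differs by 0.01 from the
  pooled-count computation because that table reports per-record means;
  the package computes and reports the pooled value.
- **Pattern-matching conventions.** Events qualify at duration ≥ 2 s
  (inclusive) and match when the overlap fraction strictly exceeds the
  threshold.

## The synthetic-data generator

`generateRecord()`/`studyScenario()` emulate the statistical structure the
classifier assumes, with ground-truth labels, so training, classification
and evaluation are fully testable without recordings:

- **SYB/ASB**: sinusoids with slow random-walk amplitude (±20%) and
  frequency (±3%) jitter at 0.76 / 0.71 Hz, the abdomen lagging the
  ribcage by the spec phase.  The default scenario fixes SYB at 4° and
  draws each ASB segment's phase from 100° + Exp(mean 15°), capped at
  175°: a right-skewed distribution with mode at 100°, mirroring reported
  infant asynchrony distributions rather than a delta at the mode.
- **PAU**: a 4%-amplitude remnant plus sensor noise, rescaled if necessary
  so the segment RMS is at most 10% of the preceding breathing RMS — the
  amplitude rule the NV metric is designed to detect, enforced by
  construction.
- **MVT**: band-limited (< 0.5 Hz, twice-smoothed white noise) stochastic
  excursions, partially correlated across channels, at 2.5× the breathing
  RMS.
- **SIH**: synchronous breathing with one Gaussian-enveloped breath at
  3.5× amplitude in the segment centre.
- **UNK filler**: irregular shallow breathing — 0.55× amplitude, frequency
  drifting over 0.25–0.5 Hz (below the scoreable band and the high-pass
  cutoff), inter-belt phase drifting over 0–180°.  The published
  definition of UNK is purely residual; this filler is deliberately
  constructed to be residual for the detectors too (too slow for SYB/ASB,
  too large for PAU), giving the "well-separated" scenario the round-trip
  tests require.
- Segments are joined with 0.1 s raised-cosine cross-fades whose samples
  take the incoming label; breathing phase is continuous across breathing
  segments.  All randomness flows through one caller seed; no global RNG
  state is touched.

The default scenario mixes 60% SYB, 15% MVT, 11% UNK, 7% ASB, 5% PAU and
2% SIH (the published prevalence profile), with segment durations SYB
~10–20 s (filling the gaps), ASB 15 s, PAU 8 s, MVT 15 s, UNK 16 s, SIH
4 s, and every non-SYB segment preceded by breathing so pauses have a
baseline.

**What the simulator does not model** — and hence what passing round-trip
tests do and do not show: no cardiogenic artifact, no belt drift or
posture shifts, no behavioural-state transitions, no co-located sigh/pause
sequences, no scorer-style context effects, and pattern changes are
instantaneous rather than gradual.  Synthetic patterns are *well
separated*: pause and asynchrony detection are substantially easier here
than in clinical recordings (pause F ≈ 0.9 on synthetic data versus 0.60
reported on real data), so round-trip accuracy (~0.9 at 1500 s, seed 1)
is an internal-consistency check of the implementation, not a performance
claim about real infants.  Conversely the residual UNKNOWN class remains
the hardest pattern in both settings.

## Problem sizes

The test suite and the acceptance script use 1500 s (75,000-sample)
records at 50 Hz for end-to-end checks — long enough that the 600 s
trailing normalisation window is fully supported for 60% of the record —
and ≤ 2,000-sample series for brute-force oracle comparisons of every
windowed statistic (tolerance 1e-9 relative).  Published-table evaluations
are exact integer computations on the shipped reference counts.

## Known limitations

- Training assumes a homogeneous pool: metrics from all supplied records
  are pooled before stage A, so atypical records are classified with
  boundaries dominated by the majority.
- Sighs are not detected (no SIH stage); they surface as MVT/UNK, which is
  why evaluation merges MVT/UNK/SIH into UNKNOWN.
- Sample-wise decisions fragment events near boundaries; events shorter
  than ~2 s should be interpreted with the fragmentation histogram in
  hand.
- The EDF reader covers continuous 16-bit EDF with a common sampling rate
  across the selected channels (the format subset RIP recorders emit); it
  is not a general EDF+ implementation.
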