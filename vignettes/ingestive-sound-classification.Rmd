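---
title: "Classifying dairy-cow ingestive sounds: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying dairy-cow ingestive sounds: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jawdio)
```

## The problem

Grazing dairy cows ingest forage through a sequence of three jaw
movements: *bites* (apprehending and severing forage — impulsive,
high-amplitude sounds), *chews* (grinding ingested material — quieter,
sustained sounds), and *chew-bites* (a chew and a bite overlapped in one
jaw movement). A forehead-mounted microphone picks these up clearly
because the sound conducts through the skull, and classifying the events
automatically supports precision grazing management. jawdio implements a
complete recognition pipeline for short, pre-segmented recordings of
single events: data cleaning, log-Mel featurization, three small neural
classifiers, and the dataset organization and evaluation protocol —
plus a synthetic sound generator so the whole chain is testable without
the original recordings.

Segments are mono, 16-bit PCM at 22.05 kHz. Almost all ingestive-sound
energy lies below 1 kHz, and events typically last under 1 s.

## Cleaning

Two deterministic cleaning stages run before featurization:

**Beep removal.** The recording device emits short beeps with center
frequencies between 3.6 and 4.5 kHz. `bandstop_filter()` removes them
with a Butterworth bandstop over exactly that band. The filter design is
a choice the band specification leaves open; we use a 4th-order
prototype applied forward and backward (`signal::filtfilt`), which
doubles the stopband attenuation in dB and has exactly zero phase
distortion — important because bite transients are the most
class-informative part of the waveform. The zero-phase response at
4 kHz is below −170 dB in theory; measured on a quantized 4 kHz tone
the attenuation is ≈ 40 dB (the residual is 16-bit requantization
noise), comfortably past the 30 dB the pipeline needs, while a 500 Hz
tone passes within 0.001 dB.

**Uninformative-data removal.** Raw absolute 16-bit samples (no
normalization) are averaged in blocks of 1100 samples (≈ 50 ms). To
avoid discarding a quiet block whose neighbor holds the tail of an
event, the block mean is computed at `n_offsets = 4` staggered window
offsets (step 275 samples) and each block retains the **maximum** over
all windows overlapping it. Blocks whose retained mean falls below 100
(16-bit counts) are dropped and the survivors concatenated; nothing is
interpolated into the gaps, because the downstream features are
per-frame spectra and never look across a gap. Equality keeps the
block: only means *strictly below* the threshold are uninformative. A
final block shorter than 1100 samples is averaged over its actual
length.

One subtlety is worth recording: under the staggered-offset rule the
removal is not idempotent *in adversarial cases* — a block kept only
through a window straddling a later-discarded neighbor can lose that
support once the signal is concatenated. On actual ingestive audio the
retained blocks are loud on their own and the operation is idempotent;
the test suite checks idempotence on generated segments, not on
adversarial block patterns.

## Featurization

`log_mel_spectrogram()` implements the standard Mel workflow:

1. **Framing**: a 512-sample (23 ms) window advanced by 220 samples
   (10 ms), giving `floor((N − 512)/220) + 1` frames; signals shorter
   than one window are zero-padded to a single frame. One second of
   audio yields 98 frames.
2. **Per-frame real FFT** of the amplitude-normalized signal
   (`samples / 2^16`), squared magnitudes over 257 bins. Each frame is
   transformed independently; there is no overlap-add reconstruction.
   The analysis window is Hann by default (leakage control); a
   rectangular window is available via `stft_config(window = "rect")`.
3. **Mel filterbank**: 26 triangular filters with centers equally
   spaced on the Mel scale `m = 2595 log10(1 + f/700)` between 0 Hz and
   Nyquist, concentrating resolution below 1 kHz where the signal
   lives.
4. **dB conversion**: `10 log10(energy + 1e-10)`, clamped at −80 dB.
   Both guards are conventional numerical floors and configurable.

The dataflow deliberately stops at dB Mel-scale spectrograms — that is
what the classifiers consume. A type-II orthonormal DCT across bands
(true cepstral coefficients) is available behind
`mel_config(use_dct = TRUE)` for users who want MFCCs proper, but the
default pipeline does not apply it.

Variable-length segments become fixed model inputs with
`to_fixed_input()`: center-crop above `t_fixed` frames, symmetric
padding at the dB floor below it. The default `t_fixed = 98` frames
(1.0 s) covers a typical event with margin; padding with the floor
value rather than zeros keeps padded frames indistinguishable from
silence.

## The classifiers

Three small architectures, all ending in a 3-way softmax, all trained
with dropout 0.1, ReLU feedforward / tanh recurrent activations, and 30
epochs:

* **Conv1D** — time-distributed: each frame's 26 Mel energies pass
  through two shared conv(kernel 3) + max-pool(2) stages (32 then 64
  filters); per-frame features are flattened across time into dense
  layers. 351,343 parameters.
* **Conv2D** — the whole spectrogram as an image: two 3×3 conv + 2×2
  pool stages (16 then 32 filters), flatten, dense. 432,147 parameters.
* **LSTM** — two serial units, each a shared per-frame dense skip path
  (32 units) concatenated with a bidirectional LSTM (32 hidden per
  direction) reading the spectrogram forward and backward; then
  flatten and dense layers. 390,931 parameters.

Exact layer widths are a reconstruction: the reference description
names the layer types and total parameter counts (348,770 / 431,290 /
392,050) but not the widths, so ours are chosen to land within 1% of
those counts; exact equality is not claimed.

The networks and their training loop are implemented in base R (matrix
algebra via BLAS): Glorot-uniform initialization (LSTM forget-gate
biases at 1), minibatch Adam (learning rate 1e-3, batch 32) on
categorical cross-entropy. Optimizer, learning rate, and batch size are
not specified by the protocol we reproduce; these are the field's
defaults for small audio classifiers and are configurable in
`train_config()`. Inputs are standardized by the global training-set
mean and standard deviation (stored in the fitted object). Every
stochastic element — initialization, shuffling, dropout — runs under a
private seeded RNG stream, so fits are bit-reproducible. Training
aborts with a diagnostic if the loss goes non-finite.

`jaw_classifier()` is the one-call fitting interface and returns a
classed object with `print`, `summary`, `predict`, and `plot`
(accuracy-curve) methods.

## Dataset protocol

`inventory()` reproduces the corpus accounting (counts and durations
per behavior × forage species × forage height). `balance_by_count()`
implements count balancing: every behavior is subsampled uniformly
without replacement to the smallest class count (521 for the reference
inventory), so the minority class — bites, 547.04 s — is retained in
full. The durations of the subsampled classes depend on the random
draw; the reference experiment's particular draw is not recoverable, so
those durations are reported, not asserted.

`split_manifest()` partitions 0.7 : 0.1 : 0.2 with the floor policy
(train and validation get `floor(r·n)`, test the remainder), which
guarantees a disjoint, exhaustive partition. Whether the original
protocol stratified its split is unstated; we default to stratifying by
behavior (guaranteeing per-class representation in every subset, and
requiring ≥ 3 files per class) with `stratify_by = "none"` available.
Under the global floor policy 3038 files split 2126/303/609; under
per-stratum floors the totals shift by one file (2125/303/610) — both
are exposed, and which applies is part of the resolved configuration.

`run_experiment()` chains the stages deterministically and writes
artifacts; `run_experiment_grid()` enumerates the 3 architectures × 2
filtering strategies × 2 balancing methods, and `run_forage_grid()`
the four forage conditions. The deterministic results (confusion
matrices, metrics) go to `report.json`; wall-clock figures — including
the normalized processing speed, milliseconds of processing per second
of audio — go to a separate `timings.txt`, so `report.json` is
byte-identical across reruns of the same configuration.

Overall metrics are support-weighted averages of the per-class values
by default (macro averaging via `average = "macro"`): on imbalanced
test sets the reference overall values track the chew-dominated
per-class scores, which is the behavior of the weighted average. A
class never predicted gets precision 0 with a warning.

## The synthetic generator

`generate_segment()` emulates the statistical structure of the real
corpus, not its physiology. Each behavior × forage cell is
parameterized by the published mean normalized amplitude and duration
of the real recordings (e.g. bites on short tall fescue: amplitude
0.488, duration 0.205 s); durations and amplitudes are drawn from
truncated normals around those means. Design choices, in order of
consequence:

* **Amplitude convention.** The normalization equation divides signed
  16-bit samples by 2^16, which yields values in [−0.5, 0.5) — yet the
  published amplitude descriptors reach 0.549. We therefore define the
  segment-level amplitude descriptor as *peak-to-peak sample range /
  2^16*, which lies in [0, 1], is consistent with descriptor values
  above 0.5, and reduces to the literal equation for spectra (where
  the normalization constant cancels anyway). `segment_descriptors()`
  implements this convention and the generator scales each waveform so
  its descriptor equals the drawn amplitude exactly (to one integer
  count).
* **Spread.** The source statistics report pooled standard errors of
  cell means, not per-segment spreads; without the per-cell n the
  SEM→SD conversion is unknowable. We use 5 × SEM as the per-segment
  standard deviation (configurable via `default_sound_specs(sem_factor=)`),
  which produces within-class spread large enough that classes overlap
  in single features but remain learnable.
* **Waveform templates.** Bite: band-limited noise with a sharp attack
  and fast exponential decay. Chew: stationary band-limited noise with
  short onset/offset ramps. Chew-bite: chew texture with an impulsive
  burst superimposed in the final third. Carrier band 60–950 Hz,
  honoring the sub-1 kHz energy concentration. Truncated-normal (not
  lognormal) sampling is the simplest model consistent with reported
  means.
* **Beeps.** `inject_beep()` adds tapered sinusoids at a center
  frequency in [3600, 4500] Hz at Poisson-placed positions, so the
  bandstop stage has realistic work to do.

What the generator does **not** emulate: cow-to-cow and day-to-day
variation, microphone transfer functions, chewing-rate periodicity,
background farm noise, or any within-segment spectral evolution beyond
the envelope templates. Consequently, classifiers reaching near-perfect
accuracy on synthetic data says the pipeline is *correct and learnable
end to end* — it does not predict field accuracy on real recordings,
where published figures are in the 0.8–0.93 range for the best model.
A trivial threshold classifier on amplitude and duration alone reaches
≈ 0.88 on the synthetic task, so the deep models are verified to beat a
shallow baseline, not merely to memorize.

## Problem sizes and tolerances

The bundled test suite and acceptance script run the full chain on a
600-segment synthetic corpus (50 per behavior × forage cell,
70/10/20 split) for 30 epochs per architecture — sizes chosen so the
complete suite runs on a laptop-class single core in minutes while
keeping every per-class cell populated. Stochastic checks (generator
parameter recovery over 200 draws per cell) use two-standard-error
bands. Filter attenuation is asserted against the designed filter's own
frequency response evaluated in closed form, not against a library
reference.

## Known limitations

* WAV support covers RIFF/PCM (16-bit natively; 8-bit and 32-bit float
  converted with a warning). Rate conversion is linear interpolation,
  adequate for integer downsampling of band-limited material but not a
  polyphase resampler.
* The pure-R networks are practical at this problem scale (hundreds of
  segments, ~400k parameters) but are not a general-purpose deep
  learning engine; there is no GPU path and no early stopping.
* Bit-reproducibility holds for a fixed BLAS/platform; across different
  BLAS builds results may differ in the last floating-point bits.
* The balanced-dataset chew/chew-bite durations depend on the
  subsampling draw and are not comparable across implementations.
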