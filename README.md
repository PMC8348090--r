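# jawdio

Automatic sound recognition of dairy-cow ingestive behaviors — **bites**,
**chews**, and **chew-bites** — from short forehead-microphone recordings.
Grazing cows ingest forage through these three jaw movements; their
acoustic signatures (impulsive high-amplitude bites, quiet sustained
chews, and their overlap) carry information about forage species, sward
height, and intake, which makes automatic classification useful for
precision livestock management. jawdio is aimed at researchers in
bioacoustics and precision livestock farming who want a complete,
reproducible, dependency-light R implementation of such a pipeline.

The package implements, end to end:

* **Synthetic sound generation** — labeled segments whose normalized
  amplitude and duration distributions match the published per-cell
  statistics of the public dairy-cow jaw-movement corpus
  (github.com/sinc-lab/dataset-jaw-movements), with optional injection
  of the 3.6–4.5 kHz device beeps, so every downstream stage is
  testable without the recordings.
* **Audio I/O** — RIFF/PCM WAV segments (16-bit mono, 22.05 kHz),
  manifest CSVs, amplitude normalization `x / 2^16`, and the absolute
  normalized magnitude (ANM) spectrum
  `ANM_i = |X_i| / Σ_j |X_j|` over the real FFT `X` of the segment.
* **Data cleaning** — zero-phase Butterworth bandstop over 3.6–4.5 kHz
  (device beeps), and uninformative-data removal: mean |amplitude| per
  1100-sample block, computed at staggered window offsets with per-block
  maxima, blocks below the threshold (100, 16-bit counts) dropped.
* **Featurization** — log-Mel spectrograms: 23 ms / 512-sample windows
  at 10 ms / 220-sample hops, per-frame real FFT, 26 triangular Mel
  filters (`m = 2595 log10(1 + f/700)`), dB scaling, and center
  crop/pad to a fixed 98 × 26 model input (1 s of audio).
* **Three classifiers** — time-distributed Conv1D, Conv2D, and a
  bidirectional-LSTM-with-skip-path network, each ≈ 350–430k
  parameters, trained 30 epochs with dropout 0.1 (Adam, categorical
  cross-entropy), implemented in base R with exact seeded
  reproducibility.
* **Dataset protocol and evaluation** — inventory accounting, count
  balancing to the minority class, stratified 0.7:0.1:0.2 splits,
  forage-stratified experiment grids, confusion matrices,
  precision/recall/F1 (`F1 = 2PR/(P+R)`, support-weighted or macro
  overall), and normalized processing speed (ms per 1 s of audio).

## Worked example

```r
library(jawdio)

## generate a small labeled corpus of synthetic ingestive sounds
corpus <- file.path(tempdir(), "cow-sounds")
manifest <- generate_dataset(default_sound_specs(), counts = 10,
                             out_dir = corpus, beep = beep_spec(rate = 2),
                             seed = 42)
inventory(manifest)
#> <inventory_summary>
#>   behavior n_files duration_s
#>       bite      40   7.845397
#>       chew      40   5.082494
#>  chew_bite      40  11.372698
#> grand total: 120 files, 24.30 s

## one synthetic bite and its descriptors
seg <- generate_segment(default_sound_specs()[["bite.tall_fescue.short"]],
                        seed = 1)
unlist(segment_descriptors(seg))
#> amplitude  duration
#> 0.5036011 0.1862132

## full pipeline: clean -> featurize -> train LSTM -> evaluate
report <- run_experiment(corpus, run_config(arch = "lstm", epochs = 10))
report
#> <evaluation_report> lstm / filtered / imbalanced
#> train/val/test: 84/12/24
#> <metrics_report>
#>   behavior precision recall    f1 support
#>       bite     1.000  0.875 0.933       8
#>       chew     1.000  1.000 1.000       8
#>  chew_bite     0.889  1.000 0.941       8
#> overall (weighted): precision 0.963, recall 0.958, F1 0.958
#> processing speed: 102.9 ms per 1 s of audio
```

The inventory shows the corpus structure (chews are the shortest events,
chew-bites the longest — the generator reproduces the published
per-behavior duration means). The bite's descriptors are one draw from
the tall-fescue/short cell, whose mean amplitude is 0.488 and mean
duration 0.205 s. The report gives per-class and support-weighted
precision/recall/F1 on the held-out 20% test split, plus throughput;
ten epochs on 84 tiny training files already separate the three
behaviors almost perfectly, because the synthetic classes are built to
be learnable (see the vignette for what that does and does not imply
about real recordings).

The command-line front end wraps the same functions:

```sh
Rscript inst/scripts/jawdio synth --out data/ --per-cell 50 --seed 1
Rscript inst/scripts/jawdio run --data data/ --out results/ --arch lstm
```

## Further reading

The vignette (`vignettes/ingestive-sound-classification.Rmd`) documents
the model and its assumptions, every tunable parameter with its default
and rationale, the synthetic generator's design and its limits, and the
numerical choices (windows, floors, tie-breaks, rounding policies).
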