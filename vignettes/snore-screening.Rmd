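---
title: "Snore-based OSAHS screening: models, parameters and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Snore-based OSAHS screening: models, parameters and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(snorescreen)
```

## The screening problem

Obstructive sleep apnea-hypopnea syndrome (OSAHS) is conventionally
diagnosed by polysomnography (PSG), which fuses EEG, SpO2, airflow and
audio over a monitored night. The acoustic channel alone already carries
a usable signature: normal snoring is periodically interrupted by apnea
events of roughly 10 s, during which snoring becomes very faint, and each
event ends with a loud gasp as breathing resumes. `snorescreen` turns
that signature into a screening estimate in four stages: segment snore
episodes from the night's audio, reduce each episode to a cepstral
feature matrix, classify it as apnea-related ("abnormal") or not
("normal"), and convert the abnormal count into an apnea-hypopnea index
(AHI) with a severity grade.

This vignette documents the models, every parameter that matters, the
numerical choices, and the places where the design was genuinely open.
It states no empirical result beyond what the package's test suite and
`scripts/acceptance.R` themselves compute.

## Signal front end

All analysis runs at the canonical 16 kHz mono rate; `read_wav()`
converts (channel-mean mixdown, band-limited polyphase resampling via the
`signal` package) on ingestion.

The shared time-domain chain, in order: pre-emphasis, framing, Hamming
windowing, power spectrum.

| parameter | default | meaning |
|---|---|---|
| `preemph_alpha` | 0.97 | high-pass `y[n] = x[n] − α x[n−1]`; the conventional speech value, the filter itself being standard while its coefficient is a free choice |
| `frame_len_s` | 0.03 s (480 samples) | analysis frame |
| `shift_s` | 0.01 s (160 samples) | frame hop |
| `n_fft` | 512 | smallest power of two ≥ 480; frames are zero-padded |

An incomplete trailing frame is **dropped**, not padded:
`n_frames = floor((n_samples − frame_len)/shift) + 1`, which is the only
convention under which a 3 s clip yields exactly 298 frames — the row
dimension every later stage assumes. The Hamming window
`w[k] = 0.54 − 0.46 cos(2πk/(N−1))` is applied after pre-emphasis and
before the transform; only the non-redundant 257 spectral bins are kept.

## Feature extractors

All three extractors output `n_frames × 40` matrices, so a 3 s clip maps
to 298 × 40 regardless of the feature kind.

**MFCC.** Mel filterbank energies
`s(m) = ln(max(Σ_k P(k) H_m(k), log_floor))` followed by the DCT-II
restricted to orders `n = 1..L`:
`C(n) = Σ_{m=0}^{M−1} s(m) cos(πn(m+0.5)/M)`.

- `M = 40` mel filters and `L = 40` coefficients. Only the product
  dimension (40) is fixed by the 298 × 40 contract; choosing `M = L = 40`
  is the unique pair that keeps the DCT non-degenerate (`L ≤ M`) while
  meeting the contract. The `n = 0` (energy) term is excluded, which
  makes coefficients invariant to waveform gain; note that the order
  `n = M` DCT column is identically zero by the basis identity
  `cos(π(m+½)) = 0`, so the 40th coefficient carries no information —
  harmless for classification and kept for the shape contract.
- Mel scale `mel(f) = 2595·log10(1 + f/700)`, band 0–8000 Hz (the full
  Nyquist range), unit-peak triangular filters.
- `log_floor = 1e-10` keeps the natural log finite on silent input; a
  silent clip therefore produces exactly zero coefficients (DCT of a
  constant).
- One printed form of the MFCC DCT in the source material has a per-term
  denominator that is ill-defined at `m = 0`; the standard DCT-II phase
  used here matches the well-formed companion formula (the LPMFCC DCT)
  and is the conventional reading.

**LPCC.** Per frame, an all-pole model of order `p = 12` (standard for
16 kHz audio; the order is otherwise a free choice) is fitted by the
autocorrelation method via Levinson–Durbin, which guarantees a
minimum-phase synthesis filter; prediction coefficients are converted to
cepstra by the recursion `c(1) = a(1)`;
`c(n) = a(n) + Σ_{k<n} (1 − k/n) a_k c(n−k)` for `1 < n ≤ p`;
`c(n) = Σ_{k≤p} (1 − k/n) a_k c(n−k)` for `n > p`. The printed branch
ranges in the source leave `n = p` unassigned; the first branch is
applied through `n = p`, the standard reading. Length 40 comes from the
`n > p` branch. All-zero frames admit no model and yield all-zero rows
by rule.

**LPMFCC.** The hybrid: per frame the LPC coefficient vector
`a_1..a_p`, zero-padded to 512 points, is Fourier-transformed; the
squared magnitude is pooled through the same mel filterbank, logged with
the same floor, and DCT-II-transformed. The source material is ambiguous
about whether the "LPC spectrum" means the transform of the coefficient
vector or the model's frequency response `1/A(e^{jω})`; the
coefficient-vector reading is implemented, literal to the description
and consistent with the degenerate case (zero coefficients → flat zero
spectrum → floored constant → zero cepstra). The leading 1 of the
prediction polynomial is *not* prepended: including it would make the
degenerate case non-zero and contradicts "the LPC coefficients are
transformed".

## Endpoint detection

The reference segmentation method for cutting 3 s snore cases from
whole-night audio is not published in retrievable form, so the classic
dual-threshold energy/ZCR endpoint detector is supplied and fully
parameterized (`segmentation_params()`):

- noise floor = 10th percentile of frame energies (percentile rather
  than leading frames, since a recording may start mid-snore);
- seed threshold `energy_high = 8×` floor; extension threshold
  `energy_low = 2×` floor;
- `zcr_threshold = 300` crossings per 480-sample frame. A broadband
  noise floor crosses zero about every other sample (~240 per frame)
  *independent of its level*, so any threshold below that makes the ZCR
  extension fire on every background frame and merge the whole recording
  into one event. 300 sits above the broadband expectation and lets the
  branch catch only strongly fricative content;
- events closer than `merge_gap_s = 0.2` s merge; events shorter than
  `min_event_s = 0.3` s are dropped.

Clips are cut as 3 s windows centered on the event's **peak-energy
frame** (symmetric context helps spectral features; onset alignment is
available by adjusting the parameters), shifted inward at recording
edges so clips always contain real context, never zero padding, and are
exactly 48 000 samples. For whole-night inputs the per-frame statistics
are computed by cumulative sums rather than a materialized frame matrix,
keeping memory linear in the recording.

## Classifiers

Three binary classifiers consume the 298 × 40 matrices. No deep-learning
framework is used: forward and backward passes are written on base
matrix operations (BLAS), verified against numeric gradients in the test
suite.

**CNNs.** `cnn3` stacks three convolution blocks — 20×8/64 filters
stride 2, 10×4/64 stride 2, 5×2/64 stride 1, each followed by a ReLU and
a 2×2 max-pool — then a single fully connected map to 2 outputs; `cnn5`
appends two 2×2/64 stride-1 blocks. Convolutions use "same" spatial
padding (without it the stride/pool chain would collapse the 298 × 40
input) and pooling is ceil-mode so odd extents survive the deeper stack.
Convolution is implemented as im2col + matrix multiply.

**LSTM.** A single recurrent layer runs one step per frame (298 steps of
40-dim input), with the standard gated cell: forget, input and output
gates on the concatenation `[h_{t−1}, x_t]`, `C_t = f⊙C_{t−1} + i⊙C̃`,
`h_t = O⊙tanh C_t`. The classifier reads the hidden state **averaged
over the 298 steps** by default (`model_config(lstm_pool = "mean")`).
The obvious alternative — reading only the final hidden state, as a
single-output sequence diagram suggests — was implemented first and is
still available (`lstm_pool = "final"`), but it fails under the study
conditions: a clip holds one 1–1.5 s snore episode inside background
context, so a final-state readout must preserve the episode's evidence
across ~100 trailing background frames; in training it memorizes instead
(perfect training accuracy, chance validation accuracy), while a plain
logistic fit on time-averaged features separates the classes — the
information is present, the readout was the bottleneck. Mean pooling
makes every frame's hidden state contribute gradient directly and
resolves this.

Training (`train_config()`): softmax cross-entropy, Adam
(`learning_rate = 1e-3`), `batch_size = 64`, `epochs = 12`,
`validation_fraction = 0.1`, `lstm_hidden = 64`. The width and schedule
were sized to the problem — a 2-class decision over 40-dim frames needs
nowhere near the capacity common in speech models, training loss
plateaus well within 12 epochs, and batches of 64 keep the BLAS calls
efficient on a single CPU; all are configuration, not constants. Weight
initialization is Glorot-uniform with the forget-gate bias at 1
(remember-by-default). Input features are standardized per coefficient
with training-split statistics stored in the model and re-applied at
inference. A fixed `seed` fixes initialization and shuffling, making
training bit-reproducible on one platform.

## Scoring

`compute_metrics()` implements accuracy, precision,
sensitivity (= recall), specificity and F1 from TP/FN/TN/FP. One printed
formula in the source material gives specificity the denominator
`TP + FP`, contradicting both the universal definition and the
surrounding prose; the standard `TN/(TN + FP)` is implemented. Metrics
with zero denominators are reported as `NA`, never 0, so averages are
not silently inflated.

`compute_ahi()` encodes AHI = (AB/2)/SH: the divisor 2 reflects the
assumption of exactly two apnea-related snores per event (one faint
in-event snore, one post-event gasp) and is exposed as
`snores_per_event`. SH is taken as the recording duration — detected
sleep time is not estimated, which will bias AHI downward when a
recording includes substantial wake time. Severity bands: ≤ 5 normal
(degree 0, present in the reference table though absent from its prose
list; the boundary AHI = 5 is graded 0, consistent with that table),
5–15 slight, 15–30 moderate, > 30 serious.

`ahi_discrepancy()` reports `|Δ|/4` — the only rule consistent with
every printed discrepancy cell of the reference subject table, verified
row by row — alongside the plain absolute difference. The published
description of that score ("squared difference") does not match its own
printed values; the reverse-engineered form is flagged as such and the
absolute difference is the interpretable quantity.

## The synthetic generator

No public snore corpus exists for this protocol, so
`gen_snore_clip()`/`gen_clip_dataset()`/`gen_session()` emulate it. A
snore is a harmonic pulse train: fundamental `f0` with slow drift,
harmonics rolled off at `spectral_tilt` dB/octave, amplitude-modulated
at the breathing rhythm, plus Gaussian background noise. Class
parameters (all configurable, chosen once as plausible for the
phenomenology, not fitted to any data):

| kind | f0 (Hz) | amplitude | character |
|---|---|---|---|
| normal | 90–140 | 0.40–0.70 | steady harmonic snore |
| abnormal_faint | 60–100 | 0.05–0.15 | weak in-apnea snore |
| abnormal_gasp | 100–180 | 0.80–1.00 | tremulous harmonics + broadband turbulence burst |

Each 3 s clip holds **one snore episode of 0.8–1.5 s near the clip
center plus background context**, mirroring what endpoint detection
produces when cutting cases from a recording. (An earlier design filled
the whole 3 s with snoring; classifiers trained on such clips collapsed
when screening sessions, whose extracted clips have the episode-plus-
context structure — the generator, not the pipeline, was wrong.)

`gen_session()` builds whole recordings: background noise at
`noise_level` (RMS 0.005), apnea events with exponential inter-arrivals
at `events_per_hour` under a 30 s minimum gap (needed for
non-overlapping ~10 s events), each event containing one faint snore at
its center and one gasp 0.2–0.6 s after its end — exactly two abnormal
snores per event, matching the AHI divisor — and normal snores at
`normal_snore_rate` (6/min, an episodic rather than every-breath
snorer) outside events. Faint snores are planted above the detection
threshold; whether real in-apnea snores always are is unknowable from
the protocol description, and a detector miss would lower AHI
proportionally. Everything is a pure function of the seed; annotations
are exact, enabling the oracle-classifier test that isolates the AHI
bookkeeping from model error (`oracle_classifier()` screening returns
the true AHI exactly).

**What passing tests show — and do not.** The generator makes the
classes separable with overlap confined mainly to faint snores near the
noise floor; the benchmark accuracy achieved on it (recomputed by
`scripts/acceptance.R`) demonstrates that the pipeline's features,
training and bookkeeping work end to end, *not* that comparable accuracy
would be reached on clinical recordings, whose variability (position,
microphone, room, pathology) the generator does not model.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use: 1000 clips per class
for the headline benchmark (80/20 split), 1 h sessions at 20 events/hour
for end-to-end AHI recovery, and smaller sessions (0.1–0.5 h) for
segmentation properties — sizes at which every behavior of interest is
already exercised and the full suite runs in minutes on one CPU.
Tolerances: oracle comparisons (LSTM cell, cepstral recursion, metric
formulas) at 1e-12; reference-implementation MFCC agreement at 1e-4; AR
parameter recovery ±0.02; detection recall ≥ 0.95 with precision 1.0 at
~20 dB event-to-noise. Degenerate inputs are handled by rule: silent
frames yield zero feature rows, all-zero count tables and non-positive
sleep durations are errors, and undefined metrics are `NA`.

## Known limitations

- The acoustic model is phenomenological; no claim of physiological
  realism.
- SH is recording time, not scored sleep time.
- No discrimination of obstructive vs central vs mixed events (PSG-only
  information), no hypopnea-specific handling, and the fixed
  two-snores-per-event rule makes AHI linear in the abnormal count.
- Snore-vs-speech/cough discrimination is left entirely to the
  classifier; detection is content-agnostic.
- No delta features, cepstral mean normalization, streaming capture or
  compressed-audio input.
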