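---
title: "Linking EEG to subjects and tasks: models, data and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking EEG to subjects and tasks: models, data and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eeglink)
```

## The problem

A multichannel EEG recording is a K x L matrix: K scalp electrodes sampled
at F Hz for L samples. Two questions are asked of such a recording:

* **Who produced it?** Subject identification treats EEG as a biometric.
  Brains differ anatomically and functionally, so spectral structure —
  the individual alpha peak frequency, its spatial topography over the
  scalp, the broadband "colour" of the background activity — is stable
  within a person and variable between people.
* **What were they doing?** Task classification asks which activity
  (eyes-open/closed rest, real or imagined fist and foot movement) the
  segment was recorded under. Motor execution and motor imagery modulate
  band power over motor cortex, so classes differ mainly in how strongly
  the rhythms are expressed.

`eeglink` answers both questions from raw signal with two small deep
models, and provides the classical feature branch (AR coefficients, Welch
band powers) that seven stock classifiers consume for comparison.

## Segmentation

The two models slice a recording differently (`segmentation_spec()`):

* **Horizontal** (`horizontal_split()`): consecutive, non-overlapping
  k x l blocks along time, r = floor(L / l) of them; the trailing
  remainder is dropped rather than padded, because padding would fabricate
  signal. Identity is present in every second of data, so many short
  segments multiply the training set. The default segment length is
  l = 150 samples. When fewer than K channels are wanted
  (`select_channels()`), indices are taken evenly spaced over 1..K with
  round-half-up, first and last channels always kept; the subsetting rule
  is this package's convention — any fixed montage-aware rule would do.
* **Vertical** (`vertical_split()`): one full-length single-channel
  sequence per electrode. Task structure lives in slow band-power
  modulations, so cutting time would destroy exactly what the classifier
  needs; cutting across channels instead yields K labelled sequences per
  recording, and recording-level predictions majority-vote over channels.

Splits for evaluation are always **task-wise within subject**
(`split_by_tasks()`): whole recordings are held out, never individual
segments, so no temporal context of a training recording leaks into the
test set. Ratio strings like `"13:1"` name the train:test task counts;
folds rotate consecutive blocks of held-out tasks, and when the test-block
size does not divide the task count the final fold simply holds out the
remainder, so the folds always partition the task set.

## The subject model: a stacked peephole LSTM

Five identical LSTM layers process a segment column by column (one
k-vector of channel values per time step). The cell is the peephole
variant: the input and forget gates observe the previous cell state, and
the output gate observes the freshly updated cell state,

$$I_t = \sigma(W_I x_t + U_I h_{t-1} + v_I \odot c_{t-1} + b_I)$$
$$F_t = \sigma(W_F x_t + U_F h_{t-1} + v_F \odot c_{t-1} + b_F)$$
$$c_t = F_t \odot c_{t-1} + I_t \odot \tanh(W_C x_t + U_C h_{t-1} + b_C)$$
$$O_t = \sigma(W_O x_t + U_O h_{t-1} + v_O \odot c_t + b_O)$$
$$h_t = O_t \odot \tanh(c_t)$$

Design notes, in decreasing order of consequence:

* **The output-gate peephole acts on the current cell $c_t$**, while the
  other two act on $c_{t-1}$. Many LSTM variants use $c_{t-1}$ throughout;
  the asymmetric form is implemented deliberately and verified against an
  independent scalar-loop oracle in the tests.
* **Peephole weights are elementwise** (diagonal), the standard peephole
  form.
* **The "forgetting rate" of 1.0** is realized as the forget-gate bias
  initialization: with $b_F = 1$ the forget gate starts near
  $\sigma(1) \approx 0.73$, so early in training the memory cell retains
  information long enough for gradients to reach early time steps.
* The final hidden state of the top layer feeds a linear softmax head with
  one score per subject; softmax is computed with max-subtraction.
* Hidden size (default 64) and depth (5) are configurable; weights are
  initialized uniformly at $\pm 1/\sqrt{\text{fan-in}}$ from the config
  seed.
* Input is raw signal by default. `standardize = TRUE` applies
  per-channel, per-segment zero-mean/unit-variance scaling; the flag is
  stored on the model and applied identically at prediction time.

Training minimizes cross-entropy with Adam at the fixed settings
$\alpha = 0.001$, $\beta_1 = 0.9$, $\beta_2 = 0.999$,
$\epsilon = 10^{-8}$. Gradients are clipped to a global norm of 5 — a
conventional guard for recurrent nets; at these scales the clip rarely
engages but makes early training insensitive to an unlucky init. The
rollout and full backpropagation through time run in compiled code
(RcppArmadillo); correctness is pinned by finite-difference gradient
checks and by the scalar-loop cell oracle.

## The task model: a five-block 1-D CNN

A vertical segment (1 x L) passes through five convolution blocks with
filter counts 16/16, 32, 64, 128, 128 — block 1 contains two convolutions
and one pool, blocks 2–5 one convolution and one pool each. Every
convolution has kernel 3, stride 1 and same-padding; every max-pool has
window 2 and stride 2 on the time axis, halving the temporal length. Only
this conv–conv–pool reading of block 1 reproduces the reference
feature-map sizes for a 9600-sample input (4800x16, 2400x32, 1200x64,
600x128, 300x128), which `cnn_output_shapes()` reproduces cell by cell
and the acceptance script reports.

Batch normalization sits **before each convolution's input** — taken
literally, including ahead of block 1, where it doubles as input
scaling. ReLU follows each convolution; dropout (default rate 0.5) is
active in blocks 4 and 5 only during training. The block-5 map is
flattened directly into a linear softmax head; no intermediate dense
layer is inserted. The head's size is computed from the shape ledger at
build time, so any input length of at least 32 samples works.

Two numerical choices matter in practice:

* **Batch-norm statistics.** During training each batch uses its own
  statistics while exponential running averages (momentum 0.1) are kept
  for evaluation. Because training can stop after very few epochs, the
  running averages are **recalibrated over the full training set** (one
  extra pass, dropout off) when training ends; without this, a model that
  converges in three epochs would evaluate through nearly-initial BN
  statistics and its held-out predictions would collapse.
* **Max-pool ties** keep the earlier sample; odd temporal lengths drop
  the final sample (floor halving).

## The classical branch

Baselines consume explicit features after two denoising steps applied per
channel: zero-mean/unit-variance normalization with the *population*
standard deviation, and a 0.5–45 Hz band-pass (4th-order Butterworth run
forward–backward for zero phase — the standard EEG choice, keeping phase
features intact). The band-pass realization is a design decision: only
the pass band is specified upstream.

Features per channel are (i) the first p = 6 Yule–Walker AR coefficients
(`stats::ar.yw` on the demeaned series; the intercept is recovered from
the mean; the moving-average part of a full ARMA treatment is omitted in
favour of the pure AR difference equation) and (ii) Welch power spectral
density (Hann window, 256-sample segments, 50% overlap, density scaling
so the integral approximates the variance) integrated over the five
classical bands: delta 0.5–4, theta 4–7.5, alpha 8–13, beta 14–30, gamma
30–45 Hz. AR order and Welch parameters are package defaults; nothing
upstream fixes them. Which block the baselines consume is switchable
(`use_ar`, `use_psd`); the default is the concatenation, d = K (6 + 5).

The seven baselines (`run_baseline()`) are linear-kernel SVM, LDA,
1-nearest-neighbour, a decision tree, naive Bayes, AdaBoost and an MLP —
all standard library implementations with default hyperparameters except
the SVM's kernel; AdaBoost is a compact SAMME over depth-1 stumps because
no boosting-specific package is available to the harness. Features are
standardized on the training fold; zero-variance columns are dropped.

## Evaluation

`macro_metrics()` computes per-class precision TP/(TP+FP) and recall
TP/(TP+FN) with the 0-when-undefined convention, macro-averages them
unweighted over classes, and reports F1 as the harmonic mean of the
*macro* precision and recall. Metrics recomputed from the stored
confusion matrix are tested to agree with metrics computed from the label
vectors.

## Synthetic EEG

`generate_dataset()` exists so that the full pipeline — segmentation,
features, both deep models, baselines, metrics — runs and is tested
without any external download. Each subject's profile holds the two
stable signatures the subject model must find:

* a personal **alpha peak frequency**, stratified across 8–13 Hz so ten
  subjects keep at least ~0.4 Hz separation, expressed not as a pure
  sinusoid but as an **AR(2) resonance** (pole radius 0.97) whose phase
  drifts the way a real alpha rhythm's does — a deterministic sinusoid
  would hand any classifier a constant cross-channel phase pattern that
  identifies the *recording* rather than the subject, a leakage real EEG
  does not offer;
* a personal **alpha topography**: per-channel amplitude weights
  U(0.4, 1.6), the spatial pattern that is stable within a person across
  sessions;
* a personal **AR(6) background** per channel (subject-level reflection
  coefficients, small per-channel perturbations, stationarity guaranteed
  by construction through the reflection-coefficient parameterization),
  plus white sensor noise (sd 0.5).

Tasks modulate the alpha amplitude multiplicatively: class q scales it by
`gain_ratio^(q-1)` on the affected channels (default: all). The default
`gain_ratio = 1.5` reflects the modest band-power modulation of motor
tasks relative to between-subject differences — the premise that makes
EEG a biometric at all; the task-classification test data instead uses a
gain ratio of 3 as its stated condition. Recordings default to 30 s at
160 Hz (L = 4800), half the one-minute sessions of the 64-channel
motor-imagery protocol; seeds fan out hierarchically (dataset → subject →
task) so regenerating with more subjects never perturbs existing ones,
and 10 p burn-in samples are discarded to reach stationarity.

What the generator does **not** emulate: eye-blink and muscle artifacts,
mains interference, volume conduction (channels are independent up to
their shared subject profile), non-stationarity across a session, and the
hard long-tail of real between-subject similarity. Tests passing on this
data therefore demonstrate that the models and plumbing are correct and
that the training loop extracts stable spectral identity — not that the
reported headline numbers on real 109-subject data are reproduced.

## Study sizes used by the test suite

The end-to-end checks train at deliberately small scale, chosen as the
smallest sizes at which the scientific claim is visible:

* subject identification: 10 subjects x 4 tasks x 8 channels, 30 s
  recordings, l = 150 → 32 segments per recording, a 3:1 task-wise
  split, hidden size 32, batch 16, at most 30 epochs. Held-out segment
  accuracy lands around 0.65 against a 0.1 chance rate.
* task classification: 3 classes (gain ratio 3), 5 subjects x 6 tasks x
  8 channels, 640-sample vertical segments, a 4:2 task-wise split, at
  most 30 epochs (training accuracy typically saturates within 3).
  Held-out per-channel accuracy is essentially perfect against a 1/3
  chance rate.

At this scale the feature-engineered baselines (notably LDA and the MLP)
outperform the small LSTM — with three training recordings per subject
that is the expected regime; the deep models' advantage materializes with
two orders of magnitude more data, which is out of scope here.

## Known limitations

* The EDF reader covers the plain EDF/EDF+ continuous-recording layout
  used by the public motor-imagery distribution (equal sampling rate
  across data signals; annotations ignored) — not the full zoo of EDF+
  discontinuous files.
* Baseline hyperparameters are library defaults; no per-dataset tuning.
* The CNN assumes single-channel input by design; spatio-temporal 2-D
  convolutions are out of scope.
* Training runs on one CPU thread; the compiled LSTM kernel makes the
  desk-scale studies take minutes, not hours, but 109-subject scale wants
  a GPU framework.
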