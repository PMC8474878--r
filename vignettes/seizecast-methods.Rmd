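---
title: "Probabilistic seizure forecasting with variational convolutional networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic seizure forecasting with variational convolutional networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seizecast)
```

## The problem

Seizure forecasting asks whether the minutes before a seizure (the
*preictal* state) can be distinguished from seizure-free baseline
(*interictal*) in scalp EEG. seizecast implements a probabilistic
pipeline for this task: a convolutional classifier over time–frequency
segments whose weights carry full Gaussian posteriors, so every
prediction comes with a sampled output distribution and therefore an
explicit uncertainty level; an evidence-fusion stage that folds auxiliary
signals (circadian seizure timing, in this release) into the network
output; and an attention probe for exploring which parts of the input the
trained network relies on.

The clinically standard alarm bookkeeping is kept throughout: an alarm is
followed by a *seizure prediction horizon* (SPH, default 5 min) in which
no seizure should occur and a *seizure occurrence period* (SOP, default
30 min) in which it is expected. These constants surface as the preictal
labelling window `[onset − 35 min, onset − 5 min)`; interictal time must
be at least 4 h from any seizure. Seizures less than 30 min (strictly)
after the previous one are merged into a single *leading* seizure,
keeping the first onset.

## Preprocessing

Recordings are split into 30-s windows with 50% overlap. Each window is
framed per channel into 1-s frames with 50% overlap (59 frames at
256 Hz), each frame is demeaned and tapered with a Hann (raised-cosine)
window, and one-sided magnitude spectra are taken (129 bins). The first
frame and the last two are trimmed against edge effects and the DC bin is
dropped, giving an `n × 56 × 128` array per window.

Two numerical choices deserve a note:

* **DC removal.** A tapered transform leaks a constant input into the
  first few bins, so dropping bin 0 alone does not remove the DC
  component (a Hann-tapered constant puts half of its DC magnitude into
  bin 1). We therefore demean each frame *and* drop bin 0; constant
  offsets then map to exactly zero and the output is exactly
  offset-invariant, which is what DC removal is meant to achieve.
* **Time-axis trim.** Trimming "the first and the last two" frames reads
  as four, but the documented output has 56 of 59 frames, which forces a
  3-frame trim. We drop frame 1 and the last two; which three frames are
  dropped is not identifiable from the stated shapes, and no downstream
  result depends on the choice.

Whether magnitudes should be log-compressed and how they should be
normalised before the network is not fixed by the source material. The
training front end applies `log1p` and a single global
standardisation (one centre, one scale for the whole tensor), which
preserves the relative prominence of high-power low-frequency bins; a
per-bin standardisation was tried and discards exactly the cue the
synthetic signature lives in, measurably hurting recovery.

## The variational network

The classifier is the usual spectrogram CNN — a channel-spanning
`(n × 5 × 5)` convolution with stride `(1 × 2 × 2)`, then two `3 × 3`
conv–pool blocks, then dense layers of 256 and 2 units — except that
every weight and bias carries an independent Gaussian posterior
`N(μ, σ²)` with `σ = softplus(ρ)`. Training minimises the negative
evidence lower bound: the expected classification cross-entropy plus the
KL divergence of the posterior from a standard-normal prior, scaled by
`1/number of mini-batches per epoch` so each epoch accounts the full KL
once. Gradients use the reparameterisation `w = μ + σ·ε` with one weight
realisation per mini-batch.

Prediction feeds the same input forward `S` times (500 in the reference
protocol) through independent weight realisations; the post-softmax
preictal probabilities form the predictive sample. The uncertainty level
of a prediction is

$$u = \frac{\mathrm{sd}(\text{samples})}{\lvert\,\overline{\text{samples}} - 0.5\,\rvert},$$

with sample (n−1) standard deviation, `+Inf` when the mean is exactly
0.5, and a display cap at 10. Predictions with `u` below a threshold are
*confident*; confident predictions disagreeing with the truth are the
clinically dangerous failure mode the taxonomy is designed to expose.

Choices the source material leaves open, and what this package does:

* **Prior**: standard normal per weight — the canonical mean-field
  choice.
* **Initialisation**: He-scaled means; `σ` initialised at 0.02
  everywhere. Larger starting noise (0.05) was tried and measurably slows
  desk-scale training: with one realisation per mini-batch the gradient
  signal-to-noise falls with σ, and at the small step budgets used here
  that difference decides whether training leaves the chance plateau.
* **Optimiser**: Adam, learning rate 3 × 10⁻³, batch 32. 1 × 10⁻³ was
  tried first and under-trains badly within 10 epochs at this scale.
* **Activations**: leaky rectifiers (negative slope 0.1) after every
  convolution and the first dense layer. Narrow networks with plain
  rectifiers frequently start dead; the leak keeps gradients alive
  without affecting the positive-part attention semantics.
* **Multi-start**: narrow CNNs on a spectrally localised signature are
  init lotteries — some initialisations sit on the chance plateau for
  most of a short training budget. `train_bcnn(restarts = k)` trains `k`
  independently initialised runs and keeps the one with the lowest
  *posterior-mean* training cross-entropy (the per-batch sampled loss is
  too noisy to rank runs). This is ordinary multi-start optimisation,
  deterministic given the seed.
* **Class balance**: the minority class is oversampled per epoch.
* **Sample sd** (not population) in the uncertainty level; samples are
  post-softmax probabilities.

With `kl_weight = 0` and `σ → 0` the model reduces exactly to a
deterministic CNN, which is the correspondence used in the baseline
comparison tests.

## Auxiliary-evidence fusion

If auxiliary signals `d₁, d₂, …` are assumed independent of the EEG and
of each other, the posterior seizure probability factorises into the
network output times per-signal likelihood ratios `p(dᵢ | seizure) /
p(dᵢ)`. The conditional densities are Gaussian-kernel KDEs over the
observed values at seizure onsets (Scott bandwidth `n^{-1/5}·sd`, equal
weights); for time-of-day the domain is circular and the KDE wraps by
evaluating data replicas at ±24 h, while the baseline is uniform, 1/24
per hour.

The fusion factor multiplies the *preictal* pre-softmax output only:
scaling both outputs would cancel in the softmax and make the modulator a
no-op, so the asymmetric reading is forced. Multiplying a logit (which
may be negative) by a ratio is the literal published rule and is the
default; the mathematically natural alternative — adding `log` ratios to
the logit — is available behind `log_domain = TRUE`. The conditional
density is floored at 10⁻⁶ so an empty region of the KDE cannot veto the
EEG evidence outright. The same modulation code path runs at training and
inference time.

## Evaluation

Performance is segment-level AUC (rank-based, ties at half credit)
between preictal and interictal mean scores. Continuous-recording review
uses uncertainty-gated risk timelines: predictions with uncertainty above
1 are discarded (marked missing, never zero-filled) and a backward moving
average over the last 50 retained predictions smooths the rest; during
warm-up the average uses however many retained points exist. Leakage-free
cross-validation folds are built per inter-ictal period: the fold testing
a period draws its training preictal and interictal segments from the
other periods only. Fold AUCs are averaged (pooling scores across folds
is the other defensible convention; averaged-per-fold is implemented).

## The synthetic world

Restricted clinical EEG cannot ship with a package, so every stage is
exercised on synthetic recordings that emulate exactly the properties the
pipeline consumes:

* 256 Hz multichannel signal; background is 1/f-shaped ("pink") noise
  plus a white floor, so all STFT bins are non-degenerate;
* a 1–4 Hz band-limited component whose gain is raised inside
  `[onset − preictal_len, onset)` so that total 1–4 Hz band power equals
  `preictal_effect` times its interictal value — the gain is solved from
  the measured band powers, so the contract holds exactly for any
  effect ≥ 1. The slow-wave placement mirrors the biomarker the attention
  probe is meant to rediscover;
* seizure onsets whose hour-of-day follows a configurable wrapped-Gaussian
  mixture, giving the time-of-day prior something real to estimate;
* per-patient metadata tables (seizure counts, leading-seizure counts,
  interictal hours) computed with the same merging and labelling rules as
  the pipeline.

What the generator does *not* model: physiological EEG morphology,
artifacts (EMG, blinks, electrode pops), spatial correlation across
channels, non-stationary background, or any claim that real preictal
EEG carries a 4× slow-wave power gain. A green end-to-end test therefore
establishes that the pipeline can recover a planted, detectable
spectral signature under its stated protocol — not clinical performance.
The effect size is a free parameter of the synthetic world, and the
desk-scale recovery experiments fix it at 4 (clearly detectable), 1
(null control: AUC should be ~0.5), and ~1.2 (weak EEG evidence, used to
show that informative circadian fusion does not hurt and typically
helps).

## Known limitations

* Training is plain R; the reference-width network (16/64/128/256) on
  19 channels trains only at demonstration scale. Desk-scale tests use
  narrow widths (8/16/16, dense 32) on 2 channels.
* The alarm-level sensitivity / false-prediction-rate semantics of
  SPH/SOP are carried entirely in the labelling; no explicit alarm
  generator is provided because AUC is the reported metric.
* Fusion currently ships one auxiliary signal type (circular
  time-of-day); the interface is generic but other signals
  (heart-rate variability, oximetry) are out of scope.
* EDF input is not supported (no EDF reader in the supported dependency
  set); recordings interchange via a documented plain-text array archive.
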