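---
title: "Two-stage visual speech recognition: models, data and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage visual speech recognition: models, data and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Patients under invasive mechanical ventilation retain habitual lip movement
but cannot phonate. `vsr2stage` implements a lip-reading system for this
setting: silent video of the mouth region in, text out. Rather than mapping
video directly to characters, the system is trained in two stages with the
utterance's *audio features* as an intermediate target:

1. **Audio Feature Estimator (AFE).** A spatio-temporal convolutional
   network (3D kernels over time x height x width) followed by GRU layers
   maps the preprocessed frame tensor $F_i$ (75 frames of 50 x 100
   grayscale pixels in $[-1,1]$) to one row of audio features per frame.
   Training minimizes the batch-mean absolute error
   $\mathcal{L}_{AFE} = \frac{1}{N}\sum_i |AF_{GT,i} - AF_{pred,i}(F_i)|$
   against features computed from the ground-truth audio, which is
   available at training time and unused at runtime.
2. **Speech-To-Text (STT).** Two 1D convolutions and GRU layers map the
   75 x $d_{AF}$ feature sequence to a per-frame distribution $p_t^c$ over
   29 symbols (a-z, space, `<pad>`, CTC blank), trained with the CTC
   negative log likelihood $-\log p(y_{GT} | AF_{GT})$ so no frame-level
   alignment is needed. Optionally the STT is then **fine-tuned** on the
   frozen AFE's *predictions* ($-\log p(y_{GT} | AF_{pred}(F))$), letting
   it adapt to the estimator's systematic errors, which are also present
   at runtime.

Decoded sentences pass a unigram spell corrector: per word, corpus words
within Levenshtein distance 2 (insert/delete/substitute), choosing minimal
distance, ties by corpus frequency.

## Frame preprocessing

Frames are converted to luminance (ITU-R BT.601 weights 0.299/0.587/0.114), cropped around the mouth
using four landmarks (mouth corners, upper/lower lip midpoints) so the
margin on each side equals half the mouth width/height, resized bilinearly
to 100 x 50, mapped to $[-1,1]$ by $x/127.5-1$, and padded with black
($-1$) frames to length 75 (3 s at 25 fps). Landmark detection itself is a
pluggable provider — any face/landmark detector can be wrapped; videos on
which the provider fails are *rejected*, not errors, mirroring the policy
of discarding undetectable videos. Crop boxes are half-open
$[x_0,x_1)\times[y_0,y_1)$ in 0-based pixel coordinates; boxes that leave
the image are black-filled rather than shrunk so the mouth stays centered.

An important geometric consequence, which shaped the synthetic data design
below: because the crop box scales with the mouth extent and is resized to
a fixed shape, absolute mouth size is normalized away; only *relative* lip
geometry survives preprocessing.

## Frame-synchronized audio features

Window, hop and FFT length all equal `rate/fps` = 640 samples (40 ms), so
feature row $t$ covers exactly video frame $t$: non-overlapping,
left-aligned Hann windows with zero padding of the final partial window.
The power spectrum is mapped through a Slaney-style triangular Mel
filterbank (area-normalized; `fmin` 0, `fmax` 8000 Hz), then
$\log(\max(x, 10^{-10}))$. MFCCs apply an orthonormal DCT-II along the Mel
axis, drop coefficient 0 (average power) and keep coefficients
1..`n_mfcc`. The study grid uses 40/80/120 Mel bands or 6/12/24 MFCCs.
Band energies are summed before the log (the standard MFCC chain).
Each coefficient is z-scored with the mean and population standard
deviation pooled over the *training split* (a leakage-avoiding departure
from whole-dataset fitting; `whole_dataset_normalizer = TRUE` restores whole-dataset fitting). Audio of padded videos is zero-padded to
75 x 640 samples so features stay aligned with the black frames.

## CTC and decoding

The CTC loss is a log-space forward dynamic program over the
blank-augmented label; an exponential brute-force enumerator
(`ctc_bruteforce`, $T \le 8$) serves as its oracle in the tests, and on
tiny instances the posterior over all admissible labels sums to 1 exactly.
`<pad>` is an ordinary symbol at loss time and stripped at decode time. Greedy
(best-path) decoding is the default; a deterministic prefix beam search
(ties broken lexicographically) is provided, and with a wide beam it
matches exhaustive max-posterior collapse on small instances. Note that
`beam_width = 1` follows the beam recursion and need not equal greedy.

## Augmentation

Per video, a horizontal flip is drawn with $p_{flip}=0.5$ and each further
step with $p_{aug}=0.8$: one composed affine transform (rotation about the
image center, translation, shear, scale; bilinear, black border), then
zero-mean Gaussian noise, then a constant luminance offset, clipped to
$[-1,1]$. Parameters are drawn once per video and applied identically to
every frame. The numeric range defaults (rotation ±5°, translation ±5 px, shear ±0.1, scale 0.9–1.1,
noise σ ≤ 0.05, brightness ±0.2) are conventional for mouth-crop video
augmentation and are all config-exposed. Padding frames beyond a video's
valid length stay black. Augmentation is applied to AFE inputs during AFE
training and STT fine-tuning, never at evaluation.

## Synthetic corpus

Real recordings cannot be bundled, so the generator emulates their
*structure*: 25 fps clips of at most 75 frames; 16 kHz mono audio of
exactly `n_frames` x 640 samples; lowercase transcripts over a-z + space;
exact per-frame landmarks. Each symbol maps to an articulation entry: a
mouth aperture and spread on a 6 x 5 level grid, and two tones on exact
multiples of 25 Hz (one STFT bin each), making audio feature targets
nearly noiseless so end-to-end failures indicate model or plumbing bugs,
not data difficulty. Because crop normalization removes absolute mouth
size (above), character identity is rendered into *relative* lip geometry:
an outer lip ellipse carries the landmarks while the inner dark mouth
ellipse's axes, relative to the outer ones, encode aperture and spread.
Each character holds 4 frames (3 in GRID-style mode, whose six-slot
grammar sentences are longer) with a one-frame 50/50 blend between
characters, mirrored in the audio amplitudes. ICU mode samples ~20 short
phrases of essential patient communication; GRID mode samples a
command–color–preposition–letter–digit–adverb grammar with reduced slot
inventories so clips fit the 75-frame budget. The generator does **not**
emulate speaker identity, coarticulation, head pose, lighting or sensor
noise — passing tests demonstrate the pipeline's correctness and
trainability, not clinical performance.

## Training configuration

Adam with $\beta_1=0.9$, $\beta_2=0.999$, $\epsilon=10^{-7}$; the
`training_config()` default learning rates are 1e-4 (AFE) and 5e-4 (STT).
Weights are Glorot-uniform with a recorded seed; batch size defaults to 8;
with a validation split, early stopping (patience 20) restores the best
weights. Fine-tuning keeps the AFE frozen and is validated on the AFE's
un-augmented predictions for held-out videos — the input distribution the
fine-tuned STT actually faces. Losses run over all 75 timesteps including
padding, matching the fixed-length formulation. Splits are a seeded
shuffle with floor(0.1 n) videos each for validation and test; the same
master seed flows through all phases, and the test split is untouched
until final evaluation.

Exact layer hyperparameters are configuration, not contract: the
full-scale defaults (`afe_config()`: 32/64/96-filter conv3d blocks with
spatial pooling, two 256-unit GRUs; `stt_config()`: 128/256-filter 1D
convolutions, two 256-unit GRUs) describe a plausible clinical-scale
system. All desk-scale work uses the micro
configs: `micro_afe_config()` (a 2x2 average-pool front, one 8-filter
3x5x5 conv3d at spatial stride 5, a 32-unit GRU; ~18k parameters) and
`micro_stt_config()` (24/24-filter convolutions, one bidirectional
32-unit GRU). The micro runs pass larger learning rates (3e-3 / 1e-2)
suited to their scale.

## Numerical choices

- Neural layers are double precision with analytic backprop; every layer
  type is gradient-checked against central differences (tolerance 1e-4
  relative) in the test suite.
- The 3D convolution is evaluated as a spatial patch unfold shared across
  temporal taps plus one BLAS GEMM per tap; "same" padding throughout,
  temporal stride fixed to 1 so the 75-step axis is preserved.
- CTC is computed in log space with $-\infty$ handling; oracle
  comparisons use 1e-9 relative tolerance.
- Bilinear resampling uses inverse mapping on pixel centers; a pure
  horizontal flip lands on exact centers and is therefore bit-exact.
- The spell corrector never rewrites in-corpus words and prefers smaller
  edit distance before higher corpus frequency (`selection =
  "max-likelihood"` instead always takes the most frequent candidate,
  which can rewrite rare in-corpus words).
- Error rates are micro-averaged (pooled edits over pooled reference
  lengths) by default; macro averaging is available. Text is normalized
  (lowercase, umlaut transliteration, whitespace collapse) before
  scoring.

## Desk-scale study sizes

The bundled end-to-end study trains the micro models on 300 ICU-mode
synthetic videos (80/10/10 split; AFE 38 epochs at batch 4, STT 25
epochs, fine-tuning 35 epochs) — large enough for the qualitative
findings (fine-tuning helps; the spell corrector helps) to be visible on
held-out data, small enough for a single-CPU run in minutes. The
direction-of-effect replicates use one 120-video corpus and one trained
AFE, then replicate the stages whose effect is claimed — STT training and
fine-tuning — across ten seeds, comparing held-out WER with/without
fine-tuning and with/without the corrector; replicating the entire
pipeline per seed at full size would add nothing to those comparisons
while multiplying the compute roughly tenfold. These sizes are the
package's own desk-scale choices; error rates on real clinical
recordings require real data and full-scale training and are out of
scope here.

## Known limitations

- The synthetic articulation model is deliberately simple; per-character
  mouth shapes with linear blends ignore coarticulation entirely.
- Unigram correction cannot fix single-letter slot words (the dominant
  error mode of slot-grammar sentences) and inherits the corpus bias of
  the training phrases.
- The micro networks are orders of magnitude smaller than a
  clinical-scale system; their error rates on the synthetic corpus say
  nothing quantitative about clinical data.
- One camera view per utterance is generated; treating multiple views as
  independent samples is left to the manifest's `view_tag` and
  configuration.
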