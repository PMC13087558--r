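---
title: "Care-aware activity recognition: model, generator and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Care-aware activity recognition: model, generator and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(cstt)
```

## The problem

Activity recognition for older adults in long-term care differs from
general-population recognition in one essential way: posture and movement are
strongly shaped by each resident's health condition. The same activity looks
different at different assistance levels, and different activities can look
alike — a resident leaning forward with hands extended may be reaching over a
meal tray or attempting to stand. Care facilities already quantify assistance
needs as a *care level* (CL), an integer from 1 (minimal assistance) to 5
(maximum assistance) assigned by medical professionals and grouped here as
low (CL 1–2), mid (CL 3) and high (CL 4–5). This package implements a
recognition model that consumes that context, together with the similarity
statistics used to demonstrate why the context matters, a synthetic
care-conditioned motion generator, and the training/evaluation harness around
them.

Four activities are modeled, with fixed class indices: sitting (0), eating
(1), stand up (2), trying to stand up (3). In the high-assistance group the
stand-up activities are structurally absent — residents in that group are
predominantly immobile — and every container in the package enforces that
invariant.

## The model

Each sample is a window of $T$ frames (default 16, stride 8), with three
inputs per frame:

* **Body keypoints** $X \in \mathbb{R}^{17 \times 2}$ in the COCO-17 joint
  order. Coordinates are normalized by the frame size and centered at the hip
  midpoint (a translation-invariance choice: seating positions vary), then
  flattened to a 34-vector and embedded by a linear layer,
  $K = x\,W_k + b_k \in \mathbb{R}^{d}$. Detector confidence scores are
  stored with the data but are not model inputs.
* **Depth heatmap** $D \in [0,1]^{64 \times 64}$. A small convolution
  (temporal kernel extent 1, i.e. acting per frame) captures local spatial
  structure; the result is cut into $8 \times 8$-pixel patches, giving
  $T_p = 64$ tokens per frame, each flattened and linearly projected to
  $\mathbb{R}^d$. Internally the convolution, patching and projection are
  fused into a single matrix product over "halo patches" (each patch plus its
  kernel margin), which is exactly equivalent and turns the convolution into
  one BLAS call.
* **Care level** $c \in \{1..5\}$, rescaled to $(c-3)/2 \in [-1,1]$ and
  embedded by a linear layer $C = s\,W_c + b_c \in \mathbb{R}^d$. Centering
  the scalar keeps the projection conditioned around the mid group.

**Care-aware attention (CAM).** The spatial block replaces self-attention
with a cross-modal attention in which the care embedding is the *sole query*
and the concatenated keypoint and heatmap tokens are keys and values:

$$\mathrm{Attention}(Q,K,V) = \mathrm{softmax}\!\left(\frac{QK^\top}{\sqrt{d_h}}\right)V,
\qquad Q = C,\; K = V = [K_{\text{kp}}, H].$$

This runs as multihead attention (4 heads on $d/4$-dimensional slices,
concatenated and projected by $W_o$), so one $d$-vector summarizes each frame
as a care-weighted mixture of its tokens. A two-layer feedforward network
with ReLU and a residual connection refines the frame feature.

**Temporal encoder.** Frame features receive the sinusoidal positional
encoding with constant $\rho = 10{,}000$ (even dimensions sine, odd cosine,
frequency $\rho^{-2i/d}$) and pass through $n$ standard pre-norm transformer
encoder layers (default 2): layer norm → multihead self-attention over the
$T$ frames → residual, then layer norm → feedforward → residual, with a final
layer norm. Mean pooling over frames yields one vector per window, and a
softmax layer $\mathrm{softmax}(z\,W_{cls} + b_{cls})$ produces the four
class probabilities. Ties at prediction resolve to the lowest class index.

**Care-blind baseline (TSTT).** For ablation, the care query is replaced by a
single learned query token shared by all windows; the care level is then not
wired into the network at all, and its gradient is exactly zero. A second
variant (`tstt+c`) keeps the learned query but appends the care embedding as
an extra key/value token — care as *content* rather than as the *query* —
matching the ablation row in which the traditional transformer also receives
care information. Further modes restrict the token set: skeleton-only
(`s+c`), heatmap-only (`d+c`), and partial-skeleton variants (`sp+...`) that
zero a fixed 30% of joints per sample (mask drawn deterministically from the
sample id).

### Default hyperparameters and why

| parameter | default | notes |
|---|---|---|
| latent dimension $d$ | 64 | compact, CPU-trainable; divisible by heads |
| heads | 4 | $d_h = 16$ per head |
| temporal layers | 2 | sufficient for 16-frame windows |
| feedforward width | 128 | $2d$ |
| window / stride | 16 / 8 frames | windowing is this artifact's choice; sequences are windowed uniformly |
| dropout | 0.1 | on feedforward hidden units, training only |
| $\rho$ | 10,000 | positional-encoding constant |
| batch / lr / weight decay / epochs | 8 / 0.001 / 0.0005 / 25 | the standard training recipe for this model |

The loss is unweighted cross-entropy — deliberately without any
class-imbalance handling, since trying-to-stand is naturally rare and
reweighting or augmenting it would distort the class distribution the model
must face — optimized with an adaptive moment estimator and *decoupled* weight
decay applied to projection matrices only, at a constant learning rate and
with no early stopping. Training is bit-reproducible on a single thread given
the seed: initialization, shuffling and dropout all draw from named streams
derived from it.

The network, its backpropagation and the optimizer are implemented directly
in vectorized R matrix code. The test suite verifies every analytic gradient
against central finite differences in all ablation modes, and the forward
pass against an independently written loop composition.

## Cross-day evaluation protocol

Recording sessions (days) are the unit of the train/test split: a greedy pass
over sessions in decreasing size order assigns each to the side with the
larger remaining deficit relative to the 80/20 target, so no session
contributes to both sides and the achieved train fraction stays within one
session of the target. Subjects do appear on both sides — the protocol tests
generalization across days, not across people. The harness asserts the
session sets are disjoint before every run. Metrics are computed per window:
macro precision/recall/F1 (classes with undefined precision or recall are
excluded from the macros, mirroring the N/A convention for structurally
absent classes), accuracy, one-vs-rest ROC/AUC with micro and macro averages,
per-class cumulative-gain curves, and row-normalized confusion matrices
overall and per care group.

## Similarity statistics

Three statistics quantify the motion structure of a dataset:

* **MPJAD** — mean per-joint angle difference: the mean absolute difference
  of joint angles over common frames and jointly defined joints. The angle at
  a joint is taken between its inbound and outbound bone vectors under the
  COCO-17 topology; this leaves angles defined at shoulders, elbows, hips and
  knees, while endpoint joints (nose, eyes, ears, wrists, ankles) are masked
  `NaN` and the average renormalizes over defined entries. Lower = more
  similar.
* **Cosine dissimilarity** — $1 - \cos$ between flattened keypoint sequences
  (truncated to the common minimum length); class homogeneity is the mean
  over within-class pairs.
* **HOG similarity** — cosine similarity of histogram-of-oriented-gradients
  descriptors. Because no installed R package provides HOG, the package
  implements the canonical configuration: $8\times 8$-pixel cells,
  $2\times 2$-cell blocks with one-cell stride, 9 unsigned orientation bins
  with linear interpolation between the two nearest bin centers,
  central-difference gradients (one-sided at borders), and L2-Hys block
  normalization (clip 0.2). A constant image has a zero descriptor, flagged,
  and its similarity is an error rather than a number.

`build_similarity_tables()` assembles the two validation views: per-activity
care-group pairs (L-H, H-M, M-L), and all 12 ordered activity pairs between
the mid and low groups. Cell values pool all cross-pairs between the two
sample pools and average; the HOG layer compares per-sample *temporal-mean*
heatmaps (which image feeds the HOG comparison was an open choice; the
temporal mean is this artifact's, as it summarizes a whole sample in one
image). Raw statistic values are reported; a min-max normalization flag
exists but is off by default, since any rescaling onto a similarity-like
scale is presentation, not measurement. Cells whose pools are empty — the
stand-up activities in the high group — are `NA`.

## The synthetic generator

Real care-facility recordings cannot be redistributed, so the package ships a
deterministic generator whose defaults encode the study conditions rather
than estimates of any private data:

* **Cohort.** The care-level distribution defaults to a realistic
  long-term-care cohort composition — low 35.3%, mid 51.0%, high 13.7% —
  split evenly within the low and high bands. Default class counts per subject (3/3/2/1) make trying-to-stand
  the rarest class, and high-group subjects receive only sitting/eating
  counts. Samples spread over 5 sessions (at least 2 per subject) so the
  cross-day split is meaningful.
* **Archetypes** are hand-designed parametric curves over normalized time in
  a virtual 640×640-pixel frame (rendered at 1/10 scale): sitting is a
  quasi-static slumped seated pose; eating is a cyclic wrist-to-nose reach
  with a hover-over-tray trunk lean; stand up is a logistic hip/knee
  extension to standing with a transient forward lean; trying to stand is a
  forward lean with partial hip rise and hands extended, settling back.
  Hand-designed curves (rather than anything learned) keep the generator
  fully deterministic and its properties provable in tests.
* **Care modulation.** Movement amplitude scales as
  $1 - 0.15\,(CL - 1)$ and the baseline trunk lean grows as
  $0.08\,(CL - 1)$ radians, with small per-subject jitter — generator
  defaults chosen to make the monotone posture-degradation property strongly
  testable, not measurements. No quantitative motion statistics (velocities,
  amplitudes) are available for any activity, so all magnitudes are declared
  synthetic defaults.
* **Confusability dial.** A parameter in $[0,1]$ blends the trying-to-stand
  pattern toward the eating reach, reproducing the eating ↔ trying-to-stand
  overlap within the low/mid groups; at high settings the HOG similarity of
  eating vs. trying exceeds eating vs. sitting, the qualitative pattern the
  similarity tables are meant to exhibit.
* **Care-interaction condition.** With `care_interaction = TRUE`, mid-group
  subjects perform swapped eating/trying motions, so the label is a function
  of care level × motion. In this mode the generator also neutralizes posture
  and subject geometry (lean, amplitude, tremor scale, seat offset, body
  scale) — otherwise the motion statistics, or a memorizable subject
  signature carried across days, would proxy for the care group and a
  care-blind model could resolve the swap without the care input. This is the
  condition under which the care-aware model demonstrably beats the
  care-blind one.
* **Rendering.** Heatmaps are sums of isotropic Gaussian blobs at joints plus
  chains of smaller Gaussians along bones, normalized to $[0,1]$ — a
  depth-like silhouette, not photorealistic depth: no camera model, no
  occlusion, no scene background.
* **Determinism.** Every (subject, sample) pair draws from a named stream
  derived from the master seed by a fixed integer fold (`derive_seed()`), so
  adding subjects or samples never perturbs existing ones.

**What passing tests on this generator do and do not show.** They show the
architecture can extract and combine the three modalities as designed: it
separates distinguishable archetypes perfectly, and it exploits the care
input when the data genuinely require it. They do not show real-world
recognition rates: synthetic motions lack detector noise and dropouts,
occlusion by caregivers and furniture, fish-eye distortion, multi-person
scenes, and the long-tailed variability of real residents. Headline numbers
on the private facility data are therefore not reproduced here, only the
qualitative orderings that motivate the design.

## Numerical choices and degenerate inputs

* Softmax is computed with max-subtraction everywhere; attention rows,
  classifier outputs and normalized confusion rows sum to 1 by construction
  and by test.
* Layer norm uses $\varepsilon = 10^{-5}$; HOG block normalization guards
  with $10^{-10}$ inside the square root.
* A zero-length bone makes the joint angle `NaN` at that joint/frame; masked
  entries are excluded with denominator renormalization.
* Zero-norm vectors make cosine dissimilarity (and HOG similarity on
  constant images) an error, not a silent 0 or 1.
* AUC uses trapezoidal integration over the tie-grouped ROC, equal to pair
  counting with half-credit for ties; degenerate classes (no positives or no
  negatives) report `NA` and are excluded from macro averages.
* Sequences shorter than the window produce zero windows; windowing counts
  are $\lfloor (T_f - T)/\text{stride} \rfloor + 1$.
* Heatmaps are stored on disk as 16-bit grayscale TIFF (values mapped
  linearly to $[0, 65535]$), a lossless single-channel container; round-trips
  are exact to $1/65535$.

## Problem sizes used by the tests and the acceptance script

The learning-sanity check trains the full model (default configuration, the
full recipe: batch 8, lr 0.001, weight decay 0.0005, 25 epochs) on a
zero-tremor 30-subject dataset of about 500–800 windows of 16 frames and
requires perfect training accuracy and at least 0.95 test accuracy across
days. The care-awareness check trains care-aware and care-blind variants on
10-subject interaction datasets for 15 epochs over five seeds and requires
the care-aware macro-F1 to win in at least four. These sizes were chosen as
the smallest at which both effects are stable and unambiguous; both
qualitative orderings match at larger scales.

## Known limitations

* The generator's kinematics are 2-D and planar; lean is an image-plane
  rotation, not a 3-D torso pitch.
* Only one resident per frame; no caregiver interaction, though caregiver
  assistance is a known source of confusion between eating and sitting in
  real data.
* The spatial block runs once per frame (the convolution's temporal extent is
  1); a clip-level spatial transformer with a temporal kernel > 1 is a
  configuration left unexplored.
* Checkpoints serialize weights as YAML text: portable and diffable, but not
  compact; fine at this model scale (~10^5 parameters).
* Care levels enter as an exact scalar; misassessed care levels would
  propagate directly, and the model has no mechanism to question them.
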