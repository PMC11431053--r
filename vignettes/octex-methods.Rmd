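---
title: "Multi-scale texture encoding for cervical OCT classification: methods and design"
author: "octex authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale texture encoding for cervical OCT classification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(octex)
```

## The problem

Optical coherence tomography (OCT) produces cross-sectional images of
cervical tissue in vivo. Each acquisition at one o'clock position of the
cervix yields a volume of ten 2-D frames. A biopsy-confirmed label places
each volume in one of five clinical categories — mild inflammation (MI),
cyst (CY), ectropion (EP), high-grade squamous intraepithelial lesion
(HSIL), and cervical cancer (CC) — of which HSIL and CC constitute the
high-risk ("positive") binary class. The diagnostic signal is largely
*textural*: healthy tissue shows stratified epithelium over a bright
basement membrane, cysts appear as dark voids, ectropion as
hyper-scattering papillary fringes, while lesions destroy the
stratification and, in carcinoma, produce alternating light/dark vertical
attenuation bands.

`octex` implements a classification pipeline built around that
observation: a convolutional backbone supplies feature maps at four
scales, a learnable texton dictionary converts each scale's map into an
orderless texture descriptor, deeply supervised auxiliary classifiers
keep every scale discriminative, and a cross-shaped threshold voting rule
lifts patch predictions to volume- and patient-level verdicts.

## Model

### Backbone and feature pyramid

A four-stage residual network maps a 224 × 224 grayscale patch to feature
maps of sizes 56 × 56, 28 × 28, 14 × 14 and 7 × 7. Two profiles share
this contract:

* **reference** — bottleneck blocks stacked (3, 4, 23, 3) with stage
  widths 256/512/1024/2048, i.e. a 101-layer residual network, the
  configuration intended for clinical-scale data;
* **test** — one basic block per stage with widths 8/16/32/32, the
  desk-scale profile used throughout the test-suite and the synthetic
  study. Its stem is a single 7 × 7 stride-4 convolution (the reference
  profile keeps the classic stride-2 convolution followed by a 3 × 3/2
  max pool); both land at quarter resolution.

The whole network is implemented in R: convolutions are `im2col` + BLAS
matrix products with the `im2col`/`col2im`/max-pool kernels in C++
(Rcpp), and batch normalization and rectification are fused C++ passes.
Every layer has an analytic backward pass; the test-suite checks the full
network gradient against central finite differences.

### Texture encoding

Let $X = \{x_i\}_{i=1}^N$ be the $D$-dimensional descriptors of one
scale's feature map (one per spatial position, after a 1 × 1
convolution–batch-norm–ReLU block that projects to $D$ channels), and let
$C = \{c_k\}_{k=1}^K$ be a dictionary of $K$ learnable textons with
learnable smoothing factors $s_k > 0$. With residuals
$r_{ik} = x_i - c_k$:

$$a_{ik} = \frac{\exp(-s_k \lVert r_{ik}\rVert^2)}
                {\sum_{j=1}^K \exp(-s_j \lVert r_{ij}\rVert^2)},
\qquad e_k = \sum_{i=1}^N a_{ik}\, r_{ik},$$

and the $K \times D$ aggregate is flattened into one feature vector.
This soft-assignment residual pooling is *orderless*: permuting the
descriptors leaves the encoding unchanged, which is what makes it a
texture representation rather than a shape representation. The softmax is
evaluated with max-subtraction; distances enter through the expanded
$\lVert x\rVert^2 + \lVert c\rVert^2 - 2\,x^\top c$ form (clamped at 0),
so no $N \times K \times D$ residual tensor is ever materialized. The
reference setting is $K = 32$, $D = 128$ (a 4096-dimensional feature per
scale); the test profile shrinks this to $K = 8$, $D = 16$.

Dictionary initialization: codewords uniform in
$(-1/\sqrt K, 1/\sqrt K)$, smoothing factors uniform in $(0, 1]$, both
trained by gradient descent.

### Deeply supervised classification

Each scale's flattened encoding is L2-normalized and passed through a
fully connected layer to per-class logits (the *auxiliary classifier*).
The four logit vectors are summed element-wise and softmaxed — the
*principal classifier*. The training objective is

$$\mathrm{Loss} = \sum_a L_a(\hat y_a, y) + L_m(\hat y_m, y),$$

an unweighted sum of the per-scale cross-entropies and the fused
cross-entropy, all against a label-smoothed target
$y_i = (1-\varepsilon)\,[i = \text{true}] + \varepsilon/C$ with
$\varepsilon = 0.1$. Two design choices here were genuinely open:

* fusion sums **pre-softmax logits**, not probabilities — "summed by
  element and fed to a softmax layer" reads most naturally as logit
  summation, and it keeps the fused head scale-equivariant;
* all five loss terms carry weight 1; the adaptive balancing of scales is
  left to joint convergence rather than explicit coefficients.

Ablation flags reproduce the structural baselines: `use_fpn = FALSE`
(single-scale encoding), `use_encoding = FALSE` (global average pooling
in place of the texton block), `deep_supervision = FALSE` (main loss
only). Each variant trains end-to-end.

### Training protocol

Defaults follow the published protocol exactly: SGD with momentum 0.9,
batch size 16, 30 epochs, initial learning rate 0.005 with per-batch
cosine annealing $\eta(t) = \tfrac{\eta_0}{2}(1 + \cos(\pi t/T))$ down to
a floor of 0 (the floor is unstated anywhere; 0 is the standard choice),
label smoothing 0.1, no weight decay (also unstated; configurable).
Class imbalance is handled by weighted random oversampling: each patch is
drawn with probability proportional to the reciprocal of its class count,
with replacement, so expected class frequencies are uniform; one epoch
makes `ceiling(n/16)` draws. Augmentation applies only the stated
transforms — horizontal/vertical flips, additive Gaussian noise (sd 2% of
the dynamic range), multiplicative brightness jitter in [0.8, 1.2] — each
with probability 0.5 (the magnitudes are unstated in the protocol; these
are conventional values). z-score normalization uses the training split's
global mean and standard deviation, stored with the checkpoint.

Cross-validation folds are **patient-grouped**: patients, not images, are
partitioned, so no subject contributes to both sides of a split.

## Patch extraction and volume verdicts

Patches are cut by a sliding window that moves horizontally within each
frame (offsets $0, s, 2s, \dots$; the last window that fits is included),
giving a (frame × window) grid per volume — one axis cross-sectional
(in-frame), one axial (cross-frame). The binary risk score of a patch is
$\rho = P(\mathrm{HSIL}) + P(\mathrm{CC})$; a patch is high-risk when
$\rho \ge \tau$ with $\tau = 0.8$.

A volume is positive under the **cross-shaped threshold voting rule**
when some high-risk patch has at least `arm_length` contiguous high-risk
neighbors along *both* axes (at least one in-frame neighbor and one
cross-frame neighbor for the default `arm_length = 1`) — the firing
pattern looks like a cross. Because the source description gives no
neighbor count, `arm_length` is configurable; a run on *one* side of the
center suffices, which lets lesions at the grid border fire without
indexing outside the grid. A patient is positive if any of her volumes
is. The rule is monotone both in $\tau$ (a verdict positive at a stricter
threshold stays positive at a looser one) and in the patch scores.

## Synthetic data: what it emulates and what it does not

The generator renders seeded, class-conditional volumes so the whole
pipeline is testable without clinical data:

* **MI** — horizontal sinusoidal stratification (period 12 px, amplitude
  35 on the 0–255 scale) plus a bright, thin basement-membrane line;
* **CY** — the same stratified background with 2–4 soft-edged dark
  elliptical voids;
* **EP** — a papillary surface: a sinusoidally undulating bright
  ("hyper-scattering") fringe with a dark lumen above;
* **HSIL** — a contiguous de-stratified homogeneous region; **CC** — the
  same with alternating light/dark vertical attenuation bands
  (period 28 px, contrast 50).

Lesions are placed uniformly at random as contiguous blocks of whole
frames × window-aligned x-ranges with extent at least
`lesion_min_extent = (3 frames, 3 windows)`, so every true lesion *can*
fire the cross rule; the (frame, x) support is returned as a ground-truth
mask. Additive Gaussian noise (sd 8/255 of full scale, clipped) stands in
for OCT speckle. Frames are 96 × 224 px with 96-px windows; defaults were
fixed once, before any acceptance measurement, so that the motifs are
cleanly separable — that is the *point* of the fixture: it makes the
training acceptance test a test of the learner, not of the data.

A fixed texture statistic quantifies the separation: the depth-profile
autocorrelation contrast $\mathrm{ac}(T) - \mathrm{ac}(T/2)$ at the
layering period $T$, averaged over columns (inside the lesion mask for
lesional volumes). Across 20 seeds per class it scores 0.45–1.12 for the
stratified classes and −0.05–−0.03 for the de-stratified ones; the
configured separation margin of 0.6 sits inside the ≈ 0.5–1.1 gap between
the closest pair and the farthest pair of class means.

Patch labels follow a purity rule: patches of a lesional volume whose
window overlaps the mask on less than half its width are *excluded*
(their content is normal tissue); negative-volume patches all carry the
volume class. Label noise from partially covered windows is thereby
bounded at 50% overlap.

What the generator does **not** emulate: physical speckle statistics and
the imaging point-spread function, probe geometry and o'clock positions,
quality-defective volumes, inter-patient texture variability beyond seed
jitter, and class co-occurrence within a patient (each synthetic patient
carries one class). Passing the synthetic study therefore demonstrates
that the architecture, optimizer, voting rule and metrics are correctly
implemented and can learn strong textural classes end-to-end — not that
the model reaches clinical performance on real OCT.

## Numerical choices and problem sizes

* Softmaxes are max-subtracted; cross-entropies floor probabilities at
  1e-12; squared distances are clamped at 0; L2 normalization guards the
  zero vector (it maps to the bias).
* Batch-norm uses batch statistics in training and running statistics
  (momentum 0.1) at evaluation.
* Prediction ties break toward the lowest class index.
* Undefined metrics (zero denominators) are reported as `NA`, never
  coerced to 0 or 1.
* The Mann–Whitney p-value is exact by enumeration for groups of at most
  8 without ties, otherwise the tie-corrected normal approximation.
* The desk-scale study trains the test profile at a 112 × 112 input
  (pyramid 28/14/7/4). The network is fully convolutional and the
  encoding is orderless, so the input side is a free parameter; the
  224-input contract (56/28/14/7, both profiles) is asserted separately.
  The synthetic study uses ~1,000 training patches (200 per class,
  patient-grouped split), 30 epochs, three seeds, reporting the median
  held-out accuracy.

## Known limitations

* At desk-scale inputs the last scale's units have near-global receptive
  fields; Grad-CAM localization at scale IV is reliable at a 112-px input
  but degrades at 64–96 px, while scales II–III localize robustly
  throughout. On clinical-scale inputs (600-px patches resized to 224)
  the scale-IV maps are coarse by construction.
* The reference backbone is provided for structural fidelity and shape
  verification; training it on CPU at clinical scale is not practical in
  this implementation.
* Checkpoints are R serializations (RDS), not interoperable with other
  frameworks.
* The voting rule's minimum run length along each axis
  (`arm_length`) follows the description's geometry, not a published
  count; it is a configuration parameter, defaulting to 1.
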