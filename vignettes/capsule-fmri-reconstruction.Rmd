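---
title: "Reconstructing visual stimuli from fMRI with a capsule network: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing visual stimuli from fMRI with a capsule network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A subject views small grayscale images (handwritten digits "6" and "9",
28x28 pixels) while BOLD responses are recorded; after preprocessing, each
trial yields one response per voxel over early visual cortex (V1–V3, about
3,000 voxels) and the goal is to reconstruct the viewed image — not merely
its class — from the voxel vector. With on the order of 100 trials, the
decoding problem is severely under-determined, so the method routes it
through a compact *equivariant* feature space learned on image data alone.

`capsrecon` implements the full two-stage procedure:

1. **Stage 1 (images only).** A capsule network is trained on digit images.
   Its per-class 16-D "digit capsules" encode both presence (vector norm)
   and instantiation parameters — orientation, scale, stroke width,
   position (vector direction) — and a jointly trained three-layer decoder
   maps a capsule back to the image. Because the decoder can reproduce the
   input from the 16 numbers, those numbers are a near-lossless,
   equivariant summary of the stimulus.
2. **Stage 2 (encoding and selection).** For each voxel, an ordinary
   least-squares encoding model predicts its response from the 16 features
   of the *longer* capsule (plus an intercept). Voxels are ranked by the
   in-sample coefficient of determination $R^2 = 1 - SS_{res}/SS_{tot}$ and
   the top 100 are kept.
3. **Stage 3 (decoding).** A three-layer network (100 → 256 → 128 → 32,
   ReLU/ReLU/linear) maps the selected voxels to both capsules; the 32-D
   output is split in half and each half squashed. At test time the longer
   predicted capsule is pushed through the frozen stage-1 decoder to
   produce the reconstruction.

## The capsule network

With $\mathbf{s}_j$ the total input of capsule $j$, the squashing
nonlinearity is

$$\mathbf{v}_j = \frac{\lVert\mathbf{s}_j\rVert^2}{1+\lVert\mathbf{s}_j\rVert^2}\,
\frac{\mathbf{s}_j}{\lVert\mathbf{s}_j\rVert},$$

implemented in the singularity-free form
$\mathbf{v} = \mathbf{s}\,\lVert\mathbf{s}\rVert/(1+\lVert\mathbf{s}\rVert^2)$,
so $\mathbf{s} = 0$ maps to $0$ exactly; the output norm is strictly below 1
(inputs of norm 1 and 3 map to norms 0.5 and 0.9). Prediction vectors are
$\hat{\mathbf{u}}_{j|i} = \mathbf{W}_{ij}\mathbf{u}_i$; routing by agreement
iterates (three times by default)

$$c_{ij} = \mathrm{softmax}_j(b_{ij}), \quad
\mathbf{s}_j = \sum_i c_{ij}\hat{\mathbf{u}}_{j|i}, \quad
\mathbf{v}_j = \mathrm{squash}(\mathbf{s}_j), \quad
b_{ij} \mathrel{+}= \hat{\mathbf{u}}_{j|i}\cdot\mathbf{v}_j,$$

with $b_{ij} = 0$ initially. Classification uses the margin loss
($m^+ = 0.9$, $m^- = 0.1$, $\lambda = 0.5$)

$$L = \sum_c T_c\,\max(0, m^+ - \lVert\mathbf{v}_c\rVert)^2 +
\lambda (1-T_c)\,\max(0, \lVert\mathbf{v}_c\rVert - m^-)^2,$$

and the overall objective adds $\mu\,\mathrm{MSE}(I, \mathrm{dec}(\mathbf{v}_k))$
with $\mu = 4$, the MSE averaged over pixels and the decoder fed the
*target-class* capsule during training. Everything — convolutions (im2col +
BLAS), routing, decoder — is differentiated by hand in R, including full
backpropagation through the routing loop; the test suite checks every
parameter group against central finite differences at 1e-4 relative error.

### Architecture and the desk-scale variant

The full-width architecture (`capsnet_config()`) follows the reference
design: 256 9x9 stride-1 ReLU filters (28x28 → 20x20), a 9x9 stride-2
convolution into 32 maps of 6x6 8-D primary capsules (1,152 capsules,
squashed before routing), two 16-D digit capsules, and a 16 → 512 → 1024 →
784 sigmoid decoder. Training it on a full digit corpus is not a
desk-scale job in base R, so `scaled_capsnet_config()` keeps the identical
topology, losses and protocol with 32 first-layer filters, 8 primary maps
(288 capsules) and a 128/256 decoder. All quantitative training tests use
the scaled network on 500 synthetic glyphs for 20 epochs (~2–3 minutes on
one CPU); the full-width network is exercised forward-pass-only by the
architecture tests.

### Numerical choices

* **Routing softmax axis.** The logits are normalized over the *upper*
  capsules for each lower capsule (couplings from one part sum to 1 over
  wholes), the routing-by-agreement convention; the printed equation's
  denominator index is ambiguous.
* **Margin loss.** Implemented with both hinge terms squared (the printed
  formula has unbalanced parentheses); this reproduces the worked values
  0, 0.81, 0.24 used in the tests.
* **Primary capsules are squashed before routing** so their norms are valid
  presence probabilities; the source text is silent here.
* **Decoder input.** One shared 16-D decoder consumes a single capsule
  (target-class during training, longer at inference) rather than a masked
  32-D concatenation; the sharing is supported by the observation that the
  same feature dimension can control the same property for both digits.
* **Squash gradient** uses a 1e-9 guard on the norm in the
  $\mathbf{s}\mathbf{s}^\top/r$ term only; the forward pass needs no guard.
* **Ties.** Wherever a longer/argmax choice can tie exactly (class choice,
  longer capsule), the first — lower — class label wins, deterministically.
* **Adam.** $\beta = (0.9, 0.999)$, $\epsilon = 10^{-8}$; learning rate
  1e-3 for stage 1 (unstated in the source; 1e-4 is stated for stage 3 and
  used there), batch size 10 everywhere.

## The synthetic stated world

No external download is used anywhere. The generator produces:

* **Stimuli** (`generate_digits()`): parametric glyphs — a loop plus a
  curved tail, with a "9" rendered as the half-turn rotation of the "6"
  path, as in handwriting. Sampled variability (orientation ±0.45 rad,
  scale 0.80–1.05, stroke width 1.4–2.4 px, loop radius 0.38–0.52, ±1.5 px
  translation) was chosen once as a plausible handwriting range that stays
  inside the 28x28 frame; ranges that can push strokes off-frame are
  rejected with an error. An IDX reader/writer is provided for real digit
  archives.
* **Voxels** (`generate_fmri()`): each informative voxel is a linear
  function of the 16 longer-capsule features plus intercept and i.i.d.
  Gaussian noise; other voxels are pure noise. This is *exactly* the model
  the selection stage fits — deliberately, so that parameter recovery is a
  meaningful acceptance surface. Noise is calibrated per voxel to a target
  in-sample $R^2$ with a degrees-of-freedom correction: the population
  explained fraction is set to $\rho = (r - p/(n-1))/(1 - p/(n-1))$
  ($p = 16$) so the OLS in-sample $R^2$ at the study size ($n = 90$
  training trials) concentrates on the requested $r$; without the
  correction, a target of 0.5 would come out near 0.59.

What a green test therefore establishes: the pipeline recovers structure
it is statistically entitled to recover — planted informative voxels land
in the top-100, the mapper inverts the (noiseless) encoding map, end-to-end
reconstructions of held-out synthetic trials reach mean SSIM ≥ 0.6 with
≥ 95% class recovery. What it does **not** establish: performance on real
BOLD data, whose noise is neither i.i.d. nor Gaussian nor spatially
unstructured, and whose stimulus–response mapping is not exactly linear in
any feature basis. No hemodynamics, scanner drift or spatial correlation is
simulated.

The command-line `simulate` stage must be runnable before any network
exists, so its default study derives voxels from a surrogate feature
embedding of the true glyph parameters rather than capsule features;
studies used in quality tests are built from capsule features of a trained
network via `generate_fmri()` directly.

## Evaluation protocol

`crossvalidate()` reproduces the study protocol: 10 folds, stratified by
class (the source states only "10-fold"; with 50/50 classes and n = 100,
stratification avoids degenerate folds). Stage 1 is shared across folds
(it uses no fMRI data); encoding fit, selection and mapper are refit per
training fold — the leakage-safe reading; a `global_selection` mode mimics
a single global selection. A paired "theoretical" reconstruction (decoding
the *true* capsule) is reported alongside the fMRI path as the method's
upper limit. Metrics: pixel-mean MSE, Pearson correlation of flattened
pixels (an error, not a silent 0, for constant images), and SSIM with the
canonical constants (11x11 Gaussian window, σ = 1.5, K1 = 0.01,
K2 = 0.03, dynamic range 1, mean over the valid map); the suite checks
SSIM against an independently coded double-loop reference at 1e-6.

Voxel responses are z-scored with training-fold statistics inside the
mapper (stored in the model and applied at prediction); $R^2$ ranking is
scale-invariant, so selection operates on raw responses.

### A finding on mapper generalization

With the stated defaults (n = 90, L2 strength 1e-3, 10,000 Adam steps at
learning rate 1e-4) the mapper's held-out MSE ends ~2–3x its training MSE
— both tiny on the capsule scale (≈ 0.001 vs ≈ 0.002–0.003, against
feature variances an order of magnitude larger), so the test curve tracks
the training curve closely in absolute terms without diverging, which is
the qualitative behavior claimed for the method. The tests therefore
assert absolute bounds frozen from a pilot run (final test MSE < 0.006 and
below its early-training value) rather than a relative train/test gap,
which is not meaningful when the training MSE approaches zero on noiseless
synthetic data.

## Interpretability

* `perturb_dimension()` decodes a capsule with one dimension offset over a
  grid (default −0.5…+0.5 by 0.1); the δ = 0 frame equals the unperturbed
  reconstruction bit-for-bit. Any semantic naming of dimensions
  ("orientation", "width", ...) is a user-supplied label; the package
  computes none.
* `attribute_voxels()` reports $|\partial z_d / \partial x_v|$ for the
  mapper's **pre-squash** 32-D output — pre-squash because then, with
  activations bypassed, the Jacobian is exactly the product of the three
  weight matrices (the linearity check in the test suite); the squash only
  rescales within a capsule and would entangle dimensions. The
  linearization point is a design choice (the source is silent): default is
  the supplied reference input, with a documented averaging mode over a set
  of inputs; gradients are chained through the input standardization by
  default so units are raw voxel response units. The map is a sensitivity
  report, not a causal claim.

## Known limitations

* Pure-R training: minutes, not seconds, for stage 1; the full-width
  architecture is practical for inference and small fine-tuning only.
* The two-class design is configurable in width but the pipeline
  conventions (longer-of-two capsules, 32-D mapper output) assume two
  classes as in the target study.
* Checkpoints and study containers use a JSON-manifest + CSV/flat-binary
  layout rather than HDF5 (no HDF5 binding is available to R here); the
  named-array contract and exact round-tripping are preserved.
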