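---
title: "Self-calibrated multi-stage Retinex enhancement: model, losses, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-calibrated multi-stage Retinex enhancement: model, losses, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

Surveillance footage from livestock barns is routinely captured in deep
dusk: a camera above a farrowing pen, minimal ambient light, and downstream
consumers (segmentation, behaviour recognition, human observers) that all
degrade badly on under-exposed frames. Paired bright references do not
exist for such scenes, so enhancement has to be learned unsupervised, and
it has to be cheap enough to run on every frame.

`scretinex` follows the Retinex decomposition: an observed image is the
element-wise product of a scene-intrinsic reflectance and a lighting field,

$$c = a \otimes b,$$

with $b \in (0, 1]$ smooth in space. Enhancement reduces to estimating the
illumination map and dividing it out, $a = c \oslash b$. Two tiny
fully-convolutional networks carry the estimation:

* **IE-Net** (the *illumination estimator*) maps a stage input $v_t$ to a
  residual $u_t = H_\theta(v_t)$, giving $b_t = \mathrm{clamp}(v_t + u_t,
  \varepsilon, 1)$. Learning the *residual* between input and illumination
  rather than the illumination itself is what lets a 258-parameter network
  do the job: the gap between a dark image and its lighting field is a
  small, spatially smooth quantity.
* **SCA-Net** (the *self-calibration* module) closes the loop: from the
  current enhanced image $a_t = c \oslash b_t$ it predicts a calibration
  map $d_t = \varphi_\vartheta(a_t)$, and the next stage consumes the
  *corrected input* $v_{t+1} = c + d_t$ (with $v_1 = c$, $d_0 = 0$).

Both networks share their weights across all $T$ stages. The point of the
calibration is not accuracy at stage $T$ but *convergence of the cascade*:
when every stage sees an input corrected toward the same state, the stage
outputs collapse onto one fixed point, and deployment can run a single
IE-Net pass (`enhance_single_stage()`) instead of the full cascade —
that single pass is the package's production path, and the cascade with
$T = 3$ exists only at training and diagnosis time. An ablation mode
(`use_sca = FALSE`) runs the literal cascade $v_{t+1} = b_t$ instead, which
is the baseline the self-calibration claim is measured against
(`convergence_report()`).

Both networks are an input 3×3 convolution + ReLU, a stack of
3×3 convolution + batch-norm + ReLU blocks, an additive fusion of the first
feature map with the last (the only parameter-free fusion consistent with
the layer table's channel counts), and a 3×3 convolution + sigmoid head.
IE-Net keeps 3 channels with one block (258 trainable scalars, 0.0003 M);
SCA-Net widens to 16 channels and 3 blocks (7 939) since it must resolve
subtler differences. The sigmoid head bounds both maps in $(0,1)$: residuals
are non-negative because illumination dominates a dark observation
($c = a \otimes b \le b$), and calibration offsets are bounded corrections.

## The four-term unsupervised loss

Training minimises, with $\alpha = 1$, $\beta = 1.5$,

$$L = \alpha L_f + \beta L_s + L_{sem} + L_\nabla .$$

* **Fidelity** $L_f = \sum_t \overline{(b_t - v_t)^2}$ anchors each stage's
  illumination to its corrected input — the only "reference" an
  unsupervised setting has.
* **Smoothness** $L_s$ is a bilateral penalty over 5×5 neighbourhoods:
  $\sum_{i}\sum_{j \in N(i)} w_{ij}\,|b_t^i - b_t^j|$ with
  $w_{ij} = \exp(-\sum_{ch}(v^{i,ch}-v^{j,ch})^2 / 2\sigma^2)$ computed from
  the corrected input in YUV (chroma edges count as edges). Uniform regions
  demand smooth lighting; true edges get exponentially small weights and
  may stay sharp.
* **Perceptual** $L_{sem}$ repeats the fidelity comparison in the feature
  space of a *fixed* extractor, preserving the structures downstream vision
  models rely on.
* **Gradient** $L_\nabla = \sum_t \overline{|\nabla_x a_t| + |\nabla_y a_t|}$
  suppresses the sensor noise that division by a small illumination map
  amplifies.

Every term is normalised by element count so magnitudes are
resolution-independent; the stage dimension remains a sum. The balance
between fidelity and smoothness sets where the illumination map sits
between "the input itself" and "a flat field"; the published weighting is
kept as the default.

### Choices the formulas leave open

* **$\sigma$ (smoothness bandwidth)**: not specified; default 0.1 on
  $[0,1]$ YUV intensities. Neighbouring-pixel differences well above 0.1
  are treated as edges; differences below it are smoothed across. Exposed
  in `loss_weights()`.
* **Per-channel differences**: $|b^i - b^j|$ is computed per channel and
  averaged; the similarity weight sums squared differences over all three
  YUV channels.
* **Weight gradient**: the bilateral weights depend on $v_t$, which for
  $t \ge 2$ depends on the calibration network, so the analytic gradient
  differentiates *through* the weights and the YUV conversion. The full
  reverse sweep is checked against central finite differences at
  $\sim 10^{-10}$ (see `test-gradients.R`).
* **Gradient operator**: forward differences with replicate edges (last
  row/column differences zero).
* **Feature extractor**: the reference choice in this literature is a
  pretrained VGG. The default here is a 3-layer seeded-random fixed
  convolutional stack (3→8→8→8 channels, ReLU) — random convolutional
  features are a long-standing baseline for perceptual similarity, fully
  deterministic and dependency-free; the extractor is pluggable and an
  identity extractor (under which $L_{sem} \equiv L_f$) is used to pin the
  semantics in tests.
* **Final-stage calibration**: $d_T$ feeds no loss term under this stage
  indexing; `decompose()` still records it for completeness, the training
  path skips computing it.

## Numerical design

* **Division guard**: illumination is clamped to $[\varepsilon, 1]$ with
  $\varepsilon = 10^{-4}$ before the division. The upper clamp encodes that
  illumination is a fraction of full light (values above 1 would darken).
* **Head initialisation**: convolution weights are Kaiming fan-in draws,
  biases zero — except the output-head bias of both networks, which starts
  at $-4$ so the sigmoid opens near $0.02$. The cascade therefore starts
  near the identity ($d \approx 0$, $v \approx c$, matching $d_0 = 0$), and
  the illumination map starts inside its responsive range: with a mid-range
  head ($u \approx d \approx 0.5$) the clamp at 1 is active almost
  everywhere at initialisation and blocks the gradient of the residual
  branch.
* **Batch norm**: batch statistics (biased variance, momentum 0.1) during
  training, frozen running statistics at inference — single-image
  enhancement never sees batch statistics.
* **Clipping**: the enhanced image is kept unclipped internally (losses see
  the real values); clipping to $[0,1]$ happens only on image export, where
  values are quantised half-away-from-zero to 8 bits.
* **Determinism**: the run seed fixes weight initialisation and epoch
  shuffling; two runs with the same configuration produce bitwise-identical
  checkpoints on one platform. Checkpoints serialise weights as decimal
  text with 17 significant digits, which round-trips IEEE doubles exactly.

All layer forward/backward passes are implemented in the package (direct
convolution in compiled code, analytic reverse-mode sweep through the
weight-shared cascade, Adam); no deep-learning framework is involved.

## The synthetic testbed

Real barn footage cannot ship with a package, and no-reference quality
models (HIGRADE, BRISQUE, CEIQ, ENIQA) used in the field are third-party
fitted models, out of scope here. Instead, `make_scene()` draws scenes from
exactly the generative model the method assumes:

* a reflectance image: low-frequency textured background (Gaussian-blurred
  noise, bandwidth 4 px, rescaled to 0.15–0.55) plus `n_shapes = 3` bright
  ellipses of distinct mean intensity (0.6–0.95) standing in, statistically
  only, for animal bodies;
* an independent smooth illumination field: Gaussian-blurred noise
  (bandwidth 12 px) rescaled to `illum_level_range = [0.1, 0.35]` — deep
  dusk — shared across channels (gray illumination, the standard Retinex
  assumption; a per-channel tint exists but is off by default);
* the observation `clip(reflectance ⊗ illumination + noise, 0, 1)` with
  additive Gaussian read noise, `noise_std = 0.01`. Poisson shot noise is
  deliberately omitted so every fixture is exactly reproducible from its
  seed.

With `noise_std = 0` the observation equals the product exactly (both
factors are ≤ 1, so the clip is inactive), which gives the tests a sharp
generative identity to assert.

What the testbed does *not* emulate: pose and shape realism, heat-lamp
hotspots and strongly uneven lighting (a known limitation of this method
family), compression artefacts, and motion. Passing tests on these scenes
demonstrates that the machinery optimises its objective and recovers the
assumed generative structure — not that enhancement quality transfers to
any particular real barn.

A property of these scenes worth stating explicitly: the ellipse scale
(6–16 px) overlaps the illumination correlation length (~12 px), and the
reflectance luminance variance is several times the realised illumination
variance. Scale separation between the two factors is therefore weak, and
*any* estimator that leaks a few percent of reflectance texture into its
illumination map loses most of its per-pixel Pearson correlation with the
true field. The illumination-recovery checks in the acceptance suite freeze
their threshold from a baseline run under exactly these conditions rather
than assuming a value.

## Desk-scale training protocol

The published protocol (Adam, $\beta_1 = 0.9$, $\beta_2 = 0.999$,
$\epsilon = 10^{-8}$, learning rate $10^{-4}$, batch 2, $T = 3$, 100
epochs) was tuned for ~1 500 real frames, i.e. ~73 000 optimiser steps;
those values are the `train_config()` defaults. The package's own
evaluation protocol — used by the test suite — is desk-scale: 20 synthetic
64×64 scenes, 50 epochs (500 steps), batch 2, $T = 3$, with 6 held-out
scenes. At 500 steps the published step size barely moves the networks, so
the protocol needs a larger one; but the step size is bounded above by a
failure mode specific to the *uncalibrated* baseline: the fidelity anchor
of the ablation cascade is the raw observation at every stage, which makes
"zero residual" a strong attractor, and at step sizes of $10^{-3}$ and
above the baseline collapses into that degenerate identity cascade within
the 500-step budget (its stage divergence is then vacuously zero and its
"enhancement" is flat). The protocol therefore uses $5 \times 10^{-4}$ —
scanned once over half-decade candidates as the largest step size at which
*both* arms keep a structured, non-collapsed residual while the loss
descends monotonically; everything else keeps the published values.
Problem sizes were chosen so the whole paired protocol (with and without
self-calibration) runs in minutes on one CPU core.

## Known limitations

* Uneven, strongly local lighting (heat lamps) violates the smooth-field
  assumption; the method brightens globally and can over-expose lit
  corners.
* The sigmoid-bounded residual forbids *darkening* ($b \ge v$ always);
  over-exposed inputs are out of scope.
* Published no-reference quality scores cannot be reproduced by this
  package (third-party fitted models); quality is assessed full-reference
  against synthetic ground truth instead, which is stronger where ground
  truth exists but not comparable across papers.
* Video is processed frame-independent; no temporal consistency.
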