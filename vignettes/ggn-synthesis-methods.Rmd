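---
title: "Methods: dual-discriminator GGN synthesis and its evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-discriminator GGN synthesis and its evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ggnforge)
```

## The problem

Ground-glass nodules (GGNs) are subsolid pulmonary lesions — hazy, increased
attenuation on CT that does not obscure the underlying parenchyma. They are
rare (a few percent of detected nodules) but disproportionately malignant,
which makes them exactly the minority class that computer-aided detection
models struggle with. One remedy is to synthesise additional GGN examples
with a generative adversarial network (GAN) and add them to the training
data. `ggnforge` implements such a synthesis model as an *inpainting* task:
the nodule region of a lung slice is blanked, and a generator learns to fill
it with a plausible nodule that is consistent with the surrounding
anatomy — judged both at the scale of the whole slice and at the scale of
the nodule region itself.

## The model

**Generator.** An SRGAN-style residual image-to-image network: a 3×3
convolution + PReLU head, `n_res_blocks` residual blocks of
(3×3 conv → batch norm → PReLU → 3×3 conv → batch norm) with identity skip
connections, a trunk convolution with a long skip back to the head features,
and a sigmoid-activated output convolution constraining intensities to
[0, 1]. Unlike the super-resolution original there is no upsampling stage:
input (the slice with the nodule region of interest, ROI, blanked to zero)
and output have identical shape.

**Two discriminators.** Residual-block classifiers with strided 3×3
convolutions, batch normalisation and leaky activations, global average
pooling and a sigmoid score strictly inside (0, 1). One judges the whole
slice (`image_size` input, 512 at full CT resolution, 64 at desk scale),
one judges only the fixed-size ROI crop (32 at full resolution). The ROI
discriminator sees the crop of the *generated whole image* at the ROI box,
not an independently generated patch, so both discriminators constrain one
output.

**Loss.** The generator objective splits the image into two parts and sums
a structural-similarity (SSIM) and an adversarial term for each:

$$L = (L_{ssim} + L_{adv})_{whole} + (L_{ssim} + L_{adv})_{ROI},
\qquad L_{adv} = \sum_n -\log D(G(x_n)),
\qquad L_{ssim} = 1 - \mathrm{SSIM}.$$

SSIM is the standard structural-similarity index
$\frac{(2\mu_x\mu_y + C_1)(2\sigma_{xy} + C_2)}
{(\mu_x^2+\mu_y^2+C_1)(\sigma_x^2+\sigma_y^2+C_2)}$ with the universal
constants $C_1 = (0.01L)^2$, $C_2 = (0.03L)^2$ at dynamic range $L = 1$.
A published variant of this loss circulates with a typographically
corrupted formula (additive numerator, $\mu_x^2\mu_y^2$ and
$\sigma_x^2\sigma_y^2$ denominator products); that form is asymmetric and
does not equal 1 at $x = y$, so it cannot be the intended similarity. We
implement the standard index and keep the literal corrupted form available
behind `ssim(..., formula = "as_printed")` purely for comparison.

By default SSIM is computed from whole-grid statistics (one value of each
moment), matching the single-statistic loss formula; an 11×11
Gaussian-windowed mode (σ = 1.5) is provided for *measurement*. The
training path uses the global form, whose analytic gradient is implemented
in closed form; the windowed gradient is not implemented.

**Discriminator objective.** Binary cross-entropy
$-\sum\log D(\mathrm{real}) - \sum\log(1 - D(\mathrm{fake}))$. The update
schedule is 1:1 (both discriminators and the generator are updated once per
step), with Adam (β = 0.9/0.999) at a single learning rate for all three
networks.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `image_size` | 64 (512 at full scale) | slice side, pixels |
| `roi_size` | `image_size/16` | ROI crop side, pixels |
| `n_res_blocks` | 8 | generator residual blocks |
| `base_channels` | 32 | first-stage feature channels |
| `learning_rate` | 1e-4 | Adam rate, all networks |
| `batch_size` | 4 | pairs per step |
| `adv_reduction` | `"sum"` | batch reduction of the adversarial term |
| `label_smoothing` | off | 0.9/0.1 discriminator targets |
| `composite_output` | on | paste generated ROI onto the known background |

The 1e-4 learning rate is the appropriate default at full 512×512 scale.
At desk scale (64×64, small channel counts, 200 steps) the adversarial and
reconstruction gradients are differently balanced: with rates at 1e-4 and
above the discriminators win quickly and the SSIM term deteriorates after
an initial descent. The desk-scale smoke experiments in the test suite
therefore run at 3e-5, where the SSIM loss descends monotonically over the
full run; this is a stability choice for the small configuration, made once
and fixed.

The ROI side also deserves a note: the full-scale setup uses a 32-px ROI in
a 512-px slice (ratio 1/16, which would be 4 px at desk scale). Because the
phantom generator implants lesions of 3–7 px radius, a 4-px crop would
truncate nearly the whole lesion, so desk-scale experiments use a 16-px ROI
that covers the implanted nodule; `roi_size` remains fully configurable.

## The phantom generator

All experiments run on seeded synthetic lung phantoms, so nothing needs to
be downloaded. A phantom emulates an axial chest-CT slice on a
Hounsfield-like scale: background air at −1000, a soft-tissue body ellipse
at +40, two lung-field ellipses at −800 with additive Gaussian noise
(σ = 25 by default), and bright curvilinear vessels simulated as damped
random walks inside the lungs. Lesions are implanted as radially decaying
blobs clipped to the lung mask: grades 1–2 (GGN) use a raised-cosine
profile scaled by a peak opacity of 0.35–0.8 of the lung-to-soft-tissue
gap and modulated by multiplicative smoothed-noise texture, so interiors
are non-constant and texture radiomics are non-degenerate; grade 5 (solid)
is a near-uniform disc. Each slice carries exactly one lesion, and
`round(n × ggn_fraction)` of a dataset's lesions are GGNs — exactly.

What the phantoms do *not* emulate: real anatomy (airways, fissures,
mediastinum), respiratory or partial-volume artefacts, scanner noise
spectra, 3-D context, or the diversity of real nodule morphology. Passing
tests on phantoms therefore demonstrate that the pipeline's mechanics are
correct (preprocessing geometry, losses, training dynamics, feature
definitions, statistics), not that the GAN reaches clinical realism —
the latter requires real CT data at full resolution.

## Preprocessing

Five stages, each a pure function: (1) slice extraction is the phantom
generator itself; (2) seed-filling lung segmentation — a 4-connected flood
fill from an interior seed over below-threshold pixels (threshold −400,
between lung parenchyma and soft tissue; 4-connectivity is the conservative
choice for boundary stopping). Automatic seeds are the intensity minima of
the mid-height row, one per lung half. Dense nodules stop the fill and
would leave holes, so interior holes (components of the complement not
touching the border) are closed before stripping; (3) background stripping
zeroes non-lung pixels, crops to the mask's tight bounding box and centres
the content on a `target_size` zero canvas (centred rather than
corner-anchored — the choice is not dictated by anything upstream, and
centring keeps annotation remapping symmetric); (4) intensity normalisation
`clip((x − low)/(high − low), 0, 1)` with the standard lung window
(−1000, 400); (5) ROI blanking: the original slice is the target, a copy
with the `roi_size` square centred on the nodule centroid zeroed is the
input. At image borders the box is shifted, never shrunk, because the ROI
discriminator needs a fixed input size; nodules larger than the box are
truncated for the same reason.

## Evaluation framework

**Radiomics.** `extract_features()` computes the standard 93-feature 2-D
signature over a masked region: first-order statistics (18), grey level
co-occurrence matrix (24), grey level dependence matrix (14), grey level
run length matrix (16), grey level size zone matrix (16) and neighbouring
grey tone difference matrix (5), to the standard reference definitions.
Grey levels are discretised with a fixed bin width (default 25 intensity
units, the conventional default on a raw CT-like scale — for [0, 1]
images use ~0.05); GLCM and GLRLM aggregate the four 2-D directions by
averaging; zones and neighbourhoods are 8-connected; the GLDM dependence
threshold is α = 0. Degenerate-region conventions: skewness and kurtosis
are 0 for constant regions, GLCM correlation is 1 for a single grey level,
and coarseness is capped at 10^6 when its denominator vanishes. The
per-family cardinalities are enforced on every extraction
(`validate_feature_vector()`), so the 93-feature contract is an invariant,
not a convention.

**Cohort comparison.** One two-sample Kolmogorov–Smirnov test per feature;
a feature counts as non-significant when p ≥ α with α = 0.05. P-values are
exact (by enumeration) when both samples have ≤ 10 observations and
asymptotic otherwise, which keeps small-sample behaviour oracle-checkable
while matching common practice at realistic cohort sizes.

**Real-vs-synthetic classification.** Logistic regression on per-fold
standardised features (zero-variance features dropped per training fold;
no explicit penalty, i.e. effectively unregularised maximum likelihood)
with stratified fourfold cross-validation; held-out scores are pooled for
the pooled AUC and accuracy at threshold 0.5. AUC uses the midrank
(Mann–Whitney) convention, ties counting one half.

**Visual Turing test analytics.** Reader ratings on the four-level scale
(confidently fake, leaning fake, leaning real, confidently real) are
binarised at the fake/real boundary for the confusion matrix and used
ordinally (0–3) as scores for the reader ROC AUC, real as positive. The
ordinal mapping is the natural one; with a single truth class the AUC is
reported as not computable rather than a number.

**Augmentation sweep.** The dataset is split into a stratified 20% held-out
test set and ten stratified, disjoint training subsets; fraction f uses the
first f/10 subsets, so larger fractions are supersets of smaller ones. For
each fraction, arm A trains the GGN-vs-solid classifier (a small residual
network with cross-entropy) on the real subset; arm B first trains the
inpainting GAN on the subset's GGN slices, synthesises one new GGN per real
GGN by inpainting a blanked box at a fresh lung-interior location of a
subset slice (doubling the minority class — the count is a design choice,
as is the 20% test fraction), and trains the classifier on the combined
set. Both arms are evaluated on the same held-out test set; test cases
never enter GAN or classifier training, which the result object exposes
for direct assertion.

## Numerical choices and degenerate inputs

- Discriminator scores are clamped to [1e−12, 1 − 1e−12] so the log-loss
  terms stay finite at double precision; the clamp is outside the gradient
  path.
- The SSIM gradient uses population (1/n) moments throughout, matching the
  loss value.
- Adam state is per-parameter with bias correction; batch-norm running
  statistics (momentum 0.1) provide deterministic inference-mode
  normalisation.
- Every stochastic routine takes an explicit seed and restores the caller's
  RNG state, so a training run is a pure function of (data, config, seed)
  and two runs with the same arguments produce bit-identical loss
  histories.
- Lesion placement is rejection-sampled inside the eroded lung mask with at
  most 20 attempts before a deterministic error — no unbounded loops.
- A zero-amplitude lesion, an empty mask, a seed on a boundary pixel, a
  degenerate normalisation window, out-of-bounds boxes and single-class
  folds all raise informative errors rather than propagating nonsense.

## Problem sizes used by the test suite

Unit tests run at 16–64 px with 1–2 residual blocks and 4–8 channels. The
end-to-end training check uses 8 phantom pairs at 64×64 for 200 steps
(twice, to assert bit-identical replay); the augmentation check uses 120
phantom slices, fractions {10, 50, 100}, both arms, with a 40-step GAN
recipe and a 60-step classifier. The type-I-error calibration of the
cohort comparison uses 500 null features over cohorts of 500 cases each —
large enough that the asymptotic Kolmogorov–Smirnov p-value is well
calibrated (the discrete statistic is visibly conservative at cohorts of
~100). These sizes were chosen so the whole suite
exercises every stage meaningfully on a single CPU; the architecture
accepts the full 512×512 configuration unchanged.

## Known limitations

- The printed-loss ambiguity is resolved in favour of standard SSIM (see
  above); results under the corrupted literal form are not meaningful.
- Global-statistics SSIM is a weak reconstruction constraint: it matches
  means, variances and covariance, not per-pixel structure, so desk-scale
  training can trade reconstruction for adversarial gain if run long or
  hot enough — visible in the loss history rather than hidden.
- The exact depth/width of a full-scale reference implementation is not
  specified anywhere authoritative; the defaults here are declared, not
  inferred, and everything is configurable.
- Texture-feature values depend on the discretisation; comparisons are
  only meaningful within one `radiomics_config`.
- Phantom realism is deliberately limited (see above); directional claims
  about augmentation benefit at phantom scale do not transfer numerically
  to real CT.
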