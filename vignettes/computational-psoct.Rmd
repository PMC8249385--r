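---
title: "Computational PS-OCT: model, phantom and validation protocol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computational PS-OCT: model, phantom and validation protocol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

Polarization-sensitive optical coherence tomography (PS-OCT) measures how
tissue alters the polarization of light, producing contrasts --- the degree
of polarization uniformity (DOPU) and the phase retardation --- that reveal
form-birefringent structures such as collagen and muscle fibers, and their
loss or derangement in tumours. The polarization channel requires extra
detectors and optics. `polsynth` implements the computational alternative:
a conditional GAN that maps ordinary single-polarization OCT intensity
B-scans to DOPU and retardation maps, together with the machinery needed to
train it, to evaluate it, and to ask whether its synthetic contrasts can be
used in place of measured ones for downstream cancer/normal classification.

Because no public co-registered OCT/PS-OCT breast dataset exists, the
package bundles a layered birefringent tissue phantom; all quantitative
statements made by the test suite and the acceptance script refer to this
phantom, not to human tissue.

## The synthesis model

The generator $G$ is a U-Net (encoder--decoder with skip connections,
instance normalization, a tanh-bounded output mapped onto the 8-bit scale).
Tiles whose sides are not multiples of $2^{\mathrm{depth}}$ are
reflect-padded up and cropped back, so $G$ preserves shape; the reference
202-pixel tile is padded to 224 at depth 5. The conditional discriminator
$D$ sees the intensity tile concatenated with a (real or synthetic)
contrast tile and applies exactly three strided convolutional feature
layers before a patch-logit head; deeper discriminators are deliberately
not offered --- in this task family they delay convergence without
improving synthesis. Training alternates single-sample updates (batch size
1 is forced by instance normalization) with Adam ($\beta_1 = 0.5$,
$\beta_2 = 0.999$).

The generator objective is

$$\mathcal{L}_G \;=\; \lambda_{adv}\,\mathrm{BCE}(D(x, G(x)), 1)
\;+\; \lambda_{L1}\,\overline{|G(x) - y|}
\;+\; \lambda_{SSIM}\,\bigl(1 - \mathrm{SSIM}(G(x), y)\bigr),$$

the pix2pix adversarial + L1 form augmented with a structural-similarity
term. SSIM uses the standard 11-pixel Gaussian window ($\sigma = 1.5$) with
stabilizers $C_1 = (0.01 L)^2$, $C_2 = (0.03 L)^2$ at dynamic range
$L = 255$, computed where the full window fits (no padding); its analytic
gradient is implemented alongside the forward map and is checked against
finite differences in the tests. Setting $\lambda_{SSIM} = 0$ recovers the
plain pix2pix objective bit-for-bit, which the suite asserts.

### Why $\lambda_{SSIM} = 2550$

All loss components are evaluated on the 8-bit scale (so a worst-case L1 is
255 while $1-\mathrm{SSIM}$ is at most 2). At that scale the conventional
weight pair $(\lambda_{L1}, \lambda_{SSIM}) = (100, 10)$ leaves the SSIM
gradient two to three orders of magnitude below the L1 gradient: the term
is numerically inert, and a paired ablation cannot distinguish it from
noise. The default $\lambda_{SSIM} = 2550$ is exactly "10 per unit of
dynamic range" --- the value 10 would take if images lived on $[0,1]$ ---
and brings the two gradients onto a common scale. With it, the ablation
below shows a consistent positive effect.

### Where the SSIM term earns its keep

On a noiseless task (the bundled `recovery_task_pairs()` benchmark, whose
target is a smooth invertible function of blurred intensity) the L1
optimum already maximizes SSIM, so adding the term cannot help; any
measured difference is optimization noise. The term matters when targets
are noisy --- precisely the situation with measured polarization contrasts,
whose noise the generator cannot and should not reproduce. The package's
ablation therefore runs on phantom DOPU synthesis (noisy targets): three
paired runs per condition, identical seeds across arms, comparing the mean
validation masked SSIM over the final three epochs. That trailing mean is
used instead of the best-checkpoint value because a maximum over a noisy
curve is an extreme-value statistic whose variance would swamp a paired
comparison.

## The phantom

A phantom B-scan is a stack of horizontal slabs spanning the depth axis.
Each slab carries a birefringence $\Delta n$, a backscatter amplitude, and
an attenuation coefficient. The channels are generated as follows.

* **Retardation.** Single-pass retardation accumulates as
  $\delta(z) = (2\pi/\lambda)\sum_{z' \le z} \Delta n(z')\,\Delta z$, is
  doubled for the round trip and folded into $[0, \pi/2]$ by triangular
  wrapping --- the standard single-detector display convention. The
  measured channel is recovered from a noisy Stokes field (below), which
  gives it realistic speckle-like grain.
* **Intensity.** Noise-free signal = slab amplitude times accumulated
  exponential attenuation; multiplicative speckle is the mean of
  `speckle_looks` unit-exponential draws; the result is log-compressed
  over a fixed display range and quantized to 16 bits.
* **DOPU.** Each retardation value maps to the unit Stokes vector
  $(\cos 2\delta, \sin 2\delta, 0)$ (the input state rotated by $2\delta$
  about the V axis); (Q,U,V) are perturbed by Gaussian noise and re-clipped
  to the physical bound; DOPU is the norm of the window-averaged normalized
  Stokes vector (5-pixel box window, clipped at borders --- chosen over
  reflect padding to keep the double-loop test oracle trivial).

The retardation channel's Stokes noise (`depol_noise_sigma_ret = 0.25`) is
constrained to exceed the DOPU channel's (`0.08`), encoding at the
simulator level the empirical fact that measured phase-retardation images
are the noisier contrast; a suite invariant checks that the high-pass
residual of retardation exceeds DOPU's in at least 95% of frames.

**Class model.** "Normal" frames draw $\Delta n$ from
$[5\times10^{-4}, 2\times10^{-3}]$ (organized birefringent stroma);
"cancer" frames draw from $[0, 2\times10^{-4}]$ --- the ranges must not
overlap, so the classes are separable by construction --- and contain at
least two lesion blobs that are simultaneously darker in backscatter and
locally depolarizing. Making every class cue visible in *both* channels is
deliberate: the premise of computational PS-OCT is that polarization
contrast is inferable from intensity structure. An earlier design that
also gave cancer a globally raised background depolarization was dropped
because that signal has no intensity correlate, so no intensity-to-contrast
mapping could recover it --- the synthetic-trained classifier was being
penalized for an impossibility rather than a deficiency. This is a
simplification of breast histology justified only qualitatively (loss of
organized fibrous structure in tumours); the phantom makes no claim of
physical fidelity to any particular instrument, and it omits photon
transport, fiber-bending artifacts and cross-device effects entirely.

## Image conditioning and splits

Raw frames are margin-cropped (leading/trailing rows and columns whose
mean falls below 2% of the global maximum --- the threshold is a package
choice), center-cropped and halved into two square tiles (256x512 frames
yield two 202x202 tiles), and converted 16-to-8-bit by the global linear
map `floor(v/257 + 0.5)` (a per-image min--max mode exists as an option
without any fidelity claim). Splits follow the 8:1:1 family only:
image-based splitting gives test and validation `floor(N/10)` tiles each
--- reproducing 4,414 of 44,144 --- with the remainder training; case-based
splitting holds out one case per class and divides its tiles half/half
between test and validation. Tiles of all three channels of a frame-half
share one manifest row, so partition membership is automatically paired.

## Evaluation and downstream validation

Masked SSIM computes the local SSIM map on the full pair and averages it
over map positions whose co-registered intensity is at or above the
threshold (default 8-bit value 10). Masking after map computation means
windows may straddle the mask boundary; the alternative (zeroing
sub-threshold pixels before the map) changes window statistics and was
rejected as the default. Raising the threshold therefore never changes
map values, only which are averaged --- an invariant the suite checks.
Overlays render sub-threshold pixels as plain grayscale and blend the
jet-mapped contrast above threshold.

The downstream check trains a cancer/normal classifier twice --- once on
real contrast tiles, once on synthetic ones --- and compares ROC/AUC. The
desk-scale classifier is a reduced residual network: a convolutional stem
and four residual blocks ending at 512 channels, global average pooling
(the 512-d penultimate width of the reference 18-layer design is
preserved), and a 512x2 head. It is randomly initialized: the reference
protocol's ImageNet-pretrained weights would require a download, so the
package treats the reduced random-feature backbone as a capability
surrogate, not a fidelity claim (the full 18-layer topology is available,
and pretrained weights can be supplied explicitly). Two further surrogate
choices matter and are deliberate:

* **No normalization in the classifier backbone.** Batch statistics do
  not exist in this per-sample pipeline, and instance normalization would
  discard each tile's mean contrast level, which is the dominant
  diagnostic signal. The backbone therefore runs unnormalized.
* **Head training as a regularized linear probe.** With the backbone
  frozen, activations are extracted once, standardized with training-set
  statistics, and the head is fit by full-batch gradient descent on the
  softmax cross-entropy with an L2 penalty (default 0.05, 20 steps per
  epoch, step size 0.5); the standardization is folded back into the head
  weights afterwards so that downstream code sees plain
  `activations %*% t(W) + b`. An unregularized per-sample head on 512
  random features overfits badly at desk-scale sample sizes. The
  `trainable_scope = "all"` path keeps per-sample Adam backpropagation.

ROC curves sweep all distinct score thresholds with ties grouped; AUC is
the trapezoid integral, which the tests pin to the Mann--Whitney pairwise
statistic at $10^{-12}$. t-SNE embeds the 512-d activations with per-point
bandwidths calibrated by binary search to entropy $\log(\mathrm{perplexity})$
(tolerance $10^{-5}$, perplexity 30, auto-reduced with a warning when
$N - 1 < 3\,\mathrm{perplexity}$), early exaggeration 4 for 100
iterations, gradient descent with momentum 0.5 rising to 0.8 at iteration
250, step size 100 with adaptive gains, and a small random Gaussian
initialization.

## Desk-scale problem sizes

The package's own experiments (test suite and `scripts/acceptance.R`) use:
40x72-pixel phantom frames tiled to 32x32; a depth-3, 12-channel U-Net
with a 16-channel discriminator at learning rate $10^{-3}$ (the reference
rate $2\times10^{-5}$ with batch size 1 is appropriate for tens of
thousands of tiles, not hundreds); 200 pairs / 10--12 epochs for the
recovery benchmark; 100 frames (200 tiles) / 6 epochs x 3 paired seeds for
the ablation; and for the end-to-end check a 60-frame-per-class training
batch, a disjoint 100-frame-per-class batch for the classifiers
(6:3:1 split), 24 head epochs, and a lesion density of 5 so that the
classes are unambiguously well separated at the tile level. On these
conditions the recovery run reaches validation masked SSIM around 0.96,
DOPU synthesis evaluates visibly higher than retardation synthesis
(mirroring the noise ordering), and real- and synthetic-trained
classifiers both exceed AUC 0.95 with an absolute gap well under 0.05.

```{r, eval = FALSE}
library(polsynth)
cfg <- run_config(global_seed = 1)
out <- run_pipeline(cfg)       # simulate -> ... -> validate, resumable
out$comparison
```

## What passing these tests does and does not show

The phantom reproduces the qualitative structure of the problem ---
co-registered triplets, class-dependent birefringence and depolarization,
channel noise ordering, intensity-visible class cues --- but real tissue
has continuous histological variation, instrument-specific speckle and
polarization artifacts, and class signals that are subtler and only partly
visible in intensity. Passing the suite demonstrates that the
implementation is correct and that the method behaves as described on data
satisfying its premise; it does not demonstrate clinical performance, and
the headline numbers reported on tissue by the method's originators are
not reproducible from this package.

## Known limitations

* Single-channel (grayscale) tiles only; no multi-GPU, no mixed precision;
  training at reference scale (tens of thousands of 202x202 tiles, 50
  epochs) is far outside this pure-R implementation's intended envelope.
* The phantom's Stokes formulation is generic; no claim is made of
  fidelity to any specific Jones-matrix processing chain.
* Whether the reference pipeline computed its SSIM loss masked or
  full-tile is unknowable from the description; the loss here is
  full-tile, masking is reserved for evaluation. Aggregation of per-tile
  SSIM is per-tile-then-average rather than pooled.
* LSGAN-style objectives are offered nowhere; the adversarial loss is
  BCE-with-logits in the pix2pix lineage.
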