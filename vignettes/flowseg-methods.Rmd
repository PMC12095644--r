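---
title: "Self-supervised per-image cell segmentation: model and methods"
author: "flowseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-supervised per-image cell segmentation: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 5, fig.height = 5)
library(flowseg)
```

## The segmentation problem

High-throughput microscopy produces far more imagery - across modalities,
magnifications and cell types - than curated training sets can keep up with.
`flowseg` implements a fully automated alternative for the two-class
pixel-classification task (cell vs background): **each image trains its own
classifier**. No annotation, no pretrained weights, and no per-image
parameter adjustment are involved; a single fixed configuration is applied
to every image and all per-image adaptation happens through self-tuning.

The method rests on one statistical premise: cell interiors are textured
(organelles, cytoskeleton) while the background is comparatively smooth, so
*local entropy* is higher inside cells than outside.

## The procedure

For one image \(I\) (min-max normalized to \([0,1]\)):

1. **Surrogate motion.** Blur the image with a Gaussian of standard
   deviation \(\sigma\) (default 0.1 px) to obtain \(I_\sigma\). Blurring
   redistributes intensity wherever the image carries fine structure, and -
   like optical flow itself - conserves total intensity, so the pair
   \((I, I_\sigma)\) looks like two frames of a conservative motion.
2. **Dense optical flow.** Estimate a Farnebäck displacement field between
   \(I\) and \(I_\sigma\) (quadratic polynomial expansion, coarse-to-fine
   pyramid, iterative warping). Only the magnitude \(\|d\|\) is used: it is
   large where texture is dense and near zero over smooth background.
3. **Entropy-based self-tuning.** Candidate threshold pairs are percentiles
   of the magnitude distribution: an upper percentile \(p_c\) marks
   provisional cell pixels (\(\|d\| \ge q_{p_c}\)), a lower percentile
   \(p_b\) marks provisional background (\(\|d\| \le q_{p_b}\)). Each pair
   is scored by the difference of class-mean local entropies
   \(\bar e_{cell} - \bar e_{bg}\), and the maximizing pair is kept.
4. **Sparse self-labels.** Pixels above \(t_{cell}\) become cell seeds,
   below \(t_{bg}\) background seeds; the band in between stays unlabelled
   and is left for the classifier to decide.
5. **Per-pixel features.** Three transparent features at every labelled
   pixel: local entropy \(e\) (bits, disk window), Sobel gradient magnitude
   \(g\), and normalized intensity \(i\).
6. **Gaussian naive Bayes.** A two-class model
   \(P(c \mid x) \propto \pi_c \prod_{j \in \{e,g,i\}} \mathcal N(x_j; \mu_{cj}, \sigma^2_{cj})\)
   is fitted on the labelled rows; stratified 10-fold cross-validation
   accuracies are recorded as the validation report, and the deployed model
   is refit on all rows. Every pixel of the image is then assigned the
   argmax-posterior class (ties to background), giving the raw mask.
7. **Cleanup.** Components smaller than `min_object_area` are removed and
   interior holes filled. Optionally, touching objects are declumped by a
   marker-controlled watershed on the negated Euclidean distance transform.

Pixel-level agreement with a reference mask is summarised by
\(F_1 = TP / (TP + \tfrac12(FN + FP))\), the harmonic mean of precision and
recall; both-empty masks are scored 1 and flagged degenerate.

## Numerical choices that matter

**Normalization.** Per-image min-max over the *observed* range, not the
dtype range, so dim 16-bit frames use the full unit interval; the intensity
feature is scale-dependent, and this puts every image on a common footing.
Constant images are refused as degenerate. Normalization is idempotent.

**The blur is spectral.** `gaussian_blur()` applies the continuous Gaussian
transfer function \(\exp(-\sigma^2\omega^2/2)\) in the frequency domain of
the symmetrically mirrored image - algebraically a convolution with
reflective boundaries and exact unit DC gain, so summed intensity is
conserved to machine precision. The spectral form is essential at the
default sub-pixel sigma: a truncated 3-tap spatial kernel at
\(\sigma = 0.1\) has off-centre weights of order \(10^{-22}\), which vanish
in double arithmetic and would return the image unchanged (and hence a
degenerate all-zero flow). The continuous transfer function still
attenuates the Nyquist band by about 5% at \(\sigma = 0.1\), which is
precisely the perturbation the flow stage needs. Because the subsequent
thresholds are *percentiles* of the magnitude distribution, the pipeline is
insensitive to the absolute displacement scale, and the same configuration
works across \(\sigma \in [0.1, 2]\) and beyond.

**Ridge-regularized flow solve.** The Farnebäck normal equations
\(G d = h\) are solved per pixel with a ridge term
\(\lambda = \mathrm{reg} \cdot \overline{\mathrm{tr}\,G}\) (default
`regularization = 0.1`). The plain least-squares solve is
amplitude-invariant - faint sensor noise produces displacements as large as
strong cell texture, because numerator and denominator both scale with the
squared local amplitude - which would destroy the cell/background contrast
the self-labeller relies on. The ridge shrinks the displacement toward zero
exactly where the image has little structure, restoring the evidence
weighting: flow magnitude then behaves as "texture energy", high inside
cells, near zero over background. Windows with strong structure are
essentially unaffected. The remaining Farnebäck parameters follow common
dense-flow practice (`pyr_scale` 0.5, 3 levels, window 15, 3 iterations,
`poly_n` 5, `poly_sigma` 1.1); none of them is tuned per image.

**Entropy window.** Disk of radius 4 px, 64 intensity bins on \([0,1]\),
reflective boundaries - a standard texture-window scale. One entropy
definition serves both the self-tuning objective and the classifier
feature.

**Threshold grid.** Upper candidates \(\{80, 85, 90, 95\}\), lower
\(\{20, 30, 40, 50\}\) (percent). Percentile candidates make the tuning
scale-free across modalities and blur scales. Ties on the objective resolve
deterministically to the smallest upper percentile, then the largest lower
percentile (the most inclusive labelling). The class-*mean* entropy
difference is the default objective; a median variant is available
(`objective = "median"`). Setting \(t_{cell} = t_{bg}\) recovers a
single-threshold labelling with no unlabelled band.

**Features are read from full-image fields.** The class masks select
*where* features are sampled; entropy and gradient are always computed on
the intact image. Computing windowed texture on a zero-masked product would
contaminate every window that straddles a mask border, so the
mask-then-measure order is interpreted as bookkeeping, not as an image
operation.

**Classifier details.** Stratified folds shuffled with the configuration
seed; class-balanced subsampling to `max_train_per_class` (default 50,000)
bounds memory on megapixel images, and priors are computed after balancing
(~0.5/0.5; `empirical_priors = TRUE` switches to pre-subsample
frequencies). Variances are floored at \(10^{-9}\) because quantized 8-bit
inputs can give a class zero within-class variance. Posteriors are computed
in log space (log-prior plus summed log-Gaussians, log-sum-exp normalized):
three Gaussian factors underflow easily at extreme feature values.
Cross-validation measures model quality; the deployed model is always the
all-rows refit - no fold model is ever deployed.

**Digital topology.** Objects are 8-connected, background 4-connected (the
standard pairing that avoids connectivity paradoxes). Declump seeds are
local maxima of the distance transform within a disk footprint (radius
7 px), greedily thinned to a minimum separation of 10 px in order of
decreasing distance (raster order breaks ties), and the watershed is a
priority flood constrained to the foreground - it partitions the mask
exactly, never growing or shrinking it. Object ids are canonicalized by the
raster position of each object's first pixel, so labellings are
deterministic. Declumping is off by default: it targets non-adherent cells
and nuclei, and partitioning flat adherent sheets is out of scope.

## What the synthetic generator emulates

`generate_fixture()` builds images with the statistical structure the
method assumes, plus exact ground truth: a constant background with
additive Gaussian noise (sd 0.03), cells as smooth random shapes (ellipses,
Fourier-perturbed blobs, lobed yeast, nuclear disks) filled with correlated
speckle texture (Gaussian-filtered white noise, correlation length ~3 px,
amplitude 0.18) on top of an intensity offset (default 0.2), quantized to
the 16-bit grid. These levels were chosen once as representative of
well-exposed fluorescence imagery - texture about six times the noise
floor - and give an entropy contrast comfortably above half a bit. The
standard suite (`generate_suite()`) fixes 20 sparse-cell 512×512 images
spanning cell-area fractions of roughly 6-33%, five texture-only images
with zero mean-intensity contrast - the measured cell/background gap sits
below the noise sd (the "invisible by eye" regime), touching-disk and three-lobed yeast declumping
fixtures, and nuclear-disk images. Those sizes keep a full suite run in the
low minutes on one CPU while still exercising pyramid levels, windowed
statistics and cleanup at realistic scales.

The generator deliberately omits: PSF convolution and modality-specific
rendering (DIC shear, IRM interference), uneven illumination, annotation
noise (truth is exact by construction), and dense adherent sheets. Passing
tests therefore demonstrate that the algorithm recovers objects whose
texture statistics match its premise - they do not certify performance on
real micrographs, where illumination structure and out-of-focus light add
failure modes the fixtures do not model.

**Boundary halo.** Every windowed quantity (entropy radius 4, flow window
15) smears object evidence a few pixels past the true boundary, and the
cell's own step edge is itself a strong flow source. Consequently the
high-magnitude self-labels concentrate *inside cells and within about half
a flow-integration window (~7 px) of their boundary*: measured against
exact ground truth their pixel-precision is modest, while at that boundary
tolerance - the natural yardstick when reference masks are hand-drawn
outlines - they are highly precise, and the test suite asserts exactly
that. The same tolerance applies to the
"classifier agrees with its seeds" property. The final masks inherit a
halo of 1-2 px, visible as near-unity recall with slightly lower precision
on the fixtures.

## Batch semantics

`run_batch()` freezes one configuration - blur sigma, flow parameters,
threshold candidate grid, entropy window, seed, i.e. the initial
self-tuning values - for an entire experiment and applies it to every
image. Threshold *selection* and classifier *training* remain per-image, so
each image keeps its uniquely associated model. Failures are isolated per
image and reported with the failing stage. A batch run is bit-identical to
the corresponding sequence of single runs under the same configuration.

## A small worked example

```{r example}
fx <- generate_fixture(fixture_spec(seed = 3, size = c(192, 192), n_cells = 3,
                                    radius_range = c(20, 30)))
fit <- flowseg(fx$image, flowseg_config(min_object_area = 16))
fit
confusion_counts(fitted(fit), fx$mask)
coef(fit)
```

```{r plot}
plot(fit)
```

## Known limitations

* Adherent-cell declumping is explicitly out of scope; the watershed is
  validated on near-convex shapes (disks, yeast lobes, nuclei).
* Multi-channel images are segmented one channel at a time; masks are
  combined downstream by the caller, never merged silently.
* Cross-image prediction (`predict(fit, newimage = ...)`) is provided as a
  diagnostic only - the method's premise is one model per image.
* The flow contract is dense, deterministic displacement between an image
  and its blur; it is not a general-purpose optical-flow implementation
  (no occlusion handling, no large-displacement robustness).
* Proprietary microscope containers (ND2, CZI, LIF) and OME-XML metadata
  are not read; convert to TIFF/PNG first.
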