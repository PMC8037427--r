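---
title: "Registering thermal and visible foot images: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Registering thermal and visible foot images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(footreg)
```

## The problem

A dual-camera rig for diabetic-foot screening pairs a visible-spectrum
camera (1280 × 720 pixels) with a much coarser thermal camera (384 × 288).
The cameras have different fields of view and sit a few centimetres apart,
so the plantar region occupies different pixel coordinates in each image.
Contralateral temperature comparison — the clinical signal — requires a
per-pixel correspondence between the two frames. Because thermal and
visible intensities are essentially uncorrelated on skin, registration
works either through a dual-spectrum calibration target (visible blobs with
a cold-contrast signature) or through segmentations of the feet themselves.

`footreg` implements the four estimators that span the practical
transform-model hierarchy (translation+fixed scale, rigid, affine, full
homography), the STAPLE fusion that builds reference segmentations from
multiple imperfect raters, the overlap metrics used to score a
registration, and a synthetic scene generator that stands in for the
(private, clinical) image data such rigs produce.

## The synthetic rig

The generator emulates a fronto-parallel scene plane at working distance
$d$ mm. Each camera maps plane coordinates (mm) to pixels through an
angular model: a point at lateral offset $X$ subtends $\approx X/d$
radians, so pixels-per-mm is $K/d$ with $K = \text{width}_{px} /
\text{hfov}_{rad}$, the camera shifted laterally by its baseline. Two
consequences are deliberate:

* image scale is inversely proportional to distance, with scale exactly 1
  relative to the focal plane at $d = 800$ mm;
* the visible-to-thermal transform has a **distance-independent** linear
  part (the ratio of angular resolutions — exactly what the GOT scaling
  step computes) while its translation varies with $1/d$ through the
  baseline. A transform calibrated at 800 mm therefore mis-translates by
  about 1 px at 760 or 850 mm, which is what makes the distance-robustness
  experiment non-trivial.

This is an invented geometry consistent with the registration problem, not
an optics model: there is no lens distortion, no depth structure, no
radiometry. Defaults (65°/50° horizontal FOVs, 40 mm baseline, 40°/38°
vertical FOVs, a 440 × 330 mm scene with two roughly 100 × 240 mm soles)
were chosen once so that the translation-induced Dice degradation away
from the focal plane spans roughly 0.96–0.99 — the regime such rigs show
in practice. Scene images are the mask at two grey levels plus Gaussian
noise with σ = 2% of the dynamic range; checkerboard keypoints carry
i.i.d. Gaussian jitter of σ = 0.3 px in the thermal view.

Coordinates everywhere are 0-based pixel centers, x rightward along
columns, y downward along rows. Mask warping uses inverse mapping with
nearest-neighbour interpolation (binariness is preserved exactly);
intensity images use bilinear interpolation. Rotation/affine centers sit at
the image center, stored explicitly while matrices remain in the absolute
pixel frame. The package fixes the estimation direction visible → thermal
throughout; the thermal frame is the scoring frame.

## The estimators and their tunables

**GOT.** Scale by the angular-resolution ratio, translate by the
component-wise **median** keypoint offset (robust to a stray
correspondence), crop to the thermal frame. No tunables.

**Homography.** Hartley-normalized DLT (centroid at origin, mean distance
$\sqrt 2$, SVD null vector) inside RANSAC: 2000 iterations, symmetric
transfer error threshold 2 px, minimum consensus 8, explicit seed. The DLT
is exact (≤ 1e−8) on noiseless inputs; the consensus threshold of 2 px is
~6σ of the default keypoint jitter, so true inliers are essentially never
rejected while gross mismatches (tens of px) never enter.

**ICP.** Contours are the morphological gradient (mask minus its 3 × 3
erosion), traced into ordered closed loops (Moore neighbour tracing) and
resampled at equal arc steps, allocated across contours in proportion to
perimeter. The default of **400 keypoints** keeps arc spacing near 3 px on
a 384 × 288 sole pair; sparser sampling (e.g. 200 points, ~6 px spacing)
measurably biases the recovered translation by up to ~0.6 px through
nearest-neighbour quantization, so the denser default is used. Iterations
alternate exact nearest-neighbour correspondence (ties to the smallest
target index) with the closed-form SVD rigid fit (determinant-corrected
against reflections) about the thermal image center, after a centroid
pre-alignment. The RMSE over matched pairs is non-increasing by
construction; iteration stops when it changes by less than 1e−6.

**Affine-ASGD.** The cost is the mean squared difference between the
Gaussian-smoothed fixed mask and the smoothed moving mask warped by the
current transform, sampled at 2048 fresh uniform random coordinates per
iteration, over a 3-level pyramid (500 iterations per level). Smoothing is
σ = 2 px in the fixed frame at every level, with the moving image's σ
widened by the inverse of the initial scale so both boundary profiles have
the same physical width. The step size follows the adaptive schedule
$\gamma_k = a/(A + t_k)^\alpha$ with $a = 600$, $A = 20$, $\alpha = 1$: the
"time" $t_k$ moves by a bounded sigmoid of the negative normalized inner
product of successive gradients, so steps stay large while gradients agree
and shrink under disagreement. Two implementation choices matter for
convergence and are easy to get wrong:

* each pyramid level is smoothed at its own scale (smoothing once at full
  resolution and then downsampling leaves coarse levels too sharp to pull
  in a 20 px initial offset);
* the six parameters are expressed as a perturbation centered on the
  initializer's image of the fixed-frame center and scaled by the mask
  radius, so a unit change in any parameter moves boundary points by about
  one pixel — otherwise the matrix and translation parameters couple into
  an ill-conditioned valley and SGD crawls.

When moving and fixed frames differ in resolution the fit needs an
initializer with roughly the right scale (the angular scaling plus
image-center alignment is enough; a fully misaligned start has zero cost
gradient and is rejected with advice to pre-align).

## STAPLE

With rater decisions $D_{ij}$ and foreground prior $\pi$, the E-step
computes the posterior $W_i = a_i/(a_i + b_i)$ with $a_i = \pi \prod_j
p_j^{D_{ij}}(1-p_j)^{1-D_{ij}}$ and $b_i = (1-\pi) \prod_j
(1-q_j)^{D_{ij}} q_j^{1-D_{ij}}$; the M-step re-estimates each rater's
sensitivity $p_j$ and specificity $q_j$ from $W$. Products are accumulated
in log space, parameters start at 0.9999, the prior defaults to the mean
foreground fraction across raters, convergence is 1e−6 on the largest
parameter change (cap 100 iterations), and the observed-data
log-likelihood is tracked (it is non-decreasing up to the 1e−6 boundary
clamp applied to degenerate all-0/all-1 raters). The consensus mask is
$W \ge 0.5$, ties included; 0.5 is this package's documented choice.

Raters are emulated as per-pixel Bernoulli processes, which is the right
model for testing STAPLE's estimator (parameter recovery to ±0.02 with
five raters on a 128² truth) but the wrong small-scale texture for human
segmentations: i.i.d. errors produce isolated specks and pinholes, whereas
human raters are spatially coherent and err almost only along boundaries.
The pipeline therefore (a) defaults the simulated raters to expert-level
accuracy (sensitivities 0.995/0.99, specificities 0.9995/0.999) and (b)
applies a one-pixel morphological opening + closing (`clean_binary_mask`)
to the fused consensus before it is used as a registration reference —
without it, speckle dominates the overlap scores and contour extraction.
Passing tests with cleaned Bernoulli raters shows the pipeline tolerates
pixel-level rater noise; it does not certify behaviour under structured
human disagreement (e.g. systematically different toe boundaries).

## Metrics and the distance experiment

With TP/FN/FP pixel counts against the thermal reference: Dice
$2TP/(2TP+FN+FP)$, Jaccard $TP/(TP+FN+FP)$, volume similarity
$2(|test|-|ref|)/(|test|+|ref|)$ (signed, test-minus-ref), and FN/FP
fractions normalized by the **reference volume**. The latter is an
interpretation: overlap studies on this kind of data report FN/FP values
of a few percent, which background-normalized specificity cannot produce
(the background is ~10× larger than the feet), so the reference-volume
normalization is used and documented. The registered visible mask is
always resampled into the 384 × 288 thermal frame before scoring.

`run_distance_experiment` estimates each method once from focal-plane data
— GOT/homography from the checkerboard, ICP/ASGD from the fused masks —
then applies those fixed transforms at every distance. On the default rig
all four methods peak at 800 mm and degrade monotonically toward 760 and
850 mm while staying above Dice 0.95, mirroring the qualitative field
behaviour; the exact values are properties of this synthetic rig, not of
any physical camera pair.

## Problem sizes and numerical conventions

The test suite and acceptance script run the generator at its native sizes
(1280 × 720 visible, 384 × 288 thermal, six distances, 5 × 5 checkerboard,
two raters) — the full study configuration; only ancillary determinism
checks use reduced variants. Tie-breaks are fixed everywhere (sync pairs:
smallest |Δt|, then earliest first-stream then second-stream timestamp;
NN correspondence: smallest target index; consensus threshold: ≥).
Homogeneous transforms are normalized so the bottom-right entry is 1;
transforms with a vanishing homogeneous coordinate at a requested point
raise an error naming the point. All stochastic components take explicit
seeds and restore the caller's RNG state.

## Limitations

* The rig geometry is a similarity emulation: no lens distortion, no
  perspective foreshortening (the homography's extra degrees of freedom are
  never *required* by the synthetic scenes), no depth channel.
* No radiometric modelling: "thermal" images are masks plus noise.
* Bernoulli raters, as discussed, under-model structured human
  disagreement.
* Registration is planar and static; online registration on raw
  multispectral intensities and deformable models are out of scope.
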