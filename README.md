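# footreg

Registration and evaluation of thermal-infrared and visible images of feet,
for camera rigs used in remote monitoring of the diabetic foot.

Screening for diabetic foot ulcers compares plantar temperature patterns
between contralateral sites. A practical low-cost rig pairs an RGB(-D)
camera (1280 × 720) with a microbolometer thermal camera (384 × 288). The
two sensors differ in resolution, field of view and mounting position, so
their images are not aligned: every downstream temperature analysis first
needs a spatial transform carrying visible-image coordinates into the
thermal frame. `footreg` implements and evaluates the four standard ways of
estimating that transform, together with the reference-segmentation
machinery needed to score them, and a synthetic two-camera scene generator
so the whole pipeline is testable without hardware or patient data.

## Methods

Writing x for a pixel coordinate and c for the image center, the four
transform models are

* **GOT** (geometric optical translation): `T(x) = S x + t`, where the
  fixed diagonal scaling S equalizes the two cameras' angular resolutions
  (degrees per pixel) and the translation t is the component-wise median
  offset of paired checkerboard keypoints; a crop re-expresses the result
  in the thermal frame.
* **Homography**: `T(x) = H x` (homogeneous, 8 free parameters), estimated
  from checkerboard keypoint pairs by the Hartley-normalized direct linear
  transform inside a RANSAC consensus loop (minimal 4-point samples,
  symmetric transfer error threshold).
* **ICP**: rigid motion `T(x) = R(x − c) + t + c` with proper orthonormal
  R, fitted by iterative closest point on keypoints sampled at equal arc
  steps along the segmentation-mask contours; resolution differences are
  absorbed by the fixed angular scaling, correspondence is exact nearest
  neighbour, and each iteration's rigid update is the closed-form
  cross-covariance SVD solution. The point-pair RMSE is non-increasing.
* **Affine-ASGD**: `T(x) = A(x − c) + t + c` (6 free parameters), estimated
  by adaptive stochastic gradient descent on the mean squared difference of
  Gaussian-smoothed masks over a coarse-to-fine pyramid, with the
  self-tuning gain `γ_k = a/(A + t_k)^α`.

Reference segmentations come from **STAPLE**: an EM algorithm that fuses
several raters' binary masks into a posterior foreground probability map W
while estimating each rater's sensitivity p_j and specificity q_j.
Registered masks are scored against the thermal reference with the **Dice**
coefficient `2|A∩B|/(|A|+|B|)`, the **Jaccard** index `|A∩B|/|A∪B|`
(related by `D = 2J/(1+J)`), signed volume similarity, and false-negative /
false-positive fractions.

The robustness experiment estimates every transform once at the rig's
focal-plane distance (800 mm) and applies it unchanged to scenes at
760–850 mm, quantifying how registration degrades away from the
calibration plane.

## Worked example

```r
library(footreg)
rig <- default_rig()                                   # 1280x720/65° + 384x288/50°, 800 mm focal plane
bundle <- make_scene_bundle(rig, distance_mm = 800, seed = 42)
fit <- register_images("icp", moving = bundle$visible_mask,
                       fixed = bundle$thermal_mask, rig = rig)
print(fit)
#> Registration fit, method: icp
#> <transform2d> model: affine
#>          [,1]      [,2]       [,3]
#> [1,] 0.390000 -0.000532 -79.719342
#> [2,] 0.000493  0.421052  -8.038535
#> [3,] 0.000000  0.000000   1.000000
#> final contour RMSE: 0.6626 px (9 iterations, converged)

warped <- predict(fit, bundle$visible_mask)
overlap_metrics(warped, bundle$thermal_mask)
#> dice 0.9949  jaccard 0.9899  vol.sim +0.0012  fn 0.0045  fp 0.0057
```

The fitted matrix maps visible pixels into the thermal frame: the ~0.39 and
~0.42 diagonal entries are the two cameras' angular-resolution ratios per
axis, and the translation column carries the baseline-induced offset. A
Dice coefficient of 0.995 means the registered visible sole segmentation
and the thermal reference overlap almost perfectly.

The full experiment — synchronization, checkerboard calibration, STAPLE
fusion of simulated raters, all four estimators, all six distances — is one
call:

```r
res <- run_pipeline(pipeline_config(seed = 1))
robustness_wide(res$table, "dice")
#>   distance_mm   asgd    got homography    icp
#> 1         760 0.9738 0.9714     0.9745 0.9738
#> 2         780 0.9849 0.9843     0.9854 0.9855
#> 3         800 0.9926 0.9935     0.9918 0.9918
#> 4         820 0.9865 0.9883     0.9857 0.9850
#> 5         835 0.9776 0.9789     0.9772 0.9766
#> 6         850 0.9685 0.9703     0.9677 0.9659
```

Every method peaks at the 800 mm focal plane and degrades monotonically
away from it, staying above Dice 0.95 across the ±50 mm working range —
the qualitative behaviour expected of a fixed-transform registration on
this kind of rig.

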