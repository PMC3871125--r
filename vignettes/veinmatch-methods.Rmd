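---
title: "Finger-vein verification: models, parameters and design choices"
author: "veinmatch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finger-vein verification: models, parameters and design choices}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(veinmatch)
```

# The verification problem

A finger-vein verification system decides whether a *probe* image and an
enrolled *gallery* image show the same finger.  Near-infrared transmission
imaging renders subcutaneous veins as dark curvilinear valleys on a bright,
unevenly lit background.  `veinmatch` implements a multi-feature pipeline:

1. **Enhancement** — per-pixel *maximum difference curvature* turns the
   grayscale image into a vesselness map.
2. **Templates** — the map is binarized into a *vein shape template*, and an
   8-level *orientation template* codes the direction of maximal curvature
   difference at each vein pixel.
3. **Keypoint matching** — scale-invariant (DoG/128-descriptor) keypoints on
   the grayscale image are matched gallery-to-probe; implausible matches are
   removed by their image-plane distance, and the mean retained descriptor
   distance is the first matcher score.
4. **Sub-region matching** — windows centered on the retained keypoints are
   compared between the two shape (and orientation) templates by an
   exhaustive translation search, giving two more scores.
5. **Fusion and evaluation** — the three distances are z-score normalized
   and fused (weighted sum or RBF C-SVC); FAR/FRR/ROC and the equal error
   rate summarize performance.

# The enhancement model

For a pixel and a direction $\theta$, let $P(z)$ be the intensity profile
sampled through the pixel at unit arc-length spacing.  Its curvature at the
center is

$$K = \frac{|P''|}{\{1 + P'^2\}^{3/2}}.$$

Directions are quantized to $\theta_j = (j-1)\pi/8$, $j = 1..8$, grouped
into orthogonal pairs $G_j = \{j, j+4\}$.  The signed group differences

$$\Delta K_j = K_j - K_{j \pm 4}$$

are large when a pixel lies on a line-like valley (large curvature across,
small along), near zero on flat regions, and near zero on isotropic blobs
(both curvatures large but equal).  The enhancement value is
$D_{\max} = \max_j \Delta K_j \ge 0$, and the orientation code is the
arg-max $j$ (smallest $j$ on ties) — the *cross-sectional* direction, i.e.
perpendicular to the vessel tangent.

**Discretization** (not specified by the method's sources; chosen here):
$P'$ and $P''$ are 3-point central differences at the profile center at
unit spacing; oblique profiles are sampled by bilinear interpolation with
coordinates reflected at the image border.  The profile halfwidth `r`
(default 4) bounds the sampled profile and validates the image size;
widening the derivative stencil instead was examined and rejected — it
pushes the convex-flank response (below) further out without removing it.
Curvature is computed on the `[0, 1]` intensity scale, where the $P'^2$
term is negligible; the formula is scale-dependent, but on the 8-bit scale
the denominator suppresses the vessel walls along with everything else and
destroys the band structure.

## Binarization and the flank halo

A Gaussian valley of scale $\sigma$ has $|P''|$ response with a central
peak, a null at the inflection $|z| = \sigma$, and a *convex-flank halo*
peaking at $2e^{-3/2} \approx 0.446$ of the center response around
$|z| = \sqrt{3}\sigma$, outside the vessel.  Consequences:

* Any global threshold low enough to capture the full vein band also
  admits the halo; `binarize(map, "otsu")` (the default) lands below the
  halo on realistic images and over-segments by roughly the halo area.
* `binarize(map, "half_max")` cuts at half the robust maximum
  (99.9th percentile), which excludes the halo *by construction* and keeps
  the half-maximum response band — consistent with the FWHM width
  convention.  It is the tighter rule on clean, isolated vessels, but
  fragile when vessel crossings inflate the map's tail.

With vessels of 2x varying width this geometry caps the whole-mask Dice
overlap against the true lumen at roughly 0.55–0.6 for *any* global
threshold (per isolated vessel ~0.7): thin-vessel halos outrank wide-vessel
centers unless the dip depth scales with width, and even then the response
null sits at the lumen edge.  The enhancement is a *verification* feature,
not a validated segmenter; the package's acceptance suite states a 0.7
Dice bar and reports it honestly as failing, with this analysis as the
explanation.  Verification accuracy is unaffected — both acquisitions pass
through the same distortion, and the matcher compares templates with each
other, not with the anatomy.

# Keypoint matching

Keypoints follow the standard construction: a Gaussian scale-space pyramid
(3 layers/octave, $\sigma_0 = 1.6$, optional 2x upsampling),
difference-of-Gaussian extrema with sub-pixel refinement, contrast and
principal-curvature-ratio rejection, orientation assignment from a smoothed
36-bin gradient histogram, and the 4x4x8 = 128-element descriptor,
L2-normalized with 0.2 clipping.  Everything is deterministic.

Two parameters matter for vein images:

* **Contrast threshold** — vein images are smooth and low-contrast; the
  0.04 gate customary for photographs leaves almost no keypoints.  The
  pipeline default is 0.005, restoring the tens-of-keypoints regime that
  the retention rule below presumes.  `detect_keypoints()` itself keeps
  the conventional 0.04 default.
* **Retention threshold `T` = 20** — after matching every gallery
  descriptor to its Euclidean-nearest probe descriptor, the $k =
  \min(T, m)$ pairs with the smallest *image-plane* distances are retained
  and the rest discarded as mismatches.  This geometric filter *replaces*
  the closest/second-closest ratio test, which discriminates poorly on
  smooth imagery; the ratio test remains available
  (`lowe_ratio_filter()`, conventional $c = 0.8$) as a baseline.  Ties at
  the cut break by smaller descriptor distance, then input order.

An image without keypoints (e.g. constant) is a *no-match*: `score_pair()`
returns `NA` scores and the CLI exits with a dedicated status, never a
crash.

# Sub-region matching

Each retained keypoint anchors one sub-region per template: gallery windows
are strictly larger than probe windows (shape 120x60 vs 110x50 px,
orientation 60x40 vs 50x30), so the probe window slides over all
non-negative integer offsets inside the gallery window; the score
$\Psi \in [0,1]$ is the minimum mismatch fraction and the template score is
the mean over the $k$ regions.  Choices:

* Windows anchor the keypoint at 0-based index $\lfloor \text{size}/2
  \rfloor$ and are zero-padded at template borders, keeping Eq.-style
  fixed sizes for edge keypoints.
* The mismatch indicator is $|P_1 - P_2| = 1$ for binary shape pixels and
  $P_1 \neq P_2$ for orientation codes; two background pixels (code 0)
  agree by default.  `exclude_background = TRUE` instead drops
  background–background pairs from the denominator — exposed because
  background dominance can flatten scores, but the literal rule is the
  default.
* Only non-negative offsets are searched; symmetry comes from the larger,
  centered gallery window, and the asymmetric (gallery, probe) roles are
  kept even in symmetric evaluations.

The search is exact (exhaustive), implemented in C++ with an early-abort
per offset; with $k \le 20$ regions a full comparison costs ~7 ms.

# Score fusion

Scores are z-normalized with training-set statistics, $z' = (z - u)/\sigma$
with the *population* standard deviation (`sample_sd = TRUE` for the
$n-1$ convention).  Two fusers:

* **Weighted sum** $z_f = \sum w_i z_i'$, $\sum w_i = 1$; defaults
  (sift 0.1, shape 0.7, orientation 0.2) are the combined-finger operating
  point reported for this pipeline family.
* **RBF C-SVC** on labeled score triplets (+1 genuine, −1 imposter),
  $\gamma = 0.006$, $C = 1.2$.  No SVM implementation is available in the
  target environment, so the package ships a sequential-minimal-
  optimization solver (maximal-violating-pair selection, Keerthi
  $b_{low}/b_{up}$ stopping rule); it reproduces an independent C-SVC
  solver's decision values to ~1e-3 on fixed problems.  Decision values
  are negated in `fuse()` so that *lower = more genuine* holds for every
  score in the package.

Evaluation splits genuine and imposter scores in half (train/test), fits
normalization and fusion on the training half only, and repeats 20 times
with seeded splits; reports are mean ± sd of EER and GAR at a configured
FAR.

# Evaluation protocol

Genuine comparisons are all unordered within-class sample pairs
($n \cdot \binom{m}{2}$); imposter comparisons take, for every unordered
class pair, all ordered sample products over a designated subset of $s$
samples per class ($\binom{n}{2} s^2$) — the subset mirrors protocols
where only the test half of each class enters the imposter set.  With
142 classes x 10 samples and $s = 5$ this yields 6,390 and 250,275
comparisons; with 85 classes x 4 samples and $s = 4$, 510 and 57,120.

Scores are accepted when at most the threshold.  FAR/FRR are evaluated at
every observed score value, which makes the EER invariant under strictly
monotone transforms; the EER interpolates linearly between the two
thresholds bracketing the FAR = FRR crossing (the crossing rule is not
prescribed by the sources; exact ties average the two rates).

# The synthetic phantom world

No public finger-vein database can be bundled, so every stage is exercised
on synthetic phantoms with per-pixel ground truth:

* **Canvas** 221x83 px — a typical cropped finger region, exercising the
  stated sub-region sizes.
* **Vessels** — 3 per image; centerlines are random natural cubic splines
  spanning the canvas lengthwise (veins run along the finger, giving the
  orientation field the encoder assumes); nominal widths are uniform in
  5–10 px.
* **Cross-profile** — a Gaussian dip whose FWHM equals the nominal width,
  so the ground-truth mask (within half-width of the centerline) is
  exactly the half-depth region.  Dip depth is `contrast * width / 10`
  (reference depth 0.25): Beer–Lambert absorption grows with the optical
  path, i.e. the vessel diameter.
* **Illumination and noise** — background 0.6 with a 0.1 left-to-right
  gradient; i.i.d. Gaussian sensor noise (sd 0.02) added per acquisition.
* **Genuine pairs** — a second acquisition of the same finger is the
  phantom warped by a global translation (±4 px), rotation (±0.05 rad,
  within the ±π/8 budget of an 8-level orientation code), a smooth elastic
  field (1.5 px amplitude, 10 px correlation length) emulating local skin
  distortion, plus *fresh* sensor noise.  Masks and tangent maps are
  warped consistently (tangents shift by the rotation, mod π).

Everything is deterministic given the seed, and the dataset generator
derives per-class and per-sample seeds from one master seed.

**What the phantom does not model:** skin scattering and optical blur
(vein restoration is out of scope), finger-boundary geometry and ROI
detection, anatomically correlated vessel trees, or sensor fixed-pattern
artifacts.  A green end-to-end test therefore establishes that the
pipeline separates same-source from different-source vascular patterns
under realistic nuisance transforms — not that it reaches any particular
accuracy on real NIR databases, whose absolute EERs depend on data the
package cannot ship.  Phantom EERs (~0.1–0.25 per feature at these
settings) are in-world quantities; the qualitative orderings (shape
strongest single feature on templates, fusion at least as good as the
best single feature) are the meaningful outcomes, and both are asserted
in the test suite.

# Numerical choices and degenerate inputs

* Convolution and profile sampling reflect coordinates at borders (no dark
  frame that could masquerade as a vessel).
* The 5x5, σ=3 smoothing kernel is normalized *after* truncation; the
  effective smoothing is much milder (sd ≈ 1.4 px) than an untruncated
  σ=3 Gaussian — intentional, as it matches the stated filter exactly.
* All arg-max ties (orientation codes, geometric filter cut, translation
  search) break deterministically toward the smallest index/offset.
* Zero-keypoint images, empty score sets, single-class SVM training sets,
  zero-variance features and out-of-frame warps raise informative errors
  or dedicated no-match signals rather than propagating NaNs.
* Seeds are plain 32-bit integers; every stochastic step (phantom
  geometry, noise, dataset splits) flows from one user-supplied master
  seed.

# Known limitations

* The segmentation-overlap ceiling of the verbatim enhancement against an
  FWHM lumen mask (analysis above); the 0.7 Dice acceptance bar stays red.
* Otsu on the enhancement map sits in the dense noise-response region of
  the histogram, so template speckle differs between acquisitions and
  keeps genuine shape scores visibly above zero (~0.15–0.2 here); the
  sub-region search still aligns the stable vein structure.
* The SMO solver materializes the kernel matrix: fine for fusion-scale
  problems (thousands of points), unsuitable for large-scale SVM use.
* `load_image()` reads PGM natively and PNG via the optional `png`
  package; BMP/TIFF are not supported in this environment.
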