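---
title: "Identifying vascular segments in intraoperative 3D contrast-enhanced ultrasound"
author: "VesselTrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying vascular segments in intraoperative 3D contrast-enhanced ultrasound}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(VesselTrace)
```

## The problem

During brain tumor resection the brain deforms — craniotomy, fluid loss
and the resection itself shift tissue by millimetres ("brain shift") —
so the preoperative MR volume registered to the patient's head at the
start of surgery progressively stops matching reality. Intraoperative 3D
contrast-enhanced ultrasound (iCEUS) shows the current state, but the
volumes are noisy, have a small field of view, and after resection are
hard to interpret. Small blood vessels near the tumor are visible in
both modalities (the contrast agent brightens them in T1 MR and in
CEUS), which makes them natural landmarks: if a vascular segment
selected in the preoperative volume can be found again in the
intraoperative volumes, the rigid transform between the two positions
estimates the local brain shift.

VesselTrace implements that workflow for volumes with voxel spacing on
the order of 1 mm and vessels of diameter below 2 mm:

1. the user delineates a box (`RoiBox`) around a vessel in the
   preoperative contrast T1 MR volume;
2. the vessel is enhanced (multiscale Hessian vesselness) and extracted
   (Otsu threshold) inside the box;
3. a search region with twice the box volume, centered on the same
   position, is built in the pre-resection iCEUS volume, segmented the
   same way, and the pattern is located by 6-DOF rigid registration
   under one of three similarity measures;
4. the located region becomes the new pattern and is located again in
   the post-resection iCEUS volume;
5. results are scored with the Dice similarity index and the Hausdorff
   distance.

A rigid model is a deliberate choice: the goal is to *identify the
position* of a short, locally rigid vascular segment, not to recover the
full nonrigid deformation field.

## Vessel enhancement

The enhancement filter is the classical bright-tube measure built from
the eigenvalues of the scale-space Hessian. The volume is smoothed with
a Gaussian of standard deviation $\sigma$ (in mm; kernels are scaled per
axis by the voxel spacing, so anisotropic grids are handled in world
units), and the Hessian $H_\sigma = \nabla^2 I_\sigma$ is formed by
central differences, in intensity/mm$^2$. With eigenvalues sorted
$\lambda_1 \ge \lambda_2 \ge \lambda_3$ and
$\lambda_c = \min(-\lambda_2, -\lambda_3)$, the per-scale response is

$$
v(\sigma) = \begin{cases}
0 & \lambda_c \le 0\\[2pt]
\exp\!\left(-\dfrac{\lambda_1^2}{2(\alpha_1\lambda_c)^2}\right)\lambda_c
  & \lambda_1 \le 0,\ \lambda_c > 0\\[8pt]
\exp\!\left(-\dfrac{\lambda_1^2}{2(\alpha_2\lambda_c)^2}\right)\lambda_c
  & \lambda_1 > 0,\ \lambda_c > 0
\end{cases}
$$

with $\alpha_1 = 0.5 < \alpha_2 = 2$, and the multiscale image keeps the
per-voxel maximum over the scale list. A bright tube has
$\lambda_1 \approx 0$ with $\lambda_2, \lambda_3$ strongly negative, so
$\lambda_c$ is large and the exponential penalty small; blob-like or
plate-like structures are damped.

Numerical choices worth knowing:

* **Negative responses.** The printed formula only distinguishes
  $\lambda_c = 0$ from $\lambda_c \ne 0$, but $\lambda_c < 0$ (a dark
  tube or a bright plate edge) would produce negative responses and an
  ill-posed threshold. Voxels with $\lambda_c < 0$ are set to zero, so
  the vesselness image is non-negative everywhere.
* **No scale normalization.** The second derivatives are *not*
  multiplied by $\sigma^2$ across scales; responses at different
  $\sigma$ are compared raw, faithful to the formulation implemented.
  The consequence — a genuine limitation — is that the raw response
  decays with $\sigma$ for every tube radius, so the arg-max scale does
  not identify the vessel radius. What survives is a relative property:
  thicker tubes retain proportionally more response at coarse scales,
  and detection is unaffected because the fine scales dominate the
  maximum for all sub-2 mm vessels. The default scale list
  $\{0.5, 1, 1.5, 2\}$ mm covers that target range at 1 mm voxels.
* **Eigenvalues** are computed by the closed-form trigonometric solution
  for symmetric $3\times 3$ matrices, vectorized over voxels, and are
  verified against a dense eigensolver in the test suite.
* **Boundaries.** All convolutions use symmetric (reflect) padding;
  finite differences clamp at the border.

## Vessel extraction

The vesselness image *of the region of interest* (never a whole-head
volume — the surrounding anatomy would dominate the histogram) is
thresholded with Otsu's method on a 256-bin histogram, applied as a
strict `>`. When the between-class variance is flat across an empty gap
between two well-separated modes, the middle edge of the maximizing
plateau is returned, which places the threshold mid-gap rather than
against the lower mode. An optional cleanup keeps only the largest
26-connected component; it is applied to the *pattern* mask (speckle
islands there would distort the registration target) but never to the
search-region mask, where the largest structure need not be the target
vessel — after resection, the bright cavity rim often is the largest
structure, and pruning to it would delete the vessel being sought.

## Similarity measures

Three measures are implemented. For same-grid volumes $X$ (fixed) and
$Y$ (moving):

* **NCC** — mean-centered correlation
  $\frac{1}{N\sigma_x\sigma_y}\sum_i (x_i-\bar x)(y_i - \bar y)$, in
  $[-1, 1]$. The $1/N$ factor (with population standard deviations) is
  included so the score is scale-free; a bare sum would grow with the
  region size.
* **NMI** — $(H(X)+H(Y))/H(X,Y)$ from a $32\times 32$ joint histogram
  (base-2 entropies, each image binned over its own range), in $[1, 2]$.
* **NGF** — gradient directions compared through the regularized
  normalized gradient field
  $n(I,x) = \nabla I / \sqrt{\|\nabla I\|^2 + \varepsilon^2}$, with the
  cross-product distance $d_c = \|n(X,x)\times n(Y,x)\|^2$ (minimized at
  alignment) and the dot-product form $d_d = \langle n(X,x), n(Y,x)
  \rangle^2$ as its complement ($d_c + d_d = 1$ wherever both fields are
  unit). $\varepsilon$ defaults to 1% of the fixed image's intensity
  range: gradients well above it behave as unit vectors, gradients far
  below (noise) are damped toward zero.

The measures see, by default, the vesselness image restricted to the
segmented support (`inputMode = "vesselness"`); a pure-binary mode
(`inputMode = "binary"`) is available and exercised in the tests. The
registration *optimizer* for NGF minimizes $\mathrm{mean}(1 - d_d)$
rather than $\mathrm{mean}(d_c)$: the two are identical on unit-gradient
voxels, but on voxels where either field vanishes $d_c$ is zero — which
would make an empty, structureless overlap look perfectly aligned —
whereas $1 - d_d$ charges such voxels the full cost. The exported
`ngfDistance()` computes the cross form as defined; the substitution is
confined to the optimization objective.

## Registration

`registerRigid()` is a two-stage optimizer:

1. **Translation scan.** Every integer voxel offset that keeps at least
   half the pattern inside the search region per axis (and a quarter of
   its volume overall) is scored. The candidate moving image is the
   search content on the full pattern grid with out-of-region voxels set
   to background 0, so partial overlaps are charged for the pattern
   structure they fail to explain — except for the intensity measures
   (NCC, NMI), which are evaluated on the common support only: padding
   the joint intensity sample with a constant would manufacture
   spurious correlation and mutual information. NCC and NMI are cheap
   per offset and their optima can be arbitrarily narrow (an exact
   match in textured data), so they are scanned exhaustively. The NGF
   objective is costlier per offset but smooth on segmented structures,
   so for offset spaces above ~1500 candidates it uses a stride-2
   coarse pass followed by stride-1 passes around the best few coarse
   candidates. Exact score ties are broken toward the smallest
   translation norm, then lexicographically.
2. **Refinement.** Nelder–Mead over all six parameters (translation in
   mm, Euler angles in degrees, bounded at ±15° — craniotomy geometry
   makes larger rotations implausible) starting from the best scanned
   offset, with the *same* objective evaluated through trilinear
   resampling. Because scan and refinement share one objective, the
   refined score can never be worse than the scan optimum, and the
   reported score is reproducible by re-evaluating the objective at the
   returned transform.

Scanning beyond the fully-inside range matters: the search region is
defined to have twice the ROI volume (each dimension scaled by
$2^{1/3}$), which for a compact ROI adds only ~13% per side — less than
the brain-shift displacements of up to 5 voxels the method must absorb.
Allowing half-overlap offsets restores the needed capture range without
enlarging the region the user sees.

No failure detection is attempted: the method cannot recognize an
incorrect identification, so results carry their similarity score for a
caller to threshold, but no verdict is emitted.

## Validation metrics

`dice()` is $2|X \cap Y|/(|X|+|Y|)$; `hausdorffDistance()` is the exact
symmetric max–min Euclidean distance between foreground voxel centers in
world mm, over all foreground voxels (no percentile truncation).
`normalizeVsReference()` expresses a report as ratios against a
reference (e.g. expert) result, and `compareMeasures()` runs the
two-sided paired t-test on per-case DSI values. Degenerate comparisons
are flagged: all-zero differences return $p = 1$ by convention, constant
nonzero differences (infinite t) return $p = 0$.

## The phantom generator

Patient volumes cannot ship with a package, so `makePhantomSet()` builds
the study conditions synthetically, with exact ground truth:

* a 64³ grid at 1 mm isotropic voxels (the reconstructed iCEUS
  resolution);
* a curved target vessel — a circular arc of radius 12 mm in a tilted
  plane, tube radius 0.8 mm (diameter below 2 mm), Gaussian
  cross-section whose half-maximum surface sits at the nominal radius —
  plus a bright tumor blob next to it;
* a cT1MR-like volume (background 10, vessel peak 100, mild additive
  Gaussian noise, sd 2);
* an iCEUS-start-like volume: the same anatomy displaced by a rigid
  transform drawn uniformly within ±5 mm translation and ±5° rotation
  per axis (brain-shift scale; explicit values can be supplied),
  remapped to ultrasound-like intensities (background 20, vessel peak
  80) and corrupted by multiplicative Rayleigh speckle of strength 0.3 —
  a first-order model of ultrasound texture (mean-preserving, clipped at
  zero), not a wave-propagation simulation;
* an iCEUS-end-like volume: displaced further, with the tumor replaced
  by a bright spherical shell emulating the resection-cavity rim — the
  structure that is notoriously mistaken for a vessel;
* optionally a straight decoy tube near the target (the
  misidentification scenario in which gradient-based similarity is
  expected to out-localize intensity correlation).

The truth masks are rasterized from the transformed centerlines, so they
are exact at voxel resolution; the truth transforms are stored in the
direction the registration recovers (preoperative → start, start → end).
Everything is a deterministic function of the seed.

What the phantoms do *not* emulate: attenuation and shadowing, spatially
correlated speckle, contrast-agent wash-in/out, elastic deformation, and
the reconstruction artifacts of freehand 2D sweeps. Passing the phantom
suite therefore demonstrates the machinery — enhancement, extraction,
search, optimization, scoring — under controlled displacement and noise,
not clinical performance.

## Parameters at a glance

| Parameter | Default | Units | Why |
|---|---|---|---|
| `sigmas` | 0.5, 1, 1.5, 2 | mm | covers vessel diameters < 2 mm at 1 mm voxels |
| `alpha1`, `alpha2` | 0.5, 2 | — | asymmetric damping of the bright-tube deviation |
| Otsu bins | 256 | — | standard histogram resolution |
| NMI bins | 32 | — | joint-histogram stability on region-sized samples |
| NGF `epsilon` | 1% of fixed range | intensity/mm | separates structure gradients from noise |
| rotation bound | ±15 | degrees | craniotomy geometry |
| search volume | 2 × ROI | — | the workflow's search-region contract |
| speckle strength | 0.3 | — | visually plausible CEUS texture |
| displacements | ≤ 5 mm, ≤ 5° | mm, degrees | brain-shift scale |

## Problem sizes in the test suite

The shipped tests run the full pipeline on 64³ phantoms: twenty seeded
trials per similarity measure for the start-step recovery, five
phantom triplets for the two-step workflow, and ten decoy scenes for
the NGF-vs-NCC robustness comparison. Localization error is measured as
the displacement discrepancy between recovered and true transform *at
the ROI center* — a convention-free quantity (independent of how the
rotation center is parameterized) and the one that matters for finding
the vessel. These sizes keep the whole suite at desk scale while
matching the reconstructed-volume resolution of the intended
application.

## Known limitations

* Rigid-only: tissue that deforms elastically within the ROI is out of
  model, by design.
* No scale selection: without $\sigma^2$ normalization the filter
  detects but does not size vessels.
* The cavity rim can still capture the end-step registration in
  unfavorable geometry — the method reports a score, not a verdict, and
  occasional misidentification on post-resection volumes is an expected
  failure mode, mitigated by selecting curved segments.
* Otsu assumes a usable bimodal histogram inside the region; a region
  with no vessel at all yields a meaningless (but flagged, via
  degenerate-input errors) segmentation.

## A worked example

```{r example, eval = FALSE}
set <- makePhantomSet(seed = 42)
res <- runIdentification(set@ct1mr, set@roi, set@iceusStart,
                         set@iceusEnd, similarityMeasure("NGF"))
res$start
# displacement error at the ROI center, in mm:
p0 <- (roiStart(set@roi) + (roiSize(set@roi) - 1) / 2)
sqrt(sum((applyTransform(res$start@transform, p0) -
            applyTransform(set@toStart, p0))^2))
scored <- evaluateIdentification(res$start)
scored@metrics[["NGF"]]
overlay <- overlayTransform(set@ct1mr, res$start)
```
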