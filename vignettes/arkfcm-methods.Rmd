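---
title: "Adaptively regularized kernel fuzzy C-means: model, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptively regularized kernel fuzzy C-means: model, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arkfcm)
```

## The segmentation problem

T1-weighted brain MR slices are, to a first approximation, three-tissue
intensity images: cerebrospinal fluid (dark), gray matter (intermediate) and
white matter (bright), corrupted by scanner noise and a smooth multiplicative
intensity nonuniformity (bias field).  Plain fuzzy C-means (FCM) clusters
pixels by grayscale alone, so every noise excursion across a class boundary
becomes a misclassified pixel.  The family of spatially regularized FCM
variants repairs this by letting each pixel's neighborhood vote on its
membership; the cost is a tendency to smooth away thin structures such as
sulcal CSF.

This package implements an adaptively regularized, kernelized member of that
family.  Its two ideas are:

1. **A per-pixel regularization weight** $\varphi_i$ instead of a global
   neighbor-influence constant.  The local variation coefficient
   $$\mathrm{LVC}_i = \frac{\sum_{k \in N_i} (x_k - \bar{x}_i)^2}{N_R\,\bar{x}_i^2}$$
   measures relative heterogeneity in the window $N_i$ around pixel $i$
   ($N_R$ pixels, $\bar x_i$ the window mean).  Neighbor LVC values (center
   excluded) are summed, exponentiated
   ($\zeta_i = \exp \sum_{k \in N_i,\,k \neq i} \mathrm{LVC}_k$) and
   normalized over the window
   ($\omega_i = \zeta_i / \sum_{k \in N_i} \zeta_k$), then
   $$\varphi_i = \begin{cases} 2 + \omega_i & \bar{x}_i < x_i \\
   2 - \omega_i & \bar{x}_i > x_i \\ 0 & \bar{x}_i = x_i.\end{cases}$$
   Noisy windows get strong context; pixels that already match their
   neighborhood mean get none and behave as under plain FCM.

2. **A Gaussian radial basis function kernel** in place of squared Euclidean
   distance: $K(x, v) = \exp(-(x-v)^2 / 2\sigma^2)$, inducing the bounded
   dissimilarity $2(1 - K)$, which saturates for outliers instead of letting
   them drag the centers.  The bandwidth is estimated once from the data as
   the standard deviation of the pixel-to-global-mean distances
   $d_i = |x_i - \bar{x}|$.

The objective is
$$J = 2\sum_i \sum_j u_{ij}^m\,(1 - K(x_i, v_j))
    + \sum_i \sum_j \varphi_i\,u_{ij}^m\,(1 - K(\bar{x}_i, v_j)),$$
where $\bar x_i$ here is the variant's smoothing input: the local mean
(`variant = "average"`), local median (`"median"`), or the devised weighted
image (`"weighted"`)
$$\bar\xi_i = \frac{1}{2 + \max\varphi}\Big(x_i +
  \tfrac{1 + \max\varphi}{N_R - 1} \sum_{r \in N_i,\,r \neq i} x_r\Big),$$
a convex center/neighborhood blend whose mixing weight follows the global
maximum of $\varphi$ over the foreground.  Memberships and centers are
updated alternately (centers first, as a one-pass fixed-point step that
evaluates the kernels at the previous centers) until the largest membership
change falls below $\varepsilon$ or the iteration cap is reached.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `window_edge` | 3 | window size (pixels) for all neighborhood operations; 5 changes little, 7+ erodes thin CSF |
| `n_clusters` | 3 | tissue classes (CSF/GM/WM); use 4 to cluster background too |
| `m` | 2 | fuzzifier; larger = softer partitions |
| `epsilon` | 0.001 | stop when no membership changes by more than this |
| `max_iter` | 100 | iteration cap (inclusive); `converged = FALSE` if hit |
| `sigma` | estimated | GRBF bandwidth in intensity units; auto mode adapts to the image scale, making results invariant to affine intensity rescaling |

The base constant 2 inside $\varphi$ is fixed: it balances convergence
speed against detail preservation and is not exposed as a tuning knob.

## Numerical choices

* **Boundary policy.** All windows use replicate (nearest-edge) padding, so
  $N_R$ is constant everywhere including borders.  Mirror padding would
  change border pixels only.
* **Window membership.** The local mean/median windows include the center
  pixel; the inner sums of $\zeta_i$ and of the weighted image exclude it,
  and $\omega_i$'s normalizer runs over the full window — exactly the
  asymmetry the update formulas prescribe.
* **Overflow-free $\omega$.** The exponent sums feeding $\zeta$ are
  unbounded, so $\omega$ is evaluated as a shifted softmax (subtracting the
  window-maximum exponent), which is algebraically identical and cannot
  overflow.
* **Degenerate windows.** $\mathrm{LVC} := 0$ where the window mean is zero;
  for non-negative images a zero mean implies zero variance, so nothing is
  lost.  Images containing negatives (possible after user preprocessing) get
  a clamped denominator and a warning.
* **Membership singularities.** A pixel at zero dissimilarity to one or more
  centers receives a crisp membership split equally among the tied centers.
  Empty clusters (denominator underflow in the center update) are re-seeded
  at the least-committed pixel with a warning.
* **Label coding.** Centers are sorted ascending after convergence and labels
  renumbered accordingly: on T1-like contrast, 1 = CSF, 2 = GM, 3 = WM,
  0 = background.  Argmax ties break toward the darker class.

## Initialization

Initialization is a genuinely open design point.  The default,
`init = "equal_interval"`, places the initial centers at
$\min + \frac{2j-1}{2c}(\max - \min)$ of the foreground grayscales — the
deterministic standard for intensity-mode clustering.  Quantile placement
(`"percentile_centers"`) is also provided but is *not* the default: when the
smallest tissue occupies well under $1/c$ of the foreground (CSF typically
does), the lowest quantile lands inside the gray-matter intensity mode, and
because the GRBF weighting is short-ranged the misplaced center cannot
migrate down to the CSF mode — the CSF and GM clusters then collapse even
for the unregularized kernel method.  `"random_membership"` (seeded uniform
simplex rows) supports randomized-initialization experiments; results are
reported after ascending-center relabeling, which makes them invariant to
the initial ordering.

## Objective monotonicity

The membership and center updates implemented here are the method's
standard ones, and they exactly minimize a functional whose data term
carries weight 1 — whereas the objective above weights it 2.  Combined with
the one-pass fixed-point
center step, the traced objective is therefore non-increasing in the large
majority of iterations (empirically $\ge 95\%$) but can rise by up to a few
parts in $10^5$ relative at isolated iterations.  The package asserts the
95% property in its test suite, records the per-iteration objective and
membership change in every run report so violations are auditable, and makes
no exact-descent guarantee.

## What the phantom generator emulates — and what it does not

`generate_phantom()` builds piecewise-constant tissue images with ground
truth so the whole pipeline is testable without external MR data:

* **Geometries.** `slice_like` is an axial-slice cartoon: a blob-shaped GM
  cortex around a WM core, a ventricular CSF blob, and a 2–3-px CSF ribbon
  at the WM/GM interface.  CSF is proportioned anatomically (the ventricular
  compartment carries roughly two thirds of the CSF area), and the thin
  ribbon deliberately keeps the known thin-structure failure mode
  exercisable.  `concentric` (area-balanced rings) and `voronoi` (random
  cells) provide neutral geometries for algorithmic tests.
* **Contrast.** Default class means `c(48, 106, 154)` follow typical
  simulated T1 tissue intensities; they are intentionally not an exact
  arithmetic progression, whose integer-ratio window means collide exactly
  with other class means — a degeneracy of synthetic grids, not of tissue.
* **Corruptions.** "p% noise" means noise SD = p% of the brightest tissue
  mean (Gaussian and Rician; Rician is $\sqrt{(x+n_1)^2 + n_2^2}$ and
  non-negative by construction).  Salt-and-pepper sets p% of pixels to the
  global min/max.  A "p%" bias field multiplies by a smooth random cosine
  surface spanning $[1 - p/2,\, 1 + p/2]$, matching the simulated-brain-
  database naming for intensity nonuniformity.  Bias is applied before
  noise; negatives are clamped to zero.

The phantom has **no partial-volume mixing** (boundaries are one-pixel
sharp) and no MR contrast physics.  This matters for interpreting tests: on
strictly piecewise-constant images at moderate noise, pixelwise FCM is close
to its ceiling (a 7% Gaussian corruption flips only ~2% of pixels), so
spatial regularization has little interior error left to repair while still
paying a deterministic price along boundaries and thin ribbons.  Under those
conditions the median variant still dominates plain FCM, the weighted
variant roughly ties it, and the average variant trades below it; under
heavier or signal-dependent noise (10% Rician) all three variants beat FCM
clearly.  Passing these tests shows the algorithm behaves as specified on
its own terms; it does not by itself establish superiority on real MR data,
where partial-volume blur penalizes purely pixelwise methods much more.

## Problem sizes

The test suite and the reproduction script use 128×128 slice-like phantoms
(≈9,200 foreground pixels) for robustness and window-size comparisons,
64×64 or smaller for exact-recovery and oracle checks, and 16×16 images for
brute-force per-pixel equivalence, with 5–20 seeded replicates per
experiment.  A 128×128 three-cluster run converges in well under a second.

## Known limitations

* Structures 1–2 px wide are eroded by any neighborhood smoothing; larger
  windows make this rapidly worse (that trend is itself asserted in the
  tests).
* The bias field is neither modeled nor corrected; strong nonuniformity
  shifts tissue modes together and degrades all intensity-only methods.
* 3-D inputs are accepted (cubic windows) but the validated configuration
  is 2-D slices.
* Multi-channel input, registration, skull stripping and bias correction
  are out of scope.
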