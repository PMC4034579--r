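---
title: "Dual-representation saliency: methods and design notes"
author: "salicsd authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-representation saliency: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(salicsd)
```

## The model in one page

Bottom-up (stimulus-driven) gaze allocation is modeled as conspicuity: a
location is salient when it differs from its surroundings.  `salicsd`
computes that difference under two complementary image representations and
fuses the results.

**Center–surround dissimilarity (CSD).**  Patches are compared by the L1
distance of their feature vectors, damped by the spatial distance between
patch centers:

$$ S(p_i) \;=\; \operatorname{avg}_{j \ne i}\;
   \frac{\lVert \alpha(p_i) - \alpha(p_j) \rVert_1}
        {1 + \lVert X_i - X_j \rVert_2} $$

with centers normalized to $[0,1]$ per axis so the "+1" is resolution-free.
`csdScores()` offers two averaging conventions.  The plain count average
(divide by $n-1$) is the textbook form, but it inherits a purely geometric
trend: central patches are nearer to everything, so their total weight mass
$\sum_j 1/(1+d_{ij})$ is larger and they score higher *even for identical
feature dissimilarity*.  The branch pipelines therefore use the weighted
mean (divide by the weight mass), which removes the positional trend
exactly and leaves a score that reflects feature dissimilarity only.  Both
modes agree that identical features score 0 and both are checked against a
brute-force pairwise oracle in the test suite.

**Sparse branch** (`sparseSaliencyMap()`).  The image is resized to
80 × 60, all 5 × 5 RGB patches (d = 75) are extracted at stride 1, and a
*complete* ICA basis is learned from those very patches with symmetric
FastICA (logcosh contrast) — an adaptive dictionary, re-learned per image.
$\alpha(p_i)$ is the patch's sparse coefficient vector.  Completeness plus
pseudoinverse unmixing makes encode→reconstruct exact to floating point,
which is the representational argument for adaptivity: a fixed dictionary
learned from other images with $m' < d$ necessarily leaves a residual, and
the test suite verifies the adaptive residual is strictly smaller on
simulated natural-statistics images.

**Covariance branch** (`covarianceSaliencyMap()`).  The image is resized
to 512 × 512 and per-pixel feature vectors $(R, G, B, x, y)$ are formed —
color plus position only, no gradients; orientation structure is carried by
the sparse branch, whose adaptive bases are Gabor-like.  Sliding square
windows of 8, 16, 32, 64 and 128 px (five scales) are summarized by their
unbiased covariance $C$ and mean $\mu$, and embedded into a single vector
by sigma points: with $l_1 \dots l_d$ the columns of the Cholesky factor of
$C + \varepsilon I$,

$$ \psi \;=\; \big(\mu,\; \mu + \sqrt{d}\,l_1, \dots, \mu + \sqrt{d}\,l_d,\;
   \mu - \sqrt{d}\,l_1, \dots, \mu - \sqrt{d}\,l_d\big), $$

a vector of length $(2d+1)\,d = 55$.  The embedding is exactly invertible
— the first block is $\mu$ and the biased covariance of the $2d$ offset
points reproduces $C$ — which the suite pins to 1e−8 over 1000 random PSD
matrices.  This construction was chosen because the model needs the
descriptor *in vector form* for the L1 CSD and because it encodes both
moments losslessly; other vectorizations of $(\mu, C)$ would serve, so the
round-trip invariant is what fixes the convention.

**Fusion** (`fuseAndSmooth()`, `runFullModel()`).  Per-scale maps are
equalized by dividing by their maximum, multiplied across scales, and the
product min–max normalized; the sparse map is resized to the covariance
resolution, the two branch maps are multiplied, normalized, convolved with
a Gaussian of $\sigma = 0.04 \times$ image width (reflective boundaries),
and returned at the input's native resolution.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| sparse resolution | 80 × 60 | px | the branch's optimal operating point for fixation prediction |
| sparse patch size / stride | 5 / 1 | px | dense overlapping coverage; d = 75 |
| `nComponents` | 75 (= d) | — | complete dictionary; invertibility makes the code exact |
| `seed` | 0 | — | all ICA initialization randomness flows through it |
| cov resolution | 512 × 512 | px | upper bound for typical photos; divisible by all window sizes |
| cov window sizes | 8…128 | px | five octaves of spatial context (l = 5) |
| cov stride | size/2, ≥ 8 | px | half overlap averages out window-phase artifacts |
| `coordinateMode` | `"local"` | — | see below |
| `sigmaFraction` | 0.04 | image widths | the optimal smoothing found for natural-scene fixation benchmarks |

## Design choices where the design was genuinely open

*Coordinate planes.*  With image-global $x, y$ planes, window *means*
differ everywhere, so even a constant image would produce structured CSD —
the spatial term drowns the color statistics and manufactures corner
saliency.  With window-local coordinates (the default) the covariance
block is unchanged — position still shapes $C$, and the color–position
cross-covariances are what encode oriented structure — but identical
content yields identical descriptors anywhere in the frame.  Both modes
are exposed and a regression test pins the dichotomy: ψ-distance between
identical patches at different positions is exactly 0 under `"local"` and
> 0 under `"global"`.

*Window layout.*  Non-overlapping tiling is the cheapest reading, but it
makes a descriptor depend strongly on how structure happens to straddle
tile borders; identical items at different lattice phases then get very
different scores.  Half-overlapping windows (stride = size/2, floored at
8 px to bound the count at ≈ 4000 windows/scale) suppress that phase noise
at modest cost; `strideFraction = 1` restores exact tiling.

*Scale combination.*  Scales are multiplied (a location must be salient at
every scale).  Equalization before the product divides by the maximum
rather than min–max rescaling: subtracting each scale's floor would zero
the product wherever any single scale touches its minimum, discarding
locations for reasons that are artifacts of the floor, not of saliency.

*ICA convergence.*  Symmetric FastICA at 75 components practically never
meets a strict rotation-change tolerance on patch data; the fixed-point
iteration keeps making sub-tolerance progress at 100 iterations.  The
iterate at the cap is used as the basis (the `converged` slot records the
criterion), with seeded restarts and a PCA-whitening fallback reserved for
hard numerical failure.  Nothing downstream depends on strict convergence:
the pseudoinverse unmixing makes reconstruction exact for any iterate.

*Degenerate inputs.*  A constant image admits no dictionary
(`degenerateDictionaryError`); the sparse branch then contributes a zero
map with a warning and the fused output is all-zero.  The covariance
branch returns an all-zero map for any image with zero color variance — a
constant stimulus carries no evidence, and coordinate planes alone should
not manufacture structure.  An exactly zero region covariance embeds as
$\mu$ repeated $2d+1$ times; otherwise a jitter of
$10^{-10}\,\mathrm{tr}(C)/d$, escalated tenfold up to three times, secures
the Cholesky factorization.  Constant maps normalize to all-0 (if zero) or
all-1, so "nothing salient" is preserved by normalization.

## Synthetic data: what it emulates, what it does not

`generatePattern()` renders the classic pop-out arrays (color,
orientation, conjunction, curvature, intersection, symmetry and size
singletons, plus an orientation-texture field) as a 6 × 6 grid of bars
(3:1 aspect, half the cell size) with 15% positional jitter, a red target
among green distractors where color is the distinguishing attribute, and
the target's bounding square as its mask.  `generateCenterBiasFixations()`
draws fixations from one shared center Gaussian per dataset
(σ = 0.2 × width), the spatial bias structure that the shuffled AUC is
designed to cancel, and `generateNaturalImage()` produces seeded 1/f color
noise with correlated channels — enough second-order structure for
Gabor-like ICA bases and full-rank patch matrices.

These generators emulate the *statistical* properties the pipeline and
metrics depend on, not real photographs: 1/f noise has no objects,
occlusions or semantic content, the pattern arrays have exactly one
deviant by construction, and synthetic fixations contain no observer- or
content-driven structure.  Passing tests therefore demonstrate mechanical
and statistical correctness of the implementation — lossless coding,
oracle-exact CSD and metrics, chance-level sAUC under shared bias, pop-out
localization — and not benchmark performance on eye-tracking corpora,
which requires the corresponding datasets.

With the shipped defaults, the model's argmax falls inside the target mask
on 10 of 10 seeds for color singletons and 10 of 10 for orientation
singletons (the suite requires ≥ 9); no such claim is made for curvature
or intersection arrays, where a color-plus-sparse representation has
little to respond to.

## Problem sizes used by the checks

The test suite and acceptance script are sized for a single CPU: ICA
oracle recovery at d = 9 on 4000 samples; CSD oracle equivalence on 100
random instances up to n = 200; the sigma-embedding round trip on 1000
random d = 5 matrices; losslessness on 20 synthetic 60 × 80 images; the
sAUC chance anchor on 50 images × 20 fixations × 20 repetitions; and 20
full-model runs for the pop-out checks.

## Known limitations

* The end-to-end sparse map is *not* numerically invariant to a global
  intensity shift, although the representation is: near-degenerate patch
  eigenvalues make the learned basis sensitive to last-bit perturbations,
  and the L1 CSD is not basis-invariant.  The invariant that actually
  holds — and is tested — is that with the per-image means re-estimated
  and the basis held fixed, shifted patches encode and score identically.
* Fixation coordinates in third-party datasets may be 0- or 1-based;
  `readFixations(origin =)` must be set by the user, as the convention
  cannot be detected from the file.
* No motion/video channels and no top-down (goal-driven) component; the
  model is purely stimulus-driven.
* Multi-scale sparse coding is implemented (`scales` in
  `sparseBranchConfig()`) but has no recommended parameterization; the
  default single scale is the documented operating point.
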