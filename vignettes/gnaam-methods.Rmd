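---
title: "Models, algorithms and design choices in gnaam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, algorithms and design choices in gnaam}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(gnaam)
```

## The generative model

gnaam fits statistical shape-and-appearance models to images. The shape of
an object annotated with $u$ landmarks is a linear point-distribution
model, $s(p) = s_0 + Sp$, with landmark vectors stored interleaved as
$[x_1, y_1, \dots, x_u, y_u]$ in 0-based pixel coordinates (x rightward, y
downward, pixel centers at integers). The basis $S$ is orthonormal and
holds two blocks: 4 similarity columns derived from the mean shape, then
the PCA deformation modes. Appearance is a second linear model
$A(c) = A_0 + Ac$ over the $N$ pixels inside the convex hull of $s_0$
(holistic models) or over $u$ concatenated $N_s \times N_s$ patches
(part-based models). Both PCA steps run on raw, un-normalized sample
values; no per-pixel variance scaling is applied.

Two motion models connect the reference frame to the image: a
piecewise-affine warp over the Delaunay triangulation of $s_0$ (holistic
AAMs), and a per-landmark translational model (part-based models), for
which warp composition degenerates to vector addition — the property that
makes part-based Gauss–Newton fitting both simple and well-behaved.

### Assumptions

* Shapes deform linearly around the mean; similarity transforms are
  handled by the 4 augmented basis columns, which linearize rotation and
  scale (exact only to first order — see the oracle baseline note below).
* Appearance varies linearly in a subspace learned from the training set;
  residual appearance (noise, unmodeled variation) is what the project-out
  algorithms must be robust to.
* Triangulation topology is computed once at training time and frozen in
  the model; all precomputations depend on it.

## The fitting family

All fitters are inverse-compositional Gauss–Newton: the model side is
linearized at $p = 0$, so Jacobians are precomputable, and each step is
composed inversely with the current warp. With steepest-descent images
$J_i$ (appearance gradients times the warp Jacobian) and
$J(c) = J_0 + \sum_i c_i J_i$:

* **SIC** solves the joint normal equations in $(\Delta p, \Delta c)$ each
  iteration — exact and slow, $O((m+n)^2 N)$.
* **Fast-SIC** produces *the same step* by block elimination:
  $\Delta p$ from the residual projected out of the appearance subspace
  ($P_A = E - AA^T$, applied matrix-free as $X - A(A^TX)$), then
  $\Delta c$ by back-substitution. $O(nmN + n^2N)$.
* **aFast-SIC** replaces the projected Hessian by $J^TJ$ — one sweep of
  block coordinate descent, $O((n+m)N + n^2N)$.
* **POIC** linearizes only the mean appearance and projects out $A$; all
  its matrices are precomputed, $O(nN)$, but the neglected
  appearance-gradient term $J_c$ costs it robustness.
* **E-POIC-v1** also projects out the span $\Phi$ of the steepest-descent
  images, so the neglected term vanishes (exactly, at full $\Phi$ rank).
* **E-POIC-v2** keeps $P_A$ but replaces the Hessian of the mean by the
  joint-alignment Hessian $\sum_i G_i^T P_A G_i$ over the training-image
  Jacobians $G_i$, which drops the harmful cross terms
  $G_i^T P_A G_j,\ i \ne j$.
* **E-POIC** combines both: $P_\Phi$ inside the joint-alignment form. The
  implementation follows the literal reading that *every* occurrence of
  $P_A$ is replaced by $P_\Phi$, including inside the Hessian sum.

Weighted variants restrict every residual and Jacobian to a binary sample
grid. The diagonal weight matrix is never materialized: kept rows are
sliced out, and because the sliced appearance basis is no longer
orthonormal the general Gram forms $(A_w^TA_w)^{-1}A_w^T$ replace $A^T$.
With all-ones weights no slicing happens and the unweighted rule is used
verbatim. The default grid keeps every other pixel in x and y (a quarter of
the samples), so an 8-channel descriptor model costs exactly twice a
full-grid intensity model per residual evaluation when the mask tiles into
2-by-2 blocks.

## Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| `n_shape` | caller-set | modes | deformation modes kept by PCA; no silent default |
| `n_app` | caller-set | modes | appearance modes per pyramid level |
| `levels`, `scale` | 2, 0.5 | – | two-level pyramid, shape model shared (rescaled), appearance trained per level |
| `iters` | 25 per level | iterations | fixed budgets; convergence also stops at `max|dp| < 1e-6` |
| `N_s` | 19 | px | part patch side; accuracy saturates around this size |
| `phi_total` | `n * ceiling(m/6)` | columns | extended-subspace size, split evenly across the n shape directions; mirrors the reference configuration of 1200 components at n = 19, m = 400 (≈ m/6 per direction). Full rank ($nm$) is available but at small m lets $\Phi$ swallow most of $J_0$ and destabilizes the update |
| `cell_size` | 8 | px | descriptor pooling window (Gaussian sd = cell/2) |
| sparse grid stride | 2 | px | quarter-grid weighting |

## Numerical choices

* **Procrustes**: centroid centering, unit-Frobenius mean, proper rotations
  only; 100-iteration cap, 1e-10 mean-change tolerance. The converged mean
  is rotated to a canonical orientation (principal axis along x, 180°
  ambiguity resolved by the farthest point's sign) so results do not
  depend on input order.
* **Similarity basis**: built from $s_0$ as (scale) $s_0$ itself,
  (rotation) per-point $[-y, x]$, and the two unit translations,
  orthonormalized in that order; PCA columns are then orthogonalized
  against them and re-orthonormalized. This recipe is one of several
  consistent constructions; it is recorded in the model container.
* **Eigenvector signs** are canonicalized (largest-magnitude entry
  positive) so serialized models are platform-reproducible.
* **Interpolation** is bilinear with border clamping; it is exact on
  affine ramps, which is what the warp oracles exploit.
* **Gradients** are central differences inside the mask/patch, one-sided
  at boundaries, zero where no stencil exists.
* **Mask ties**: a boundary pixel belonging to two triangles is assigned
  to the lowest triangle index.
* **Inverse composition** for piecewise-affine warps uses first-order
  vertex transfer: displace $s_0$ by $-S\Delta p$, map each displaced
  vertex through the current warp averaging over the triangles sharing it,
  and project the result back onto the shape model. For pure translations
  this is exact (verified to 1e-8 against plain subtraction); in general
  it is a first-order approximation.
* **Inverted triangles** during fitting produce a warning and are sampled
  anyway (the affine map is still defined); hard failure would abort
  recoverable iterations. A fit whose landmarks leave the image entirely
  is aborted with a `diverged` flag.
* **Near-singular Hessians** fall back to a ridge of
  `1e-8 · trace/dim`, always with a warning recorded in the fit result;
  condition numbers of every solved system are reported.
* **Appearance coefficient schedule**: the simultaneous algorithms
  initialize $c = A^T(I[p_0] - A_0)$ at each level and accumulate
  $c \leftarrow c + \Delta c$; project-out algorithms never track $c$ and
  report $c = A^T(I[p_{final}] - A_0)$.
* **"First shape parameter" perturbation** acts on the first *deformation*
  mode (index `n_sim + 1`), since the leading 4 columns of this package's
  basis are similarity transforms.

## The synthetic world: what it emulates, and what it does not

`make_world()` builds a fully known ground truth: a landmark ring plus
interior points; deformation fields from low-order trigonometric
harmonics of the ring angle (so 3-sigma draws never fold the
triangulation); band-limited textures for the appearance mean and modes.
Everything is a deterministic function of `(u, n, m, image_size, seed)`.

The default conditions are chosen to reproduce the *generic fitting*
regime: the mean texture's structured contrast dominates, with appearance
modes carrying roughly 45 % of its energy (draw scale `1.5/sqrt(i)` on
unit-norm modes against a mean field of amplitude `0.15/h` per harmonic) —
enough unmodeled-per-instance appearance that plain project-out fitting
degrades noticeably while the simultaneous and extended project-out
algorithms do not. Rendering inverse-warps each canvas pixel and adds
i.i.d. Gaussian noise (suite default sd 0.005 in intensity units);
the background is the constant mean texture value.

Initialization jitter emulates a face detector: the mean shape is placed
into the ground-truth bounding box perturbed by *uniform* noise of
±`magnitude` × face size per axis and ±`magnitude` relative scale.
Bounded (detector-like) noise is part of the suite's definition: beyond
roughly 12 % of face size the extended project-out basin ends and it
diverges rather than stalls, which is a property of the algorithm, not of
the implementation.

The default recovery suite uses u = 20, n = 6 (+4 similarity), m = 12,
96-px images, 40 training renders, 100 test trials at jitter magnitude
0.05, a single pyramid level and a uniform 60-iteration budget — generous
enough for the slower-converging project-out family, so the comparison
measures accuracy, not budget. These sizes keep the whole suite under a
minute on one CPU while leaving every estimate well-conditioned. A second
pyramid level adds nothing here because band-limited textures contain no
fine detail to coarsen away; it remains the package default for real
imagery.

Passing tests on this world therefore demonstrates correctness of the
algebra and the expected *relative* behavior of the algorithms under
known, in-model appearance variation. It does not demonstrate performance
on real images: occlusions, illumination, out-of-span appearance,
annotation noise and detector failure modes are all absent (an optional
rectangle-occlusion corruption exists for exploration but is outside the
default suite).

## Oracles and verification strategy

Every fast update rule is checked against a deliberately naive reference:
dense projectors $E - AA^T$ and $E - A_\Phi(A_\Phi^TA_\Phi)^{-1}A_\Phi^T$,
a stacked pseudo-inverse solve, Schur-complement elimination, an explicit
diagonal-matrix weighted solve, and a ray-casting point-in-polygon scan
for the mask. The oracles are size-guarded (N ≤ 500, m + n ≤ 30) and
refuse anything bigger — they exist to be obviously correct, not fast.
The central equivalences (Fast-SIC ≡ SIC; weighted = unweighted at
identity weights; the joint-alignment cross-term identity) are asserted at
1e-8–1e-9 on seeded random fixtures.

## Known limitations

* The oracle baseline similarity-aligns the ground truth before
  projection; because the model's similarity columns are linearized, its
  error is exactly zero only when the optimal alignment is the identity
  (otherwise of second order in the rotation angle).
* The piecewise-affine inverse composition is first-order; long
  fixed-budget runs of project-out algorithms can random-walk at the
  interpolation noise floor.
* Descriptor models on smooth synthetic textures localize more coarsely
  than intensity models (contrast normalization removes amplitude
  information) — on real textured images the trade-off reverses.
* Model containers use R's native serialization; they are bitwise
  round-trip exact but not language-neutral.
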