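# gnaam

Gauss–Newton fitting of Active Appearance Models (AAMs) and part-based
deformable models for landmark localization in images.

## The problem

An AAM pairs a linear point-distribution shape model with a linear
appearance model in a shape-normalized reference frame. The shape of an
object annotated with *u* landmarks is

    s(p) = s0 + S p,

where `s0` is the mean shape and the orthonormal columns of `S` (2u × n)
hold 4 similarity bases plus PCA deformation modes. The appearance in the
reference frame (the N pixels inside the convex hull of `s0`) is

    A(c) = A0 + A c,

with `A` orthonormal (N × m). Fitting the model to an image `I` means
minimizing the sample-space residual

    min_{p,c} || I[p] − A0 − A c ||²,

where `I[p]` is the image sampled under the piecewise-affine warp defined
by `s(p)` (or under a per-landmark translational motion model for the
part-based variant). The package implements the inverse-compositional
Gauss–Newton family for this problem:

| algorithm | per-iteration cost | character |
|---|---|---|
| SIC | O((m+n)²N) | exact simultaneous step |
| Fast-SIC | O(nmN + n²N) | identical step to SIC by block elimination |
| aFast-SIC | O((n+m)N + n²N) | one sweep of block coordinate descent |
| POIC | O(nN) | project-out; fully precomputed, least robust |
| E-POIC-v1 | O(nN) | project-out of the appearance *and* steepest-descent subspace Φ |
| E-POIC-v2 | O(nN) | joint-alignment Hessian Σᵢ GᵢᵀP_A Gᵢ (no cross terms) |
| E-POIC | O(nN) | v1 + v2 combined |

plus multi-channel (dense gradient-orientation descriptor) appearance
models and weighted least-squares fitting on a sparse sample grid (stride-2,
keeping a quarter of the pixels), which makes an 8-channel descriptor model
cost only twice a full-grid intensity model per iteration.

A synthetic-data module generates fully known ground-truth worlds (shape
basis from smooth trigonometric deformation fields, band-limited textures),
renders instances with known `(p*, c*)`, and provides the naive dense
reference solvers used to verify every fast update rule.

## Worked example

```r
library(gnaam)

world <- make_world(u = 20, n = 6, m = 12, image_size = 96, seed = 42)
set.seed(43)
train <- lapply(1:40, function(i) {
  par <- draw_parameters(world)
  render_instance(world, par$p, par$c, noise_sd = 0.005)
})
model <- train_aam(lapply(train, `[[`, "image"),
                   lapply(train, `[[`, "landmarks"),
                   n_shape = 6, n_app = 12, type = "aam", levels = 1)
model <- precompute_fitters(model, c("poic", "epoic"))

set.seed(44)
par <- draw_parameters(world)
test <- render_instance(world, par$p, par$c, noise_sd = 0.005)
init <- perturb_init(test$landmarks, world, 0.05, "bbox_jitter", seed = 45)
cat(sprintf("initialization error: %.4f\n",
            normalized_pt_pt_error(init, test$landmarks)))
for (alg in c("fast_sic", "afast_sic", "epoic", "poic")) {
  res <- fit(test$image, init, model, algorithm = alg,
             config = fit_config(iters = 60, record_trace = FALSE))
  cat(sprintf("%-10s error: %.4f  (%d iterations)\n", alg,
              normalized_pt_pt_error(res$landmarks, test$landmarks),
              res$iterations))
}
```

prints

```
initialization error: 0.0413
fast_sic   error: 0.0019  (11 iterations)
afast_sic  error: 0.0019  (24 iterations)
epoic      error: 0.0021  (27 iterations)
poic       error: 0.0019  (60 iterations)
```

Errors are mean point-to-point distances normalized by the face size
(geometric mean of the ground-truth bounding-box sides), so 0.0019 means
the average landmark lands within 0.2 % of the face size of its true
position — down from 4.1 % at the detector-style initialization. The
simultaneous algorithms converge fastest; E-POIC reaches the same accuracy
at a fraction of the per-iteration cost; on harder instances plain POIC
frequently fails where the others do not (`run_recovery_suite()` quantifies
this over 100 seeded trials).

A thin command-line front end (`synth`, `train`, `fit`, `eval` subcommands)
is installed at `system.file("cli/gnfit.R", package = "gnaam")`.

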