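---
title: "Shape-based disease grading: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shape-based disease grading: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Morphometric classification asks whether the shape of an anatomical
structure — here, surfaces in the style of segmented hippocampi — predicts a
disease state. Classical shape spaces require dense point-to-point
correspondences, which break down when a collection contains incomplete or
topologically varying meshes (a genus-1 segmentation artifact cannot be
diffeomorphically matched to a genus-0 surface). `shapegrade` instead
compares surfaces through *functional maps*: linear operators between
function spaces on the surfaces, encoded as small matrices in truncated
Laplace–Beltrami eigenbases. Functional correspondence is well defined across
topological variation, and collections of maps can be made mutually
consistent, which is what group-wise analysis needs.

# The pipeline

1. **Operators.** Per surface, the lumped mass matrix \(A\) and cotangent
   stiffness \(W\) of the discrete Laplace–Beltrami operator, and the
   eigenbasis \(\Phi\) of the smallest `k_eigen = 42` eigenvalues
   (\(W\phi = \lambda A \phi\), \(\Phi^\top A \Phi = I\)).
2. **Pairwise maps.** For every ordered pair, approximate landmarks
   (rigid coherent-point-drift alignment, 130 farthest-point samples paired
   by nearest neighbour) initialize a \(30 \times 30\) map matrix by ridge
   least squares; 12 ZoomOut steps grow it to \(42\times42\), alternating a
   spectral nearest-neighbour conversion to a pointwise map and the
   mass-weighted projection back to a functional matrix.
3. **Network and consistent latent basis (CLB).** Edges are the symmetrized
   k-nearest-neighbour graph of the 2-cycle-consistency score
   \(\lVert C_{N,M} C_{M,N} - I\rVert_F\), with the smallest \(k\) that
   connects the collection. Consistent ZoomOut starts from the leading
   \(8\times8\) principal submatrices and performs 20 steps, each growing the
   spectral dimension by 1 and the latent dimension by 7/10; the CLB at each
   step is the set of smallest eigenvectors of the network's quadratic
   consistency form under the stacked orthonormality constraint
   \(\sum_S Y_S^\top Y_S = n I\). The schedule ends at spectral dimension 28
   and latent dimension 22.
4. **Descriptors.** The regularized isophotic metric
   \(g_\omega = \mathrm{I} + \omega\,\mathrm{III}\) blends the intrinsic
   metric with the Gauss-map pullback (extrinsic curvature). Each shape is
   summarized by two Gram matrices of its latent functions: the area-based
   product \(\int f_1 f_2\, d\mu_\omega\) and the conformal product
   \(\int \nabla f_1^\top \nabla f_2\, d\mu_\omega\) on zero-mean functions.
   A correspondence preserves the first iff it is locally area-preserving,
   the second iff conformal, and both iff it is an isometry — so at
   \(\omega = 0\) the descriptors are blind to isometric deformations, and
   \(\omega > 0\) injects extrinsic sensitivity. The SPD matrices are
   linearized by the matrix logarithm (Log-Euclidean framework); network
   features are the unit-normalized lower triangles of the logs.
5. **Classification.** A population graph
   \(W_{ij} = \mathrm{Sim}(S_i, S_j)\,\delta_{ij}\) with
   \(\mathrm{Sim} = \exp(-0.5\, d_{ij}^2/\sigma^2)\) (\(\sigma\) the median
   pairwise Log-Euclidean distance) and a phenotype gate \(\delta_{ij} = 1\)
   iff sex and ApoE genotype coincide and one subject is among the other's 30
   nearest neighbours. A three-layer Chebyshev-polynomial graph
   convolutional network (order \(K = 2\), hidden widths 64, 64, ReLU,
   dropout, node-wise softmax) is trained transductively with cross-entropy
   on the training nodes; evaluation is stratified 70/30 Monte Carlo
   cross-validation with full retraining per draw.

```{r}
library(shapegrade)
cohort <- synthetic_cohort(n = 60, effect_kind = "bump", effect_size = 0.15,
                           genus1_fraction = 2/60, seed = 101)
cv <- grade_cohort(cohort, pipeline_config(cv_draws = 25, seed = 101))
print(cv)
```

# Discretizing the isophotic metric

The continuous definition never prescribes a discretization. The package
uses the 6-dimensional lift \(v \mapsto (v, \sqrt{\omega}\, n(v))\) with
area-weighted unit vertex normals \(n\): the pullback metric of the lift is
exactly \(\mathrm{I} + \omega\,\mathrm{III}\), so the lifted edge lengths
\(\sqrt{\lVert v_i - v_j\rVert^2 + \omega \lVert n_i - n_j\rVert^2}\)
discretize \(g_\omega\). Mass and stiffness are then assembled *intrinsically*
from these lengths — Heron's formula for the barycentric lumped areas, the
law-of-cosines cotangent formula for the stiffness — so at \(\omega = 0\)
the construction reduces to the standard weighted cotangent scheme (verified
elementwise against an independent coordinate-based implementation). On a
planar mesh the normals are constant, \(\mathrm{III} = 0\), and the operators
are \(\omega\)-independent; on the unit sphere \(\mathrm{I} = \mathrm{III}\)
and \(\omega = 1\) scales all lengths by \(\sqrt{2}\). Both properties are
tested.

Very large \(\omega\) on coarse meshes can violate the triangle inequality
in the lifted metric; the affected faces then have their cotangent weights
clamped to zero with a warning rather than aborting the run.

The eigenbasis is always computed at \(\omega = 0\) (the standard scheme);
\(\omega\) enters only through the descriptor-stage inner products. This
keeps the map network independent of \(\omega\) and makes sweeps over the
blending factor cheap. \(\omega\) itself is parameterized scale-free as
\(\omega = \alpha\,\ell^2\) with \(\ell\) the bounding-box diagonal, because
\(\mathrm{III}\) is scale-invariant while \(\mathrm{I}\) scales
quadratically; the default is \(\alpha = 2^{-6}\).

# Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `k_eigen` | 42 | spectral truncation of each shape's function space |
| `landmark_count` | 130 | approximate correspondences for map initialization |
| `fmap_init_dim` / `zoomout_steps` | 30 / 12 | initial map size, grown by 1 per step to 42 |
| `clb_init_dim` / `clb_steps` | 8 / 20 | Consistent ZoomOut start and length (ends at 28 / 22) |
| `clb_latent_step` | 7/10 | latent growth per step; realized size is the floor of the accumulated value |
| `alpha` | \(2^{-6}\) | extrinsic blending, \(\omega = \alpha \ell^2\) (0 = purely intrinsic) |
| `knn` | 30 | phenotype-gate neighbourhood (clipped to \(n-1\) on small cohorts) |
| `cv_draws` / `train_fraction` | 100 / 0.7 | Monte Carlo cross-validation protocol |

GCN training hyper-parameters (adaptive-moments gradient descent, learning
rate \(10^{-2}\), weight decay \(5\times10^{-4}\), dropout 0.5, 200 epochs)
follow common graph-convolution practice and are exposed in
`gcn_config()`.

# Numerical choices

- **Eigen-solvers.** The lumped mass is diagonal, so generalized eigenpairs
  come from a dense symmetric eigendecomposition of
  \(A^{-1/2} W A^{-1/2}\); eigenvector signs are fixed by making the first
  non-negligible entry positive, so bases are reproducible across runs.
- **Nearest-neighbour conversions.** Exact over all vertices, computed in
  compiled code as \(\arg\max_j (2 x_i^\top y_j - \lVert y_j\rVert^2)\) with
  ties broken by smallest index (determinism). An optional farthest-point
  vertex subsample (`zoomout_nn_subsample`) accelerates the ZoomOut inner
  loop for large collections; it is off by default because subsampled
  projections degrade map accuracy measurably on ~500-vertex meshes.
- **Landmark least squares** uses a ridge term of \(10^{-8}\) for
  conditioning; rank-deficient systems are reported with a request for more
  landmarks.
- **Registration** defaults to rigid coherent point drift on a 300-vertex
  subsample, aligned once per collection against the first shape (linear
  rather than quadratic cost); pairwise and no-op alignment are options.
  On strongly anisotropic shapes CPD recovers rotations up to roughly 25-40
  degrees; near-spherical shapes are inherently ambiguous.
- **Latent growth by 7/10** accumulates a real-valued counter whose floor is
  the realized dimension (with an epsilon guard so that \(8 + 20 \cdot 0.7\)
  floors to 22, not 21). The schedule log records every step.
- **Consistency residuals** are reported both raw
  (\(\sum_E \lVert C Y_M - Y_N \rVert_F^2\)) and normalized per edge and
  latent column; the refinement contract (output at most the initialization)
  is stated on the normalized residual because the raw sums at latent
  dimension 8 and 22 are not commensurable.
- **SPD projection** floors eigenvalues at \(10^{-8}\) relative to the
  largest before taking matrix logarithms — the conformal Gram is only
  positive semidefinite (constants have zero Dirichlet energy).
- **Zero logarithms.** The unit-norm feature rule is undefined when
  \(\log D = 0\) (an exact identity descriptor); the feature is then the
  zero vector.
- **Graph scaling.** The Chebyshev domain requires the rescaled Laplacian
  spectrum inside \([-1, 1]\); since population graphs are cohort-sized the
  default uses the exact largest eigenvalue rather than a power-iteration
  estimate, which can undershoot. Power iteration and the fixed
  \(\lambda_{\max} = 2\) shortcut remain options.
- **Stratified splits** take \(\lfloor 0.7\, n_c \rfloor\) per class and
  assign remainders by largest fractional part — deterministic given the
  draw seed.

# The synthetic cohort: what it emulates and what it does not

No clinical meshes ship with the package; `synthetic_cohort()` emulates the
*structure* of a two-class hippocampus study so that every stage is testable:

- **Base anatomy:** an ellipsoidal blob per side (482 vertices by default —
  ample for smooth shapes whose individual variability is band-limited to
  spherical-harmonic degree 6, and small enough that a 60-subject all-pairs
  map network runs on a laptop core in minutes).
- **Individual variability:** band-limited spherical-harmonic radial noise,
  standard deviation 2.5% of the radius — comparable to reported
  inter-subject hippocampal variation and several times smaller than the
  disease effect, as in a well-powered study.
- **Disease effect** (diseased subjects only): `bump` contracts a polar cap
  so that its area shrinks by `effect_size` (the amplitude is calibrated by
  root search on the noise-free blob), changing intrinsic and extrinsic
  geometry — a stylized atrophy. `bend` reflects the cap above a cutting
  plane through a vertex ring; the ring is pinned onto the plane for *all*
  subjects (so the pin itself carries no label information), which makes the
  reflection an exact isometry of the mesh: the omega = 0 operators of a
  dented shape equal those of its undented counterpart exactly, isolating
  the extrinsic-sensitivity mechanism.
- **Topological artifacts:** a fraction of subjects get a thin genus-1
  handle (two vertex-disjoint faces removed and their boundary loops
  stitched by a 6-triangle tube), emulating partial-voluming segmentation
  errors; the pipeline requires no special handling for them.
- **Phenotypes:** sex uniform; ApoE with the E4 frequency elevated in the
  diseased class (association 0.5 by default, echoing the E4 risk-factor
  enrichment in clinical cohorts).

What passing tests on this cohort *do not* show: robustness to segmentation
noise with sharp features, to meshes of heterogeneous resolution or vertex
count, to misaligned acquisitions beyond modest rigid motion, or to class
effects smaller than individual variability. The synthetic effect is a
single localized deformation common to all diseased subjects; clinical
atrophy is heterogeneous.

Two caveats on the `bend` control arm: even with an exactly isometric
deformation, intrinsically blind features do not force chance-level
accuracy, because (a) the pairwise maps are estimated from extrinsic
geometry (landmarks and spectral embeddings), so correspondence noise is
label-correlated, and (b) the ApoE-gated population graph itself carries
label signal. The mechanism claim is therefore comparative — accuracy at
\(\omega > 0\) exceeds accuracy at \(\omega = 0\) on the same cohort — not
absolute.

# Problem sizes used by the tests and the acceptance script

Unit tests run on 82-642-vertex primitives. The end-to-end checks use a
60-subject single-side cohort (balanced classes, bump effect 0.15 with two
genus-1 subjects, or bend effect 0.15), 25 Monte Carlo draws for the main
and permutation-null arms and 15 per \(\omega\) for the mechanism
comparison. These sizes make the full suite reproducible on a single CPU
core while leaving the per-draw standard errors a few percent.

# Known limitations

- All-pairs map computation is quadratic in the collection size; the
  default exact path is practical to low hundreds of shapes. The
  `zoomout_nn_subsample` option and the reference-alignment scope are the
  provided escape hatches.
- The CLB eigenproblem is solved densely; collections beyond a few hundred
  shapes at spectral dimension 28 would need an iterative solver.
- ZoomOut is run independently per ordered pair (no joint symmetrization),
  and no orientation/symmetry disambiguation is attempted: a strongly
  bilaterally symmetric shape pair can converge to the mirrored
  correspondence if the landmarks do.
- The strain-based tuning of map smoothness is exposed only as a diagnostic
  (`map_distortion()`), not as a stopping criterion — no principled
  threshold is available.
- Descriptor distances for the similarity kernel use the unnormalized
  matrix logarithms (the Log-Euclidean metric proper); the unit-norm
  vectors are used as node features only. For multi-descriptor or
  two-sided configurations, feature vectors are concatenated without
  re-normalization and squared distances add.
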