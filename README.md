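# shapegrade

Shape-based disease grading for anatomical surfaces, without point-to-point
correspondence. `shapegrade` implements a full morphometric classification
pipeline for collections of triangle meshes (e.g. segmented hippocampi in a
normal-control vs. Alzheimer's-disease study), tolerating incomplete
registration and topological artifacts such as genus-1 segmentation errors.

## The method

Shapes are compared through **functional maps**: linear operators
`F: X_M -> X_N` between function spaces on two surfaces, encoded as small
matrices `C` in truncated Laplace–Beltrami eigenbases (`a_N ≈ C a_M`). The
pipeline is:

1. **Spectral operators** of the regularized *isophotic metric*
   `g_ω = I + ω·III` — the first fundamental form blended with the Gauss-map
   pullback, so `ω` tunes sensitivity to extrinsic curvature. Discretized by
   the 6-D lift `v ↦ (v, √ω·n(v))` feeding an intrinsic cotangent/Heron
   scheme; at `ω = 0` this is the standard weighted cotangent Laplacian.
   The 42 smallest eigenpairs span each shape's function space.
2. **Pairwise maps**: 130 coherent-point-drift landmarks initialize a 30×30
   matrix, refined by 12 ZoomOut steps to 42×42.
3. **Map network + consistent latent basis (CLB)**: edges are the smallest-k
   symmetrized k-NN graph of the 2-cycle consistency `‖C_NM C_MN − I‖_F`;
   Consistent ZoomOut (8×8 init, 20 steps, +1 spectral / +7/10 latent per
   step) produces latent functions shared across the collection.
4. **Shape-difference descriptors**: per shape, the SPD Gram matrices of the
   area-based (`∫ f₁f₂ dμ_ω`) and conformal (`∫ ∇f₁ᵀ∇f₂ dμ_ω`) inner
   products on the CLB. Isometries leave them invariant at `ω = 0`;
   `ω = α·ℓ²` (bounding-box diagonal `ℓ`, default `α = 2⁻⁶`) adds extrinsic
   sensitivity. Features are unit-norm lower triangles of the matrix
   logarithms (Log-Euclidean framework).
5. **Transductive GCN**: a population graph
   `W_ij = exp(−0.5 d_ij²/σ²) · δ(sex, ApoE, 30-NN)` with a three-layer
   Chebyshev graph convolutional network (K = 2, hidden 64/64), evaluated by
   stratified 70/30 Monte Carlo cross-validation.

No clinical data ship with the package; a first-class synthetic generator
produces two-class cohorts (localized atrophy or a near-isometric dent,
genus-1 handles, class-correlated ApoE) and the sphere–dome interpolation
series used to demonstrate isometry blindness at `ω = 0`.

## Worked example

```r
library(shapegrade)

cohort <- synthetic_cohort(n = 16, effect_kind = "bump", effect_size = 0.2, seed = 7)
print(cohort)
#> synthetic_cohort: 16 subjects (8/8), effect 'bump' size 0.2, sides: right, 0 genus-1
print(cohort$meshes[["subj001"]]$right)
#> triangle_mesh 'subj001' (right): 482 vertices, 960 faces, closed, genus 0

cfg <- pipeline_config(cv_draws = 10, seed = 7)
cv  <- grade_cohort(cohort, cfg)
print(cv)
#> Monte Carlo CV (10 draws, 70%/30% split):
#>   accuracy    0.880 +/- 0.193
#>   precision   0.889 +/- 0.220
#>   recall      0.900 +/- 0.316
#>   specificity 0.867 +/- 0.281
```

Sixteen subjects, half with a calibrated 20% cap-area atrophy on top of
2.5% smooth individual variability: the pipeline estimates all 240 ordered
functional maps, aligns a consistent latent basis, computes Log-Euclidean
descriptor features at `ω = 2⁻⁶ℓ²`, and classifies transductively — the
mean held-out accuracy of 0.88 (over 10 stratified draws of a 16-subject
cohort; the standard deviation reflects the 5-subject test sets) is the
quantity a power analysis of a shape biomarker would start from.

A command-line interface mirrors the R API:

```sh
Rscript inst/cli/grade.R simulate --n 60 --effect bump --size 0.15 --seed 7 --out cohort/
Rscript inst/cli/grade.R evaluate --cache cache/ --alpha 0.015625 --draws 100 --out results.json
Rscript inst/cli/grade.R config --show
```

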