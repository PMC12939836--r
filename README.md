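# bandelet

Geometry-adaptive bandelet analysis of 2D greyscale ultrasound-like images,
with the full preprocessing / feature / classification / evaluation workflow
of an ultrasound nodule-classification study.

Separable wavelets represent smooth regions sparsely but smear edges and
curved contours across many coefficients at every scale. The bandelet
transform fixes this by *adapting the basis to the local geometry*: each
wavelet detail subband is recursively partitioned by a quadtree, every leaf
is assigned a geometric flow — a slope c′ with unit tangent

    tau(x) = (1, c') / sqrt(1 + c'^2)

— and the leaf's coefficients are reordered along the warped coordinate
x2 − c′·x1 and transformed by a full-depth orthonormal 1D wavelet
(*bandeletisation*). Because the warp is realised as an exact permutation,
the whole transform is orthonormal and losslessly invertible. The partition
and the flows are chosen by minimising the Lagrangian rate–distortion cost

    L(S) = ||f − f_R||^2 + lambda * T^2 * (R_G + R_B)
    L0(S) = min( L_direct(S), L0(S1)+L0(S2)+L0(S3)+L0(S4) + lambda*T^2 )

where T is the quantisation step, R_B the number of significant
coefficients (|c| > T), and R_G the bits indexing the leaf's flow. The
result is a representation in which anisotropic structure — nodule margins,
curved tissue boundaries — needs markedly fewer significant coefficients
than in the plain wavelet basis.

Around the transform the package implements the study workflow: a seeded
B-mode speckle-phantom generator (class-dependent nodule geometry), SMOTE
oversampling of the minority class, geometric/photometric augmentation,
stratified splitting, four-channel bandelet feature tensors (approximation +
horizontal/vertical/diagonal coefficient maps) with training-set z-score
normalisation, a small trainable CNN with a freeze-then-unfreeze
transfer-learning schedule, and confusion-matrix metrics (accuracy,
sensitivity, specificity, precision, F1) with repeated k-fold descriptive
statistics.

## Worked example

```r
library(bandelet)

img <- curved_boundary_phantom(size = 128, seed = 5)  # curved-edge test image
fit <- bandelet(img, wavelet = "db2", levels = 2, T = 30, lambda = 1)
fit
#> Bandelet representation
#>   image: 128 x 128, wavelet db2, 2 level(s)
#>   T = 30, lambda = 1, min_block = 4, 18 flow candidates
#>   6 quadtree leaves, 231 significant detail coefficients, total L0 = 3.21e+05

max(abs(predict(fit) - img))          # exact inverse
#> [1] 3.126388e-13

compare_wavelet(img, T_values = 30)
#>    T wavelet_significant bandelet_significant wavelet_psnr bandelet_psnr
#> 1 30                 281                  231     41.28581      40.09865
```

The bandelet best basis represents the same curved boundary with 231
significant coefficients against 281 for the separable wavelet at the same
threshold — the sparsity gain that motivates feeding bandelet coefficient
maps, rather than raw pixels, to the classifier. `plot(fit)` draws the
chosen quadtree with the per-leaf flows.

The full pipeline (synthesis → SMOTE → augmentation → tensors → training →
metrics) runs from one call, `run_pipeline(config, out_dir)`, and writes the
run directory (config, count trace, manifest, training history, metrics
table). With the default configuration the count trace is
14 benign → 28 after SMOTE → 56 balanced → 2048 augmented → 1638/410 split;
`scripts/acceptance.R` recomputes it (see below).

A thin command-line front end over these functions is installed at
`inst/scripts/bandelet.R` (subcommands `synth`, `transform`, `reconstruct`,
`compare-wavelet`, `run`).

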