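# fcmseg

Fuzzy C-means (FCM) tissue segmentation for grayscale brain MR slices,
with a gray-difference neighborhood regularization that makes the
partition robust to noise, PSO-initialized cluster centers, the SB
accuracy / reconstruction-error evaluation criteria, baseline methods,
and a synthetic three-tissue phantom generator so everything is testable
without patient data.

## Who it is for

Image-analysis researchers and method developers who need a reproducible,
well-tested reference implementation of spatially constrained FCM for
CSF/GM/WM-style intensity segmentation — as a library (R functions on
plain matrices and S4 result objects), or as a small CLI over
PNG/TIFF/NIfTI images.

## The method

FCM minimizes the fuzzified within-cluster scatter

> J(U, V) = Σᵢ Σₖ u_ik^m d_ik²,  d_ik = |vᵢ − x_k|,  Σᵢ u_ik = 1,

by alternating the closed-form membership and center updates

> u_ik = [ Σⱼ (d_ik/d_jk)^{2/(m−1)} ]⁻¹,  vᵢ = Σₖ u_ik^m x_k / Σₖ u_ik^m,

until the membership matrix changes by less than ε (default 1e-4,
max-absolute norm) or 100 iterations. The spatial variant replaces
d_ik² by the convex blend

> d̃_ik² = (1−β) d_ik² + β · Σ_{r∈N_k} w_kr d_ir² / Σ_{r∈N_k} w_kr,
> w_kr = exp(−(I_k − I_r)²/σ_g²),

over a 3×3 mirror-padded neighborhood: gray-similar neighbors pull a
pixel toward their cluster (suppressing isolated noise labels) while
dissimilar neighbors — genuine tissue boundaries — are down-weighted.
Initial centers come from global-best particle swarm optimization of the
same fuzzy objective. Accuracy against a reference map is the SB
criterion (matched-pixel fraction after optimal label matching); partition
quality without a reference is the reconstruction error rate W_RE (mean
squared difference between the image and its membership-weighted
reconstruction from the centers). See the vignette
(`vignettes/fcm-brain-segmentation.Rmd`) for assumptions, parameter
guidance and design notes.

## Worked example

```r
library(fcmseg)

ph  <- generatePhantom(phantomSpec(shape = c(64, 64), classSigma = 0.08,
                                   seed = 0))
out <- segmentImage(phantomImage(ph), truth = phantomTruth(ph),
                    config = runConfig(seed = 1, beta = 0.6, init = "pso"))

centers(out$result)
#> [1] 0.2025652 0.5088936 0.7834416
out$metrics$sb
#> [1] 0.9875488
out$metrics$wRE
#> [1] 0.001215626
```

The phantom is a 64×64 three-tissue slice (true class means 0.2, 0.5,
0.8 for CSF/GM/WM) under Gaussian noise σ = 0.08. The fitted centers
recover the generative means to ~0.01; `sb = 0.988` says 98.8% of pixels
received the correct tissue after optimal label matching; the
reconstruction error 0.0012 (mean squared intensity units) says the
three-center fuzzy partition explains almost all gray structure.
`clusterLabels(out$result)` is the label matrix, `out$reconstruction`
the reconstructed image, and passing `outDir=` writes `labels.png`,
`reconstruction.png`, `report.json` and `run.yaml`.

A command-line wrapper with `segment`, `phantom` and `evaluate`
subcommands is installed at
`system.file("cli", "fcmseg.R", package = "fcmseg")`.

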