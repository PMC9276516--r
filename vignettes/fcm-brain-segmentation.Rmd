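---
title: "Spatially regularized fuzzy C-means segmentation: model, parameters and design"
author: "fcmseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatially regularized fuzzy C-means segmentation: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcmseg)
```

## The problem

T1-weighted brain MR slices show three dominant tissue classes —
cerebrospinal fluid (CSF), gray matter (GM) and white matter (WM) — as
three bands of gray intensity corrupted by acquisition noise and, on real
scanners, smooth intensity inhomogeneity. Tissue segmentation assigns
each pixel to a class. Hard thresholding handles the noiseless case but
fragments under noise; fuzzy clustering with a spatial prior is the
standard remedy, and that combination is what this package implements.

## The model

### Classical fuzzy C-means

Given pixel intensities $x_1,\dots,x_n$ (normalized to $[0,1]$) and $c$
clusters, fuzzy C-means (FCM) minimizes

$$J(U, V) \;=\; \sum_{i=1}^{c}\sum_{k=1}^{n} u_{ik}^{\,m}\, d_{ik}^{2},
\qquad d_{ik} = |v_i - x_k|,$$

over cluster centers $V = (v_1,\dots,v_c)$ and the membership matrix
$U \in [0,1]^{c\times n}$ with $\sum_i u_{ik} = 1$ for every pixel. The
fuzzifier $m > 1$ controls partition softness. Alternate optimization
iterates the two closed-form stationary updates:

$$u_{ik} = \Bigl[\sum_{j=1}^{c}
  \bigl(d_{ik}/d_{jk}\bigr)^{2/(m-1)}\Bigr]^{-1},
\qquad
v_i = \frac{\sum_k u_{ik}^{\,m}\, x_k}{\sum_k u_{ik}^{\,m}}.$$

A pixel coinciding with one or more centers (zero distance — the set
$H_k$) gets all of its membership mass on those centers; we distribute it
uniformly over $H_k$, the only symmetric deterministic choice consistent
with the sum-to-one constraint. The loop stops when
$\max_{i,k}\lvert u^{(e)}_{ik} - u^{(e+1)}_{ik}\rvert < \varepsilon$ or
after `maxIter` iterations; the max-absolute-entry norm is used because
it bounds every individual membership change, which is what the stop rule
is meant to control. The objective recorded at the end of each iteration
is non-increasing (a property the test suite asserts with $10^{-9}$
slack).

### The neighborhood gray-difference regularization

Pure intensity clustering ignores where a pixel sits, so isolated noise
pixels flip class. `spatialFcmFit` regularizes the distance term with the
pixel's neighborhood, weighted by gray-level similarity. For each pixel
$k$ and neighbor $r$ in a $(2\rho+1)^2$ window (center excluded, mirror
padding at borders):

$$w_{kr} = \exp\!\bigl(-(I_k - I_r)^2/\sigma_g^2\bigr),$$

and the squared distance entering the objective becomes the convex blend

$$\tilde d^{\,2}_{ik} = (1-\beta)\, d^{2}_{ik}
 + \beta\,\frac{\sum_{r\in N_k} w_{kr}\, d^{2}_{ir}}
               {\sum_{r\in N_k} w_{kr}}.$$

A noise pixel surrounded by gray-similar tissue is pulled toward its
neighbors' cluster; at a genuine boundary the intensity difference makes
$w_{kr}$ small, so the other tissue contributes little and edges are not
smeared. Because the modification is confined to the distance term, both
closed-form updates survive unchanged: the membership update uses
$\tilde d$, and the center update stays the plain weighted mean of the
original intensities. That choice keeps the center formula exact, at a
price discussed under *Numerical behavior*.

### PSO center initialization

FCM converges to a local optimum of a non-convex objective, so the
starting centers matter. `psoInitCenters` runs standard global-best
particle swarm optimization over candidate center vectors: velocities
$v \leftarrow \omega v + c_1 r_1 (p - x) + c_2 r_2 (g - x)$, positions
clamped to the data range, fitness = the FCM objective with memberships
computed optimally for the candidate centers (the most literal reading of
"initial centers for fuzzy clustering": the initializer optimizes the
same criterion the main loop does). Defaults $\omega = 0.72$,
$c_1 = c_2 = 1.49$, 20 particles, 50 iterations, velocity clamp 20% of
the data range — canonical, stable settings. Equal seeds give
bit-identical swarms.

## Evaluation criteria

With a reference label map available, two criteria are reported.

**SB classification accuracy.** After matching predicted to reference
labels by the overlap-maximizing permutation (exhaustive over the $c!$
assignments — exact, and cheap for $c \le 8$; greedy matching was
rejected as order-dependent),

$$SB = \frac{\sum_i |B_i \cap C_i|}{\sum_l |C_l|}$$

is the fraction of pixels whose matched predicted class equals the
reference class.

**Reconstruction error rate.** The fuzzy partition reconstructs each
pixel as the membership-weighted blend of centers,
$I^n_k = \sum_i u_{ik}^m v_i \big/ \sum_i u_{ik}^m$ (exact for crisp
memberships), and

$$W_{RE} = \tfrac1n \sum_k \bigl(I^n_k - I_k\bigr)^2$$

is the mean squared difference from the original — the squared-difference
form is used rather than a ratio, which would be undefined at
zero-intensity pixels.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `clusters` | 3 | tissue classes (CSF/GM/WM) |
| `m` | 2 | fuzzifier; larger = softer partition |
| `maxIter` | 100 | iteration cap of the alternate optimization |
| `epsilon` | 1e-4 | stop tolerance on the max membership change |
| `radius` | 1 | neighborhood radius (1 = 3×3 window), pixels |
| `sigmaG` | image SD | gray-difference scale of the weights, intensity units |
| `beta` | 0.5 | spatial mixing weight in [0,1]; 0 = classical FCM |
| `init` | varies | `"pso"` in the pipeline; `"random"`/`"kmeanspp"` available |

`sigmaG` defaults to the standard deviation of the image because that
scale separates "within-tissue" gray differences (small relative to the
overall spread, weight near 1) from "across-boundary" differences
(comparable to the class separation, weight well below 1) without
requiring a per-image choice. The pipeline's `beta = 0.6` weights the
neighborhood slightly above the pixel's own evidence, appropriate at the
noise levels the phantom protocol probes; `beta = 0` reduces the method
to classical FCM exactly (bit-identically — the reduction is special-cased
so no `sqrt(x^2)` round-off can differ).

## The phantom generator

Real patient MR images are not distributed with the package, so every
claim is exercised on synthetic phantoms with known per-pixel truth.
`generatePhantom` emulates a 2D T1-like slice: class means
$(0.2, 0.5, 0.8)$ for CSF/GM/WM, additive Gaussian noise of chosen
$\sigma$, optional smooth multiplicative bias field (a slow sinusoid
product; default off), clipping to $[0,1]$. The default *slice* geometry
is a head-shaped ellipse on a CSF background with central ventricles and
a convoluted GM/WM boundary drawn from the level set of a seeded sum of
random sinusoids — giving realistic class imbalance (roughly 54/24/21 at
128×128) and an irregular boundary. *Concentric* and *blobs* geometries
are simpler controls.

What the phantom does **not** emulate: Rician noise statistics, partial
volume averaging, 3D continuity, skull/scalp structures, and scanner
bias fields beyond a smooth sinusoid. Passing the phantom protocol
therefore demonstrates correct optimization and genuine noise
robustness, not clinical-grade performance on scanner data.

## Numerical behavior and design choices

- **Center ordering.** Centers are reported sorted ascending and
  memberships/labels permuted to match, so label 1 is always the darkest
  tissue — results are relabeling-deterministic across seeds.
- **Ties.** Hard labels take the maximum membership; exact ties go to the
  lowest cluster index.
- **Degenerate clusters.** A cluster whose total membership mass is zero
  raises an error rather than silently reseeding, keeping runs
  reproducible; callers choose whether to retry with a new seed.
- **Spatial objective monotonicity.** With the effective distance held
  fixed, each membership update cannot increase the blended objective
  (asserted in the tests). Across iterations the *blended* trace is not
  guaranteed monotone, because the center update minimizes the
  plain-distance term (keeping the printed closed form) rather than the
  blend; observed rises are rare and small (order $10^{-4}$ relative on
  noisy phantoms). The classical trace is strictly non-increasing.
- **Overflow in the membership update.** For fuzzifiers close to 1 the
  exponent $2/(m-1)$ is large and $d^{-2/(m-1)}$ can overflow; overflowed
  entries are treated as the coincident-pixel limit (all mass there),
  which is the correct limit of the formula.
- **Preprocessing.** The pipeline's default filter is a 3×3
  sliding-window median with mirror padding, implemented exactly (no
  intensity quantization) so it can be verified against a brute-force
  oracle. Median filtering rounds off image structures thinner than the
  window — visible as a handful of flipped pixels on noiseless phantoms
  with high-curvature boundaries — which is why the exactness tests
  disable it.
- **Multilevel Otsu.** The baseline's $c-1$ thresholds maximize
  between-class variance by exhaustive search over a 256-bin histogram;
  labels are assigned from bin indices so they are exactly consistent
  with the partition the search optimized.
- **Baseline comparison design.** The robustness comparison treats each
  arm as a complete method: the FCM arms run the full pipeline (median
  filter, PSO init) with `beta = 0.6` versus `beta = 0`, while the
  multithreshold arm is the standalone histogram algorithm applied to
  the input image — thresholding has no internal denoising step, and
  granting it the pipeline's filter would compare filtered thresholding,
  a different method. On identically filtered inputs, plain FCM and
  multilevel Otsu are statistically indistinguishable on this phantom
  family (both are near-optimal 1D intensity partitioners there).

## Problem sizes used by the test protocol

The accuracy protocol uses ten 128×128 slice phantoms per noise level
(seeds 0–9) with the full pipeline; property and oracle tests use 1D
mixtures of 80–200 points and images from 4×4 to 64×64, sizes at which
brute-force oracle evaluation is exact and fast. These sizes were chosen
so the entire suite exercises every contract while remaining quick to
run routinely.

## Worked example

```{r example}
ph <- generatePhantom(phantomSpec(shape = c(64, 64), classSigma = 0.08,
                                  seed = 0))
out <- segmentImage(phantomImage(ph), truth = phantomTruth(ph),
                    config = runConfig(seed = 1, beta = 0.6, init = "pso"))
centers(out$result)
out$metrics$sb
out$metrics$wRE
```

## Known limitations

- Scalar (single-channel) intensities only; no multivariate features.
- 2D processing; volumes are handled slice-wise through the NIfTI reader.
- The spatial term assumes noise is spatially uncorrelated; structured
  artifacts (motion ghosting, bias fields much stronger than the
  amplitude the generator models) are out of scope.
- Exhaustive label matching and multilevel Otsu are exponential in $c$;
  both are intended for the small class counts of tissue segmentation.
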