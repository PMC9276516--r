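test_that("gray-difference weights follow the Gaussian kernel", {
  w <- neighborhoodWeights(matrix(0.4, 5, 5), neighborhoodSpec(1),
                           sigmaG = 0.1)
  expect_true(all(vapply(w$weights, function(m) all(m == 1), logical(1))))
  ## a neighbor exactly sigmaG away gives weight exp(-1)
  img <- matrix(0, 1, 2); img[1, 2] <- 0.1
  w <- neighborhoodWeights(img, neighborhoodSpec(1), sigmaG = 0.1)
  j <- which(w$offsets[, "dr"] == 0 & w$offsets[, "dc"] == 1)
  expect_equal(w$weights[[j]][1, 1], exp(-1))
  expect_error(neighborhoodWeights(img, neighborhoodSpec(1), sigmaG = 0),
               "invalid config")
})

test_that("weights equal a per-pixel brute-force loop", {
  set.seed(2)
  img <- matrix(runif(25), 5, 5)
  sg <- 0.2
  w <- neighborhoodWeights(img, neighborhoodSpec(1), sigmaG = sg)
  for (j in seq_len(nrow(w$offsets))) {
    for (r in 1:5) for (c in 1:5) {
      expect_equal(w$weights[[j]][r, c],
                   naiveWeight(img, r, c, w$offsets[j, 1], w$offsets[j, 2],
                               sg),
                   tolerance = 1e-14)
    }
  }
})

test_that("effective distance blends neighborhoods as specified", {
  set.seed(3)
  img <- matrix(runif(16), 4, 4)
  v <- c(0.2, 0.6, 0.9)
  d <- computeDistances(as.numeric(img), v)
  w <- neighborhoodWeights(img, neighborhoodSpec(1), sigmaG = 0.25)
  ## beta = 0: untouched, bit for bit
  expect_identical(effectiveDistance(d, w, beta = 0), d)
  ## constant image: neighborhood distance equals own distance
  cimg <- matrix(0.5, 4, 4)
  cd <- computeDistances(as.numeric(cimg), v)
  cw <- neighborhoodWeights(cimg, neighborhoodSpec(1), sigmaG = 0.25)
  expect_equal(effectiveDistance(cd, cw, beta = 0.7), cd)
  ## random case against the direct-summation oracle
  de <- effectiveDistance(d, w, beta = 0.5)
  expect_lt(max(abs(de - naiveEffectiveDistance(d, img, 1, 0.25, 0.5))),
            1e-12)
  expect_error(effectiveDistance(d, w, beta = 2), "invalid config")
})

test_that("noiseless phantoms are segmented perfectly", {
  ph <- generatePhantom(phantomSpec(shape = c(32, 32), classSigma = 0,
                                    seed = 1))
  fit <- spatialFcmFit(phantomImage(ph), fcmConfig(seed = 1), beta = 0.5)
  expect_equal(classificationAccuracySB(clusterLabels(fit),
                                        phantomTruth(ph)), 1.0)
})

test_that("beta = 0 reduces to the classical fit exactly", {
  ph <- generatePhantom(phantomSpec(shape = c(24, 24), classSigma = 0.08,
                                    seed = 4))
  f1 <- fcmFit(phantomImage(ph), fcmConfig(seed = 2))
  f2 <- spatialFcmFit(phantomImage(ph), fcmConfig(seed = 2), beta = 0)
  expect_identical(centers(f1), centers(f2))
  expect_identical(membership(f1), membership(f2))
  expect_identical(clusterLabels(f1), clusterLabels(f2))
  expect_identical(objectiveTrace(f1), objectiveTrace(f2))
})

test_that("spatial regularization improves noisy-phantom accuracy", {
  wins <- 0L
  for (i in 0:9) {
    ph <- generatePhantom(phantomSpec(shape = c(64, 64), classSigma = 0.08,
                                      seed = i))
    cfg <- fcmConfig(seed = 100 + i)
    sbS <- classificationAccuracySB(
      clusterLabels(spatialFcmFit(phantomImage(ph), cfg, beta = 0.6)),
      phantomTruth(ph))
    sbP <- classificationAccuracySB(
      clusterLabels(fcmFit(phantomImage(ph), cfg)), phantomTruth(ph))
    if (sbS > sbP) wins <- wins + 1L
  }
  expect_gt(wins, 5L)   # strictly higher for the majority of seeds
})

test_that("membership updates decrease the objective at fixed effective distance", {
  ph <- generatePhantom(phantomSpec(shape = c(24, 24), classSigma = 0.1,
                                    seed = 6))
  img <- phantomImage(ph)
  w <- neighborhoodWeights(img, neighborhoodSpec(1))
  v <- c(0.1, 0.45, 0.9)
  u <- matrix(1 / 3, 3, length(img))
  for (step in 1:5) {
    d <- effectiveDistance(computeDistances(as.numeric(img), v), w, 0.6)
    before <- fcmObjective(u, d, 2)
    u <- updateMembership(d, 2)
    expect_lte(fcmObjective(u, d, 2), before + 1e-9)
    v <- updateCenters(as.numeric(img), u, 2)
  }
})
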