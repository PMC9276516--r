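test_that("noiseless phantoms take exactly the class means", {
  for (geom in c("slice", "concentric", "blobs")) {
    ph <- generatePhantom(phantomSpec(shape = c(32, 32), classSigma = 0,
                                      geometry = geom, seed = 2))
    img <- phantomImage(ph); tr <- phantomTruth(ph)
    expect_identical(img, matrix(c(0.2, 0.5, 0.8)[tr], 32, 32))
    expect_true(all(tr %in% 1:3))
    expect_gt(length(unique(as.integer(tr))), 1)
  }
})

test_that("phantom generation is seed-reproducible", {
  s <- phantomSpec(shape = c(40, 40), classSigma = 0.08, seed = 5)
  a <- generatePhantom(s); b <- generatePhantom(s)
  expect_identical(phantomImage(a), phantomImage(b))
  expect_identical(phantomTruth(a), phantomTruth(b))
  d <- generatePhantom(phantomSpec(shape = c(40, 40), classSigma = 0.08,
                                   seed = 6))
  expect_false(identical(phantomImage(a), phantomImage(d)))
})

test_that("per-class noise level matches the specification", {
  ph <- generatePhantom(phantomSpec(shape = c(128, 128), classSigma = 0.05,
                                    seed = 8))
  img <- phantomImage(ph); tr <- phantomTruth(ph)
  for (cls in 1:3) {
    expect_lt(abs(sd(img[tr == cls]) - 0.05), 0.01)
  }
})

test_that("the bias field perturbs intensities smoothly and boundedly", {
  base <- generatePhantom(phantomSpec(shape = c(64, 64), classSigma = 0,
                                      seed = 3))
  biased <- generatePhantom(phantomSpec(shape = c(64, 64), classSigma = 0,
                                        biasAmplitude = 0.2, seed = 3))
  rel <- phantomImage(biased) / phantomImage(base)
  expect_true(all(rel >= 0.8 - 1e-12 & rel <= 1.2 + 1e-12))
  expect_gt(max(rel) - min(rel), 0.05)   # the field actually varies
})

test_that("cluster-point fixtures are seeded equal-weight mixtures", {
  a <- generateClusterPoints(50, c(0.2, 0.8), 0, seed = 1)
  expect_true(all(a$features %in% c(0.2, 0.8)))
  expect_identical(a$features, c(0.2, 0.8)[a$labels])
  b <- generateClusterPoints(50, c(0.2, 0.8), 0, seed = 1)
  expect_identical(a, b)
  big <- generateClusterPoints(200, c(0.2, 0.8), 0.02, seed = 4)
  mus <- tapply(big$features, big$labels, mean)
  expect_lt(abs(mus[[1]] - 0.2), 0.01)
  expect_lt(abs(mus[[2]] - 0.8), 0.01)
  expect_error(generateClusterPoints(10, c(0.2, 0.8), -1), "invalid spec")
  expect_error(generateClusterPoints(1, c(0.2, 0.8), 0.1), "invalid spec")
})

test_that("classical FCM segments noiseless phantoms perfectly", {
  ph <- generatePhantom(phantomSpec(shape = c(48, 48), classSigma = 0,
                                    seed = 9))
  fit <- fcmFit(phantomImage(ph), fcmConfig(seed = 1))
  expect_equal(classificationAccuracySB(clusterLabels(fit),
                                        phantomTruth(ph)), 1.0)
})

test_that("plain-FCM accuracy degrades monotonically with noise", {
  meanSB <- vapply(c(0, 0.05, 0.1), function(sg) {
    mean(vapply(0:9, function(i) {
      ph <- generatePhantom(phantomSpec(shape = c(48, 48), classSigma = sg,
                                        seed = i))
      classificationAccuracySB(
        clusterLabels(fcmFit(phantomImage(ph), fcmConfig(seed = i))),
        phantomTruth(ph))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(meanSB) <= 0))
})

test_that("invalid phantom specifications are rejected", {
  expect_error(phantomSpec(classMeans = c(0.5, 0.2)), "increasing")
  expect_error(phantomSpec(classMeans = 0.5), "2 class")
  expect_error(phantomSpec(classSigma = -0.1), "classSigma")
  expect_error(phantomSpec(biasAmplitude = 0.6), "biasAmplitude")
})
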