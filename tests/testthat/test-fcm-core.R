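test_that("distances are absolute center-to-point differences", {
  expect_equal(computeDistances(0.0, 0.0), matrix(0, 1, 1))
  expect_equal(computeDistances(0.2, c(0.2, 0.7)),
               matrix(c(0, 0.5), 2, 1))
  set.seed(1)
  x <- runif(8); v <- runif(3)
  d <- computeDistances(x, v)
  for (i in 1:3) for (k in 1:8)
    expect_identical(d[i, k], abs(v[i] - x[k]))
  expect_error(computeDistances(numeric(0), 1), "invalid input")
  expect_error(computeDistances(c(1, NA), 1), "invalid input")
})

test_that("membership update matches the closed form and the H_k rule", {
  expect_equal(updateMembership(matrix(c(1, 1), 2, 1), 2),
               matrix(c(0.5, 0.5), 2, 1))
  ## coincident point: all mass on the zero-distance cluster
  expect_equal(updateMembership(matrix(c(0, 3), 2, 1), 2),
               matrix(c(1, 0), 2, 1))
  ## two coincident centers share the mass uniformly
  expect_equal(updateMembership(matrix(c(0, 0, 2), 3, 1), 2),
               matrix(c(0.5, 0.5, 0), 3, 1))
  expect_equal(updateMembership(matrix(c(1, 2), 2, 1), 2),
               matrix(c(0.8, 0.2), 2, 1))
  expect_error(updateMembership(matrix(1, 2, 1), m = 1), "invalid config")
  expect_error(updateMembership(matrix(-1, 2, 1), m = 2), "invalid input")
})

test_that("center update is the weighted mean and stays in the data range", {
  u <- matrix(1, 1, 2)               # all mass on one cluster: crisp mean
  expect_equal(updateCenters(c(0.1, 0.3), u, 2), 0.2)
  u1 <- matrix(1, 1, 1)
  expect_equal(updateCenters(0.4, u1, 2), 0.4)
  u <- matrix(c(0.8, 0.2, 0.2, 0.8), 2, 2)
  expect_equal(updateCenters(c(0, 1), u, 2)[1], 0.04 / 0.68)
  expect_error(updateCenters(c(0, 1), matrix(c(0, 1, 0, 1), 2, 2), 2),
               "degenerate cluster")
})

test_that("objective is the fuzzified within-cluster scatter", {
  expect_identical(fcmObjective(matrix(c(1, 0), 2, 1),
                                matrix(0, 2, 1), 2), 0)
  expect_equal(fcmObjective(matrix(0.5, 2, 1), matrix(1, 2, 1), 2), 0.5)
  expect_error(fcmObjective(matrix(1, 2, 1), matrix(1, 1, 2), 2),
               "invalid input")
})

test_that("updates agree with brute-force loop oracles to 1e-12", {
  set.seed(42)
  for (rep in 1:10) {
    n <- sample(3:20, 1)
    cc <- sample(2:4, 1)
    x <- runif(n)
    v <- runif(cc)
    m <- sample(c(1.5, 2, 2.5), 1)
    d <- computeDistances(x, v)
    u <- updateMembership(d, m)
    expect_lt(max(abs(u - naiveMembership(d, m))), 1e-12)
    expect_lt(max(abs(updateCenters(x, u, m) - naiveCenters(x, u, m))),
              1e-12)
    expect_lt(abs(fcmObjective(u, d, m) - naiveObjective(u, d, m)), 1e-12)
  }
})

test_that("membership columns always sum to one", {
  set.seed(7)
  for (rep in 1:20) {
    d <- matrix(runif(3 * 15), 3, 15)
    d[sample(length(d), 3)] <- 0   # force some H_k columns
    u <- updateMembership(d, 2)
    expect_lt(max(abs(colSums(u) - 1)), 1e-9)
    expect_true(all(u >= 0 & u <= 1))
  }
})

test_that("well-separated pairs are recovered crisply", {
  fit <- fcmFit(c(0, 0, 10, 10), fcmConfig(clusters = 2, seed = 1))
  expect_equal(centers(fit), c(0, 10), tolerance = 1e-6)
  own <- apply(membership(fit), 2, max)
  expect_true(all(own >= 0.99))
  expect_equal(clusterLabels(fit), c(1L, 1L, 2L, 2L))
})

test_that("configuration defaults are recorded in the result", {
  fit <- fcmFit(c(0.1, 0.2, 0.8, 0.9), fcmConfig(clusters = 2, seed = 3))
  expect_identical(fit@config@m, 2)
  expect_identical(fit@config@maxIter, 100L)
  expect_identical(fit@config@epsilon, 1e-4)
  expect_s4_class(fit, "FCMResult")
  expect_true(validObject(fit))
})

test_that("fit matches an independently coded reference loop", {
  pts <- generateClusterPoints(200, c(0.3, 0.7), 0.05, seed = 9)
  v0 <- c(0.25, 0.75)
  fit <- fcmFit(pts$features, fcmConfig(clusters = 2, maxIter = 500,
                                        epsilon = 1e-10), initCenters = v0)
  ref <- referenceFcmLoop(pts$features, 2, 2, v0)
  expect_lt(max(abs(centers(fit) - ref$centers)), 1e-6)
})

test_that("fit agrees with e1071::cmeans at a shared fixed point", {
  skip_if_not_installed("e1071")
  pts <- generateClusterPoints(150, c(0.2, 0.8), 0.03, seed = 5)
  fit <- fcmFit(pts$features, fcmConfig(clusters = 2, maxIter = 300,
                                        epsilon = 1e-9, seed = 1))
  cm <- e1071::cmeans(matrix(pts$features), centers = matrix(c(0.3, 0.7)),
                      m = 2, iter.max = 300)
  expect_equal(centers(fit), unname(sort(cm$centers[, 1])),
               tolerance = 1e-4)
})

test_that("objective trace is non-increasing and the fit is idempotent", {
  set.seed(11)
  for (rep in 1:5) {
    x <- c(rnorm(40, 0.25, 0.05), rnorm(40, 0.7, 0.05))
    fit <- fcmFit(x, fcmConfig(clusters = 2, seed = rep))
    expect_true(all(diff(objectiveTrace(fit)) <= 1e-9))
    expect_true(converged(fit))
    expect_identical(length(objectiveTrace(fit)), nIter(fit))
    ## one more update pair barely moves the membership
    d <- computeDistances(x, centers(fit))
    u2 <- updateMembership(d, 2)
    expect_lt(max(abs(u2 - membership(fit))), fit@config@epsilon)
  }
})

test_that("permuting input points permutes memberships equivariantly", {
  set.seed(13)
  x <- runif(30)
  perm <- sample(30)
  v0 <- c(0.2, 0.5, 0.9)
  f1 <- fcmFit(x, fcmConfig(seed = 1), initCenters = v0)
  f2 <- fcmFit(x[perm], fcmConfig(seed = 1), initCenters = v0)
  expect_equal(membership(f2), membership(f1)[, perm])
  expect_equal(centers(f1), centers(f2))
  expect_equal(tail(objectiveTrace(f1), 1), tail(objectiveTrace(f2), 1))
  expect_identical(clusterLabels(f2), clusterLabels(f1)[perm])
})

test_that("degenerate requests fail loudly", {
  expect_error(fcmFit(rep(0.5, 10), fcmConfig(clusters = 2, seed = 1)),
               "distinct")
  expect_error(fcmConfig(clusters = 2, m = 1), "m")
  expect_error(fcmConfig(clusters = 1), "clusters")
  expect_error(fcmConfig(epsilon = 0), "epsilon")
})
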