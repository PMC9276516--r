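## Classical fuzzy C-means: distances, membership update, center update,
## objective, and the alternate-optimization loop.

#' Distances between cluster centers and data points
#'
#' For scalar intensity features the Euclidean distance reduces to the
#' absolute difference \eqn{d_{ik} = |c_i - x_k|}.
#'
#' @param features numeric vector of n gray intensities.
#' @param centers numeric vector of c cluster centers.
#' @return A c x n matrix of non-negative distances.
#' @examples
#' computeDistances(c(0.2), c(0.2, 0.7))
#' @export
computeDistances <- function(features, centers) {
  if (length(features) < 1L || length(centers) < 1L)
    stop("invalid input: 'features' and 'centers' must be non-empty")
  if (any(!is.finite(features)) || any(!is.finite(centers)))
    stop("invalid input: non-finite values in 'features' or 'centers'")
  abs(outer(centers, features, "-"))
}

#' Membership update from a distance matrix
#'
#' Computes the optimal fuzzy memberships for fixed centers,
#' \eqn{u_{ik} = 1 / \sum_j (d_{ik}/d_{jk})^{2/(m-1)}}. Points coinciding
#' with one or more centers (zero distance, the set \eqn{H_k}) receive all
#' membership mass on those centers, distributed uniformly; every column of
#' the result sums to 1.
#'
#' @param d c x n non-negative distance matrix.
#' @param m fuzzifier (> 1).
#' @return A c x n membership matrix, columns summing to 1.
#' @examples
#' updateMembership(matrix(c(1, 2), 2, 1), m = 2)  # 0.8 / 0.2
#' @export
updateMembership <- function(d, m) {
  if (!is.matrix(d) || any(d < 0) || any(!is.finite(d)))
    stop("invalid input: 'd' must be a finite non-negative matrix")
  if (length(m) != 1L || !is.finite(m) || m <= 1)
    stop("invalid config: fuzzifier 'm' must be > 1")
  p <- 2 / (m - 1)
  w <- d^(-p)                       # Inf where d == 0
  u <- sweep(w, 2L, colSums(w), "/")
  ## zero distance (the H_k set) and numerical overflow of d^(-p) for
  ## small m are both the "effectively coincident" limit: all mass goes
  ## there, uniformly
  zero <- d == 0 | !is.finite(w)
  zcols <- which(colSums(zero) > 0L)
  if (length(zcols)) {
    u[, zcols] <- 0
    hk <- zero[, zcols, drop = FALSE]
    u[, zcols] <- sweep(hk * 1, 2L, colSums(hk), "/")
  }
  u
}

#' Center update from a membership matrix
#'
#' \eqn{c_i = \sum_k u_{ik}^m x_k / \sum_k u_{ik}^m}: each center is the
#' membership-weighted mean of the intensities and therefore lies inside
#' the data range.
#'
#' @param features numeric vector of n intensities.
#' @param u c x n membership matrix (columns sum to 1).
#' @param m fuzzifier (> 1).
#' @return Numeric vector of c updated centers.
#' @examples
#' u <- matrix(c(0.8, 0.2, 0.2, 0.8), 2, 2)
#' updateCenters(c(0, 1), u, m = 2)
#' @export
updateCenters <- function(features, u, m) {
  if (!is.matrix(u) || ncol(u) != length(features))
    stop("invalid input: 'u' must be a c x n matrix matching 'features'")
  if (length(m) != 1L || !is.finite(m) || m <= 1)
    stop("invalid config: fuzzifier 'm' must be > 1")
  um <- u^m
  denom <- rowSums(um)
  if (any(denom == 0))
    stop("degenerate cluster: a cluster received zero membership mass; ",
         "retry with a different seed or fewer clusters")
  as.numeric(um %*% features) / denom
}

#' Fuzzy C-means objective
#'
#' The weighted within-cluster scatter
#' \eqn{J = \sum_i \sum_k u_{ik}^m d_{ik}^2}.
#'
#' @param u c x n membership matrix.
#' @param d c x n distance matrix.
#' @param m fuzzifier (> 1).
#' @return A non-negative scalar.
#' @examples
#' fcmObjective(matrix(0.5, 2, 1), matrix(1, 2, 1), m = 2)  # 0.5
#' @export
fcmObjective <- function(u, d, m) {
  if (!is.matrix(u) || !is.matrix(d) || !identical(dim(u), dim(d)))
    stop("invalid input: 'u' and 'd' must be matrices of identical shape")
  sum(u^m * d^2)
}

## Evaluate a user RNG-dependent expression under a seed without
## clobbering the caller's RNG state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

## c distinct data points as initial centers, drawn under the config seed.
randomInitCenters <- function(features, clusters, seed) {
  ux <- unique(features)
  if (length(ux) < clusters)
    stop("invalid input: fewer distinct intensities than clusters")
  sort(withSeed(seed, sample(ux, clusters)))
}

## k-means++ seeding: first center uniform, then D^2-weighted draws.
kmeansppInitCenters <- function(features, clusters, seed) {
  withSeed(seed, {
    v <- numeric(clusters)
    v[1] <- features[sample.int(length(features), 1L)]
    for (i in seq_len(clusters - 1L) + 1L) {
      d2 <- apply(abs(outer(features, v[seq_len(i - 1L)], "-")), 1L, min)^2
      if (sum(d2) == 0)
        stop("invalid input: fewer distinct intensities than clusters")
      v[i] <- features[sample.int(length(features), 1L, prob = d2)]
    }
    sort(v)
  })
}

## Shared alternate-optimization loop. effectiveDist, when supplied, maps
## the plain distance matrix (and current centers) to the regularized one;
## it is held fixed within each membership update.
fcmIterate <- function(features, config, initCenters = NULL,
                       effectiveDist = NULL, imageDim = integer(0)) {
  validObject(config)
  cc <- config@clusters
  m <- config@m
  if (is.null(initCenters)) {
    initCenters <- switch(config@init,
      random = randomInitCenters(features, cc, config@seed),
      kmeanspp = kmeansppInitCenters(features, cc, config@seed),
      pso = psoInitCenters(features, cc, psoConfig(seed = config@seed),
                           m = m))
  } else {
    if (length(initCenters) != cc)
      stop("invalid input: 'initCenters' must have length 'clusters'")
    initCenters <- sort(as.numeric(initCenters))
  }
  v <- initCenters
  u <- NULL
  trace <- numeric(config@maxIter)
  convergedFlag <- FALSE
  e <- 0L
  repeat {
    e <- e + 1L
    d <- computeDistances(features, v)
    if (!is.null(effectiveDist)) d <- effectiveDist(d, v)
    uNew <- updateMembership(d, m)
    delta <- if (is.null(u)) Inf else max(abs(u - uNew))
    u <- uNew
    v <- updateCenters(features, u, m)
    dEnd <- computeDistances(features, v)
    if (!is.null(effectiveDist)) dEnd <- effectiveDist(dEnd, v)
    trace[e] <- fcmObjective(u, dEnd, m)
    if (!is.finite(trace[e]))
      stop("numerical failure: non-finite objective value")
    if (delta < config@epsilon) { convergedFlag <- TRUE; break }
    if (e >= config@maxIter) break
  }
  ## deterministic labeling: darkest tissue first
  ord <- order(v)
  v <- v[ord]
  u <- u[ord, , drop = FALSE]
  labels <- max.col(t(u), ties.method = "first")
  new("FCMResult", centers = v, membership = u, labels = as.integer(labels),
      objectiveTrace = trace[seq_len(e)], nIter = e,
      converged = convergedFlag, config = config,
      imageDim = as.integer(imageDim))
}

#' Fit fuzzy C-means by alternate optimization
#'
#' Starting from initial centers (given, or drawn per
#' \code{config@init}), alternates the membership update and the center
#' update until the maximum absolute change of the membership matrix
#' between successive iterations falls below \code{epsilon}, or
#' \code{maxIter} iterations have run. The objective is recorded at the end
#' of every iteration and is non-increasing. Centers are reported sorted
#' ascending, so with a T1-like phantom label 1 is the darkest tissue (CSF)
#' and label c the brightest (WM); memberships and labels are permuted to
#' match. Hard labels take the maximum membership, ties to the lowest
#' cluster index.
#'
#' @param features numeric vector of intensities (or a matrix, flattened
#'   column-major; its dimensions are kept so labels reshape to the image).
#' @param config an \code{\link{fcmConfig}}.
#' @param initCenters optional numeric vector of c starting centers;
#'   overrides \code{config@init}.
#' @return An \code{\linkS4class{FCMResult}}.
#' @examples
#' fit <- fcmFit(c(0, 0, 10, 10), fcmConfig(clusters = 2, seed = 1))
#' centers(fit)
#' @export
fcmFit <- function(features, config = fcmConfig(), initCenters = NULL) {
  imageDim <- if (is.matrix(features)) dim(features) else integer(0)
  fcmIterate(as.numeric(features), config, initCenters,
             effectiveDist = NULL, imageDim = imageDim)
}
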