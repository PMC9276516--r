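## Global-best particle swarm optimization of the initial FCM centers.

#' Fitness of a candidate center vector
#'
#' Evaluates the fuzzy C-means objective for the candidate centers with
#' memberships computed optimally for those centers; lower is better.
#' Permuting the candidate centers leaves the fitness unchanged.
#'
#' @param position numeric vector of candidate centers.
#' @param features numeric vector of intensities.
#' @param m fuzzifier (> 1).
#' @return The scalar objective value.
#' @examples
#' psoFitness(c(0, 1), c(0, 0, 1, 1), m = 2)  # perfect centers: 0
#' @export
psoFitness <- function(position, features, m = 2) {
  if (any(!is.finite(position)))
    stop("invalid particle: non-finite position")
  d <- computeDistances(features, position)
  u <- updateMembership(d, m)
  fcmObjective(u, d, m)
}

#' Initialize FCM cluster centers by particle swarm optimization
#'
#' Runs standard global-best PSO over candidate center vectors: each
#' particle's velocity is updated as
#' \eqn{v \leftarrow \omega v + c_1 r_1 (p - x) + c_2 r_2 (g - x)} with
#' uniform random \eqn{r_1, r_2}, positions are clamped to the data range
#' and velocities to a fraction of it, and the fitness is the fuzzy
#' objective of \code{\link{psoFitness}}. The global-best fitness is
#' non-increasing over iterations; equal seeds give bit-identical output.
#'
#' @param features numeric vector of intensities.
#' @param clusters number of centers to place.
#' @param pso a \code{\link{psoConfig}}.
#' @param m fuzzifier used in the fitness (> 1).
#' @return Numeric vector of \code{clusters} centers, sorted ascending,
#'   with attributes \code{fitness} (best objective found) and
#'   \code{fitnessTrace} (global-best fitness per iteration).
#' @examples
#' pts <- generateClusterPoints(100, means = c(0.2, 0.8), sigma = 0.02,
#'                              seed = 4)
#' psoInitCenters(pts$features, 2, psoConfig(seed = 4))
#' @export
psoInitCenters <- function(features, clusters, pso = psoConfig(), m = 2) {
  validObject(pso)
  clusters <- as.integer(clusters)
  if (clusters < 2L) stop("invalid input: 'clusters' must be >= 2")
  lo <- min(features); hi <- max(features)
  range <- hi - lo
  if (range == 0) stop("invalid input: constant features")
  vmax <- pso@velocityClamp * range
  ns <- pso@swarmSize
  withSeed(pso@seed, {
    x <- matrix(stats::runif(ns * clusters, lo, hi), ns, clusters)
    v <- matrix(stats::runif(ns * clusters, -vmax, vmax), ns, clusters)
    fit <- apply(x, 1L, psoFitness, features = features, m = m)
    pbest <- x
    pfit <- fit
    gi <- which.min(pfit)
    gbest <- pbest[gi, ]
    gfit <- pfit[gi]
    traceG <- numeric(pso@iterations)
    for (t in seq_len(pso@iterations)) {
      r1 <- matrix(stats::runif(ns * clusters), ns, clusters)
      r2 <- matrix(stats::runif(ns * clusters), ns, clusters)
      v <- pso@inertia * v +
        pso@cognitive * r1 * (pbest - x) +
        pso@social * r2 * (matrix(gbest, ns, clusters, byrow = TRUE) - x)
      v <- pmin(pmax(v, -vmax), vmax)
      x <- pmin(pmax(x + v, lo), hi)
      fit <- apply(x, 1L, psoFitness, features = features, m = m)
      improved <- fit < pfit
      pbest[improved, ] <- x[improved, , drop = FALSE]
      pfit[improved] <- fit[improved]
      gi <- which.min(pfit)
      if (pfit[gi] < gfit) { gbest <- pbest[gi, ]; gfit <- pfit[gi] }
      traceG[t] <- gfit
    }
    structure(sort(gbest), fitness = gfit, fitnessTrace = traceG)
  })
}
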