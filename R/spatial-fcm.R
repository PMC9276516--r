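## Spatially regularized FCM: gray-difference correlation weights over a
## pixel neighborhood blended into the squared distances of the objective.

## Shift a matrix by (dr, dc) with mirror (symmetric) padding: the value at
## [r, c] of the result is x[reflect(r + dr), reflect(c + dc)].
shiftMirror <- function(x, dr, dc) {
  n <- nrow(x); p <- ncol(x)
  ri <- seq_len(n) + dr
  ci <- seq_len(p) + dc
  reflect <- function(i, k) {
    while (any(i < 1L | i > k)) {
      i[i < 1L] <- 1L - i[i < 1L]
      i[i > k] <- 2L * k + 1L - i[i > k]
    }
    i
  }
  x[reflect(ri, n), reflect(ci, p), drop = FALSE]
}

#' Gray-difference correlation weights over pixel neighborhoods
#'
#' For every pixel k and every neighbor r inside the window, the
#' correlation weight is the Gaussian kernel of their gray difference,
#' \eqn{w_{kr} = \exp(-(I_k - I_r)^2 / \sigma_g^2)}: identical intensities
#' give weight 1, intensities differing by \eqn{\sigma_g} give
#' \eqn{e^{-1}}. Borders are mirror-padded so every pixel has a full
#' neighborhood.
#'
#' @param image numeric matrix of gray intensities.
#' @param spec a \code{\link{neighborhoodSpec}}.
#' @param sigmaG gray-difference scale (> 0); \code{NULL} uses the standard
#'   deviation of the image intensities.
#' @return A \code{CorrelationWeights} list with elements \code{offsets}
#'   (two-column matrix of (dr, dc)), \code{weights} (one matrix per
#'   offset, each entry \eqn{w_{kr}}), \code{totalWeight} (per-pixel sum
#'   over neighbors), and \code{sigmaG}.
#' @examples
#' w <- neighborhoodWeights(matrix(0.5, 4, 4), neighborhoodSpec(1))
#' all(w$weights[[1]] == 1)  # constant image: zero gray difference
#' @export
neighborhoodWeights <- function(image, spec = neighborhoodSpec(),
                                sigmaG = NULL) {
  stopifnot(is.matrix(image))
  validObject(spec)
  if (is.null(sigmaG)) sigmaG <- stats::sd(as.numeric(image))
  if (length(sigmaG) != 1L || !is.finite(sigmaG) || sigmaG <= 0)
    stop("invalid config: 'sigmaG' must be a single value > 0")
  r <- spec@radius
  off <- expand.grid(dr = -r:r, dc = -r:r)
  if (!spec@includeCenter) off <- off[off$dr != 0L | off$dc != 0L, ]
  off <- as.matrix(off)
  weights <- vector("list", nrow(off))
  total <- matrix(0, nrow(image), ncol(image))
  for (j in seq_len(nrow(off))) {
    nb <- shiftMirror(image, off[j, 1L], off[j, 2L])
    weights[[j]] <- exp(-((image - nb)^2) / sigmaG^2)
    total <- total + weights[[j]]
  }
  structure(list(offsets = off, weights = weights, totalWeight = total,
                 sigmaG = sigmaG, dim = dim(image)),
            class = "CorrelationWeights")
}

#' Blend plain distances with neighborhood-correlated distances
#'
#' The regularized squared distance is the convex blend
#' \deqn{\tilde d^2_{ik} = (1-\beta)\, d^2_{ik} +
#'   \beta\, \frac{\sum_{r \in N_k} w_{kr} d^2_{ir}}{\sum_{r \in N_k} w_{kr}}}
#' so a pixel is pulled toward the cluster its gray-similar neighbors are
#' close to. \code{beta = 0} returns the plain distances exactly. Pixels
#' whose total neighbor weight underflows to zero fall back to the plain
#' distance (with a warning).
#'
#' @param d c x n plain distance matrix, columns in column-major pixel
#'   order of the image the weights were built from.
#' @param weights a \code{CorrelationWeights} object from
#'   \code{\link{neighborhoodWeights}}.
#' @param beta mixing weight in [0, 1].
#' @return A c x n matrix of regularized distances.
#' @examples
#' img <- matrix(0.5, 4, 4)
#' d <- computeDistances(as.numeric(img), c(0.3, 0.8))
#' w <- neighborhoodWeights(img, sigmaG = 0.1)
#' all.equal(effectiveDistance(d, w, beta = 0.7), d)  # homogeneous image
#' @export
effectiveDistance <- function(d, weights, beta) {
  if (length(beta) != 1L || !is.finite(beta) || beta < 0 || beta > 1)
    stop("invalid config: 'beta' must lie in [0, 1]")
  if (beta == 0) return(d)
  stopifnot(inherits(weights, "CorrelationWeights"))
  dm <- weights$dim
  if (ncol(d) != prod(dm))
    stop("invalid input: distance matrix does not match the weight image")
  zero <- weights$totalWeight == 0
  if (any(zero))
    warning(sum(zero), " pixel(s) with zero total neighbor weight; ",
            "using the plain distance there")
  out <- matrix(0, nrow(d), ncol(d))
  for (i in seq_len(nrow(d))) {
    d2 <- matrix(d[i, ]^2, dm[1], dm[2])
    acc <- matrix(0, dm[1], dm[2])
    for (j in seq_along(weights$weights))
      acc <- acc + weights$weights[[j]] *
        shiftMirror(d2, weights$offsets[j, 1L], weights$offsets[j, 2L])
    nbr <- ifelse(zero, d2, acc / weights$totalWeight)
    out[i, ] <- as.numeric(sqrt((1 - beta) * d2 + beta * nbr))
  }
  out
}

#' Fit spatially regularized fuzzy C-means on an image
#'
#' Runs the alternate-optimization FCM loop with the plain center-to-pixel
#' distances replaced by \code{\link{effectiveDistance}}: each pixel's
#' squared distance to a cluster is blended with the gray-difference-
#' weighted average squared distance of its neighbors, which suppresses
#' isolated noise labels while the weights protect genuine tissue
#' boundaries (dissimilar neighbors contribute little). The correlation
#' weights depend only on the image and are computed once; the center
#' update is the plain membership-weighted mean of the original
#' intensities. With \code{beta = 0} the fit is numerically identical to
#' \code{\link{fcmFit}}.
#'
#' @param image numeric matrix of gray intensities.
#' @param config an \code{\link{fcmConfig}}.
#' @param spec a \code{\link{neighborhoodSpec}}; default 3x3 window,
#'   center excluded.
#' @param sigmaG gray-difference scale; \code{NULL} uses the image
#'   standard deviation.
#' @param beta spatial mixing weight in [0, 1]; 0.5 balances own and
#'   neighborhood evidence.
#' @param initCenters optional starting centers, as in \code{\link{fcmFit}}.
#' @return An \code{\linkS4class{FCMResult}}; \code{clusterLabels} returns
#'   the segmentation as a label matrix.
#' @examples
#' ph <- generatePhantom(phantomSpec(shape = c(32, 32), classSigma = 0,
#'                                   geometry = "concentric", seed = 1))
#' fit <- spatialFcmFit(phantomImage(ph), fcmConfig(seed = 1), beta = 0.5)
#' classificationAccuracySB(clusterLabels(fit), phantomTruth(ph))
#' @export
spatialFcmFit <- function(image, config = fcmConfig(),
                          spec = neighborhoodSpec(), sigmaG = NULL,
                          beta = 0.5, initCenters = NULL) {
  stopifnot(is.matrix(image))
  if (length(beta) != 1L || !is.finite(beta) || beta < 0 || beta > 1)
    stop("invalid config: 'beta' must lie in [0, 1]")
  if (beta == 0)
    return(fcmFit(image, config, initCenters))
  w <- neighborhoodWeights(image, spec, sigmaG)
  eff <- function(d, v) effectiveDistance(d, w, beta)
  fcmIterate(as.numeric(image), config, initCenters, effectiveDist = eff,
             imageDim = dim(image))
}
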