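#' @import methods
NULL

#' Configuration for fuzzy C-means clustering
#'
#' Holds every tunable of the alternate-optimization FCM loop: the number of
#' clusters \code{clusters} (the tissue classes), the fuzzifier \code{m}
#' (partition softness, must exceed 1), the iteration cap \code{maxIter}, the
#' convergence tolerance \code{epsilon} on the max-absolute change of the
#' membership matrix between successive iterations, the RNG \code{seed}, and
#' the center-initialization mode \code{init} (one of \code{"random"},
#' \code{"pso"}, \code{"kmeanspp"}).
#'
#' Defaults follow common practice for T1-weighted brain tissue clustering:
#' 3 clusters (CSF/GM/WM), m = 2, at most 100 iterations, epsilon = 1e-4.
#'
#' @slot clusters integer, number of clusters (>= 2).
#' @slot m numeric fuzzifier (> 1).
#' @slot maxIter integer iteration cap (>= 1).
#' @slot epsilon numeric convergence tolerance (> 0).
#' @slot seed integer RNG seed.
#' @slot init character, one of "random", "pso", "kmeanspp".
#' @export
setClass("FCMConfig",
  representation(clusters = "integer", m = "numeric", maxIter = "integer",
                 epsilon = "numeric", seed = "integer", init = "character"),
  prototype(clusters = 3L, m = 2, maxIter = 100L, epsilon = 1e-4,
            seed = 1L, init = "random"))

setValidity("FCMConfig", function(object) {
  msg <- character(0)
  if (length(object@clusters) != 1L || is.na(object@clusters) ||
      object@clusters < 2L)
    msg <- c(msg, "'clusters' must be a single integer >= 2")
  if (length(object@m) != 1L || !is.finite(object@m) || object@m <= 1)
    msg <- c(msg, "fuzzifier 'm' must be a single finite value > 1")
  if (length(object@maxIter) != 1L || is.na(object@maxIter) ||
      object@maxIter < 1L)
    msg <- c(msg, "'maxIter' must be >= 1")
  if (length(object@epsilon) != 1L || !is.finite(object@epsilon) ||
      object@epsilon <= 0)
    msg <- c(msg, "'epsilon' must be > 0")
  if (length(object@init) != 1L ||
      !object@init %in% c("random", "pso", "kmeanspp"))
    msg <- c(msg, "'init' must be one of 'random', 'pso', 'kmeanspp'")
  if (length(msg)) msg else TRUE
})

#' Construct an FCM configuration
#'
#' @param clusters number of clusters c (>= 2).
#' @param m fuzzifier (> 1); m = 2 is the usual choice for MR tissue maps.
#' @param maxIter maximum number of alternate-optimization iterations.
#' @param epsilon stop when the max-absolute change of the membership matrix
#'   between successive iterations falls below this value.
#' @param seed integer RNG seed used by the chosen initializer.
#' @param init center initialization: \code{"random"} draws c distinct data
#'   points, \code{"pso"} runs particle swarm optimization
#'   (\code{\link{psoInitCenters}}), \code{"kmeanspp"} uses k-means++
#'   seeding.
#' @return An \code{FCMConfig} object.
#' @examples
#' fcmConfig(clusters = 3, m = 2)
#' @export
fcmConfig <- function(clusters = 3, m = 2, maxIter = 100, epsilon = 1e-4,
                      seed = 1, init = c("random", "pso", "kmeanspp")) {
  init <- match.arg(init)
  new("FCMConfig", clusters = as.integer(clusters), m = as.numeric(m),
      maxIter = as.integer(maxIter), epsilon = as.numeric(epsilon),
      seed = as.integer(seed), init = init)
}

#' Neighborhood specification for spatial regularization
#'
#' Defines the pixel window over which gray-difference correlation weights
#' are computed: \code{radius} 1 means the 3x3 window, the center pixel is
#' excluded by default, and image borders are handled by mirror padding so
#' every pixel has a full neighborhood.
#'
#' @slot radius integer window radius in pixels (>= 1).
#' @slot includeCenter logical, whether the pixel itself is a neighbor.
#' @slot padding character border rule; only "mirror" is implemented.
#' @export
setClass("NeighborhoodSpec",
  representation(radius = "integer", includeCenter = "logical",
                 padding = "character"),
  prototype(radius = 1L, includeCenter = FALSE, padding = "mirror"))

setValidity("NeighborhoodSpec", function(object) {
  msg <- character(0)
  if (length(object@radius) != 1L || is.na(object@radius) ||
      object@radius < 1L)
    msg <- c(msg, "'radius' must be a single integer >= 1")
  if (!identical(object@padding, "mirror"))
    msg <- c(msg, "only 'mirror' padding is implemented")
  if (length(msg)) msg else TRUE
})

#' Construct a neighborhood specification
#'
#' @param radius window radius in pixels; 1 gives the 3x3 window.
#' @param includeCenter whether the center pixel participates in its own
#'   neighborhood average (default \code{FALSE}).
#' @param padding border rule; \code{"mirror"} reflects indices at the edge.
#' @return A \code{NeighborhoodSpec} object.
#' @examples
#' neighborhoodSpec(radius = 1)
#' @export
neighborhoodSpec <- function(radius = 1, includeCenter = FALSE,
                             padding = "mirror") {
  new("NeighborhoodSpec", radius = as.integer(radius),
      includeCenter = isTRUE(includeCenter), padding = padding)
}

#' Configuration for particle swarm optimization of initial centers
#'
#' Standard global-best PSO settings. The defaults (inertia 0.72,
#' cognitive = social = 1.49, swarm of 20, 50 iterations, velocities clamped
#' to 20 percent of the data range) are the canonical constriction-like
#' values that keep the swarm stable on low-dimensional problems.
#'
#' @slot swarmSize integer particle count (>= 2).
#' @slot iterations integer PSO iterations (>= 1).
#' @slot inertia numeric inertia weight in [0, 1].
#' @slot cognitive numeric attraction to the particle's own best (> 0).
#' @slot social numeric attraction to the global best (> 0).
#' @slot seed integer RNG seed.
#' @slot velocityClamp numeric max speed as a fraction of the data range.
#' @export
setClass("PSOConfig",
  representation(swarmSize = "integer", iterations = "integer",
                 inertia = "numeric", cognitive = "numeric",
                 social = "numeric", seed = "integer",
                 velocityClamp = "numeric"),
  prototype(swarmSize = 20L, iterations = 50L, inertia = 0.72,
            cognitive = 1.49, social = 1.49, seed = 1L,
            velocityClamp = 0.2))

setValidity("PSOConfig", function(object) {
  msg <- character(0)
  if (object@swarmSize < 2L) msg <- c(msg, "'swarmSize' must be >= 2")
  if (object@iterations < 1L) msg <- c(msg, "'iterations' must be >= 1")
  if (!is.finite(object@inertia) || object@inertia < 0 || object@inertia > 1)
    msg <- c(msg, "'inertia' must be in [0, 1]")
  if (object@cognitive <= 0 || object@social <= 0)
    msg <- c(msg, "'cognitive' and 'social' must be > 0")
  if (!is.finite(object@velocityClamp) || object@velocityClamp <= 0)
    msg <- c(msg, "'velocityClamp' must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct a PSO configuration
#'
#' @param swarmSize number of particles.
#' @param iterations number of PSO iterations.
#' @param inertia inertia weight on the previous velocity.
#' @param cognitive weight of attraction to the particle's personal best.
#' @param social weight of attraction to the swarm's global best.
#' @param seed integer RNG seed; equal seeds give bit-identical runs.
#' @param velocityClamp maximum speed per coordinate, as a fraction of the
#'   data range.
#' @return A \code{PSOConfig} object.
#' @examples
#' psoConfig(seed = 7)
#' @export
psoConfig <- function(swarmSize = 20, iterations = 50, inertia = 0.72,
                      cognitive = 1.49, social = 1.49, seed = 1,
                      velocityClamp = 0.2) {
  new("PSOConfig", swarmSize = as.integer(swarmSize),
      iterations = as.integer(iterations), inertia = as.numeric(inertia),
      cognitive = as.numeric(cognitive), social = as.numeric(social),
      seed = as.integer(seed), velocityClamp = as.numeric(velocityClamp))
}

#' Result of a fuzzy C-means fit
#'
#' Container for everything the alternate-optimization loop produces:
#' ascending cluster centers, the c x n membership matrix (columns sum
#' to 1), hard labels in 1..c by maximum membership (ties to the lowest
#' index), the per-iteration objective values, the iteration count and the
#' convergence flag. When the fit was run on an image, \code{imageDim}
#' stores its dimensions so labels and memberships can be reshaped.
#'
#' @slot centers numeric vector of c cluster centers, ascending.
#' @slot membership c x n numeric matrix; every column sums to 1.
#' @slot labels integer vector of per-point hard labels in 1..c.
#' @slot objectiveTrace numeric, objective value at the end of each
#'   iteration.
#' @slot nIter integer, iterations executed.
#' @slot converged logical, whether the epsilon criterion was met.
#' @slot config the \code{FCMConfig} used.
#' @slot imageDim integer vector, \code{c(rows, cols)} or empty for 1D data.
#' @export
setClass("FCMResult",
  representation(centers = "numeric", membership = "matrix",
                 labels = "integer", objectiveTrace = "numeric",
                 nIter = "integer", converged = "logical",
                 config = "FCMConfig", imageDim = "integer"))

setValidity("FCMResult", function(object) {
  msg <- character(0)
  cc <- length(object@centers)
  if (nrow(object@membership) != cc)
    msg <- c(msg, "membership must have one row per center")
  if (length(object@labels) != ncol(object@membership))
    msg <- c(msg, "one label per data point required")
  if (length(object@labels) &&
      (min(object@labels) < 1L || max(object@labels) > cc))
    msg <- c(msg, "labels must lie in 1..clusters")
  if (length(object@objectiveTrace) != object@nIter)
    msg <- c(msg, "objectiveTrace must have one entry per iteration")
  if (is.unsorted(object@centers))
    msg <- c(msg, "centers must be sorted ascending")
  sums <- colSums(object@membership)
  if (length(sums) && max(abs(sums - 1)) > 1e-9)
    msg <- c(msg, "membership columns must sum to 1")
  if (length(msg)) msg else TRUE
})

#' Specification of a synthetic brain phantom
#'
#' Describes a 2D three-tissue (by default) phantom: image shape, the
#' ascending per-class intensity means (T1-like contrast CSF < GM < WM),
#' the additive Gaussian noise level, the peak amplitude of an optional
#' smooth multiplicative bias field, the label-map geometry and the seed.
#'
#' @slot shape integer vector c(rows, cols).
#' @slot classMeans numeric, strictly increasing class means in [0, 1].
#' @slot classSigma numeric additive Gaussian noise sd (>= 0).
#' @slot biasAmplitude numeric in [0, 0.5), peak of the bias field.
#' @slot geometry character, one of "concentric", "blobs", "slice".
#' @slot seed integer RNG seed.
#' @export
setClass("PhantomSpec",
  representation(shape = "integer", classMeans = "numeric",
                 classSigma = "numeric", biasAmplitude = "numeric",
                 geometry = "character", seed = "integer"),
  prototype(shape = c(128L, 128L), classMeans = c(0.2, 0.5, 0.8),
            classSigma = 0.05, biasAmplitude = 0, geometry = "slice",
            seed = 1L))

setValidity("PhantomSpec", function(object) {
  msg <- character(0)
  if (length(object@shape) != 2L || any(object@shape < 4L))
    msg <- c(msg, "'shape' must be c(rows, cols), both >= 4")
  if (length(object@classMeans) < 2L)
    msg <- c(msg, "at least 2 class means required")
  if (any(diff(object@classMeans) <= 0))
    msg <- c(msg, "class means must be strictly increasing")
  if (any(object@classMeans < 0 | object@classMeans > 1))
    msg <- c(msg, "class means must lie in [0, 1]")
  if (object@classSigma < 0) msg <- c(msg, "'classSigma' must be >= 0")
  if (object@biasAmplitude < 0 || object@biasAmplitude >= 0.5)
    msg <- c(msg, "'biasAmplitude' must be in [0, 0.5)")
  if (!object@geometry %in% c("concentric", "blobs", "slice"))
    msg <- c(msg, "'geometry' must be 'concentric', 'blobs' or 'slice'")
  if (length(msg)) msg else TRUE
})

#' Construct a phantom specification
#'
#' @param shape image dimensions \code{c(rows, cols)}.
#' @param classMeans strictly increasing intensity means, one per tissue
#'   class; the default (0.2, 0.5, 0.8) emulates CSF/GM/WM contrast in a
#'   normalized T1-weighted slice.
#' @param classSigma additive Gaussian noise standard deviation.
#' @param biasAmplitude peak amplitude of a smooth multiplicative intensity
#'   inhomogeneity field (0 disables it).
#' @param geometry label-map layout: \code{"concentric"} ellipses,
#'   random \code{"blobs"}, or \code{"slice"} (a head-like ellipse with a
#'   convoluted GM/WM boundary and CSF background/ventricles).
#' @param seed integer RNG seed; equal seeds give identical phantoms.
#' @return A \code{PhantomSpec} object.
#' @examples
#' phantomSpec(shape = c(64, 64), classSigma = 0.08, seed = 3)
#' @export
phantomSpec <- function(shape = c(128, 128), classMeans = c(0.2, 0.5, 0.8),
                        classSigma = 0.05, biasAmplitude = 0,
                        geometry = c("slice", "concentric", "blobs"),
                        seed = 1) {
  geometry <- match.arg(geometry)
  new("PhantomSpec", shape = as.integer(shape),
      classMeans = as.numeric(classMeans),
      classSigma = as.numeric(classSigma),
      biasAmplitude = as.numeric(biasAmplitude), geometry = geometry,
      seed = as.integer(seed))
}

#' A synthetic phantom: image plus ground-truth labels
#'
#' @slot image numeric matrix of gray intensities in [0, 1].
#' @slot truth integer matrix of per-pixel class labels in 1..c.
#' @slot spec the generating \code{PhantomSpec}.
#' @export
setClass("Phantom",
  representation(image = "matrix", truth = "matrix", spec = "PhantomSpec"))

setValidity("Phantom", function(object) {
  msg <- character(0)
  if (!identical(dim(object@image), dim(object@truth)))
    msg <- c(msg, "image and truth must have identical dimensions")
  cc <- length(object@spec@classMeans)
  if (min(object@truth) < 1L || max(object@truth) > cc)
    msg <- c(msg, "truth labels must lie in 1..number of classes")
  if (any(!is.finite(object@image)))
    msg <- c(msg, "image must be finite")
  if (length(msg)) msg else TRUE
})
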