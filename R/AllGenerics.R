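#' Accessors for fitted FCM results and phantoms
#'
#' \code{centers} returns the ascending cluster centers; \code{membership}
#' the c x n membership matrix (as an array of per-pixel membership images
#' when the fit was on an image and \code{asImage = TRUE});
#' \code{clusterLabels} the hard label assignment (a matrix for image fits);
#' \code{objectiveTrace}, \code{nIter} and \code{converged} describe the
#' optimization run; \code{phantomImage} and \code{phantomTruth} extract the
#' two layers of a \code{\link{Phantom}}.
#'
#' @param object an \code{FCMResult} or \code{Phantom}.
#' @param ... further arguments for methods.
#' @return The requested component.
#' @examples
#' pts <- generateClusterPoints(60, means = c(0.2, 0.8), sigma = 0.02,
#'                              seed = 1)
#' fit <- fcmFit(pts$features, fcmConfig(clusters = 2, seed = 1))
#' centers(fit)
#' nIter(fit)
#' @name fcmseg-accessors
NULL

#' @rdname fcmseg-accessors
#' @export
setGeneric("centers", function(object, ...) standardGeneric("centers"))

#' @rdname fcmseg-accessors
#' @export
setGeneric("membership", function(object, ...) standardGeneric("membership"))

#' @rdname fcmseg-accessors
#' @export
setGeneric("clusterLabels",
           function(object, ...) standardGeneric("clusterLabels"))

#' @rdname fcmseg-accessors
#' @export
setGeneric("objectiveTrace",
           function(object, ...) standardGeneric("objectiveTrace"))

#' @rdname fcmseg-accessors
#' @export
setGeneric("nIter", function(object, ...) standardGeneric("nIter"))

#' @rdname fcmseg-accessors
#' @export
setGeneric("converged", function(object, ...) standardGeneric("converged"))

#' @rdname fcmseg-accessors
#' @export
setGeneric("phantomImage",
           function(object, ...) standardGeneric("phantomImage"))

#' @rdname fcmseg-accessors
#' @export
setGeneric("phantomTruth",
           function(object, ...) standardGeneric("phantomTruth"))

#' @rdname fcmseg-accessors
#' @export
setMethod("centers", "FCMResult", function(object, ...) object@centers)

#' @rdname fcmseg-accessors
#' @param asImage logical; for image fits, reshape per-cluster memberships
#'   into an rows x cols x clusters array.
#' @export
setMethod("membership", "FCMResult", function(object, asImage = FALSE, ...) {
  if (asImage && length(object@imageDim) == 2L) {
    d <- object@imageDim
    array(t(object@membership), dim = c(d[1], d[2], nrow(object@membership)))
  } else object@membership
})

#' @rdname fcmseg-accessors
#' @export
setMethod("clusterLabels", "FCMResult", function(object, ...) {
  if (length(object@imageDim) == 2L)
    matrix(object@labels, object@imageDim[1], object@imageDim[2])
  else object@labels
})

#' @rdname fcmseg-accessors
#' @export
setMethod("objectiveTrace", "FCMResult",
          function(object, ...) object@objectiveTrace)

#' @rdname fcmseg-accessors
#' @export
setMethod("nIter", "FCMResult", function(object, ...) object@nIter)

#' @rdname fcmseg-accessors
#' @export
setMethod("converged", "FCMResult", function(object, ...) object@converged)

#' @rdname fcmseg-accessors
#' @export
setMethod("phantomImage", "Phantom", function(object, ...) object@image)

#' @rdname fcmseg-accessors
#' @export
setMethod("phantomTruth", "Phantom", function(object, ...) object@truth)

setMethod("show", "FCMResult", function(object) {
  cat("FCMResult:", length(object@centers), "clusters,",
      ncol(object@membership), "points\n")
  cat("  centers:", paste(signif(object@centers, 5), collapse = ", "), "\n")
  cat("  iterations:", object@nIter,
      if (object@converged) "(converged)" else "(iteration cap reached)",
      "\n")
  cat("  final objective:",
      signif(utils::tail(object@objectiveTrace, 1), 6), "\n")
  if (length(object@imageDim) == 2L)
    cat("  image:", object@imageDim[1], "x", object@imageDim[2], "\n")
  invisible(NULL)
})

setMethod("show", "FCMConfig", function(object) {
  cat("FCMConfig: c =", object@clusters, ", m =", object@m,
      ", maxIter =", object@maxIter, ", epsilon =", object@epsilon,
      ", init =", object@init, ", seed =", object@seed, "\n")
  invisible(NULL)
})

setMethod("show", "Phantom", function(object) {
  d <- dim(object@image)
  cat("Phantom:", d[1], "x", d[2], "image,",
      length(object@spec@classMeans), "classes,",
      "geometry =", object@spec@geometry,
      ", sigma =", object@spec@classSigma,
      ", seed =", object@spec@seed, "\n")
  invisible(NULL)
})
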