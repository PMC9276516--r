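## Evaluation criteria: SB classification accuracy with optimal label
## matching, and the reconstruction error rate of the fuzzy partition.

permutationsOf <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutationsOf(k - 1L)
  out <- matrix(0L, 0L, k)
  for (i in seq_len(k)) {
    rest <- seq_len(k)[-i]
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub), k - 1L)))
  }
  out
}

#' Optimal matching of predicted to reference cluster labels
#'
#' Cluster labels are arbitrary up to permutation; overlap metrics need the
#' correspondence that maximizes total agreement. The permutation is found
#' by exhaustive search over all c! assignments of the c x c contingency
#' table (exact; practical for the small c of tissue segmentation, c <= 8).
#'
#' @param pred integer labels in 1..c (vector or matrix).
#' @param truth reference labels, same shape.
#' @param clusters number of classes c; default the larger label maximum.
#' @return Integer vector \code{perm} of length c: predicted label i
#'   corresponds to reference label \code{perm[i]}.
#' @examples
#' matchLabels(c(2, 2, 1), c(1, 1, 2))  # swap: c(2, 1)
#' @export
matchLabels <- function(pred, truth, clusters = max(pred, truth)) {
  if (!identical(dim(pred), dim(truth)) || length(pred) != length(truth))
    stop("invalid input: 'pred' and 'truth' must have identical shape")
  clusters <- as.integer(clusters)
  if (clusters > 8L)
    stop("exhaustive matching supports at most 8 clusters")
  tab <- table(factor(as.integer(pred), levels = seq_len(clusters)),
               factor(as.integer(truth), levels = seq_len(clusters)))
  perms <- permutationsOf(clusters)
  scores <- apply(perms, 1L, function(p)
    sum(tab[cbind(seq_len(clusters), p)]))
  as.integer(perms[which.max(scores), ])
}

#' SB classification accuracy
#'
#' After optimal label matching, the fraction of pixels whose predicted
#' cluster agrees with the reference cluster:
#' \eqn{SB = \sum_i |B_i \cap C_i| / \sum_l |C_l|}, where \eqn{B_i} is the
#' set of pixels in predicted cluster i and \eqn{C_i} the reference set.
#' Invariant under any relabeling of the prediction; 1 means a perfect
#' segmentation.
#'
#' @param pred predicted labels in 1..c (vector or matrix).
#' @param truth reference labels, same shape.
#' @param clusters number of classes; default inferred.
#' @return Accuracy in [0, 1].
#' @examples
#' classificationAccuracySB(c(1, 1, 2, 2), c(1, 2, 2, 2))  # 0.75
#' @export
classificationAccuracySB <- function(pred, truth,
                                     clusters = max(pred, truth)) {
  if (length(pred) == 0L) stop("invalid input: empty label maps")
  perm <- matchLabels(pred, truth, clusters)
  mean(perm[as.integer(pred)] == as.integer(truth))
}

#' Reconstruct an image from a fuzzy partition
#'
#' Each pixel's reconstructed gray value is the membership-weighted blend
#' of the cluster centers,
#' \eqn{I^n_k = \sum_i u_{ik}^m v_i / \sum_i u_{ik}^m}; for crisp
#' memberships every pixel receives its own cluster's center exactly, and
#' all values lie within the center range.
#'
#' @param u c x n membership matrix, or an \code{FCMResult} (in which case
#'   \code{centersV} and \code{m} are taken from it and the result is
#'   shaped like the fitted image).
#' @param centersV numeric vector of c cluster centers.
#' @param m fuzzifier (> 1).
#' @return Numeric vector of n reconstructed intensities (a matrix for an
#'   image-shaped \code{FCMResult}).
#' @examples
#' reconstructImage(matrix(0.5, 2, 1), c(0, 1), m = 2)  # 0.5
#' @export
reconstructImage <- function(u, centersV = NULL, m = 2) {
  if (is(u, "FCMResult")) {
    res <- u
    recon <- reconstructImage(res@membership, res@centers, res@config@m)
    if (length(res@imageDim) == 2L)
      recon <- matrix(recon, res@imageDim[1], res@imageDim[2])
    return(recon)
  }
  if (!is.matrix(u) || length(centersV) != nrow(u))
    stop("invalid input: 'u' must be c x n with one center per row")
  um <- u^m
  denom <- colSums(um)
  if (any(denom == 0))
    stop("numerical failure: pixel with zero total membership")
  as.numeric(crossprod(um, centersV)) / denom
}

#' Reconstruction error rate
#'
#' Mean squared difference between an image and its reconstruction from
#' the fuzzy partition, \eqn{W_{RE} = \frac1n \sum_k (I^n_k - I_k)^2}:
#' zero iff the reconstruction is identical, and small when the partition
#' preserves the original gray structure.
#'
#' @param original numeric image (vector or matrix).
#' @param recon reconstructed image, same shape.
#' @return Non-negative scalar.
#' @examples
#' reconstructionError(rep(0, 10), rep(0.1, 10))  # 0.01
#' @export
reconstructionError <- function(original, recon) {
  if (length(original) != length(recon) ||
      !identical(dim(original), dim(recon)))
    stop("invalid input: shapes differ")
  mean((as.numeric(recon) - as.numeric(original))^2)
}

#' Evaluate a segmentation against ground truth
#'
#' Convenience wrapper producing the metric report: SB classification
#' accuracy (after optimal label matching), per-class matched pixel
#' counts, and — when a fit is supplied — the reconstruction error rate of
#' its fuzzy partition against the original image.
#'
#' @param pred predicted label map (or an \code{FCMResult}).
#' @param truth reference label map.
#' @param image original image; required for the reconstruction error when
#'   \code{pred} is an \code{FCMResult}.
#' @param clusters number of classes; default inferred.
#' @return A list with elements \code{sb}, \code{perClassOverlap}
#'   (named matched counts per reference class) and, if computable,
#'   \code{wRE}.
#' @examples
#' ph <- generatePhantom(phantomSpec(shape = c(24, 24), classSigma = 0,
#'                                   geometry = "concentric", seed = 1))
#' fit <- fcmFit(phantomImage(ph), fcmConfig(seed = 1))
#' evaluateSegmentation(fit, phantomTruth(ph), phantomImage(ph))
#' @export
evaluateSegmentation <- function(pred, truth, image = NULL,
                                 clusters = NULL) {
  fit <- NULL
  if (is(pred, "FCMResult")) { fit <- pred; pred <- clusterLabels(fit) }
  if (is.null(clusters)) clusters <- max(pred, truth)
  perm <- matchLabels(pred, truth, clusters)
  mapped <- perm[as.integer(pred)]
  overlap <- vapply(seq_len(clusters), function(i)
    sum(mapped == i & as.integer(truth) == i), integer(1))
  names(overlap) <- paste0("class", seq_len(clusters))
  out <- list(sb = mean(mapped == as.integer(truth)),
              perClassOverlap = overlap)
  if (!is.null(fit) && !is.null(image))
    out$wRE <- reconstructionError(image, reconstructImage(fit))
  out
}
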