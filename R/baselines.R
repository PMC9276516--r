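## Comparison arms: multilevel Otsu thresholding and crisp k-means.

#' Multilevel Otsu thresholding baseline
#'
#' Histogram-based crisp segmentation: c - 1 thresholds over a 256-bin
#' intensity histogram are chosen by exhaustive search to maximize the
#' between-class variance (the multilevel generalization of Otsu's
#' criterion); labels are assigned in ascending intensity order. Being
#' purely histogram-based, the result is invariant to any spatial
#' rearrangement of the pixels.
#'
#' @param image numeric matrix (or vector) of intensities.
#' @param clusters number of classes c (>= 2; exhaustive search is
#'   practical for c <= 4).
#' @param nbins number of histogram bins.
#' @return Integer label map, same shape as \code{image}, labels 1..c
#'   ascending with intensity; thresholds in attribute
#'   \code{"thresholds"}.
#' @examples
#' img <- matrix(c(0.1, 0.1, 0.9, 0.9), 2, 2)
#' baselineMultithreshold(img, 2)
#' @export
baselineMultithreshold <- function(image, clusters = 3, nbins = 256) {
  clusters <- as.integer(clusters)
  if (clusters < 2L) stop("invalid input: 'clusters' must be >= 2")
  x <- as.numeric(image)
  if (length(unique(x)) < clusters)
    stop("invalid input: fewer distinct gray levels than clusters")
  lo <- min(x); hi <- max(x)
  bin <- if (hi > lo)
    pmin(floor((x - lo) / (hi - lo) * nbins) + 1L, nbins) else
      rep(1L, length(x))
  counts <- tabulate(bin, nbins)
  mids <- lo + (seq_len(nbins) - 0.5) * (hi - lo) / nbins
  cw <- cumsum(counts)                  # cumulative weight
  cm <- cumsum(counts * mids)           # cumulative first moment
  groupStat <- function(a, b) {         # between-class contribution
    w <- cw[b] - if (a > 1L) cw[a - 1L] else 0
    s <- cm[b] - if (a > 1L) cm[a - 1L] else 0
    if (w == 0) 0 else s^2 / w
  }
  cuts <- utils::combn(nbins - 1L, clusters - 1L)
  best <- -Inf; bestCut <- cuts[, 1L]
  for (j in seq_len(ncol(cuts))) {
    edges <- c(0L, cuts[, j], nbins)
    stat <- 0
    for (g in seq_len(clusters))
      stat <- stat + groupStat(edges[g] + 1L, edges[g + 1L])
    if (stat > best) { best <- stat; bestCut <- cuts[, j] }
  }
  thr <- lo + bestCut * (hi - lo) / nbins
  ## classify by bin so the labels are exactly consistent with the
  ## histogram partition the search optimized
  lab <- findInterval(bin - 0.5, bestCut) + 1L
  out <- if (is.matrix(image))
    matrix(as.integer(lab), nrow(image), ncol(image)) else as.integer(lab)
  attr(out, "thresholds") <- thr
  out
}

#' Crisp k-means baseline
#'
#' Lloyd's algorithm (\code{stats::kmeans}) with seeded initialization as
#' the hard-clustering control arm; labels are renumbered so cluster 1 is
#' the darkest center. An empty cluster triggers one automatic re-seed
#' before failing.
#'
#' @param features numeric vector or matrix of intensities.
#' @param clusters number of clusters (>= 2).
#' @param seed integer RNG seed.
#' @return Integer label vector (or matrix, matching the input shape) with
#'   the sorted centers in attribute \code{"centers"}.
#' @examples
#' baselineKmeans(c(0, 0.05, 0.9, 0.95), 2, seed = 1)
#' @export
baselineKmeans <- function(features, clusters = 3, seed = 1) {
  clusters <- as.integer(clusters)
  if (clusters < 2L) stop("invalid input: 'clusters' must be >= 2")
  x <- as.numeric(features)
  runOnce <- function(s) withSeed(s, stats::kmeans(x, centers = clusters,
                                                   algorithm = "Lloyd",
                                                   iter.max = 100L))
  km <- tryCatch(runOnce(seed), error = function(e) NULL)
  if (is.null(km) || any(km$size == 0L))
    km <- runOnce(seed + 1L)
  if (any(km$size == 0L)) stop("degenerate cluster: empty k-means cluster")
  ord <- order(km$centers[, 1L])
  relabel <- integer(clusters); relabel[ord] <- seq_len(clusters)
  lab <- relabel[km$cluster]
  out <- if (is.matrix(features))
    matrix(as.integer(lab), nrow(features), ncol(features)) else
      as.integer(lab)
  attr(out, "centers") <- sort(km$centers[, 1L])
  out
}
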