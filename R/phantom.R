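## Synthetic brain-slice phantoms with known ground truth.

## Normalized elliptical radius of every pixel around the image center.
ellipticalRadius <- function(nr, nc, a, b, r0 = (nr + 1) / 2,
                             c0 = (nc + 1) / 2) {
  r <- matrix(seq_len(nr), nr, nc)
  cl <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  sqrt(((r - r0) / a)^2 + ((cl - c0) / b)^2)
}

## Smooth random scalar field as a seeded sum of random plane sinusoids;
## its level sets give convoluted, organic-looking boundaries.
smoothRandomField <- function(nr, nc, nWaves = 6L, maxFreq = 4) {
  r <- matrix(seq_len(nr) / nr, nr, nc)
  cl <- matrix(seq_len(nc) / nc, nr, nc, byrow = TRUE)
  s <- matrix(0, nr, nc)
  for (j in seq_len(nWaves)) {
    fr <- stats::runif(1, 0.5, maxFreq)
    fc <- stats::runif(1, 0.5, maxFreq)
    ph <- stats::runif(1, 0, 2 * pi)
    amp <- stats::runif(1, 0.5, 1)
    sgnr <- sample(c(-1, 1), 1)
    s <- s + amp * sin(2 * pi * (sgnr * fr * r + fc * cl) + ph)
  }
  s
}

buildTruthMap <- function(spec) {
  nr <- spec@shape[1]; nc <- spec@shape[2]
  k <- length(spec@classMeans)
  switch(spec@geometry,
    concentric = {
      re <- ellipticalRadius(nr, nc, a = 0.55 * nr, b = 0.48 * nc)
      ring <- findInterval(re / max(re), seq(0, 1, length.out = k + 1),
                           rightmost.closed = TRUE, all.inside = TRUE)
      matrix(k + 1L - as.integer(ring), nr, nc)   # brightest at the center
    },
    blobs = {
      truth <- matrix(1L, nr, nc)
      for (cls in seq_len(k)[-1]) {
        for (b in 1:3) {
          r0 <- stats::runif(1, 0.2 * nr, 0.8 * nr)
          c0 <- stats::runif(1, 0.2 * nc, 0.8 * nc)
          a <- stats::runif(1, 0.08, 0.22) * nr
          bb <- stats::runif(1, 0.08, 0.22) * nc
          re <- ellipticalRadius(nr, nc, a, bb, r0, c0)
          truth[re < 1] <- cls
        }
      }
      truth
    },
    slice = {
      truth <- matrix(1L, nr, nc)            # darkest class: CSF/background
      head <- ellipticalRadius(nr, nc, a = 0.42 * nr, b = 0.36 * nc) < 1
      vent <- ellipticalRadius(nr, nc, a = 0.10 * nr, b = 0.06 * nc) < 1
      tissue <- head & !vent
      if (k >= 2L) {
        s <- smoothRandomField(nr, nc)
        vals <- s[tissue]
        ## split interior among classes 2..k at slightly uneven quantiles
        qs <- stats::quantile(vals, seq(0, 1, length.out = k)[-c(1, k)]^0.9)
        truth[tissue] <- 2L + findInterval(vals, qs)
        truth[truth > k] <- k
      }
      truth
    })
}

#' Generate a synthetic brain phantom
#'
#' Builds the geometric ground-truth label map, assigns each class its mean
#' intensity, applies the optional smooth multiplicative bias field, adds
#' seeded Gaussian noise, and clips to [0, 1] (which slightly truncates
#' noise tails near the intensity bounds). Identical specs (including the
#' seed) give identical phantoms.
#'
#' @param spec a \code{\link{phantomSpec}}.
#' @return A \code{\linkS4class{Phantom}} with \code{phantomImage} and
#'   \code{phantomTruth} accessors.
#' @examples
#' ph <- generatePhantom(phantomSpec(shape = c(64, 64), classSigma = 0.08,
#'                                   seed = 0))
#' table(phantomTruth(ph))
#' @export
generatePhantom <- function(spec = phantomSpec()) {
  validObject(spec)
  if (length(spec@classMeans) < 2L)
    stop("invalid spec: at least 2 classes required")
  withSeed(spec@seed, {
    truth <- buildTruthMap(spec)
    img <- matrix(spec@classMeans[truth], spec@shape[1], spec@shape[2])
    if (spec@biasAmplitude > 0) {
      nr <- spec@shape[1]; nc <- spec@shape[2]
      r <- matrix(seq_len(nr) / nr, nr, nc)
      cl <- matrix(seq_len(nc) / nc, nr, nc, byrow = TRUE)
      field <- sin(pi * (1.3 * r + 0.2)) * sin(pi * (1.1 * cl + 0.35))
      img <- img * (1 + spec@biasAmplitude * field / max(abs(field)))
    }
    if (spec@classSigma > 0)
      img <- img + matrix(stats::rnorm(length(img), 0, spec@classSigma),
                          nrow(img), ncol(img))
    img <- pmin(pmax(img, 0), 1)
    new("Phantom", image = img, truth = truth, spec = spec)
  })
}

#' Generate a seeded 1D Gaussian-mixture feature set
#'
#' Equal-weight mixture fixture for clustering experiments: each point's
#' component is drawn uniformly and its intensity from a Gaussian around
#' that component's mean.
#'
#' @param n number of points (>= number of components).
#' @param means numeric vector of component means.
#' @param sigma common component standard deviation (>= 0).
#' @param seed integer RNG seed.
#' @return A list with \code{features} (numeric vector) and \code{labels}
#'   (generating component of each point, in 1..length(means)).
#' @examples
#' pts <- generateClusterPoints(200, c(0.2, 0.8), sigma = 0.02, seed = 4)
#' tapply(pts$features, pts$labels, mean)
#' @export
generateClusterPoints <- function(n, means, sigma, seed = 1) {
  if (sigma < 0) stop("invalid spec: 'sigma' must be >= 0")
  if (n < length(means))
    stop("invalid spec: need at least one point per component")
  withSeed(seed, {
    comp <- sample.int(length(means), n, replace = TRUE)
    x <- stats::rnorm(n, mean = means[comp], sd = sigma)
    list(features = x, labels = as.integer(comp))
  })
}
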