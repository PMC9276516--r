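## End-to-end segmentation pipeline and its YAML-serializable run
## configuration.

#' Build a pipeline run configuration
#'
#' Bundles every tunable of the segmentation pipeline — clustering,
#' spatial regularization, PSO initialization, preprocessing and I/O —
#' into one plain, YAML-serializable list. All numeric fields are
#' normalized (integer counts stored as integers) so that a
#' write/read round trip through \code{\link{writeRunConfig}} /
#' \code{\link{readRunConfig}} reproduces the object exactly.
#'
#' @param input input image path (or \code{NULL} when the image is passed
#'   directly to \code{\link{segmentImage}}).
#' @param truth optional ground-truth label-map path.
#' @param slice axial slice index for NIfTI volumes.
#' @param clusters,m,maxIter,epsilon,seed,init clustering settings, see
#'   \code{\link{fcmConfig}}.
#' @param beta,radius,sigmaG spatial-regularization settings, see
#'   \code{\link{spatialFcmFit}}; \code{sigmaG = NULL} means "image sd".
#' @param pso named list of \code{\link{psoConfig}} settings (the seed is
#'   taken from \code{seed}).
#' @param filter,filterSize preprocessing, see \code{\link{preprocess}}.
#' @return A list of class \code{"RunConfig"}.
#' @examples
#' cfg <- runConfig(clusters = 3, beta = 0.6, init = "pso", seed = 2)
#' @export
runConfig <- function(input = NULL, truth = NULL, slice = NULL,
                      clusters = 3, m = 2, maxIter = 100, epsilon = 1e-4,
                      seed = 1, init = "pso", beta = 0.5, radius = 1,
                      sigmaG = NULL,
                      pso = list(swarmSize = 20, iterations = 50,
                                 inertia = 0.72, cognitive = 1.49,
                                 social = 1.49, velocityClamp = 0.2),
                      filter = "median", filterSize = 3) {
  psoDefaults <- list(swarmSize = 20L, iterations = 50L, inertia = 0.72,
                      cognitive = 1.49, social = 1.49, velocityClamp = 0.2)
  pso <- utils::modifyList(psoDefaults, pso[!vapply(pso, is.null,
                                                    logical(1))])
  pso$swarmSize <- as.integer(pso$swarmSize)
  pso$iterations <- as.integer(pso$iterations)
  cfg <- list(input = input, truth = truth,
              slice = if (is.null(slice)) NULL else as.integer(slice),
              clusters = as.integer(clusters), m = as.numeric(m),
              maxIter = as.integer(maxIter), epsilon = as.numeric(epsilon),
              seed = as.integer(seed), init = as.character(init),
              beta = as.numeric(beta), radius = as.integer(radius),
              sigmaG = if (is.null(sigmaG)) NULL else as.numeric(sigmaG),
              pso = pso, filter = as.character(filter),
              filterSize = as.integer(filterSize))
  ## validate by constructing the component configs
  fcmConfig(cfg$clusters, cfg$m, cfg$maxIter, cfg$epsilon, cfg$seed,
            cfg$init)
  if (cfg$beta < 0 || cfg$beta > 1) stop("'beta' must lie in [0, 1]")
  structure(cfg, class = "RunConfig")
}

#' Serialize a run configuration to YAML
#'
#' @param config a \code{\link{runConfig}}.
#' @param path output YAML path.
#' @return The path, invisibly.
#' @export
writeRunConfig <- function(config, path) {
  stopifnot(inherits(config, "RunConfig"))
  flat <- config[!vapply(config, is.null, logical(1))]
  yaml::write_yaml(unclass(flat), path)
  invisible(path)
}

#' Read a run configuration from YAML
#'
#' Unknown keys are rejected; missing keys take their defaults.
#'
#' @param path YAML path written by \code{\link{writeRunConfig}} (or by
#'   hand, with the same keys).
#' @return A \code{\link{runConfig}}.
#' @export
readRunConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(runConfig))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("invalid config: unknown key(s): ", paste(bad, collapse = ", "))
  do.call(runConfig, raw)
}

#' Run the full segmentation pipeline
#'
#' The end-to-end method: load (or accept) a grayscale image, median
#' filter it, initialize cluster centers (PSO, k-means++ or random draw,
#' per the config), run spatially regularized fuzzy C-means
#' (\code{beta = 0} falls back to the classical fit), derive the hard
#' label map and the membership-weighted reconstruction, and — when
#' ground truth is available — the SB accuracy and reconstruction error
#' rate. With \code{outDir} set, writes \code{labels.png} (fixed tissue
#' palette), \code{reconstruction.png}, \code{report.json} and
#' \code{run.yaml} (config, seed, centers, iterations); all outputs are a
#' deterministic function of the configuration, so repeated runs are
#' file-identical.
#'
#' @param input image matrix, or a path readable by \code{\link{loadImage}};
#'   \code{NULL} uses \code{config$input}.
#' @param truth optional ground-truth label matrix (or label-map PNG path).
#' @param config a \code{\link{runConfig}}.
#' @param outDir optional output directory for artifacts.
#' @return A list: \code{result} (\code{FCMResult}), \code{labels} (label
#'   matrix), \code{reconstruction}, \code{metrics} (list with \code{sb},
#'   \code{wRE}, per-class overlap; \code{NULL} without truth), and
#'   \code{files} (paths written).
#' @examples
#' ph <- generatePhantom(phantomSpec(shape = c(32, 32), classSigma = 0.05,
#'                                   seed = 1))
#' out <- segmentImage(phantomImage(ph), truth = phantomTruth(ph),
#'                     config = runConfig(seed = 1, init = "random",
#'                                        maxIter = 30))
#' out$metrics$sb
#' @export
segmentImage <- function(input = NULL, truth = NULL,
                         config = runConfig(), outDir = NULL) {
  stopifnot(inherits(config, "RunConfig"))
  if (is.null(input)) input <- config$input
  img <- if (is.character(input)) loadImage(input, config$slice) else input
  if (!is.matrix(img)) stop("invalid input: expected an image matrix")
  if (is.null(truth) && !is.null(config$truth)) truth <- config$truth
  if (is.character(truth)) truth <- loadLabelMap(truth, config$clusters)

  img <- preprocess(img, config$filter, config$filterSize)
  fc <- fcmConfig(config$clusters, config$m, config$maxIter,
                  config$epsilon, config$seed, config$init)
  init <- if (config$init == "pso") {
    pc <- do.call(psoConfig, c(config$pso, list(seed = config$seed)))
    psoInitCenters(as.numeric(img), config$clusters, pc, m = config$m)
  } else NULL
  fit <- spatialFcmFit(img, fc, neighborhoodSpec(config$radius),
                       sigmaG = config$sigmaG, beta = config$beta,
                       initCenters = init)
  labels <- clusterLabels(fit)
  recon <- reconstructImage(fit)
  metrics <- if (!is.null(truth)) {
    evaluateSegmentation(labels, truth, clusters = config$clusters)
  } else NULL
  if (!is.null(metrics)) metrics$wRE <- reconstructionError(img, recon)

  files <- character(0)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    files <- c(labels = file.path(outDir, "labels.png"),
               reconstruction = file.path(outDir, "reconstruction.png"),
               report = file.path(outDir, "report.json"),
               config = file.path(outDir, "run.yaml"))
    saveLabelMap(labels, files[["labels"]])
    saveImage(recon, files[["reconstruction"]])
    report <- list(centers = centers(fit), nIter = nIter(fit),
                   converged = converged(fit), seed = config$seed,
                   objective = utils::tail(objectiveTrace(fit), 1L))
    if (!is.null(metrics))
      report <- c(report, list(sb = metrics$sb, wRE = metrics$wRE))
    jsonlite::write_json(report, files[["report"]], auto_unbox = TRUE,
                         digits = NA)
    writeRunConfig(config, files[["config"]])
  }
  list(result = fit, labels = labels, reconstruction = recon,
       metrics = metrics, files = files)
}
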