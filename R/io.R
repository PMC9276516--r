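## Image input/output and preprocessing.

imageFormat <- function(path) {
  lower <- tolower(path)
  if (grepl("\\.png$", lower)) "png"
  else if (grepl("\\.(tif|tiff)$", lower)) "tiff"
  else if (grepl("\\.nii(\\.gz)?$", lower)) "nifti"
  else stop("I/O error: unsupported image format for '", path,
            "' (PNG, TIFF or NIfTI expected)")
}

#' Load a grayscale image and normalize it to [0, 1]
#'
#' Reads 8/16-bit PNG or TIFF, or a NIfTI volume (with \code{slice}
#' selecting an axial slice), converts multi-channel input to its channel
#' mean, and min-max normalizes the intensities to [0, 1]. The source
#' path and the normalization offset/scale are recorded in the
#' \code{"provenance"} attribute so results can be mapped back to the
#' original gray scale. A constant image normalizes to all zeros (with a
#' warning).
#'
#' @param path image file path.
#' @param slice axial slice index, required for 3D NIfTI volumes.
#' @return A numeric matrix in [0, 1] with a \code{"provenance"} attribute
#'   (list: \code{path}, \code{min}, \code{max}, \code{slice}).
#' @export
loadImage <- function(path, slice = NULL) {
  if (!file.exists(path)) stop("I/O error: file not found: ", path)
  fmt <- imageFormat(path)
  px <- switch(fmt,
    png = png::readPNG(path),
    tiff = tiff::readTIFF(path),
    nifti = {
      vol <- RNifti::readNifti(path)
      arr <- as.array(vol)
      if (length(dim(arr)) >= 3L && dim(arr)[3] > 1L) {
        if (is.null(slice))
          stop("I/O error: NIfTI volume requires a 'slice' index")
        arr <- arr[, , slice]
      } else if (length(dim(arr)) == 3L) arr <- arr[, , 1L]
      arr
    })
  if (length(dim(px)) == 3L) px <- apply(px, c(1, 2), mean)  # channel mean
  px <- matrix(as.numeric(px), nrow(px), ncol(px))
  if (any(!is.finite(px))) stop("I/O error: non-finite pixels in ", path)
  lo <- min(px); hi <- max(px)
  if (hi == lo) {
    warning("constant image: normalized to all zeros")
    out <- matrix(0, nrow(px), ncol(px))
  } else out <- (px - lo) / (hi - lo)
  attr(out, "provenance") <- list(path = path, min = lo, max = hi,
                                  slice = slice)
  out
}

#' Write a grayscale image
#'
#' Writes a [0, 1] intensity matrix as 8-bit PNG, float TIFF, or NIfTI
#' depending on the file extension. Values are clipped to [0, 1] first.
#'
#' @param image numeric matrix.
#' @param path output path (.png, .tif/.tiff, .nii/.nii.gz).
#' @return The path, invisibly.
#' @export
saveImage <- function(image, path) {
  img <- pmin(pmax(unclass(image), 0), 1)
  attributes(img) <- list(dim = dim(image))
  switch(imageFormat(path),
    png = png::writePNG(img, path),
    tiff = tiff::writeTIFF(img, path),
    nifti = RNifti::writeNifti(RNifti::asNifti(img), path))
  invisible(path)
}

#' Write a label map as a paletted PNG
#'
#' Fixed palette for visual diffing of tissue maps: class 1 dark blue
#' (CSF), class 2 mid gray (GM), class 3 near-white (WM), further classes
#' cycle through distinct colors.
#'
#' @param labels integer matrix of labels in 1..c.
#' @param path output PNG path.
#' @return The path, invisibly.
#' @export
saveLabelMap <- function(labels, path) {
  palette <- matrix(c(
    0.10, 0.15, 0.45,   # CSF: dark blue
    0.55, 0.55, 0.55,   # GM: mid gray
    0.95, 0.95, 0.90,   # WM: near white
    0.80, 0.25, 0.20,
    0.20, 0.65, 0.30,
    0.85, 0.65, 0.10), ncol = 3, byrow = TRUE)
  idx <- ((as.integer(labels) - 1L) %% nrow(palette)) + 1L
  rgb <- array(0, dim = c(nrow(labels), ncol(labels), 3))
  for (ch in 1:3)
    rgb[, , ch] <- matrix(palette[idx, ch], nrow(labels), ncol(labels))
  png::writePNG(rgb, path)
  invisible(path)
}

#' Read a label map written by \code{saveLabelMap}
#'
#' @param path PNG path.
#' @param clusters number of classes expected.
#' @return Integer matrix of labels in 1..clusters.
#' @export
loadLabelMap <- function(path, clusters = 3) {
  rgb <- png::readPNG(path)
  palette <- matrix(c(
    0.10, 0.15, 0.45, 0.55, 0.55, 0.55, 0.95, 0.95, 0.90,
    0.80, 0.25, 0.20, 0.20, 0.65, 0.30, 0.85, 0.65, 0.10),
    ncol = 3, byrow = TRUE)[seq_len(clusters), , drop = FALSE]
  flat <- matrix(rgb, ncol = 3)
  d2 <- outer(rowSums(flat^2), rowSums(palette^2), "+") -
    2 * flat %*% t(palette)
  matrix(as.integer(apply(d2, 1L, which.min)), dim(rgb)[1], dim(rgb)[2])
}

#' Median-filter an image
#'
#' Sliding-window median with mirror padding; the default 3x3 window
#' removes impulse noise while preserving edges, the usual light denoising
#' step before intensity clustering. The output range is contained in the
#' input range; \code{filter = "none"} returns the image unchanged.
#'
#' @param image numeric matrix.
#' @param filter \code{"median"} or \code{"none"}.
#' @param size odd window side length >= 3.
#' @return The filtered matrix.
#' @examples
#' img <- matrix(0.5, 5, 5); img[3, 3] <- 1   # impulse
#' max(preprocess(img))                        # 0.5: removed
#' @export
preprocess <- function(image, filter = c("median", "none"), size = 3) {
  filter <- match.arg(filter)
  if (filter == "none") return(image)
  size <- as.integer(size)
  if (size %% 2L == 0L || size < 3L)
    stop("invalid config: window 'size' must be odd and >= 3")
  r <- (size - 1L) %/% 2L
  offs <- expand.grid(dr = -r:r, dc = -r:r)
  stack <- vapply(seq_len(nrow(offs)),
                  function(j) as.numeric(shiftMirror(image, offs$dr[j],
                                                     offs$dc[j])),
                  numeric(length(image)))
  out <- apply(stack, 1L, stats::median)
  matrix(out, nrow(image), ncol(image))
}
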