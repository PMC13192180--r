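# Automated Iba1+ cell counting: z-projection, background subtraction,
# DAPI colocalization masking, auto-thresholding, despeckling, particle
# filtering and per-mm^2 extrapolation.

#' Maximum-intensity z-projection
#'
#' Per-pixel maximum over a stack of equally shaped planes (stacks of seven
#' planes at 0.85 um steps in the acquisition convention).
#'
#' @param planes list of numeric matrices of identical dimension.
#' @return single projected matrix.
#' @export
zProject <- function(planes) {
  stopifnot2(length(planes) >= 1, "need at least one plane")
  d <- dim(planes[[1]])
  ok <- vapply(planes, function(p) identical(dim(p), d), logical(1))
  stopifnot2(all(ok), "plane shapes differ")
  Reduce(pmax, planes)
}

#' Count Iba1+ microglia in an ROI and extrapolate density
#'
#' The counting pipeline: background subtraction on the Iba1 channel (large
#' Gaussian background estimate), DAPI binarized with the "default dark"
#' (iterative intermeans) threshold, the DAPI mask clears Iba1 signal that
#' does not colocalize with a nucleus, the remaining Iba1 is binarized with
#' the same threshold rule, despeckled (3x3 median), outlier-cleaned, and
#' connected components of at least \code{minParticlePx} pixels are counted
#' as somata. The cutoff discards small patches where nuclei of other cell
#' types cross microglial ramifications. Counts from the default
#' 200 x 200 um ROI extrapolate to a density of \code{25 * n} per mm^2.
#'
#' @param dapi,iba1 \code{\linkS4class{ChannelImage}}s with equal pixel
#'   sizes.
#' @param roiUm c(x0, y0, width, height) of the ROI in um; default the full
#'   200 x 200 um window anchored at the origin.
#' @param minParticlePx minimal particle area in pixels (default 400).
#' @param backgroundSigmaPx sigma of the Gaussian background estimate
#'   (pixels).
#' @return list: \code{nSomata}, \code{densityPerMm2}, \code{roiUm},
#'   \code{labels} (component label matrix inside the ROI).
#' @export
countMicroglia <- function(dapi, iba1, roiUm = NULL, minParticlePx = 400,
                           backgroundSigmaPx = 50) {
  stopifnot2(is(dapi, "ChannelImage") && is(iba1, "ChannelImage"),
             "inputs must be ChannelImages")
  stopifnot2(isTRUE(all.equal(dapi@pixelUm, iba1@pixelUm)),
             "pixel sizes differ between channels")
  px <- dapi@pixelUm
  if (is.null(roiUm)) roiUm <- c(0, 0, 200, 200)
  i0 <- floor(roiUm[1] / px) + 1; j0 <- floor(roiUm[2] / px) + 1
  i1 <- i0 + round(roiUm[3] / px) - 1; j1 <- j0 + round(roiUm[4] / px) - 1
  stopifnot2(i0 >= 1 && j0 >= 1 && i1 <= nrow(dapi@pixels) &&
               j1 <= ncol(dapi@pixels), "ROI outside image")
  d <- dapi@pixels[i0:i1, j0:j1]
  b <- iba1@pixels[i0:i1, j0:j1]
  # background subtraction on Iba1
  bg <- ebMat(EBImage::gblur(EBImage::Image(b),
                                 sigma = backgroundSigmaPx))
  b <- pmax(b - bg, 0)
  b <- b / max(b, 1e-12)
  # DAPI mask
  dMask <- thresholdDefaultDark(d)
  b[!dMask] <- 0
  # binarize the colocalizing Iba1 signal
  bMask <- thresholdDefaultDark(b)
  # despeckle (3x3 median) and remove outliers
  bMask <- ebMat(EBImage::medianFilter(EBImage::Image(bMask * 1), 1)) > 0.5
  bMask <- EBImage::opening(bMask, EBImage::makeBrush(3, "diamond")) > 0.5
  lab <- EBImage::bwlabel(EBImage::Image(bMask * 1))
  sizes <- table(lab[lab > 0])
  keep <- as.integer(names(sizes)[sizes >= minParticlePx])
  labM <- ebMat(EBImage::Image(lab))
  labM[!(labM %in% keep)] <- 0
  # relabel contiguously
  old <- sort(unique(labM[labM > 0]))
  labM[] <- match(labM, old, nomatch = 0)
  n <- length(old)
  density <- n * (1000 / roiUm[3]) * (1000 / roiUm[4])
  list(nSomata = n, densityPerMm2 = density, roiUm = roiUm, labels = labM)
}
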