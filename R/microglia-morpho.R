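# Per-cell morphometry: soma markers from DAPI/Iba1 colocalization,
# marker-controlled watershed territories, skeletonization, Sholl analysis.

#' Find soma markers from DAPI/Iba1 colocalization
#'
#' The colocalization image (pixelwise minimum of the two channels) is
#' binarized with the "minimum" thresholding algorithm; centers of the
#' resulting components mark microglial nuclei. The Iba1 channel is
#' thresholded at \code{somaThreshold} (a fixed, reproducible replacement
#' for the interactive soma threshold, with a triangle-method fallback),
#' cleaned by binary area filtering (components above
#' \code{attributeAreaPx} px are kept, emulating grayscale area-attribute
#' filtering of somata), and components smaller than \code{minSomaPx} are
#' discarded.
#' One marker is returned per retained soma containing a colocalization
#' center.
#'
#' @param dapi,iba1 \code{\linkS4class{ChannelImage}}s.
#' @param attributeAreaPx area-filter cutoff (px), default 99.
#' @param minSomaPx minimal soma area (px), default 300.
#' @param somaThreshold fixed intensity threshold isolating somata from
#'   processes (default 0.7 of the dynamic range); \code{NA} uses the
#'   triangle method instead.
#' @return list: \code{centersPx} (n x 2, pixel coords), \code{centersUm},
#'   \code{somaMask} (logical), \code{markerLabels} (matrix; one label per
#'   soma).
#' @export
findSomaMarkers <- function(dapi, iba1, attributeAreaPx = 99,
                            minSomaPx = 300, somaThreshold = 0.7) {
  px <- dapi@pixelUm
  coloc <- pmin(dapi@pixels, iba1@pixels)
  if (max(coloc) <= 0.02)
    return(list(centersPx = matrix(numeric(0), ncol = 2),
                centersUm = matrix(numeric(0), ncol = 2),
                somaMask = matrix(FALSE, nrow(coloc), ncol(coloc)),
                markerLabels = matrix(0L, nrow(coloc), ncol(coloc))))
  cMask <- coloc > autoThreshold(coloc, "minimum")
  cLab <- ebMat(EBImage::bwlabel(EBImage::Image(cMask * 1)))
  nC <- max(cLab)
  if (nC == 0)
    return(list(centersPx = matrix(numeric(0), ncol = 2),
                centersUm = matrix(numeric(0), ncol = 2),
                somaMask = matrix(FALSE, nrow(coloc), ncol(coloc)),
                markerLabels = matrix(0L, nrow(coloc), ncol(coloc))))
  centers <- t(vapply(seq_len(nC), function(k) {
    w <- which(cLab == k, arr.ind = TRUE)
    colMeans(w)
  }, numeric(2)))
  # soma mask from Iba1: somata are the brightest structures, so a fixed
  # high threshold (the reproducible replacement for the interactive soma
  # threshold) separates them from processes; NA falls back to the
  # triangle method
  sThr <- if (is.na(somaThreshold)) autoThreshold(iba1@pixels, "triangle")
          else somaThreshold
  sMask <- iba1@pixels > sThr
  sLab <- ebMat(EBImage::bwlabel(EBImage::Image(sMask * 1)))
  sz <- table(sLab[sLab > 0])
  dropSmall <- as.integer(names(sz)[sz <= attributeAreaPx])
  sLab[sLab %in% dropSmall] <- 0L
  sz <- table(sLab[sLab > 0])
  dropSoma <- as.integer(names(sz)[sz < minSomaPx])
  sLab[sLab %in% dropSoma] <- 0L
  # one marker per soma component that contains a colocalization center
  ci <- pmin(pmax(round(centers[, 1]), 1), nrow(sLab))
  cj <- pmin(pmax(round(centers[, 2]), 1), ncol(sLab))
  somaOf <- sLab[cbind(ci, cj)]
  keep <- somaOf > 0 & !duplicated(somaOf)
  if (any(somaOf > 0 & duplicated(somaOf)))
    warning("duplicate markers in one soma were merged")
  centers <- centers[keep, , drop = FALSE]
  markers <- matrix(0L, nrow(sLab), ncol(sLab))
  if (nrow(centers)) {
    # seed a small disk around each center so watershed seeds are robust
    for (k in seq_len(nrow(centers)))
      markers <- drawDisk(markers, centers[k, 1], centers[k, 2], 3, k)
  }
  somaMask <- sLab > 0
  list(centersPx = centers, centersUm = (centers - 1) * px,
       somaMask = somaMask, markerLabels = markers)
}

#' Assign a territory to each microglial cell
#'
#' The soma mask is dilated by a disk of radius \code{dilationPx} to define
#' the admissible domain; a marker-controlled watershed (seeded region
#' growing on the inverted, Gaussian-smoothed Iba1 intensity) partitions
#' that domain into one territory per marker.
#'
#' @param iba1 a \code{\linkS4class{ChannelImage}}.
#' @param markers marker structure from \code{\link{findSomaMarkers}}.
#' @param dilationPx dilation radius (px), default 100.
#' @return a \code{\linkS4class{CellTerritoryMap}}.
#' @export
assignTerritories <- function(iba1, markers, dilationPx = 100) {
  stopifnot2(nrow(markers$centersPx) >= 1, "need at least one marker")
  # disk dilation via the Euclidean distance transform (fast for large radii)
  dist <- ebMat(EBImage::distmap(EBImage::Image(1 - markers$somaMask)))
  domain <- dist <= dilationPx
  relief <- ebMat(EBImage::gblur(EBImage::Image(iba1@pixels), sigma = 1))
  relief <- max(relief) - relief          # invert: bright cells become basins
  seg <- EBImage::propagate(EBImage::Image(relief),
                            EBImage::Image(markers$markerLabels),
                            mask = EBImage::Image(domain * 1))
  lab <- EBImage::imageData(seg)
  storage.mode(lab) <- "integer"
  new("CellTerritoryMap", labels = lab,
      somaCenters = markers$centersUm, pixelUm = iba1@pixelUm)
}

#' Skeletonize one cell's processes
#'
#' Within the cell's territory, the Iba1 signal is sharpened (unsharp
#' mask), median-despeckled, thresholded with the Kapur max-entropy rule,
#' morphologically closed to reconnect process fragments, reduced to the
#' connected component containing the soma center (reconstruction from the
#' nucleus seed), and thinned to 1-px-wide curves (Zhang-Suen).
#'
#' @param iba1 a \code{\linkS4class{ChannelImage}}.
#' @param territories a \code{\linkS4class{CellTerritoryMap}}.
#' @param cellId which territory to skeletonize.
#' @return list: \code{skeleton} (logical matrix), \code{centerPx},
#'   \code{cellId}; an empty foreground yields an empty skeleton with a
#'   warning.
#' @export
skeletonizeCell <- function(iba1, territories, cellId) {
  lab <- territoryLabels(territories)
  inTfull <- lab == cellId
  stopifnot2(any(inTfull), "territory is empty")
  # work on the territory's bounding box (plus margin) for speed
  wIdx <- which(inTfull, arr.ind = TRUE)
  r0 <- max(1L, min(wIdx[, 1]) - 5L); r1 <- min(nrow(lab), max(wIdx[, 1]) + 5L)
  c0 <- max(1L, min(wIdx[, 2]) - 5L); c1 <- min(ncol(lab), max(wIdx[, 2]) + 5L)
  inT <- inTfull[r0:r1, c0:c1]
  img <- iba1@pixels[r0:r1, c0:c1]
  blur <- ebMat(EBImage::gblur(EBImage::Image(img), sigma = 2))
  sharp <- pmin(pmax(img + 0.6 * (img - blur), 0), 1)
  sharp <- ebMat(EBImage::medianFilter(EBImage::Image(sharp), 1))
  sharp[!inT] <- 0
  fg <- sharp[inT]
  if (max(fg) == 0) {
    warning("empty foreground after threshold: empty skeleton")
    return(list(skeleton = matrix(FALSE, nrow(lab), ncol(lab)),
                centerPx = territories@somaCenters[cellId, ] /
                  territories@pixelUm + 1,
                cellId = cellId))
  }
  thr <- autoThreshold(sharp[inT], "maxentropy")
  mask <- sharp > thr & inT
  mask <- ebMat(EBImage::closing(EBImage::Image(mask * 1),
                                     EBImage::makeBrush(5, "disc"))) > 0.5
  # unsharp masking over-weights object rims; filling enclosed holes keeps
  # a uniform soma from degenerating into a ring
  mask <- ebMat(EBImage::fillHull(EBImage::Image(mask * 1))) > 0.5
  # reconstruct from the soma seed: keep the component under the center
  ctr <- territories@somaCenters[cellId, ] / territories@pixelUm + 1
  ctrB <- ctr - c(r0 - 1, c0 - 1)          # center in bounding-box coords
  comp <- ebMat(EBImage::bwlabel(EBImage::Image(mask * 1)))
  ci <- pmin(pmax(round(ctrB[1]), 1), nrow(comp))
  cj <- pmin(pmax(round(ctrB[2]), 1), ncol(comp))
  own <- comp[ci, cj]
  if (own == 0) {
    near <- which(comp > 0, arr.ind = TRUE)
    if (!nrow(near)) {
      warning("empty foreground after threshold: empty skeleton")
      return(list(skeleton = matrix(FALSE, nrow(lab), ncol(lab)),
                  centerPx = ctr, cellId = cellId))
    }
    d <- (near[, 1] - ctrB[1])^2 + (near[, 2] - ctrB[2])^2
    own <- comp[near[which.min(d), , drop = FALSE]]
  }
  mask <- comp == own
  storage.mode(mask) <- "integer"
  skelB <- .thinBinary(mask) == 1L
  skel <- matrix(FALSE, nrow(lab), ncol(lab))
  skel[r0:r1, c0:c1] <- skelB
  list(skeleton = skel, centerPx = ctr, cellId = cellId)
}

#' Sholl analysis of a skeleton
#'
#' For each radius on an arithmetic grid, counts the distinct crossings of
#' the skeleton with the circle around the soma center. The circle is
#' sampled densely and a crossing is a maximal run of skeleton-occupied
#' samples (with circular wrap-around), which avoids double-counting thick
#' diagonal pixel steps.
#'
#' @param skeleton list from \code{\link{skeletonizeCell}} (or any list
#'   with \code{skeleton}, \code{centerPx}, \code{cellId}).
#' @param pixelUm pixel size (um/pixel).
#' @param stepUm radius step (um), default 5.
#' @param rStartUm first radius (um), default 5 (about the soma radius).
#' @param rMaxUm last radius (um); default reaches the image corner.
#' @return a \code{\linkS4class{ShollProfile}}.
#' @export
sholl <- function(skeleton, pixelUm, stepUm = 5, rStartUm = 5,
                  rMaxUm = NULL) {
  sk <- skeleton$skeleton
  ctr <- skeleton$centerPx
  if (is.null(rMaxUm))
    rMaxUm <- sqrt(nrow(sk)^2 + ncol(sk)^2) * pixelUm
  radii <- seq(rStartUm, rMaxUm, by = stepUm)
  counts <- vapply(radii, function(r) {
    rp <- r / pixelUm
    nA <- max(64L, ceiling(2 * pi * rp * 2))
    th <- seq(0, 2 * pi, length.out = nA + 1)[-(nA + 1)]
    ii <- round(ctr[1] + rp * cos(th))
    jj <- round(ctr[2] + rp * sin(th))
    ok <- ii >= 1 & ii <= nrow(sk) & jj >= 1 & jj <= ncol(sk)
    hit <- logical(nA)
    hit[ok] <- sk[cbind(ii[ok], jj[ok])]
    if (!any(hit)) return(0L)
    if (all(hit)) return(1L)
    runs <- sum(hit & !c(hit[nA], hit[-nA]))   # circular run starts
    as.integer(runs)
  }, integer(1))
  new("ShollProfile", radii = radii, intersections = counts,
      center = (ctr - 1) * pixelUm, cellId = as.integer(skeleton$cellId))
}

#' Full morphometry pipeline
#'
#' Composition of \code{\link{findSomaMarkers}},
#' \code{\link{assignTerritories}}, \code{\link{skeletonizeCell}} and
#' \code{\link{sholl}} over every detected cell. Per-cell records carry the
#' configuration used.
#'
#' @param dapi,iba1 \code{\linkS4class{ChannelImage}}s.
#' @param dilationPx watershed domain dilation (px), default 100.
#' @param minSomaPx minimal soma area (px), default 300.
#' @param attributeAreaPx area-filter cutoff (px), default 99.
#' @param shollStepUm Sholl radius step (um), default 5.
#' @return list: \code{territories} (\code{\linkS4class{CellTerritoryMap}}
#'   or NULL for an empty field), \code{profiles} (list of
#'   \code{\linkS4class{ShollProfile}}), \code{config}.
#' @export
morphometryPipeline <- function(dapi, iba1, dilationPx = 100,
                                minSomaPx = 300, attributeAreaPx = 99,
                                shollStepUm = 5) {
  cfg <- list(dilationPx = dilationPx, minSomaPx = minSomaPx,
              attributeAreaPx = attributeAreaPx, shollStepUm = shollStepUm)
  mk <- findSomaMarkers(dapi, iba1, attributeAreaPx = attributeAreaPx,
                        minSomaPx = minSomaPx)
  if (nrow(mk$centersPx) == 0)
    return(list(territories = NULL, profiles = list(), config = cfg))
  terr <- assignTerritories(iba1, mk, dilationPx = dilationPx)
  profiles <- lapply(seq_len(nCells(terr)), function(k) {
    sk <- skeletonizeCell(iba1, terr, k)
    sholl(sk, pixelUm = iba1@pixelUm, stepUm = shollStepUm)
  })
  list(territories = terr, profiles = profiles, config = cfg)
}
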