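# Seeded two-channel (DAPI / Iba1) fluorescence-image generator with
# ground-truth cell centers and branch graphs. Emulates z-projected confocal
# fields of ramified, de-ramified or hypertrophic microglia over a DAPI
# nuclei field; it does not attempt a realistic confocal PSF or tissue
# autofluorescence.

#' Specification for a synthetic DAPI/Iba1 image pair
#'
#' Defaults describe a 300 x 300 um field at 0.31 um/pixel (a 2048-px
#' confocal scan convention) with ramified microglia: 4.5 um soma radius,
#' five primary branches of 40 um carrying secondary branches, plus a
#' background field of non-microglial DAPI nuclei. The de-ramified phenotype
#' shortens processes to 35\% at the same branch count; the hypertrophic
#' phenotype shortens to 60\% and thickens soma and processes.
#'
#' @param fieldUm c(width, height) of the field (um).
#' @param pixelUm pixel size (um/pixel).
#' @param nCells number of microglia (>= 0).
#' @param phenotype "ramified", "deramified" or "hypertrophic".
#' @param somaRadiusUm soma radius (um).
#' @param nBranches primary branches per cell.
#' @param branchLengthUm primary branch length (um) before the phenotype
#'   scaling.
#' @param nucleiDensity density of non-microglial nuclei (per mm^2).
#' @param psfSigmaUm Gaussian blur sigma (um) emulating the optics.
#' @param noiseSd additive Gaussian noise SD (fraction of dynamic range).
#' @param bitDepth 8 or 16.
#' @param seed integer seed.
#' @return list of class \code{"ImageGenSpec"}.
#' @export
imageGenSpec <- function(fieldUm = c(300, 300), pixelUm = 0.31, nCells = 6,
                         phenotype = c("ramified", "deramified",
                                       "hypertrophic"),
                         somaRadiusUm = 4.5, nBranches = 5,
                         branchLengthUm = 40, nucleiDensity = 800,
                         psfSigmaUm = 0.4, noiseSd = 0, bitDepth = 8,
                         seed = 1L) {
  phenotype <- match.arg(phenotype)
  stopifnot2(nCells >= 0, "nCells must be non-negative")
  stopifnot2(bitDepth %in% c(8, 16), "bitDepth must be 8 or 16")
  stopifnot2(all(fieldUm > 0) && pixelUm > 0, "field and pixel sizes must be positive")
  structure(list(fieldUm = fieldUm, pixelUm = pixelUm, nCells = nCells,
                 phenotype = phenotype, somaRadiusUm = somaRadiusUm,
                 nBranches = nBranches, branchLengthUm = branchLengthUm,
                 nucleiDensity = nucleiDensity, psfSigmaUm = psfSigmaUm,
                 noiseSd = noiseSd, bitDepth = bitDepth,
                 seed = as.integer(seed)),
            class = "ImageGenSpec")
}

# phenotype-dependent geometry knobs
phenoPars <- function(spec) {
  switch(spec$phenotype,
    ramified = list(lenScale = 1, widthUm = 1.2, somaScale = 1,
                    secondary = TRUE),
    deramified = list(lenScale = 0.35, widthUm = 1.6, somaScale = 1,
                      secondary = FALSE),
    hypertrophic = list(lenScale = 0.6, widthUm = 2.4, somaScale = 1.3,
                        secondary = FALSE))
}

#' Generate a synthetic DAPI/Iba1 image pair with ground truth
#'
#' Places \code{nCells} microglia by dart throwing with a minimal
#' center-to-center separation of \code{2 * somaRadiusUm + 6} um, draws the
#' DAPI channel (microglial nuclei plus a random background nuclei field)
#' and the Iba1 channel (soma disks plus piecewise-linear branch trees),
#' blurs both with a Gaussian of \code{psfSigmaUm}, adds Gaussian noise and
#' quantizes to \code{bitDepth}. Ground truth records the microglia centers
#' (um) and each cell's branch segments and total branch length, from which
#' Sholl expectations are computable analytically.
#'
#' @param spec an \code{\link{imageGenSpec}}.
#' @return list with \code{dapi}, \code{iba1}
#'   (\code{\linkS4class{ChannelImage}}) and \code{truth} (list: spec,
#'   \code{centersUm} n x 2 matrix, \code{cells} per-cell segment tables,
#'   \code{totalBranchLengthUm}).
#' @export
generateImagePair <- function(spec) {
  stopifnot2(inherits(spec, "ImageGenSpec"), "spec must come from imageGenSpec()")
  px <- spec$pixelUm
  nr <- round(spec$fieldUm[1] / px); nc <- round(spec$fieldUm[2] / px)
  pp <- phenoPars(spec)
  somaR <- spec$somaRadiusUm * pp$somaScale
  minSep <- 2 * spec$somaRadiusUm + 6
  margin <- somaR + 2
  withSeed(spec$seed, {
    # dart-throwing placement
    centers <- matrix(numeric(0), ncol = 2)
    tries <- 0
    while (nrow(centers) < spec$nCells) {
      tries <- tries + 1
      if (tries > 5000 * max(1, spec$nCells))
        stop("field too small for requested nCells at the minimum separation",
             call. = FALSE)
      cand <- c(runif(1, margin, spec$fieldUm[1] - margin),
                runif(1, margin, spec$fieldUm[2] - margin))
      if (!nrow(centers) ||
          min(sqrt((centers[, 1] - cand[1])^2 + (centers[, 2] - cand[2])^2)) >=
            minSep)
        centers <- rbind(centers, cand)
    }
    dapi <- matrix(0.02, nr, nc)
    iba1 <- matrix(0.02, nr, nc)
    cells <- list()
    totalLen <- 0
    for (ci in seq_len(nrow(centers))) {
      cx <- centers[ci, 1] / px; cy <- centers[ci, 2] / px
      iba1 <- drawDisk(iba1, cx, cy, somaR / px, 0.85)
      # microglia have scant perinuclear cytoplasm: the nucleus fills most
      # of the soma, so DAPI-masked Iba1 somata stay above the 400 px cutoff
      dapi <- drawDisk(dapi, cx, cy, 0.9 * somaR / px, 0.75)
      segs <- list()
      ang0 <- runif(1, 0, 2 * pi)
      len1 <- spec$branchLengthUm * pp$lenScale
      for (b in seq_len(spec$nBranches)) {
        a <- ang0 + 2 * pi * (b - 1) / spec$nBranches +
          runif(1, -0.15, 0.15)
        x0 <- centers[ci, 1] + somaR * cos(a)
        y0 <- centers[ci, 2] + somaR * sin(a)
        x1 <- centers[ci, 1] + (somaR + len1) * cos(a)
        y1 <- centers[ci, 2] + (somaR + len1) * sin(a)
        iba1 <- drawSegment(iba1, x0 / px, y0 / px, x1 / px, y1 / px,
                            pp$widthUm / px, 0.55)
        segs[[length(segs) + 1]] <- c(x0, y0, x1, y1)
        totalLen <- totalLen + len1
        if (pp$secondary) {
          for (sgn in c(-1, 1)) {
            ab <- a + sgn * 0.6
            bx0 <- centers[ci, 1] + (somaR + 0.6 * len1) * cos(a)
            by0 <- centers[ci, 2] + (somaR + 0.6 * len1) * sin(a)
            bx1 <- bx0 + 0.45 * len1 * cos(ab)
            by1 <- by0 + 0.45 * len1 * sin(ab)
            iba1 <- drawSegment(iba1, bx0 / px, by0 / px, bx1 / px, by1 / px,
                                0.8 * pp$widthUm / px, 0.5)
            segs[[length(segs) + 1]] <- c(bx0, by0, bx1, by1)
            totalLen <- totalLen + 0.45 * len1
          }
        }
      }
      segM <- do.call(rbind, segs)
      colnames(segM) <- c("x0", "y0", "x1", "y1")
      cells[[ci]] <- list(centerUm = centers[ci, ], segmentsUm = segM)
    }
    # background nuclei (non-microglial cells): DAPI only
    areaMm2 <- prod(spec$fieldUm) / 1e6
    nNuc <- rpois(1, spec$nucleiDensity * areaMm2)
    if (nNuc > 0) {
      nx <- runif(nNuc, 2, spec$fieldUm[1] - 2)
      ny <- runif(nNuc, 2, spec$fieldUm[2] - 2)
      for (k in seq_len(nNuc))
        dapi <- drawDisk(dapi, nx[k] / px, ny[k] / px, 2.8 / px, 0.7)
    }
    blurAndNoise <- function(m) {
      if (spec$psfSigmaUm > 0)
        m <- ebMat(EBImage::gblur(EBImage::Image(m),
                                      sigma = spec$psfSigmaUm / px))
      if (spec$noiseSd > 0) m <- m + rnorm(length(m), 0, spec$noiseSd)
      q <- 2^spec$bitDepth - 1
      matrix(round(pmin(pmax(m, 0), 1) * q) / q, nrow(m), ncol(m))
    }
    dapi <- blurAndNoise(dapi)
    iba1 <- blurAndNoise(iba1)
    dimnames(centers) <- NULL
    list(dapi = ChannelImage(dapi, px, "DAPI"),
         iba1 = ChannelImage(iba1, px, "Iba1"),
         truth = list(spec = spec, centersUm = centers, cells = cells,
                      totalBranchLengthUm = totalLen))
  })
}
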