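# Histogram-based automatic thresholding, re-implemented from the classic
# recurrences: iterative intermeans (IsoData variant, the "default dark"
# algorithm), Minimum (histogram smoothing until bimodal), Kapur
# max-entropy, and the triangle method. All operate on a 256-bin histogram;
# the returned threshold is a bin index T in 0..(nbins-1), with foreground
# defined as levels strictly above T ("dark" background convention).

#' Automatic threshold of an intensity histogram
#'
#' @param counts integer vector of histogram counts (one per gray level,
#'   level 0 first).
#' @param method one of "isodata" (iterative intermeans / "default dark"),
#'   "minimum" (smooth until exactly two modes, take the valley),
#'   "maxentropy" (Kapur), "triangle".
#' @return threshold level T (0-based); foreground = levels > T. For a
#'   constant histogram the full mass sits in one bin and T is that bin
#'   (empty foreground), with a warning.
#' @export
autoThresholdHist <- function(counts,
                              method = c("isodata", "minimum", "maxentropy",
                                         "triangle")) {
  method <- match.arg(method)
  counts <- as.numeric(counts)
  nb <- length(counts)
  lev <- 0:(nb - 1)
  nz <- which(counts > 0)
  if (length(nz) <= 1) {
    warning("constant image: empty foreground")
    return(nb - 1L)
  }
  switch(method,
    isodata = {
      t0 <- floor(mean(range(nz))) - 1
      for (it in 1:1000) {
        lo <- lev <= t0
        mLo <- sum(counts[lo] * lev[lo]) / max(sum(counts[lo]), 1)
        mHi <- sum(counts[!lo] * lev[!lo]) / max(sum(counts[!lo]), 1)
        t1 <- floor((mLo + mHi) / 2)
        if (t1 == t0) break
        t0 <- t1
      }
      as.integer(t0)
    },
    minimum = {
      h <- counts
      iter <- 0
      while (countModes(h) > 2 && iter < 10000) {
        h <- smooth3(h)
        iter <- iter + 1
      }
      if (countModes(h) != 2) {
        warning("histogram could not be made bimodal; falling back to isodata")
        return(autoThresholdHist(counts, "isodata"))
      }
      pk <- which(localMax1d(h))
      valley <- (pk[1]:pk[2])[which.min(h[pk[1]:pk[2]])]
      as.integer(valley - 1L)
    },
    maxentropy = {
      p <- counts / sum(counts)
      P <- cumsum(p)
      best <- -Inf; bestT <- nz[1]
      for (t in nz[1]:(nz[length(nz)] - 1)) {
        pb <- P[t + 1]; pf <- 1 - pb
        if (pb <= 0 || pf <= 0) next
        lo <- p[1:(t + 1)]; hi <- p[(t + 2):nb]
        lo <- lo[lo > 0]; hi <- hi[hi > 0]
        H <- -sum(lo / pb * log(lo / pb)) - sum(hi / pf * log(hi / pf))
        if (H > best) { best <- H; bestT <- t }
      }
      as.integer(bestT)
    },
    triangle = {
      pk <- which.max(counts)
      # farthest non-empty tail from the mode
      tailIdx <- if ((pk - nz[1]) > (nz[length(nz)] - pk)) nz[1] else nz[length(nz)]
      rng <- sort(c(pk, tailIdx))
      xs <- rng[1]:rng[2]
      x1 <- pk; y1 <- counts[pk]; x2 <- tailIdx; y2 <- counts[tailIdx]
      d <- abs((y2 - y1) * xs - (x2 - x1) * counts[xs] + x2 * y1 - y2 * x1) /
        sqrt((y2 - y1)^2 + (x2 - x1)^2)
      as.integer(xs[which.max(d)] - 1L)
    })
}

countModes <- function(h) sum(localMax1d(h))

localMax1d <- function(h) {
  n <- length(h)
  left <- c(-Inf, h[-n]); right <- c(h[-1], -Inf)
  h > left & h >= right
}

smooth3 <- function(h) {
  n <- length(h)
  (c(h[1], h[-n]) + h + c(h[-1], h[n])) / 3
}

#' Automatic threshold of a grayscale image
#'
#' Bins intensities into \code{nbins} levels over [0, 1], thresholds the
#' histogram with \code{\link{autoThresholdHist}}, and returns the intensity
#' cut: pixels strictly above it are foreground.
#'
#' @param img numeric matrix with values in [0, 1].
#' @param method see \code{\link{autoThresholdHist}}.
#' @param nbins number of histogram bins (default 256).
#' @return intensity threshold in [0, 1].
#' @export
autoThreshold <- function(img, method = "isodata", nbins = 256L) {
  v <- pmin(pmax(as.vector(img), 0), 1)
  lev <- pmin(floor(v * nbins), nbins - 1L)
  counts <- tabulate(lev + 1L, nbins)
  t <- autoThresholdHist(counts, method)
  (t + 1) / nbins            # upper edge of bin T: foreground = levels > T
}

#' Binarize with the "default dark" rule
#'
#' Iterative-intermeans threshold with dark-background convention:
#' foreground is everything above the computed threshold. A constant image
#' yields an all-background mask with a warning.
#'
#' @param img numeric matrix in [0, 1].
#' @return logical matrix (TRUE = foreground).
#' @export
thresholdDefaultDark <- function(img) {
  img > autoThreshold(img, "isodata")
}
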