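# Accessors and show methods for the core classes. Slot access from user
# code should go through these.

#' @describeIn Trace sampling rate in Hz
#' @param x,object a \code{Trace}
#' @export
traceFs <- function(x) x@fs

#' @describeIn Trace voltage samples (mV)
#' @export
traceSamples <- function(x) x@samples

#' @describeIn Trace time of first sample (s)
#' @export
traceT0 <- function(x) x@t0

#' @describeIn Trace duration in seconds (n / fs)
#' @export
traceDuration <- function(x) length(x@samples) / x@fs

#' @describeIn Trace sample time grid (s)
#' @export
traceTimes <- function(x) x@t0 + (seq_along(x@samples) - 1) / x@fs

setMethod("show", "Trace", function(object) {
  cat(sprintf("Trace: %d samples @ %g Hz, %.3f s, t0 = %g s, range [%.4g, %.4g] mV\n",
              length(object@samples), object@fs, traceDuration(object),
              object@t0, min(object@samples), max(object@samples)))
})

#' @describeIn PSDEstimate frequency grid (Hz)
#' @param x,object a \code{PSDEstimate}
#' @export
psdFreqs <- function(x) x@freqs

#' @describeIn PSDEstimate power spectral density (mV^2/Hz)
#' @export
psdPower <- function(x) x@power

#' @describeIn PSDEstimate frequency bin spacing (Hz)
#' @export
psdBinHz <- function(x) x@binHz

setMethod("show", "PSDEstimate", function(object) {
  cat(sprintf("PSDEstimate: %d bins, spacing %.4f Hz, %s window (%d pts, %.0f%% overlap)\n",
              length(object@freqs), object@binHz, object@window,
              object@windowLen, 100 * object@overlapFrac))
})

#' @describeIn SpectralPeak peak frequency (Hz)
#' @param x,object a \code{SpectralPeak}
#' @export
peakFreq <- function(x) x@peakFreq

#' @describeIn SpectralPeak power at the peak (mV^2/Hz)
#' @export
peakPower <- function(x) x@peakPower

setMethod("show", "SpectralPeak", function(object) {
  cat(sprintf("SpectralPeak: %.4g Hz at %.4g mV^2/Hz (band %g-%g Hz)\n",
              object@peakFreq, object@peakPower, object@band[1], object@band[2]))
})

#' @describeIn StateCall state label
#' @param x,object a \code{StateCall}
#' @export
callState <- function(x) x@state

#' @describeIn StateCall data.frame of detected burst events
#' @export
burstEvents <- function(x) x@burstEvents

#' @describeIn StateCall heuristic burst subtype ("1", "2", "none",
#'   "undetermined")
#' @export
burstSubtype <- function(x) x@burstSubtype

setMethod("show", "StateCall", function(object) {
  cat(sprintf("StateCall: %s (peak %.3g Hz @ %.3g mV^2/Hz, %d bursts, subtype %s)\n",
              object@state, object@peak@peakFreq, object@peak@peakPower,
              nrow(object@burstEvents), object@burstSubtype))
})

#' @describeIn CellTerritoryMap number of cells (territories)
#' @param x,object a \code{CellTerritoryMap}
#' @export
nCells <- function(x) nrow(x@somaCenters)

#' @describeIn CellTerritoryMap integer label image
#' @export
territoryLabels <- function(x) x@labels

#' @describeIn CellTerritoryMap soma centers (um), n x 2
#' @export
somaCenters <- function(x) x@somaCenters

setMethod("show", "CellTerritoryMap", function(object) {
  cat(sprintf("CellTerritoryMap: %d cells over %d x %d px (%.3g um/px)\n",
              nCells(object), nrow(object@labels), ncol(object@labels),
              object@pixelUm))
})

#' @describeIn ShollProfile radius grid (um)
#' @param x,object a \code{ShollProfile}
#' @export
shollRadii <- function(x) x@radii

#' @describeIn ShollProfile intersection counts
#' @export
shollCounts <- function(x) x@intersections

#' @describeIn ShollProfile area under the intersection profile
#'   (trapezoidal, um * intersections)
#' @export
shollAuc <- function(x) {
  r <- x@radii; y <- as.numeric(x@intersections)
  if (length(r) < 2) return(0)
  sum(diff(r) * (head(y, -1) + tail(y, -1)) / 2)
}

setMethod("show", "ShollProfile", function(object) {
  cat(sprintf("ShollProfile (cell %d): %d radii %g-%g um, max %d intersections, AUC %.1f\n",
              object@cellId, length(object@radii), min(object@radii),
              max(object@radii), max(object@intersections), shollAuc(object)))
})

#' @describeIn StandardCurve fit coefficients, intercept first
#' @param x,object a \code{StandardCurve}
#' @export
curveCoefficients <- function(x) x@coefficients

setMethod("show", "StandardCurve", function(object) {
  cat(sprintf("StandardCurve (%s): %d standards, conc %g-%g, coef [%s]\n",
              object@fitKind, length(object@concentrations),
              min(object@concentrations), max(object@concentrations),
              paste(signif(object@coefficients, 6), collapse = ", ")))
})

#' @importFrom utils head tail
NULL
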