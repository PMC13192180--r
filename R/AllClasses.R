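#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib gliaSlice, .registration = TRUE
NULL

#' Uniformly sampled voltage trace
#'
#' Container for an extracellular (LFP) or intracellular voltage recording:
#' a vector of samples in mV, the sampling rate in Hz and the time origin in
#' seconds. All signal-processing functions in the package consume and return
#' \code{Trace} objects.
#'
#' @slot samples numeric vector of voltages (mV); finite, length >= 2.
#' @slot fs sampling rate (Hz), > 0.
#' @slot t0 time of the first sample (s).
#'
#' @aliases Trace-class
#' @exportClass Trace
setClass("Trace",
  representation(samples = "numeric", fs = "numeric", t0 = "numeric"),
  prototype(samples = numeric(0), fs = 1, t0 = 0)
)

setValidity("Trace", function(object) {
  msg <- character(0)
  if (length(object@fs) != 1 || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive finite number")
  if (length(object@t0) != 1 || !is.finite(object@t0))
    msg <- c(msg, "t0 must be a single finite number")
  if (length(object@samples) < 2)
    msg <- c(msg, "trace must contain at least 2 samples")
  if (anyNA(object@samples) || any(!is.finite(object@samples)))
    msg <- c(msg, "samples must be finite (no NA/NaN/Inf)")
  if (length(msg)) msg else TRUE
})

#' Construct a Trace
#'
#' @param samples numeric vector of voltages in mV.
#' @param fs sampling rate in Hz.
#' @param t0 time of the first sample in seconds.
#' @return A \code{\linkS4class{Trace}}.
#' @examples
#' tr <- Trace(sin(2 * pi * 35 * seq(0, 1, by = 1e-4)), fs = 1e4)
#' traceDuration(tr)
#' @export
Trace <- function(samples, fs, t0 = 0) {
  new("Trace", samples = as.numeric(samples), fs = as.numeric(fs),
      t0 = as.numeric(t0))
}

#' Welch power spectral density estimate
#'
#' One-sided PSD in mV^2/Hz on a uniform frequency grid starting at 0 Hz.
#' The bin spacing equals \code{fs / windowLen}; with a 10 kHz recording and
#' the default 8192-point window this is 1.2207 Hz.
#'
#' @slot freqs frequency grid (Hz), uniform, starting at 0.
#' @slot power one-sided power spectral density (mV^2/Hz), non-negative.
#' @slot binHz bin spacing (Hz).
#' @slot window window kind ("hamming").
#' @slot windowLen window length in samples.
#' @slot overlapFrac fractional overlap of adjacent segments.
#'
#' @aliases PSDEstimate-class
#' @exportClass PSDEstimate
setClass("PSDEstimate",
  representation(freqs = "numeric", power = "numeric", binHz = "numeric",
                 window = "character", windowLen = "integer",
                 overlapFrac = "numeric")
)

setValidity("PSDEstimate", function(object) {
  msg <- character(0)
  if (length(object@freqs) != length(object@power))
    msg <- c(msg, "freqs and power must have equal length")
  d <- diff(object@freqs)
  if (length(d) && (any(d <= 0) || diff(range(d)) > 1e-8 * mean(d)))
    msg <- c(msg, "freqs must be strictly increasing and uniform")
  if (any(object@power < 0))
    msg <- c(msg, "power must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Spectral peak within a search band
#'
#' @slot peakFreq frequency of the maximal PSD bin inside the band (Hz).
#' @slot peakPower PSD at that bin (mV^2/Hz).
#' @slot band searched frequency band, c(lo, hi) in Hz.
#' @aliases SpectralPeak-class
#' @exportClass SpectralPeak
setClass("SpectralPeak",
  representation(peakFreq = "numeric", peakPower = "numeric", band = "numeric")
)

#' Network-state call for one LFP segment
#'
#' Classification of a 5-min LFP segment into one of the four network states
#' used for carbachol-driven slice recordings: \code{"Gamma"} (gamma
#' oscillations, peak frequency > 23 Hz and peak power >= 1e-4 mV^2/Hz),
#' \code{"Bursts"} (recurrent high-amplitude transients), \code{"LowActivity"}
#' and \code{"NoActivity"}, together with the evidence used for the call.
#'
#' @slot state one of "Gamma", "LowActivity", "Bursts", "NoActivity".
#' @slot peak the \code{\linkS4class{SpectralPeak}} of the segment.
#' @slot burstEvents data.frame of detected bursts (time_s, prominence,
#'   peak_amp); may have zero rows.
#' @slot burstSubtype "1", "2", "none" or "undetermined" (heuristic).
#' @slot evidence named list of auxiliary quantities (rms, thresholds used).
#' @aliases StateCall-class
#' @exportClass StateCall
setClass("StateCall",
  representation(state = "character", peak = "SpectralPeak",
                 burstEvents = "data.frame", burstSubtype = "character",
                 evidence = "list")
)

setValidity("StateCall", function(object) {
  ok <- object@state %in% c("Gamma", "LowActivity", "Bursts", "NoActivity")
  if (!ok) return("unknown state label")
  if (object@state == "Bursts" && nrow(object@burstEvents) == 0)
    return("a Bursts call requires at least one burst event")
  TRUE
})

#' Single fluorescence channel with pixel calibration
#'
#' A 2-D grayscale image (values in [0, 1] after projection and
#' normalization) with its pixel size in micrometres and its channel label
#' ("DAPI" or "Iba1").
#'
#' @slot pixels numeric matrix in [0, 1].
#' @slot pixelUm pixel size (um/pixel), > 0.
#' @slot channel "DAPI" or "Iba1".
#' @aliases ChannelImage-class
#' @exportClass ChannelImage
setClass("ChannelImage",
  representation(pixels = "matrix", pixelUm = "numeric", channel = "character")
)

setValidity("ChannelImage", function(object) {
  if (length(object@pixelUm) != 1 || object@pixelUm <= 0)
    return("pixelUm must be a single positive number")
  if (!object@channel %in% c("DAPI", "Iba1"))
    return("channel must be 'DAPI' or 'Iba1'")
  TRUE
})

#' Construct a ChannelImage
#' @param pixels numeric matrix in [0, 1].
#' @param pixelUm pixel size (um/pixel).
#' @param channel "DAPI" or "Iba1".
#' @return a \code{\linkS4class{ChannelImage}}.
#' @export
ChannelImage <- function(pixels, pixelUm, channel) {
  new("ChannelImage", pixels = pixels, pixelUm = pixelUm, channel = channel)
}

setMethod("show", "ChannelImage", function(object) {
  cat(sprintf("ChannelImage [%s]: %d x %d px at %.3g um/px\n",
              object@channel, nrow(object@pixels), ncol(object@pixels),
              object@pixelUm))
})

#' Per-cell microglial territory map
#'
#' Label image produced by marker-controlled watershed segmentation: pixel
#' value 0 is background, k > 0 assigns the pixel to microglial cell k. Soma
#' centers are stored in micrometres (image coordinate convention: x along
#' rows, y along columns, origin at pixel (1,1)).
#'
#' @slot labels integer label matrix.
#' @slot somaCenters n x 2 matrix of soma centers (um).
#' @slot pixelUm pixel size (um/pixel).
#' @aliases CellTerritoryMap-class
#' @exportClass CellTerritoryMap
setClass("CellTerritoryMap",
  representation(labels = "matrix", somaCenters = "matrix", pixelUm = "numeric")
)

setValidity("CellTerritoryMap", function(object) {
  n <- nrow(object@somaCenters)
  labs <- sort(unique(as.integer(object@labels)))
  labs <- labs[labs > 0]
  if (length(labs) && !identical(labs, seq_len(max(labs))))
    return("labels must be contiguous 1..n")
  if (length(labs) && max(labs) != n)
    return("number of territories must equal number of soma centers")
  TRUE
})

#' Sholl intersection profile of one cell
#'
#' Counts of distinct skeleton crossings of concentric circles around the
#' soma center, as a function of radius. The area under the profile is a
#' scalar summary of arbor complexity.
#'
#' @slot radii increasing radius grid (um).
#' @slot intersections non-negative integer counts per radius.
#' @slot center soma center c(x, y) in um.
#' @slot cellId integer cell label.
#' @aliases ShollProfile-class
#' @exportClass ShollProfile
setClass("ShollProfile",
  representation(radii = "numeric", intersections = "integer",
                 center = "numeric", cellId = "integer")
)

setValidity("ShollProfile", function(object) {
  if (length(object@radii) != length(object@intersections))
    return("radii and intersections must have equal length")
  if (any(diff(object@radii) <= 0))
    return("radii must be strictly increasing")
  if (any(object@intersections < 0))
    return("intersection counts must be non-negative")
  TRUE
})

#' Assay standard curve
#'
#' Least-squares fit of optical density against standard concentrations,
#' linear or quadratic, with the calibrated range recorded so inversion can
#' refuse extrapolation.
#'
#' @slot concentrations standard concentrations (pg/mL or uM), decreasing
#'   twofold series by convention.
#' @slot meanOd mean background-corrected OD per standard.
#' @slot fitKind "linear" or "quadratic".
#' @slot coefficients fit coefficients, intercept first.
#' @slot odRange calibrated OD range c(lo, hi).
#' @slot concRange calibrated concentration range c(lo, hi).
#' @slot residuals fit residuals.
#' @aliases StandardCurve-class
#' @exportClass StandardCurve
setClass("StandardCurve",
  representation(concentrations = "numeric", meanOd = "numeric",
                 fitKind = "character", coefficients = "numeric",
                 odRange = "numeric", concRange = "numeric",
                 residuals = "numeric")
)

setValidity("StandardCurve", function(object) {
  if (!object@fitKind %in% c("linear", "quadratic"))
    return("fitKind must be 'linear' or 'quadratic'")
  if (any(!is.finite(object@residuals)))
    return("residuals must be finite")
  TRUE
})
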