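# Offline LFP processing: segment extraction, zero-phase Butterworth
# low-pass, Welch power spectral density, spectral peak extraction.
# Conventions follow the standard slice-culture gamma workflow: 5-min
# analysis segments, 200 Hz low-pass, Hamming-windowed Welch PSD whose
# 8192-point window at 10 kHz yields the 1.2207 Hz bin spacing.

#' Extract a time segment from a trace
#'
#' Half-open window \code{[startS, endS)} relative to the start of the
#' trace; the time origin of the result is updated accordingly. Offline
#' analysis conventionally uses the 5-min segment from minute 30 to 35 of a
#' 40-min recording.
#'
#' @param trace a \code{\linkS4class{Trace}}.
#' @param startS,endS window boundaries in seconds from trace start;
#'   \code{0 <= startS < endS <= duration}.
#' @return a \code{Trace} with \code{round((endS - startS) * fs)} samples.
#' @export
extractSegment <- function(trace, startS, endS) {
  dur <- traceDuration(trace)
  stopifnot2(startS >= 0 && startS < endS && endS <= dur + 1e-9,
             "segment window out of range")
  i0 <- round(startS * trace@fs)
  i1 <- round(endS * trace@fs)
  Trace(trace@samples[(i0 + 1):i1], fs = trace@fs, t0 = trace@t0 + startS)
}

#' Zero-phase Butterworth low-pass filter
#'
#' Order-4 digital Butterworth applied forward and backward
#' (\code{signal::filtfilt}), so the effective magnitude response is the
#' square of the single-pass response and the phase is zero --- burst timing
#' is preserved.
#'
#' @param trace a \code{\linkS4class{Trace}}.
#' @param cornerHz corner frequency (Hz), default 200; must be below Nyquist.
#' @param order filter order of the single pass (default 4).
#' @return filtered \code{Trace}, same length and sampling rate.
#' @export
lowpassButterworth <- function(trace, cornerHz = 200, order = 4) {
  stopifnot2(cornerHz < trace@fs / 2, "corner frequency must be below Nyquist")
  bf <- signal::butter(order, cornerHz / (trace@fs / 2), type = "low")
  x <- trace@samples
  n <- length(x)
  # reflective padding suppresses the zero-initial-condition edge
  # transients of the forward-backward pass
  p <- min(n - 1, ceiling(3 * trace@fs / cornerHz))
  xp <- c(2 * x[1] - x[(p + 1):2], x, 2 * x[n] - x[(n - 1):(n - p)])
  y <- signal::filtfilt(bf, xp)[(p + 1):(p + n)]
  Trace(y, fs = trace@fs, t0 = trace@t0)
}

#' Welch power spectral density
#'
#' One-sided Welch estimate in mV^2/Hz with constant detrending per segment.
#' Bin spacing is \code{fs / windowLen}; 10 kHz with the default 8192-point
#' window gives 1.2207 Hz. Scaling is Parseval-consistent: the integral of
#' the PSD over frequency approximates the signal variance.
#'
#' @param trace a \code{\linkS4class{Trace}} at least one window long.
#' @param windowLen window length in samples (default 8192).
#' @param window window kind; only "hamming" is implemented.
#' @param overlapFrac fractional overlap of adjacent windows (default 0.5).
#' @return a \code{\linkS4class{PSDEstimate}}.
#' @examples
#' tr <- Trace(rnorm(1e5), fs = 1e4)
#' psdBinHz(welchPsd(tr))   # 1.2207
#' @export
welchPsd <- function(trace, windowLen = 8192, window = "hamming",
                     overlapFrac = 0.5) {
  n <- length(trace@samples)
  windowLen <- as.integer(windowLen)
  stopifnot2(windowLen <= n, "trace shorter than one window")
  stopifnot2(identical(window, "hamming"), "only the Hamming window is implemented")
  stopifnot2(overlapFrac >= 0 && overlapFrac < 1, "overlapFrac must be in [0,1)")
  N <- windowLen
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(N - 1)) / (N - 1))
  U <- sum(w^2)
  hop <- max(1L, as.integer(round(N * (1 - overlapFrac))))
  starts <- seq(1L, n - N + 1L, by = hop)
  nf <- N %/% 2 + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- trace@samples[s:(s + N - 1L)]
    seg <- (seg - mean(seg)) * w
    X <- fft(seg)[seq_len(nf)]
    acc <- acc + (Re(X)^2 + Im(X)^2)
  }
  pxx <- acc / (length(starts) * trace@fs * U)
  # one-sided: double everything except DC and (for even N) Nyquist
  scl <- rep(2, nf); scl[1] <- 1
  if (N %% 2 == 0) scl[nf] <- 1
  pxx <- pxx * scl
  freqs <- (seq_len(nf) - 1) * trace@fs / N
  new("PSDEstimate", freqs = freqs, power = pxx, binHz = trace@fs / N,
      window = window, windowLen = windowLen, overlapFrac = overlapFrac)
}

#' Locate the spectral peak inside a band
#'
#' Argmax of the PSD restricted to \code{band} (inclusive); ties resolve to
#' the lowest frequency. The default 1--200 Hz band excludes DC drift below
#' and the low-pass corner above.
#'
#' @param psd a \code{\linkS4class{PSDEstimate}}.
#' @param band numeric c(lo, hi) in Hz, within the PSD range.
#' @return a \code{\linkS4class{SpectralPeak}}.
#' @export
findSpectralPeak <- function(psd, band = c(1, 200)) {
  idx <- which(psd@freqs >= band[1] & psd@freqs <= band[2])
  stopifnot2(length(idx) > 0, "empty search band")
  k <- idx[which.max(psd@power[idx])]
  new("SpectralPeak", peakFreq = psd@freqs[k], peakPower = psd@power[k],
      band = as.numeric(band))
}
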