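# Network-state classification, burst detection, burst-triggered analytic
# Morlet wavelet averaging, gamma suppression timing, and Fisher's exact
# test for state-distribution comparisons.

#' Detect burst events by relative peak prominence
#'
#' Local maxima of the rectified trace whose topographic prominence reaches
#' \code{prominenceFrac} (the "85\% prominence cutoff" convention) of a
#' per-segment prominence reference, separated by at least
#' \code{refractoryS}. The reference is robust: the single largest
#' prominence in a segment is set by one noise excursion and grows with
#' segment length, so the cutoff is anchored instead to the median
#' prominence of the peaks that clear a first, max-referenced pass. The
#' relative cutoff makes detection invariant to amplitude scaling and to
#' sign flips of the trace.
#'
#' @param trace a low-pass-filtered \code{\linkS4class{Trace}}.
#' @param prominenceFrac fraction of the prominence reference (default
#'   0.85).
#' @param refractoryS minimal spacing between events (s), default 0.2.
#' @param smoothS optional moving-average width (s) applied to the
#'   rectified trace before peak finding; 0 (the default) finds peaks on
#'   the raw rectified trace.
#' @return data.frame with columns \code{time_s}, \code{prominence},
#'   \code{peak_amp}; zero rows when nothing qualifies.
#' @export
detectBursts <- function(trace, prominenceFrac = 0.85, refractoryS = 0.2,
                         smoothS = 0) {
  x <- abs(trace@samples)
  if (max(x) == 0) return(emptyBursts())
  k <- round(smoothS * trace@fs)
  if (k > 1) {
    # centered moving average via cumulative sums (edges use partial windows)
    h <- k %/% 2
    n <- length(x)
    cs <- c(0, cumsum(x))
    lo <- pmax(seq_len(n) - h, 1)
    hi <- pmin(seq_len(n) + h, n)
    x <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  }
  peaks <- .localMaxima(x)
  if (!length(peaks)) return(emptyBursts())
  # prominence <= height, and the tallest peak's prominence lower-bounds the
  # maximum, so only peaks at least that tall can matter for the first pass
  tallest <- peaks[which.max(x[peaks])]
  promTall <- .peakProminences(x, tallest)
  cand <- peaks[x[peaks] >= prominenceFrac * promTall]
  prom <- .peakProminences(x, cand)
  # the prominence reference: the single maximal prominence is set by one
  # noise excursion and grows with segment length, so the cutoff is anchored
  # to the median prominence of the events that clear the max-referenced
  # cutoff (a robust location of the event population), then applied once
  # more with that lower anchor
  ref <- stats::median(prom[prom >= prominenceFrac * max(prom)])
  cutoff <- prominenceFrac * ref
  cand <- peaks[x[peaks] >= cutoff]
  prom <- .peakProminences(x, cand)
  keep <- prom >= cutoff
  cand <- cand[keep]; prom <- prom[keep]
  # enforce refractory period, keeping the more prominent event
  ord <- order(cand)
  cand <- cand[ord]; prom <- prom[ord]
  sel <- logical(length(cand))
  last <- -Inf
  refSamp <- refractoryS * trace@fs
  for (i in seq_along(cand)) {
    if (cand[i] - last >= refSamp) {
      sel[i] <- TRUE
      last <- cand[i]
    } else if (prom[i] > prom[which(sel)[sum(sel)]]) {
      sel[which(sel)[sum(sel)]] <- FALSE
      sel[i] <- TRUE
      last <- cand[i]
    }
  }
  cand <- cand[sel]; prom <- prom[sel]
  data.frame(time_s = trace@t0 + (cand - 1) / trace@fs,
             prominence = prom, peak_amp = x[cand])
}

emptyBursts <- function()
  data.frame(time_s = numeric(0), prominence = numeric(0),
             peak_amp = numeric(0))

#' Classify the network state of an LFP segment
#'
#' Applies the four-state rule with the precedence
#' NoActivity > Bursts > Gamma > LowActivity: a segment whose RMS falls
#' below the silence criterion is "NoActivity"; otherwise at least
#' \code{minEvents} detected bursts give "Bursts"; otherwise a spectral peak
#' above 23 Hz with peak power >= 1e-4 mV^2/Hz gives "Gamma"; anything else
#' is "LowActivity". The silence criterion defaults to 0.005 mV RMS (five
#' times a 1 uV assumed recording-chain noise floor) and is configurable.
#'
#' Because the prominence rule in \code{\link{detectBursts}} is relative, it
#' reports maxima even in continuous oscillations; the classifier therefore
#' counts only events whose peak amplitude stands at least
#' \code{burstAmpFactor} times above the segment RMS -- the automated
#' surrogate for the visual criterion that bursts are transients of high
#' amplitude over a quiet background. Continuous sinusoids peak near 1.4 x
#' RMS, so the default 2.5 separates transient from oscillatory activity.
#'
#' @param trace the analyzed (filtered) 5-min \code{\linkS4class{Trace}}.
#' @param psdPeak the segment's \code{\linkS4class{SpectralPeak}}.
#' @param bursts data.frame from \code{\link{detectBursts}} on the same
#'   segment (optional; recomputed if \code{NULL}).
#' @param gammaFreqMin gamma peak-frequency threshold (Hz), default 23.
#' @param powerMin gamma peak-power threshold (mV^2/Hz), default 1e-4.
#' @param silenceRms RMS below which the segment is silent (mV).
#' @param minEvents minimal burst count for a Bursts call (default 3).
#' @param burstAmpFactor minimal ratio of a counted burst peak amplitude to
#'   the segment RMS (default 2.5).
#' @return a \code{\linkS4class{StateCall}}.
#' @export
classifyState <- function(trace, psdPeak, bursts = NULL,
                          gammaFreqMin = 23, powerMin = 1e-4,
                          silenceRms = 0.005, minEvents = 3,
                          burstAmpFactor = 2.5) {
  stopifnot2(is(psdPeak, "SpectralPeak"), "psdPeak must be a SpectralPeak")
  if (is.null(bursts)) bursts <- detectBursts(trace)
  rms <- sqrt(mean(trace@samples^2))
  bursts <- bursts[bursts$peak_amp >= burstAmpFactor * rms, , drop = FALSE]
  evid <- list(rms_mv = rms, gammaFreqMin = gammaFreqMin,
               powerMin = powerMin, silenceRms = silenceRms,
               minEvents = minEvents, burstAmpFactor = burstAmpFactor)
  state <- if (rms < silenceRms) {
    "NoActivity"
  } else if (nrow(bursts) >= minEvents) {
    "Bursts"
  } else if (psdPeak@peakFreq > gammaFreqMin && psdPeak@peakPower >= powerMin) {
    "Gamma"
  } else {
    "LowActivity"
  }
  if (state != "Bursts") bursts <- emptyBursts()
  subtype <- if (state == "Bursts") {
    classifyBurstSubtype(bursts, trace)$subtype
  } else "none"
  new("StateCall", state = state, peak = psdPeak, burstEvents = bursts,
      burstSubtype = subtype, evidence = evid)
}

# Analytic Morlet CWT magnitude at one frequency, computed by
# frequency-domain multiplication. L1 normalization: equal-amplitude
# sinusoids give equal magnitude regardless of frequency. omega0 = 6.
# Pass X = fft(x) so the forward transform is shared across frequencies.
morletCwtRow <- function(X, fs, freq, omega0 = 6) {
  n <- length(X)
  omega <- 2 * pi * fs * c(0:(floor(n / 2)), -(ceiling(n / 2) - 1):-1) / n
  s <- omega0 / (2 * pi * freq)
  psiHat <- numeric(n)
  pos <- omega > 0
  psiHat[pos] <- exp(-(s * omega[pos] - omega0)^2 / 2)
  Mod(fft(X * psiHat, inverse = TRUE) / n)
}

#' Burst-triggered Morlet wavelet spectrum
#'
#' Continuous wavelet transform with analytic Morlet wavelets
#' (center-frequency parameter 6); the magnitude columns at the supplied
#' event times are averaged and normalized to their maximum, giving the
#' characteristic two-peak signature of rhythmic bursting (one peak at the
#' burst recurrence rate, one at the intra-burst oscillation frequency) or a
#' single gamma peak when regular surrogate timepoints are used on a gamma
#' trace. Events inside the cone of influence of a frequency are excluded
#' from that frequency's average. The trace is internally decimated so the
#' Nyquist rate stays a factor \code{2.5} above the highest analysis
#' frequency; the input should already be low-pass filtered.
#'
#' @param trace a \code{\linkS4class{Trace}} (low-pass filtered).
#' @param eventTimes numeric vector of event times (s, same origin as the
#'   trace); must be non-empty.
#' @param freqGrid analysis frequencies (Hz), default 120 log-spaced points
#'   over 0.1--200 Hz.
#' @return list with \code{freqs}, \code{magnitude} (normalized to max 1),
#'   and \code{nEvents} actually averaged per frequency.
#' @export
burstTriggeredWavelet <- function(trace, eventTimes,
                                  freqGrid = 10^seq(log10(0.1), log10(200),
                                                    length.out = 120)) {
  stopifnot2(length(eventTimes) > 0, "event list must be non-empty")
  dur <- traceDuration(trace)
  stopifnot2(max(freqGrid) < trace@fs / 2 && min(freqGrid) > 1 / dur,
             "freqGrid must lie within (1/duration, fs/2)")
  # decimate: keep the working rate at least 5 x the highest analysis
  # frequency (the input is low-pass filtered, so this loses nothing)
  dec <- max(1L, floor(trace@fs / (5 * max(freqGrid)) + 1e-9))
  x <- trace@samples
  fs <- trace@fs
  if (dec > 1) {
    x <- x[seq(1, length(x), by = dec)]
    fs <- fs / dec
  }
  # zero-pad to a 2-3-5-smooth length: R's mixed-radix FFT is quadratic on
  # large prime factors. The pad sits beyond the cone-of-influence cut.
  nOrig <- length(x)
  nPad <- stats::nextn(nOrig, c(2, 3, 5))
  if (nPad > nOrig) x <- c(x, numeric(nPad - nOrig))
  X <- fft(x)
  relT <- eventTimes - trace@t0
  idx <- pmin(pmax(round(relT * fs) + 1, 1), nOrig)
  avg <- numeric(length(freqGrid))
  nEv <- integer(length(freqGrid))
  for (k in seq_along(freqGrid)) {
    magRow <- morletCwtRow(X, fs, freqGrid[k])
    s <- 6 / (2 * pi * freqGrid[k])
    coi <- sqrt(2) * s
    ok <- relT >= coi & relT <= (nOrig / fs - coi)
    use <- if (any(ok)) idx[ok] else idx
    avg[k] <- mean(magRow[use])
    nEv[k] <- length(use)
  }
  m <- max(avg)
  if (m > 0) avg <- avg / m
  list(freqs = freqGrid, magnitude = avg, nEvents = nEv)
}

#' Time to suppression of band-limited activity
#'
#' Slides a window along the trace and reports the onset (in seconds from
#' the start of the trace, i.e. from drug application) of the first window
#' at which the peak power inside \code{band} stays below \code{powerMin}
#' for at least two consecutive windows; \code{NA} if activity never
#' disappears. Used to time the suppression of gamma oscillations after TTX.
#'
#' @param trace a \code{\linkS4class{Trace}} longer than \code{windowS}.
#' @param band frequency band c(lo, hi) in Hz (default gamma, 23--70 Hz).
#' @param powerMin suppression threshold on band peak power (mV^2/Hz).
#' @param windowS sliding window length (s), default 30.
#' @param stepS window step (s), default 5.
#' @return onset time in seconds, or \code{NA_real_}.
#' @export
suppressionTime <- function(trace, band = c(23, 70), powerMin = 1e-4,
                            windowS = 30, stepS = 5) {
  dur <- traceDuration(trace)
  stopifnot2(dur > windowS, "trace must be longer than windowS")
  stopifnot2(band[2] < trace@fs / 2, "band outside Nyquist range")
  onsets <- seq(0, dur - windowS, by = stepS)
  below <- logical(length(onsets))
  for (i in seq_along(onsets)) {
    seg <- extractSegment(trace, onsets[i], onsets[i] + windowS)
    wl <- min(8192L, length(seg@samples))
    pk <- findSpectralPeak(welchPsd(seg, windowLen = wl), band = band)
    below[i] <- pk@peakPower < powerMin
  }
  run <- which(below & c(below[-1], FALSE))
  if (!length(run)) return(NA_real_)
  onsets[run[1]]
}

#' Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value by summing, over all tables with the observed
#' margins, the hypergeometric probabilities not exceeding that of the
#' observed table (the convention of the mainstream statistics packages).
#' Used to compare the presence of one activity state against its absence
#' between conditions.
#'
#' @param tbl 2x2 matrix of non-negative integer counts.
#' @return two-sided p-value in (0, 1].
#' @examples
#' fisherExact2x2(matrix(c(3, 0, 0, 3), 2))  # 0.1
#' @export
fisherExact2x2 <- function(tbl) {
  tbl <- as.matrix(tbl)
  stopifnot2(all(dim(tbl) == c(2, 2)), "table must be 2x2")
  stopifnot2(all(tbl >= 0) && all(tbl == round(tbl)),
             "entries must be non-negative integers")
  m <- sum(tbl[1, ])        # row 1 margin
  nn <- sum(tbl[2, ])       # row 2 margin
  k <- sum(tbl[, 1])        # column 1 margin
  if (m + nn == 0 || k == 0 || k == m + nn) return(1)
  support <- max(0, k - nn):min(k, m)
  probs <- stats::dhyper(support, m, nn, k)
  pObs <- stats::dhyper(tbl[1, 1], m, nn, k)
  p <- sum(probs[probs <= pObs * (1 + 1e-7)])
  min(1, p)
}

#' Heuristic burst subtype
#'
#' Labels a bursting segment "1" when the median inter-event interval is at
#' most 5 s and the mean intra-event dominant frequency is at least 50 Hz,
#' otherwise "2"; fewer than two events give "undetermined". The dominant
#' frequency of each event is the periodogram argmax over 10--200 Hz in a
#' window of \code{windowS} centered on the event.
#'
#' @param events burst data.frame from \code{\link{detectBursts}}.
#' @param trace the corresponding \code{\linkS4class{Trace}}.
#' @param windowS per-event analysis window (s), default 0.4.
#' @return list with \code{subtype} ("1", "2" or "undetermined"),
#'   \code{medianIeiS} and \code{meanIntraFreqHz}.
#' @export
classifyBurstSubtype <- function(events, trace, windowS = 0.4) {
  if (nrow(events) < 2)
    return(list(subtype = "undetermined", medianIeiS = NA_real_,
                meanIntraFreqHz = NA_real_))
  iei <- stats::median(diff(sort(events$time_s)))
  fs <- trace@fs
  half <- round(windowS / 2 * fs)
  fdom <- vapply(events$time_s, function(tc) {
    c0 <- round((tc - trace@t0) * fs) + 1
    i0 <- max(1, c0 - half); i1 <- min(length(trace@samples), c0 + half)
    seg <- trace@samples[i0:i1]
    seg <- seg - mean(seg)
    nseg <- length(seg)
    P <- Mod(fft(seg)[seq_len(nseg %/% 2 + 1)])^2
    fr <- (seq_len(nseg %/% 2 + 1) - 1) * fs / nseg
    sel <- fr >= 10 & fr <= 200
    fr[sel][which.max(P[sel])]
  }, numeric(1))
  sub <- if (iei <= 5 && mean(fdom) >= 50) "1" else "2"
  list(subtype = sub, medianIeiS = iei, meanIntraFreqHz = mean(fdom))
}
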