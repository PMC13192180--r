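# Seeded LFP generators with ground truth. The four activity classes mirror
# what carbachol-driven hippocampal slice cultures produce: sustained gamma
# oscillations, low-amplitude/slow activity, recurrent high-frequency burst
# transients over a quiet background, and electrical silence.

#' Specification for a synthetic LFP trace
#'
#' Builds a validated parameter set for \code{\link{generateLfp}}. Defaults
#' describe the study conditions: 10 kHz sampling, 300 s (one 5-min analysis
#' segment), a 35 Hz gamma oscillation of 0.05 mV amplitude with slow (0.1 Hz)
#' amplitude modulation over 1/f background noise, and bursting at 0.55 Hz
#' with a 100 Hz intra-burst oscillation. Burst amplitude defaults to ten
#' times the background noise SD.
#'
#' @param stateKind one of "gamma", "low", "bursts", "silent".
#' @param durationS trace duration (s).
#' @param fs sampling rate (Hz); must exceed twice every component frequency.
#' @param gammaFreq gamma oscillation frequency (Hz).
#' @param gammaAmp gamma oscillation amplitude (mV).
#' @param burstRate mean burst event rate (Hz).
#' @param intraBurstFreq oscillation frequency inside each burst (Hz).
#' @param burstAmp burst envelope amplitude (mV); default 10 x noiseSd.
#' @param burstWidthS burst envelope width (s).
#' @param noiseSd SD of the 1/f-like background noise (mV).
#' @param seed integer seed; same spec + seed is bit-identical.
#' @return A list of class \code{"LfpGenSpec"}.
#' @export
lfpGenSpec <- function(stateKind = c("gamma", "low", "bursts", "silent"),
                       durationS = 300, fs = 10000,
                       gammaFreq = 35, gammaAmp = 0.05,
                       burstRate = 0.55, intraBurstFreq = 100,
                       burstAmp = 10 * noiseSd, burstWidthS = 0.2,
                       noiseSd = 0.002, seed = 1L) {
  stateKind <- match.arg(stateKind)
  stopifnot2(durationS > 0, "durationS must be positive")
  stopifnot2(fs > 2 * max(gammaFreq, intraBurstFreq),
             "fs must exceed twice every component frequency (aliasing)")
  stopifnot2(gammaAmp >= 0 && burstAmp >= 0 && noiseSd >= 0,
             "amplitudes must be non-negative")
  structure(list(stateKind = stateKind, durationS = durationS, fs = fs,
                 gammaFreq = gammaFreq, gammaAmp = gammaAmp,
                 burstRate = burstRate, intraBurstFreq = intraBurstFreq,
                 burstAmp = burstAmp, burstWidthS = burstWidthS,
                 noiseSd = noiseSd, seed = as.integer(seed)),
            class = "LfpGenSpec")
}

# 1/f-like ("pink") noise with SD sd, length n, via spectral shaping.
pinkNoise <- function(n, sd) {
  if (sd == 0) return(numeric(n))
  w <- rnorm(n)
  W <- fft(w)
  k <- c(1, seq_len(n - 1))            # avoid division by zero at DC
  shape <- 1 / sqrt(k)
  # keep Hermitian symmetry so the inverse transform is real
  half <- ceiling((n + 1) / 2)
  shape[(half + 1):n] <- rev(shape[2:(n - half + 1)])
  x <- Re(fft(W * shape, inverse = TRUE)) / n
  x <- x - mean(x)
  x * sd / stats::sd(x)
}

#' Generate a synthetic LFP trace with ground truth
#'
#' Deterministic (seeded) simulator for the four network-activity classes.
#' Gamma mode is a sinusoid at \code{gammaFreq} with shallow 0.1 Hz amplitude
#' modulation over 1/f noise. Bursts mode places Gaussian-windowed
#' oscillations at \code{intraBurstFreq}, riding on a slower monophasic field
#' deflection, at a jittered \code{burstRate} (uniform jitter of +/-10\% of
#' the inter-event interval, refractory period twice the burst width). Low
#' mode is a weak sub-gamma oscillation; silent mode is background noise only.
#'
#' @param spec an \code{\link{lfpGenSpec}}.
#' @return list with elements \code{trace} (a \code{\linkS4class{Trace}}) and
#'   \code{truth} (list: the spec, and for bursts mode \code{eventTimes} in
#'   seconds).
#' @examples
#' lfp <- generateLfp(lfpGenSpec("gamma", durationS = 20, seed = 7))
#' lfp$trace
#' @export
generateLfp <- function(spec) {
  stopifnot2(inherits(spec, "LfpGenSpec"), "spec must come from lfpGenSpec()")
  n <- round(spec$durationS * spec$fs)
  t <- (seq_len(n) - 1) / spec$fs
  withSeed(spec$seed, {
    x <- pinkNoise(n, spec$noiseSd)
    truth <- list(spec = spec)
    if (spec$stateKind == "gamma") {
      am <- 1 + 0.3 * sin(2 * pi * 0.1 * t + runif(1, 0, 2 * pi))
      x <- x + spec$gammaAmp * am * sin(2 * pi * spec$gammaFreq * t +
                                          runif(1, 0, 2 * pi))
    } else if (spec$stateKind == "low") {
      # weak slow oscillation: below the gamma band and power criterion
      x <- x + 0.2 * spec$gammaAmp * sin(2 * pi * 12 * t + runif(1, 0, 2 * pi))
    } else if (spec$stateKind == "bursts") {
      interval <- 1 / spec$burstRate
      refractory <- 2 * spec$burstWidthS
      times <- numeric(0)
      tk <- interval / 2
      while (tk < spec$durationS - spec$burstWidthS) {
        jit <- runif(1, -0.1 * interval, 0.1 * interval)
        cand <- tk + jit
        if (!length(times) || cand - times[length(times)] >= refractory)
          times <- c(times, cand)
        tk <- tk + interval
      }
      sigOsc <- spec$burstWidthS / 4        # oscillation packet envelope SD
      sigSlow <- max(0.15, spec$burstWidthS) # slow field deflection SD
      for (tc in times) {
        i0 <- max(1L, floor((tc - 4 * sigSlow) * spec$fs) + 1L)
        i1 <- min(n, ceiling((tc + 4 * sigSlow) * spec$fs) + 1L)
        idx <- i0:i1
        dt <- t[idx] - tc
        ph <- runif(1, 0, 2 * pi)
        x[idx] <- x[idx] +
          spec$burstAmp * exp(-dt^2 / (2 * sigOsc^2)) *
            sin(2 * pi * spec$intraBurstFreq * dt + ph) -
          spec$burstAmp * exp(-dt^2 / (2 * sigSlow^2))
      }
      truth$eventTimes <- times
    }
    list(trace = Trace(x, fs = spec$fs), truth = truth)
  })
}
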