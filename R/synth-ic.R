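# Seeded generator for stylized sharp-electrode recordings. Spike waveforms
# are piecewise linear with exactly known threshold, amplitude, half-width,
# mAHP and sAHP, so the intracellular metrics can be validated by
# round-trip parameter recovery.

#' Specification for a synthetic intracellular trace
#'
#' Defaults describe a CA3 pyramidal cell recorded at 20 kHz: resting
#' membrane potential -70 mV, spike threshold -50 mV, 80 mV spike amplitude,
#' 1.2 ms half-width, 5 mV medium afterhyperpolarization, 3 mV slow
#' afterhyperpolarization (bursting mode), 20 MOhm input resistance. The
#' firing-rate rule for regular spiking is
#' \code{rate = 100 Hz/nA * (I - 0.1 nA)}, with a 20 ms latency to the first
#' spike; a 0.5 nA / 200 ms step therefore yields 8 action potentials.
#' Bursting mode fires an initial high-frequency cluster (5 ms inter-spike
#' intervals) that then slows geometrically and ends in a slow
#' afterhyperpolarization below resting potential.
#'
#' @param firingMode "regular" or "bursting".
#' @param rmpMv resting membrane potential (mV).
#' @param apAmpMv spike amplitude, peak minus threshold (mV), > 0.
#' @param apThresholdMv spike threshold (mV).
#' @param halfWidthMs spike width at half amplitude (ms), > 0.
#' @param mahpMv medium AHP depth below threshold (mV).
#' @param sahpMv slow AHP depth below resting potential (mV).
#' @param stepProtocol list of steps, each \code{list(ampNa=, durS=, onsetS=)};
#'   windows must not overlap.
#' @param adaptationRate geometric ISI growth factor per spike in bursting
#'   mode (dimensionless, > 1 slows the train).
#' @param inputResistanceMohm input resistance (MOhm) governing passive
#'   deflections.
#' @param noiseSd additive Gaussian noise SD (mV).
#' @param fs sampling rate (Hz).
#' @param seed integer seed.
#' @return list of class \code{"IcGenSpec"}.
#' @export
icGenSpec <- function(firingMode = c("regular", "bursting"),
                      rmpMv = -70, apAmpMv = 80, apThresholdMv = -50,
                      halfWidthMs = 1.2, mahpMv = 5, sahpMv = 3,
                      stepProtocol = list(list(ampNa = 0.5, durS = 0.2,
                                               onsetS = 0.5)),
                      adaptationRate = 1.6, inputResistanceMohm = 20,
                      noiseSd = 0, fs = 20000, seed = 1L) {
  firingMode <- match.arg(firingMode)
  stopifnot2(apAmpMv > 0, "apAmpMv must be positive")
  stopifnot2(halfWidthMs > 0, "halfWidthMs must be positive")
  stopifnot2(mahpMv >= 0 && sahpMv >= 0, "AHP depths must be non-negative")
  ons <- vapply(stepProtocol, function(s) s$onsetS, numeric(1))
  off <- ons + vapply(stepProtocol, function(s) s$durS, numeric(1))
  o <- order(ons)
  if (length(ons) > 1 && any(ons[o][-1] < off[o][-length(off)] + 1.2))
    stop("protocol windows must not overlap (and need a 1.2 s tail for the sAHP)",
         call. = FALSE)
  structure(list(firingMode = firingMode, rmpMv = rmpMv, apAmpMv = apAmpMv,
                 apThresholdMv = apThresholdMv, halfWidthMs = halfWidthMs,
                 mahpMv = mahpMv, sahpMv = sahpMv, stepProtocol = stepProtocol,
                 adaptationRate = adaptationRate,
                 inputResistanceMohm = inputResistanceMohm,
                 noiseSd = noiseSd, fs = fs, seed = as.integer(seed)),
            class = "IcGenSpec")
}

# AP times for one step, on the sample grid, relative to step onset (s).
icApTimes <- function(spec, ampNa, durS) {
  if (ampNa <= 0.1) return(numeric(0))     # below rheobase
  dt <- 1 / spec$fs
  if (spec$firingMode == "regular") {
    rate <- 100 * (ampNa - 0.1)
    tt <- seq(0.020, durS - 0.004, by = 1 / rate)
  } else {
    tt <- 0.005
    isi <- 0.005
    k <- 0
    repeat {
      k <- k + 1
      if (k > 4) isi <- isi * spec$adaptationRate
      nxt <- tt[length(tt)] + isi
      if (nxt > durS - 0.004) break
      tt <- c(tt, nxt)
    }
  }
  round(tt / dt) * dt
}

#' Generate a synthetic intracellular trace with ground truth
#'
#' Builds the voltage response to the step protocol in \code{spec}:
#' hyperpolarizing or sub-rheobase steps produce exponential passive
#' deflections of \code{I * R} mV at steady state; supra-rheobase steps
#' produce spike trains per the firing mode, each spike a piecewise-linear
#' waveform with exactly the requested threshold, amplitude, half-width and
#' mAHP, and (bursting mode) a terminal sAHP of \code{sahpMv} below resting
#' potential after step offset.
#'
#' @param spec an \code{\link{icGenSpec}}.
#' @return list with \code{trace} (a \code{\linkS4class{Trace}}) and
#'   \code{truth} (spec, per-step AP times in seconds, passive parameters).
#' @export
generateIcTrace <- function(spec) {
  stopifnot2(inherits(spec, "IcGenSpec"), "spec must come from icGenSpec()")
  fs <- spec$fs; dt <- 1 / fs
  offMax <- max(vapply(spec$stepProtocol,
                       function(s) s$onsetS + s$durS, numeric(1)))
  durTot <- offMax + 1.5
  n <- round(durTot * fs)
  tgrid <- (seq_len(n) - 1) * dt
  rmp <- spec$rmpMv; thr <- spec$apThresholdMv
  amp <- spec$apAmpMv; mahp <- spec$mahpMv
  vIs <- thr - 0.4 * mahp                  # inter-spike plateau
  # downstroke slope solved so the width at half amplitude is exact:
  # rise crosses half level 0.2 ms after threshold; the peak and the mAHP
  # trough carry 0.4 ms plateaus (extrema are rounded, and a flat top
  # survives the detector's smoothing); the fall then needs
  # (amp/2)/slope, so half-width = 0.2 ms + 0.4 ms + (amp/2)/slope
  fallSlope <- (amp / 2) / (spec$halfWidthMs / 1000 - 6e-4)  # mV per second
  stopifnot2(spec$halfWidthMs > 0.65,
             "halfWidthMs must exceed the 0.65 ms waveform rise budget")
  apSteps <- list()
  v <- rep(rmp, n)
  tau <- 0.010
  for (si in seq_along(spec$stepProtocol)) {
    st <- spec$stepProtocol[[si]]
    onset <- st$onsetS; dur <- st$durS; offT <- onset + dur
    apT <- icApTimes(spec, st$ampNa, dur)
    apSteps[[si]] <- onset + apT
    idxStep <- which(tgrid >= onset & tgrid < offT)
    idxTail <- which(tgrid >= offT & tgrid < offT + 1.2)
    if (!length(apT)) {
      defl <- st$ampNa * spec$inputResistanceMohm
      v[idxStep] <- rmp + defl * (1 - exp(-(tgrid[idxStep] - onset) / tau))
      vOff <- rmp + defl * (1 - exp(-dur / tau))
      v[idxTail] <- rmp + (vOff - rmp) * exp(-(tgrid[idxTail] - offT) / tau)
      next
    }
    # piecewise-linear node track across the step window
    riseS <- 4e-4                           # 0.4 ms spike upstroke
    nodesT <- c(onset)
    nodesV <- c(rmp)
    rampEnd <- min(onset + 0.015, apT[1] + onset - 0.001)
    nodesT <- c(nodesT, rampEnd); nodesV <- c(nodesV, vIs)
    for (k in seq_along(apT)) {
      ta <- onset + apT[k]
      tPre <- ta - 0.001
      tPeak <- ta + riseS
      tPeak2 <- tPeak + 4e-4                # flat top
      tDip <- tPeak2 + (amp + mahp) / fallSlope
      tDip2 <- tDip + 4e-4                  # flat trough
      nxt <- if (k < length(apT)) onset + apT[k + 1] - 0.001 else offT
      tRec <- min(tDip2 + 0.010, nxt - 1e-4)
      if (tRec <= tDip2) tRec <- tDip2 + dt
      nodesT <- c(nodesT, tPre, ta, tPeak, tPeak2, tDip, tDip2, tRec)
      nodesV <- c(nodesV, vIs, thr, thr + amp, thr + amp, thr - mahp,
                  thr - mahp, vIs)
    }
    # post-step: sAHP (bursting) or plain return to rest
    if (spec$firingMode == "bursting" && spec$sahpMv > 0) {
      nodesT <- c(nodesT, offT, offT + 0.2, offT + 0.8, offT + 1.2)
      nodesV <- c(nodesV, vIs, rmp - spec$sahpMv, rmp, rmp)
    } else {
      nodesT <- c(nodesT, offT, offT + 0.05, offT + 1.2)
      nodesV <- c(nodesV, vIs, rmp, rmp)
    }
    keep <- c(TRUE, diff(nodesT) > 0)
    idx <- which(tgrid >= onset & tgrid < offT + 1.2)
    v[idx] <- stats::approx(nodesT[keep], nodesV[keep], xout = tgrid[idx],
                            rule = 2)$y
  }
  truth <- list(spec = spec, apTimes = apSteps,
                vIs = vIs, tau = tau)
  withSeed(spec$seed, {
    if (spec$noiseSd > 0) v <- v + rnorm(n, 0, spec$noiseSd)
    list(trace = Trace(v, fs = fs), truth = truth)
  })
}
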