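# Intracellular (sharp-electrode) metrics: AP detection and waveform
# parameters, step-response latency/counts, afterhyperpolarizations,
# passive properties.

#' Detect action potentials and measure waveform parameters
#'
#' The trace first passes a 3-sample median filter (impulse-noise
#' suppression that leaves piecewise-linear waveforms untouched). Events
#' are detected where the voltage slope over a 0.2 ms span reaches
#' \code{dvdtThresh} (default 20 mV/ms) -- the windowed derivative keeps
#' sample-to-sample noise from triggering -- and the crossing is then
#' refined to the first sample whose single-step slope reaches the
#' threshold. The voltage at that sample is the AP threshold, which is
#' robust to shifts of the resting membrane potential. Per event:
#' amplitude = peak - threshold; half-width = width at
#' threshold + amplitude/2 with sub-sample linear interpolation of the
#' crossings; mAHP = threshold minus the minimum between the peak and the
#' next AP threshold (or +50 ms, or \code{searchEndS}, whichever is first).
#'
#' @param trace a \code{\linkS4class{Trace}} sampled at >= 10 kHz.
#' @param dvdtThresh detection threshold on dV/dt (mV/ms).
#' @param searchEndS absolute time (s) past which the mAHP search window is
#'   truncated, e.g. the current-step offset; default \code{Inf}.
#' @return data.frame with one row per AP: \code{t} (s, threshold crossing),
#'   \code{threshold_mV}, \code{peak_mV}, \code{amplitude_mV},
#'   \code{half_width_ms}, \code{mahp_mV}.
#' @export
detectAps <- function(trace, dvdtThresh = 20, searchEndS = Inf) {
  stopifnot2(trace@fs >= 10000, "AP analysis requires fs >= 10 kHz")
  fs <- trace@fs
  v0 <- trace@samples
  n <- length(v0)
  # 3-sample median prefilter
  a <- v0[c(1, 1:(n - 1))]; b <- v0; cc <- v0[c(2:n, n)]
  v <- pmax(pmin(a, b), pmin(pmax(a, b), cc))
  # windowed derivative over ~0.2 ms
  k <- max(1L, round(2e-4 * fs))
  slopeW <- (v[(1 + k):n] - v[1:(n - k)]) * fs / (k * 1000)   # mV/ms
  fast <- slopeW >= dvdtThresh
  if (!any(fast)) return(emptyAps())
  # first fast window of each depolarization run
  starts <- which(fast & !c(FALSE, fast[-length(fast)]))
  # merge runs closer than 1 ms (one AP's upstroke can fragment under noise)
  if (length(starts) > 1) {
    gap <- diff(starts) > fs / 1000
    starts <- starts[c(TRUE, gap)]
  }
  # refine each onset to the first sample whose single-step slope crosses
  starts <- vapply(starts, function(i) {
    win <- i:min(i + k, n - 1)
    j <- win[(v[win + 1] - v[win]) * fs / 1000 >= dvdtThresh]
    if (length(j)) j[1] else i
  }, integer(1))
  # a centered ~0.45 ms moving average for extrema: AP peaks and AHP
  # troughs are locally flat at that scale, and the averaging keeps noise
  # excursions from setting the peak and the mAHP minimum
  cs <- c(0, cumsum(v))
  lo <- pmax(seq_len(n) - 4L, 1L); hi <- pmin(seq_len(n) + 4L, n)
  vSm <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  out <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    i <- starts[k]
    # threshold: least-squares line through the last ~1 ms of the
    # pre-threshold trajectory (raw samples, iid noise), evaluated at the
    # crossing sample -- unbiased when the approach is locally linear, and
    # with much smaller variance than a single-sample read
    i0w <- max(1, i - 19)
    w <- v0[i0w:i]
    xs <- seq_along(w)
    thr <- if (length(w) >= 3) {
      sl <- stats::cov(xs, w) / stats::var(xs)
      mean(w) + sl * (length(w) - mean(xs))
    } else v[i]
    # peak: maximum within 5 ms of threshold crossing
    iEnd <- min(length(v), i + round(0.005 * fs))
    ipk <- i - 1 + which.max(vSm[i:iEnd])
    pk <- vSm[ipk]
    ampl <- pk - thr
    half <- thr + ampl / 2
    tUp <- upCrossing(v, half, i0 = max(1, i - 1))
    # falling crossing after peak
    jj <- ipk
    while (jj < length(v) && v[jj + 1] > half) jj <- jj + 1
    tDown <- if (jj < length(v) && v[jj + 1] <= half) {
      jj + (v[jj] - half) / (v[jj] - v[jj + 1])
    } else NA_real_
    hw <- (tDown - tUp) / fs * 1000
    # mAHP window: peak -> next AP threshold, +50 ms, or searchEndS
    nextI <- if (k < length(starts)) starts[k + 1] else length(v)
    mEnd <- min(nextI, ipk + round(0.050 * fs),
                floor((searchEndS - trace@t0) * fs) + 1, length(v))
    mahp <- if (mEnd > ipk) thr - min(vSm[(ipk + 1):mEnd]) else NA_real_
    out[[k]] <- data.frame(t = trace@t0 + (i - 1) / fs, threshold_mV = thr,
                           peak_mV = pk, amplitude_mV = ampl,
                           half_width_ms = hw, mahp_mV = mahp)
  }
  do.call(rbind, out)
}

emptyAps <- function()
  data.frame(t = numeric(0), threshold_mV = numeric(0), peak_mV = numeric(0),
             amplitude_mV = numeric(0), half_width_ms = numeric(0),
             mahp_mV = numeric(0))

#' Metrics of the response to one current step
#'
#' Measures, for the step window \code{[onsetS, onsetS + durS)}: latency of
#' the first AP (threshold-crossing time minus onset), AP counts over the
#' full window and the first 100 ms, the mAHP (mean over APs, excluding the
#' final AP whose afterpotential merges into the post-step trajectory) and
#' the sAHP (pre-stimulus resting potential minus the most hyperpolarized
#' potential within 1 s after step offset).
#'
#' @param trace a \code{\linkS4class{Trace}}.
#' @param step list with \code{ampNa}, \code{durS}, \code{onsetS}.
#' @return list: \code{step}, \code{apEvents} (data.frame),
#'   \code{latency_first_ms} (NA when no AP), \code{n_aps_total},
#'   \code{n_aps_first_100ms}, \code{mahp_mV}, \code{sahp_mV},
#'   \code{rmp_mV} (pre-stimulus mean).
#' @export
stepMetrics <- function(trace, step) {
  onset <- step$onsetS; offT <- onset + step$durS
  dur <- traceDuration(trace)
  stopifnot2(onset >= trace@t0 && offT <= trace@t0 + dur,
             "step window outside trace")
  fs <- trace@fs
  relOn <- onset - trace@t0
  i0 <- max(1, round((relOn - 0.05) * fs))
  i1 <- max(1, round(relOn * fs))
  rmp <- mean(trace@samples[i0:i1])
  aps <- detectAps(trace, searchEndS = offT)
  inStep <- aps[aps$t >= onset & aps$t < offT, , drop = FALSE]
  lat <- if (nrow(inStep)) (inStep$t[1] - onset) * 1000 else NA_real_
  n100 <- sum(inStep$t < onset + 0.1)
  mahp <- if (nrow(inStep) > 1) {
    mean(inStep$mahp_mV[-nrow(inStep)], na.rm = TRUE)
  } else NA_real_
  j0 <- round((offT - trace@t0) * fs) + 1
  j1 <- min(length(trace@samples), round((offT - trace@t0 + 1) * fs))
  post <- trace@samples[j0:j1]
  # the sAHP is slow: a 1 ms moving average keeps the minimum from being a
  # noise excursion without distorting the trough
  kk <- max(1L, round(0.001 * fs))
  if (kk > 1) {
    cs <- c(0, cumsum(post))
    m <- length(post)
    lo <- pmax(seq_len(m) - kk %/% 2, 1); hi <- pmin(seq_len(m) + kk %/% 2, m)
    post <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  }
  sahp <- rmp - min(post)
  list(step = step, apEvents = inStep, latency_first_ms = lat,
       n_aps_total = nrow(inStep), n_aps_first_100ms = n100,
       mahp_mV = mahp, sahp_mV = sahp, rmp_mV = rmp)
}

#' Input resistance from a hyperpolarizing pulse
#'
#' Ohm's law with unit bookkeeping: a deflection in mV divided by a current
#' in nA gives MOhm. The conventional pulse is -0.2 nA for 200 ms with the
#' deflection read at late steady state, so a -4 mV deflection means
#' 20 MOhm. A hyperpolarizing pulse with a negative deflection yields a
#' positive resistance.
#'
#' @param deflectionMv steady-state voltage deflection (mV).
#' @param currentNa injected current (nA), non-zero.
#' @return input resistance (MOhm); zero or negative values trigger a
#'   warning as physiologically implausible.
#' @examples
#' inputResistance(-4, -0.2)   # 20
#' @export
inputResistance <- function(deflectionMv, currentNa = -0.2) {
  stopifnot2(currentNa != 0, "current must be non-zero")
  r <- deflectionMv / currentNa
  if (r <= 0) warning("non-positive input resistance is implausible")
  r
}

#' Group APs into doublets/triplets
#'
#' Maximal runs of consecutive inter-spike intervals at most
#' \code{isiMaxMs} are labelled by their length ("doublet", "triplet",
#' "multiplet" for longer runs); isolated spikes are not reported.
#'
#' @param apEvents data.frame from \code{\link{detectAps}} (time-sorted).
#' @param isiMaxMs maximal within-group interval (ms), default 30.
#' @return data.frame with \code{t_first} (s), \code{n}, \code{kind};
#'   zero rows if there are no multiplets.
#' @export
detectMultiplets <- function(apEvents, isiMaxMs = 30) {
  t <- apEvents$t
  if (length(t) < 2)
    return(data.frame(t_first = numeric(0), n = integer(0),
                      kind = character(0)))
  close <- diff(t) * 1000 <= isiMaxMs
  r <- rle(close)
  out <- list()
  pos <- 1L
  for (q in seq_along(r$lengths)) {
    if (r$values[q]) {
      nAp <- r$lengths[q] + 1L
      out[[length(out) + 1L]] <-
        data.frame(t_first = t[pos], n = nAp,
                   kind = switch(min(nAp, 4L) - 1L,
                                 "doublet", "triplet", "multiplet"))
    }
    pos <- pos + r$lengths[q]
  }
  if (!length(out))
    return(data.frame(t_first = numeric(0), n = integer(0),
                      kind = character(0)))
  do.call(rbind, out)
}
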