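# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Squared magnitude response of a bilinear-transformed (digital) Butterworth
# low-pass of given order at frequency f (Hz): closed form via prewarped
# frequencies. A forward-backward pass squares this once more.
butterMag2 <- function(f, fc, fs, order) {
  ratio <- tan(pi * f / fs) / tan(pi * fc / fs)
  1 / (1 + ratio^(2 * order))
}

# Two-sided Fisher p by direct enumeration over all tables with the
# observed margins, using factorial probabilities.
fisherOracle <- function(tbl) {
  r1 <- sum(tbl[1, ]); r2 <- sum(tbl[2, ]); c1 <- sum(tbl[, 1])
  n <- r1 + r2
  if (n == 0 || c1 == 0 || c1 == n) return(1)
  aMin <- max(0, c1 - r2); aMax <- min(c1, r1)
  prob <- function(a) {
    b <- r1 - a; cc <- c1 - a; d <- r2 - cc
    exp(lfactorial(r1) + lfactorial(r2) + lfactorial(c1) +
          lfactorial(n - c1) - lfactorial(n) - lfactorial(a) -
          lfactorial(b) - lfactorial(cc) - lfactorial(d))
  }
  ps <- vapply(aMin:aMax, prob, numeric(1))
  pObs <- prob(tbl[1, 1])
  sum(ps[ps <= pObs * (1 + 1e-7)])
}

# Naive iterative-intermeans threshold on a histogram (level 0 first).
isodataOracle <- function(counts) {
  lev <- seq_along(counts) - 1
  nz <- which(counts > 0)
  t0 <- floor(mean(range(nz))) - 1
  for (i in 1:1000) {
    lo <- lev <= t0
    mLo <- sum(counts[lo] * lev[lo]) / max(sum(counts[lo]), 1)
    mHi <- sum(counts[!lo] * lev[!lo]) / max(sum(counts[!lo]), 1)
    t1 <- floor((mLo + mHi) / 2)
    if (t1 == t0) break
    t0 <- t1
  }
  t0
}

# Naive Kapur max-entropy threshold: direct double loop over thresholds,
# entropies computed from scratch at each.
maxentOracle <- function(counts) {
  p <- counts / sum(counts)
  nb <- length(counts)
  best <- -Inf; bestT <- NA
  for (t in 0:(nb - 2)) {
    pb <- sum(p[1:(t + 1)]); pf <- 1 - pb
    if (pb <= 0 || pf <= 0) next
    H <- 0
    for (i in 1:(t + 1)) if (p[i] > 0) H <- H - p[i] / pb * log(p[i] / pb)
    for (i in (t + 2):nb) if (p[i] > 0) H <- H - p[i] / pf * log(p[i] / pf)
    if (H > best) { best <- H; bestT <- t }
  }
  bestT
}

# The two most prominent local maxima of a spectrum, by topographic
# prominence computed directly on the magnitude vector.
topTwoLocalMaxima <- function(freqs, mag) {
  n <- length(mag)
  lm <- which(diff(sign(diff(mag))) == -2) + 1
  if (!length(lm)) return(numeric(0))
  prom <- vapply(lm, function(i) {
    h <- mag[i]
    l <- i; while (l > 1 && mag[l] <= h) l <- l - 1
    r <- i; while (r < n && mag[r] <= h) r <- r + 1
    minL <- min(mag[l:i]); minR <- min(mag[i:r])
    h - max(minL, minR)
  }, numeric(1))
  freqs[lm[order(prom, decreasing = TRUE)][seq_len(min(2, length(lm)))]]
}

# Draw a 1-px-wide plus-sign "skeleton" directly: four axis-aligned arms of
# length armUm around a central pixel.
plusSkeleton <- function(armUm, pixelUm, pad = 10) {
  armPx <- round(armUm / pixelUm)
  n <- 2 * (armPx + pad) + 1
  ctr <- armPx + pad + 1
  sk <- matrix(FALSE, n, n)
  sk[(ctr - armPx):(ctr + armPx), ctr] <- TRUE
  sk[ctr, (ctr - armPx):(ctr + armPx)] <- TRUE
  list(skeleton = sk, centerPx = c(ctr, ctr), cellId = 1L)
}
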