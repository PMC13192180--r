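# Burst detection, state classification, wavelet averaging, suppression
# timing, Fisher's exact test, burst subtyping.

test_that("burst detection handles silence and symmetric transients", {
  z <- Trace(numeric(1e4), fs = 1e3)
  expect_equal(nrow(detectBursts(z)), 0)
  # two identical Gaussian transients on a flat background
  fs <- 1e3
  t <- (0:(30 * fs - 1)) / fs
  x <- exp(-(t - 10)^2 / (2 * 0.05^2)) + exp(-(t - 20)^2 / (2 * 0.05^2))
  ev <- detectBursts(Trace(x, fs = fs))
  expect_equal(nrow(ev), 2)
  expect_equal(ev$time_s, c(10, 20), tolerance = 1.5 / fs)
})

test_that("burst detection is invariant to a sign flip (rectification)", {
  lfp <- generateLfp(lfpGenSpec("bursts", durationS = 60, seed = 2))
  f <- lowpassButterworth(lfp$trace)
  a <- detectBursts(f)
  b <- detectBursts(Trace(-traceSamples(f), fs = traceFs(f)))
  expect_equal(a$time_s, b$time_s)
  expect_equal(a$prominence, b$prominence)
})

test_that("burst fixtures are recovered within 25 ms", {
  lfp <- generateLfp(lfpGenSpec("bursts", burstRate = 0.55, durationS = 120,
                                seed = 8))
  ev <- detectBursts(lowpassButterworth(lfp$trace))
  tt <- lfp$truth$eventTimes
  hit <- vapply(tt, function(x) min(abs(ev$time_s - x)), numeric(1))
  expect_gte(mean(hit <= 0.025), 0.95)
})

test_that("state classification follows the printed threshold rule", {
  peakAt <- function(f, p) new("SpectralPeak", peakFreq = f, peakPower = p,
                               band = c(1, 200))
  g <- generateLfp(lfpGenSpec("gamma", durationS = 10, seed = 1))$trace
  expect_equal(callState(classifyState(g, peakAt(34, 2e-4))), "Gamma")
  expect_equal(callState(classifyState(g, peakAt(15, 2e-4))), "LowActivity")
  expect_equal(callState(classifyState(g, peakAt(34, 5e-5))), "LowActivity")
  z <- Trace(numeric(1e4), fs = 1e4)
  expect_equal(callState(classifyState(z, peakAt(34, 0))), "NoActivity")
})

test_that("scaling a gamma trace down flips Gamma to Low, never to Bursts", {
  lfp <- generateLfp(lfpGenSpec("gamma", durationS = 10, seed = 6))
  tr <- lowpassButterworth(lfp$trace)
  calls <- vapply(seq(1, 0.2, length.out = 10), function(s) {
    scaled <- Trace(s * traceSamples(tr), fs = traceFs(tr))
    pk <- findSpectralPeak(welchPsd(scaled))
    callState(classifyState(scaled, pk))
  }, character(1))
  expect_equal(calls[1], "Gamma")
  expect_true("LowActivity" %in% calls)
  expect_false("Bursts" %in% calls)
  # once Gamma is lost it is not regained at lower amplitude
  expect_true(all(diff(calls == "Gamma") <= 0))
})

test_that("burst-triggered wavelet is normalized and scale-invariant", {
  lfp <- generateLfp(lfpGenSpec("bursts", durationS = 60, seed = 3))
  f <- lowpassButterworth(lfp$trace)
  ev <- detectBursts(f)
  w1 <- burstTriggeredWavelet(f, ev$time_s)
  expect_equal(max(w1$magnitude), 1)
  w2 <- burstTriggeredWavelet(Trace(7.3 * traceSamples(f), fs = traceFs(f)),
                              ev$time_s)
  expect_lt(max(abs(w1$magnitude - w2$magnitude)), 1e-12)
  expect_error(burstTriggeredWavelet(f, numeric(0)), "non-empty")
})

test_that("gamma trace with regular surrogate timepoints peaks at 34 Hz", {
  fs <- 1e4
  t <- (0:(60 * fs - 1)) / fs
  tr <- Trace(0.05 * sin(2 * pi * 34 * t), fs = fs)
  w <- burstTriggeredWavelet(tr, seq(10, 50, by = 2))
  expect_lt(abs(w$freqs[which.max(w$magnitude)] - 34) / 34, 0.10)
})

test_that("bursting fixture shows peaks at the rate and intra-burst freq", {
  lfp <- generateLfp(lfpGenSpec("bursts", burstRate = 0.55,
                                intraBurstFreq = 100, durationS = 300,
                                seed = 4))
  f <- lowpassButterworth(lfp$trace)
  ev <- detectBursts(f)
  w <- burstTriggeredWavelet(f, ev$time_s)
  top2 <- sort(topTwoLocalMaxima(w$freqs, w$magnitude))
  expect_length(top2, 2)
  expect_lt(abs(top2[1] - 0.55) / 0.55, 0.20)
  expect_lt(abs(top2[2] - 100) / 100, 0.20)
})

test_that("suppression time finds the switch to silence", {
  fs <- 1e3
  t <- (0:(400 * fs - 1)) / fs
  x <- ifelse(t < 240, 0.05 * sin(2 * pi * 35 * t), 0) +
    rnorm(length(t), 0, 1e-4)
  tr <- Trace(x, fs = fs)
  ts <- suppressionTime(tr, windowS = 30, stepS = 5)
  expect_gte(ts, 240 - 5)
  expect_lte(ts, 270)
  persist <- Trace(0.05 * sin(2 * pi * 35 * t), fs = fs)
  expect_true(is.na(suppressionTime(persist, windowS = 30)))
  silent <- Trace(rnorm(length(t), 0, 1e-4), fs = fs)
  expect_lte(suppressionTime(silent, windowS = 30), 30)
})

test_that("Fisher's exact test matches enumeration and known values", {
  expect_equal(fisherExact2x2(matrix(c(1, 1, 1, 1), 2)), 1)
  expect_equal(fisherExact2x2(matrix(c(3, 0, 0, 3), 2)), 0.1)
  tbl <- matrix(c(7, 2, 1, 6), 2)
  expect_equal(fisherExact2x2(tbl), fisherExact2x2(tbl[2:1, ]))
  # spot-check against the reference implementation
  for (tb in list(matrix(c(5, 1, 2, 7), 2), matrix(c(10, 3, 2, 15), 2),
                  matrix(c(0, 5, 5, 0), 2)))
    expect_equal(fisherExact2x2(tb), stats::fisher.test(tb)$p.value,
                 tolerance = 1e-12)
  expect_error(fisherExact2x2(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
})

test_that("burst subtype follows the interval/frequency heuristic", {
  fast <- generateLfp(lfpGenSpec("bursts", burstRate = 0.55,
                                 intraBurstFreq = 100, durationS = 60,
                                 seed = 5))
  f <- lowpassButterworth(fast$trace)
  ev <- detectBursts(f)
  expect_equal(classifyBurstSubtype(ev, f)$subtype, "1")
  slow <- generateLfp(lfpGenSpec("bursts", burstRate = 0.05,
                                 intraBurstFreq = 20, durationS = 120,
                                 seed = 5))
  fs <- lowpassButterworth(slow$trace)
  evs <- detectBursts(fs)
  expect_equal(classifyBurstSubtype(evs, fs)$subtype, "2")
  expect_equal(classifyBurstSubtype(ev[1, , drop = FALSE], f)$subtype,
               "undetermined")
})
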