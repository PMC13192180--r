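mkTrace <- function(f, amp = 1, durS = 2, fs = 1e4)
  Trace(amp * sin(2 * pi * f * (0:(durS * fs - 1)) / fs), fs = fs)

test_that("extractSegment returns the half-open window with updated origin", {
  tr <- Trace(rnorm(40 * 60 * 100), fs = 100)   # 40 min at 100 Hz
  seg <- extractSegment(tr, 1800, 2100)         # minutes 30 to 35
  expect_equal(length(traceSamples(seg)), 300 * 100)
  expect_equal(traceT0(seg), 1800)
  expect_identical(traceSamples(extractSegment(tr, 0, traceDuration(tr))),
                   traceSamples(tr))
  tr2 <- Trace(rnorm(2e5), fs = 1e4)
  expect_equal(length(traceSamples(extractSegment(tr2, 10, 10.001))), 10)
  expect_error(extractSegment(tr2, -1, 5), "out of range")
})

test_that("zero-phase Butterworth matches its closed-form digital response", {
  fs <- 1e4
  const <- Trace(rep(3.2, 1e4), fs = fs)
  expect_equal(traceSamples(lowpassButterworth(const)),
               traceSamples(const), tolerance = 1e-6)
  # 35 Hz passband tone: amplitude preserved within 1%
  y35 <- lowpassButterworth(mkTrace(35))
  mid <- 5000:15000
  expect_equal(max(abs(traceSamples(y35)[mid])), 1, tolerance = 0.01)
  # 500 Hz stopband tone: attenuation equals the analytic squared response
  # of a forward-backward order-4 digital Butterworth within 5%
  y500 <- lowpassButterworth(mkTrace(500))
  got <- max(abs(traceSamples(y500)[mid]))
  want <- butterMag2(500, 200, fs, 4)       # filtfilt applies |H|^2
  expect_equal(got, want, tolerance = 0.05)
  expect_error(lowpassButterworth(mkTrace(10), cornerHz = 6000), "Nyquist")
})

test_that("Welch PSD has the printed bin spacing and Parseval scaling", {
  tr <- Trace(rnorm(1e5), fs = 1e4)
  psd <- welchPsd(tr)
  expect_equal(round(psdBinHz(psd), 4), 1.2207)
  expect_equal(psdFreqs(psd)[1], 0)
  # zero trace -> zero PSD
  z <- welchPsd(Trace(numeric(2e4), fs = 1e4), windowLen = 8192)
  expect_true(all(psdPower(z) == 0))
  # integral of the PSD approximates the variance of white noise
  set.seed(4)
  wn <- Trace(rnorm(3e5), fs = 1e3)
  p <- welchPsd(wn, windowLen = 4096)
  expect_equal(sum(psdPower(p)) * psdBinHz(p), stats::var(traceSamples(wn)),
               tolerance = 0.05)
  expect_error(welchPsd(Trace(rnorm(100), fs = 1e4)), "shorter")
})

test_that("power scales with the square of the amplitude scale", {
  tr <- mkTrace(35, durS = 3)
  p1 <- findSpectralPeak(welchPsd(tr))
  p2 <- findSpectralPeak(welchPsd(Trace(2 * traceSamples(tr), fs = 1e4)))
  expect_equal(peakPower(p2) / peakPower(p1), 4, tolerance = 1e-6)
})

test_that("the frequency grid depends only on fs and window length", {
  a <- welchPsd(Trace(rnorm(2e4), fs = 1e4))
  b <- welchPsd(Trace(rnorm(9e4), fs = 1e4))
  expect_identical(psdFreqs(a), psdFreqs(b))
})

test_that("spectral peak is the band-restricted argmax with low-freq ties", {
  freqs <- seq(0, 200, by = 1)
  power <- rep(1, length(freqs))
  power[freqs == 34] <- 5
  psd <- new("PSDEstimate", freqs = freqs, power = power, binHz = 1,
             window = "hamming", windowLen = 8192L, overlapFrac = 0.5)
  expect_equal(peakFreq(findSpectralPeak(psd)), 34)
  power[freqs %in% c(30, 60)] <- 9
  psd@power <- power
  expect_equal(peakFreq(findSpectralPeak(psd)), 30)  # tie -> lowest
  expect_error(findSpectralPeak(psd, band = c(300, 400)), "empty")
})
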