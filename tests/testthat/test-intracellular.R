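# AP detection, waveform parameter recovery, step metrics, passive
# properties, multiplet grouping.

test_that("regular-firing step yields the designed count and latency", {
  ic <- generateIcTrace(icGenSpec("regular"))
  st <- stepMetrics(ic$trace, list(ampNa = 0.5, durS = 0.2, onsetS = 0.5))
  expect_equal(st$n_aps_total, 8)
  expect_equal(st$latency_first_ms,
               (ic$truth$apTimes[[1]][1] - 0.5) * 1000, tolerance = 1e-6)
  expect_equal(st$apEvents$t, ic$truth$apTimes[[1]], tolerance = 2e-4)
})

test_that("noiseless waveform parameters are recovered within tolerance", {
  ic <- generateIcTrace(icGenSpec("regular", apAmpMv = 80, halfWidthMs = 1.2,
                                  mahpMv = 5))
  st <- stepMetrics(ic$trace, list(ampNa = 0.5, durS = 0.2, onsetS = 0.5))
  aps <- st$apEvents
  expect_lt(max(abs(aps$amplitude_mV - 80)), 0.5)
  expect_lt(max(abs(aps$threshold_mV - (-50))), 0.5)
  expect_lt(max(abs(aps$half_width_ms - 1.2)), 0.05)
  expect_lt(abs(st$mahp_mV - 5), 0.1)
})

test_that("noisy recovery holds within the relaxed tolerance over seeds", {
  for (seed in 1:20) {
    ic <- generateIcTrace(icGenSpec("regular", noiseSd = 0.5, seed = seed))
    st <- stepMetrics(ic$trace, list(ampNa = 0.5, durS = 0.2, onsetS = 0.5))
    aps <- st$apEvents
    expect_equal(nrow(aps), 8)
    expect_lt(max(abs(aps$amplitude_mV - 80)), 1.0)
    expect_lt(max(abs(aps$half_width_ms - 1.2)), 0.2)
  }
})

test_that("bursting mode recovers mAHP and sAHP, with more early APs", {
  ic <- generateIcTrace(icGenSpec("bursting", mahpMv = 5, sahpMv = 3,
                                  stepProtocol = list(list(ampNa = 0.6,
                                                           durS = 0.2,
                                                           onsetS = 0.5))))
  st <- stepMetrics(ic$trace, list(ampNa = 0.6, durS = 0.2, onsetS = 0.5))
  expect_lt(abs(st$mahp_mV - 5), 0.1)
  expect_lt(abs(st$sahp_mV - 3), 0.1)
  reg <- generateIcTrace(icGenSpec("regular",
                                   stepProtocol = list(list(ampNa = 0.6,
                                                            durS = 0.2,
                                                            onsetS = 0.5))))
  stR <- stepMetrics(reg$trace, list(ampNa = 0.6, durS = 0.2, onsetS = 0.5))
  expect_gt(st$n_aps_first_100ms, stR$n_aps_first_100ms)
  expect_lt(st$latency_first_ms, stR$latency_first_ms)
})

test_that("subthreshold traces yield no APs and the designed deflection", {
  ic <- generateIcTrace(icGenSpec("regular", inputResistanceMohm = 20,
                                  stepProtocol = list(list(ampNa = -0.2,
                                                           durS = 0.2,
                                                           onsetS = 0.5))))
  expect_equal(nrow(detectAps(ic$trace)), 0)
  v <- traceSamples(ic$trace); fs <- traceFs(ic$trace)
  # steady state over the last quarter of the pulse
  defl <- mean(v[round(0.65 * fs):round(0.7 * fs)]) -
    mean(v[1:round(0.45 * fs)])
  expect_equal(defl, -4, tolerance = 1e-3)
  expect_equal(inputResistance(defl, -0.2), 20, tolerance = 1e-3)
})

test_that("input resistance is Ohm's law with unit bookkeeping", {
  expect_equal(inputResistance(-4, -0.2), 20)
  expect_equal(inputResistance(-8, -0.2), 40)
  expect_warning(r0 <- inputResistance(0, -0.2), "implausible")
  expect_equal(r0, 0)
  expect_error(inputResistance(-4, 0), "non-zero")
})

test_that("AP counts never decrease with step amplitude (regular mode)", {
  amps <- seq(0.2, 0.6, by = 0.1)
  counts <- vapply(amps, function(a) {
    ic <- generateIcTrace(icGenSpec("regular",
                                    stepProtocol = list(list(ampNa = a,
                                                             durS = 0.2,
                                                             onsetS = 0.5))))
    stepMetrics(ic$trace, list(ampNa = a, durS = 0.2, onsetS = 0.5))$n_aps_total
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("time shift moves event times by exactly the shift", {
  spec1 <- icGenSpec("regular",
                     stepProtocol = list(list(ampNa = 0.5, durS = 0.2,
                                              onsetS = 0.5)))
  spec2 <- icGenSpec("regular",
                     stepProtocol = list(list(ampNa = 0.5, durS = 0.2,
                                              onsetS = 0.8)))
  t1 <- detectAps(generateIcTrace(spec1)$trace)$t
  t2 <- detectAps(generateIcTrace(spec2)$trace)$t
  expect_equal(t2 - t1, rep(0.3, length(t1)), tolerance = 1e-9)
})

test_that("multiplet grouping follows maximal ISI runs", {
  aps <- data.frame(t = c(0, 0.010, 0.022, 0.222))
  m <- detectMultiplets(aps)
  expect_equal(nrow(m), 1)
  expect_equal(m$kind, "triplet")
  expect_equal(m$n, 3)
  far <- data.frame(t = c(0, 0.1, 0.2))
  expect_equal(nrow(detectMultiplets(far)), 0)
  expect_equal(nrow(detectMultiplets(data.frame(t = 1))), 0)
  pair <- data.frame(t = c(0, 0.02))
  expect_equal(detectMultiplets(pair)$kind, "doublet")
})
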