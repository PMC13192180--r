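# Dilution series, standard-curve fitting/inversion, LDH formula.

test_that("twofold dilution series hits the documented endpoints", {
  s <- dilutionSeries(80, 9)
  expect_equal(s[9], 80 / 2^8)
  expect_equal(s[9], 0.3125)
  expect_equal(dilutionSeries(8000, 7)[7], 125)
  expect_equal(dilutionSeries(5, 1), 5)
  expect_error(dilutionSeries(-1, 3), "positive")
})

test_that("exact data are fitted exactly", {
  concs <- dilutionSeries(8000, 7)
  ods <- 0.001 * concs + 0.05
  cv <- fitStandardCurve(concs, ods, "linear")
  expect_equal(curveCoefficients(cv), c(0.05, 0.001), tolerance = 1e-10)
  # three points on a known parabola: y = 2 + 3x + 0.5 x^2
  x <- c(1, 2, 4); y <- 2 + 3 * x + 0.5 * x^2
  cq <- fitStandardCurve(x, y, "quadratic")
  expect_equal(curveCoefficients(cq), c(2, 3, 0.5), tolerance = 1e-9)
  # quadratic fit to linear data: curvature vanishes
  cl <- fitStandardCurve(concs, ods, "quadratic")
  expect_lt(abs(curveCoefficients(cl)[3]), 1e-10)
})

test_that("reference-wavelength correction is applied before fitting", {
  concs <- dilutionSeries(80, 9)
  ods <- 0.004 * concs + 0.08
  ref <- rep(0.03, 9)
  cv <- fitStandardCurve(concs, ods + ref, "linear", odRef = ref)
  expect_equal(curveCoefficients(cv), c(0.08, 0.004), tolerance = 1e-10)
})

test_that("fit -> invert round trips are exact for both kinds", {
  concs <- dilutionSeries(8000, 7)
  lin <- 0.001 * concs + 0.05
  cv <- fitStandardCurve(concs, lin, "linear")
  expect_equal(invertCurve(cv, lin), concs, tolerance = 1e-9)
  quad <- 0.05 + 2e-4 * concs - 1e-8 * concs^2
  cq <- fitStandardCurve(concs, quad, "quadratic")
  expect_equal(invertCurve(cq, quad), concs, tolerance = 1e-9)
  # OD at the top standard maps to the high standard
  expect_equal(invertCurve(cv, lin[1]), 8000, tolerance = 1e-9)
})

test_that("inversion refuses ambiguity and extrapolation", {
  # parabola with vertex inside the calibrated range: two in-range roots
  amb <- new("StandardCurve", concentrations = c(0, 5, 10),
             meanOd = c(0, 25, 0), fitKind = "quadratic",
             coefficients = c(0, 10, -1), odRange = c(0, 25),
             concRange = c(0, 10), residuals = numeric(3))
  expect_error(invertCurve(amb, 9), "both quadratic roots")
  concs <- dilutionSeries(80, 9)
  cv <- fitStandardCurve(concs, 0.004 * concs + 0.08, "linear")
  expect_error(invertCurve(cv, 10), "extrapolation")
  expect_equal(invertCurve(cv, 10, allowExtrapolation = TRUE),
               (10 - 0.08) / 0.004)
})

test_that("automatic kind selection prefers the simpler model", {
  concs <- dilutionSeries(8000, 7)
  linFit <- fitStandardCurve(concs, 0.001 * concs + 0.05, "auto")
  expect_equal(linFit@fitKind, "linear")
  bent <- 0.05 + 2e-4 * concs - 2e-8 * concs^2
  expect_equal(fitStandardCurve(concs, bent, "auto")@fitKind, "quadratic")
})

test_that("LDH activity follows the endpoint formula and is homogeneous", {
  expect_equal(ldhActivity(5, 10, 0.1), 5)
  expect_equal(ldhActivity(0, 10, 0.1), 0)
  set.seed(3)
  for (i in 1:10) {
    n <- runif(1, 0, 10); t <- runif(1, 1, 30); v <- runif(1, 0.05, 1)
    a <- ldhActivity(n, t, v)
    expect_equal(ldhActivity(2 * n, t, v), 2 * a)
    expect_equal(ldhActivity(n, 2 * t, v), a / 2)
    expect_equal(ldhActivity(n, t, 2 * v), a / 2)
  }
  expect_error(ldhActivity(5, 0, 0.1), "positive")
})

test_that("plate generator inverts exactly in the noiseless case", {
  pl <- generateAssayPlate(c(200, 1500, 6000), high = 8000, noiseSd = 0,
                           seed = 2)
  std <- pl$plate[pl$plate$role == "standard", ]
  expect_equal(std$conc, dilutionSeries(8000, 7))
  blank <- pl$plate[pl$plate$role == "blank", ]
  expect_equal(blank$od, 0.05)   # zero concentration reads the intercept
  cv <- fitStandardCurve(std$conc, std$od, "linear")
  smp <- pl$plate[pl$plate$role == "sample", ]
  expect_equal(invertCurve(cv, smp$od), c(200, 1500, 6000), tolerance = 1e-9)
})
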