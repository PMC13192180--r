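# Standard-curve math for plate assays (ELISA, Griess) and the LDH
# activity formula, plus the seeded plate generator.

#' Twofold dilution series
#'
#' \code{c(high, high/2, ..., high/2^(n-1))}: the standard-series
#' convention, e.g. seven points from 8000 pg/mL (IL-6) or nine points from
#' 80 uM sodium nitrite.
#'
#' @param high top standard concentration, > 0.
#' @param nPoints number of points, >= 1.
#' @return numeric vector of length \code{nPoints}, decreasing.
#' @examples
#' dilutionSeries(80, 9)[9]    # 0.3125
#' @export
dilutionSeries <- function(high, nPoints) {
  stopifnot2(high > 0, "high standard must be positive")
  stopifnot2(nPoints >= 1, "nPoints must be at least 1")
  high / 2^(seq_len(nPoints) - 1)
}

#' Fit a standard curve
#'
#' Least-squares linear or quadratic fit of (background-corrected) optical
#' density against standard concentration. With \code{fitKind = "auto"} the
#' quadratic is chosen only when it reduces the residual sum of squares by
#' more than 20\%. When a reference OD column is supplied (dual-wavelength
#' reading, e.g. 450 nm minus 540 nm) it is subtracted before fitting.
#'
#' @param concs standard concentrations.
#' @param ods optical densities, same length.
#' @param fitKind "linear", "quadratic" or "auto".
#' @param odRef optional reference-wavelength ODs to subtract.
#' @return a \code{\linkS4class{StandardCurve}}.
#' @export
fitStandardCurve <- function(concs, ods, fitKind = c("linear", "quadratic",
                                                     "auto"),
                             odRef = NULL) {
  fitKind <- match.arg(fitKind)
  if (!is.null(odRef)) ods <- ods - odRef
  stopifnot2(length(concs) == length(ods), "concs and ods must match")
  fit1 <- stats::lm(ods ~ concs)
  if (fitKind == "auto") {
    rss1 <- sum(stats::resid(fit1)^2)
    # exactly-linear data leave only floating-point dust in rss1; never
    # prefer the quadratic for noise below numerical resolution
    if (length(concs) >= 3 && rss1 > 1e-20 * sum(ods^2)) {
      fit2 <- stats::lm(ods ~ concs + I(concs^2))
      fitKind <- if (sum(stats::resid(fit2)^2) < 0.8 * rss1) "quadratic"
                 else "linear"
    } else fitKind <- "linear"
  }
  stopifnot2(length(concs) >= if (fitKind == "linear") 2 else 3,
             "not enough standards for the requested fit")
  fit <- if (fitKind == "linear") fit1 else
    stats::lm(ods ~ concs + I(concs^2))
  co <- unname(stats::coef(fit))
  if (anyNA(co)) stop("rank-deficient standard-curve design", call. = FALSE)
  new("StandardCurve", concentrations = as.numeric(concs),
      meanOd = as.numeric(ods), fitKind = fitKind, coefficients = co,
      odRange = range(stats::fitted(fit)), concRange = range(concs),
      residuals = unname(stats::resid(fit)))
}

#' Predict OD from a standard curve
#' @param curve a \code{\linkS4class{StandardCurve}}.
#' @param conc concentrations.
#' @return predicted optical densities.
#' @export
predictOd <- function(curve, conc) {
  co <- curve@coefficients
  if (curve@fitKind == "linear") co[1] + co[2] * conc
  else co[1] + co[2] * conc + co[3] * conc^2
}

#' Invert a standard curve
#'
#' Maps an optical density back to concentration. Linear curves invert in
#' closed form; quadratic curves take the real root inside the calibrated
#' concentration range and raise an error when both roots are in range
#' (ambiguous) or neither is. ODs outside the calibrated OD range are
#' refused as extrapolation unless \code{allowExtrapolation = TRUE}.
#'
#' @param curve a \code{\linkS4class{StandardCurve}}.
#' @param od optical density (vectorized).
#' @param allowExtrapolation permit ODs outside the calibrated range.
#' @return concentrations.
#' @export
invertCurve <- function(curve, od, allowExtrapolation = FALSE) {
  tol <- 1e-9 * max(1, abs(diff(curve@odRange)))
  if (!allowExtrapolation &&
      any(od < curve@odRange[1] - tol | od > curve@odRange[2] + tol))
    stop("OD outside the calibrated range (extrapolation)", call. = FALSE)
  co <- curve@coefficients
  if (curve@fitKind == "linear") {
    stopifnot2(co[2] != 0, "flat standard curve cannot be inverted")
    return((od - co[1]) / co[2])
  }
  vapply(od, function(y) {
    a <- co[3]; b <- co[2]; cc <- co[1] - y
    if (a == 0) return((y - co[1]) / b)
    disc <- b^2 - 4 * a * cc
    if (disc < 0) stop("no real root for this OD", call. = FALSE)
    roots <- (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
    rtol <- 1e-9 * max(1, abs(diff(curve@concRange)))
    inR <- roots >= curve@concRange[1] - rtol &
           roots <= curve@concRange[2] + rtol
    if (sum(inR) == 2 && abs(roots[1] - roots[2]) > rtol)
      stop("both quadratic roots lie in the calibrated range (ambiguous)",
           call. = FALSE)
    if (!any(inR)) stop("no root inside the calibrated range", call. = FALSE)
    roots[inR][1]
  }, numeric(1))
}

#' LDH activity from the endpoint formula
#'
#' \code{activity = NADH generated (nmol) / (reaction time (min) x
#' reaction volume (mL))}, in nmol min^-1 mL^-1.
#'
#' @param nadhNmol NADH generated (nmol), >= 0.
#' @param timeMin reaction time (min), > 0.
#' @param volumeMl reaction volume (mL), > 0.
#' @return activity in nmol min^-1 mL^-1.
#' @examples
#' ldhActivity(5, 10, 0.1)   # 5
#' @export
ldhActivity <- function(nadhNmol, timeMin, volumeMl) {
  stopifnot2(all(nadhNmol >= 0), "nadhNmol must be non-negative")
  stopifnot2(all(timeMin > 0) && all(volumeMl > 0),
             "time and volume must be positive")
  nadhNmol / (timeMin * volumeMl)
}

#' Generate a synthetic assay plate
#'
#' Simulates optical densities for a standard series plus samples with known
#' concentrations, from a stated monotone curve plus Gaussian noise.
#'
#' @param trueConcentrations sample concentrations (ground truth).
#' @param curveParams list: \code{kind} ("linear"/"quadratic") and
#'   \code{coef} (intercept first).
#' @param high top standard; \code{nStandards} points of twofold dilution
#'   are included.
#' @param nStandards number of standard wells.
#' @param noiseSd OD noise SD.
#' @param seed integer seed.
#' @return list: \code{plate} data.frame (well, role, conc, od) and
#'   \code{truth}.
#' @export
generateAssayPlate <- function(trueConcentrations,
                               curveParams = list(kind = "linear",
                                                  coef = c(0.05, 0.001)),
                               high = max(trueConcentrations) * 2,
                               nStandards = 7, noiseSd = 0, seed = 1L) {
  evalCurve <- function(conc) {
    co <- curveParams$coef
    y <- co[1] + co[2] * conc
    if (length(co) > 2) y <- y + co[3] * conc^2
    y
  }
  std <- dilutionSeries(high, nStandards)
  allC <- c(std, 0, trueConcentrations)
  dy <- diff(evalCurve(sort(allC)))
  stopifnot2(all(dy >= 0) || all(dy <= 0),
             "curve must be monotone over the concentration range")
  withSeed(seed, {
    od <- evalCurve(allC) + rnorm(length(allC), 0, noiseSd)
    plate <- data.frame(
      well = sprintf("W%02d", seq_along(allC)),
      role = c(rep("standard", nStandards), "blank",
               rep("sample", length(trueConcentrations))),
      conc = c(std, 0, rep(NA_real_, length(trueConcentrations))),
      od = od)
    list(plate = plate,
         truth = list(trueConcentrations = trueConcentrations,
                      curveParams = curveParams, high = high,
                      standards = std))
  })
}
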