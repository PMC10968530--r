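## Probe calibration: deflection (mm) vs balance force (mN) regression.

#' Fit the probe spring constant
#'
#' Ordinary least squares of force on deflection.  The default fit is
#' through the origin (a spring exerts no force at zero deflection); the
#' intercept mode is retained for balance-offset diagnostics.  A negative
#' fitted slope is a physical implausibility and raises an error rather
#' than being clamped.
#'
#' @param deflections probe-tip deflections in mm.
#' @param forces balance-measured forces in mN.
#' @param throughOrigin fit through the origin (default TRUE).
#' @return A \code{\link{ProbeCalibration-class}}.
#' @examples
#' fitProbeStiffness(c(0.1, 0.2, 0.3), c(0.05, 0.10, 0.15))   # k = 0.5
#' @export
fitProbeStiffness <- function(deflections, forces, throughOrigin = TRUE) {
  d <- as.numeric(deflections); f <- as.numeric(forces)
  if (length(d) != length(f))
    iwireStop("iwireCalibrationError", "deflections and forces differ in length")
  nmin <- if (throughOrigin) 2L else 3L
  if (length(d) < nmin)
    iwireStop("iwireCalibrationError",
              sprintf("need at least %d calibration points", nmin))
  if (max(d) == min(d) || (throughOrigin && all(d == 0)))
    iwireStop("iwireCalibrationError",
              "deflections are rank-deficient (all identical)")
  fit <- if (throughOrigin) stats::lm(f ~ 0 + d) else stats::lm(f ~ d)
  k <- unname(stats::coef(fit)[if (throughOrigin) "d" else "d"])
  b <- if (throughOrigin) 0 else unname(stats::coef(fit)["(Intercept)"])
  if (k <= 0)
    iwireStop("iwireImplausibleCalibrationError",
              sprintf("fitted stiffness %g mN/mm is not positive", k))
  res <- stats::residuals(fit)
  ssr <- sum(res^2)
  sst <- if (throughOrigin) sum(f^2) else sum((f - mean(f))^2)
  r2 <- if (sst > 0) 1 - ssr / sst else 1
  dfres <- length(d) - if (throughOrigin) 1L else 2L
  new("ProbeCalibration", kProbe = k, intercept = b,
      rSquared = min(max(r2, 0), 1), nPoints = length(d),
      residualSd = if (dfres > 0) sqrt(ssr / dfres) else 0,
      throughOrigin = isTRUE(throughOrigin))
}

#' Probe calibration from a known stiffness
#'
#' Convenience constructor for analyses where the spring constant is known
#' (e.g. synthetic studies).
#'
#' @param kProbe stiffness in mN/mm.
#' @param intercept force offset in mN (default 0).
#' @return A \code{ProbeCalibration}.
#' @export
probeCalibration <- function(kProbe, intercept = 0) {
  new("ProbeCalibration", kProbe = as.numeric(kProbe),
      intercept = as.numeric(intercept), rSquared = 1, nPoints = 2L,
      residualSd = 0, throughOrigin = intercept == 0)
}

#' Force exerted by the probe at a given deflection
#'
#' @param cal a \code{ProbeCalibration}.
#' @param deflection probe deflection in mm (vectorized, finite).
#' @return Force in mN.
#' @export
forceFromDeflection <- function(cal, deflection) {
  if (any(!is.finite(deflection))) iwireParamStop("deflection must be finite")
  cal@kProbe * deflection + cal@intercept
}

#' Read a calibration table CSV
#'
#' The reader accepts only the canonical header
#' \code{deflection_mm,force_mN} rather than guessing units.
#'
#' @param path CSV path.
#' @return data.frame with columns \code{deflection_mm}, \code{force_mN}.
#' @export
readCalibrationTable <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("deflection_mm", "force_mN") %in% names(df)))
    iwireStop("iwireFormatError",
              "calibration CSV must have columns deflection_mm, force_mN")
  df
}

#' Write a probe calibration as JSON
#'
#' @param cal a \code{ProbeCalibration}.
#' @param path output path.
#' @return Invisibly, the path.
#' @export
writeCalibrationJson <- function(cal, path) {
  jsonlite::write_json(list(
    k_probe_mN_per_mm = cal@kProbe, intercept_mN = cal@intercept,
    r_squared = cal@rSquared, n_points = cal@nPoints,
    residual_sd_mN = cal@residualSd, through_origin = cal@throughOrigin),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
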