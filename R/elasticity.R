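## Elasticity: diastolic stretch-stress curve and Young's modulus.

#' Strain of the half-fiber at a given tip deflection
#'
#' \eqn{\epsilon = (\sqrt{L_0^2 + y^2} - L_0)/L_0}: the engineering strain
#' of each straight half-segment against the unloaded wire-to-wire
#' geometry (no pre-strain).
#'
#' @param tipY transverse tip position in mm (vectorized, >= 0).
#' @param geom a \code{ConstructGeometry}.
#' @return Dimensionless strain.
#' @examples
#' strainFromTip(5, ConstructGeometry())   # sqrt(2) - 1
#' @export
strainFromTip <- function(tipY, geom) {
  if (any(tipY < 0)) iwireParamStop("tipY must be >= 0")
  .strainOfY(tipY, geom@halfLength)
}

#' Engineering stress from axial tension
#'
#' \eqn{\sigma = T / A}; with T in mN and A in mm^2 the result is in kPa
#' (1 mN/mm^2 = 1 kPa exactly).
#'
#' @param tension axial tension in mN (vectorized, >= 0).
#' @param geom a \code{ConstructGeometry}.
#' @return Stress in kPa.
#' @export
stressFromTension <- function(tension, geom) {
  if (any(tension < 0)) iwireParamStop("tension must be >= 0")
  tension / geom@crossSection
}

#' Build the diastolic stretch-stress curve of one construct
#'
#' One point per stage position: the diastolic tip position gives strain,
#' the diastolic applied force gives axial tension and hence stress.
#' Points are sorted by strain; repeated positions (duplicate target
#' forces) are averaged with provenance preserved.
#'
#' @param summaries per-recording summaries of one construct (rows of
#'   \code{\link{summarizeRecording}} output, with a \code{targetForce}
#'   column identifying the stage position).
#' @param geom a \code{ConstructGeometry}.
#' @return data.frame with columns \code{strain}, \code{stress},
#'   \code{appliedForce}, \code{recordingIds}, ordered by strain.
#' @export
buildStretchStress <- function(summaries, geom) {
  if (!all(c("strainDia", "tensionDia") %in% names(summaries)))
    iwireParamStop("summaries must carry strainDia and tensionDia")
  key <- if ("targetForce" %in% names(summaries))
    summaries$targetForce else round(summaries$strainDia, 9)
  parts <- split(summaries, key)
  pts <- lapply(parts, function(s) data.frame(
    strain = mean(s$strainDia),
    stress = stressFromTension(mean(s$tensionDia), geom),
    appliedForce = mean(s$appliedForce),
    recordingIds = paste(s$recordingId, collapse = ";"),
    stringsAsFactors = FALSE))
  out <- do.call(rbind, pts)
  out <- out[order(out$strain), , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) < 4L)
    iwireStop("iwireInsufficientDataError",
              sprintf("need >= 4 stage positions, got %d", nrow(out)))
  if (any(diff(out$strain) <= 0))
    iwireStop("iwireInsufficientDataError",
              "diastolic strains are not strictly increasing across positions")
  out
}

#' Young's modulus from the linear part of a stretch-stress curve
#'
#' OLS slope of stress on strain over a window of the curve.  The automatic
#' window is the contiguous window of at least 4 points maximizing the fit
#' R-squared, ties broken by the larger window and then the lower starting
#' index ("the linear part").  If no window reaches R-squared 0.8 a
#' poor-linearity error carrying the best diagnostic is raised.
#'
#' @param curve data.frame from \code{\link{buildStretchStress}} (columns
#'   \code{strain}, \code{stress}).
#' @param window "auto" or an integer vector of point indices (contiguous,
#'   length >= 4).
#' @param minR2 acceptance threshold for the fit (default 0.8).
#' @return data.frame (one row): \code{youngsModulus} (kPa),
#'   \code{slopeSe}, \code{rSquared}, \code{windowStart}, \code{windowEnd},
#'   \code{strainMin}, \code{strainMax}, \code{nPoints}.
#' @export
fitYoungModulus <- function(curve, window = "auto", minR2 = 0.8) {
  n <- nrow(curve)
  if (n < 4L)
    iwireStop("iwireInsufficientDataError",
              sprintf("need >= 4 points, got %d", n))
  fitWin <- function(i0, i1) {
    e <- curve$strain[i0:i1]; s <- curve$stress[i0:i1]
    fit <- stats::lm(s ~ e)
    res <- stats::residuals(fit)
    sst <- sum((s - mean(s))^2)
    r2 <- if (sst > 0) 1 - sum(res^2) / sst else 1
    list(slope = unname(stats::coef(fit)["e"]),
         se = tryCatch(
           suppressWarnings(summary(fit)$coefficients["e", "Std. Error"]),
           error = function(e2) NA_real_),
         r2 = r2, i0 = i0, i1 = i1)
  }
  if (identical(window, "auto")) {
    best <- NULL
    for (len in 4:n) for (i0 in 1:(n - len + 1)) {
      cur <- fitWin(i0, i0 + len - 1L)
      if (is.null(best) ||
          cur$r2 > best$r2 + 1e-12 ||
          (abs(cur$r2 - best$r2) <= 1e-12 &&
           ((len > best$i1 - best$i0 + 1L) ||
            (len == best$i1 - best$i0 + 1L && i0 < best$i0))))
        best <- cur
    }
  } else {
    window <- as.integer(window)
    if (length(window) < 4L || any(diff(window) != 1L) ||
        min(window) < 1L || max(window) > n)
      iwireParamStop("explicit window must be >= 4 contiguous indices")
    best <- fitWin(min(window), max(window))
  }
  if (best$r2 < minR2)
    iwireStop("iwirePoorLinearityError",
              sprintf("best window R^2 = %.4f < %.2f (points %d-%d)",
                      best$r2, minR2, best$i0, best$i1))
  if (best$slope <= 0)
    iwireStop("iwirePoorLinearityError",
              sprintf("fitted modulus %g kPa is not positive", best$slope))
  data.frame(youngsModulus = best$slope, slopeSe = best$se,
             rSquared = best$r2, windowStart = best$i0, windowEnd = best$i1,
             strainMin = curve$strain[best$i0],
             strainMax = curve$strain[best$i1],
             nPoints = best$i1 - best$i0 + 1L)
}
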