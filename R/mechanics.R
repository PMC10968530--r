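## Mechanics: centroid trace -> probe force -> per-beat forces -> curves.

#' Convert a centroid trace to a probe-force trace
#'
#' \eqn{F(t) = k\,(\Delta - y(t)) + intercept}: the probe is a linear spring
#' between the motorized stage (at \code{deltaStage}) and the tip, so
#' contraction (tip moving toward the fiber axis) increases force.
#'
#' @param trace a \code{CentroidTrace}.
#' @param cal a \code{ProbeCalibration}.
#' @param deltaStage stage position in mm (defaults to the trace metadata).
#' @param tolerance force tolerance in mN below zero before the geometry is
#'   declared inconsistent (default 1e-6).
#' @return A \code{\link{ForceTrace-class}}.
#' @export
forceTrace <- function(trace, cal, deltaStage = trace@meta$deltaStage,
                       tolerance = 1e-6) {
  if (is.null(deltaStage))
    iwireParamStop("deltaStage missing (not in trace metadata either)")
  if (deltaStage < max(trace@tipMm) - tolerance / cal@kProbe)
    iwireStop("iwireGeometryError",
              "stage position is below the maximal tip position")
  f <- cal@kProbe * (deltaStage - trace@tipMm) + cal@intercept
  if (any(f < -tolerance))
    iwireStop("iwireGeometryError",
              sprintf("negative probe force (min %g mN): geometry inconsistent",
                      min(f)))
  new("ForceTrace", time = trace@time, force = f,
      deltaStage = as.numeric(deltaStage), calibration = cal)
}

# Internal: robust noise-floor estimate of a force trace (mN): scaled median
# absolute frame-to-frame difference.
.noiseFloor <- function(f) 1.4826 * stats::median(abs(diff(f)))

# Internal: strict local maxima with plateau handling (plateau -> its middle
# sample), vectorized over runs of equal values.
.localMaxima <- function(f) {
  r <- rle(f)
  k <- length(r$values)
  if (k < 3L) return(integer())
  v <- r$values
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  i <- 2:(k - 1L)
  pk <- i[v[i] > v[i - 1L] & v[i] > v[i + 1L]]
  as.integer(floor((starts[pk] + ends[pk]) / 2))
}

# Internal: topographic prominence of candidate peaks: height minus the
# higher of the two minima separating the peak from higher ground (or the
# trace ends).
.prominence <- function(f, peaks) {
  vapply(peaks, function(p) {
    h <- f[p]
    left <- f[seq_len(p - 1)]
    higher <- which(left > h)
    lmin <- if (length(higher)) min(f[(max(higher) + 1):p]) else min(f[1:p])
    right <- f[(p + 1):length(f)]
    higher <- which(right > h)
    rmin <- if (length(higher))
      min(f[p:(p + min(higher) - 1)]) else min(f[p:length(f)])
    h - max(lmin, rmin)
  }, numeric(1))
}

#' Detect beats in a force trace
#'
#' Peaks are local maxima whose topographic prominence is at least
#' \code{minProminenceFrac} of the force range, separated by at least
#' \code{minIntervalS}.  The per-beat diastolic baseline is the minimum
#' force between the preceding peak and the current one (for the first
#' beat, from the start of the trace); developed force = systolic peak
#' minus that baseline.  Beats with developed force below twice the
#' noise-floor estimate (1.4826 x median absolute frame-to-frame
#' difference) are dropped and counted.  A trace whose total range is
#' below six noise floors is treated as beat-free and raises a
#' \code{iwireNoBeatError}.
#'
#' @param ft a \code{ForceTrace}.
#' @param minProminenceFrac prominence threshold as a fraction of the force
#'   range (default 0.3).
#' @param minIntervalS minimal inter-peak interval in s (default 0.25).
#' @param refinePeakTimes if TRUE (default) peak times are refined by a
#'   3-point parabolic fit (clamped to one frame), giving sub-frame beat
#'   timing.
#' @return A beat table (data.frame) with columns \code{peakTime},
#'   \code{systolicForce}, \code{diastolicForce}, \code{developedForce},
#'   and attributes \code{nDropped} (QC-dropped beats) and
#'   \code{noiseFloor}.
#' @export
detectBeats <- function(ft, minProminenceFrac = 0.3, minIntervalS = 0.25,
                        refinePeakTimes = TRUE) {
  f <- ft@force
  t <- ft@time
  if (max(t) - min(t) < 2)
    iwireParamStop("need at least 2 s of data")
  rng <- max(f) - min(f)
  floorF <- .noiseFloor(f)
  if (rng == 0 || rng < 6 * floorF)
    iwireStop("iwireNoBeatError",
              "no contraction signal above the noise floor")
  cand <- .localMaxima(f)
  cand <- cand[f[cand] >= min(f) + minProminenceFrac * rng]  # necessary cond.
  if (!length(cand))
    iwireStop("iwireNoBeatError", "no peaks at the requested prominence")
  prom <- .prominence(f, cand)
  cand <- cand[prom >= minProminenceFrac * rng]
  if (!length(cand))
    iwireStop("iwireNoBeatError", "no peaks at the requested prominence")
  # enforce minimal separation, keeping higher peaks first
  cand <- cand[order(f[cand], decreasing = TRUE)]
  kept <- integer()
  for (p in cand)
    if (!length(kept) || all(abs(t[p] - t[kept]) >= minIntervalS))
      kept <- c(kept, p)
  kept <- sort(kept)
  dt <- 1 / (t[2] - t[1])
  peakTime <- t[kept]
  if (refinePeakTimes) {
    for (j in seq_along(kept)) {
      p <- kept[j]
      if (p > 1 && p < length(f)) {
        denom <- f[p - 1] - 2 * f[p] + f[p + 1]
        if (denom < 0) {
          off <- 0.5 * (f[p - 1] - f[p + 1]) / denom
          peakTime[j] <- t[p] + max(-1, min(1, off)) * (t[2] - t[1])
        }
      }
    }
  }
  sys <- f[kept]
  dia <- numeric(length(kept))
  for (j in seq_along(kept)) {
    from <- if (j == 1) 1L else kept[j - 1]
    dia[j] <- min(f[from:kept[j]])
  }
  dev <- sys - dia
  drop <- dev < 2 * floorF
  bt <- data.frame(peakTime = peakTime, systolicForce = sys,
                   diastolicForce = dia, developedForce = dev)[!drop, ]
  if (!nrow(bt))
    iwireStop("iwireNoBeatError", "all detected beats fell below the QC floor")
  rownames(bt) <- NULL
  attr(bt, "nDropped") <- sum(drop)
  attr(bt, "noiseFloor") <- floorF
  bt
}

#' Spontaneous beating frequency from a beat table
#'
#' Peak-span estimator: \eqn{(n_{peaks} - 1) / (t_{last} - t_{first})},
#' robust for short (12-15 s) recordings.
#'
#' @param bt a beat table from \code{\link{detectBeats}}.
#' @return Frequency in Hz.
#' @export
beatFrequency <- function(bt) {
  if (nrow(bt) < 2L)
    iwireStop("iwireNoFrequencyError",
              "need at least 2 peaks for a frequency")
  (nrow(bt) - 1) / (bt$peakTime[nrow(bt)] - bt$peakTime[1])
}

#' Axial tension from probe force and tip position
#'
#' String-geometry inverse: \eqn{T = F\,\ell / (2 y)} with
#' \eqn{\ell = \sqrt{L_0^2 + y^2}}.  Diverges as \eqn{y \to 0} under load,
#' so callers must pass diastolic loaded states.
#'
#' @param fProbe transverse probe force, mN (>= 0; vectorized).
#' @param tipY transverse tip position, mm (> \code{tipEpsilon}).
#' @param geom a \code{ConstructGeometry}.
#' @param tipEpsilon guard below which the geometry is rejected (default
#'   1e-3 mm).
#' @return Axial tension in mN.
#' @examples
#' axialTension(0.5, 1, ConstructGeometry())   # 0.5 * sqrt(26) / 2
#' @export
axialTension <- function(fProbe, tipY, geom, tipEpsilon = 1e-3) {
  if (any(fProbe < 0)) iwireParamStop("fProbe must be >= 0")
  if (any(tipY <= tipEpsilon))
    iwireStop("iwireGeometryError",
              sprintf("tipY <= %g mm: axial tension is unbounded", tipEpsilon))
  fProbe * sqrt(geom@halfLength^2 + tipY^2) / (2 * tipY)
}

#' Summarize a single recording
#'
#' Composes \code{\link{forceTrace}}, \code{\link{detectBeats}} and
#' \code{\link{beatFrequency}}; the applied diastolic transverse force is
#' the median of the per-beat diastolic forces, from which the diastolic
#' tip position, axial tension and strain follow.  Beat-free recordings
#' (e.g. zero active tension) yield a row with \code{NA} beat fields
#' rather than an error.
#'
#' @param trace a \code{CentroidTrace}.
#' @param cal a \code{ProbeCalibration}.
#' @param geom a \code{ConstructGeometry}.
#' @param deltaStage stage position in mm (defaults to trace metadata).
#' @param recordingId identity attached to errors and the output row.
#' @param ... passed to \code{\link{detectBeats}}.
#' @return One-row data.frame: \code{recordingId, appliedForce,
#'   devForceMean, devForceSd, beatRate, nBeats, nDropped, tipDia,
#'   tensionDia, strainDia, noBeat}.
#' @export
summarizeRecording <- function(trace, cal, geom,
                               deltaStage = trace@meta$deltaStage,
                               recordingId = NA_character_, ...) {
  ft <- tryCatch(
    forceTrace(trace, cal, deltaStage),
    iwireError = function(e)
      iwireStop(class(e)[1],
                paste0("[", recordingId, "] ", conditionMessage(e))))
  bt <- tryCatch(detectBeats(ft, ...), iwireNoBeatError = function(e) NULL)
  if (is.null(bt)) {
    fDia <- stats::median(ft@force)
    tipDia <- deltaStage - (fDia - cal@intercept) / cal@kProbe
    return(data.frame(
      recordingId = recordingId, appliedForce = fDia,
      devForceMean = NA_real_, devForceSd = NA_real_,
      beatRate = NA_real_, nBeats = 0L, nDropped = 0L,
      tipDia = tipDia,
      tensionDia = axialTension(fDia, tipDia, geom),
      strainDia = .strainOfY(tipDia, geom@halfLength),
      noBeat = TRUE, stringsAsFactors = FALSE))
  }
  freq <- tryCatch(beatFrequency(bt), iwireNoFrequencyError = function(e)
    NA_real_)
  fDia <- stats::median(bt$diastolicForce)
  tipDia <- deltaStage - (fDia - cal@intercept) / cal@kProbe
  data.frame(
    recordingId = recordingId, appliedForce = fDia,
    devForceMean = mean(bt$developedForce),
    devForceSd = stats::sd(bt$developedForce),
    beatRate = freq, nBeats = nrow(bt),
    nDropped = attr(bt, "nDropped"),
    tipDia = tipDia,
    tensionDia = axialTension(fDia, tipDia, geom),
    strainDia = .strainOfY(tipDia, geom@halfLength),
    noBeat = FALSE, stringsAsFactors = FALSE)
}

#' Build a Frank-Starling force-tension curve
#'
#' Aggregates per-recording summaries over constructs: one point per
#' applied-force level (mean +- SD of developed force across constructs),
#' ordered by applied force, with a plateau annotation: the maximal
#' contiguous suffix of levels over which successive mean increments stay
#' below \code{plateauFrac} of the curve range.
#'
#' @param summaries data.frame of per-recording summaries carrying columns
#'   \code{constructId}, \code{targetForce} and \code{devForceMean}.
#' @param plateauFrac plateau increment threshold as a fraction of curve
#'   range (default 0.05).
#' @return data.frame with one row per level: \code{targetForce, mean, sd,
#'   se, n, plateau}.
#' @export
buildForceTensionCurve <- function(summaries, plateauFrac = 0.05) {
  need <- c("constructId", "targetForce", "devForceMean")
  if (!all(need %in% names(summaries)))
    iwireParamStop("summaries must carry constructId, targetForce, devForceMean")
  levelsOf <- function(cid)
    sort(unique(summaries$targetForce[summaries$constructId == cid]))
  cids <- unique(summaries$constructId)
  ref <- levelsOf(cids[1])
  bad <- cids[!vapply(cids, function(cid) identical(levelsOf(cid), ref),
                      logical(1))]
  if (length(bad))
    iwireStop("iwireAlignmentError",
              paste("inconsistent level sets for constructs:",
                    paste(bad, collapse = ", ")))
  if (length(ref) < 2L)
    iwireStop("iwireAlignmentError", "need at least 2 tension levels")
  agg <- lapply(ref, function(tf) {
    v <- summaries$devForceMean[summaries$targetForce == tf]
    v <- v[!is.na(v)]
    data.frame(targetForce = tf, mean = mean(v), sd = stats::sd(v),
               se = stats::sd(v) / sqrt(length(v)), n = length(v))
  })
  out <- do.call(rbind, agg)
  rng <- max(out$mean) - min(out$mean)
  inc <- c(Inf, abs(diff(out$mean)))
  plateau <- rep(FALSE, nrow(out))
  if (rng > 0) {
    j <- nrow(out)
    while (j >= 2 && inc[j] < plateauFrac * rng) j <- j - 1
    if (j < nrow(out)) plateau[j:nrow(out)] <- TRUE
  } else plateau[] <- TRUE
  out$plateau <- plateau
  out
}
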