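#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

## ---------------------------------------------------------------------------
## ConstructGeometry
## ---------------------------------------------------------------------------

#' Geometry of an anchored tissue fiber
#'
#' Describes an engineered cardiac tissue construct (ECTC) suspended between
#' two anchor wires and deflected transversely at its midpoint.  The fiber is
#' modeled as two straight half-segments of unloaded length \code{halfLength}
#' (mm) each; the circular cross-section of diameter \code{diameter} (mm)
#' gives the area used to convert axial tension to engineering stress.
#' \code{pixelScale} is the optical magnification in micrometres per pixel.
#'
#' @slot halfLength numeric(1), unloaded half-length L0 in mm.
#' @slot diameter numeric(1), fiber diameter in mm.
#' @slot crossSection numeric(1), cross-sectional area in mm^2
#'   (pi * diameter^2 / 4).
#' @slot pixelScale numeric(1), micrometres per pixel.
#' @export
setClass("ConstructGeometry",
  representation(
    halfLength   = "numeric",
    diameter     = "numeric",
    crossSection = "numeric",
    pixelScale   = "numeric"
  )
)

setValidity("ConstructGeometry", function(object) {
  msg <- character()
  for (s in c("halfLength", "diameter", "crossSection", "pixelScale")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v) || v <= 0)
      msg <- c(msg, sprintf("'%s' must be a single positive finite number", s))
  }
  if (!length(msg)) {
    a <- pi * object@diameter^2 / 4
    if (abs(object@crossSection - a) > 1e-12 * a)
      msg <- c(msg, "crossSection disagrees with pi * diameter^2 / 4")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a \code{ConstructGeometry}
#'
#' Defaults describe the reference device: a 10 mm channel (half-length 5 mm
#' from each anchor wire to the midpoint probe) and a fiber of 0.4 mm
#' diameter, imaged at 10 um per pixel.
#'
#' @param halfLength unloaded half-length L0 in mm.
#' @param diameter fiber diameter in mm.
#' @param pixelScale micrometres per pixel.
#' @return A \code{ConstructGeometry} object.
#' @examples
#' geom <- ConstructGeometry()
#' crossSection(geom)            # pi * 0.4^2 / 4 = 0.1257 mm^2
#' @export
ConstructGeometry <- function(halfLength = 5, diameter = 0.4, pixelScale = 10) {
  new("ConstructGeometry",
      halfLength = as.numeric(halfLength),
      diameter = as.numeric(diameter),
      crossSection = pi * as.numeric(diameter)^2 / 4,
      pixelScale = as.numeric(pixelScale))
}

#' @describeIn ConstructGeometry-class unloaded half-length in mm
#' @param object,x a \code{ConstructGeometry}
#' @aliases halfLength crossSection pixelScale
#' @export
setGeneric("halfLength", function(x) standardGeneric("halfLength"))
#' @export
setGeneric("crossSection", function(x) standardGeneric("crossSection"))
#' @export
setGeneric("pixelScale", function(x) standardGeneric("pixelScale"))
setMethod("halfLength", "ConstructGeometry", function(x) x@halfLength)
setMethod("crossSection", "ConstructGeometry", function(x) x@crossSection)
setMethod("pixelScale", "ConstructGeometry", function(x) x@pixelScale)

setMethod("show", "ConstructGeometry", function(object) {
  cat("ConstructGeometry: L0 =", object@halfLength, "mm, d =",
      object@diameter, "mm, A =", signif(object@crossSection, 6),
      "mm^2,", object@pixelScale, "um/px\n")
})

## ---------------------------------------------------------------------------
## TissueParams
## ---------------------------------------------------------------------------

#' Generative tissue parameters
#'
#' Ground-truth parameters for the synthetic recording generator: passive
#' linear elasticity (Young's modulus \code{youngsModulus}, kPa), peak active
#' axial tension per half-fiber (\code{activeTension}, mN), a Hill-type
#' length-dependent (Frank-Starling) activation in strain
#' (\code{fsStrain50}, \code{fsHill}), spontaneous beat rate
#' (\code{beatRate}, Hz), bi-exponential twitch time constants
#' (\code{tauRise} < \code{tauDecay}, s), and dimensionless drug multipliers
#' (\code{inotropy} on active tension, \code{chronotropy} on beat rate).
#'
#' @slot youngsModulus numeric(1), kPa, >= 0.
#' @slot activeTension numeric(1), mN, >= 0.
#' @slot fsStrain50 numeric(1), strain at half-maximal activation, in (0, 1).
#' @slot fsHill numeric(1), Hill exponent, >= 1.
#' @slot beatRate numeric(1), Hz, > 0.
#' @slot tauRise,tauDecay numeric(1), s, with tauDecay > tauRise > 0.
#' @slot inotropy,chronotropy numeric(1), >= 0.
#' @export
setClass("TissueParams",
  representation(
    youngsModulus = "numeric",
    activeTension = "numeric",
    fsStrain50    = "numeric",
    fsHill        = "numeric",
    beatRate      = "numeric",
    tauRise       = "numeric",
    tauDecay      = "numeric",
    inotropy      = "numeric",
    chronotropy   = "numeric"
  )
)

setValidity("TissueParams", function(object) {
  msg <- character()
  one <- function(s) {
    v <- slot(object, s)
    length(v) == 1L && is.finite(v)
  }
  for (s in slotNames(object))
    if (!one(s)) msg <- c(msg, sprintf("'%s' must be a single finite number", s))
  if (!length(msg)) {
    if (object@youngsModulus < 0) msg <- c(msg, "youngsModulus must be >= 0")
    if (object@activeTension < 0) msg <- c(msg, "activeTension must be >= 0")
    if (object@fsStrain50 <= 0 || object@fsStrain50 >= 1)
      msg <- c(msg, "fsStrain50 must lie in (0, 1)")
    if (object@fsHill < 1) msg <- c(msg, "fsHill must be >= 1")
    if (object@beatRate <= 0) msg <- c(msg, "beatRate must be > 0")
    if (!(object@tauDecay > object@tauRise && object@tauRise > 0))
      msg <- c(msg, "need tauDecay > tauRise > 0")
    if (object@inotropy < 0) msg <- c(msg, "inotropy must be >= 0")
    if (object@chronotropy < 0) msg <- c(msg, "chronotropy must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a \code{TissueParams}
#'
#' Defaults are centered on the control engineered-tissue phenotype: modulus
#' 5.4 kPa, spontaneous rate 0.76 Hz, peak active tension 0.15 mN, twitch
#' rise/decay 0.05/0.2 s, Frank-Starling half-activation at 2% strain with
#' Hill exponent 2, and neutral drug multipliers.
#'
#' @param youngsModulus,activeTension,fsStrain50,fsHill,beatRate,tauRise,tauDecay,inotropy,chronotropy see class slots.
#' @return A \code{TissueParams} object.
#' @export
TissueParams <- function(youngsModulus = 5.4, activeTension = 0.15,
                         fsStrain50 = 0.02, fsHill = 2, beatRate = 0.76,
                         tauRise = 0.05, tauDecay = 0.2,
                         inotropy = 1, chronotropy = 1) {
  new("TissueParams",
      youngsModulus = as.numeric(youngsModulus),
      activeTension = as.numeric(activeTension),
      fsStrain50 = as.numeric(fsStrain50),
      fsHill = as.numeric(fsHill),
      beatRate = as.numeric(beatRate),
      tauRise = as.numeric(tauRise),
      tauDecay = as.numeric(tauDecay),
      inotropy = as.numeric(inotropy),
      chronotropy = as.numeric(chronotropy))
}

setMethod("show", "TissueParams", function(object) {
  cat(sprintf(
    "TissueParams: E = %.3g kPa, Tmax = %.3g mN, f0 = %.3g Hz (x%.3g), taus = %.3g/%.3g s, FS(e50 = %.3g, h = %.3g), inotropy x%.3g\n",
    object@youngsModulus, object@activeTension, object@beatRate,
    object@chronotropy, object@tauRise, object@tauDecay,
    object@fsStrain50, object@fsHill, object@inotropy))
})

## ---------------------------------------------------------------------------
## AcquisitionParams
## ---------------------------------------------------------------------------

#' Optical acquisition parameters
#'
#' Frame rate and duration follow the acquisition protocol of the platform
#' (160-200 frames/s, 12-15 s movies).  \code{centroidNoiseSd} (um) is the
#' standard deviation of the per-frame centroid localization noise applied to
#' generated traces; the image-rendering fields describe the synthetic
#' probe-tip movies (a bright disk of radius \code{tipRadiusPx} on a dark
#' background, 8-bit intensities).
#'
#' @slot fps numeric(1), frames per second, in [160, 200].
#' @slot duration numeric(1), s, in [12, 15].
#' @slot centroidNoiseSd numeric(1), um, >= 0.
#' @slot imageSize integer(2), (rows, cols) of rendered frames.
#' @slot tipRadiusPx numeric(1), px.
#' @slot intensityFg,intensityBg numeric(1), 8-bit levels in [0, 255].
#' @slot pixelNoiseSd numeric(1), intensity units, >= 0.
#' @slot roiOriginMm numeric, physical tip coordinate (mm) mapped to column 1,
#'   or NULL for automatic centering of the motion range.
#' @slot seed integer(1), default RNG seed for generated recordings.
#' @export
setClass("AcquisitionParams",
  representation(
    fps             = "numeric",
    duration        = "numeric",
    centroidNoiseSd = "numeric",
    imageSize       = "integer",
    tipRadiusPx     = "numeric",
    intensityFg     = "numeric",
    intensityBg     = "numeric",
    pixelNoiseSd    = "numeric",
    roiOriginMm     = "numericOrNULL",
    seed            = "integer"
  )
)

setValidity("AcquisitionParams", function(object) {
  msg <- character()
  if (!(length(object@fps) == 1L && is.finite(object@fps) &&
        object@fps >= 160 && object@fps <= 200))
    msg <- c(msg, "fps must lie in [160, 200]")
  if (!(length(object@duration) == 1L && is.finite(object@duration) &&
        object@duration >= 12 && object@duration <= 15))
    msg <- c(msg, "duration must lie in [12, 15] s")
  if (object@centroidNoiseSd < 0) msg <- c(msg, "centroidNoiseSd must be >= 0")
  if (object@pixelNoiseSd < 0) msg <- c(msg, "pixelNoiseSd must be >= 0")
  if (length(object@imageSize) != 2L || any(object@imageSize < 8L))
    msg <- c(msg, "imageSize must be two integers >= 8")
  if (object@tipRadiusPx <= 0) msg <- c(msg, "tipRadiusPx must be > 0")
  if (any(c(object@intensityFg, object@intensityBg) < 0) ||
      any(c(object@intensityFg, object@intensityBg) > 255))
    msg <- c(msg, "intensities must lie in [0, 255]")
  if (length(msg)) msg else TRUE
})

#' Construct an \code{AcquisitionParams}
#'
#' @param fps frames per second (160-200; default 180).
#' @param duration recording length in s (12-15; default 14).
#' @param centroidNoiseSd centroid localization noise SD in um (default 2).
#' @param imageSize rendered frame size, c(rows, cols).
#' @param tipRadiusPx rendered probe-tip disk radius in px.
#' @param intensityFg,intensityBg foreground/background 8-bit levels.
#' @param pixelNoiseSd Gaussian pixel noise SD (intensity units).
#' @param roiOriginMm physical coordinate of column 1 (NULL = auto-center).
#' @param seed default RNG seed for generated recordings.
#' @return An \code{AcquisitionParams} object.
#' @export
AcquisitionParams <- function(fps = 180, duration = 14, centroidNoiseSd = 2,
                              imageSize = c(64L, 192L), tipRadiusPx = 10,
                              intensityFg = 200, intensityBg = 20,
                              pixelNoiseSd = 0, roiOriginMm = NULL,
                              seed = 1L) {
  new("AcquisitionParams",
      fps = as.numeric(fps), duration = as.numeric(duration),
      centroidNoiseSd = as.numeric(centroidNoiseSd),
      imageSize = as.integer(imageSize), tipRadiusPx = as.numeric(tipRadiusPx),
      intensityFg = as.numeric(intensityFg),
      intensityBg = as.numeric(intensityBg),
      pixelNoiseSd = as.numeric(pixelNoiseSd),
      roiOriginMm = if (is.null(roiOriginMm)) NULL else as.numeric(roiOriginMm),
      seed = as.integer(seed))
}

setMethod("show", "AcquisitionParams", function(object) {
  cat(sprintf(
    "AcquisitionParams: %g fps x %g s, centroid noise %g um, frames %dx%d px\n",
    object@fps, object@duration, object@centroidNoiseSd,
    object@imageSize[1], object@imageSize[2]))
})

## ---------------------------------------------------------------------------
## ProbeCalibration
## ---------------------------------------------------------------------------

#' Flexible-probe calibration
#'
#' Result of regressing balance-measured force (mN) on probe deflection (mm).
#' \code{kProbe} is the spring constant in mN/mm; \code{intercept} is 0 for
#' the default through-origin fit.
#'
#' @slot kProbe numeric(1), mN/mm, > 0.
#' @slot intercept numeric(1), mN.
#' @slot rSquared numeric(1) in [0, 1].
#' @slot nPoints integer(1), >= 2.
#' @slot residualSd numeric(1), mN.
#' @slot throughOrigin logical(1).
#' @export
setClass("ProbeCalibration",
  representation(
    kProbe        = "numeric",
    intercept     = "numeric",
    rSquared      = "numeric",
    nPoints       = "integer",
    residualSd    = "numeric",
    throughOrigin = "logical"
  )
)

setValidity("ProbeCalibration", function(object) {
  msg <- character()
  if (!(length(object@kProbe) == 1L && is.finite(object@kProbe) &&
        object@kProbe > 0))
    msg <- c(msg, "kProbe must be a single positive number")
  if (object@rSquared < -1e-12 || object@rSquared > 1 + 1e-12)
    msg <- c(msg, "rSquared must lie in [0, 1]")
  if (object@nPoints < 2L) msg <- c(msg, "nPoints must be >= 2")
  if (length(msg)) msg else TRUE
})

#' @export
setGeneric("kProbe", function(x) standardGeneric("kProbe"))
setMethod("kProbe", "ProbeCalibration", function(x) x@kProbe)

setMethod("show", "ProbeCalibration", function(object) {
  cat(sprintf(
    "ProbeCalibration: k = %.6g mN/mm, intercept = %.3g mN, R^2 = %.6g, n = %d\n",
    object@kProbe, object@intercept, object@rSquared, object@nPoints))
})

## ---------------------------------------------------------------------------
## ImageStack / CentroidTrace / ForceTrace
## ---------------------------------------------------------------------------

#' A grayscale time-lapse image stack
#'
#' Frames are stored as a 3-D numeric array (frame, row, col) of 8-bit-scale
#' intensities in [0, 255].  \code{originMm} records the physical transverse
#' coordinate (mm) of column 1 so that traces recovered from rendered stacks
#' live in the same coordinate system as the generator.
#'
#' @slot frames 3-D numeric array (frame, row, col).
#' @slot fps numeric(1), Hz.
#' @slot pixelScale numeric(1), um/px.
#' @slot originMm numeric(1), mm.
#' @export
setClass("ImageStack",
  representation(
    frames     = "array",
    fps        = "numeric",
    pixelScale = "numeric",
    originMm   = "numeric"
  )
)

setValidity("ImageStack", function(object) {
  msg <- character()
  d <- dim(object@frames)
  if (length(d) != 3L) msg <- c(msg, "frames must be a 3-D array")
  else if (d[1] < 2L) msg <- c(msg, "stack needs at least 2 frames")
  if (!(length(object@fps) == 1L && object@fps > 0))
    msg <- c(msg, "fps must be > 0")
  if (!(length(object@pixelScale) == 1L && object@pixelScale > 0))
    msg <- c(msg, "pixelScale must be > 0")
  if (length(msg)) msg else TRUE
})

#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
setMethod("nFrames", "ImageStack", function(x) dim(x@frames)[1])
setMethod("pixelScale", "ImageStack", function(x) x@pixelScale)

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@frames)
  cat(sprintf("ImageStack: %d frames of %dx%d px, %g fps, %g um/px\n",
              d[1], d[2], d[3], object@fps, object@pixelScale))
})

#' Per-frame transverse probe-tip position
#'
#' The bridge from pixels to mechanics: tip position in mm versus time, on a
#' uniform time grid of step 1/fps.  \code{meta} carries provenance (source
#' file, binarization threshold(s), interpolated frame indices, stage
#' position if known).
#'
#' @slot time numeric, s, uniform step 1/fps.
#' @slot tipMm numeric, transverse tip coordinate in mm.
#' @slot fps numeric(1), Hz.
#' @slot meta list of provenance fields.
#' @export
setClass("CentroidTrace",
  representation(
    time  = "numeric",
    tipMm = "numeric",
    fps   = "numeric",
    meta  = "list"
  )
)

setValidity("CentroidTrace", function(object) {
  msg <- character()
  n <- length(object@time)
  if (n < 2L) msg <- c(msg, "trace needs at least 2 samples")
  if (length(object@tipMm) != n)
    msg <- c(msg, "time and tipMm must have equal length")
  if (anyNA(object@tipMm)) msg <- c(msg, "tipMm must have no missing values")
  if (!(length(object@fps) == 1L && object@fps > 0))
    msg <- c(msg, "fps must be > 0")
  if (!length(msg)) {
    dt <- diff(object@time)
    if (any(abs(dt - 1 / object@fps) > 1e-9))
      msg <- c(msg, "time must be uniform with step 1/fps (tol 1e-9 s)")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a \code{CentroidTrace}
#' @param time sample times in s (uniform, step 1/fps).
#' @param tipMm tip positions in mm.
#' @param fps frame rate in Hz.
#' @param meta provenance list.
#' @return A \code{CentroidTrace}.
#' @export
CentroidTrace <- function(time, tipMm, fps, meta = list()) {
  new("CentroidTrace", time = as.numeric(time), tipMm = as.numeric(tipMm),
      fps = as.numeric(fps), meta = meta)
}

#' @export
setGeneric("tipPosition", function(x) standardGeneric("tipPosition"))
#' @export
setGeneric("traceTime", function(x) standardGeneric("traceTime"))
setMethod("tipPosition", "CentroidTrace", function(x) x@tipMm)
setMethod("traceTime", "CentroidTrace", function(x) x@time)

setMethod("show", "CentroidTrace", function(object) {
  cat(sprintf(
    "CentroidTrace: %d frames at %g fps (%.3g s), tip in [%.4g, %.4g] mm\n",
    length(object@time), object@fps, max(object@time) - min(object@time),
    min(object@tipMm), max(object@tipMm)))
})

#' Calibrated probe-force trace
#'
#' Probe force F(t) = k (Delta - y(t)) + intercept, in mN, derived from a
#' centroid trace, a probe calibration and the motorized-stage position
#' \code{deltaStage} (mm).  Contraction pulls the tip toward the fiber axis
#' (y decreases), so force rises during systole.
#'
#' @slot time numeric, s.
#' @slot force numeric, mN.
#' @slot deltaStage numeric(1), mm.
#' @slot calibration a \code{ProbeCalibration}.
#' @export
setClass("ForceTrace",
  representation(
    time        = "numeric",
    force       = "numeric",
    deltaStage  = "numeric",
    calibration = "ProbeCalibration"
  )
)

setValidity("ForceTrace", function(object) {
  msg <- character()
  if (length(object@time) != length(object@force))
    msg <- c(msg, "time and force must have equal length")
  if (anyNA(object@force) || any(!is.finite(object@force)))
    msg <- c(msg, "force must be finite")
  if (length(msg)) msg else TRUE
})

#' @export
setGeneric("probeForce", function(x) standardGeneric("probeForce"))
setMethod("probeForce", "ForceTrace", function(x) x@force)
setMethod("traceTime", "ForceTrace", function(x) x@time)

setMethod("show", "ForceTrace", function(object) {
  cat(sprintf(
    "ForceTrace: %d frames, F in [%.4g, %.4g] mN, stage at %.4g mm\n",
    length(object@force), min(object@force), max(object@force),
    object@deltaStage))
})

## ---------------------------------------------------------------------------
## SyntheticRecording
## ---------------------------------------------------------------------------

#' A ground-truth-known synthetic recording
#'
#' Bundles an observed (noise-added) centroid trace with the noiseless tip
#' trajectory and every generative input, so downstream estimates can be
#' scored against truth.
#'
#' @slot trace a \code{CentroidTrace} (observed).
#' @slot tipTrue numeric, noiseless tip positions in mm.
#' @slot activation numeric, per-frame twitch activation in [0, 1].
#' @slot deltaStage numeric(1), stage position in mm.
#' @slot params the generating \code{TissueParams}.
#' @slot geometry the \code{ConstructGeometry}.
#' @slot kProbe numeric(1), probe stiffness mN/mm.
#' @slot seed integer(1), RNG seed used for the noise draw.
#' @export
setClass("SyntheticRecording",
  representation(
    trace      = "CentroidTrace",
    tipTrue    = "numeric",
    activation = "numeric",
    deltaStage = "numeric",
    params     = "TissueParams",
    geometry   = "ConstructGeometry",
    kProbe     = "numeric",
    seed       = "integer"
  )
)

setValidity("SyntheticRecording", function(object) {
  msg <- character()
  if (length(object@tipTrue) != length(object@trace@time))
    msg <- c(msg, "tipTrue must match the trace length")
  if (any(object@tipTrue < -1e-12) ||
      any(object@tipTrue > object@deltaStage + 1e-12))
    msg <- c(msg, "noiseless tip positions must lie in [0, deltaStage]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SyntheticRecording", function(object) {
  cat(sprintf(
    "SyntheticRecording: %d frames, stage %.4g mm, diastolic tip %.4g mm, seed %d\n",
    length(object@tipTrue), object@deltaStage, max(object@tipTrue),
    object@seed))
})

## ---------------------------------------------------------------------------
## StudyDesign
## ---------------------------------------------------------------------------

#' Design of a simulated multi-construct study
#'
#' One experimental line (group) of \code{nConstructs} constructs, each
#' recorded under every treatment at every target diastolic transverse force
#' of the stage protocol.  Between-construct variability is lognormal with
#' coefficient of variation \code{cv} around the group-mean
#' \code{TissueParams}.
#'
#' @slot label character(1), group label.
#' @slot params group-mean \code{TissueParams}.
#' @slot cv numeric(1), between-construct lognormal CV, >= 0.
#' @slot nConstructs integer(1), >= 1.
#' @slot targetForces numeric, strictly increasing target diastolic forces mN.
#' @slot treatments data.frame with columns label, inotropy, chronotropy.
#' @slot kProbe numeric(1), probe stiffness mN/mm.
#' @slot geometry a \code{ConstructGeometry}.
#' @slot acquisition an \code{AcquisitionParams}.
#' @slot seed integer(1), master seed.
#' @export
setClass("StudyDesign",
  representation(
    label        = "character",
    params       = "TissueParams",
    cv           = "numeric",
    nConstructs  = "integer",
    targetForces = "numeric",
    treatments   = "data.frame",
    kProbe       = "numeric",
    geometry     = "ConstructGeometry",
    acquisition  = "AcquisitionParams",
    seed         = "integer"
  )
)

setValidity("StudyDesign", function(object) {
  msg <- character()
  if (object@nConstructs < 1L) msg <- c(msg, "nConstructs must be >= 1")
  if (object@cv < 0) msg <- c(msg, "cv must be >= 0")
  tf <- object@targetForces
  if (length(tf) < 1L || any(tf < 0) || any(diff(tf) <= 0))
    msg <- c(msg, "targetForces must be non-negative and strictly increasing")
  if (!all(c("label", "inotropy", "chronotropy") %in%
           names(object@treatments)) || nrow(object@treatments) < 1L)
    msg <- c(msg, "treatments needs columns label, inotropy, chronotropy")
  if (object@kProbe <= 0) msg <- c(msg, "kProbe must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct a \code{StudyDesign}
#'
#' The default stage protocol targets diastolic transverse forces of 0.424,
#' 0.530, 0.636 and 0.742 mN, the four-level lateral-tension protocol used
#' for Frank-Starling and chronotropy analyses.
#'
#' @param label group label.
#' @param params group-mean \code{TissueParams}.
#' @param cv between-construct lognormal CV (default 0.2).
#' @param nConstructs number of constructs.
#' @param targetForces target diastolic transverse forces in mN.
#' @param treatments data.frame(label, inotropy, chronotropy); the first row
#'   is conventionally the control arm.
#' @param kProbe probe stiffness in mN/mm.
#' @param geometry a \code{ConstructGeometry}.
#' @param acquisition an \code{AcquisitionParams}.
#' @param seed master seed; all recording seeds are derived from it.
#' @return A \code{StudyDesign}.
#' @export
StudyDesign <- function(label = "group", params = TissueParams(), cv = 0.2,
                        nConstructs = 9L,
                        targetForces = c(0.424, 0.530, 0.636, 0.742),
                        treatments = data.frame(
                          label = "control", inotropy = 1, chronotropy = 1,
                          stringsAsFactors = FALSE),
                        kProbe = 0.5, geometry = ConstructGeometry(),
                        acquisition = AcquisitionParams(), seed = 1L) {
  new("StudyDesign", label = label, params = params, cv = as.numeric(cv),
      nConstructs = as.integer(nConstructs),
      targetForces = as.numeric(targetForces), treatments = treatments,
      kProbe = as.numeric(kProbe), geometry = geometry,
      acquisition = acquisition, seed = as.integer(seed))
}

setMethod("show", "StudyDesign", function(object) {
  cat(sprintf(
    "StudyDesign '%s': %d constructs x %d levels x %d treatments (seed %d)\n",
    object@label, object@nConstructs, length(object@targetForces),
    nrow(object@treatments), object@seed))
})

## ---------------------------------------------------------------------------
## SyntheticStudy / StudyReport
## ---------------------------------------------------------------------------

#' A generated study: recordings plus manifest
#'
#' @slot design the \code{StudyDesign}.
#' @slot manifest data.frame, one row per recording (recordingId,
#'   constructId, group, treatment, targetForce, deltaStage, seed).
#' @slot recordings list of \code{SyntheticRecording}, parallel to manifest.
#' @slot constructParams list of per-construct \code{TissueParams}.
#' @export
setClass("SyntheticStudy",
  representation(
    design          = "StudyDesign",
    manifest        = "data.frame",
    recordings      = "list",
    constructParams = "list"
  )
)

setValidity("SyntheticStudy", function(object) {
  if (nrow(object@manifest) != length(object@recordings))
    "manifest rows must match recordings" else TRUE
})

setMethod("show", "SyntheticStudy", function(object) {
  cat(sprintf("SyntheticStudy '%s': %d recordings (%d constructs)\n",
              object@design@label, length(object@recordings),
              object@design@nConstructs))
})

#' Full study report
#'
#' @slot summaries per-recording summary table.
#' @slot forceTension per-arm force-tension curve tables.
#' @slot chronotropy chronotropy tables and comparisons.
#' @slot inotropy per-level inotropy comparisons.
#' @slot elasticity per-construct Young's modulus table.
#' @slot comparisons all group comparisons, one row each.
#' @slot qcExclusions recordings excluded from analysis, with reasons.
#' @slot config the configuration used (echoed).
#' @slot seed integer(1), master seed.
#' @slot version package version string.
#' @export
setClass("StudyReport",
  representation(
    summaries    = "data.frame",
    forceTension = "list",
    chronotropy  = "list",
    inotropy     = "list",
    elasticity   = "data.frame",
    comparisons  = "data.frame",
    qcExclusions = "data.frame",
    config       = "list",
    seed         = "integer",
    version      = "character"
  )
)

setMethod("show", "StudyReport", function(object) {
  cat(sprintf(
    "StudyReport: %d recordings summarized, %d comparisons, %d QC exclusions (seed %d)\n",
    nrow(object@summaries), nrow(object@comparisons),
    nrow(object@qcExclusions), object@seed))
})
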