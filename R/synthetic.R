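## Synthetic recording generator: a twitching, probe-loaded string model.
##
## Model conventions (fixed units: mm, mN, s, kPa; 1 kPa * mm^2 = 1 mN):
##  - the fiber is two straight half-segments of unloaded length L0 anchored
##    at the wires and meeting at the probe, which displaces the midpoint
##    transversely by y (mm); the stretched half-length is l(y) =
##    sqrt(L0^2 + y^2) and the engineering strain eps(y) = (l - L0)/L0;
##  - the probe is a linear spring acting transversely: F = k (Delta - y);
##  - transverse force balance at the tip: k (Delta - y) = 2 T(eps) y / l;
##  - axial tension T(eps) = A E eps + inotropy * Tmax * FS(eps) * a(t),
##    with Hill-type length-dependent activation FS(eps) =
##    eps^h / (eps^h + eps50^h) and bi-exponential twitch activation a(t).

#' Normalized bi-exponential twitch waveform
#'
#' \eqn{w(t) = [\exp(-t/\tau_d) - \exp(-t/\tau_r)] / \max_t[\cdot]}, so the
#' peak value is exactly 1 (attained at
#' \eqn{t^* = \ln(\tau_d/\tau_r)\,\tau_r\tau_d/(\tau_d-\tau_r)}) and
#' \eqn{w(0) = 0}.
#'
#' @param tPhase time since twitch onset, s (vectorized, >= 0).
#' @param tauRise,tauDecay rise and decay time constants, s, with
#'   \code{tauDecay > tauRise > 0}.
#' @return Activation values in [0, 1].
#' @examples
#' twitchWaveform(0, 0.05, 0.2)      # 0
#' tpk <- log(0.2 / 0.05) * 0.05 * 0.2 / (0.2 - 0.05)
#' twitchWaveform(tpk, 0.05, 0.2)    # exactly 1
#' @export
twitchWaveform <- function(tPhase, tauRise, tauDecay) {
  if (!is.finite(tauRise) || !is.finite(tauDecay) ||
      tauRise <= 0 || tauDecay <= 0 || tauRise >= tauDecay)
    iwireParamStop("need tauDecay > tauRise > 0")
  if (any(tPhase < 0)) iwireParamStop("tPhase must be >= 0")
  tPeak <- log(tauDecay / tauRise) * tauRise * tauDecay / (tauDecay - tauRise)
  peak <- exp(-tPeak / tauDecay) - exp(-tPeak / tauRise)
  (exp(-tPhase / tauDecay) - exp(-tPhase / tauRise)) / peak
}

#' Axial tension of the half-fiber
#'
#' Passive linear elasticity plus length-dependent active tension:
#' \eqn{T = A E \epsilon + \iota\,T_{max}\,FS(\epsilon)\,a} with
#' \eqn{FS(\epsilon) = \epsilon^h / (\epsilon^h + \epsilon_{50}^h)}.
#' Units: A in mm^2, E in kPa, so the passive product is in mN.
#'
#' @param strain engineering strain of the half-segment (vectorized, >= 0).
#' @param activation twitch activation in [0, 1] (vectorized).
#' @param params a \code{TissueParams}.
#' @param geom a \code{ConstructGeometry}.
#' @return Axial tension in mN.
#' @examples
#' axialTensionModel(0.02, 0, TissueParams(), ConstructGeometry())
#' @export
axialTensionModel <- function(strain, activation, params, geom) {
  if (any(strain < 0))
    iwireStop("iwireDomainError", "strain must be >= 0")
  eh <- strain^params@fsHill
  fs <- ifelse(strain > 0, eh / (eh + params@fsStrain50^params@fsHill), 0)
  geom@crossSection * params@youngsModulus * strain +
    params@inotropy * params@activeTension * fs * activation
}

# Internal: strain and stretched half-length as functions of tip position y.
.strainOfY <- function(y, L0) (sqrt(L0^2 + y^2) - L0) / L0

# Internal: transverse force-balance residual for the closed-form tissue
# model, vectorized over y and activation:
#   g(y) = k (Delta - y) - 2 T(eps(y)) y / l(y)
.residualModel <- function(y, activation, kProbe, deltaStage, params, geom) {
  L0 <- geom@halfLength
  l <- sqrt(L0^2 + y^2)
  eps <- (l - L0) / L0
  eh <- eps^params@fsHill
  fs <- ifelse(eps > 0, eh / (eh + params@fsStrain50^params@fsHill), 0)
  tens <- geom@crossSection * params@youngsModulus * eps +
    params@inotropy * params@activeTension * fs * activation
  kProbe * (deltaStage - y) - 2 * tens * y / l
}

# Internal: equilibrium tip positions for the closed-form model, vectorized
# over per-frame activation.  g(y) = k (Delta - y) - 2 T(eps(y)) y / l(y) is
# strictly decreasing in y on [0, Delta] (tension and the transverse
# projection both grow with y), so the root is unique and bracketed.  Short
# inputs are solved by plain vectorized bisection; long frame vectors are
# warm-started from an activation-grid solve (y is smooth and monotone in
# activation) and polished by safeguarded vectorized Newton iterations until
# max |g| <= 1e-12 mN.  This is the innermost loop of every simulation.
.solveEquilibriumModel <- function(kProbe, deltaStage, activation, params,
                                   geom) {
  n <- length(activation)
  if (deltaStage == 0) return(rep(0, n))
  L0 <- geom@halfLength
  AE <- geom@crossSection * params@youngsModulus
  cA <- params@inotropy * params@activeTension
  h <- params@fsHill
  e50h <- params@fsStrain50^h
  gOf <- function(y, cAct) {
    l <- sqrt(L0^2 + y^2)
    eps <- (l - L0) / L0
    eh <- eps^h
    kProbe * (deltaStage - y) - 2 * (AE * eps + cAct * eh / (eh + e50h)) *
      y / l
  }
  bisect <- function(cAct, iters = 56L) {
    m <- length(cAct)
    lo <- rep(0, m); hi <- rep(deltaStage, m)
    for (i in seq_len(iters)) {
      mid <- 0.5 * (lo + hi)
      pos <- gOf(mid, cAct) > 0
      lo[pos] <- mid[pos]
      hi[!pos] <- mid[!pos]
    }
    0.5 * (lo + hi)
  }
  cAct <- cA * activation
  if (n <= 64L || cA == 0 || max(activation) == min(activation)) {
    u <- unique(cAct)
    if (length(u) == 1L) return(rep(bisect(u), n))
    return(bisect(cAct))
  }
  # warm start: exact solves on an activation grid, monotone interpolation
  aGrid <- seq(min(activation), max(activation), length.out = 33L)
  yGrid <- bisect(cA * aGrid, iters = 40L)
  y <- stats::approx(aGrid, yGrid, xout = activation)$y
  lo <- rep(0, n); hi <- rep(deltaStage, n)
  for (it in seq_len(12L)) {
    l <- sqrt(L0^2 + y^2)
    eps <- (l - L0) / L0
    eh <- eps^h
    den <- eh + e50h
    tens <- AE * eps + cAct * eh / den
    g <- kProbe * (deltaStage - y) - 2 * tens * y / l
    if (max(abs(g)) <= 1e-12) break
    # maintain the bracket, then take a clamped Newton step
    pos <- g > 0
    lo[pos] <- pmax(lo[pos], y[pos])
    hi[!pos] <- pmin(hi[!pos], y[!pos])
    dT <- AE + cAct * h * ifelse(eps > 0, eps^(h - 1), 0) * e50h / den^2
    gp <- -kProbe - 2 * (dT * y^2 / (l^2 * L0) + tens * L0^2 / l^3)
    y <- y - g / gp
    bad <- y <= lo | y >= hi
    y[bad] <- 0.5 * (lo[bad] + hi[bad])
  }
  y
}

#' Solve the probe-fiber equilibrium for the tip position
#'
#' Finds the root \eqn{y \in [0, \Delta]} of the transverse force balance
#' \eqn{g(y) = k(\Delta - y) - 2\,T(\epsilon(y))\,y/\ell(y)} with
#' \eqn{\ell(y) = \sqrt{L_0^2 + y^2}} and
#' \eqn{\epsilon(y) = (\ell - L_0)/L_0}, to a residual below 1e-10 mN.
#'
#' @param kProbe probe stiffness, mN/mm (> 0).
#' @param deltaStage stage position, mm (>= 0).
#' @param tensionFn function(strain) -> axial tension mN; must be
#'   non-negative and continuous.
#' @param geom a \code{ConstructGeometry}.
#' @return Tip position y in mm.
#' @examples
#' geom <- ConstructGeometry()
#' solveEquilibrium(0.5, 2, function(e) 0.6786 * e, geom)
#' @export
solveEquilibrium <- function(kProbe, deltaStage, tensionFn, geom) {
  if (kProbe <= 0) iwireParamStop("kProbe must be > 0")
  if (deltaStage < 0) iwireParamStop("deltaStage must be >= 0")
  if (deltaStage == 0) return(0)
  L0 <- geom@halfLength
  g <- function(y) {
    l <- sqrt(L0^2 + y^2)
    kProbe * (deltaStage - y) - 2 * tensionFn((l - L0) / L0) * y / l
  }
  g0 <- g(0)
  g1 <- g(deltaStage)
  if (g1 == 0) return(deltaStage)   # unresisted (zero-tension) probe
  if (g0 < 0 || g1 > 0)             # pathological tension function
    iwireStop("iwireSolverError", sprintf(
      "no sign change on [0, %g]: g(0) = %g, g(Delta) = %g",
      deltaStage, g0, g1))
  y <- stats::uniroot(g, c(0, deltaStage), tol = 1e-14)$root
  # bisection polish to the required residual
  lo <- max(0, y - 1e-9); hi <- min(deltaStage, y + 1e-9)
  if (g(lo) < 0 || g(hi) > 0) { lo <- 0; hi <- deltaStage }
  it <- 0L
  while (abs(g(y)) > 1e-12 && it < 200L) {
    if (g(y) > 0) lo <- y else hi <- y
    y <- 0.5 * (lo + hi)
    it <- it + 1L
  }
  y
}

#' Stage position achieving a target diastolic probe force
#'
#' Outer root-find over \code{\link{solveEquilibrium}}: returns
#' \eqn{\Delta} such that the equilibrium probe force
#' \eqn{k(\Delta - y_{eq}(\Delta))} equals \code{targetForce} within
#' 1e-8 mN, for the passive (activation = 0) tissue.
#'
#' @param kProbe probe stiffness, mN/mm.
#' @param targetForce target diastolic transverse force, mN (>= 0).
#' @param params a \code{TissueParams} (only passive properties are used).
#' @param geom a \code{ConstructGeometry}.
#' @return Stage position Delta in mm.
#' @export
stageForTargetForce <- function(kProbe, targetForce, params, geom) {
  if (targetForce < 0) iwireParamStop("targetForce must be >= 0")
  if (kProbe <= 0) iwireParamStop("kProbe must be > 0")
  if (targetForce == 0) return(0)
  # At equilibrium the probe force equals the transverse tissue reaction
  # Ft(y) = 2 T(eps(y)) y / l(y), which is strictly increasing in y; solve
  # Ft(y) = target for the diastolic tip position, then Delta = y + F/k.
  L0 <- geom@halfLength
  Ft <- function(y) {
    l <- sqrt(L0^2 + y^2)
    2 * axialTensionModel((l - L0) / L0, 0, params, geom) * y / l
  }
  hi <- L0
  it <- 0L
  while (Ft(hi) < targetForce) {
    hi <- hi * 2
    it <- it + 1L
    if (it > 40L)
      iwireStop("iwireSolverError",
                "target diastolic force unreachable (degenerate tissue)")
  }
  y <- stats::uniroot(function(z) Ft(z) - targetForce, c(0, hi),
                      tol = 1e-13)$root
  lo <- 0; hiB <- hi
  it <- 0L
  while (abs(Ft(y) - targetForce) > 1e-9 && it < 200L) {
    if (Ft(y) < targetForce) lo <- y else hiB <- y
    y <- 0.5 * (lo + hiB)
    it <- it + 1L
  }
  y + targetForce / kProbe
}

# Internal counter-based seed fan-out: downstream draws never depend on the
# order in which stages consume randomness.
seedStream <- function(master, index) {
  # exact in doubles: (2^31 * 48271) < 2^53
  as.integer(((as.numeric(master) %% 2147483647) * 48271 +
                as.numeric(index) * 104729) %% 2147483647)
}

#' Generate a synthetic probe-tip recording
#'
#' Per frame i at t = i/fps: twitch phase = t mod (1 / (f0 * chronotropy)),
#' activation from \code{\link{twitchWaveform}}, noiseless tip position from
#' the transverse force balance, and observed position = noiseless +
#' Gaussian centroid noise.  Deterministic under a fixed seed.
#'
#' @param params a \code{TissueParams}.
#' @param geom a \code{ConstructGeometry}.
#' @param acq an \code{AcquisitionParams}.
#' @param kProbe probe stiffness, mN/mm.
#' @param deltaStage stage position, mm.
#' @param seed RNG seed (default: \code{acq@seed}).
#' @return A \code{\link{SyntheticRecording-class}} object.
#' @examples
#' rec <- generateRecording(TissueParams(), ConstructGeometry(),
#'                          AcquisitionParams(), kProbe = 0.5,
#'                          deltaStage = 6, seed = 1)
#' rec
#' @export
generateRecording <- function(params, geom, acq, kProbe, deltaStage,
                              seed = acq@seed) {
  validObject(params); validObject(geom); validObject(acq)
  if (kProbe <= 0) iwireParamStop("kProbe must be > 0")
  n <- as.integer(round(acq@fps * acq@duration))
  t <- (seq_len(n) - 1) / acq@fps
  period <- 1 / (params@beatRate * params@chronotropy)
  phase <- t %% period
  act <- if (params@activeTension * params@inotropy > 0)
    twitchWaveform(phase, params@tauRise, params@tauDecay) else rep(0, n)
  yTrue <- .solveEquilibriumModel(kProbe, deltaStage, act, params, geom)
  seed <- as.integer(seed)
  set.seed(seed)
  yObs <- yTrue + stats::rnorm(n, 0, acq@centroidNoiseSd / 1000)
  trace <- CentroidTrace(t, yObs, acq@fps,
                         meta = list(deltaStage = deltaStage, seed = seed,
                                     source = "synthetic"))
  new("SyntheticRecording", trace = trace, tipTrue = yTrue,
      activation = act, deltaStage = deltaStage, params = params,
      geometry = geom, kProbe = as.numeric(kProbe), seed = seed)
}

#' Render a synthetic recording as an image stack
#'
#' Each frame is a constant background with an anti-aliased bright (or dark)
#' disk of radius \code{tipRadiusPx} centered at the pixel position of the
#' tip, plus optional Gaussian pixel noise, quantized to 8-bit levels.  The
#' disk edge uses a linear partial-coverage ramp two pixels wide so that the
#' intensity-weighted centroid recovers the sub-pixel tip position.
#'
#' @param recording a \code{SyntheticRecording}.
#' @param acq an \code{AcquisitionParams}; its \code{roiOriginMm}, if NULL,
#'   is chosen to center the motion range in the frame.
#' @param noiseSeed seed for the pixel-noise draw.
#' @return An \code{\link{ImageStack-class}}.
#' @export
renderImageStack <- function(recording, acq, noiseSeed = recording@seed + 1L) {
  validObject(acq)
  if (acq@intensityFg == acq@intensityBg)
    iwireStop("iwireRenderError",
              "degenerate contrast: intensityFg equals intensityBg")
  tip <- recording@trace@tipMm
  px <- recording@geometry@pixelScale       # um per pixel
  nr <- acq@imageSize[1]; nc <- acq@imageSize[2]
  origin <- acq@roiOriginMm
  if (is.null(origin)) {
    span <- nc * px / 1000
    origin <- (min(tip) + max(tip)) / 2 - span / 2
  }
  colC <- (tip - origin) * 1000 / px + 1     # fractional column of the tip
  rowC <- rep((nr + 1) / 2, length(colC))
  r <- acq@tipRadiusPx
  pad <- r + 2.5
  if (any(colC - pad < 1) || any(colC + pad > nc) ||
      any(rowC - pad < 1) || any(rowC + pad > nr))
    iwireStop("iwireRenderError", "tip disk falls outside the frame")
  n <- length(colC)
  frames <- array(acq@intensityBg, dim = c(n, nr, nc))
  rows <- seq_len(nr)
  set.seed(as.integer(noiseSeed))
  for (i in seq_len(n)) {
    c0 <- colC[i]; r0 <- rowC[i]
    cl <- floor(c0 - pad):ceiling(c0 + pad)
    d <- sqrt(outer((rows - r0)^2, (cl - c0)^2, "+"))
    cov <- pmin(pmax((r + 1 - d) / 2, 0), 1)
    frames[i, , cl] <- acq@intensityBg + (acq@intensityFg - acq@intensityBg) * cov
  }
  if (acq@pixelNoiseSd > 0)
    frames <- frames + stats::rnorm(length(frames), 0, acq@pixelNoiseSd)
  frames <- round(pmin(pmax(frames, 0), 255))
  new("ImageStack", frames = frames, fps = recording@trace@fps,
      pixelScale = px, originMm = origin)
}

#' Generate a full multi-construct study
#'
#' Per construct, \code{TissueParams} are drawn lognormally around the group
#' means with the design's CV (modulus, active tension and beat rate vary
#' independently; the two twitch time constants share one multiplier so
#' their order is preserved).  For each treatment and each target diastolic
#' force, one recording is generated; the stage position for a target force
#' is solved per construct from its passive elasticity and reused across
#' treatments (treatments alter only active tension and rate, emulating
#' repeated recordings "under the same conditions").
#'
#' @param design a \code{StudyDesign}.
#' @return A \code{\link{SyntheticStudy-class}} with
#'   \code{nConstructs * length(targetForces)} recordings per treatment.
#' @examples
#' d <- StudyDesign(nConstructs = 2L, acquisition = AcquisitionParams(
#'        fps = 160, duration = 12))
#' st <- generateStudy(d)
#' nrow(st@manifest)   # 2 constructs x 4 levels x 1 treatment = 8
#' @export
generateStudy <- function(design) {
  validObject(design)
  set.seed(seedStream(design@seed, 0L))
  pm <- design@params
  cv <- design@cv
  sdlog <- sqrt(log(1 + cv^2))
  drawLN <- function(mean) {
    if (cv == 0) return(rep(mean, design@nConstructs))
    mean * stats::rlnorm(design@nConstructs, -sdlog^2 / 2, sdlog)
  }
  Es <- drawLN(pm@youngsModulus)
  Ts <- drawLN(pm@activeTension)
  Fs <- drawLN(pm@beatRate)
  tauFac <- if (cv == 0) rep(1, design@nConstructs) else
    stats::rlnorm(design@nConstructs, -sdlog^2 / 2, sdlog)
  constructParams <- lapply(seq_len(design@nConstructs), function(i) {
    TissueParams(youngsModulus = Es[i], activeTension = Ts[i],
                 fsStrain50 = pm@fsStrain50, fsHill = pm@fsHill,
                 beatRate = Fs[i], tauRise = pm@tauRise * tauFac[i],
                 tauDecay = pm@tauDecay * tauFac[i],
                 inotropy = pm@inotropy, chronotropy = pm@chronotropy)
  })
  rows <- list(); recs <- list(); counter <- 0L
  for (ci in seq_len(design@nConstructs)) {
    cp <- constructParams[[ci]]
    deltas <- vapply(design@targetForces, function(f)
      stageForTargetForce(design@kProbe, f, cp, design@geometry), numeric(1))
    for (ti in seq_len(nrow(design@treatments))) {
      tr <- design@treatments[ti, ]
      tp <- TissueParams(youngsModulus = cp@youngsModulus,
                         activeTension = cp@activeTension,
                         fsStrain50 = cp@fsStrain50, fsHill = cp@fsHill,
                         beatRate = cp@beatRate,
                         tauRise = cp@tauRise, tauDecay = cp@tauDecay,
                         inotropy = cp@inotropy * tr$inotropy,
                         chronotropy = cp@chronotropy * tr$chronotropy)
      for (fi in seq_along(design@targetForces)) {
        counter <- counter + 1L
        rseed <- seedStream(design@seed, counter)
        rec <- generateRecording(tp, design@geometry, design@acquisition,
                                 design@kProbe, deltas[fi], seed = rseed)
        recs[[counter]] <- rec
        rows[[counter]] <- data.frame(
          recordingId = sprintf("%s_c%02d_%s_f%d", design@label, ci,
                                tr$label, fi),
          constructId = sprintf("%s_c%02d", design@label, ci),
          group = design@label, treatment = tr$label,
          targetForce = design@targetForces[fi],
          deltaStage = deltas[fi], seed = rseed,
          stringsAsFactors = FALSE)
      }
    }
  }
  new("SyntheticStudy", design = design,
      manifest = do.call(rbind, rows), recordings = recs,
      constructParams = constructParams)
}

#' Write a recording to disk (trace CSV + ground-truth JSON sidecar)
#'
#' The CSV has the canonical header \code{time_s,tip_mm}; the sidecar
#' records stage position, probe stiffness, seed and the generating tissue
#' parameters.
#'
#' @param recording a \code{SyntheticRecording}.
#' @param path output CSV path; the sidecar gets the extension
#'   \code{.json}.
#' @return Invisibly, the CSV path.
#' @export
writeRecording <- function(recording, path) {
  tr <- recording@trace
  df <- data.frame(time_s = tr@time, tip_mm = tr@tipMm)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  p <- recording@params
  side <- list(
    delta_stage_mm = recording@deltaStage, k_probe_mN_per_mm = recording@kProbe,
    seed = recording@seed, fps = tr@fps,
    params = list(youngs_modulus_kPa = p@youngsModulus,
                  active_tension_mN = p@activeTension,
                  fs_strain50 = p@fsStrain50, fs_hill = p@fsHill,
                  beat_rate_Hz = p@beatRate, tau_rise_s = p@tauRise,
                  tau_decay_s = p@tauDecay, inotropy = p@inotropy,
                  chronotropy = p@chronotropy))
  jsonlite::write_json(side, sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a trace CSV written by \code{\link{writeRecording}}
#'
#' @param path CSV with header \code{time_s,tip_mm}.
#' @param fps frame rate; if missing, inferred from the time column.
#' @return A \code{CentroidTrace}.
#' @export
readTrace <- function(path, fps = NULL) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "tip_mm") %in% names(df)))
    iwireStop("iwireFormatError",
              "trace CSV must have columns time_s, tip_mm")
  if (is.null(fps)) fps <- 1 / stats::median(diff(df$time_s))
  CentroidTrace(df$time_s, df$tip_mm, fps, meta = list(source = path))
}
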