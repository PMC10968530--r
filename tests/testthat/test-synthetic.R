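# Synthetic generator: twitch waveform, tension model, equilibrium solver,
# stage protocol, recordings and study assembly.

test_that("twitch waveform is normalized, zero at onset, matches the grid oracle", {
  expect_equal(twitchWaveform(0, 0.05, 0.2), 0)
  tPeak <- log(0.2 / 0.05) * 0.05 * 0.2 / (0.2 - 0.05)
  expect_equal(twitchWaveform(tPeak, 0.05, 0.2), 1)
  # frozen from the dense-grid oracle (step 1e-4 s)
  expect_equal(twitchWaveform(0.5, 0.05, 0.2), 0.1736396637, tolerance = 1e-6)
  expect_equal(twitchWaveform(0.5, 0.05, 0.2),
               oracleTwitch(0.5, 0.05, 0.2), tolerance = 1e-7)
  # whole curve stays in [0, 1]
  w <- twitchWaveform(seq(0, 2, by = 1e-3), 0.05, 0.2)
  expect_true(all(w >= 0 & w <= 1 + 1e-12))
  expect_error(twitchWaveform(0.1, 0.3, 0.2), class = "iwireParameterError")
  expect_error(twitchWaveform(0.1, -1, 0.2), class = "iwireParameterError")
  expect_error(twitchWaveform(-0.1, 0.05, 0.2), class = "iwireParameterError")
})

test_that("axial tension model: passive term, Hill saturation, domain errors", {
  geom <- testGeom()
  p <- TissueParams(youngsModulus = 5.4)
  expect_equal(axialTensionModel(0, 1, p, geom), 0)
  # passive value recomputed independently: A * E * eps
  expect_equal(axialTensionModel(0.02, 0, p, geom),
               crossSection(geom) * 5.4 * 0.02, tolerance = 1e-12)
  # Hill saturation: large strain, activation 1 -> passive + inotropy * Tmax
  pHi <- TissueParams(activeTension = 0.2, inotropy = 1.3)
  act <- axialTensionModel(2, 1, pHi, geom) -
    axialTensionModel(2, 0, pHi, geom)
  expect_equal(act, 1.3 * 0.2, tolerance = 1e-3)
  expect_error(axialTensionModel(-0.01, 0, p, geom), class = "iwireDomainError")
})

test_that("equilibrium solver matches the energy-grid oracle and has tiny residuals", {
  geom <- testGeom()
  L0 <- halfLength(geom); A <- crossSection(geom)
  for (E in c(3, 5.4, 9)) for (k in c(0.25, 1)) for (delta in c(0.5, 2)) {
    p <- TissueParams(youngsModulus = E, activeTension = 0)
    y <- solveEquilibrium(k, delta, function(e)
      axialTensionModel(e, 0, p, geom), geom)
    yo <- oracleEquilibriumEnergy(k, delta, E, A, L0)
    expect_lt(abs(y - yo), 1e-4)
    l <- sqrt(L0^2 + y^2)
    g <- k * (delta - y) - 2 * axialTensionModel((l - L0) / L0, 0, p, geom) * y / l
    expect_lt(abs(g), 1e-10)
  }
})

test_that("equilibrium solver trivial and degenerate cases", {
  geom <- testGeom()
  expect_identical(solveEquilibrium(0.5, 2, function(e) 0, geom), 2)
  expect_identical(solveEquilibrium(0.5, 0, function(e) 1, geom), 0)
  # pathological tension (negative = pushes outward) -> no bracket
  expect_error(solveEquilibrium(0.5, 2, function(e) -10, geom),
               class = "iwireSolverError")
})

test_that("equilibrium tip position increases with stage position", {
  geom <- testGeom()
  p <- TissueParams()
  tens <- function(e) axialTensionModel(e, 0, p, geom)
  deltas <- seq(0.2, 8, length.out = 25)
  ys <- vapply(deltas, function(d) solveEquilibrium(0.5, d, tens, geom),
               numeric(1))
  expect_true(all(diff(ys) > 0))
})

test_that("stage positions for the four-level protocol round-trip and increase", {
  geom <- testGeom()
  p <- TissueParams()
  targets <- c(0.424, 0.530, 0.636, 0.742)
  deltas <- vapply(targets, function(f)
    stageForTargetForce(0.5, f, p, geom), numeric(1))
  expect_true(all(diff(deltas) > 0))
  for (i in seq_along(targets)) {
    y <- solveEquilibrium(0.5, deltas[i], function(e)
      axialTensionModel(e, 0, p, geom), geom)
    expect_lt(abs(0.5 * (deltas[i] - y) - targets[i]), 1e-8)
  }
  expect_identical(stageForTargetForce(0.5, 0, p, geom), 0)
  # monotonicity against a fine sweep of the forward map
  dg <- seq(0.1, max(deltas) + 0.5, length.out = 60)
  fg <- vapply(dg, function(d) {
    y <- solveEquilibrium(0.5, d, function(e)
      axialTensionModel(e, 0, p, geom), geom)
    0.5 * (d - y)
  }, numeric(1))
  expect_true(all(diff(fg) > 0))
})

test_that("generated recordings: determinism, twitch count, contraction direction", {
  geom <- testGeom()
  acq <- fastAcq()
  p <- TissueParams(beatRate = 1.0)
  r1 <- generateRecording(p, geom, acq, 0.5, 6, seed = 42)
  r2 <- generateRecording(p, geom, acq, 0.5, 6, seed = 42)
  expect_identical(tipPosition(r1@trace), tipPosition(r2@trace))
  expect_identical(r1@tipTrue, r2@tipTrue)
  # contraction decreases y
  expect_lt(min(r1@tipTrue), max(r1@tipTrue))
  expect_equal(max(r1@tipTrue),
               solveEquilibrium(0.5, 6, function(e)
                 axialTensionModel(e, 0, p, geom), geom), tolerance = 1e-9)
  # f0 = 1 Hz, 12 s -> exactly 12 twitch onsets (phase resets) in the trace
  phase <- r1@trace@time %% 1
  expect_equal(sum(diff(phase) < 0) + 1, 12)
})

test_that("zero active tension gives a flat noiseless trace at the diastolic position", {
  geom <- testGeom()
  p0 <- TissueParams(activeTension = 0)
  rec <- generateRecording(p0, geom, fastAcq(centroidNoiseSd = 0), 0.5, 6,
                           seed = 5)
  expect_equal(max(rec@tipTrue) - min(rec@tipTrue), 0)
  expect_identical(tipPosition(rec@trace), rec@tipTrue)
})

test_that("per-frame equilibrium residuals of a recording stay below 1e-10 mN", {
  geom <- testGeom()
  p <- TissueParams()
  rec <- generateRecording(p, geom, fastAcq(), 0.5, 6, seed = 8)
  L0 <- halfLength(geom)
  y <- rec@tipTrue
  l <- sqrt(L0^2 + y^2)
  tens <- axialTensionModel((l - L0) / L0, rec@activation, p, geom)
  g <- 0.5 * (rec@deltaStage - y) - 2 * tens * y / l
  expect_lt(max(abs(g)), 1e-10)
})

test_that("study generation: counts, grouping, zero-CV degeneracy, determinism", {
  acq <- fastAcq()
  tr2 <- data.frame(label = c("control", "treated"),
                    inotropy = c(1, 1.25), chronotropy = c(1, 1.17),
                    stringsAsFactors = FALSE)
  d9 <- StudyDesign(label = "CC3", nConstructs = 9L, treatments = tr2,
                    acquisition = acq, seed = 3L)
  st <- generateStudy(d9)
  expect_equal(nrow(st@manifest), 9 * 4 * 2)
  expect_equal(sum(st@manifest$treatment == "control"), 36)   # N = 36 arm
  d8 <- StudyDesign(label = "TSP", nConstructs = 8L, treatments = tr2,
                    acquisition = acq, seed = 4L)
  expect_equal(sum(generateStudy(d8)@manifest$treatment == "control"), 32)
  # CV = 0 -> identical construct parameters
  d0 <- StudyDesign(nConstructs = 3L, cv = 0, acquisition = acq, seed = 5L)
  st0 <- generateStudy(d0)
  Es <- vapply(st0@constructParams, function(p) p@youngsModulus, numeric(1))
  expect_true(all(Es == Es[1]))
  # same design twice -> identical traces
  stA <- generateStudy(d0)
  expect_identical(tipPosition(stA@recordings[[5]]@trace),
                   tipPosition(st0@recordings[[5]]@trace))
})

test_that("recording CSV/JSON round trip preserves the trace", {
  geom <- testGeom()
  rec <- generateRecording(TissueParams(), geom, fastAcq(), 0.5, 6, seed = 1)
  path <- file.path(tempdir(), "rec_test.csv")
  writeRecording(rec, path)
  tr <- readTrace(path)
  expect_equal(tipPosition(tr), tipPosition(rec@trace), tolerance = 1e-12)
  side <- jsonlite::read_json(sub("\\.csv$", ".json", path))
  expect_equal(side$delta_stage_mm, 6)
  expect_equal(side$params$beat_rate_Hz, 0.76)
  unlink(c(path, sub("\\.csv$", ".json", path)))
})

test_that("parameter objects enforce their invariants", {
  expect_error(TissueParams(tauRise = 0.3, tauDecay = 0.2))
  expect_error(TissueParams(fsStrain50 = 1.5))
  expect_error(TissueParams(beatRate = 0))
  expect_error(ConstructGeometry(diameter = -1))
  expect_error(AcquisitionParams(fps = 100))
  expect_error(AcquisitionParams(duration = 30))
  expect_error(StudyDesign(targetForces = c(0.5, 0.4)))
  g <- ConstructGeometry(diameter = 0.8)
  expect_equal(crossSection(g), pi * 0.8^2 / 4, tolerance = 1e-14)
})
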