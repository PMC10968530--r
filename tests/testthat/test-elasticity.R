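# Elasticity: strain/stress maps, stretch-stress curves, modulus fits.

test_that("strain map: closed forms and geometry oracle", {
  geom <- testGeom()
  expect_equal(strainFromTip(0, geom), 0)
  expect_equal(strainFromTip(halfLength(geom), geom), sqrt(2) - 1,
               tolerance = 1e-12)
  # frozen arc-length value: y = 1, L0 = 5
  expect_equal(strainFromTip(1, geom), 0.019803902719, tolerance = 1e-10)
  # direct recomputation
  expect_equal(strainFromTip(1, geom), (sqrt(25 + 1) - 5) / 5,
               tolerance = 1e-14)
  expect_error(strainFromTip(-0.1, geom), class = "iwireParameterError")
})

test_that("stress map: unit identity mN/mm^2 = kPa and scaling in diameter", {
  geom <- testGeom()
  expect_equal(stressFromTension(0, geom), 0)
  # frozen arithmetic: T = 1.2747549 mN over A = pi 0.4^2/4 mm^2
  expect_equal(stressFromTension(1.274754878398, geom), 10.14417701,
               tolerance = 1e-7)
  expect_equal(stressFromTension(1, geom), 1 / crossSection(geom),
               tolerance = 1e-14)
  # doubling the diameter quarters the stress
  g2 <- ConstructGeometry(diameter = 0.8)
  expect_equal(stressFromTension(1, g2), stressFromTension(1, geom) / 4,
               tolerance = 1e-12)
})

test_that("noiseless passive fibers give stretch-stress points on sigma = E * eps", {
  geom <- testGeom()
  cal <- testCal()
  p <- TissueParams(youngsModulus = 5.4, activeTension = 0)
  acq <- fastAcq(centroidNoiseSd = 0)
  sums <- lapply(seq_along(c(0.424, 0.530, 0.636, 0.742)), function(i) {
    f <- c(0.424, 0.530, 0.636, 0.742)[i]
    delta <- stageForTargetForce(0.5, f, p, geom)
    rec <- generateRecording(p, geom, acq, 0.5, delta, seed = i)
    s <- summarizeRecording(rec@trace, cal, geom, recordingId = i)
    s$constructId <- "c1"; s$targetForce <- f; s$treatment <- "control"
    s
  })
  sums <- do.call(rbind, sums)
  curve <- buildStretchStress(sums, geom)
  expect_equal(nrow(curve), 4)
  expect_true(all(diff(curve$strain) > 0))
  expect_lt(max(abs(curve$stress - 5.4 * curve$strain)), 1e-9)
  fit <- fitYoungModulus(curve)
  expect_lt(abs(fit$youngsModulus / 5.4 - 1), 1e-6)
  expect_equal(fit$nPoints, 4L)
})

test_that("beating does not disturb the diastolic stretch-stress extraction", {
  geom <- testGeom()
  cal <- testCal()
  targets <- c(0.424, 0.530, 0.636, 0.742)
  mkCurve <- function(tmax) {
    p <- TissueParams(youngsModulus = 5.4, activeTension = tmax)
    sums <- lapply(seq_along(targets), function(i) {
      delta <- stageForTargetForce(0.5, targets[i], p, geom)
      rec <- generateRecording(p, geom, fastAcq(centroidNoiseSd = 0), 0.5,
                               delta, seed = i)
      s <- summarizeRecording(rec@trace, cal, geom, recordingId = i)
      s$constructId <- "c1"; s$targetForce <- targets[i]
      s
    })
    buildStretchStress(do.call(rbind, sums), geom)
  }
  active <- mkCurve(0.15)
  passive <- mkCurve(0)
  expect_equal(active$strain, passive$strain, tolerance = 0.01)
  expect_equal(active$stress, passive$stress, tolerance = 0.02)
  fitA <- fitYoungModulus(active)
  expect_lt(abs(fitA$youngsModulus / 5.4 - 1), 0.02)
})

test_that("duplicate stage positions are averaged with provenance", {
  geom <- testGeom()
  s <- data.frame(
    recordingId = c("a", "b", "c", "d", "e"),
    constructId = "c1",
    targetForce = c(0.4, 0.4, 0.5, 0.6, 0.7),
    appliedForce = c(0.40, 0.41, 0.5, 0.6, 0.7),
    strainDia = c(0.40, 0.42, 0.50, 0.60, 0.70),
    tensionDia = c(1.0, 1.1, 1.3, 1.6, 1.9),
    stringsAsFactors = FALSE)
  curve <- buildStretchStress(s, geom)
  expect_equal(nrow(curve), 4)
  expect_equal(curve$strain[1], 0.41)
  expect_equal(curve$stress[1], stressFromTension(1.05, geom))
  expect_match(curve$recordingIds[1], "a;b")
  expect_error(buildStretchStress(s[1:4, ], geom),
               class = "iwireInsufficientDataError")
})

test_that("modulus fit: exact line, toe-region window selection, window oracle", {
  # exact line at the stiffer reference phenotype
  eps <- seq(0.05, 0.6, length.out = 8)
  curve <- data.frame(strain = eps, stress = 6.8 * eps)
  fit <- fitYoungModulus(curve)
  expect_lt(abs(fit$youngsModulus - 6.8), 1e-9)
  expect_equal(c(fit$windowStart, fit$windowEnd), c(1, 8))
  # saturating toe region before a linear segment
  toe <- c(0.001, 0.004, 0.012, 0.03)
  lin <- 0.05 + 6.8 * (eps[5:8] - eps[4])
  curve2 <- data.frame(strain = eps, stress = c(toe, lin))
  fit2 <- fitYoungModulus(curve2)
  o <- oracleBestWindow(curve2$strain, curve2$stress)
  expect_equal(c(fit2$windowStart, fit2$windowEnd), c(o$i0, o$i1))
  expect_gte(fit2$windowStart, 4)
  # random curves: auto window equals the exhaustive maximizer
  set.seed(11)
  for (i in 1:10) {
    n <- sample(6:10, 1)
    st <- sort(runif(n, 0.05, 0.7))
    sg <- 5 * st + rnorm(n, 0, 0.1) + ifelse(st < 0.2, -0.3 * (0.2 - st), 0)
    cv <- data.frame(strain = st, stress = pmax(sg, 0))
    f <- tryCatch(fitYoungModulus(cv), iwireError = function(e) NULL)
    ob <- oracleBestWindow(cv$strain, cv$stress)
    if (!is.null(f))
      expect_equal(c(f$windowStart, f$windowEnd), c(ob$i0, ob$i1))
  }
  expect_error(fitYoungModulus(curve[1:3, ]),
               class = "iwireInsufficientDataError")
})

test_that("poor linearity raises a diagnostic error", {
  set.seed(2)
  curve <- data.frame(strain = seq(0.1, 0.8, length.out = 6),
                      stress = runif(6, 0, 5))
  err <- tryCatch(fitYoungModulus(curve), iwirePoorLinearityError = identity)
  if (inherits(err, "iwirePoorLinearityError")) {
    expect_match(conditionMessage(err), "R\\^2")
  } else {
    succeed("random curve happened to be linear enough")
  }
})

test_that("noisy modulus recovery across 100 constructs has < 5% median error", {
  geom <- testGeom()
  cal <- testCal()
  targets <- c(0.424, 0.530, 0.636, 0.742)
  acq <- fastAcq()
  set.seed(42)
  Es <- runif(100, 3, 9)
  relErr <- numeric(100)
  for (ci in 1:100) {
    p <- TissueParams(youngsModulus = Es[ci])
    sums <- lapply(seq_along(targets), function(i) {
      delta <- stageForTargetForce(0.5, targets[i], p, geom)
      rec <- generateRecording(p, geom, acq, 0.5, delta,
                               seed = 1000 * ci + i)
      s <- summarizeRecording(rec@trace, cal, geom, recordingId = i)
      s$constructId <- "c"; s$targetForce <- targets[i]
      s
    })
    fit <- fitYoungModulus(buildStretchStress(do.call(rbind, sums), geom))
    relErr[ci] <- abs(fit$youngsModulus / Es[ci] - 1)
  }
  expect_lt(stats::median(relErr), 0.05)
})
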