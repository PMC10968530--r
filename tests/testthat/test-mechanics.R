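# Mechanics: force traces, beat detection, frequency, axial tension,
# recording summaries and force-tension curves.

mkTrace <- function(tip, fps = 160, delta = 6)
  CentroidTrace((seq_along(tip) - 1) / fps, tip, fps,
                meta = list(deltaStage = delta))

test_that("force trace: linear spring, direction, geometry errors", {
  cal <- testCal()
  tr <- mkTrace(rep(6, 400))
  expect_true(all(probeForce(forceTrace(tr, cal)) == 0))
  # square-wave tip of amplitude 0.2 mm -> developed force 0.1 mN
  tip <- rep(c(5.0, 4.8), each = 160, times = 4)
  ft <- forceTrace(mkTrace(tip), cal)
  expect_equal(max(ft@force) - min(ft@force), 0.1, tolerance = 1e-12)
  expect_gt(cor(-tip, ft@force), 0.999)   # contraction raises force
  expect_error(forceTrace(mkTrace(rep(6.5, 400)), cal),
               class = "iwireGeometryError")
})

test_that("synthetic round trip: force trace matches k * (Delta - y_true) within noise", {
  geom <- testGeom()
  cal <- testCal()
  rec <- generateRecording(TissueParams(), geom, fastAcq(), 0.5, 6, seed = 4)
  ft <- forceTrace(rec@trace, cal)
  fTrue <- 0.5 * (rec@deltaStage - rec@tipTrue)
  expect_lt(max(abs(ft@force - fTrue)), 6 * 0.5 * 0.002)  # 6 sd of noise * k
})

test_that("beat detection on a sinusoid finds every cycle and its amplitude", {
  fps <- 160
  t <- (0:(14 * fps - 1)) / fps
  tip <- 5 + 0.2 * cos(2 * pi * t)   # 1 Hz, force peaks at t = 0.5, 1.5, ...
  ft <- forceTrace(mkTrace(tip, fps), testCal())
  bt <- detectBeats(ft)
  expect_equal(nrow(bt), 14)
  expect_equal(beatFrequency(bt), 1.0, tolerance = 1e-3)
  # developed force = peak-to-trough amplitude of the spring force
  expect_equal(mean(bt$developedForce), 0.2, tolerance = 1e-3)
})

test_that("flat or noise-only traces raise a no-beat error", {
  cal <- testCal()
  set.seed(12)
  noisy <- mkTrace(5 + rnorm(2000, 0, 0.002))
  expect_error(detectBeats(forceTrace(noisy, cal)), class = "iwireNoBeatError")
  flat <- mkTrace(rep(5, 2000))
  expect_error(detectBeats(forceTrace(flat, cal)), class = "iwireNoBeatError")
  short <- mkTrace(rep(5, 100))
  expect_error(detectBeats(forceTrace(short, cal)),
               class = "iwireParameterError")
})

test_that("peak sets agree with the exhaustive local-extrema oracle on twitch trains", {
  geom <- testGeom()
  cal <- testCal()
  set.seed(9)
  for (f0 in c(0.76, 1.09)) {
    rec <- generateRecording(TissueParams(beatRate = f0), geom,
                             fastAcq(), 0.5, 6, seed = round(100 * f0))
    ft <- forceTrace(rec@trace, cal)
    bt <- detectBeats(ft, refinePeakTimes = FALSE)
    # every reported peak is a genuine local maximum of the raw trace
    lm <- oracleLocalMaxima(ft@force)
    peakIdx <- round(bt$peakTime * rec@trace@fps) + 1
    expect_true(all(peakIdx %in% lm))
    # count matches the number of generator onsets (to within the partial
    # first/last cycle)
    nOnsets <- floor(max(ft@time) * f0) + 1
    expect_lte(abs(nrow(bt) - nOnsets), 1)
  }
})

test_that("developed force and frequency recover ground truth on noisy recordings", {
  geom <- testGeom()
  cal <- testCal()
  for (f0 in c(0.93, 1.5)) {
    rec <- generateRecording(TissueParams(beatRate = f0), geom,
                             AcquisitionParams(), 0.5, 6,
                             seed = round(10 * f0))
    ft <- forceTrace(rec@trace, cal)
    bt <- detectBeats(ft)
    devTrue <- 0.5 * (max(rec@tipTrue) - min(rec@tipTrue))
    expect_lt(abs(mean(bt$developedForce) / devTrue - 1), 0.05)
    expect_lt(abs(beatFrequency(bt) - f0), 0.02)
  }
})

test_that("developed force is invariant to a constant baseline shift", {
  geom <- testGeom()
  cal <- testCal()
  rec <- generateRecording(TissueParams(), geom, fastAcq(), 0.5, 6, seed = 6)
  ft1 <- forceTrace(rec@trace, cal)
  sh <- rec@trace
  sh@tipMm <- sh@tipMm - 0.15
  ft2 <- forceTrace(sh, cal)
  b1 <- detectBeats(ft1); b2 <- detectBeats(ft2)
  expect_equal(b2$developedForce, b1$developedForce, tolerance = 1e-12)
})

test_that("beat frequency estimator: exact on regular peaks, error bounds", {
  bt <- data.frame(peakTime = 1:14, systolicForce = 1, diastolicForce = 0,
                   developedForce = 1)
  expect_equal(beatFrequency(bt), 1.0)
  expect_error(beatFrequency(bt[1, , drop = FALSE]),
               class = "iwireNoFrequencyError")
})

test_that("axial tension inverse: closed forms and force-balance residual", {
  geom <- testGeom()
  expect_equal(axialTension(0, 2, geom), 0)
  # 45-degree geometry: T = F / sqrt(2)
  expect_equal(axialTension(0.7, halfLength(geom), geom), 0.7 / sqrt(2),
               tolerance = 1e-12)
  # frozen closed form: F = 0.5, y = 1, L0 = 5 -> 0.5 * sqrt(26) / 2
  expect_equal(axialTension(0.5, 1, geom), 1.274754878398, tolerance = 1e-10)
  # transverse balance residual across a grid: F - 2 T y / l = ... the
  # inverse halves the applied force over the two half-segments, so the
  # recomputed transverse component of one segment is F/2
  for (y in c(0.5, 1, 3, 5)) for (f in c(0.1, 0.5, 1)) {
    tens <- axialTension(f, y, geom)
    l <- sqrt(halfLength(geom)^2 + y^2)
    expect_lt(abs(2 * tens * y / l - f), 1e-12)
  }
  expect_error(axialTension(0.5, 1e-6, geom), class = "iwireGeometryError")
})

test_that("recording summaries recover truth and are deterministic", {
  geom <- testGeom()
  cal <- testCal()
  rec <- generateRecording(TissueParams(), geom, AcquisitionParams(), 0.5,
                           6, seed = 14)
  s1 <- summarizeRecording(rec@trace, cal, geom, recordingId = "a")
  s2 <- summarizeRecording(rec@trace, cal, geom, recordingId = "a")
  expect_identical(s1, s2)
  devTrue <- 0.5 * (max(rec@tipTrue) - min(rec@tipTrue))
  expect_lt(abs(s1$devForceMean / devTrue - 1), 0.05)
  expect_lt(abs(s1$beatRate - 0.76), 0.02)
  fDiaTrue <- 0.5 * (6 - max(rec@tipTrue))
  expect_lt(abs(s1$appliedForce - fDiaTrue), 0.01)
  # beat-free recording -> beat-free summary, not an error
  rec0 <- generateRecording(TissueParams(activeTension = 0), geom,
                            fastAcq(), 0.5, 6, seed = 15)
  s0 <- summarizeRecording(rec0@trace, cal, geom, recordingId = "flat")
  expect_true(s0$noBeat)
  expect_true(is.na(s0$beatRate))
})

test_that("force-tension curves: ordering, plateau annotation, alignment errors", {
  s <- expand.grid(constructId = paste0("c", 1:5),
                   targetForce = c(0.424, 0.530, 0.636, 0.742))
  set.seed(3)
  # saturating generator-like means with small construct scatter
  base <- c(0.10, 0.140, 0.148, 0.150)
  s$devForceMean <- base[match(s$targetForce,
                               sort(unique(s$targetForce)))] +
    rnorm(nrow(s), 0, 0.001)
  cur <- buildForceTensionCurve(s)
  expect_identical(cur$targetForce, sort(unique(s$targetForce)))
  expect_true(all(diff(cur$mean) > -0.01))
  expect_true(all(cur$plateau[3:4]))
  expect_false(cur$plateau[1])
  expect_equal(cur$se, cur$sd / sqrt(cur$n), tolerance = 1e-12)
  # single level -> alignment error
  expect_error(buildForceTensionCurve(s[s$targetForce == 0.424, ]),
               class = "iwireAlignmentError")
  # inconsistent level sets -> alignment error naming the construct
  bad <- s[!(s$constructId == "c1" & s$targetForce == 0.530), ]
  expect_error(buildForceTensionCurve(bad), class = "iwireAlignmentError")
})

test_that("200 seeded recordings: median developed-force and frequency errors are small", {
  geom <- testGeom()
  cal <- testCal()
  acq <- fastAcq()
  set.seed(20)
  f0s <- runif(200, 0.7, 1.5)
  devErr <- freqErr <- numeric(200)
  deltas <- c(6, 6.8, 7.5)
  for (i in 1:200) {
    p <- TissueParams(beatRate = f0s[i],
                      activeTension = runif(1, 0.08, 0.2),
                      youngsModulus = runif(1, 3.5, 7.5))
    rec <- generateRecording(p, geom, acq, 0.5, sample(deltas, 1), seed = i)
    s <- summarizeRecording(rec@trace, cal, geom, recordingId = i)
    devTrue <- 0.5 * (max(rec@tipTrue) - min(rec@tipTrue))
    devErr[i] <- abs(s$devForceMean / devTrue - 1)
    freqErr[i] <- abs(s$beatRate - f0s[i])
  }
  expect_lt(stats::median(devErr, na.rm = TRUE), 0.05)
  expect_lt(stats::median(freqErr, na.rm = TRUE), 0.02)
})
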