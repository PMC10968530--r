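# Independent brute-force oracles used across the suite.  These deliberately
# re-derive quantities by enumeration / dense grids rather than calling the
# package's own code paths.

# Unnormalized bi-exponential maximum by dense grid search, then the
# normalized waveform value at t (step 1e-4 s).
oracleTwitch <- function(t, tauRise, tauDecay) {
  grid <- seq(0, 5 * tauDecay, by = 1e-4)
  un <- function(x) exp(-x / tauDecay) - exp(-x / tauRise)
  un(t) / max(un(grid))
}

# Total elastic energy of the probe + passive linear fiber at tip position y:
# 1/2 k (Delta - y)^2 + 2 * 1/2 A E eps^2 L0   (strain energy of two halves).
# Minimized by two-stage dense grid search, final resolution 1e-6 mm (valid
# because the energy is strictly convex in y).
oracleEquilibriumEnergy <- function(kProbe, delta, E, A, L0,
                                    coarse = 1e-3, fine = 1e-6) {
  U <- function(y) {
    eps <- (sqrt(L0^2 + y^2) - L0) / L0
    0.5 * kProbe * (delta - y)^2 + A * E * eps^2 * L0
  }
  g1 <- seq(0, delta, by = coarse)
  y1 <- g1[which.min(U(g1))]
  g2 <- seq(max(0, y1 - 2 * coarse), min(delta, y1 + 2 * coarse), by = fine)
  g2[which.min(U(g2))]
}

# Exhaustive 256-level Otsu: between-class variance computed naively per
# threshold with mean() on explicit subsets.
oracleOtsu <- function(frame) {
  x <- as.vector(round(frame))
  best <- -Inf; bestT <- 0L
  for (t in 0:254) {
    lo <- x[x <= t]; hi <- x[x > t]
    if (!length(lo) || !length(hi)) next
    v <- length(lo) * length(hi) * (mean(lo) - mean(hi))^2
    if (v > best + 1e-9) { best <- v; bestT <- t }
  }
  bestT
}

# Exhaustive 8-connectivity labeling by BFS over a queue of pixels.
oracleLabel <- function(fg) {
  lab <- matrix(0L, nrow(fg), ncol(fg))
  cur <- 0L
  for (i in seq_len(nrow(fg))) for (j in seq_len(ncol(fg))) {
    if (!fg[i, j] || lab[i, j] != 0L) next
    cur <- cur + 1L
    queue <- list(c(i, j)); lab[i, j] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (di in -1:1) for (dj in -1:1) {
        r <- p[1] + di; c <- p[2] + dj
        if (r >= 1 && r <= nrow(fg) && c >= 1 && c <= ncol(fg) &&
            fg[r, c] && lab[r, c] == 0L) {
          lab[r, c] <- cur
          queue[[length(queue) + 1L]] <- c(r, c)
        }
      }
    }
  }
  lab
}

# Matrix-free normal-equations OLS (through origin and with intercept).
oracleSlopeOrigin <- function(d, f) sum(d * f) / sum(d * d)
oracleSlopeIntercept <- function(d, f) {
  n <- length(d)
  sl <- (n * sum(d * f) - sum(d) * sum(f)) / (n * sum(d * d) - sum(d)^2)
  c(slope = sl, intercept = mean(f) - sl * mean(d))
}

# Exhaustive local-extrema scan: all indices that are >= both neighbors,
# restricted to strict maxima of the smoothed-free trace.
oracleLocalMaxima <- function(f) {
  out <- integer()
  for (i in 2:(length(f) - 1))
    if (f[i] > f[i - 1] && f[i] > f[i + 1]) out <- c(out, i)
  out
}

# Exhaustive best-R^2 contiguous window (>= minLen points) for a straight
# line fit; ties: larger window, then lower start.
oracleBestWindow <- function(strain, stress, minLen = 4L) {
  n <- length(strain)
  best <- NULL
  for (i0 in 1:(n - minLen + 1)) for (i1 in (i0 + minLen - 1L):n) {
    fit <- stats::lm(stress[i0:i1] ~ strain[i0:i1])
    sst <- sum((stress[i0:i1] - mean(stress[i0:i1]))^2)
    r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else 1
    len <- i1 - i0 + 1L
    if (is.null(best) || r2 > best$r2 + 1e-12 ||
        (abs(r2 - best$r2) <= 1e-12 &&
         (len > best$len || (len == best$len && i0 < best$i0))))
      best <- list(i0 = i0, i1 = i1, r2 = r2, len = len)
  }
  best
}

# Standard test fixtures ----------------------------------------------------

testGeom <- function() ConstructGeometry()
testCal <- function(k = 0.5) probeCalibration(k)

# A small, fast acquisition within the protocol ranges.
fastAcq <- function(...) AcquisitionParams(fps = 160, duration = 12, ...)
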