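## Imaging: binarization, centroid detection, trace reconstruction.
##
## Frames are numeric matrices of 8-bit-scale intensities in [0, 255]
## (values in [0, 1], e.g. from TIFF readers, are rescaled).  The tracked
## object is the single dominant bright blob (probe tip); dark-probe movies
## are handled by `invert = TRUE`.

.as8bit <- function(frame) {
  if (max(frame) <= 1 && min(frame) >= 0) round(frame * 255) else round(frame)
}

#' Otsu threshold of an 8-bit frame
#'
#' Exhaustive search over the 256 intensity levels for the threshold
#' maximizing between-class variance; ties are broken by the lowest
#' threshold.  Returns the threshold t such that foreground = pixels with
#' intensity > t.
#'
#' @param frame numeric matrix, intensities in [0, 255] (or [0, 1], which is
#'   rescaled).
#' @return Integer threshold in 0..254.
#' @export
otsuThreshold <- function(frame) {
  x <- .as8bit(frame)
  counts <- tabulate(as.vector(x) + 1L, nbins = 256L)
  n <- sum(counts)
  lev <- 0:255
  w0 <- cumsum(counts)                     # pixels with intensity <= t
  s0 <- cumsum(counts * lev)
  stot <- s0[256]
  w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  mu0 <- s0 / w0
  mu1 <- (stot - s0) / w1
  bc <- ifelse(valid, w0 * w1 * (mu0 - mu1)^2, -Inf)
  which.max(bc) - 1L                       # lowest maximizer
}

#' Binarize a frame
#'
#' @param frame numeric matrix (8-bit scale).
#' @param method "otsu" (default, parameter-free) or "fixed".
#' @param fixedThreshold threshold for \code{method = "fixed"}; foreground
#'   is intensity > threshold.
#' @param invert if TRUE the probe is dark on a bright background and the
#'   comparison is reversed.
#' @return Logical matrix (foreground TRUE) with attribute
#'   \code{"threshold"}.
#' @export
binarizeFrame <- function(frame, method = c("otsu", "fixed"),
                          fixedThreshold = NULL, invert = FALSE) {
  method <- match.arg(method)
  if (length(frame) == 0) iwireParamStop("empty frame")
  x <- .as8bit(frame)
  thr <- if (method == "otsu") {
    if (min(x) == max(x))
      iwireStop("iwireDegenerateFrameError", "uniform frame cannot be binarized")
    otsuThreshold(frame)
  } else {
    if (is.null(fixedThreshold))
      iwireStop("iwireConfigError", "fixed method requires fixedThreshold")
    fixedThreshold
  }
  fg <- if (invert) x < thr else x > thr
  if (all(fg) || !any(fg))
    iwireStop("iwireDegenerateFrameError",
              "binarization produced an all-foreground or all-background frame")
  structure(fg, threshold = thr)
}

# Internal: label 8-connected foreground components by iterative min-label
# propagation over the foreground pixel set (converges in O(component
# diameter) sweeps; foreground is expected to be a small blob).
# Returns a list(rows, cols, label) or NULL when foreground is empty.
.labelComponents <- function(fg) {
  idx <- which(fg)
  if (!length(idx)) return(NULL)
  nr <- nrow(fg)
  r <- ((idx - 1L) %% nr) + 1L
  c <- ((idx - 1L) %/% nr) + 1L
  stride <- nr + 2L
  key <- (c + 1L) * stride + r
  off <- c(-1L, 1L, -stride, stride, -stride - 1L, -stride + 1L,
           stride - 1L, stride + 1L)
  lab <- seq_along(idx)
  neigh <- lapply(off, function(o) match(key + o, key))
  repeat {
    new <- lab
    for (m in neigh) {
      nl <- lab[m]
      ok <- !is.na(nl) & nl < new
      new[ok] <- nl[ok]
    }
    # path-compress through one extra hop to speed convergence
    new <- pmin(new, new[new])
    if (identical(new, lab)) break
    lab <- new
  }
  list(rows = r, cols = c, label = match(lab, unique(lab)), raw = lab)
}

# Internal: indices (into the pixel list) of the largest component.
# Ties by size are broken by smaller min row, then smaller min col.
.largestComponent <- function(comp) {
  sizes <- tabulate(comp$label)
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    minr <- vapply(best, function(b) min(comp$rows[comp$label == b]), 0L)
    best <- best[minr == min(minr)]
    if (length(best) > 1L) {
      minc <- vapply(best, function(b) min(comp$cols[comp$label == b]), 0L)
      best <- best[which.min(minc)]
    } else best <- best[1]
  }
  which(comp$label == best[1])
}

#' Sub-pixel centroid of the dominant foreground blob
#'
#' The centroid of the largest 8-connected foreground component.  With
#' \code{weighting = "binary"} member coordinates are averaged
#' arithmetically; with \code{"intensity"} they are weighted by the original
#' frame intensities (better sub-pixel accuracy on anti-aliased spots).
#'
#' @param binary logical matrix from \code{\link{binarizeFrame}}.
#' @param frame original intensity matrix (required for intensity
#'   weighting).
#' @param weighting "binary" or "intensity".
#' @return c(row, col), sub-pixel.
#' @export
frameCentroid <- function(binary, frame = NULL,
                          weighting = c("intensity", "binary")) {
  weighting <- match.arg(weighting)
  comp <- .labelComponents(binary)
  if (is.null(comp))
    iwireStop("iwireEmptyFrameError", "no foreground pixels")
  keep <- .largestComponent(comp)
  r <- comp$rows[keep]; c <- comp$cols[keep]
  if (weighting == "binary") return(c(mean(r), mean(c)))
  if (is.null(frame))
    iwireStop("iwireConfigError", "intensity weighting requires the frame")
  w <- .as8bit(frame)[cbind(r, c)]
  # weights = intensity excess over the binarization threshold: pixels at
  # the membership margin get ~zero weight, so the sub-pixel centroid is
  # insensitive to which marginal pixels the threshold includes
  thr <- attr(binary, "threshold")
  w <- w - if (is.null(thr)) min(w) else thr
  w[w < 0] <- 0
  if (sum(w) <= 0) return(c(mean(r), mean(c)))
  c(sum(r * w) / sum(w), sum(c * w) / sum(w))
}

#' Reconstruct a contraction trace from an image stack
#'
#' Per frame: binarize, take the largest connected component, project its
#' sub-pixel centroid on the requested axis and convert pixels to mm via
#' the stack's pixel scale and origin.  Frames whose foreground is empty
#' (at most 2% of frames) are linearly interpolated from their neighbors
#' and flagged in the trace metadata.
#'
#' @param stack an \code{ImageStack}.
#' @param axis "col" (the transverse/stage-motion axis of rendered stacks)
#'   or "row".
#' @param method,fixedThreshold,invert passed to \code{\link{binarizeFrame}}.
#' @param weighting passed to \code{\link{frameCentroid}}.
#' @return A \code{\link{CentroidTrace-class}}.
#' @export
reconstructTrace <- function(stack, axis = c("col", "row"),
                             method = "otsu", fixedThreshold = NULL,
                             invert = FALSE,
                             weighting = c("intensity", "binary")) {
  axis <- match.arg(axis)
  weighting <- match.arg(weighting)
  validObject(stack)
  n <- dim(stack@frames)[1]
  pos <- rep(NA_real_, n)
  thrs <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    fr <- stack@frames[i, , ]
    res <- tryCatch({
      bin <- binarizeFrame(fr, method = method,
                           fixedThreshold = fixedThreshold, invert = invert)
      ctr <- frameCentroid(bin, fr, weighting = weighting)
      list(ctr = ctr, thr = attr(bin, "threshold"))
    }, iwireEmptyFrameError = function(e) NULL,
       iwireDegenerateFrameError = function(e) NULL)
    if (!is.null(res)) {
      pos[i] <- if (axis == "col") res$ctr[2] else res$ctr[1]
      thrs[i] <- res$thr
    }
  }
  empty <- which(is.na(pos))
  if (length(empty) > 0.02 * n)
    iwireStop("iwireQualityError",
              sprintf("%d of %d frames (> 2%%) have empty foreground: %s",
                      length(empty), n,
                      paste(utils::head(empty, 20), collapse = ", ")),
              frames = empty)
  if (length(empty)) {
    ok <- which(!is.na(pos))
    pos[empty] <- stats::approx(ok, pos[ok], xout = empty, rule = 2)$y
  }
  tip <- stack@originMm + (pos - 1) * stack@pixelScale / 1000
  CentroidTrace(
    time = (seq_len(n) - 1) / stack@fps, tipMm = tip, fps = stack@fps,
    meta = list(threshold = stats::median(thrs, na.rm = TRUE),
                interpolatedFrames = empty, axis = axis,
                invert = invert, weighting = weighting))
}

#' Write an image stack as a multi-page 8-bit grayscale TIFF
#'
#' @param stack an \code{ImageStack}.
#' @param path output TIFF path.
#' @return Invisibly, the path.
#' @export
writeImageStack <- function(stack, path) {
  pages <- lapply(seq_len(dim(stack@frames)[1]),
                  function(i) stack@frames[i, , ] / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

#' Read a multi-page grayscale TIFF as an \code{ImageStack}
#'
#' @param path TIFF path.
#' @param fps frame rate in Hz.
#' @param pixelScale um per pixel.
#' @param originMm physical coordinate of column 1 (default 0).
#' @return An \code{\link{ImageStack-class}}.
#' @export
readImageStack <- function(path, fps, pixelScale, originMm = 0) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]   # drop extra channels
    p
  })
  d <- dim(pages[[1]])
  frames <- array(0, dim = c(length(pages), d[1], d[2]))
  for (i in seq_along(pages)) frames[i, , ] <- round(pages[[i]] * 255)
  new("ImageStack", frames = frames, fps = as.numeric(fps),
      pixelScale = as.numeric(pixelScale), originMm = as.numeric(originMm))
}
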