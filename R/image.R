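#' Segment the CSF region of interest by cardiac-band pulsatility
#'
#' Semi-automatic segmentation: for every pixel, the fraction of mean-removed
#' spectral power falling in the cardiac frequency band is computed over the
#' whole record; a 4-connected region is grown from a user-supplied seed
#' pixel over pixels whose band-energy fraction exceeds the threshold.
#' Deterministic given its inputs, and invariant to constant velocity
#' offsets (the per-pixel mean is removed before the FFT).
#'
#' @param series a [VelocityMapSeries-class]; the record must span at least
#'   5 cardiac periods at the lower band edge.
#' @param seedPixel integer(2), (row, col) of a pixel inside the CSF lumen.
#' @param cardiacBand numeric(2), Hz; default 0.8-2.0 Hz (48-120 bpm).
#' @param threshold minimum band-energy fraction for a pixel to be included.
#' @return a [SegmentationMask-class].
#' @seealso [selectStationaryRegion()], [extractFlow()]
#' @export
segmentCsfRoi <- function(series, seedPixel, cardiacBand = c(0.8, 2.0),
                          threshold = 0.3) {
  stopifnot(is(series, "VelocityMapSeries"))
  d <- dim(series@frames); H <- d[1]; W <- d[2]; Tn <- d[3]
  fs <- 1 / series@frameInterval
  if (Tn * series@frameInterval < 5 / cardiacBand[1])
    stop("record too short: need at least 5 cardiac periods at the lower band edge")
  seedPixel <- as.integer(seedPixel)
  if (seedPixel[1] < 1 || seedPixel[1] > H || seedPixel[2] < 1 ||
      seedPixel[2] > W)
    stop("seed pixel outside the image")
  mat <- matrix(series@frames, nrow = H * W, ncol = Tn)
  frac <- matrix(.bandEnergyFraction(mat, fs, cardiacBand), H, W)
  above <- frac > threshold
  if (!above[seedPixel[1], seedPixel[2]])
    stop("no pulsatile region at seed: seed pixel band-energy fraction ",
         sprintf("%.3f <= threshold %.3f", frac[seedPixel[1], seedPixel[2]],
                 threshold))
  ## 4-connected region growing (breadth-first)
  mask <- matrix(FALSE, H, W)
  queue <- matrix(seedPixel, ncol = 2)
  mask[seedPixel[1], seedPixel[2]] <- TRUE
  off <- rbind(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  while (nrow(queue) > 0) {
    p <- queue[1, , drop = TRUE]
    queue <- queue[-1, , drop = FALSE]
    for (k in 1:4) {
      r <- p[1] + off[k, 1]; cl <- p[2] + off[k, 2]
      if (r >= 1 && r <= H && cl >= 1 && cl <= W &&
          !mask[r, cl] && above[r, cl]) {
        mask[r, cl] <- TRUE
        queue <- rbind(queue, c(r, cl))
      }
    }
  }
  new("SegmentationMask", mask = mask, pixelSpacing = series@pixelSpacing)
}

## Euclidean distance (pixels) from every pixel to the nearest mask pixel
.distanceToMask <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  idx <- which(mask, arr.ind = TRUE)
  r <- matrix(seq_len(H), H, W)
  cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  dmin <- matrix(Inf, H, W)
  for (k in seq_len(nrow(idx))) {
    dk <- sqrt((r - idx[k, 1])^2 + (cc - idx[k, 2])^2)
    dmin <- pmin(dmin, dk)
  }
  dmin
}

#' Select a stationary-tissue reference region around the CSF mask
#'
#' A ring of pixels at Euclidean distance in `[2, 2 + ringWidth]` pixels from
#' the mask, excluding pixels whose cardiac-band energy fraction exceeds the
#' segmentation threshold (i.e. excluding other pulsatile structures). The
#' spatiotemporal mean velocity of the ring is the new zero-velocity
#' reference.
#'
#' @param series a [VelocityMapSeries-class].
#' @param mask the CSF [SegmentationMask-class].
#' @param ringWidth ring thickness in pixels (default 3).
#' @param cardiacBand,threshold as in [segmentCsfRoi()].
#' @return a [StationaryRegion-class].
#' @export
selectStationaryRegion <- function(series, mask, ringWidth = 3,
                                   cardiacBand = c(0.8, 2.0),
                                   threshold = 0.3) {
  stopifnot(is(series, "VelocityMapSeries"), is(mask, "SegmentationMask"))
  if (ringWidth <= 0)
    stop("empty stationary ring: ringWidth must be > 0; widen the ring")
  d <- dim(series@frames); H <- d[1]; W <- d[2]; Tn <- d[3]
  dmin <- .distanceToMask(mask@mask)
  ring <- dmin >= 2 & dmin <= 2 + ringWidth
  if (any(ring)) {
    fs <- 1 / series@frameInterval
    mat <- matrix(series@frames, nrow = H * W, ncol = Tn)
    frac <- matrix(.bandEnergyFraction(mat, fs, cardiacBand), H, W)
    ring <- ring & frac <= threshold
  }
  if (!any(ring))
    stop("empty stationary ring after exclusions; widen ringWidth")
  ref <- mean(matrix(series@frames, nrow = H * W)[which(ring), ])
  new("StationaryRegion", region = ring, referenceVelocity = ref)
}

#' Background-field (eddy current) correction
#'
#' Shifts every pixel velocity by minus the stationary-tissue reference
#' velocity, so that quiescent tissue averages to zero.
#'
#' @param series a [VelocityMapSeries-class].
#' @param stationary a [StationaryRegion-class].
#' @return the corrected [VelocityMapSeries-class].
#' @export
correctBackground <- function(series, stationary) {
  stopifnot(is(series, "VelocityMapSeries"), is(stationary, "StationaryRegion"))
  velocityMapSeries(series@frames - stationary@referenceVelocity,
                    series@pixelSpacing, series@frameInterval, series@venc)
}

#' Temporal de-aliasing of wrapped velocities
#'
#' Unwraps each pixel's velocity time course: frame-to-frame jumps larger
#' than the VENC are corrected by the nearest multiple of 2 VENC (the first
#' frame is assumed unwrapped). Pixels whose corrected course still contains
#' a jump above the VENC, or leaves the `[-3 VENC, 3 VENC]` single-wrap
#' range, are reported as unresolvable and left untouched.
#'
#' @param series a [VelocityMapSeries-class].
#' @param venc velocity encoding limit (cm/s); defaults to the series VENC.
#' @return a [VelocityMapSeries-class]; unresolvable pixels (if any) are
#'   attached as an integer matrix of (row, col) in `attr(, "flaggedPixels")`
#'   and reported via a warning.
#' @export
dealias <- function(series, venc = NULL) {
  stopifnot(is(series, "VelocityMapSeries"))
  v <- if (is.null(venc)) series@venc else venc
  d <- dim(series@frames); H <- d[1]; W <- d[2]; Tn <- d[3]
  mat <- matrix(series@frames, nrow = H * W, ncol = Tn)
  jumps <- mat[, -1L, drop = FALSE] - mat[, -Tn, drop = FALSE]
  k <- round(jumps / (2 * v))
  k[abs(jumps) <= v] <- 0
  corr <- mat
  corr[, -1L] <- mat[, -1L, drop = FALSE] -
    2 * v * t(apply(k, 1L, cumsum))
  ## temporal unwrapping leaves a per-pixel global 2*VENC ambiguity (the
  ## first frame may itself be wrapped); resolve it by minimizing the mean
  ## speed, since CSF and stationary-tissue velocities average near zero
  k0 <- round(rowMeans(corr) / (2 * v))
  corr <- corr - 2 * v * k0
  newJumps <- corr[, -1L, drop = FALSE] - corr[, -Tn, drop = FALSE]
  bad <- apply(abs(newJumps) > v, 1L, any) | apply(abs(corr) >= 3 * v, 1L, any)
  flagged <- NULL
  if (any(bad)) {
    corr[bad, ] <- mat[bad, ]
    flagged <- which(matrix(bad, H, W), arr.ind = TRUE)
    warning(sum(bad), " pixel(s) with unresolvable velocity wraps left uncorrected")
  }
  out <- velocityMapSeries(array(corr, dim = d), series@pixelSpacing,
                           series@frameInterval, series@venc)
  attr(out, "flaggedPixels") <- flagged
  out
}

#' Integrate masked velocities into a flow-rate signal
#'
#' \deqn{Q(t) = \sum_{mask} v \cdot s^2 \cdot 10 \cdot 60/1000 \;
#'   \mathrm{ml/min}}
#' with `v` in cm/s and the pixel spacing `s` in mm. Linear in the pixel
#' velocities.
#'
#' @param series a corrected, de-aliased [VelocityMapSeries-class].
#' @param mask a [SegmentationMask-class].
#' @return a [FlowSeries-class]; time stamps are frame index times the frame
#'   interval.
#' @examples
#' # 2 pixels of 4 mm^2 at 1 cm/s -> 4.8 ml/min
#' fr <- array(1, dim = c(1, 2, 40))
#' s <- velocityMapSeries(fr, pixelSpacing = 2, frameInterval = 0.1, venc = 5)
#' m <- new("SegmentationMask", mask = matrix(TRUE, 1, 2), pixelSpacing = 2)
#' flowRate(extractFlow(s, m))[1]
#' @export
extractFlow <- function(series, mask) {
  stopifnot(is(series, "VelocityMapSeries"), is(mask, "SegmentationMask"))
  d <- dim(series@frames)
  mat <- matrix(series@frames, nrow = d[1] * d[2], ncol = d[3])
  vsum <- colSums(mat[which(mask@mask), , drop = FALSE])
  q <- vsum * series@pixelSpacing^2 * 10 * 60 / 1000
  flowSeries((seq_len(d[3]) - 1L) * series@frameInterval, q)
}
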