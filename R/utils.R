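#' Construct a FlowSeries
#'
#' @param time numeric, uniform sample times in seconds.
#' @param flow numeric, flow in ml/min (positive = caudocranial).
#' @return a [FlowSeries-class] object.
#' @examples
#' fs <- flowSeries(seq(0, 1, by = 0.1), sin(seq(0, 1, by = 0.1)))
#' @export
flowSeries <- function(time, flow)
  new("FlowSeries", time = as.numeric(time), flow = as.numeric(flow))

#' Construct a BreathingSignal
#'
#' @param time numeric, uniform sample times in seconds.
#' @param amplitude numeric, chest-belt amplitude (a.u.).
#' @return a [BreathingSignal-class] object.
#' @export
breathingSignal <- function(time, amplitude)
  new("BreathingSignal", time = as.numeric(time),
      amplitude = as.numeric(amplitude))

#' Construct a VelocityMapSeries
#'
#' @param frames numeric H x W x T array, cm/s.
#' @param pixelSpacing isotropic in-plane spacing, mm.
#' @param frameInterval frame interval, seconds.
#' @param venc velocity encoding limit, cm/s.
#' @return a [VelocityMapSeries-class] object.
#' @export
velocityMapSeries <- function(frames, pixelSpacing, frameInterval, venc)
  new("VelocityMapSeries", frames = frames,
      pixelSpacing = as.numeric(pixelSpacing),
      frameInterval = as.numeric(frameInterval), venc = as.numeric(venc))

## ---- unit conversions (centralized; ml/min, mm^3, cm/s, s) ----

## ml/min over an area in mm^2 -> mean velocity in cm/s
.flowToVelocity <- function(q_ml_min, area_mm2)
  q_ml_min * (1000 / 60) / (area_mm2 * 10)

## cm/s over an area in mm^2 -> ml/min
.velocityToFlow <- function(v_cm_s, area_mm2)
  v_cm_s * area_mm2 * 10 * 60 / 1000

## integral of Q (ml/min) over dt seconds -> mm^3
.flowTimeToVolume <- function(q_dt_ml_min_s) q_dt_ml_min_s * 1000 / 60

## ---- seeded RNG scope ----

.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

## ---- signal helpers ----

## zero-phase Butterworth low pass; near-Nyquist cutoffs degrade to identity
.lowpass <- function(x, fs, cutoffHz, order = 2L) {
  w <- cutoffHz / (fs / 2)
  if (w >= 0.99) return(x)
  bf <- signal::butter(order, w, type = "low")
  as.numeric(signal::filtfilt(bf, x))
}

## indices of strict local minima of y (interior points)
.localMinima <- function(y) {
  n <- length(y)
  if (n < 3L) return(integer(0))
  i <- 2:(n - 1)
  i[y[i] < y[i - 1] & y[i] <= y[i + 1]]
}

## prune extrema closer than minGap, keeping the deeper (for minima) one
.pruneClose <- function(idx, depth, minGap) {
  repeat {
    if (length(idx) < 2L) return(idx)
    gaps <- diff(idx)
    j <- which(gaps < minGap)
    if (length(j) == 0L) return(idx)
    j <- j[1L]
    drop <- if (depth[j] <= depth[j + 1L]) j + 1L else j
    idx <- idx[-drop]
    depth <- depth[-drop]
  }
}

## 3-point parabolic sub-sample refinement of an extremum at sample i
.parabolicRefine <- function(y, i, t, dt) {
  if (i <= 1L || i >= length(y)) return(t[i])
  a <- y[i - 1L]; b <- y[i]; cc <- y[i + 1L]
  den <- a - 2 * b + cc
  if (abs(den) < .Machine$double.eps * max(abs(c(a, b, cc)), 1)) return(t[i])
  delta <- 0.5 * (a - cc) / den
  delta <- max(-0.5, min(0.5, delta))
  t[i] + delta * dt
}

## per-pixel fraction of mean-removed spectral power inside a frequency band
## mat: nPix x T matrix of time courses; returns nPix vector in [0, 1]
.bandEnergyFraction <- function(mat, fs, band) {
  T <- ncol(mat)
  xc <- mat - rowMeans(mat)
  sp <- Mod(stats::mvfft(t(xc)))^2          # T x nPix
  nyq <- floor(T / 2)
  freqs <- (seq_len(nyq)) * fs / T          # positive frequencies, bins 2..nyq+1
  pos <- sp[seq_len(nyq) + 1L, , drop = FALSE]
  inBand <- freqs >= band[1] & freqs <= band[2]
  tot <- colSums(pos)
  frac <- colSums(pos[inBand, , drop = FALSE]) / tot
  frac[tot <= 0] <- 0
  frac
}

#' Disc-shaped region-of-interest mask
#'
#' Convenience constructor for synthetic lumen shapes.
#'
#' @param dim integer(2), image height and width in pixels.
#' @param center numeric(2), disc center (row, col) in pixel coordinates.
#' @param radius numeric(1), radius in pixels.
#' @return logical `dim[1] x dim[2]` matrix.
#' @examples
#' m <- discMask(c(16, 16), c(8, 8), 3)
#' sum(m)
#' @export
discMask <- function(dim, center, radius) {
  r <- matrix(seq_len(dim[1]), dim[1], dim[2])
  cc <- matrix(seq_len(dim[2]), dim[1], dim[2], byrow = TRUE)
  (r - center[1])^2 + (cc - center[2])^2 <= radius^2
}

#' Acquisition arithmetic helpers
#'
#' `kSpaceSegments()` gives the number of k-space segments of a segmented-EPI
#' real-time acquisition (acquisition matrix / parallel-imaging factor /
#' EPI factor). `pointsPerCycle()` gives the number of frames falling within
#' one cardiac cycle at a given heart rate and frame interval.
#'
#' @param acquisitionMatrix acquired matrix lines.
#' @param senseFactor parallel-imaging (sensitivity encoding) factor.
#' @param epiFactor echoes collected per excitation.
#' @return `kSpaceSegments()`: number of segments; `pointsPerCycle()`: integer
#'   frames per cardiac cycle.
#' @examples
#' kSpaceSegments(70, 2.5, 7)
#' pointsPerCycle(60, 0.096)
#' @export
kSpaceSegments <- function(acquisitionMatrix, senseFactor, epiFactor)
  acquisitionMatrix / senseFactor / epiFactor

#' @rdname kSpaceSegments
#' @param bpm heart rate in beats per minute.
#' @param frameIntervalS frame interval in seconds.
#' @export
pointsPerCycle <- function(bpm, frameIntervalS)
  floor((60 / bpm) / frameIntervalS)
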