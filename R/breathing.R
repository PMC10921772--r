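#' Delineate inspiratory and expiratory phases from a chest-belt signal
#'
#' On a smoothed copy of the belt trace, troughs and peaks are located (and
#' refined to sub-sample precision); inspiration (IN) runs from a trough to
#' the next peak (ascending belt, thoracic expansion), expiration (EX) from a
#' peak to the next trough. Only complete trough-to-trough breathing cycles
#' are retained; incomplete edge cycles are excluded.
#'
#' @param belt a [BreathingSignal-class] containing at least 2 complete
#'   breathing cycles.
#' @param smoothHz low-pass cutoff for the smoothing filter (Hz).
#' @param maxPeriodVariation maximum tolerated relative deviation of any
#'   breathing period from the mean (default 0.5); beyond it the record is
#'   rejected as irregular breathing.
#' @return a [BreathingPhases-class].
#' @export
delineatePhases <- function(belt, smoothHz = 1, maxPeriodVariation = 0.5) {
  stopifnot(is(belt, "BreathingSignal"))
  y <- belt@amplitude; t <- belt@time
  dt <- frameInterval(belt); fs <- 1 / dt
  if (diff(range(y)) <= .Machine$double.eps * max(abs(y), 1))
    stop("fewer than 2 complete breathing cycles: belt signal is constant")
  ys <- .lowpass(y, fs, smoothHz)
  troughIdx <- .localMinima(ys)
  peakIdx <- .localMinima(-ys)
  if (length(troughIdx) >= 2L) {
    med <- stats::median(diff(t[troughIdx]))
    gap <- max(1, round(0.5 * med / dt))
    troughIdx <- .pruneClose(troughIdx, ys[troughIdx], gap)
    peakIdx <- .pruneClose(peakIdx, -ys[peakIdx], gap)
  }
  if (length(troughIdx) < 2L)
    stop("fewer than 2 complete breathing cycles in the record")
  troughs <- vapply(troughIdx, function(i) .parabolicRefine(ys, i, t, dt),
                    numeric(1))
  peaks <- vapply(peakIdx, function(i) .parabolicRefine(-ys, i, t, dt),
                  numeric(1))
  periods <- diff(troughs)
  mp <- mean(periods)
  if (length(periods) < 1L || any(abs(periods - mp) / mp > maxPeriodVariation))
    stop("irregular breathing pattern: period variability exceeds ",
         100 * maxPeriodVariation, "%")
  ## build alternating IN/EX intervals inside the complete-cycle window
  peaks <- peaks[peaks > troughs[1] & peaks < troughs[length(troughs)]]
  bnds <- sort(c(troughs, peaks))
  starts <- bnds[-length(bnds)]
  ends <- bnds[-1L]
  isIn <- starts %in% troughs
  intervals <- data.frame(start = starts, end = ends,
                          phase = ifelse(isIn, "IN", "EX"))
  new("BreathingPhases", intervals = intervals, boundaries = troughs,
      meanPeriod = mp, nCycles = as.integer(length(periods)))
}

#' Assign cardiac cycles to breathing phases under a phase shift
#'
#' The IN/EX windows are translated by the shift `phi`: a cardiac cycle
#' belongs to inspiration at shift `phi` when its midpoint falls inside a
#' shifted inspiratory interval, i.e. when `midpoint - phi` lies in the
#' unshifted interval (half-open `[start, end)`: a midpoint exactly on a
#' boundary belongs to the interval starting there). Cycles whose shifted
#' midpoint leaves the window of complete breathing cycles are dropped for
#' that shift.
#'
#' @param cycles a [CardiacCycleSet-class].
#' @param phases a [BreathingPhases-class].
#' @param phi phase shift in seconds.
#' @return list with integer index vectors `insp` and `exp`.
#' @export
assignCycles <- function(cycles, phases, phi = 0) {
  stopifnot(is(cycles, "CardiacCycleSet"), is(phases, "BreathingPhases"))
  m <- cycles@midpoint - phi
  iv <- phases@intervals
  lo <- phases@boundaries[1]
  hi <- phases@boundaries[length(phases@boundaries)]
  inside <- m >= lo & m < hi
  k <- findInterval(m, iv$start)            # half-open [start, end)
  lab <- rep(NA_character_, length(m))
  ok <- inside & k >= 1 & k <= nrow(iv)
  lab[ok] <- iv$phase[k[ok]]
  list(insp = which(!is.na(lab) & lab == "IN"),
       exp = which(!is.na(lab) & lab == "EX"))
}

#' Reconstruct inspiratory and expiratory Qt curves
#'
#' @param cycles a [CardiacCycleSet-class].
#' @param assignment list with `insp` and `exp` indices, from
#'   [assignCycles()].
#' @return list of two [ReconstructedQt-class] objects, `insp` and `exp`.
#' @export
reconstructPhaseQt <- function(cycles, assignment) {
  if (length(assignment$insp) < 1L || length(assignment$exp) < 1L)
    stop("both breathing phases need at least one cardiac cycle")
  list(insp = averageCycles(cycles, assignment$insp),
       exp = averageCycles(cycles, assignment$exp))
}

#' Inspiration-minus-expiration parameter differences
#'
#' @param qtIn,qtEx [ReconstructedQt-class] for inspiration and expiration.
#' @param area segment area (mm^2) or `NA`.
#' @return named numeric: `Qnet` (ml/min), `Amplitude` (ml/min), `SV`
#'   (mm^3), `Tc` (s), each inspiration minus expiration.
#' @export
computeDelta <- function(qtIn, qtEx, area = NA_real_) {
  pin <- parameterValues(computeParameters(qtIn, area))
  pex <- parameterValues(computeParameters(qtEx, area))
  p <- c("Qnet", "Amplitude", "SV", "Tc")
  stats::setNames(pin[p] - pex[p], p)
}

## truncate a periodic 32-point curve to its first K harmonics (FFT)
.harmonicSmooth <- function(v, K) {
  if (K <= 0L || 2 * K + 1 >= length(v)) return(v)
  n <- length(v)
  sp <- stats::fft(v)
  keep <- c(seq_len(K + 1L), seq(n - K + 1L, n))
  sp[-keep] <- 0
  Re(stats::fft(sp, inverse = TRUE)) / n
}

.smoothQt <- function(qt, K) {
  if (K <= 0L) return(qt)
  new("ReconstructedQt", values = .harmonicSmooth(qt@values, K),
      tc = qt@tc, nCycles = qt@nCycles)
}

## wrap a phase percentage into (-50, 50]
.wrapPhiPercent <- function(x) {
  w <- ((x + 50) %% 100) - 50
  ifelse(w == -50, 50, w)
}

#' Summarize a delta curve into intensity and phase of the breathing effect
#'
#' Given a \eqn{\Delta p(\Phi)} curve, computes the intensity (half the
#' peak-to-peak excursion, signed by the curve value at the selected
#' extreme), and the phase \eqn{\Phi_p}: the grid point of whichever extreme
#' has the smaller `|phi%|` after wrapping into `(-50, 50]` of the breathing
#' cycle (ties broken toward the maximum). A flat curve yields intensity 0,
#' phase 0 and `flat = TRUE`.
#'
#' Since the delta curve of a breathing-modulated record oscillates at the
#' breathing frequency, the extremes are by default read off a least-squares
#' harmonic fit (fundamental plus second harmonic of the breathing period)
#' to the curve, which suppresses the upward bias that picking raw extremes
#' of a noisy curve would introduce; a curve that is exactly
#' breathing-periodic (such as the worked-example cosine) is reproduced by
#' the fit, so the summary is unchanged for noiseless curves. Set
#' `harmonics = 0` to use the raw extremes.
#'
#' @param phiGrid numeric, shifts in seconds.
#' @param curve numeric, delta values on the grid.
#' @param meanPeriod mean breathing period, seconds.
#' @param harmonics integer, number of breathing harmonics in the smoothing
#'   fit (0 = no fit).
#' @return list with `delta` (signed intensity), `phiS`, `phiPercent`,
#'   `phiDeg`, `flat`.
#' @examples
#' g <- seq(-3, 3, by = 0.1)
#' deltaCurveSummary(g, 3.5 + 140.5 * cos(2 * pi * (g + 0.3) / 3.4), 3.4)
#' @export
deltaCurveSummary <- function(phiGrid, curve, meanPeriod, harmonics = 2L) {
  stopifnot(length(phiGrid) == length(curve))
  if (harmonics > 0L) {
    X <- do.call(cbind, c(list(rep(1, length(phiGrid))),
      lapply(seq_len(harmonics), function(k)
        cbind(cos(2 * pi * k * phiGrid / meanPeriod),
              sin(2 * pi * k * phiGrid / meanPeriod)))))
    curve <- as.numeric(X %*% stats::lm.fit(X, curve)$coefficients)
  }
  hi <- max(curve); lo <- min(curve)
  intensity <- (hi - lo) / 2
  scale <- max(abs(c(hi, lo)), 1e-12)
  if (intensity <= 1e-9 * scale)
    return(list(delta = 0, phiS = 0, phiPercent = 0, phiDeg = 0, flat = TRUE))
  pctOf <- function(idx) .wrapPhiPercent(100 * phiGrid[idx] / meanPeriod)
  ## among grid points attaining each extreme, take the smallest |phi%|
  tol <- 1e-9 * scale
  iMax <- which(curve >= hi - tol)
  iMax <- iMax[which.min(abs(pctOf(iMax)))]
  iMin <- which(curve <= lo + tol)
  iMin <- iMin[which.min(abs(pctOf(iMin)))]
  pMax <- pctOf(iMax); pMin <- pctOf(iMin)
  useMax <- abs(pMax) <= abs(pMin)          # tie -> positive (max) extreme
  i <- if (useMax) iMax else iMin
  pct <- if (useMax) pMax else pMin
  list(delta = if (useMax) intensity else -intensity,
       phiS = phiGrid[i], phiPercent = pct, phiDeg = 3.6 * pct, flat = FALSE)
}

#' Sweep the breathing phase shift and quantify breathing effects
#'
#' For every shift on the grid the cardiac cycles are re-assigned to
#' inspiration/expiration, the two phase Qt curves are reconstructed, and
#' the parameter differences \eqn{\Delta p(\Phi)} are computed for p in
#' Qnet, Amplitude, SV, Tc. Each curve is then summarized
#' (see [deltaCurveSummary()]) into the intensity \eqn{\Delta p}, its
#' normalized form \eqn{\Delta p\%} (divided by the record-mean parameter;
#' \eqn{\Delta Q_{net}} is divided by the mean Amplitude since net flow
#' approaches zero) and the phase \eqn{\Phi_p} (s, % and degrees of the
#' breathing cycle). Record means are computed once, from all retained
#' cycles at zero shift.
#'
#' Shifts at which either phase set is empty are recorded as missing and
#' filled by linear interpolation before extreme-finding; more than 20%
#' missing aborts.
#'
#' The per-shift inspiratory and expiratory averaged curves are smoothed by
#' a `qtHarmonics`-harmonic Fourier fit before the parameters are extracted:
#' a physiological beat waveform is captured by a few cardiac harmonics, so
#' the fit passes the waveform while suppressing sample noise that would
#' otherwise bias the amplitude (max minus min) of every noisy curve
#' upwards. Set `qtHarmonics = 0` to disable. The record-mean normalization
#' values use the same smoothing so that multiplicative effects cancel in
#' the ratios.
#'
#' @param cycles a [CardiacCycleSet-class].
#' @param phases a [BreathingPhases-class].
#' @param area segment area in mm^2 (or `NA` to skip velocities).
#' @param phiRange numeric(2), sweep range in seconds.
#' @param phiStep grid step in seconds.
#' @param qtHarmonics cardiac harmonics kept when smoothing the per-phase
#'   averaged curves (0 = raw curves).
#' @param curveHarmonics breathing harmonics for the delta-curve fit passed
#'   to [deltaCurveSummary()].
#' @return a [PhaseSweepResult-class].
#' @export
sweepPhase <- function(cycles, phases, area = NA_real_,
                       phiRange = c(-3, 3), phiStep = 0.1,
                       qtHarmonics = 6L, curveHarmonics = 2L) {
  stopifnot(is(cycles, "CardiacCycleSet"), is(phases, "BreathingPhases"))
  if (phases@nCycles < 2L)
    stop("need at least 2 complete breathing cycles")
  grid <- seq(phiRange[1], phiRange[2], by = phiStep)
  pnames <- c("Qnet", "Amplitude", "SV", "Tc")
  curves <- matrix(NA_real_, length(grid), 4,
                   dimnames = list(NULL, pnames))
  nInsp <- nExp <- integer(length(grid))
  for (g in seq_along(grid)) {
    a <- assignCycles(cycles, phases, grid[g])
    nInsp[g] <- length(a$insp); nExp[g] <- length(a$exp)
    if (nInsp[g] < 1L || nExp[g] < 1L) next
    qt <- reconstructPhaseQt(cycles, a)
    curves[g, ] <- computeDelta(.smoothQt(qt$insp, qtHarmonics),
                                .smoothQt(qt$exp, qtHarmonics), area)
  }
  miss <- is.na(curves[, 1])
  if (mean(miss) > 0.2)
    stop("more than 20% of phase-shift grid points have an empty phase set")
  if (any(miss)) {
    ok <- which(!miss)
    for (j in 1:4)
      curves[miss, j] <- stats::approx(grid[ok], curves[ok, j], grid[miss],
                                       rule = 2)$y
  }
  ## record-mean parameter values (all retained cycles, zero shift)
  pAll <- parameterValues(computeParameters(
    .smoothQt(averageCycles(cycles), qtHarmonics), area))
  meanValues <- pAll[pnames]
  denom <- meanValues
  denom["Qnet"] <- meanValues["Amplitude"]   # Qnet normalized by Amplitude
  rows <- lapply(pnames, function(p) {
    s <- deltaCurveSummary(grid, curves[, p], phases@meanPeriod,
                           harmonics = curveHarmonics)
    data.frame(parameter = p, delta = s$delta,
               deltaPercent = 100 * s$delta / denom[[p]],
               phiS = s$phiS, phiPercent = s$phiPercent, phiDeg = s$phiDeg,
               flat = s$flat)
  })
  summary <- do.call(rbind, rows)
  rownames(summary) <- pnames
  new("PhaseSweepResult", phiGrid = grid, curves = curves,
      nInsp = nInsp, nExp = nExp, meanPeriod = phases@meanPeriod,
      meanValues = meanValues, summary = summary)
}
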