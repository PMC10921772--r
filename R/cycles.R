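## dominant cardiac frequency (Hz) of a mean-removed signal within a band
.dominantFrequency <- function(y, fs, band) {
  n <- length(y)
  sp <- Mod(stats::fft(y - mean(y)))^2
  nyq <- floor(n / 2)
  freqs <- seq_len(nyq) * fs / n
  sel <- which(freqs >= band[1] & freqs <= band[2])
  if (length(sel) == 0L) return(NA_real_)
  pk <- sp[sel + 1L]
  if (max(pk) <= 0) return(NA_real_)
  freqs[sel[which.max(pk)]]
}

#' Detect cardiac-cycle minima in a continuous flow signal
#'
#' The cardiac fundamental frequency is first estimated from the spectral
#' peak of the mean-removed signal inside the expected heart-rate band. The
#' signal is then low-pass filtered (zero-phase, cutoff capped at three
#' times the fundamental so that cardiac harmonics pass but broadband noise
#' does not), its local minima are pruned to a minimum spacing of 0.6
#' cardiac periods (keeping the deeper of two close minima), and each
#' minimum is refined to sub-sample precision by a 3-point parabolic vertex
#' fit on the filtered samples. The refined times are the min-to-min
#' segmentation points of the record.
#'
#' @param flow a [FlowSeries-class] covering at least ~5 cardiac periods.
#' @param expectedBpmRange numeric(2), plausible heart-rate range (bpm);
#'   bounds the spectral search and sanity-checks the detected rhythm.
#' @param lowpassHz upper bound on the detection-filter cutoff (Hz).
#' @return numeric vector of minimum times in seconds.
#' @seealso [splitCycles()]
#' @export
detectCycleMinima <- function(flow, expectedBpmRange = c(40, 120),
                              lowpassHz = 5) {
  stopifnot(is(flow, "FlowSeries"))
  y <- flow@flow; t <- flow@time
  dt <- frameInterval(flow); fs <- 1 / dt
  if (diff(range(y)) <= .Machine$double.eps * max(abs(y), 1))
    stop("too short / no cardiac structure: signal is constant")
  band <- expectedBpmRange / 60
  f0 <- .dominantFrequency(y, fs, band)
  if (is.na(f0))
    stop("too short / no cardiac structure: no spectral peak in the cardiac band")
  period0 <- 1 / f0
  if (diff(range(t)) < 5 * period0)
    stop("too short / no cardiac structure: record spans fewer than 5 cardiac periods")
  cutoff <- min(lowpassHz, 3 * f0, 0.45 * fs)

  onePass <- function(z) {
    zs <- .lowpass(z, fs, cutoff)
    idx <- .localMinima(zs)
    idx <- .pruneClose(idx, zs[idx], minGap = max(1, round(0.6 * period0 / dt)))
    if (length(idx) < 3L) return(NULL)
    half <- max(1L, round(0.25 * stats::median(diff(t[idx])) / dt))
    vapply(idx, function(i) {
      lo <- max(2L, i - half); hi <- min(length(zs) - 1L, i + half)
      j <- lo - 1L + which.min(zs[lo:hi])
      .parabolicRefine(zs, j, t, dt)
    }, numeric(1))
  }

  ## pass 1 on the raw signal; beat-to-beat offset/amplitude variation makes
  ## the signal step slightly at each trough, which biases the smoothed
  ## minimum towards the deeper neighbour. Later passes therefore
  ## standardize each provisional cycle (subtract its mean, divide by its
  ## range) and re-detect on the step-free signal.
  ## piecewise standardization between provisional minima; the partial edge
  ## segments borrow the statistics of their complete neighbours
  standardize <- function(mins) {
    ci <- findInterval(t, mins) + 1L            # 1..length(mins)+1
    nseg <- length(mins) + 1L
    if (nseg >= 3L) ci <- pmin(pmax(ci, 2L), nseg - 1L)
    ## per-segment offset as the integral mean (trapezoid with interpolated
    ## boundary values): the plain sample mean fluctuates strongly with the
    ## fractional sample coverage of each beat and would inject artificial
    ## offset steps into the standardized signal
    mu <- .segmentIntegralMeans(t, y, mins)[ci]
    rg <- tapply(y, ci, function(v) diff(range(v)))[as.character(ci)]
    rg[!is.finite(rg) | rg <= 0] <- stats::median(rg[is.finite(rg) & rg > 0])
    (y - mu) / rg
  }

  mins <- onePass(y)
  if (is.null(mins))
    stop("too short / no cardiac structure: fewer than 3 minima found")
  for (pass in 1:2) {
    nm <- onePass(standardize(mins))
    if (is.null(nm)) break
    mins <- nm
  }
  if (length(mins) < 3L)
    stop("too short / no cardiac structure: fewer than 3 minima found")

  ## final pass: matched-filter refinement on the standardized (step-free)
  ## signal. Each boundary is re-aligned by least squares against the
  ## record's own average beat waveform (scale and offset free), which uses
  ## the whole local waveform rather than only the trough curvature and is
  ## therefore robust to noise and to trough asymmetry.
  mins <- .templateRefine(t, standardize(mins), mins, dt)

  med <- stats::median(diff(mins))
  bpm <- 60 / med
  if (bpm < expectedBpmRange[1] || bpm > expectedBpmRange[2])
    warning(sprintf("detected rhythm %.1f bpm outside expected range [%g, %g]",
                    bpm, expectedBpmRange[1], expectedBpmRange[2]))
  mins
}

## integral mean of y over each segment delimited by the boundary times
## (trapezoid rule with linearly interpolated values at the boundaries);
## segment 1 is [t_1, mins_1], segment k+1 is [mins_k, mins_{k+1}], ...
.segmentIntegralMeans <- function(t, y, mins) {
  edges <- c(t[1L], mins, t[length(t)])
  ye <- stats::approx(t, y, xout = edges, rule = 2)$y
  nseg <- length(edges) - 1L
  out <- numeric(nseg)
  for (k in seq_len(nseg)) {
    a <- edges[k]; b <- edges[k + 1L]
    sel <- which(t > a & t < b)
    xs <- c(a, t[sel], b)
    vs <- c(ye[k], y[sel], ye[k + 1L])
    out[k] <- sum(diff(xs) * (vs[-1L] + vs[-length(vs)]) / 2) / (b - a)
  }
  out
}

## matched-filter boundary refinement: build the mean standardized beat
## waveform on a fine phase grid, then re-align every boundary to it by
## least squares over a local window (per-boundary shift; scale and offset
## solved in closed form at each candidate shift)
.templateRefine <- function(t, y, mins, dt, nPhase = 64L) {
  nb <- length(mins)
  if (nb < 3L) return(mins)
  period <- stats::median(diff(mins))
  ## standardized template from the provisional segmentation
  ph <- (seq_len(nPhase) - 1L) / nPhase
  rows <- vapply(seq_len(nb - 1L), function(i) {
    s <- mins[i]; e <- mins[i + 1L]
    sel <- which(t >= s & t < e)
    if (length(sel) < 4L) return(rep(NA_real_, nPhase))
    v <- y[sel]
    stats::approx((t[sel] - s) / (e - s), (v - mean(v)) / diff(range(v)),
                  xout = ph, rule = 2)$y
  }, numeric(nPhase))
  tpl <- rowMeans(rows, na.rm = TRUE)
  tplFun <- function(phase) {
    i0 <- floor(phase * nPhase) %% nPhase
    frac <- phase * nPhase - floor(phase * nPhase)
    tpl[i0 + 1L] * (1 - frac) + tpl[(i0 + 1L) %% nPhase + 1L] * frac
  }
  shifts <- seq(-0.2, 0.2, length.out = 33L) * period
  durs <- diff(mins)
  refined <- mins
  for (b in seq_len(nb)) {
    m0 <- mins[b]
    ## local periods on each side of the boundary, so that beat-to-beat
    ## period variation is not regressed towards the record median
    dL <- if (b > 1L) durs[b - 1L] else durs[1L]
    dR <- if (b <= length(durs)) durs[b] else durs[length(durs)]
    ## keep the provisional estimate when the window is truncated by the
    ## record edges (the template fit would be one-sided and unreliable)
    if (m0 - 0.45 * dL < t[1L] || m0 + 0.45 * dR > t[length(t)]) next
    sel <- which(t >= m0 - 0.45 * dL & t <= m0 + 0.45 * dR)
    if (length(sel) < 5L) next
    tv <- t[sel]; yv <- y[sel]
    sse <- vapply(shifts, function(dl) {
      rel <- tv - m0 - dl
      u <- tplFun(ifelse(rel >= 0, (rel / dR) %% 1, (rel / dL) %% 1))
      r <- stats::lm.fit(cbind(1, u), yv)$residuals
      sum(r^2)
    }, numeric(1))
    k <- which.min(sse)
    if (k > 1L && k < length(shifts)) {
      a <- sse[k - 1L]; bb <- sse[k]; cc <- sse[k + 1L]
      den <- a - 2 * bb + cc
      frac <- if (abs(den) > 0) max(-0.5, min(0.5, 0.5 * (a - cc) / den)) else 0
      refined[b] <- m0 + shifts[k] + frac * diff(shifts[1:2])
    } else refined[b] <- m0 + shifts[k]
  }
  refined[order(refined)]
}

## zero-slope-at-origin cubic v(d) = c + a d^2 + b d^3 through 3 points
## (d_i > 0); used to model the flow around a cycle-boundary trough from
## one side only, so that neighbouring cycles do not leak into the estimate
.boundaryCubic <- function(d, y) {
  A <- cbind(1, d^2, d^3)
  co <- tryCatch(solve(A, y), error = function(e) NULL)
  if (is.null(co)) {
    beta <- max(0, (y[2] - y[1]) / (d[2]^2 - d[1]^2))
    co <- c(y[1] - beta * d[1]^2, beta, 0)
  }
  co
}

#' Resample one cardiac cycle to n equispaced phase points
#'
#' Shape-preserving piecewise-cubic (Fritsch-Carlson) interpolation of the
#' cycle's own raw samples, evaluated at `n` equispaced normalized phases in
#' `[0, 1)` of the cycle `[start, end)`. Because the boundaries are flow
#' minima lying between samples, the flow around each boundary is modelled
#' by a one-sided cubic with zero slope at the boundary, fitted to the three
#' nearest samples of this cycle only; this pins the trough value without
#' borrowing information from the neighbouring beats (whose amplitude may
#' differ) and keeps per-cycle parameter estimates unbiased ratios. Interior
#' phases interpolate the samples exactly (knot samples are reproduced) and
#' without overshoot; the extrapolated boundary troughs are clamped to at
#' most one local sample step below the adjacent samples.
#'
#' @param flow the [FlowSeries-class] the cycle was cut from.
#' @param start,end cycle boundaries in seconds (successive minima).
#' @param n number of output points (default 32, the gated CINE-PC format).
#' @return numeric(n) flow values, ml/min.
#' @export
resampleCycle <- function(flow, start, end, n = 32L, boundaryGuard = 0.25) {
  stopifnot(is(flow, "FlowSeries"), end > start)
  time <- flow@time; yv <- flow@flow
  sel <- which(time >= start - 1e-9 & time < end - 1e-9)
  if (length(sel) < 4L) stop("cycle has fewer than 4 samples")
  ts <- time[sel]; ys <- yv[sel]; m <- length(ts)
  ## samples closer to a boundary than the guard (fraction of a frame) may
  ## belong to the neighbouring beat when the detected minimum is slightly
  ## off; exclude them from the one-sided boundary fits
  dt <- frameInterval(flow)
  guard <- boundaryGuard * dt
  atS0 <- ts[1] - start <= 1e-9
  if (!atS0 && ts[1] - start < guard && m > 4L) {
    ts <- ts[-1L]; ys <- ys[-1L]; m <- m - 1L
  }
  if (end - ts[m] < guard && m > 4L) {
    ts <- ts[-m]; ys <- ys[-m]; m <- m - 1L
  }
  atS <- ts[1] - start <= 1e-9
  if (atS) {
    c0 <- ys[1]; coS <- NULL
    preX <- 2 * start - ts[2]; preY <- ys[2]   # mirror: zero slope at trough
  } else {
    coS <- .boundaryCubic(ts[1:3] - start, ys[1:3])
    c0 <- min(max(coS[1], ys[1] - abs(ys[2] - ys[1])), min(ys[1], ys[2]))
    coS[1] <- c0
    preX <- 2 * start - ts[1]; preY <- ys[1]
  }
  coE <- .boundaryCubic(end - ts[m:(m - 2)], ys[m:(m - 2)])
  cE <- min(max(coE[1], ys[m] - abs(ys[m - 1] - ys[m])), min(ys[m], ys[m - 1]))
  coE[1] <- cE
  kx <- c(preX, start, ts[if (atS) -1L else TRUE], end, 2 * end - ts[m])
  ky <- c(preY, c0, ys[if (atS) -1L else TRUE], cE, ys[m])
  sf <- stats::splinefun(kx, ky, method = "monoH.FC")
  tout <- start + (seq_len(n) - 1L) / n * (end - start)
  out <- sf(tout)
  if (!atS) {
    g <- tout < ts[1]
    d <- tout[g] - start
    out[g] <- coS[1] + coS[2] * d^2 + coS[3] * d^3
  }
  g2 <- tout > ts[m]
  if (any(g2)) {
    e <- end - tout[g2]
    out[g2] <- coE[1] + coE[2] * e^2 + coE[3] * e^3
  }
  out
}

#' Split a flow record into cardiac cycles at the detected minima
#'
#' One cycle per consecutive pair of minima. Cycles whose duration falls
#' outside `durationGate` times the median duration are discarded (and
#' counted), guarding against missed or spurious minima. Each retained cycle
#' is resampled to 32 phase points at construction.
#'
#' @param flow a [FlowSeries-class].
#' @param minima numeric, minimum times from [detectCycleMinima()].
#' @param durationGate numeric(2), plausibility gate as multiples of the
#'   median duration (default `c(0.6, 1.4)`).
#' @return a [CardiacCycleSet-class].
#' @export
splitCycles <- function(flow, minima, durationGate = c(0.6, 1.4)) {
  stopifnot(is(flow, "FlowSeries"))
  if (length(minima) < 2L) stop("need at least 2 minima to form a cycle")
  start <- minima[-length(minima)]
  end <- minima[-1L]
  dur <- end - start
  med <- stats::median(dur)
  keep <- dur >= durationGate[1] * med & dur <= durationGate[2] * med
  ## also require enough raw samples for interpolation
  nIn <- vapply(seq_along(start), function(i)
    sum(flow@time >= start[i] & flow@time < end[i]), numeric(1))
  keep <- keep & nIn >= 4
  nDisc <- sum(!keep)
  if (nDisc > 0)
    message(nDisc, " cycle(s) discarded by the duration gate")
  if (!any(keep)) stop("no cycles retained")
  start <- start[keep]; end <- end[keep]; dur <- dur[keep]
  qt32 <- t(vapply(seq_along(start), function(i)
    resampleCycle(flow, start[i], end[i]), numeric(32)))
  new("CardiacCycleSet", start = start, end = end,
      midpoint = (start + end) / 2, duration = dur, qt32 = qt32,
      nDiscarded = as.integer(nDisc))
}

#' Average cardiac cycles into a reconstructed 32-point Qt
#'
#' Pointwise (unweighted) mean of the 32-point phase-normalized cycles; the
#' cardiac period of the result is the mean duration of the contributing
#' cycles.
#'
#' @param cycles a [CardiacCycleSet-class].
#' @param which integer indices of the cycles to average (default all).
#' @return a [ReconstructedQt-class].
#' @export
averageCycles <- function(cycles, which = seq_len(nCycles(cycles))) {
  stopifnot(is(cycles, "CardiacCycleSet"))
  if (length(which) < 1L) stop("need at least 1 cycle to average")
  new("ReconstructedQt",
      values = colMeans(cycles@qt32[which, , drop = FALSE]),
      tc = mean(cycles@duration[which]), nCycles = length(which))
}

#' Compute the scalar CSF parameters of a reconstructed cycle
#'
#' With `Q` the 32-point cycle (ml/min) and `dt = Tc/32`:
#' \itemize{
#'   \item `Qnet = mean(Q)` (ml/min), the net flow;
#'   \item `Amplitude = max(Q) - min(Q)` (ml/min);
#'   \item `SVpos = integral of max(Q, 0) dt * 1000/60` (mm^3), the
#'     caudocranial volume; `SVneg` likewise on `-min(Q, 0)`;
#'   \item `SV = (SVpos + SVneg)/2` (mm^3), the oscillatory stroke volume;
#'   \item `Vmax = max(Q) * (1000/60)/(area * 10)` (cm/s), the peak
#'     caudocranial mean velocity; `Vmin` likewise on `|min(Q)|`.
#' }
#' Integrals use the periodic trapezoid rule on the 32-point grid (all
#' points weighted equally).
#'
#' @param qt a [ReconstructedQt-class].
#' @param area segment area in mm^2; if `NA`, velocities are omitted.
#' @return a [CycleParameters-class].
#' @examples
#' qt <- new("ReconstructedQt", values = 160 * sin(2 * pi * (0:31) / 32),
#'           tc = 0.87, nCycles = 1L)
#' parameterValues(computeParameters(qt))[["SV"]]  # ~ 160*0.87*1000/(60*pi)
#' @export
computeParameters <- function(qt, area = NA_real_) {
  stopifnot(is(qt, "ReconstructedQt"))
  q <- qt@values
  dt <- qt@tc / 32
  if (!is.na(area) && area <= 0)
    stop("segment area must be > 0 to compute velocities")
  svPos <- .flowTimeToVolume(sum(pmax(q, 0)) * dt)
  svNeg <- .flowTimeToVolume(sum(pmax(-q, 0)) * dt)
  vmax <- if (is.na(area)) NA_real_ else .flowToVelocity(max(q), area)
  vmin <- if (is.na(area)) NA_real_ else .flowToVelocity(abs(min(q)), area)
  new("CycleParameters", qnet = mean(q), amplitude = max(q) - min(q),
      tc = qt@tc, svPos = svPos, svNeg = svNeg, sv = (svPos + svNeg) / 2,
      vmax = vmax, vmin = vmin, segmentArea = as.numeric(area))
}
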