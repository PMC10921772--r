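#' Simulation configuration
#'
#' Builds a validated [SimulationConfig-class]. Defaults emulate a cervical
#' (C2-C3) free-breathing CSF record: a ~45 s acquisition at 96 ms/frame, a
#' 0.832 s cardiac period, 338 ml/min peak-to-peak flow amplitude, 9.4 ml/min
#' net flow and a 3.4 s breathing period.
#'
#' Modulation depths are expressed directly as the inspiration/expiration
#' contrast Delta-p% the analysis pipeline is expected to measure, and lags
#' as the breathing-cycle phase shift Phi-p in degrees it is expected to
#' recover; see [generateFlowRecord()] for the calibration.
#'
#' @param duration record length, s.
#' @param frameInterval sampling interval, s.
#' @param cardiacPeriod base cardiac period T0, s.
#' @param amplitude base peak-to-peak amplitude A0, ml/min.
#' @param netFlow base net flow N0, ml/min.
#' @param breathingPeriod breathing period Tb, s.
#' @param depths named numeric: target Delta-p% for `Qnet`, `Amplitude`, `Tc`
#'   (percent; missing names default to 0).
#' @param lags named numeric: target Phi-p for the same parameters (degrees
#'   of the breathing cycle; missing names default to 0).
#' @param waveform `"sinusoid"` (closed-form oracle) or `"csf_like"`
#'   (two-harmonic asymmetric template).
#' @param noiseSd additive Gaussian noise SD on flow samples, ml/min.
#' @param seed integer; fixes all randomness of the generator.
#' @return a [SimulationConfig-class].
#' @examples
#' cfg <- simulationConfig(depths = c(Tc = 6), lags = c(Tc = -64))
#' @export
simulationConfig <- function(duration = 45, frameInterval = 0.096,
                             cardiacPeriod = 0.832, amplitude = 338,
                             netFlow = 9.4, breathingPeriod = 3.4,
                             depths = c(Qnet = 0, Amplitude = 0, Tc = 0),
                             lags = c(Qnet = 0, Amplitude = 0, Tc = 0),
                             waveform = c("csf_like", "sinusoid"),
                             noiseSd = 0, seed = 1L) {
  waveform <- match.arg(waveform)
  full <- function(x) {
    out <- c(Qnet = 0, Amplitude = 0, Tc = 0)
    if (length(x)) {
      if (is.null(names(x)) || !all(names(x) %in% names(out)))
        stop("depths/lags must be named with Qnet, Amplitude, Tc")
      out[names(x)] <- x
    }
    out
  }
  new("SimulationConfig", duration = duration, frameInterval = frameInterval,
      cardiacPeriod = cardiacPeriod, amplitude = amplitude, netFlow = netFlow,
      breathingPeriod = breathingPeriod, depths = full(depths),
      lags = full(lags), waveform = waveform, noiseSd = noiseSd,
      seed = as.integer(seed))
}

## normalized cardiac waveform: zero mean, unit peak-to-peak, minimum at
## phase 0 (min-to-min convention). "csf_like" is a two-harmonic template
## with the asymmetric systolic trough of aqueductal/cervical CSF curves.
.cardiacTemplate <- function(waveform) {
  if (waveform == "sinusoid")
    return(function(phi) -cos(2 * pi * phi) / 2)
  raw <- function(phi) sin(2 * pi * phi) + 0.35 * sin(4 * pi * phi + pi / 3)
  phiMin <- stats::optimize(raw, c(0, 1))$minimum
  lo <- stats::optimize(raw, c(0, 1))$objective
  hi <- -stats::optimize(function(p) -raw(p), c(0, 1))$objective
  p2p <- hi - lo
  ## the two harmonics integrate to zero over a period, so only shift/scale
  function(phi) raw((phi + phiMin) %% 1) / p2p
}

## Delta-p% (half-cycle contrast) -> sinusoidal modulation depth m.
## For p(phi) = p0 (1 + m sin(2 pi phi)), the difference between the means
## over the two half-cycles is p0 * m * 4 / pi, so m = (Delta-p%) * pi / 400.
.depthToM <- function(depthPercent) depthPercent * pi / 400

#' Generate a synthetic CSF flow record with known breathing modulation
#'
#' Produces a continuous flow signal built cycle by cycle: cardiac cycle i
#' has period `Tc_i`, peak-to-peak amplitude `A_i` and net offset `N_i` drawn
#' from the breathing phase at the cycle midpoint,
#' \deqn{p_i = p_0 \, (1 + m_p \sin(2\pi(\phi_i - lag_p/360))),}
#' with `m_p` calibrated so that the pipeline's expected measured Delta-p%
#' equals the configured depth (`m = depth * pi/400`; the half-cycle mean
#' contrast of a unit sinusoid is 4/pi). The net-flow modulation is additive
#' with amplitude referenced to A0, matching the pipeline's normalization of
#' Delta-Qnet% by the mean Amplitude. A synchronized chest-belt trace (raised
#' cosine, ascending half = inspiration) and the exact per-cycle ground truth
#' are returned alongside.
#'
#' @param config a [SimulationConfig-class].
#' @return a list with elements `flow` ([FlowSeries-class]), `belt`
#'   ([BreathingSignal-class]) and `truth` ([SyntheticTruth-class]).
#' @examples
#' rec <- generateFlowRecord(simulationConfig(duration = 10, breathingPeriod = 3.4))
#' rec$flow
#' @export
generateFlowRecord <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  T0 <- config@cardiacPeriod; A0 <- config@amplitude; N0 <- config@netFlow
  Tb <- config@breathingPeriod; dur <- config@duration
  dt <- config@frameInterval
  mA <- .depthToM(config@depths[["Amplitude"]])
  mT <- .depthToM(config@depths[["Tc"]])
  aN <- .depthToM(config@depths[["Qnet"]]) * A0   # additive, ml/min
  lag <- config@lags / 360                         # fraction of Tb
  tpl <- .cardiacTemplate(config@waveform)

  ## lay down cycles until the record is covered
  starts <- numeric(0); durs <- numeric(0); amps <- numeric(0)
  nets <- numeric(0); phis <- numeric(0)
  s <- 0
  while (s < dur) {
    Tc <- T0
    for (k in 1:3) {                               # fixed point on midpoint phase
      phi <- ((s + Tc / 2) / Tb) %% 1
      Tc <- T0 * (1 + mT * sin(2 * pi * (phi - lag[["Tc"]])))
    }
    phi <- ((s + Tc / 2) / Tb) %% 1
    starts <- c(starts, s); durs <- c(durs, Tc); phis <- c(phis, phi)
    amps <- c(amps, A0 * (1 + mA * sin(2 * pi * (phi - lag[["Amplitude"]]))))
    nets <- c(nets, N0 + aN * sin(2 * pi * (phi - lag[["Qnet"]])))
    s <- s + Tc
  }

  n <- floor(dur / dt) + 1L
  t <- (seq_len(n) - 1L) * dt
  ci <- findInterval(t, starts)
  phiLocal <- (t - starts[ci]) / durs[ci]
  q <- nets[ci] + amps[ci] * tpl(phiLocal)
  if (config@noiseSd > 0)
    q <- q + .withSeed(config@seed, stats::rnorm(n, 0, config@noiseSd))

  belt <- 0.5 * (1 - cos(2 * pi * t / Tb))

  complete <- starts + durs <= dur + 1e-9
  cyc <- data.frame(start = starts[complete],
                    midpoint = starts[complete] + durs[complete] / 2,
                    duration = durs[complete], amplitude = amps[complete],
                    qnet = nets[complete], breathingPhase = phis[complete],
                    phase = ifelse(phis[complete] < 0.5, "IN", "EX"))
  truth <- new("SyntheticTruth", cycles = cyc, depths = config@depths,
               lags = config@lags,
               breathBoundaries = seq(0, dur, by = Tb))
  list(flow = flowSeries(t, q), belt = breathingSignal(t, belt),
       truth = truth)
}

#' Image rendering configuration
#'
#' @param gridSize integer(2), image height and width in pixels.
#' @param pixelSpacing isotropic pixel spacing, mm.
#' @param roi logical H x W matrix: the CSF lumen pixels (see [discMask()]).
#' @param venc velocity encoding limit, cm/s.
#' @param backgroundOffset constant eddy-current-like velocity bias, cm/s,
#'   applied to every pixel.
#' @param noiseSd per-pixel velocity noise SD, cm/s.
#' @param alias logical; wrap velocities whose magnitude exceeds the VENC by
#'   multiples of 2 VENC, as a phase-contrast acquisition would.
#' @return an [ImageRenderConfig-class].
#' @export
imageRenderConfig <- function(gridSize, pixelSpacing, roi, venc,
                              backgroundOffset = 0, noiseSd = 0,
                              alias = FALSE) {
  new("ImageRenderConfig", gridSize = as.integer(gridSize),
      pixelSpacing = as.numeric(pixelSpacing), roi = roi,
      venc = as.numeric(venc), backgroundOffset = as.numeric(backgroundOffset),
      noiseSd = as.numeric(noiseSd), alias = as.logical(alias))
}

#' Render a flow signal as a velocity-map image series
#'
#' Inverse of [extractFlow()] for validation: at each frame the ROI pixels
#' carry the uniform (plug-profile) velocity `v = Q * (1000/60) / (area * 10)`
#' cm/s implied by the flow and the ROI area, all pixels carry the constant
#' background offset plus Gaussian noise, and, if `alias = TRUE`, velocities
#' beyond the VENC are wrapped by multiples of 2 VENC.
#'
#' @param flow a [FlowSeries-class].
#' @param img an [ImageRenderConfig-class].
#' @param seed integer seed for the pixel noise.
#' @return a [VelocityMapSeries-class] (H x W x T).
#' @export
renderVelocitySeries <- function(flow, img, seed = 1L) {
  stopifnot(is(flow, "FlowSeries"), is(img, "ImageRenderConfig"))
  validObject(img)
  H <- img@gridSize[1]; W <- img@gridSize[2]
  Tn <- length(flow@time)
  area <- sum(img@roi) * img@pixelSpacing^2
  vroi <- .flowToVelocity(flow@flow, area)
  if (img@alias && max(abs(vroi + img@backgroundOffset)) >= 3 * img@venc)
    stop("ROI velocity exceeds 3*VENC; single-wrap de-aliasing not guaranteed")
  frames <- array(img@backgroundOffset, dim = c(H, W, Tn))
  roiIdx <- which(img@roi)
  for (k in seq_len(Tn))
    frames[, , k][roiIdx] <- frames[, , k][roiIdx] + vroi[k]
  if (img@noiseSd > 0)
    frames <- frames + .withSeed(seed,
      array(stats::rnorm(H * W * Tn, 0, img@noiseSd), dim = c(H, W, Tn)))
  if (img@alias) {
    v <- img@venc
    frames <- ((frames + v) %% (2 * v)) - v
  }
  velocityMapSeries(frames, img@pixelSpacing, frameInterval(flow), img@venc)
}
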