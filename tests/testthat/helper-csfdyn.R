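# shared fixtures, all generated in code

# pure sinusoidal flow record: Q(t) = N + (A/2) sin(2 pi t / period)
makeSineFlow <- function(period = 0.9, duration = 45, dt = 0.096,
                         amplitude = 320, net = 0) {
  t <- seq(0, duration, by = dt)
  flowSeries(t, net + amplitude / 2 * sin(2 * pi * t / period))
}

# reconstructed cycle built directly from a closed-form waveform
makeQt <- function(values, tc) {
  new("ReconstructedQt", values = values, tc = tc, nCycles = 1L)
}

# C2-C3-like rendering fixture: 37 pixels of 2 mm -> 148 mm^2 lumen
defaultRenderConfig <- function(venc = 5, backgroundOffset = 0.3,
                                noiseSd = 0.1, alias = FALSE) {
  imageRenderConfig(c(24, 24), 2, discMask(c(24, 24), c(12, 12), 3.4),
                    venc = venc, backgroundOffset = backgroundOffset,
                    noiseSd = noiseSd, alias = alias)
}

# full flow pipeline on a generated record
runFlowPipeline <- function(cfg, area = 148) {
  rec <- generateFlowRecord(cfg)
  cyc <- suppressMessages(splitCycles(rec$flow, detectCycleMinima(rec$flow)))
  ph <- delineatePhases(rec$belt)
  list(rec = rec, cyc = cyc, ph = ph,
       sweep = sweepPhase(cyc, ph, area = area))
}

tableC2C3Depths <- c(Tc = 6.0, Amplitude = 6.8, Qnet = 6.3)
tableC2C3Lags <- c(Tc = -64, Amplitude = -11, Qnet = 33)
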