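#' @title Accessors for csfdyn objects
#' @description Small generic accessors used throughout the package instead
#'   of direct slot access.
#' @param object a csfdyn S4 object.
#' @name accessors
NULL

#' @describeIn accessors sample times (s) of a signal object.
#' @export
setGeneric("sampleTimes", function(object) standardGeneric("sampleTimes"))
#' @describeIn accessors flow values (ml/min) of a `FlowSeries`.
#' @export
setGeneric("flowRate", function(object) standardGeneric("flowRate"))
#' @describeIn accessors sampling interval in seconds.
#' @export
setGeneric("frameInterval", function(object) standardGeneric("frameInterval"))
#' @describeIn accessors velocity encoding limit (cm/s).
#' @export
setGeneric("venc", function(object) standardGeneric("venc"))
#' @describeIn accessors segment area in mm^2.
#' @export
setGeneric("segmentArea", function(object) standardGeneric("segmentArea"))
#' @describeIn accessors number of cycles contained in / averaged by the object.
#' @export
setGeneric("nCycles", function(object) standardGeneric("nCycles"))
#' @describeIn accessors scalar cycle parameters as a named numeric vector.
#' @export
setGeneric("parameterValues", function(object) standardGeneric("parameterValues"))

setMethod("sampleTimes", "FlowSeries", function(object) object@time)
setMethod("sampleTimes", "BreathingSignal", function(object) object@time)
setMethod("flowRate", "FlowSeries", function(object) object@flow)
setMethod("frameInterval", "FlowSeries",
          function(object) mean(diff(object@time)))
setMethod("frameInterval", "BreathingSignal",
          function(object) mean(diff(object@time)))
setMethod("frameInterval", "VelocityMapSeries",
          function(object) object@frameInterval)
setMethod("venc", "VelocityMapSeries", function(object) object@venc)
setMethod("segmentArea", "SegmentationMask",
          function(object) sum(object@mask) * object@pixelSpacing^2)
setMethod("segmentArea", "CycleParameters", function(object) object@segmentArea)
setMethod("nCycles", "CardiacCycleSet", function(object) length(object@start))
setMethod("nCycles", "ReconstructedQt", function(object) object@nCycles)
setMethod("parameterValues", "CycleParameters", function(object)
  c(Qnet = object@qnet, Amplitude = object@amplitude, Tc = object@tc,
    SVpos = object@svPos, SVneg = object@svNeg, SV = object@sv,
    Vmax = object@vmax, Vmin = object@vmin, SegmentArea = object@segmentArea))

#' @describeIn accessors amplitude values of a `BreathingSignal` (a.u.).
#' @export
beltAmplitude <- function(object) {
  stopifnot(is(object, "BreathingSignal"))
  object@amplitude
}

#' @describeIn accessors the 32 flow values (ml/min) of a `ReconstructedQt`.
#' @export
qtValues <- function(object) {
  stopifnot(is(object, "ReconstructedQt"))
  object@values
}

#' @describeIn accessors velocity frames array (H x W x T, cm/s).
#' @export
velocityFrames <- function(object) {
  stopifnot(is(object, "VelocityMapSeries"))
  object@frames
}

#' @describeIn accessors logical mask matrix of a `SegmentationMask`.
#' @export
maskMatrix <- function(object) {
  stopifnot(is(object, "SegmentationMask"))
  object@mask
}

#' @describeIn accessors per-parameter summary of a `PhaseSweepResult`.
#' @export
sweepSummary <- function(object) {
  stopifnot(is(object, "PhaseSweepResult"))
  object@summary
}

#' @describeIn accessors the delta curves matrix of a `PhaseSweepResult`.
#' @export
deltaCurves <- function(object) {
  stopifnot(is(object, "PhaseSweepResult"))
  object@curves
}

setMethod("show", "FlowSeries", function(object) {
  cat(sprintf("FlowSeries: %d samples, %.4g s at %.3g ms/frame, %.4g-%.4g ml/min\n",
              length(object@time), diff(range(object@time)),
              1000 * frameInterval(object), min(object@flow), max(object@flow)))
})

setMethod("show", "BreathingSignal", function(object) {
  cat(sprintf("BreathingSignal: %d samples over %.4g s\n",
              length(object@time), diff(range(object@time))))
})

setMethod("show", "VelocityMapSeries", function(object) {
  d <- dim(object@frames)
  cat(sprintf(
    "VelocityMapSeries: %d x %d pixels x %d frames, %.3g mm, %.3g ms/frame, VENC %.3g cm/s\n",
    d[1], d[2], d[3], object@pixelSpacing, 1000 * object@frameInterval,
    object@venc))
})

setMethod("show", "SegmentationMask", function(object) {
  cat(sprintf("SegmentationMask: %d pixels, area %.4g mm^2\n",
              sum(object@mask), segmentArea(object)))
})

setMethod("show", "CardiacCycleSet", function(object) {
  cat(sprintf("CardiacCycleSet: %d cycles (%d discarded), Tc %.3g +/- %.2g s\n",
              nCycles(object), object@nDiscarded,
              mean(object@duration), stats::sd(object@duration)))
})

setMethod("show", "ReconstructedQt", function(object) {
  cat(sprintf("ReconstructedQt: 32 points, Tc %.4g s, %d cycles averaged\n",
              object@tc, object@nCycles))
})

setMethod("show", "CycleParameters", function(object) {
  v <- parameterValues(object)
  cat("CycleParameters:\n")
  cat(sprintf("  Qnet %.4g ml/min | Amplitude %.4g ml/min | Tc %.4g s\n",
              v["Qnet"], v["Amplitude"], v["Tc"]))
  cat(sprintf("  SV %.4g mm^3 (pos %.4g, neg %.4g)\n",
              v["SV"], v["SVpos"], v["SVneg"]))
  if (is.finite(v["Vmax"]))
    cat(sprintf("  Vmax %.3g cm/s | Vmin %.3g cm/s (area %.4g mm^2)\n",
                v["Vmax"], v["Vmin"], v["SegmentArea"]))
})

setMethod("show", "BreathingPhases", function(object) {
  cat(sprintf("BreathingPhases: %d complete cycles, mean period %.4g s\n",
              object@nCycles, object@meanPeriod))
})

setMethod("show", "PhaseSweepResult", function(object) {
  cat(sprintf("PhaseSweepResult over [%.2g, %.2g] s (%d shifts), Tb %.4g s\n",
              min(object@phiGrid), max(object@phiGrid),
              length(object@phiGrid), object@meanPeriod))
  print(object@summary, digits = 3)
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(
    "SimulationConfig: %.4g s at %.3g ms, T0 %.4g s, A0 %.4g ml/min, N0 %.4g ml/min, Tb %.4g s\n",
    object@duration, 1000 * object@frameInterval, object@cardiacPeriod,
    object@amplitude, object@netFlow, object@breathingPeriod))
  cat(sprintf("  waveform %s, noise SD %.3g ml/min, seed %d\n",
              object@waveform, object@noiseSd, object@seed))
  cat("  depths (%):", sprintf("%s=%.3g", names(object@depths), object@depths),
      "\n  lags (deg):", sprintf("%s=%.3g", names(object@lags), object@lags),
      "\n")
})

setMethod("show", "SyntheticTruth", function(object) {
  cat(sprintf("SyntheticTruth: %d cycles, %d breathing boundaries\n",
              nrow(object@cycles), length(object@breathBoundaries)))
})
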