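#' @import methods
NULL

#' Uniformly sampled continuous flow-rate signal
#'
#' The central signal object of the pipeline: a cerebrospinal fluid flow rate
#' \eqn{Q(t)} in ml/min (positive = caudocranial, i.e. towards the cranium)
#' sampled on a uniform time grid, as produced by real-time phase-contrast
#' (RT-PC) acquisitions or by [generateFlowRecord()].
#'
#' @slot time numeric, sample times in seconds, strictly increasing and
#'   uniform to within 1 ppm of the step.
#' @slot flow numeric, flow rate in ml/min, same length as `time`.
#'
#' @seealso [flowSeries()], [extractFlow()], [detectCycleMinima()]
#' @export
setClass("FlowSeries",
  representation(time = "numeric", flow = "numeric"),
  validity = function(object) {
    if (length(object@time) != length(object@flow))
      return("time and flow must have the same length")
    if (length(object@time) < 2L)
      return("need at least 2 samples")
    dt <- diff(object@time)
    if (any(dt <= 0)) return("time must be strictly increasing")
    if (diff(range(dt)) > 1e-6 * mean(dt))
      return("sampling must be uniform (within 1 ppm)")
    if (anyNA(object@flow)) return("flow must not contain NA")
    TRUE
  })

#' Chest-belt breathing signal
#'
#' Respiratory bellows amplitude in arbitrary units on a uniform time grid.
#' Ascending amplitude corresponds to inspiration (thoracic expansion).
#'
#' @slot time numeric, seconds, uniform.
#' @slot amplitude numeric, arbitrary units.
#' @seealso [breathingSignal()], [delineatePhases()]
#' @export
setClass("BreathingSignal",
  representation(time = "numeric", amplitude = "numeric"),
  validity = function(object) {
    if (length(object@time) != length(object@amplitude))
      return("time and amplitude must have the same length")
    if (length(object@time) < 2L) return("need at least 2 samples")
    dt <- diff(object@time)
    if (any(dt <= 0)) return("time must be strictly increasing")
    if (diff(range(dt)) > 1e-6 * mean(dt))
      return("sampling must be uniform (within 1 ppm)")
    TRUE
  })

#' Velocity-map image time series
#'
#' A 2D+t phase-contrast velocity image: one in-plane slice of signed
#' velocities (cm/s, positive = caudocranial) per frame, with the acquisition
#' metadata needed for flow quantification.
#'
#' @slot frames numeric array `H x W x T` of velocities in cm/s.
#' @slot pixelSpacing numeric(1), isotropic in-plane pixel spacing in mm.
#' @slot frameInterval numeric(1), time between frames in seconds.
#' @slot venc numeric(1), velocity encoding limit in cm/s; stored velocities
#'   of an aliased acquisition lie within `[-venc, venc]`.
#' @seealso [velocityMapSeries()], [segmentCsfRoi()], [extractFlow()]
#' @export
setClass("VelocityMapSeries",
  representation(frames = "array", pixelSpacing = "numeric",
                 frameInterval = "numeric", venc = "numeric"),
  validity = function(object) {
    d <- dim(object@frames)
    if (length(d) != 3L) return("frames must be an H x W x T array")
    if (object@pixelSpacing <= 0) return("pixelSpacing must be > 0")
    if (object@frameInterval <= 0) return("frameInterval must be > 0")
    if (object@venc <= 0) return("venc must be > 0")
    TRUE
  })

#' Binary CSF segmentation mask
#'
#' @slot mask logical `H x W` matrix, TRUE inside the CSF lumen; a single
#'   4-connected component.
#' @slot pixelSpacing numeric(1), mm; the segment area in mm^2 is
#'   `sum(mask) * pixelSpacing^2` (see [segmentArea()]).
#' @export
setClass("SegmentationMask",
  representation(mask = "matrix", pixelSpacing = "numeric"),
  validity = function(object) {
    if (!is.logical(object@mask)) return("mask must be logical")
    if (!any(object@mask)) return("mask must be nonempty")
    if (object@pixelSpacing <= 0) return("pixelSpacing must be > 0")
    TRUE
  })

#' Stationary-tissue reference region
#'
#' Pixels of quiescent tissue surrounding the CSF region whose mean velocity
#' serves as the zero-velocity reference for background (eddy current)
#' correction.
#'
#' @slot region logical `H x W` matrix, disjoint from the CSF mask.
#' @slot referenceVelocity numeric(1), spatiotemporal mean velocity (cm/s) of
#'   the region, to be subtracted from the whole series.
#' @export
setClass("StationaryRegion",
  representation(region = "matrix", referenceVelocity = "numeric"),
  validity = function(object) {
    if (!is.logical(object@region)) return("region must be logical")
    if (!any(object@region)) return("region must be nonempty")
    if (!is.finite(object@referenceVelocity))
      return("referenceVelocity must be finite")
    TRUE
  })

#' Set of segmented cardiac cycles
#'
#' One row per retained beat of a continuous flow record, segmented at flow
#' minima (min-to-min convention). Each cycle is stored both by its temporal
#' extent and as its 32-point phase-normalized resampling, so that averaging
#' over arbitrary subsets (e.g. inspiratory vs expiratory beats) is a column
#' mean.
#'
#' @slot start,end numeric, cycle boundaries in seconds (successive minima).
#' @slot midpoint numeric, cycle midpoints in seconds (used to assign a beat
#'   to a breathing phase).
#' @slot duration numeric, per-cycle cardiac period Tc_i in seconds.
#' @slot qt32 numeric matrix `n x 32`, each row the cycle resampled at 32
#'   equispaced normalized phases in `[0, 1)`.
#' @slot nDiscarded integer, cycles removed by the duration plausibility gate.
#' @seealso [splitCycles()], [averageCycles()]
#' @export
setClass("CardiacCycleSet",
  representation(start = "numeric", end = "numeric", midpoint = "numeric",
                 duration = "numeric", qt32 = "matrix",
                 nDiscarded = "integer"),
  validity = function(object) {
    n <- length(object@start)
    if (length(object@end) != n || length(object@midpoint) != n ||
        length(object@duration) != n || nrow(object@qt32) != n)
      return("inconsistent cycle count across slots")
    if (n > 0 && ncol(object@qt32) != 32L)
      return("qt32 must have 32 columns")
    if (any(object@duration <= 0)) return("durations must be > 0")
    TRUE
  })

#' Reconstructed 32-point cardiac cycle
#'
#' The averaged flow curve over one cardiac cycle on 32 equispaced phase
#' points, the format of a gated (CINE-PC) acquisition.
#'
#' @slot values numeric(32), flow in ml/min at phases `(0:31)/32` of the
#'   cycle, phase origin at the cycle minimum.
#' @slot tc numeric(1), mean duration (s) of the contributing cycles.
#' @slot nCycles integer(1), number of averaged cycles.
#' @seealso [averageCycles()], [computeParameters()]
#' @export
setClass("ReconstructedQt",
  representation(values = "numeric", tc = "numeric", nCycles = "integer"),
  validity = function(object) {
    if (length(object@values) != 32L) return("values must have length 32")
    if (object@tc <= 0) return("tc must be > 0")
    if (object@nCycles < 1L) return("nCycles must be >= 1")
    TRUE
  })

#' Scalar descriptors of a reconstructed cardiac cycle
#'
#' @slot qnet numeric(1), net (mean) flow over the cycle, ml/min.
#' @slot amplitude numeric(1), max minus min of the cycle flow curve, ml/min.
#' @slot tc numeric(1), cardiac period, seconds.
#' @slot svPos,svNeg numeric(1), positive (caudocranial) and negative
#'   (craniocaudal) flow-time integrals over the cycle, mm^3.
#' @slot sv numeric(1), stroke volume `(svPos + svNeg)/2`, mm^3.
#' @slot vmax,vmin numeric(1), magnitudes of the peak mean velocities (cm/s)
#'   at maximum and minimum flow; `NA` when no segment area is available.
#' @slot segmentArea numeric(1), mm^2 (NA if not supplied).
#' @seealso [computeParameters()]
#' @export
setClass("CycleParameters",
  representation(qnet = "numeric", amplitude = "numeric", tc = "numeric",
                 svPos = "numeric", svNeg = "numeric", sv = "numeric",
                 vmax = "numeric", vmin = "numeric", segmentArea = "numeric"),
  validity = function(object) {
    if (object@amplitude < 0) return("amplitude must be >= 0")
    if (object@svPos < 0 || object@svNeg < 0) return("svPos/svNeg must be >= 0")
    TRUE
  })

#' Inspiration/expiration delineation of a breathing record
#'
#' @slot intervals data.frame with columns `start`, `end` (seconds) and
#'   `phase` ("IN" or "EX"); alternating intervals tiling the window of
#'   complete breathing cycles.
#' @slot boundaries numeric, trough times delimiting complete breathing
#'   cycles (trough-to-trough).
#' @slot meanPeriod numeric(1), mean breathing period in seconds.
#' @slot nCycles integer(1), number of complete breathing cycles retained.
#' @seealso [delineatePhases()], [assignCycles()]
#' @export
setClass("BreathingPhases",
  representation(intervals = "data.frame", boundaries = "numeric",
                 meanPeriod = "numeric", nCycles = "integer"),
  validity = function(object) {
    need <- c("start", "end", "phase")
    if (!all(need %in% names(object@intervals)))
      return("intervals needs columns start, end, phase")
    if (object@meanPeriod <= 0) return("meanPeriod must be > 0")
    if (object@nCycles < 1L) return("need at least one complete cycle")
    TRUE
  })

#' Result of the breathing phase-shift sweep
#'
#' For each CSF parameter p (Qnet, Amplitude, SV, Tc), the
#' inspiration-minus-expiration difference curve \eqn{\Delta p(\Phi)} over
#' the phase-shift grid, and the derived intensity and phase of the breathing
#' effect.
#'
#' @slot phiGrid numeric, phase shifts in seconds.
#' @slot curves numeric matrix `length(phiGrid) x 4`, columns Qnet,
#'   Amplitude, SV, Tc, each in the parameter's native units (ml/min, ml/min,
#'   mm^3, s).
#' @slot nInsp,nExp integer, number of beats assigned to each phase per shift.
#' @slot meanPeriod numeric(1), mean breathing period (s).
#' @slot meanValues numeric(4), per-record mean parameter values used to
#'   normalize (Qnet is normalized by the mean Amplitude).
#' @slot summary data.frame, one row per parameter with columns `delta`
#'   (signed intensity, native units), `deltaPercent`, `phiS`, `phiPercent`,
#'   `phiDeg`, `flat`.
#' @seealso [sweepPhase()]
#' @export
setClass("PhaseSweepResult",
  representation(phiGrid = "numeric", curves = "matrix", nInsp = "integer",
                 nExp = "integer", meanPeriod = "numeric",
                 meanValues = "numeric", summary = "data.frame"),
  validity = function(object) {
    if (nrow(object@curves) != length(object@phiGrid))
      return("curves must have one row per grid point")
    if (ncol(object@curves) != 4L) return("curves must have 4 columns")
    TRUE
  })

#' Simulation configuration for the synthetic CSF flow generator
#'
#' Defines a continuous CSF-like flow record: a cardiac oscillation whose
#' amplitude, period and net offset are sinusoidally modulated at the
#' breathing period, with per-parameter modulation depths expressed directly
#' as the inspiration/expiration contrast (Delta-p%) the analysis pipeline
#' should measure, and phase lags as the Phi-p-degrees it should recover.
#'
#' @slot duration numeric(1), record length, seconds.
#' @slot frameInterval numeric(1), sampling interval, seconds.
#' @slot cardiacPeriod numeric(1), base cardiac period T0, seconds.
#' @slot amplitude numeric(1), base peak-to-peak cardiac amplitude A0, ml/min.
#' @slot netFlow numeric(1), base net flow offset N0, ml/min.
#' @slot breathingPeriod numeric(1), breathing period Tb, seconds.
#' @slot depths named numeric(3) (`Qnet`, `Amplitude`, `Tc`), target
#'   Delta-p% in percent.
#' @slot lags named numeric(3), target Phi-p in degrees of the breathing
#'   cycle.
#' @slot waveform character(1), "sinusoid" or "csf_like".
#' @slot noiseSd numeric(1), additive Gaussian noise SD on flow samples,
#'   ml/min.
#' @slot seed integer(1), fixes all randomness.
#' @seealso [simulationConfig()], [generateFlowRecord()]
#' @export
setClass("SimulationConfig",
  representation(duration = "numeric", frameInterval = "numeric",
                 cardiacPeriod = "numeric", amplitude = "numeric",
                 netFlow = "numeric", breathingPeriod = "numeric",
                 depths = "numeric", lags = "numeric", waveform = "character",
                 noiseSd = "numeric", seed = "integer"),
  validity = function(object) {
    p <- c("Qnet", "Amplitude", "Tc")
    if (!identical(sort(names(object@depths)), sort(p)) ||
        !identical(sort(names(object@lags)), sort(p)))
      return("depths and lags must be named Qnet, Amplitude, Tc")
    if (object@cardiacPeriod <= 0) return("cardiacPeriod must be > 0")
    if (object@breathingPeriod <= object@cardiacPeriod)
      return("breathingPeriod must exceed cardiacPeriod")
    if (object@duration < 2 * object@breathingPeriod)
      return("duration must cover at least 2 breathing cycles")
    if (object@frameInterval >= object@cardiacPeriod / 4)
      return("frameInterval must be < cardiacPeriod/4")
    if (any(object@depths < 0)) return("modulation depths must be >= 0")
    if (!object@waveform %in% c("sinusoid", "csf_like"))
      return("waveform must be 'sinusoid' or 'csf_like'")
    if (object@noiseSd < 0) return("noiseSd must be >= 0")
    TRUE
  })

#' Ground truth of a generated record
#'
#' Book-keeping object for recovery tests: the injected modulation targets and
#' the exact per-cycle parameter values and timings of a synthetic record.
#'
#' @slot cycles data.frame, one row per generated complete cardiac cycle:
#'   `start`, `midpoint`, `duration`, `amplitude`, `qnet`, `breathingPhase`
#'   (in `[0,1)`, 0 = belt trough) and `phase` ("IN"/"EX" at zero shift).
#' @slot depths,lags named numeric(3), the injected Delta-p% and Phi-p-deg.
#' @slot breathBoundaries numeric, true breathing-cycle boundaries, seconds.
#' @export
setClass("SyntheticTruth",
  representation(cycles = "data.frame", depths = "numeric", lags = "numeric",
                 breathBoundaries = "numeric"))

#' Rendering configuration for synthetic velocity maps
#'
#' @slot gridSize integer(2), image height and width in pixels.
#' @slot pixelSpacing numeric(1), mm.
#' @slot roi logical matrix `H x W`, the CSF lumen (plug-flow profile).
#' @slot venc numeric(1), cm/s.
#' @slot backgroundOffset numeric(1), constant eddy-current-like velocity
#'   bias (cm/s) added to every pixel.
#' @slot noiseSd numeric(1), per-pixel velocity noise SD, cm/s.
#' @slot alias logical(1), wrap velocities exceeding the VENC.
#' @seealso [imageRenderConfig()], [renderVelocitySeries()]
#' @export
setClass("ImageRenderConfig",
  representation(gridSize = "integer", pixelSpacing = "numeric",
                 roi = "matrix", venc = "numeric",
                 backgroundOffset = "numeric", noiseSd = "numeric",
                 alias = "logical"),
  validity = function(object) {
    if (!is.logical(object@roi)) return("roi must be a logical matrix")
    if (!any(object@roi)) return("roi must be nonempty")
    if (!identical(dim(object@roi), as.integer(object@gridSize)))
      return("roi dimensions must match gridSize")
    if (object@venc <= 0) return("venc must be > 0")
    if (object@pixelSpacing <= 0) return("pixelSpacing must be > 0")
    if (object@noiseSd < 0) return("noiseSd must be >= 0")
    TRUE
  })
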