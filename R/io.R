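#' Read and write csfdyn signals and results
#'
#' Flow and belt signals are exchanged as two-column CSV files with fixed
#' headers (`time_s, flow_ml_min` and `time_s, belt_au`); velocity-map
#' series as NIfTI-1 volumes (`X x Y x 1 x T`, cm/s) with a JSON sidecar
#' carrying `venc_cm_s`, `pixel_spacing_mm`, `frame_interval_s` and
#' `positive_direction`; masks as NIfTI-1 uint8; parameters and sweep
#' results as JSON. All numeric payloads round-trip losslessly at double
#' precision (CSV values are written with full precision).
#'
#' @param x object to write.
#' @param path file path.
#' @name csfdyn-io
NULL

.writeSignalCsv <- function(time, value, header, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  writeLines(sprintf("%.17g,%.17g", time, value), con)
}

.readSignalCsv <- function(path, header) {
  df <- utils::read.csv(path, check.names = FALSE)
  want <- strsplit(header, ",")[[1]]
  if (!all(want %in% names(df)))
    stop("file ", path, ": expected columns ", header)
  df[want]
}

#' @rdname csfdyn-io
#' @export
writeFlowSeries <- function(x, path) {
  stopifnot(is(x, "FlowSeries"))
  .writeSignalCsv(x@time, x@flow, "time_s,flow_ml_min", path)
  invisible(path)
}

#' @rdname csfdyn-io
#' @export
readFlowSeries <- function(path) {
  df <- .readSignalCsv(path, "time_s,flow_ml_min")
  flowSeries(df$time_s, df$flow_ml_min)
}

#' @rdname csfdyn-io
#' @export
writeBreathingSignal <- function(x, path) {
  stopifnot(is(x, "BreathingSignal"))
  .writeSignalCsv(x@time, x@amplitude, "time_s,belt_au", path)
  invisible(path)
}

#' @rdname csfdyn-io
#' @export
readBreathingSignal <- function(path) {
  df <- .readSignalCsv(path, "time_s,belt_au")
  breathingSignal(df$time_s, df$belt_au)
}

#' @rdname csfdyn-io
#' @param sidecarPath path of the JSON sidecar; defaults to the image path
#'   with the extension replaced by `.json`.
#' @export
writeVelocitySeries <- function(x, path, sidecarPath = NULL) {
  stopifnot(is(x, "VelocityMapSeries"))
  if (is.null(sidecarPath)) sidecarPath <- sub("\\.nii(\\.gz)?$", ".json", path)
  d <- dim(x@frames)
  vol <- array(x@frames, dim = c(d[1], d[2], 1L, d[3]))
  img <- RNifti::asNifti(vol)
  RNifti::pixdim(img) <- c(x@pixelSpacing, x@pixelSpacing, 1, x@frameInterval)
  RNifti::writeNifti(img, path, datatype = "float")
  jsonlite::write_json(
    list(venc_cm_s = x@venc, pixel_spacing_mm = x@pixelSpacing,
         frame_interval_s = x@frameInterval,
         positive_direction = "caudocranial"),
    sidecarPath, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname csfdyn-io
#' @export
readVelocitySeries <- function(path, sidecarPath = NULL) {
  if (is.null(sidecarPath)) sidecarPath <- sub("\\.nii(\\.gz)?$", ".json", path)
  meta <- jsonlite::read_json(sidecarPath, simplifyVector = TRUE)
  for (f in c("venc_cm_s", "pixel_spacing_mm", "frame_interval_s"))
    if (is.null(meta[[f]]))
      stop("sidecar ", sidecarPath, ": missing required field '", f, "'")
  vol <- RNifti::readNifti(path)
  d <- dim(vol)
  if (length(d) == 4L) vol <- array(vol, dim = c(d[1], d[2], d[4]))
  velocityMapSeries(array(as.numeric(vol), dim = dim(vol)),
                    meta$pixel_spacing_mm, meta$frame_interval_s,
                    meta$venc_cm_s)
}

#' @rdname csfdyn-io
#' @export
writeMask <- function(x, path) {
  stopifnot(is(x, "SegmentationMask"))
  img <- RNifti::asNifti(array(as.integer(x@mask), dim = c(dim(x@mask), 1L)),
                         datatype = "uint8")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname csfdyn-io
#' @export
writeCycleParameters <- function(x, path) {
  stopifnot(is(x, "CycleParameters"))
  jsonlite::write_json(as.list(parameterValues(x)), path, auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' @rdname csfdyn-io
#' @export
writeSweepResult <- function(x, path) {
  stopifnot(is(x, "PhaseSweepResult"))
  s <- x@summary
  perParam <- lapply(rownames(s), function(p) list(
    delta = s[p, "delta"], delta_percent = s[p, "deltaPercent"],
    phi_s = s[p, "phiS"], phi_percent = s[p, "phiPercent"],
    phi_deg = s[p, "phiDeg"], flat = s[p, "flat"],
    curve = unname(x@curves[, p])))
  names(perParam) <- rownames(s)
  out <- list(mean_breathing_period_s = x@meanPeriod,
              phi_grid_s = x@phiGrid,
              sign_convention = "inspiration minus expiration",
              parameters = perParam)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
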