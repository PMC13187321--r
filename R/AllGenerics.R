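#' Accessors for FrameStack and SyncedRecording
#'
#' `frames()` returns the list of frame matrices, `getFrame()` one frame,
#' `nFrames()` the frame count, `frameRate()` the acquisition rate in Hz and
#' `bitDepth()` the sensor bit depth.  `greenChannel()`/`redChannel()` return
#' the two [FrameStack-class] channels of a [SyncedRecording-class],
#' `stageLog()` its stage-position log and `pixelScaleUm()` its micrometres
#' per pixel.
#'
#' @param x a [FrameStack-class] or [SyncedRecording-class].
#' @param i frame number (1-based).
#' @return See the individual descriptions.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))
#' @rdname accessors
#' @export
setGeneric("getFrame", function(x, i) standardGeneric("getFrame"))
#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setGeneric("frameRate", function(x) standardGeneric("frameRate"))
#' @rdname accessors
#' @export
setGeneric("bitDepth", function(x) standardGeneric("bitDepth"))
#' @rdname accessors
#' @export
setGeneric("greenChannel", function(x) standardGeneric("greenChannel"))
#' @rdname accessors
#' @export
setGeneric("redChannel", function(x) standardGeneric("redChannel"))
#' @rdname accessors
#' @export
setGeneric("stageLog", function(x) standardGeneric("stageLog"))
#' @rdname accessors
#' @export
setGeneric("pixelScaleUm", function(x) standardGeneric("pixelScaleUm"))

#' @rdname accessors
setMethod("frames", "FrameStack", function(x) x@frames)
#' @rdname accessors
setMethod("getFrame", "FrameStack", function(x, i) x@frames[[i]])
#' @rdname accessors
setMethod("nFrames", "FrameStack", function(x) length(x@frames))
#' @rdname accessors
setMethod("frameRate", "FrameStack", function(x) x@frameRate)
#' @rdname accessors
setMethod("bitDepth", "FrameStack", function(x) x@bitDepth)

#' @rdname accessors
setMethod("nFrames", "SyncedRecording", function(x) length(x@green@frames))
#' @rdname accessors
setMethod("greenChannel", "SyncedRecording", function(x) x@green)
#' @rdname accessors
setMethod("redChannel", "SyncedRecording", function(x) x@red)
#' @rdname accessors
setMethod("stageLog", "SyncedRecording", function(x) x@stage)
#' @rdname accessors
setMethod("pixelScaleUm", "SyncedRecording", function(x) x@pixelScaleUm)

setMethod("show", "FrameStack", function(object) {
  d <- if (length(object@frames)) dim(object@frames[[1L]]) else c(0L, 0L)
  cat(sprintf("FrameStack: %d frame(s) of %d x %d px, %g Hz, %d-bit\n",
              length(object@frames), d[2L], d[1L], object@frameRate,
              object@bitDepth))
})

setMethod("show", "SyncedRecording", function(object) {
  d <- if (nFrames(object)) dim(object@green@frames[[1L]]) else c(0L, 0L)
  cat(sprintf(paste0(
    "SyncedRecording: %d synced frame pair(s), %d x %d px @ %g um/px,\n",
    "  %g Hz, stage log with %d row(s)\n"),
    nFrames(object), d[2L], d[1L], object@pixelScaleUm,
    object@green@frameRate, nrow(object@stage)))
})

setMethod("show", "CalciumTrace", function(object) {
  cat(sprintf("CalciumTrace (%s): %d frame(s)", object@channel,
              length(object@values)))
  if (!is.na(object@baselineF0))
    cat(sprintf(", F0 = %.4g, max dF/F = %.3g", object@baselineF0,
                if (length(object@dff)) max(object@dff) else NA_real_))
  cat("\n")
})

#' @rdname deltaFOverF
#' @export
setGeneric("deltaFOverF", function(x, baselinePercentile = 0.1)
  standardGeneric("deltaFOverF"))
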