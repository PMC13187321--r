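#' @import methods
#' @importFrom stats approx cor fft median quantile rnorm rpois runif sd var
#' @importFrom utils head read.csv tail write.csv
NULL

#' FrameStack: an ordered single-channel image sequence
#'
#' A `FrameStack` holds the frames of one camera channel as a list of
#' integer matrices (row = image y, column = image x, origin top-left,
#' 0-based pixel centres at integer coordinates), together with the
#' acquisition frame rate and the sensor bit depth.  All frames share one
#' geometry and pixel values never exceed `2^bitDepth - 1`.
#'
#' @slot frames list of integer matrices, all of identical dimension.
#' @slot frameRate acquisition rate in Hz (> 0).
#' @slot bitDepth sensor bit depth; pixel values lie in `[0, 2^bitDepth - 1]`.
#'
#' @seealso [FrameStack()], [readStack()], [writeStack()]
#' @exportClass FrameStack
setClass("FrameStack",
  representation(frames = "list", frameRate = "numeric", bitDepth = "integer"),
  prototype(frames = list(), frameRate = 10, bitDepth = 16L)
)

setValidity("FrameStack", function(object) {
  msg <- character()
  if (length(object@frameRate) != 1L || !is.finite(object@frameRate) ||
      object@frameRate <= 0)
    msg <- c(msg, "frameRate must be a single positive number")
  if (length(object@bitDepth) != 1L || object@bitDepth < 1L ||
      object@bitDepth > 32L)
    msg <- c(msg, "bitDepth must be in [1, 32]")
  if (length(object@frames)) {
    d <- dim(object@frames[[1L]])
    ok <- vapply(object@frames, function(f)
      is.matrix(f) && identical(dim(f), d), logical(1L))
    if (!all(ok))
      msg <- c(msg, "all frames must be matrices of identical dimension")
    mx <- 2^object@bitDepth - 1
    rng <- vapply(object@frames, function(f) {
      r <- range(f)
      r[1L] >= 0 && r[2L] <= mx
    }, logical(1L))
    if (!all(rng))
      msg <- c(msg, sprintf("pixel values must lie in [0, %d]", as.integer(mx)))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a FrameStack
#'
#' @param frames list of numeric matrices (coerced to integer) or a single
#'   matrix.
#' @param frameRate frames per second.
#' @param bitDepth sensor bit depth (default 16).
#' @return A [FrameStack-class] object.
#' @examples
#' fs <- FrameStack(list(matrix(0L, 4, 6), matrix(1L, 4, 6)), frameRate = 10)
#' nFrames(fs)
#' @export
FrameStack <- function(frames, frameRate = 10, bitDepth = 16L) {
  if (is.matrix(frames)) frames <- list(frames)
  frames <- lapply(frames, function(f) {
    storage.mode(f) <- "integer"
    f
  })
  new("FrameStack", frames = frames, frameRate = as.numeric(frameRate),
      bitDepth = as.integer(bitDepth))
}

#' SyncedRecording: frame-synced two-channel recording plus stage log
#'
#' Pairs the green (fluorescence) and red (brightfield/ratiometric) camera
#' channels of one session.  The two cameras are frame synced, so the
#' channels can be compared frame by frame; the stage log records the XYZ
#' stage position (mm) and, when tracking was active, the tracked-point
#' pixel coordinates per frame.
#'
#' @slot green,red [FrameStack-class] objects with equal frame counts.
#' @slot stage `data.frame` with columns `frame` (0-based, strictly
#'   increasing), `time_s` (nondecreasing), `x_mm`, `y_mm`, `z_mm`,
#'   `target_x_px`, `target_y_px` (the last two may be `NA`).
#' @slot pixelScaleUm micrometres per pixel of both channels.
#'
#' @seealso [loadRecording()], [saveRecording()], [runSession()]
#' @exportClass SyncedRecording
setClass("SyncedRecording",
  representation(green = "FrameStack", red = "FrameStack",
                 stage = "data.frame", pixelScaleUm = "numeric")
)

.stageLogCols <- c("frame", "time_s", "x_mm", "y_mm", "z_mm",
                   "target_x_px", "target_y_px")

setValidity("SyncedRecording", function(object) {
  msg <- character()
  ng <- length(object@green@frames); nr <- length(object@red@frames)
  if (ng != nr)
    msg <- c(msg, sprintf("green (%d) and red (%d) frame counts differ", ng, nr))
  if (!all(.stageLogCols %in% names(object@stage)))
    msg <- c(msg, paste("stage log must have columns",
                        paste(.stageLogCols, collapse = ", ")))
  else if (nrow(object@stage)) {
    fr <- object@stage$frame
    if (any(diff(fr) <= 0))
      msg <- c(msg, "stage log frame indices must be strictly increasing")
    if (any(fr < 0) || any(fr >= ng))
      msg <- c(msg, "stage log references frames beyond the stack length")
    if (any(diff(object@stage$time_s) < 0))
      msg <- c(msg, "stage log time_s must be nondecreasing")
  }
  if (length(object@pixelScaleUm) != 1L || object@pixelScaleUm <= 0)
    msg <- c(msg, "pixelScaleUm must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Construct a SyncedRecording
#'
#' @param green,red [FrameStack-class] channels (equal frame counts).
#' @param stage stage-log `data.frame`; see [SyncedRecording-class].
#' @param pixelScaleUm micrometres per pixel.
#' @return A [SyncedRecording-class].
#' @export
SyncedRecording <- function(green, red, stage, pixelScaleUm) {
  for (col in .stageLogCols)
    if (!col %in% names(stage)) stage[[col]] <- NA_real_
  stage <- stage[, .stageLogCols]
  new("SyncedRecording", green = green, red = red, stage = stage,
      pixelScaleUm = as.numeric(pixelScaleUm))
}

#' CalciumTrace: a per-frame fluorescence intensity trace
#'
#' Raw per-frame intensities (camera counts) for one target and channel,
#' optionally with a baseline F0 and the derived relative change
#' dF/F = (F - F0)/F0 filled in by [deltaFOverF()].
#'
#' @slot values numeric vector of nonnegative intensities (counts).
#' @slot channel `"green"` or `"red"`.
#' @slot frames integer frame indices (0-based).
#' @slot baselineF0 baseline intensity F0 (counts), `NA` until computed.
#' @slot dff per-frame dF/F, length 0 until computed.
#' @exportClass CalciumTrace
setClass("CalciumTrace",
  representation(values = "numeric", channel = "character",
                 frames = "integer", baselineF0 = "numeric", dff = "numeric"),
  prototype(baselineF0 = NA_real_, dff = numeric())
)

setValidity("CalciumTrace", function(object) {
  msg <- character()
  if (any(object@values < 0)) msg <- c(msg, "values must be nonnegative")
  if (!object@channel %in% c("green", "red"))
    msg <- c(msg, "channel must be 'green' or 'red'")
  if (length(object@frames) != length(object@values))
    msg <- c(msg, "frames and values lengths differ")
  if (length(object@dff) && length(object@dff) != length(object@values))
    msg <- c(msg, "dff length must match values")
  if (length(object@dff) && (is.na(object@baselineF0) || object@baselineF0 <= 0))
    msg <- c(msg, "dff requires a positive baselineF0")
  if (length(msg)) msg else TRUE
})

#' Construct a CalciumTrace
#'
#' @param values per-frame intensities (counts).
#' @param channel `"green"` (default) or `"red"`.
#' @param frames 0-based frame indices (default `0:(n-1)`).
#' @return A [CalciumTrace-class].
#' @export
CalciumTrace <- function(values, channel = "green",
                         frames = seq_along(values) - 1L) {
  new("CalciumTrace", values = as.numeric(values), channel = channel,
      frames = as.integer(frames))
}
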