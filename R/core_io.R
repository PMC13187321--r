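## On-disk formats: multi-page 16-bit grayscale TIFF per channel plus a CSV
## stage log `frame,time_s,x_mm,y_mm,z_mm,target_x_px,target_y_px` (empty
## cells where no target was tracked).  TIFF+CSV round-trips are bit-exact.

#' Read a multi-page grayscale TIFF stack
#'
#' @param path TIFF file written by [writeStack()] or any single-channel
#'   multi-page grayscale TIFF.
#' @param frameRate frame rate to attach (Hz); not stored in the TIFF.
#' @param bitDepth expected bit depth (default 16).
#' @return A [FrameStack-class] of integer frames.
#' @export
readStack <- function(path, frameRate = 10, bitDepth = 16L) {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!length(pages)) stop("TIFF contains zero frames: ", path)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) {
      if (dim(p)[3L] != 1L)
        stop("multi-channel TIFF page; expected single-channel grayscale")
      p <- p[, , 1L]
    }
    storage.mode(p) <- "integer"
    p
  })
  FrameStack(pages, frameRate = frameRate, bitDepth = bitDepth)
}

#' Write a FrameStack as a lossless multi-page TIFF
#'
#' Pages are written uncompressed, one per frame, at the stack's bit depth;
#' `readStack(writeStack(x))` reproduces pixel values bit-exactly.
#'
#' @param stack a [FrameStack-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeStack <- function(stack, path) {
  stopifnot(is(stack, "FrameStack"))
  validObject(stack)
  mx <- 2^stack@bitDepth - 1
  pages <- lapply(stack@frames, function(f) f / mx)
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  ok <- try(tiff::writeTIFF(pages, path,
                            bits.per.sample = as.integer(stack@bitDepth),
                            compression = "none"), silent = TRUE)
  if (inherits(ok, "try-error")) stop("cannot write TIFF: ", path)
  invisible(path)
}

#' Read/write the CSV stage-position log
#'
#' The log has one row per frame with columns `frame` (0-based index),
#' `time_s`, `x_mm`, `y_mm`, `z_mm`, `target_x_px`, `target_y_px`; the two
#' target columns are empty when no point was being tracked.  Values
#' round-trip at full double precision (>= 15 significant digits).
#'
#' @param path CSV file.
#' @return `readStageLog`: a `data.frame` with the columns above.
#' @export
readStageLog <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  log <- read.csv(path, na.strings = c("", "NA"))
  missing <- setdiff(.stageLogCols, names(log))
  if (length(missing))
    stop("stage log lacks column(s): ", paste(missing, collapse = ", "))
  log <- log[, .stageLogCols]
  if (nrow(log)) {
    if (any(diff(log$frame) <= 0))
      stop("stage log frame indices must be strictly increasing")
    if (any(diff(log$time_s) < 0))
      stop("stage log time_s must be nondecreasing")
  }
  log
}

#' @rdname readStageLog
#' @param log stage-log `data.frame`.
#' @export
writeStageLog <- function(log, path) {
  stopifnot(all(.stageLogCols %in% names(log)))
  out <- log[, .stageLogCols]
  num <- vapply(out, is.numeric, logical(1L))
  out[num] <- lapply(out[num], function(x) {
    s <- formatC(x, digits = 17, format = "g")
    s[is.na(x)] <- ""
    trimws(s)
  })
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Load a frame-synced two-channel recording from disk
#'
#' Reads the green and red TIFF stacks and the stage log and assembles a
#' validated [SyncedRecording-class].  When the two stacks differ in length
#' the trailing unmatched frames of the longer one are dropped with a
#' warning (the cameras are frame synced, so only paired frames are
#' meaningful); a stage log referencing frames beyond the paired length is
#' an error.
#'
#' @param greenPath,redPath multi-page TIFF stacks, one per channel.
#' @param logPath CSV stage log ([readStageLog()]).
#' @param pixelScaleUm micrometres per pixel.
#' @param frameRate frame rate in Hz.
#' @return A [SyncedRecording-class].
#' @export
loadRecording <- function(greenPath, redPath, logPath, pixelScaleUm,
                          frameRate = 10) {
  green <- readStack(greenPath, frameRate = frameRate)
  red <- readStack(redPath, frameRate = frameRate)
  ng <- nFrames(green); nr <- nFrames(red)
  if (ng != nr) {
    n <- min(ng, nr)
    warning(sprintf(
      "channel lengths differ (green %d, red %d); truncating to %d frames",
      ng, nr, n))
    green@frames <- green@frames[seq_len(n)]
    red@frames <- red@frames[seq_len(n)]
  }
  log <- readStageLog(logPath)
  if (nrow(log) && max(log$frame) >= nFrames(green))
    stop(sprintf("stage log references frame %d but only %d frames exist",
                 max(log$frame), nFrames(green)))
  SyncedRecording(green, red, log, pixelScaleUm)
}

#' Save a SyncedRecording to a directory
#'
#' Writes `green.tiff`, `red.tiff` (lossless 16-bit multi-page TIFF) and
#' `stage_log.csv`; loading them back with [loadRecording()] reproduces the
#' pixel values bit-exactly and the log rows exactly.
#'
#' @param rec a [SyncedRecording-class].
#' @param outDir output directory (created if needed).
#' @return Named character vector of the three paths, invisibly.
#' @export
saveRecording <- function(rec, outDir) {
  stopifnot(is(rec, "SyncedRecording"))
  validObject(rec)
  if (!dir.exists(outDir) &&
      !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", outDir)
  paths <- c(green = file.path(outDir, "green.tiff"),
             red = file.path(outDir, "red.tiff"),
             log = file.path(outDir, "stage_log.csv"))
  writeStack(rec@green, paths[["green"]])
  writeStack(rec@red, paths[["red"]])
  writeStageLog(rec@stage, paths[["log"]])
  invisible(paths)
}
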