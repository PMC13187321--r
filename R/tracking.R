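## Closed-loop centroid tracking (modes 1 and 2 of the acquisition
## software): threshold the target, take the centroid of the largest blob,
## convert the pixel error from image centre into a clamped proportional
## stage command, and log pixel coordinates so stage-relative positions can
## later be converted into absolute arena trajectories.

#' Tracker configuration
#'
#' @param mode `"dark_on_light"` (mode 1: a dark worm silhouetted on a
#'   light brightfield background) or `"bright_on_dark"` (mode 2: the
#'   brightest fluorescent object on a dark background).
#' @param threshold `"otsu"` for automatic thresholding, or a fixed numeric
#'   intensity.
#' @param minBlobPx blobs smaller than this are treated as no target.
#' @param deadbandPx per-axis pixel error below which no command is issued.
#' @param gain proportional command scaling in (0, 1].
#' @param maxStepMm per-frame per-axis command clamp (mm).
#' @return A list of class `trackerConfig`.
#' @export
trackerConfig <- function(mode = c("dark_on_light", "bright_on_dark"),
                          threshold = "otsu", minBlobPx = 20L,
                          deadbandPx = 5L, gain = 1.0, maxStepMm = 0.5) {
  mode <- match.arg(mode)
  stopifnot(deadbandPx >= 0, gain > 0, gain <= 1, maxStepMm > 0)
  if (!identical(threshold, "otsu") && !is.numeric(threshold))
    stop("threshold must be \"otsu\" or a numeric value")
  structure(list(mode = mode, threshold = threshold,
                 minBlobPx = as.integer(minBlobPx),
                 deadbandPx = as.integer(deadbandPx), gain = gain,
                 maxStepMm = maxStepMm),
            class = "trackerConfig")
}

## Otsu threshold of an integer frame (EBImage works on [0,1] images).
.otsu <- function(frame) {
  mx <- max(frame, 1L)
  EBImage::otsu(EBImage::Image(t(frame) / mx),
                range = c(0, 1), levels = 256L) * mx
}

## Largest connected component of a binary mask (8-connectivity); empty
## mask if the largest is below minPx or covers more than half the frame
## (a background-sized region is never the tracked object, e.g. the light
## background thresholded at the wrong polarity).  Ties on size are broken
## by smaller centroid distance to prevPx when given, else by label (scan)
## order.
.largestComponent <- function(bin, minPx, prevPx = NULL) {
  lab <- EBImage::bwlabel(EBImage::Image(t(bin) * 1))
  lab <- t(EBImage::imageData(lab))
  nl <- max(lab)
  if (nl == 0L) return(matrix(FALSE, nrow(bin), ncol(bin)))
  sizes <- tabulate(lab[lab > 0L], nbins = nl)
  best <- which(sizes == max(sizes))
  if (length(best) > 1L && !is.null(prevPx)) {
    d <- vapply(best, function(l) {
      idx <- which(lab == l, arr.ind = TRUE)
      sum((colMeans(idx)[2:1] - 1 - prevPx)^2)
    }, numeric(1L))
    best <- best[which.min(d)]
  } else best <- best[1L]
  if (sizes[best] < minPx || sizes[best] > 0.5 * length(bin))
    return(matrix(FALSE, nrow(bin), ncol(bin)))
  lab == best
}

#' Segment the tracking target in a frame
#'
#' Thresholds the frame at the configured polarity and returns the binary
#' mask of the largest connected component; an all-`FALSE` mask signals
#' "target lost" (largest blob below `minBlobPx`, or nothing on the
#' thresholded side).
#'
#' @param frame single-channel integer matrix.
#' @param cfg a [trackerConfig()].
#' @param prevPx previous target position c(x, y) for tie-breaking, or
#'   `NULL`.
#' @return Logical matrix the size of `frame`.
#' @export
segmentTarget <- function(frame, cfg, prevPx = NULL) {
  stopifnot(is.matrix(frame))
  thr <- if (identical(cfg$threshold, "otsu")) .otsu(frame) else cfg$threshold
  bin <- if (cfg$mode == "dark_on_light") frame < thr else frame > thr
  .largestComponent(bin, cfg$minBlobPx, prevPx)
}

#' Centroid of a binary mask
#'
#' Unweighted mean of the foreground pixel coordinates (x right, y down,
#' 0-based, pixel centres at integers).
#'
#' @param mask logical matrix.
#' @return c(x, y) in pixels, or `NULL` for an empty mask.
#' @export
blobCentroid <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (!nrow(idx)) return(NULL)
  c(x = mean(idx[, 2L]) - 1, y = mean(idx[, 1L]) - 1)
}

#' Convert a target pixel position into a centering stage command
#'
#' The command recentres the field of view on the target: per axis,
#' `command = gain * (point - image centre) * pixelScaleUm` (converted to
#' mm), zero inside the deadband, clamped to `maxStepMm`.  Under the
#' virtual rig, stage +x shifts the FOV +x in arena coordinates, so a
#' positive pixel error maps to a positive command.
#'
#' @param pointPx target c(x, y) in pixels.
#' @param imagePx raster size c(width, height).
#' @param pixelScaleUm micrometres per pixel.
#' @param cfg a [trackerConfig()].
#' @return c(dx_mm, dy_mm).
#' @export
centeringCommand <- function(pointPx, imagePx, pixelScaleUm, cfg) {
  centre <- (imagePx - 1) / 2
  err <- pointPx - centre
  cmd <- ifelse(abs(err) <= cfg$deadbandPx, 0,
                cfg$gain * err * pixelScaleUm / 1000)
  unname(pmax(pmin(cmd, cfg$maxStepMm), -cfg$maxStepMm))
}

#' Tracking controller for [runSession()]
#'
#' Wraps [segmentTarget()], [blobCentroid()] and [centeringCommand()] into
#' a controller closure.  Mode 1 tracks the brightfield channel, mode 2
#' the fluorescence channel.  When the target is lost the stage holds
#' position (no search pattern).
#'
#' @param cfg a [trackerConfig()].
#' @param pixelScaleUm micrometres per pixel of the rig.
#' @return A controller `function(bf, fl, stage, ctx)`.
#' @export
trackingController <- function(cfg, pixelScaleUm) {
  function(bf, fl, stage, ctx) {
    frame <- if (cfg$mode == "dark_on_light") bf else fl
    mask <- segmentTarget(frame, cfg, prevPx = ctx$prevPx)
    cen <- blobCentroid(mask)
    if (is.null(cen)) {
      list(commandMm = c(0, 0, 0), targetPx = NULL,
           ctx = list(prevPx = ctx$prevPx, lost = TRUE))
    } else {
      cmd <- centeringCommand(cen, c(ncol(frame), nrow(frame)),
                              pixelScaleUm, cfg)
      list(commandMm = c(cmd, 0), targetPx = cen,
           ctx = list(prevPx = cen, lost = FALSE))
    }
  }
}

#' Run a closed-loop tracking session on the virtual rig
#'
#' Runs [runSession()] with the tracking controller and reports the
#' per-frame pixel error of the tracked centroid from the image centre and
#' the fraction of frames where the target was lost.
#'
#' @param config a [rigConfig()].
#' @param trackerCfg a [trackerConfig()].
#' @param durationS session length (s).
#' @param seed RNG seed.
#' @param keepFrames,keepCenterlines see [runSession()].
#' @return list with `session` (the [runSession()] result) and `report`:
#'   a data.frame (`frame`, `error_px_x`, `error_px_y`, `lost`) plus
#'   attributes; and summary elements `lostFraction` and `maxErrorPx`.
#' @export
trackSession <- function(config, trackerCfg = trackerConfig(),
                         durationS = 60, seed = 1L, keepFrames = FALSE,
                         keepCenterlines = FALSE) {
  ses <- runSession(config, trackingController(trackerCfg,
                                               config$optics$pixelScaleUm),
                    durationS = durationS, seed = seed,
                    keepFrames = keepFrames,
                    keepCenterlines = keepCenterlines)
  log <- ses$log
  centre <- (config$optics$imagePx - 1) / 2
  err <- cbind(log$target_x_px - centre[1L], log$target_y_px - centre[2L])
  lost <- is.na(log$target_x_px)
  report <- data.frame(frame = log$frame,
                       error_px_x = err[, 1L], error_px_y = err[, 2L],
                       lost = lost)
  maxErr <- if (all(lost)) Inf else
    max(sqrt(err[!lost, 1L]^2 + err[!lost, 2L]^2))
  list(session = ses, report = report,
       lostFraction = mean(lost), maxErrorPx = maxErr)
}

#' Absolute arena trajectory from a stage log
#'
#' Converts stage-relative tracking into the worm's absolute position:
#' per frame, `arena = (stage - home) * 1000 + (target_px - image centre)
#' * pixelScaleUm` (um).  The result is continuous across pure stage
#' recentring moves because the pixel term compensates them exactly.
#'
#' @param stageLog stage-log data.frame with target pixel columns.
#' @param pixelScaleUm micrometres per pixel.
#' @param imagePx raster size c(width, height).
#' @param homeMm stage home position c(x, y) in mm (subtracted so the
#'   trajectory is relative to the arena home, e.g. a food patch centre).
#' @return data.frame (`frame`, `time_s`, `x_um`, `y_um`); rows without
#'   target coordinates are dropped with a warning.
#' @export
wormAbsolutePosition <- function(stageLog, pixelScaleUm, imagePx,
                                 homeMm = c(0, 0)) {
  has <- !is.na(stageLog$target_x_px) & !is.na(stageLog$target_y_px)
  if (!all(has))
    warning(sprintf("%d row(s) without target coordinates skipped",
                    sum(!has)))
  log <- stageLog[has, , drop = FALSE]
  centre <- (imagePx - 1) / 2
  data.frame(frame = log$frame, time_s = log$time_s,
             x_um = (log$x_mm - homeMm[1L]) * 1000 +
                    (log$target_x_px - centre[1L]) * pixelScaleUm,
             y_um = (log$y_mm - homeMm[2L]) * 1000 +
                    (log$target_y_px - centre[2L]) * pixelScaleUm)
}
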