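## Fluorescence quantification: brightest-N means, soma tracking, dF/F,
## signal-to-background ratio, ratiometric motion-artifact correction,
## rotational registration of neuron crops, and deterministic
## two-compartment (nrV/nrD) segmentation of the registered stack.

#' Mean of the n brightest pixels in a region
#'
#' The soma measurement: the average of the `n` largest pixel values
#' within the region (default n = 25).  Ties at the cutoff are broken in
#' largest-first scan order (stable sort), so exactly `n` values enter the
#' mean.
#'
#' @param frame single-channel intensity matrix.
#' @param region logical mask (same size as `frame`) or `NULL` for the
#'   whole frame.
#' @param n number of brightest pixels to average.
#' @return Mean intensity (counts).
#' @export
topNMean <- function(frame, region = NULL, n = 25L) {
  vals <- if (is.null(region)) as.vector(frame) else frame[region]
  if (length(vals) < n)
    stop(sprintf("region holds %d pixels, fewer than n = %d",
                 length(vals), n))
  mean(vals[order(vals, decreasing = TRUE)[seq_len(n)]])
}

#' Background intensity outside a dilated target mask
#'
#' Mean of the pixels outside a dilation of the target mask by (twice) its
#' own equivalent radius -- the background estimate used for
#' signal-to-background ratios and lost-target tests.
#'
#' @param frame intensity matrix.
#' @param mask logical target mask.
#' @return Mean background (counts).
#' @export
backgroundMean <- function(frame, mask) {
  if (!any(mask)) return(mean(frame))
  r <- 2L * max(1L, ceiling(sqrt(sum(mask) / pi)))
  brush <- EBImage::makeBrush(2L * r + 1L, shape = "disc")
  dil <- t(EBImage::imageData(
    EBImage::dilate(EBImage::Image(t(mask) * 1), brush))) > 0
  if (all(dil)) return(mean(frame[!mask]))
  mean(frame[!dil])
}

#' Track a bright soma through a stack
#'
#' Per frame, a square search window is recentred on the
#' intensity-weighted centroid of the brightest connected component found
#' within a margin of the previous window; the initial window defaults to
#' the brightest blob of frame 1.  The target counts as lost when its peak
#' falls below twice the background estimate (the window then holds
#' position).
#'
#' @param stack a [FrameStack-class] (fluorescence channel).
#' @param initCentrePx initial window centre c(x, y), or `NULL` to
#'   auto-detect.
#' @param sizePx window edge length (default 80, the neuron-crop size).
#' @param marginPx search margin added around the window.
#' @return A data.frame of class `somaTrack` (`frame`, `x_px`, `y_px`,
#'   `lost`) with attribute `sizePx`.
#' @export
trackSoma <- function(stack, initCentrePx = NULL, sizePx = 80L,
                      marginPx = 20L) {
  n <- nFrames(stack)
  f1 <- getFrame(stack, 1L)
  h <- nrow(f1); w <- ncol(f1)
  half <- sizePx / 2
  brightBlob <- function(sub) {
    thr <- .otsu(sub)
    lab <- EBImage::bwlabel(EBImage::Image(t(sub > thr) * 1))
    lab <- t(EBImage::imageData(lab))
    nl <- max(lab)
    if (nl == 0L) return(NULL)
    peaks <- vapply(seq_len(nl), function(l) max(sub[lab == l]), numeric(1L))
    lab == which.max(peaks)
  }
  wcentroid <- function(sub, m) {
    idx <- which(m, arr.ind = TRUE)
    wts <- sub[m]
    c(x = sum((idx[, 2L] - 1) * wts) / sum(wts),
      y = sum((idx[, 1L] - 1) * wts) / sum(wts))
  }
  if (is.null(initCentrePx)) {
    m <- brightBlob(f1)
    if (is.null(m)) stop("no bright blob found in frame 1")
    initCentrePx <- wcentroid(f1, m)
  }
  cen <- initCentrePx
  out <- data.frame(frame = seq_len(n) - 1L, x_px = NA_real_,
                    y_px = NA_real_, lost = FALSE)
  for (i in seq_len(n)) {
    fr <- getFrame(stack, i)
    r <- half + marginPx
    i0 <- max(0L, floor(cen[1L] - r)); i1 <- min(w - 1L, ceiling(cen[1L] + r))
    j0 <- max(0L, floor(cen[2L] - r)); j1 <- min(h - 1L, ceiling(cen[2L] + r))
    sub <- fr[(j0:j1) + 1L, (i0:i1) + 1L, drop = FALSE]
    m <- brightBlob(sub)
    lost <- TRUE
    if (!is.null(m) && sum(m) < 0.5 * length(m)) {
      bg <- backgroundMean(sub, m)
      if (is.finite(bg) && bg > 0 && max(sub[m]) >= 2 * bg) {
        wc <- wcentroid(sub, m)
        cen <- c(wc[1L] + i0, wc[2L] + j0)
        lost <- FALSE
      }
    }
    cen <- c(min(max(cen[1L], half), w - 1 - half),
             min(max(cen[2L], half), h - 1 - half))
    out$x_px[i] <- cen[1L]; out$y_px[i] <- cen[2L]; out$lost[i] <- lost
  }
  structure(out, sizePx = as.integer(sizePx), class = c("somaTrack",
                                                        "data.frame"))
}

#' Crop fixed-size windows around a tracked soma
#'
#' @param stack a [FrameStack-class].
#' @param track a [trackSoma()] result.
#' @return A [FrameStack-class] of `sizePx` x `sizePx` crops (edges padded
#'   with the frame median where the window leaves the sensor).
#' @export
cropSoma <- function(stack, track) {
  size <- attr(track, "sizePx")
  n <- nFrames(stack)
  stopifnot(nrow(track) == n)
  crops <- vector("list", n)
  for (i in seq_len(n)) {
    fr <- getFrame(stack, i)
    h <- nrow(fr); w <- ncol(fr)
    cx <- round(track$x_px[i]); cy <- round(track$y_px[i])
    i0 <- cx - size %/% 2L; j0 <- cy - size %/% 2L
    out <- matrix(as.integer(median(fr)), size, size)
    ii <- pmax(0L, i0):pmin(w - 1L, i0 + size - 1L)
    jj <- pmax(0L, j0):pmin(h - 1L, j0 + size - 1L)
    out[jj - j0 + 1L, ii - i0 + 1L] <- fr[jj + 1L, ii + 1L]
    crops[[i]] <- out
  }
  FrameStack(crops, frameRate = frameRate(stack), bitDepth = bitDepth(stack))
}

#' Relative fluorescence change dF/F
#'
#' Baseline F0 is the given percentile of the trace (default 10th);
#' `dff_t = (F_t - F0)/F0`.  The conventional summary is `max(dff)`, the
#' largest relative change observed.
#'
#' @param x a [CalciumTrace-class] or numeric vector of intensities.
#' @param baselinePercentile baseline percentile in [0, 1] (default 0.1).
#' @return For a `CalciumTrace`: the trace with `baselineF0` and `dff`
#'   filled in.  For a numeric vector: the dff vector with attribute
#'   `baselineF0`.
#' @rdname deltaFOverF
#' @export
setMethod("deltaFOverF", "CalciumTrace", function(x, baselinePercentile = 0.1) {
  f0 <- as.numeric(quantile(x@values, baselinePercentile))
  if (f0 <= 0) stop("baseline F0 is not positive")
  x@baselineF0 <- f0
  x@dff <- (x@values - f0) / f0
  validObject(x)
  x
})

#' @rdname deltaFOverF
#' @export
setMethod("deltaFOverF", "numeric", function(x, baselinePercentile = 0.1) {
  if (!length(x)) stop("empty trace")
  f0 <- as.numeric(quantile(x, baselinePercentile))
  if (f0 <= 0) stop("baseline F0 is not positive")
  structure((x - f0) / f0, baselineF0 = f0)
})

#' Signal-to-background ratio
#'
#' `SBR = median target pixel value / mean background`, reported to one
#' decimal place.
#'
#' @param signalMedian median pixel value of the target (counts).
#' @param backgroundMean mean background (counts, > 0).
#' @return Ratio rounded to one decimal.
#' @examples
#' sbr(15540, 3264)   # 4.8
#' sbr(37623, 1408)   # 26.7
#' @export
sbr <- function(signalMedian, backgroundMean) {
  if (backgroundMean <= 0) stop("background mean must be positive")
  round(signalMedian / backgroundMean, 1L)
}

#' Ratiometric motion-artifact correction
#'
#' Divides the activity channel by the activity-independent channel and
#' baselines the ratio: `R_t = G_t / Red_t`, `corrected = (R_t - R0)/R0`
#' with R0 the baseline percentile of R.  Any gain applied to both
#' channels simultaneously (motion, defocus) cancels exactly; this is a
#' transparent ratio correction, not a Bayesian artifact model.
#'
#' @param green,red [CalciumTrace-class]s or numeric vectors of equal
#'   length; `red` must be strictly positive.
#' @param baselinePercentile baseline percentile for R0.
#' @return Corrected trace (numeric) with attributes `r0` and `ratio`.
#' @export
ratiometricCorrect <- function(green, red, baselinePercentile = 0.1) {
  g <- if (is(green, "CalciumTrace")) green@values else as.numeric(green)
  r <- if (is(red, "CalciumTrace")) red@values else as.numeric(red)
  if (length(g) != length(r)) stop("channel lengths differ")
  if (any(r <= 0)) stop("red channel contains nonpositive values")
  ratio <- g / r
  r0 <- as.numeric(quantile(ratio, baselinePercentile))
  if (r0 <= 0) stop("ratio baseline is not positive")
  structure((ratio - r0) / r0, r0 = r0, ratio = ratio)
}

#' Rotationally register neuron crops by head orientation
#'
#' Rotates each crop about its centre by the negative of the per-frame
#' head orientation (bilinear interpolation, constant fill from a
#' background estimate), cancelling the rotation of the neuron as the
#' head turns: after registration the nose direction maps to +x and the
#' worm's ventral side to +y.
#'
#' @param crops a [FrameStack-class] of square crops.
#' @param headOrientationDeg one orientation per crop (degrees,
#'   [headOrientation()] convention).
#' @return A registered [FrameStack-class].
#' @export
rotateRegister <- function(crops, headOrientationDeg) {
  n <- nFrames(crops)
  if (length(headOrientationDeg) != n)
    stop("need one head orientation per crop")
  out <- vector("list", n)
  for (i in seq_len(n)) {
    fr <- getFrame(crops, i)
    bg <- median(fr[c(1L, nrow(fr)), ])
    img <- .rotateAbout(EBImage::Image(t(fr)), -headOrientationDeg[i], bg)
    m <- t(EBImage::imageData(img))
    out[[i]] <- .quantize(m, 2^bitDepth(crops) - 1)
  }
  FrameStack(out, frameRate = frameRate(crops), bitDepth = bitDepth(crops))
}

## Rotate an EBImage Image's content by angleDeg about the image centre
## (in (x, y-down) coordinates), keeping dimensions.  EBImage::affine maps
## input point p to p %*% A + b (row-vector convention), so A = t(R) and b
## fixes the centre.
.rotateAbout <- function(img, angleDeg, bg) {
  d <- dim(img)[1:2]
  th <- angleDeg * pi / 180
  cen <- matrix(d / 2, 1L)   # EBImage's affine origin is the pixel corner
  R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2L, byrow = TRUE)
  A <- t(R)
  off <- cen - cen %*% A
  EBImage::affine(img, rbind(A, off), filter = "bilinear",
                  output.dim = d, bg.col = bg)
}

#' Segment the two axonal compartments from a registered stack
#'
#' Thresholds the temporal-maximum projection (Otsu) and takes the two
#' largest connected components as the compartment masks, fixed for the
#' whole recording.  In registered coordinates the ventral side is +y
#' (larger row), so the component with the larger y centroid is labelled
#' nrV and the other nrD.
#'
#' @param registered a [rotateRegister()]ed [FrameStack-class].
#' @param minSizePx minimum component size (default 25 px).
#' @return list of class `compartmentMasks` with disjoint logical masks
#'   `nrv` and `nrd`.
#' @export
splitCompartments <- function(registered, minSizePx = 25L) {
  mp <- Reduce(pmax, frames(registered))
  thr <- .otsu(mp)
  lab <- t(EBImage::imageData(EBImage::bwlabel(EBImage::Image(t(mp > thr) * 1))))
  nl <- max(lab)
  if (nl < 2L) stop("fewer than two bright components in the max projection")
  sizes <- tabulate(lab[lab > 0L], nbins = nl)
  big <- order(sizes, decreasing = TRUE)[1:2]
  if (sizes[big[2L]] < minSizePx)
    stop("second compartment below minimum size")
  ys <- vapply(big, function(l) mean(which(lab == l, arr.ind = TRUE)[, 1L]),
               numeric(1L))
  nrvLab <- big[which.max(ys)]
  nrdLab <- big[which.min(ys)]
  structure(list(nrv = lab == nrvLab, nrd = lab == nrdLab),
            class = "compartmentMasks")
}

#' Per-compartment brightest-N traces
#'
#' @param registered registered [FrameStack-class].
#' @param masks a [splitCompartments()] result.
#' @param n brightest pixels averaged per compartment per frame.
#' @return list of two [CalciumTrace-class]s, `nrv` and `nrd`.
#' @export
compartmentTraces <- function(registered, masks, n = 25L) {
  vals <- vapply(frames(registered), function(fr)
    c(topNMean(fr, masks$nrv, n), topNMean(fr, masks$nrd, n)),
    numeric(2L))
  list(nrv = CalciumTrace(vals[1L, ], channel = "green"),
       nrd = CalciumTrace(vals[2L, ], channel = "green"))
}
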