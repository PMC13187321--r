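## Time-series analysis of behaviour and calcium traces: moving-average
## smoothing, min/max and head-angle normalization, adjacent-point
## derivatives, phase angles phi = atan2(scaled derivative, value), polar
## binning (24 x 15 degree bins), cross-correlation, gait frequency and
## event-aligned averaging.

#' Centred equally weighted moving average
#'
#' Window 5 at 10 Hz is the conventional 0.5 s smoothing for calcium
#' traces.  Edges use shrunken (one-sided) windows so the output has the
#' input length.
#'
#' @param x numeric trace.
#' @param window odd window length in frames (default 5).
#' @return Smoothed trace, same length as `x`.
#' @export
smoothMA <- function(x, window = 5L) {
  n <- length(x)
  if (window %% 2L == 0L) stop("window must be odd")
  if (window < 1L || window > n) stop("window must be in [1, length(x)]")
  half <- window %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Min/max normalization to [0, 1]
#'
#' @param x numeric trace with `max(x) > min(x)`.
#' @return `(x - min)/(max - min)`.
#' @export
minmaxNorm <- function(x) {
  r <- range(x, finite = TRUE)
  if (r[2L] <= r[1L]) stop("constant trace cannot be min/max normalized")
  (x - r[1L]) / (r[2L] - r[1L])
}

#' Normalize head angles to the deepest dorsal (-1) / ventral (+1) bend
#'
#' Ventral (positive) angles are divided by the maximum ventral excursion
#' and dorsal (negative) angles by the maximum dorsal excursion, so the
#' extremes map to exactly +1 and -1.  A one-sided trace (no excursion on
#' one side) is scaled on its populated side and flagged with attribute
#' `oneSided`.
#'
#' @param anglesDeg signed head angles (degrees, ventral positive).
#' @return Normalized values in [-1, 1], attribute `oneSided`.
#' @export
normHeadAngle <- function(anglesDeg) {
  vmax <- max(c(0, anglesDeg[anglesDeg > 0]), na.rm = TRUE)
  dmax <- max(c(0, -anglesDeg[anglesDeg < 0]), na.rm = TRUE)
  if (vmax == 0 && dmax == 0) stop("no head-angle excursion")
  oneSided <- vmax == 0 || dmax == 0
  if (oneSided)
    warning("one-sided head-angle excursion; unpopulated side passes through zero only")
  out <- anglesDeg
  out[anglesDeg > 0] <- anglesDeg[anglesDeg > 0] / vmax
  out[anglesDeg < 0] <- anglesDeg[anglesDeg < 0] / dmax
  structure(out, oneSided = oneSided)
}

#' Adjacent-point derivative
#'
#' First difference divided by `dt`, aligned to the later frame (length
#' `n - 1`).
#'
#' @param x numeric trace (length >= 2).
#' @param dt time step (s).
#' @return Derivative trace of length `length(x) - 1`.
#' @export
traceDerivative <- function(x, dt = 1) {
  if (length(x) < 2L) stop("need at least two points")
  diff(x) / dt
}

#' Phase angle of an oscillating signal
#'
#' `phi = atan2(dvalue * dscale, value)`: phase 0 at the positive peak
#' (deepest ventral bend for a normalized head angle), pi at the negative
#' peak, +pi/2 at the steepest rise.  `dscale` rescales the derivative so
#' a sinusoid traces a circle; the default is `max|value| / max|dvalue|`
#' per trace.
#'
#' @param value signal values (aligned with `dvalue`; when `dvalue` comes
#'   from [traceDerivative()] pass `value[-1]`, the later frames).
#' @param dvalue derivative values.
#' @param dscale derivative scaling; `NULL` for the per-trace default.
#' @return Phase angles in (-pi, pi].
#' @export
phaseAngle <- function(value, dvalue, dscale = NULL) {
  if (length(value) != length(dvalue))
    stop("value and dvalue must be aligned (equal length)")
  if (is.null(dscale)) {
    md <- max(abs(dvalue))
    dscale <- if (md > 0) max(abs(value)) / md else 1
  }
  stopifnot(dscale > 0)
  atan2(dvalue * dscale, value)
}

#' Phase series of an oscillating trace (the analysis recipe)
#'
#' Convenience wrapper assembling the standard phase pipeline for a
#' normalized trace: centred-difference derivative (`(x[i+1] -
#' x[i-1])/(2 dt)`, unbiased in phase, trimming one frame at each end)
#' and [phaseAngle()] with the per-trace default `dscale`.  Feed a
#' smoothed, normalized signal (e.g. [normHeadAngle()] of a smoothed
#' head-angle trace).
#'
#' @param x normalized trace.
#' @param dt frame interval (s).
#' @return list(`idx` (frame indices into `x`), `value`, `dvalue`,
#'   `phi`).
#' @export
phaseSeries <- function(x, dt = 1) {
  n <- length(x)
  if (n < 3L) stop("need at least three points")
  d <- (x[3:n] - x[1:(n - 2L)]) / (2 * dt)
  v <- x[2:(n - 1L)]
  list(idx = 2:(n - 1L), value = v, dvalue = d,
       phi = phaseAngle(v, d))
}

#' Polar (phase-binned) profile of a signal
#'
#' Bins the signal by phase angle into `nBins` equal bins spanning 360
#' degrees (default 24 bins of 15 degrees, edges at multiples of 15
#' degrees from -180) and reports the per-bin mean, sem and count; empty
#' bins report `NA`.
#'
#' @param phi phase angles (radians, (-pi, pi]).
#' @param signal aligned signal values.
#' @param nBins number of bins (default 24).
#' @return data.frame of class `polarProfile`: `binCentreDeg`, `mean`,
#'   `sem`, `n`.
#' @export
polarProfile <- function(phi, signal, nBins = 24L) {
  if (length(phi) != length(signal)) stop("phi and signal must be aligned")
  widthDeg <- 360 / nBins
  deg <- phi * 180 / pi
  deg[deg >= 180] <- deg[deg >= 180] - 360    # half-open [edge, edge+width)
  bin <- floor((deg + 180) / widthDeg) + 1L
  bin[bin > nBins] <- nBins
  centres <- -180 + widthDeg * (seq_len(nBins) - 0.5)
  mean_ <- sem_ <- rep(NA_real_, nBins)
  n_ <- integer(nBins)
  for (b in seq_len(nBins)) {
    v <- signal[bin == b & is.finite(signal)]
    n_[b] <- length(v)
    if (length(v)) {
      mean_[b] <- mean(v)
      sem_[b] <- if (length(v) > 1L) sd(v) / sqrt(length(v)) else NA_real_
    }
  }
  structure(data.frame(binCentreDeg = centres, mean = mean_, sem = sem_,
                       n = n_),
            class = c("polarProfile", "data.frame"))
}

#' Normalized cross-correlation over integer lags
#'
#' Pearson correlation of the overlapping segments of `a` and `b` at every
#' lag in `[-maxLag, maxLag]`.  Positive lag means `b` lags `a` (`b[t]`
#' resembles `a[t - lag]`); `peakLag` is the lag of maximum correlation.
#'
#' @param a,b equal-length numeric traces (length >= 2 * maxLag).
#' @param maxLag maximum lag in frames.
#' @return list of class `crossCorr`: `lags`, `correlation`, `peakLag`.
#' @export
xcorrTrace <- function(a, b, maxLag) {
  n <- length(a)
  if (length(b) != n) stop("traces must have equal length")
  if (n < 2L * maxLag) stop("traces shorter than 2 * maxLag")
  lags <- -maxLag:maxLag
  cc <- vapply(lags, function(l) {
    if (l >= 0L) { av <- a[seq_len(n - l)]; bv <- b[seq_len(n - l) + l] }
    else { av <- a[seq_len(n + l) - l]; bv <- b[seq_len(n + l)] }
    if (sd(av) == 0 || sd(bv) == 0)
      stop("zero-variance segment at lag ", l)
    cor(av, bv)
  }, numeric(1L))
  structure(list(lags = lags, correlation = cc,
                 peakLag = lags[which.max(cc)]),
            class = "crossCorr")
}

#' Dominant gait frequency from a head-angle trace
#'
#' Periodogram (Hann taper) of the mean-subtracted trace; the dominant
#' frequency is the peak in (0, frameRate/2).  The peak is flagged
#' low-confidence unless its power reaches `prominence` times the median
#' spectral power: for white noise the largest of n periodogram ordinates
#' only reaches about `log(n)/log(2)` times the median (around 8-10 for
#' typical trace lengths), while a genuine oscillation concentrates power
#' hundreds-fold, so the default 15 separates the two.
#'
#' @param x head-angle trace (at least ~5 gait periods for a stable peak).
#' @param frameRate sampling rate (Hz).
#' @param prominence peak-to-median power ratio required for confidence.
#' @return list(`frequencyHz`, `confident`, `freq`, `power`).
#' @export
gaitFrequency <- function(x, frameRate, prominence = 15) {
  n <- length(x)
  if (n < 8L) stop("trace too short")
  if (var(x) == 0) stop("flat trace has no gait frequency")
  w <- 0.5 * (1 - cos(2 * pi * seq_len(n) / (n + 1)))  # Hann taper
  X <- fft((x - mean(x)) * w)
  half <- floor(n / 2)
  power <- Mod(X[2:(half + 1L)])^2
  freq <- (1:half) * frameRate / n
  pk <- which.max(power)
  list(frequencyHz = freq[pk],
       confident = power[pk] >= prominence * median(power),
       freq = freq, power = power)
}

#' Event-aligned mean +/- sem of traces
#'
#' Extracts windows around each event, averages across events per offset
#' and reports the standard error.  Events whose window exceeds the trace
#' contribute only their in-range offsets (per-offset counts keep the
#' bookkeeping); sem is `NA` where fewer than two events contribute.
#'
#' @param traces numeric vector or list of numeric vectors (one per
#'   recording).
#' @param eventFrames integer vector or list of vectors of event frames
#'   (1-based, matching `traces`).
#' @param window frames around the event: a single number w for
#'   `[-w, +w]`, or c(before, after).
#' @return data.frame (`offset`, `mean`, `sem`, `n`).
#' @export
alignToEvent <- function(traces, eventFrames, window) {
  if (!is.list(traces)) traces <- list(traces)
  if (!is.list(eventFrames)) eventFrames <- list(eventFrames)
  if (length(traces) != length(eventFrames))
    stop("traces and eventFrames must match")
  if (length(window) == 1L) window <- c(window, window)
  offs <- -window[1L]:window[2L]
  segs <- list()
  for (i in seq_along(traces)) {
    tr <- traces[[i]]
    for (ev in eventFrames[[i]]) {
      pos <- ev + offs
      v <- rep(NA_real_, length(offs))
      ok <- pos >= 1L & pos <= length(tr)
      v[ok] <- tr[pos[ok]]
      segs[[length(segs) + 1L]] <- v
    }
  }
  if (!length(segs)) stop("no events")
  m <- do.call(rbind, segs)
  n_ <- colSums(!is.na(m))
  mean_ <- colMeans(m, na.rm = TRUE)
  mean_[n_ == 0L] <- NA_real_
  sem_ <- apply(m, 2L, function(col) {
    v <- col[!is.na(col)]
    if (length(v) > 1L) sd(v) / sqrt(length(v)) else NA_real_
  })
  data.frame(offset = offs, mean = mean_, sem = sem_, n = n_)
}
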