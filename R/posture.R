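## Offline body-posture pipeline: worm segmentation, midline
## skeletonization (28 points for muscle imaging, 12 for head-angle
## analysis), per-segment bend angles (ventral positive), dorsal/ventral
## muscle ROIs from perpendiculars to the midline, and gait summaries.

#' Segment the worm body in a frame
#'
#' Otsu threshold at the requested polarity, largest connected component,
#' holes filled.  An unusable frame (no blob of at least `minBlobPx`)
#' returns an all-`FALSE` mask with attribute `usable = FALSE`.
#'
#' @param frame single-channel integer matrix.
#' @param polarity `"dark"` (worm dark on light background, brightfield)
#'   or `"bright"`.
#' @param minBlobPx minimum body size in pixels.
#' @return Logical mask with attribute `usable`.
#' @export
binarizeWorm <- function(frame, polarity = c("dark", "bright"),
                         minBlobPx = 100L) {
  polarity <- match.arg(polarity)
  thr <- .otsu(frame)
  bin <- if (polarity == "dark") frame < thr else frame > thr
  mask <- .largestComponent(bin, minBlobPx)
  if (any(mask)) {
    filled <- EBImage::fillHull(EBImage::Image(t(mask) * 1))
    mask <- t(EBImage::imageData(filled)) > 0
  }
  attr(mask, "usable") <- any(mask)
  mask
}

## Zhang-Suen binary thinning to a 1-px skeleton (8-connected).
.thinMask <- function(mask) {
  m <- mask * 1L
  h <- nrow(m); w <- ncol(m)
  sh <- function(x, dr, dc) {
    out <- matrix(0L, h, w)
    r1 <- max(1L, 1L - dr); r2 <- min(h, h - dr)
    c1 <- max(1L, 1L - dc); c2 <- min(w, w - dc)
    if (r1 <= r2 && c1 <= c2)
      out[r1:r2, c1:c2] <- x[(r1 + dr):(r2 + dr), (c1 + dc):(c2 + dc)]
    out
  }
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      p2 <- sh(m, -1L, 0L); p3 <- sh(m, -1L, 1L); p4 <- sh(m, 0L, 1L)
      p5 <- sh(m, 1L, 1L);  p6 <- sh(m, 1L, 0L);  p7 <- sh(m, 1L, -1L)
      p8 <- sh(m, 0L, -1L); p9 <- sh(m, -1L, -1L)
      B <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      A <- (p2 == 0L & p3 == 1L) + (p3 == 0L & p4 == 1L) +
           (p4 == 0L & p5 == 1L) + (p5 == 0L & p6 == 1L) +
           (p6 == 0L & p7 == 1L) + (p7 == 0L & p8 == 1L) +
           (p8 == 0L & p9 == 1L) + (p9 == 0L & p2 == 1L)
      if (sub == 1L) {
        c1 <- p2 * p4 * p6 == 0L; c2 <- p4 * p6 * p8 == 0L
      } else {
        c1 <- p2 * p4 * p8 == 0L; c2 <- p2 * p6 * p8 == 0L
      }
      del <- m == 1L & B >= 2L & B <= 6L & A == 1L & c1 & c2
      if (any(del)) { m[del] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  m == 1L
}

## Longest path (graph diameter) through a skeleton; returns ordered
## (row, col) coordinates.  Off-path side branches longer than
## `pruneFrac` of the main path raise an error (coiled/self-touching).
.skeletonPath <- function(skel, pruneFrac = 0.1) {
  idx <- which(skel, arr.ind = TRUE)
  np <- nrow(idx)
  if (np < 3L) stop("skeleton too small")
  idm <- matrix(0L, nrow(skel), ncol(skel))
  idm[idx] <- seq_len(np)
  h <- nrow(skel); w <- ncol(skel)
  off <- cbind(c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
               c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L))
  nbrs <- lapply(seq_len(np), function(i) {
    r <- idx[i, 1L] + off[, 1L]; c <- idx[i, 2L] + off[, 2L]
    ok <- r >= 1L & r <= h & c >= 1L & c <= w
    ids <- idm[cbind(r[ok], c[ok])]
    ids[ids > 0L]
  })
  bfs <- function(start) {
    dist <- rep(-1L, np); par <- rep(0L, np)
    dist[start] <- 0L
    q <- start; qi <- 1L
    while (qi <= length(q)) {
      v <- q[qi]; qi <- qi + 1L
      for (u in nbrs[[v]]) if (dist[u] < 0L) {
        dist[u] <- dist[v] + 1L; par[u] <- v; q <- c(q, u)
      }
    }
    list(dist = dist, par = par)
  }
  b1 <- bfs(1L)
  a <- which.max(b1$dist)
  b2 <- bfs(a)
  b <- which.max(b2$dist)
  path <- b
  while (b2$par[path[1L]] > 0L) path <- c(b2$par[path[1L]], path)
  offPath <- setdiff(which(b1$dist >= 0L), path)
  if (length(offPath) > pruneFrac * length(path)) {
    # measure the largest connected off-path branch, not the total
    rem <- skel
    rem[idx[path, , drop = FALSE]] <- FALSE
    if (any(rem)) {
      lab <- t(EBImage::imageData(EBImage::bwlabel(EBImage::Image(t(rem) * 1))))
      if (max(tabulate(lab[lab > 0L])) > pruneFrac * length(path))
        stop("skeleton has major side branches (coiled or self-touching worm)")
    }
  }
  idx[path, , drop = FALSE]
}

## Light moving-average smoothing of path coordinates (shrunken windows at
## the ends) to suppress pixel staircase noise.
.smoothPath <- function(xy, window = 5L) {
  n <- nrow(xy)
  if (n < window) return(xy)
  half <- window %/% 2L
  out <- xy
  for (j in 1:2) {
    cs <- cumsum(c(0, xy[, j]))
    lo <- pmax(seq_len(n) - half, 1L); hi <- pmin(seq_len(n) + half, n)
    out[, j] <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  out
}

## Extend a path end along its local direction to the mask boundary (the
## thinned skeleton stops about half a body width short of the tips).
.extendEnd <- function(pt, dirv, mask, maxStep = 60L) {
  nv <- sqrt(sum(dirv^2))
  if (nv < 1e-9) return(NULL)
  dirv <- dirv / nv
  h <- nrow(mask); w <- ncol(mask)
  last <- NULL
  for (s in seq(0.5, maxStep, by = 0.5)) {
    p <- pt + s * dirv
    r <- round(p[1L]) + 1L; c <- round(p[2L]) + 1L
    if (r < 1L || r > h || c < 1L || c > w || !mask[r, c]) break
    last <- p
  }
  last
}

#' Extract an ordered midline from a worm mask
#'
#' Topological thinning (Zhang-Suen) to a 1-px skeleton, longest path
#' between skeleton endpoints, light coordinate smoothing, extension of
#' both ends to the mask boundary (nose/tail), then arc-length resampling
#' to `nPoints` equally spaced points.  Orientation is provisional until
#' [orientMidlines()]; a skeleton with major side branches (a coiled or
#' self-touching worm) is an error.
#'
#' @param mask logical body mask from [binarizeWorm()].
#' @param nPoints number of midline points (28 for muscle ROIs, 12 for
#'   head-angle analysis).
#' @return A list of class `midline`: `pointsPx` (`nPoints` x 2 matrix,
#'   columns x, y, 0-based pixels, provisional head first),
#'   `arcSpacingPx`, `headConfident` (`NA` until oriented).
#' @export
extractMidline <- function(mask, nPoints = 28L) {
  stopifnot(nPoints >= 3L)
  if (!any(mask)) stop("empty mask")
  # thinning cost scales with the raster, so work on the body's bounding
  # box (1 px pad) and shift coordinates back afterwards
  idxAll <- which(mask, arr.ind = TRUE)
  r0 <- max(1L, min(idxAll[, 1L]) - 1L); r1 <- min(nrow(mask), max(idxAll[, 1L]) + 1L)
  c0 <- max(1L, min(idxAll[, 2L]) - 1L); c1 <- min(ncol(mask), max(idxAll[, 2L]) + 1L)
  sub <- mask[r0:r1, c0:c1, drop = FALSE]
  off <- c(r0 - 1L, c0 - 1L)
  path <- .skeletonPath(.thinMask(sub))
  path[, 1L] <- path[, 1L] + off[1L]
  path[, 2L] <- path[, 2L] + off[2L]
  path <- .smoothPath(path)
  # (row, col) -> 0-based (y, x)
  py <- path[, 1L] - 1; px <- path[, 2L] - 1
  k <- min(5L, nrow(path) - 1L)
  headExt <- .extendEnd(c(path[1L, 1L], path[1L, 2L]),
                        c(path[1L, 1L] - path[1L + k, 1L],
                          path[1L, 2L] - path[1L + k, 2L]), mask)
  n <- nrow(path)
  tailExt <- .extendEnd(c(path[n, 1L], path[n, 2L]),
                        c(path[n, 1L] - path[n - k, 1L],
                          path[n, 2L] - path[n - k, 2L]), mask)
  if (!is.null(headExt)) { py <- c(headExt[1L] - 1, py); px <- c(headExt[2L] - 1, px) }
  if (!is.null(tailExt)) { py <- c(py, tailExt[1L] - 1); px <- c(px, tailExt[2L] - 1) }
  arc <- c(0, cumsum(sqrt(diff(px)^2 + diff(py)^2)))
  sOut <- seq(0, arc[length(arc)], length.out = nPoints)
  pts <- cbind(x = approx(arc, px, xout = sOut, ties = "ordered")$y,
               y = approx(arc, py, xout = sOut, ties = "ordered")$y)
  spacing <- sqrt(diff(pts[, 1L])^2 + diff(pts[, 2L])^2)
  structure(list(pointsPx = pts, nPoints = as.integer(nPoints),
                 arcSpacingPx = mean(spacing), headConfident = NA),
            class = "midline")
}

#' Resample a midline to a different point count
#'
#' Arc-length resampling of the existing points (e.g. 28 -> 12 for the
#' head-angle definition).
#'
#' @param m a `midline`.
#' @param nPoints new point count.
#' @return A `midline` with `nPoints` points, orientation preserved.
#' @export
resampleMidline <- function(m, nPoints) {
  p <- m$pointsPx
  arc <- c(0, cumsum(sqrt(diff(p[, 1L])^2 + diff(p[, 2L])^2)))
  sOut <- seq(0, arc[length(arc)], length.out = nPoints)
  pts <- cbind(x = approx(arc, p[, 1L], xout = sOut, ties = "ordered")$y,
               y = approx(arc, p[, 2L], xout = sOut, ties = "ordered")$y)
  structure(list(pointsPx = pts, nPoints = as.integer(nPoints),
                 arcSpacingPx = mean(sqrt(diff(pts[, 1L])^2 +
                                          diff(pts[, 2L])^2)),
                 headConfident = m$headConfident),
            class = "midline")
}

#' Orient a time series of midlines consistently, head first
#'
#' Per frame the midline is flipped to minimize point-to-point displacement
#' from the previous frame; the global head/tail choice then puts the head
#' at the end that leads the net displacement (forward runs).  When the
#' net centroid displacement is below one worm length the head assignment
#' is ambiguous and `headConfident` is set to `FALSE` on all midlines.
#'
#' @param midlines list of `midline` objects in time order (>= 2).
#' @return The list, consistently oriented, with `headConfident` set.
#' @export
orientMidlines <- function(midlines) {
  stopifnot(length(midlines) >= 2L)
  n <- length(midlines)
  for (i in 2:n) {
    p <- midlines[[i]]$pointsPx
    q <- midlines[[i - 1L]]$pointsPx
    dFwd <- mean(sqrt(rowSums((p - q)^2)))
    dRev <- mean(sqrt(rowSums((p[rev(seq_len(nrow(p))), ] - q)^2)))
    if (dRev < dFwd)
      midlines[[i]]$pointsPx <- p[rev(seq_len(nrow(p))), ]
  }
  cenFirst <- colMeans(midlines[[1L]]$pointsPx)
  cenLast <- colMeans(midlines[[n]]$pointsPx)
  netVec <- cenLast - cenFirst
  net <- sqrt(sum(netVec^2))
  bodyLen <- mean(vapply(midlines, function(m)
    sum(sqrt(diff(m$pointsPx[, 1L])^2 + diff(m$pointsPx[, 2L])^2)),
    numeric(1L)))
  confident <- net >= bodyLen
  if (confident) {
    # head end = the end whose mean projection on the motion vector leads
    proj <- function(endRow) {
      mean(vapply(midlines, function(m) {
        sum((m$pointsPx[endRow, ] - colMeans(m$pointsPx)) * netVec) / net
      }, numeric(1L)))
    }
    if (proj(1L) < proj(nrow(midlines[[1L]]$pointsPx))) {
      midlines <- lapply(midlines, function(m) {
        m$pointsPx <- m$pointsPx[rev(seq_len(nrow(m$pointsPx))), ]
        m
      })
    }
  }
  lapply(midlines, function(m) { m$headConfident <- confident; m })
}

#' Signed bend angle of each segment relative to its anterior neighbour
#'
#' For an `n`-point midline there are `n - 1` segments and `n - 2` relative
#' angles (28 points -> 26 angles): `angle_i = atan2(cross(v_{i-1}, v_i),
#' dot(v_{i-1}, v_i))` on consecutive head-to-tail segment vectors, in
#' degrees, ventral positive (a bend toward the worm's ventral side).
#'
#' @param m an oriented `midline`.
#' @return Numeric vector of `nPoints - 2` angles (degrees).
#' @export
bendAngles <- function(m) {
  p <- m$pointsPx
  v <- diff(p)
  len <- sqrt(rowSums(v^2))
  if (any(len < 1e-9)) stop("zero-length midline segment")
  n <- nrow(v)
  # cross(v_i, v_{i-1}) > 0 for a bend toward the ventral side (the
  # plus-normal side of the head-to-tail traversal), either orientation
  cr <- v[-1L, 1L] * v[-n, 2L] - v[-1L, 2L] * v[-n, 1L]
  dt <- rowSums(v[-n, , drop = FALSE] * v[-1L, , drop = FALSE])
  atan2(cr, dt) * 180 / pi
}

#' Head angle of a 12-point midline
#'
#' Signed angle (degrees, ventral positive) between the vectors joining
#' midline points 3 to 2 and 2 to 0 (0-based from the nose) of the
#' 12-point skeleton.
#'
#' @param m an oriented `midline` with 12 points.
#' @return Angle in degrees.
#' @export
headAngle <- function(m) {
  if (m$nPoints != 12L)
    stop("head angle is defined on the 12-point midline")
  .headAngleFromPoints(m$pointsPx)
}

#' Absolute head orientation of a midline
#'
#' Direction (degrees, atan2 convention in image coordinates) of the nose
#' vector, point 2 to point 0; used to rotationally register neuron crops.
#'
#' @param m an oriented `midline`.
#' @return Orientation in degrees.
#' @export
headOrientation <- function(m) {
  v <- m$pointsPx[1L, ] - m$pointsPx[3L, ]
  atan2(v[2L], v[1L]) * 180 / pi
}

#' Dorsal and ventral muscle ROIs along the midline
#'
#' At each of the 28 midline points the perpendicular to the local tangent
#' is traced to the mask boundary on both sides; quadrilateral ROIs are
#' formed between consecutive perpendiculars and split at the midline,
#' giving exactly 27 ROIs per side.  For intensity measurement every body
#' pixel is assigned to its nearest segment and side (an equivalent
#' disjoint partition of the body).  Which geometric side is dorsal is a
#' label: the default matches a worm whose ventral side faces +y; use
#' `dorsalSide = "plus"` (or [postureAnalysis()]'s self-calibration) to
#' flip.
#'
#' @param m an oriented 28-point `midline`.
#' @param mask the body mask the midline was extracted from.
#' @param dorsalSide `"minus"` or `"plus"`: which normal side is dorsal.
#' @return A list of class `lateralRois`: `polys$dorsal` / `polys$ventral`
#'   (27 quadrilaterals each, 4 x 2 matrices), `segIdx` and `sideIdx`
#'   (per-pixel assignment matrices; 0 = not body, side 1 = dorsal,
#'   2 = ventral), `valid` (27 x 2 logical), `dorsalSide`.
#' @export
lateralRois <- function(m, mask, dorsalSide = c("minus", "plus")) {
  dorsalSide <- match.arg(dorsalSide)
  p <- m$pointsPx
  nP <- nrow(p)
  if (nP != 28L) stop("lateral ROIs are defined on the 28-point midline")
  h <- nrow(mask); w <- ncol(mask)
  # tangents (central differences) and unit "plus" normals (T_y, -T_x)
  tp <- rbind(p[2L, ] - p[1L, ],
              p[3:nP, ] - p[1:(nP - 2L), ],
              p[nP, ] - p[nP - 1L, ])
  tl <- sqrt(rowSums(tp^2))
  nrm <- cbind(tp[, 2L], -tp[, 1L]) / tl
  inMask <- function(q) {
    r <- round(q[2L]) + 1L; c <- round(q[1L]) + 1L
    r >= 1L && r <= h && c >= 1L && c <= w && mask[r, c]
  }
  march <- function(pt, dirv) {
    if (!inMask(pt)) return(NULL)
    last <- pt
    for (s in seq(0.5, max(h, w), by = 0.5)) {
      q <- pt + s * dirv
      if (!inMask(q)) break
      last <- q
    }
    last
  }
  bPlus <- vector("list", nP); bMinus <- vector("list", nP)
  for (i in seq_len(nP)) {
    bPlus[i] <- list(march(p[i, ], nrm[i, ]))
    bMinus[i] <- list(march(p[i, ], -nrm[i, ]))
  }
  quad <- function(i, b) {
    if (is.null(b[[i]]) || is.null(b[[i + 1L]])) return(NULL)
    rbind(p[i, ], b[[i]], b[[i + 1L]], p[i + 1L, ])
  }
  polyPlus <- lapply(1:(nP - 1L), quad, b = bPlus)
  polyMinus <- lapply(1:(nP - 1L), quad, b = bMinus)
  valid <- cbind(minus = !vapply(polyMinus, is.null, logical(1L)),
                 plus = !vapply(polyPlus, is.null, logical(1L)))

  # per-pixel partition: nearest segment midpoint, side by normal dot sign
  idx <- which(mask, arr.ind = TRUE)
  pxy <- cbind(idx[, 2L] - 1, idx[, 1L] - 1)
  mids <- (p[-nP, ] + p[-1L, ]) / 2
  midN <- (nrm[-nP, ] + nrm[-1L, ]) / 2
  nSeg <- nP - 1L
  dmin <- rep(Inf, nrow(pxy)); kmin <- rep(1L, nrow(pxy))
  for (k in seq_len(nSeg)) {
    d2 <- (pxy[, 1L] - mids[k, 1L])^2 + (pxy[, 2L] - mids[k, 2L])^2
    upd <- d2 < dmin
    dmin[upd] <- d2[upd]; kmin[upd] <- k
  }
  sidePlus <- rowSums((pxy - mids[kmin, , drop = FALSE]) *
                      midN[kmin, , drop = FALSE]) > 0
  segIdx <- matrix(0L, h, w); sideIdx <- matrix(0L, h, w)
  segIdx[idx] <- kmin
  dorsalIsMinus <- dorsalSide == "minus"
  sideIdx[idx] <- ifelse(sidePlus == dorsalIsMinus, 2L, 1L)
  if (dorsalIsMinus) {
    polys <- list(dorsal = polyMinus, ventral = polyPlus)
    valid <- valid[, c("minus", "plus")]
  } else {
    polys <- list(dorsal = polyPlus, ventral = polyMinus)
    valid <- valid[, c("plus", "minus")]
  }
  colnames(valid) <- c("dorsal", "ventral")
  structure(list(polys = polys, segIdx = segIdx, sideIdx = sideIdx,
                 valid = valid, dorsalSide = dorsalSide),
            class = "lateralRois")
}

#' Mean intensity per muscle ROI
#'
#' @param frame single-channel intensity matrix.
#' @param rois a [lateralRois()] object for the same frame geometry.
#' @return 27 x 2 matrix (columns `dorsal`, `ventral`); `NA` where the ROI
#'   was flagged invalid or holds no pixels.
#' @export
roiMeans <- function(frame, rois) {
  out <- matrix(NA_real_, 27L, 2L, dimnames = list(NULL, c("dorsal", "ventral")))
  sel <- rois$segIdx > 0L
  seg <- rois$segIdx[sel]; side <- rois$sideIdx[sel]; val <- frame[sel]
  for (s in 1:2) {
    means <- tapply(val[side == s], seg[side == s], mean)
    out[as.integer(names(means)), s] <- means
  }
  out[!rois$valid] <- NA_real_
  out
}

#' ROI pixel areas
#'
#' @param rois a [lateralRois()] object.
#' @return 27 x 2 matrix of pixel counts (columns `dorsal`, `ventral`).
#' @export
roiAreas <- function(rois) {
  out <- matrix(0L, 27L, 2L, dimnames = list(NULL, c("dorsal", "ventral")))
  sel <- rois$segIdx > 0L
  seg <- rois$segIdx[sel]; side <- rois$sideIdx[sel]
  for (s in 1:2) {
    cnt <- table(factor(seg[side == s], levels = 1:27))
    out[, s] <- as.integer(cnt)
  }
  out
}

#' Midline displacement profile across a session
#'
#' Per frame, the principal axis through the midline points is fitted;
#' the displacement at body position `i` is the RMS over frames of the
#' perpendicular distance of point `i` from that axis.
#'
#' @param midlines list of oriented `midline` objects.
#' @param pixelScaleUm micrometres per pixel (1 for a profile in px).
#' @return Numeric vector of length `nPoints` (um).
#' @export
midlineDisplacement <- function(midlines, pixelScaleUm = 1) {
  d2 <- vapply(midlines, function(m) {
    p <- sweep(m$pointsPx, 2L, colMeans(m$pointsPx))
    ax <- eigen(crossprod(p), symmetric = TRUE)$vectors[, 1L]
    (p[, 1L] * ax[2L] - p[, 2L] * ax[1L])^2
  }, numeric(midlines[[1L]]$nPoints))
  sqrt(rowMeans(d2)) * pixelScaleUm
}

#' Head-angle histogram and dispersion
#'
#' @param anglesDeg head angles over time (degrees, >= 100 frames).
#' @param binWidthDeg histogram bin width (degrees).
#' @return list(`breaks`, `mids`, `counts`, `sdDeg`, `n`).
#' @export
headAngleDistribution <- function(anglesDeg, binWidthDeg = 2) {
  anglesDeg <- anglesDeg[is.finite(anglesDeg)]
  if (length(anglesDeg) < 100L)
    stop("need at least 100 frames for a head-angle distribution")
  lo <- floor(min(anglesDeg) / binWidthDeg) * binWidthDeg
  hi <- ceiling(max(anglesDeg) / binWidthDeg) * binWidthDeg
  if (hi <= lo) hi <- lo + binWidthDeg
  breaks <- seq(lo, hi, by = binWidthDeg)
  counts <- tabulate(findInterval(anglesDeg, breaks,
                                  rightmost.closed = TRUE),
                     nbins = length(breaks) - 1L)
  list(breaks = breaks, mids = breaks[-length(breaks)] + binWidthDeg / 2,
       counts = counts, sdDeg = sd(anglesDeg), n = length(anglesDeg))
}

#' Run the posture pipeline over a brightfield stack
#'
#' Segments every frame, extracts and orients midlines, and assembles the
#' per-frame outputs into kymograph-ready matrices: bend angles
#' (frames x 26), dorsal/ventral ROI mean intensities (frames x 27, from
#' the paired fluorescence stack when given) and head angles from the
#' 12-point resampling.  When `flipDV = "auto"` and fluorescence is given,
#' the dorsal/ventral labelling is self-calibrated: dorsal-ROI intensity
#' must correlate positively with dorsal bending; if it does not, ROI
#' labels and angle signs are flipped together.
#'
#' @param brightfield a [FrameStack-class] (worm dark on light).
#' @param fluorescence optional paired [FrameStack-class] for ROI means.
#' @param nPoints midline points (default 28).
#' @param flipDV `"auto"`, `"none"` or `"flip"`.
#' @param stageLog optional stage log of the recording.  Under closed-loop
#'   tracking the stage cancels the worm's motion in image coordinates, so
#'   head/tail orientation (which needs the direction of travel) must be
#'   decided in arena coordinates; when a log is given the midlines are
#'   shifted by the per-frame stage position for that step.
#' @param pixelScaleUm micrometres per pixel (required with `stageLog`).
#' @return list of class `postureAnalysis`: `midlines`, `angles`
#'   (frames x nPoints-2), `headAngleDeg`, `headOrientationDeg`, `dorsal`,
#'   `ventral` (frames x 27 or `NULL`), `usable` (logical per frame),
#'   `flipped`.
#' @export
postureAnalysis <- function(brightfield, fluorescence = NULL, nPoints = 28L,
                            flipDV = c("auto", "none", "flip"),
                            stageLog = NULL, pixelScaleUm = NULL) {
  flipDV <- match.arg(flipDV)
  if (!is.null(stageLog) && is.null(pixelScaleUm))
    stop("pixelScaleUm is required when a stageLog is given")
  n <- nFrames(brightfield)
  needMasks <- !is.null(fluorescence) && nPoints == 28L
  masks <- vector("list", n)
  midlines <- vector("list", n)
  usable <- logical(n)
  for (i in seq_len(n)) {
    mask <- binarizeWorm(getFrame(brightfield, i))
    if (needMasks) masks[[i]] <- mask   # only kept when ROIs are measured
    if (!attr(mask, "usable")) next
    m <- try(extractMidline(mask, nPoints), silent = TRUE)
    if (inherits(m, "try-error")) next
    midlines[[i]] <- m
    usable[i] <- TRUE
  }
  ok <- which(usable)
  if (length(ok) < 2L) stop("fewer than two usable frames")
  if (is.null(stageLog)) {
    midlines[ok] <- orientMidlines(midlines[ok])
  } else {
    # orient in arena coordinates, then strip the stage offset again
    offs <- cbind(stageLog$x_mm, stageLog$y_mm) * 1000 / pixelScaleUm
    shifted <- lapply(ok, function(i) {
      m <- midlines[[i]]
      m$pointsPx <- sweep(m$pointsPx, 2L, offs[i, ], "+")
      m
    })
    shifted <- orientMidlines(shifted)
    midlines[ok] <- lapply(seq_along(ok), function(j) {
      m <- shifted[[j]]
      m$pointsPx <- sweep(m$pointsPx, 2L, offs[ok[j], ], "-")
      m
    })
  }

  nAng <- nPoints - 2L
  angles <- matrix(NA_real_, n, nAng)
  headA <- rep(NA_real_, n)
  headO <- rep(NA_real_, n)
  dorsal <- ventral <- NULL
  if (!is.null(fluorescence)) dorsal <- ventral <- matrix(NA_real_, n, 27L)
  for (i in ok) {
    m <- midlines[[i]]
    angles[i, ] <- bendAngles(m)
    m12 <- if (nPoints == 12L) m else resampleMidline(m, 12L)
    headA[i] <- headAngle(m12)
    headO[i] <- headOrientation(m)
    if (!is.null(fluorescence) && nPoints == 28L) {
      rois <- lateralRois(m, masks[[i]])
      rm <- roiMeans(getFrame(fluorescence, i), rois)
      dorsal[i, ] <- rm[, "dorsal"]; ventral[i, ] <- rm[, "ventral"]
    }
  }

  flipped <- FALSE
  if (flipDV == "flip") flipped <- TRUE
  if (flipDV == "auto" && !is.null(dorsal)) {
    # dorsal muscle calcium must rise with dorsal (negative) bending
    j <- seq_len(min(nAng, 26L))
    cc <- cor(as.vector(dorsal[ok, j + 1L, drop = FALSE]),
              as.vector(pmax(0, -angles[ok, j, drop = FALSE])),
              use = "complete.obs")
    if (is.finite(cc) && cc < 0) flipped <- TRUE
  }
  if (flipped) {
    angles <- -angles
    headA <- -headA
    if (!is.null(dorsal)) { tmp <- dorsal; dorsal <- ventral; ventral <- tmp }
  }
  structure(list(midlines = midlines, angles = angles, headAngleDeg = headA,
                 headOrientationDeg = headO, dorsal = dorsal,
                 ventral = ventral, usable = usable, flipped = flipped),
            class = "postureAnalysis")
}
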