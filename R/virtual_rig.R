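## Virtual rig: a ground-truthed simulation of the microscope platform.
## An undulating worm crawls in a fixed arena; the optics (camera + stage)
## view a field of view whose arena position is set by the XY stage, with
## defocus blur set by the Z axis.  Every downstream module is tested
## against sessions generated here.

#' Gait parameters of the simulated worm
#'
#' The worm is a travelling-wave sinusoid: the lateral offset of the body
#' point at axial coordinate `u` (micrometres from the head along the body
#' axis) at time `t` is `A * sin(2*pi*(u/lambda - f*t))`, advected forward
#' at crawl speed `v`.  The axial extent is solved at each instant so the
#' total arc length of the midline equals `lengthUm`.
#'
#' @param amplitudeUm peak lateral displacement A (um).
#' @param wavelengthUm undulation wavelength lambda along the body axis (um).
#' @param frequencyHz gait frequency f (Hz).
#' @param speedUmS forward crawl speed v (um/s).
#' @param lengthUm worm length L (um).
#' @param widthProfile function of normalized arc position s in [0,1]
#'   returning the body half-width (um); must vanish at both ends
#'   (tapered nose and tail).
#' @return A validated list of class `gaitParams`.
#' @examples
#' g <- gaitParams()
#' cl <- centerlineAt(0, g, nPoints = 28)
#' @export
gaitParams <- function(amplitudeUm = 100, wavelengthUm = 500,
                       frequencyHz = 0.3, speedUmS = 150, lengthUm = 1000,
                       widthProfile = function(s) 35 * sin(pi * s)^0.4) {
  stopifnot(amplitudeUm >= 0, wavelengthUm > 0, frequencyHz > 0,
            speedUmS >= 0, lengthUm > 0)
  if (abs(widthProfile(0)) > 1e-3 || abs(widthProfile(1)) > 1e-3)
    stop("widthProfile must vanish at s = 0 and s = 1 (tapered nose/tail)")
  structure(list(amplitudeUm = amplitudeUm, wavelengthUm = wavelengthUm,
                 frequencyHz = frequencyHz, speedUmS = speedUmS,
                 lengthUm = lengthUm, widthProfile = widthProfile),
            class = "gaitParams")
}

#' Fluorescent reporter configuration for the virtual rig
#'
#' Three reporter kinds are simulated.  `muscle`: body-wall muscle bands
#' whose drive is the rectified signed midline curvature (dorsal drive =
#' `max(0, -kappa)`, ventral = `max(0, +kappa)`, curvature normalized to its
#' gait maximum), so calcium rises in dorsal muscle during dorsal bends.
#' `soma`: a single cell body at arc position `somaPositionS` whose drive
#' follows `0.5*(1 + normalized head angle)`.  `axon_compartments`: a
#' small tonic soma blob (the stable structure the crop window tracks)
#' plus two axonal blobs anterior of it, offset perpendicular to the
#' head direction, with ventral (nrV) drive =
#' `max(0, +normalized head angle)` and dorsal (nrD) drive =
#' `max(0, -normalized head angle)`, emulating compartmentalized axonal
#' calcium that peaks at the deepest ventral/dorsal head bend.
#'
#' @param kind `"muscle"`, `"soma"` or `"axon_compartments"`.
#' @param gain fluorescence (camera counts) per unit drive (drive is
#'   normalized to [0, 1]).
#' @param phaseLagS delay (s) between mechanical drive and fluorescence.
#' @param baseline background-equivalent intensity (counts) filling the
#'   whole fluorescence frame.
#' @param somaPositionS arc position of the soma/axon (0 = nose).
#' @param blobSigmaUm Gaussian radius of soma/axon blobs (um).
#' @param compartmentAntUm anterior offset of the axonal compartments from
#'   the soma (um, axon kind only).
#' @param compartmentSepUm perpendicular offset of each compartment from
#'   the head axis (um, axon kind only).
#' @return A validated list of class `reporterConfig`.
#' @export
reporterConfig <- function(kind = c("muscle", "soma", "axon_compartments"),
                           gain = 8000, phaseLagS = 0, baseline = 200,
                           somaPositionS = 0.1, blobSigmaUm = 4,
                           compartmentAntUm = 20, compartmentSepUm = 12) {
  kind <- match.arg(kind)
  stopifnot(gain >= 0, phaseLagS >= 0, baseline >= 0,
            somaPositionS >= 0, somaPositionS <= 1, blobSigmaUm > 0,
            compartmentAntUm >= 0, compartmentSepUm > 0)
  structure(list(kind = kind, gain = gain, phaseLagS = phaseLagS,
                 baseline = baseline, somaPositionS = somaPositionS,
                 blobSigmaUm = blobSigmaUm,
                 compartmentAntUm = compartmentAntUm,
                 compartmentSepUm = compartmentSepUm),
            class = "reporterConfig")
}

#' Optics and camera configuration
#'
#' The field of view is 1440 x 900 um (7.5x objective); the camera raster
#' maps it at `fovUm/imagePx` micrometres per pixel (the two axes must
#' agree within 1%).  Defocus is modelled as a Gaussian blur of
#' `sigma_um = |z - focusZMm| * blurUmPerMm`, which is monotone in the
#' focus error -- all the focus-lock controller requires.  Optional Poisson
#' (shot) noise is applied first, then additive Gaussian read noise, then
#' clipping and quantization to `bitDepth`.
#'
#' @param fovUm field of view c(width, height) in um.
#' @param imagePx raster c(width, height) in px.
#' @param focusZMm in-focus stage Z (mm).
#' @param blurUmPerMm defocus blur scale (um of Gaussian sigma per mm of
#'   focus error).
#' @param noiseSd Gaussian read-noise sd (counts); 0 disables.
#' @param poisson logical, apply Poisson shot noise.
#' @param bitDepth sensor bit depth.
#' @param bgBrightfield brightfield background level (counts); the worm
#'   silhouettes dark against it.
#' @param wormLevel brightfield level inside the worm body (counts).
#' @return A validated list of class `opticsConfig`.
#' @export
opticsConfig <- function(fovUm = c(1440, 900), imagePx = c(240, 150),
                         focusZMm = 5, blurUmPerMm = 40, noiseSd = 60,
                         poisson = FALSE, bitDepth = 16L,
                         bgBrightfield = 30000, wormLevel = 6000) {
  sx <- fovUm[1L] / imagePx[1L]; sy <- fovUm[2L] / imagePx[2L]
  if (abs(sx - sy) / sx > 0.01)
    stop("anisotropic pixels: fov/image ratios differ by more than 1%")
  stopifnot(blurUmPerMm >= 0, noiseSd >= 0, bitDepth >= 8)
  structure(list(fovUm = fovUm, imagePx = as.integer(imagePx),
                 focusZMm = focusZMm, blurUmPerMm = blurUmPerMm,
                 noiseSd = noiseSd, poisson = isTRUE(poisson),
                 bitDepth = as.integer(bitDepth),
                 bgBrightfield = bgBrightfield, wormLevel = wormLevel,
                 pixelScaleUm = (sx + sy) / 2),
            class = "opticsConfig")
}

#' The virtual XYZ stage
#'
#' XY travel is 50.4 mm per axis (the tracking area of the physical
#' platform); positions are clamped to `[0, travelMm]` and per-step motion
#' to `maxSpeedMmS * dt`.
#'
#' @param xMm,yMm,zMm initial position (mm).
#' @param travelMm XY travel per axis (mm).
#' @param travelZMm Z travel (mm).
#' @param maxSpeedMmS maximum speed per axis (mm/s).
#' @return A list of class `virtualStage`.
#' @export
virtualStage <- function(xMm = 25.2, yMm = 25.2, zMm = 5, travelMm = 50.4,
                         travelZMm = 20, maxSpeedMmS = 10) {
  stopifnot(xMm >= 0, xMm <= travelMm, yMm >= 0, yMm <= travelMm,
            zMm >= 0, zMm <= travelZMm, maxSpeedMmS > 0)
  structure(list(xMm = xMm, yMm = yMm, zMm = zMm, travelMm = travelMm,
                 travelZMm = travelZMm, maxSpeedMmS = maxSpeedMmS),
            class = "virtualStage")
}

#' Step the virtual stage by a commanded displacement
#'
#' Per-axis motion is clamped to `maxSpeedMmS * dt` and the resulting
#' position to the travel range; clamping is the contract, not an error.
#'
#' @param stage a [virtualStage()].
#' @param commandMm c(dx, dy) or c(dx, dy, dz) in mm.
#' @param dt time step (s), > 0.
#' @return The stepped `virtualStage`.
#' @export
stageStep <- function(stage, commandMm, dt) {
  stopifnot(dt > 0)
  if (length(commandMm) == 2L) commandMm <- c(commandMm, 0)
  lim <- stage$maxSpeedMmS * dt
  d <- pmax(pmin(commandMm, lim), -lim)
  stage$xMm <- min(max(stage$xMm + d[1L], 0), stage$travelMm)
  stage$yMm <- min(max(stage$yMm + d[2L], 0), stage$travelMm)
  stage$zMm <- min(max(stage$zMm + d[3L], 0), stage$travelZMm)
  stage
}

## --- worm geometry -------------------------------------------------------

## Dense sample of the worm curve at time t: axial extent solved so the
## midline arc length equals gait$lengthUm.  Returns arena-coordinate
## points (um, head first), the axial coordinate u and the wave phase.
.wormCurve <- function(t, gait, nDense = 512L, originUm = c(25200, 25200)) {
  A <- gait$amplitudeUm; lam <- gait$wavelengthUm
  f <- gait$frequencyHz; L <- gait$lengthUm
  headX <- originUm[1L] + gait$speedUmS * t
  ud <- seq(0, L, length.out = nDense)
  th <- 2 * pi * (ud / lam - f * t)
  yd <- A * sin(th)
  seg <- sqrt(diff(ud)^2 + diff(yd)^2)
  ca <- c(0, cumsum(seg))
  list(x = headX - ud, y = originUm[2L] + yd, u = ud, arc = ca,
       theta = th, headX = headX)
}

#' Analytic worm centerline at a time point
#'
#' Returns `nPoints` points (head first) equally spaced in arc length along
#' the travelling-sinusoid midline, in arena coordinates (um; x right,
#' y down -- the worm's ventral side is +y).  Total arc length equals
#' `gait$lengthUm` within 1%.
#'
#' @param t time (s).
#' @param gait a [gaitParams()].
#' @param nPoints number of points (>= 3).
#' @param originUm arena position (um) of the head at t = 0.
#' @return `nPoints` x 2 matrix with columns `x`, `y` (um).
#' @export
centerlineAt <- function(t, gait, nPoints = 28L, originUm = c(25200, 25200)) {
  stopifnot(nPoints >= 3L)
  cv <- .wormCurve(t, gait, originUm = originUm)
  L <- gait$lengthUm
  sArc <- seq(0, min(L, max(cv$arc)), length.out = nPoints)
  ux <- approx(cv$arc, cv$u, xout = sArc, ties = "ordered")$y
  th <- 2 * pi * (ux / gait$wavelengthUm - gait$frequencyHz * t)
  cbind(x = cv$headX - ux,
        y = originUm[2L] + gait$amplitudeUm * sin(th))
}

## Signed normalized curvature at given axial coordinates and time.
## Positive = ventral bend (body concave toward +y).  Normalized by the
## gait's maximum curvature A*(2*pi/lambda)^2 so drives live in [-1, 1].
.curvatureNorm <- function(u, t, gait) {
  A <- gait$amplitudeUm; k <- 2 * pi / gait$wavelengthUm
  if (A == 0) return(rep(0, length(u)))
  th <- k * u - 2 * pi * gait$frequencyHz * t
  yp <- A * k * cos(th)
  ypp <- -A * k^2 * sin(th)
  (ypp / (1 + yp^2)^1.5) / (A * k^2)
}

## Signed head angle (degrees, ventral positive) from an ordered midline:
## angle between the vectors p3->p2 and p2->p0 of the 12-point skeleton
## (0-based point labels).  Shared by the rig ground truth (analytic
## centerline) and the posture pipeline (image-extracted midline).
.headAngleFromPoints <- function(p) {
  v1 <- p[3L, ] - p[4L, ]    # points 3 -> 2 (0-based) = rows 4 -> 3
  v2 <- p[1L, ] - p[3L, ]    # points 2 -> 0 (0-based) = rows 3 -> 1
  if (all(v1 == 0) || all(v2 == 0)) stop("coincident midline points")
  # anterior-pointing chain: cross(v1, v2) > 0 for a bend toward the
  # ventral side (the plus-normal side of the head-to-tail traversal)
  cr <- v1[1L] * v2[2L] - v1[2L] * v2[1L]
  dt <- sum(v1 * v2)
  atan2(cr, dt) * 180 / pi
}

## Ground-truth head angle at time t from the analytic 12-point midline.
.headAngleGT <- function(t, gait, originUm = c(25200, 25200)) {
  .headAngleFromPoints(centerlineAt(t, gait, nPoints = 12L,
                                    originUm = originUm))
}

#' Full simulated worm state at a time point
#'
#' Bundles everything the renderer and the ground-truth log need: a dense
#' equally spaced centerline, per-point normalized signed curvature
#' (ventral positive), the ground-truth head angle (12-point definition)
#' and its gait-maximum normalization.
#'
#' @inheritParams centerlineAt
#' @param nDense number of dense centerline points used for rendering.
#' @param haMaxDeg head-angle normalization (deg); computed from the gait
#'   if `NULL`.
#' @return A list of class `wormState` with elements `timeS`, `centerline`
#'   (nDense x 2, um), `arcS` (normalized arc positions), `curvature`,
#'   `headAngleDeg`, `haNorm`, `gait`.
#' @export
wormStateAt <- function(t, gait, nDense = 61L, originUm = c(25200, 25200),
                        haMaxDeg = NULL) {
  cl <- centerlineAt(t, gait, nPoints = nDense, originUm = originUm)
  u <- (originUm[1L] + gait$speedUmS * t) - cl[, 1L]
  kap <- .curvatureNorm(u, t, gait)
  if (is.null(haMaxDeg)) haMaxDeg <- .headAngleMax(gait, originUm)
  ha <- .headAngleGT(t, gait, originUm)
  structure(list(timeS = t, centerline = cl,
                 arcS = seq(0, 1, length.out = nDense), curvature = kap,
                 headAngleDeg = ha,
                 haNorm = if (haMaxDeg > 0) ha / haMaxDeg else 0,
                 haMaxDeg = haMaxDeg, originUm = originUm, gait = gait),
            class = "wormState")
}

## Peak |head angle| over one gait cycle (normalization for drives).
.headAngleMax <- function(gait, originUm = c(25200, 25200)) {
  ts <- seq(0, 1 / gait$frequencyHz, length.out = 64L)
  max(abs(vapply(ts, .headAngleGT, numeric(1L), gait = gait,
                 originUm = originUm)))
}

## --- rendering -----------------------------------------------------------

## Reporter drives for a state, with per-reporter phase lag applied by
## re-evaluating the mechanical signal at t - phaseLagS.
.reporterDrives <- function(state, rep) {
  g <- state$gait; tl <- state$timeS - rep$phaseLagS
  if (rep$kind == "muscle") {
    u <- (state$originUm[1L] + g$speedUmS * state$timeS) - state$centerline[, 1L]
    kap <- .curvatureNorm(u, tl, g)
    list(ventral = pmax(0, kap), dorsal = pmax(0, -kap))
  } else {
    ha <- .headAngleGT(tl, g, state$originUm)
    han <- if (state$haMaxDeg > 0) ha / state$haMaxDeg else 0
    if (rep$kind == "soma") list(soma = 0.5 * (1 + max(-1, min(1, han))))
    else list(nrv = max(0, han), nrd = max(0, -han))
  }
}

#' Render the two camera channels for a worm state
#'
#' Brightfield: high background with the worm body silhouetted dark (the
#' red transmission channel of the physical rig).  Fluorescence: constant
#' reporter baseline plus per-reporter emission -- muscle bands on the
#' bent side of the body, or Gaussian soma/axon blobs.  Both channels are
#' then blurred by the defocus model, noised and quantized.  Consumes the
#' caller's RNG stream; seed before calling for reproducibility.
#'
#' @param state a [wormStateAt()] state.
#' @param stage a [virtualStage()] giving the FOV arena position (the FOV
#'   top-left corner sits at the stage XY position; stage +x shifts the
#'   FOV +x in arena coordinates) and the Z focus error.
#' @param optics an [opticsConfig()].
#' @param reporters list of [reporterConfig()]s (possibly empty).
#' @return list with integer matrices `brightfield` and `fluorescence`
#'   (row = y, col = x) and logical `empty` (worm fully outside the FOV).
#' @export
renderChannels <- function(state, stage, optics, reporters = list()) {
  w <- optics$imagePx[1L]; h <- optics$imagePx[2L]
  sc <- optics$pixelScaleUm
  x0 <- stage$xMm * 1000; y0 <- stage$yMm * 1000
  cl <- state$centerline
  cx <- (cl[, 1L] - x0) / sc
  cy <- (cl[, 2L] - y0) / sc
  hw <- state$gait$widthProfile(state$arcS) / sc
  baseline <- 0
  for (rp in reporters) baseline <- max(baseline, rp$baseline)
  bf <- matrix(optics$bgBrightfield, h, w)
  fl <- matrix(baseline, h, w)

  marg <- max(hw) + 2
  i0 <- max(0L, floor(min(cx) - marg)); i1 <- min(w - 1L, ceiling(max(cx) + marg))
  j0 <- max(0L, floor(min(cy) - marg)); j1 <- min(h - 1L, ceiling(max(cy) + marg))
  empty <- i0 > i1 || j0 > j1
  if (!empty) {
    xs <- i0:i1; ys <- j0:j1
    nx <- length(xs); ny <- length(ys)
    # nearest-centerline-point labelling, restricted to a local window
    # around each point (the body is a union of discs of radius hw)
    dmin <- matrix(Inf, ny, nx); kmin <- matrix(1L, ny, nx)
    wrad <- max(hw) + 2
    for (k in seq_len(nrow(cl))) {
      a0 <- max(1L, floor(cx[k] - wrad) - i0 + 1L)
      a1 <- min(nx, ceiling(cx[k] + wrad) - i0 + 1L)
      b0 <- max(1L, floor(cy[k] - wrad) - j0 + 1L)
      b1 <- min(ny, ceiling(cy[k] + wrad) - j0 + 1L)
      if (a0 > a1 || b0 > b1) next
      d2 <- outer((ys[b0:b1] - cy[k])^2, (xs[a0:a1] - cx[k])^2, "+")
      cur <- dmin[b0:b1, a0:a1]
      upd <- d2 < cur
      cur[upd] <- d2[upd]
      dmin[b0:b1, a0:a1] <- cur
      kk <- kmin[b0:b1, a0:a1]
      kk[upd] <- k
      kmin[b0:b1, a0:a1] <- kk
    }
    body <- dmin <= hw[kmin]^2
    if (any(body)) {
      sub <- bf[ys + 1L, xs + 1L, drop = FALSE]
      sub[body] <- optics$wormLevel
      bf[ys + 1L, xs + 1L] <- sub

      for (rp in reporters) {
        if (rp$kind == "muscle") {
          dr <- .reporterDrives(state, rp)
          # side of the midline: ventral normal = head->tail tangent
          # rotated so that it points toward the worm's ventral (+y) side
          n <- nrow(cl)
          tx <- cl[pmin(seq_len(n) + 1L, n), 1L] - cl[pmax(seq_len(n) - 1L, 1L), 1L]
          ty <- cl[pmin(seq_len(n) + 1L, n), 2L] - cl[pmax(seq_len(n) - 1L, 1L), 2L]
          vnx <- ty; vny <- -tx    # (Ty, -Tx): ventral for head->tail order
          PX <- matrix(xs, ny, nx, byrow = TRUE)
          PY <- matrix(ys, ny, nx)
          k <- kmin[body]
          side <- (PX[body] - cx[k]) * (vnx[k] / sc) +
                  (PY[body] - cy[k]) * (vny[k] / sc)
          drive <- ifelse(side > 0, dr$ventral[k], dr$dorsal[k])
          subf <- fl[ys + 1L, xs + 1L, drop = FALSE]
          subf[body] <- subf[body] + rp$gain * drive
          fl[ys + 1L, xs + 1L] <- subf
        }
      }
    }
  }

  # point reporters render independently of the body raster
  for (rp in reporters) {
    if (rp$kind == "muscle") next
    dr <- .reporterDrives(state, rp)
    sp <- .arcPointPx(cl, rp$somaPositionS, cx, cy)
    sig <- rp$blobSigmaUm / sc
    if (rp$kind == "soma") {
      fl <- .addBlob(fl, sp["x"], sp["y"], sig, rp$gain * dr$soma)
    } else {
      # tonic soma blob (small, bright: the stable tracking anchor) with
      # the two compartments anterior of it, perpendicular to the head
      # direction; the head direction is the chord from skeleton point 2
      # to point 0 of the 12-point midline -- the same definition the
      # posture pipeline measures, so rotational registration can cancel
      # the axon's rotation exactly
      p0 <- .arcPointPx(cl, 0, cx, cy)
      p2 <- .arcPointPx(cl, 2 / 11, cx, cy)
      hd <- c(p0["x"] - p2["x"], p0["y"] - p2["y"])
      hd <- hd / sqrt(sum(hd^2))
      vn <- c(-hd[2L], hd[1L]) * (rp$compartmentSepUm / sc)
      ant <- hd * (rp$compartmentAntUm / sc)
      fl <- .addBlob(fl, sp["x"], sp["y"], 0.6 * sig, rp$gain)
      fl <- .addBlob(fl, sp["x"] + ant[1L] + vn[1L],
                     sp["y"] + ant[2L] + vn[2L], sig,
                     0.75 * rp$gain * dr$nrv)
      fl <- .addBlob(fl, sp["x"] + ant[1L] - vn[1L],
                     sp["y"] + ant[2L] - vn[2L], sig,
                     0.75 * rp$gain * dr$nrd)
    }
  }

  sigUm <- abs(stage$zMm - optics$focusZMm) * optics$blurUmPerMm
  sigPx <- sigUm / sc
  if (sigPx > 0.05) {
    bf <- .gblur(bf, sigPx)
    fl <- .gblur(fl, sigPx)
  }
  mx <- 2^optics$bitDepth - 1
  list(brightfield = .quantize(.noise(bf, optics), mx),
       fluorescence = .quantize(.noise(fl, optics), mx),
       empty = empty)
}

## Pixel coordinates of the centerline point at normalized arc position s.
.arcPointPx <- function(cl, s, cx, cy) {
  n <- nrow(cl)
  idx <- 1 + s * (n - 1)
  lo <- floor(idx); hi <- min(lo + 1, n); fr <- idx - lo
  c(x = (1 - fr) * cx[lo] + fr * cx[hi],
    y = (1 - fr) * cy[lo] + fr * cy[hi])
}

## Add a Gaussian blob (amplitude amp, sd sig px) at floating-point pixel
## position (px, py) into frame m, over a +/-4 sigma window.
.addBlob <- function(m, px, py, sig, amp) {
  if (amp <= 0) return(m)
  h <- nrow(m); w <- ncol(m)
  r <- ceiling(4 * sig)
  i0 <- max(0L, floor(px - r)); i1 <- min(w - 1L, ceiling(px + r))
  j0 <- max(0L, floor(py - r)); j1 <- min(h - 1L, ceiling(py + r))
  if (i0 > i1 || j0 > j1) return(m)
  xs <- i0:i1; ys <- j0:j1
  g <- amp * exp(-outer((ys - py)^2, (xs - px)^2, "+") / (2 * sig^2))
  m[ys + 1L, xs + 1L] <- m[ys + 1L, xs + 1L] + g
  m
}

.gblur <- function(m, sigma) {
  out <- EBImage::gblur(m, sigma = sigma)
  as.matrix(out)
}

.noise <- function(m, optics) {
  if (optics$poisson) m[] <- rpois(length(m), pmax(m, 0))
  if (optics$noiseSd > 0) m <- m + rnorm(length(m), 0, optics$noiseSd)
  m
}

.quantize <- function(m, mx) {
  m <- round(pmin(pmax(m, 0), mx))
  storage.mode(m) <- "integer"
  m
}

## --- sessions ------------------------------------------------------------

#' Assemble a virtual-rig session configuration
#'
#' @param gait a [gaitParams()].
#' @param optics an [opticsConfig()].
#' @param reporters list of [reporterConfig()]s.
#' @param frameRateHz acquisition rate (Hz).
#' @param originUm arena position of the worm head at t = 0 (um).
#' @param startZMm initial stage Z (mm; defaults to in focus).
#' @param stage a [virtualStage()]; by default positioned so the FOV is
#'   centred on the worm's initial centroid.
#' @return A list of class `rigConfig`.
#' @export
rigConfig <- function(gait = gaitParams(), optics = opticsConfig(),
                      reporters = list(), frameRateHz = 10,
                      originUm = c(25200, 25200), startZMm = NULL,
                      stage = NULL) {
  stopifnot(frameRateHz >= 1)
  if (is.null(stage)) {
    cl0 <- centerlineAt(0, gait, nPoints = 28L, originUm = originUm)
    cen <- colMeans(cl0)
    stage <- virtualStage(
      xMm = (cen[1L] - optics$fovUm[1L] / 2) / 1000,
      yMm = (cen[2L] - optics$fovUm[2L] / 2) / 1000,
      zMm = if (is.null(startZMm)) optics$focusZMm else startZMm)
  } else if (!is.null(startZMm)) stage$zMm <- startZMm
  structure(list(gait = gait, optics = optics, reporters = reporters,
                 frameRateHz = frameRateHz, originUm = originUm,
                 stage = stage),
            class = "rigConfig")
}

## Evaluate an expression under a fixed RNG seed, restoring the caller's
## RNG state afterwards (all session stochasticity flows through this).
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

#' Run a closed-loop virtual-rig session
#'
#' Per frame: advance the worm, render both channels at the current stage
#' position, query the controller for a stage command, step the stage.
#' The controller is any `function(brightfield, fluorescence, stage, ctx)`
#' returning `list(commandMm = c(dx, dy, dz), targetPx = c(x, y) | NULL,
#' ctx = <state carried to the next frame>)`; `NULL` means a fixed stage.
#' Identical `seed` and config give bit-identical output.
#'
#' @param config a [rigConfig()].
#' @param controller controller callable or `NULL`.
#' @param durationS session length (s).
#' @param seed integer RNG seed for all stochastic elements.
#' @param keepFrames keep rendered frames (`TRUE`), or drop them
#'   (`FALSE`, for long sessions where only the log/ground truth matter).
#' @param keepCenterlines store the ground-truth centerline per frame.
#' @return list with `recording` (a [SyncedRecording-class], or `NULL`
#'   when `keepFrames = FALSE`), `log` (the stage log data.frame) and
#'   `truth`: per-frame data.frame (`frame`, `time_s`, centroid/head arena
#'   position in um, `head_angle_deg`, `ha_norm`, reporter drives,
#'   `out_of_fov`) plus, for a muscle reporter, `dorsalDrive` and
#'   `ventralDrive` matrices (frames x 27 segments) and optionally
#'   `centerlines` (list of 28 x 2 matrices, um).
#' @export
runSession <- function(config, controller = NULL, durationS, seed = 1L,
                       keepFrames = TRUE, keepCenterlines = FALSE) {
  stopifnot(inherits(config, "rigConfig"), durationS > 0)
  fps <- config$frameRateHz
  n <- max(1L, round(durationS * fps))
  dt <- 1 / fps
  gait <- config$gait; optics <- config$optics
  haMax <- .headAngleMax(gait, config$originUm)
  muscleRep <- Filter(function(r) r$kind == "muscle", config$reporters)
  pointRep <- Filter(function(r) r$kind != "muscle", config$reporters)

  .withSeed(seed, {
    stage <- config$stage
    gFr <- if (keepFrames) vector("list", n) else NULL
    rFr <- if (keepFrames) vector("list", n) else NULL
    cls <- if (keepCenterlines) vector("list", n) else NULL
    log <- data.frame(frame = seq_len(n) - 1L, time_s = (seq_len(n) - 1L) * dt,
                      x_mm = NA_real_, y_mm = NA_real_, z_mm = NA_real_,
                      target_x_px = NA_real_, target_y_px = NA_real_)
    truth <- data.frame(frame = seq_len(n) - 1L,
                        time_s = (seq_len(n) - 1L) * dt,
                        centroid_x_um = NA_real_, centroid_y_um = NA_real_,
                        head_x_um = NA_real_, head_y_um = NA_real_,
                        head_angle_deg = NA_real_, ha_norm = NA_real_,
                        soma_drive = NA_real_, nrv_drive = NA_real_,
                        nrd_drive = NA_real_, out_of_fov = FALSE)
    dD <- if (length(muscleRep)) matrix(NA_real_, n, 27L) else NULL
    vD <- if (length(muscleRep)) matrix(NA_real_, n, 27L) else NULL
    ctx <- NULL

    for (i in seq_len(n)) {
      t <- (i - 1L) * dt
      st <- wormStateAt(t, gait, originUm = config$originUm, haMaxDeg = haMax)
      ch <- renderChannels(st, stage, optics, config$reporters)
      cl28 <- centerlineAt(t, gait, nPoints = 28L, originUm = config$originUm)
      cen <- colMeans(cl28)
      truth$centroid_x_um[i] <- cen[1L]; truth$centroid_y_um[i] <- cen[2L]
      truth$head_x_um[i] <- cl28[1L, 1L]; truth$head_y_um[i] <- cl28[1L, 2L]
      truth$head_angle_deg[i] <- st$headAngleDeg
      truth$ha_norm[i] <- st$haNorm
      truth$out_of_fov[i] <- ch$empty
      if (length(muscleRep)) {
        rp <- muscleRep[[1L]]
        # axial coordinate of each of the 27 segment midpoints of the
        # arc-resampled midline (ROIs are arc-indexed, the wave is axial)
        uMid <- (config$originUm[1L] + gait$speedUmS * t) -
                (cl28[-28L, 1L] + cl28[-1L, 1L]) / 2
        kap <- .curvatureNorm(uMid, t - rp$phaseLagS, gait)
        dD[i, ] <- pmax(0, -kap); vD[i, ] <- pmax(0, kap)
      }
      if (length(pointRep)) {
        rp <- pointRep[[1L]]
        dr <- .reporterDrives(st, rp)
        if (rp$kind == "soma") truth$soma_drive[i] <- dr$soma
        else { truth$nrv_drive[i] <- dr$nrv; truth$nrd_drive[i] <- dr$nrd }
      }
      if (keepFrames) { gFr[[i]] <- ch$fluorescence; rFr[[i]] <- ch$brightfield }
      if (keepCenterlines) cls[[i]] <- cl28
      log$x_mm[i] <- stage$xMm; log$y_mm[i] <- stage$yMm; log$z_mm[i] <- stage$zMm

      cmd <- c(0, 0, 0)
      if (!is.null(controller)) {
        res <- controller(ch$brightfield, ch$fluorescence, stage, ctx)
        if (!is.null(res$commandMm)) cmd <- res$commandMm
        if (!is.null(res$targetPx)) {
          log$target_x_px[i] <- res$targetPx[1L]
          log$target_y_px[i] <- res$targetPx[2L]
        }
        ctx <- res$ctx
      }
      stage <- stageStep(stage, cmd, dt)
    }

    truthOut <- list(perFrame = truth, dorsalDrive = dD, ventralDrive = vD,
                     centerlines = cls, haMaxDeg = haMax,
                     finalStage = stage)
    rec <- NULL
    if (keepFrames) {
      rec <- SyncedRecording(
        FrameStack(gFr, frameRate = fps, bitDepth = optics$bitDepth),
        FrameStack(rFr, frameRate = fps, bitDepth = optics$bitDepth),
        log, optics$pixelScaleUm)
    }
    list(recording = rec, log = log, truth = truthOut)
  })
}
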