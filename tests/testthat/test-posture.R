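# geometry helpers for constructed midlines
mkMidline <- function(pts, oriented = TRUE) {
  structure(list(pointsPx = pts, nPoints = nrow(pts),
                 arcSpacingPx = mean(sqrt(diff(pts[, 1L])^2 +
                                          diff(pts[, 2L])^2)),
                 headConfident = oriented),
            class = "midline")
}

test_that("binarizeWorm recovers the simulated body within IoU 0.9", {
  fx <- fixtureMuscle()
  i <- 5L
  mask <- binarizeWorm(getFrame(redChannel(fx$ses$recording), i))
  expect_true(attr(mask, "usable"))
  truth <- truthBodyMask(fx$ses, fx$cfg, i)
  iou <- sum(mask & truth) / sum(mask | truth)
  expect_gte(iou, 0.9)
  # blank frame is flagged unusable
  blank <- matrix(30000L, 50L, 50L)
  expect_false(attr(binarizeWorm(blank), "usable"))
  # inverted polarity: the "worm" side is the background; the largest
  # bright blob is the background itself or nothing worm-like survives
  inv <- binarizeWorm(getFrame(redChannel(fx$ses$recording), i),
                      polarity = "bright", minBlobPx = 100000L)
  expect_false(attr(inv, "usable"))
})

test_that("a straight rectangular worm yields a collinear evenly spaced midline", {
  mask <- matrix(FALSE, 100L, 700L)
  mask[31:70, 51:650] <- TRUE
  m <- extractMidline(mask, 28L)
  expect_identical(nrow(m$pointsPx), 28L)
  expect_lt(diff(range(m$pointsPx[, 2L])), 1)      # collinear
  seg <- sqrt(diff(m$pointsPx[, 1L])^2 + diff(m$pointsPx[, 2L])^2)
  expect_lt((max(seg) - min(seg)) / mean(seg), 0.02)
  expect_true(all(abs(bendAngles(m)) < 1e-6))
})

test_that("a semicircular band skeletonizes onto the centre-radius arc", {
  h <- 130L; w <- 130L
  cx <- 64; cy <- 120; r <- 45
  xs <- matrix(0:(w - 1L), h, w, byrow = TRUE)
  ys <- matrix(0:(h - 1L), h, w)
  rad <- sqrt((xs - cx)^2 + (ys - cy)^2)
  mask <- rad > r - 6 & rad < r + 6 & ys < cy
  m <- extractMidline(mask, 28L)
  d <- abs(sqrt((m$pointsPx[, 1L] - cx)^2 + (m$pointsPx[, 2L] - cy)^2) - r)
  expect_lt(mean(d), 2)
})

test_that("rig midlines stay within 3 px of the true centerline", {
  fx <- fixtureMuscle()
  ok <- which(fx$pa$usable)[1:20]
  sc <- fx$cfg$optics$pixelScaleUm
  dists <- vapply(ok, function(i) {
    gt <- fx$ses$truth$centerlines[[i]]
    gx <- (gt[, 1L] - fx$ses$log$x_mm[i] * 1000) / sc
    gy <- (gt[, 2L] - fx$ses$log$y_mm[i] * 1000) / sc
    p <- fx$pa$midlines[[i]]$pointsPx
    mean(vapply(seq_len(28L), function(j)
      min(sqrt((gx - p[j, 1L])^2 + (gy - p[j, 2L])^2)), numeric(1L)))
  }, numeric(1L))
  expect_lt(mean(dists), 3)
})

test_that("coiled skeletons with major branches are rejected", {
  # a T-shaped mask produces a long side branch
  mask <- matrix(FALSE, 120L, 120L)
  mask[55:65, 10:110] <- TRUE
  mask[10:110, 55:65] <- TRUE
  expect_error(extractMidline(mask, 28L), "branch|coiled")
})

test_that("orientMidlines points the head at the leading end", {
  fx <- fixtureMuscle()
  ok <- which(fx$pa$usable)
  sc <- fx$cfg$optics$pixelScaleUm
  hits <- vapply(ok[1:30], function(i) {
    gt <- fx$ses$truth$perFrame
    hx <- (gt$head_x_um[i] - fx$ses$log$x_mm[i] * 1000) / sc
    hy <- (gt$head_y_um[i] - fx$ses$log$y_mm[i] * 1000) / sc
    p <- fx$pa$midlines[[i]]$pointsPx
    dHead <- sqrt((p[1L, 1L] - hx)^2 + (p[1L, 2L] - hy)^2)
    dTail <- sqrt((p[28L, 1L] - hx)^2 + (p[28L, 2L] - hy)^2)
    dHead < dTail
  }, logical(1L))
  expect_true(all(hits))
  expect_true(fx$pa$midlines[[ok[1L]]]$headConfident)
})

test_that("orientMidlines is invariant to flipped input and flags stationary worms", {
  set.seed(51)
  base <- lapply(1:6, function(i) {
    t <- seq(0, 1, length.out = 20L)
    # head-first, translating +x by well over one body length in total
    mkMidline(cbind(100 - 50 * t + 30 * i, 50 + 10 * sin(2 * pi * t)))
  })
  o1 <- orientMidlines(base)
  flipped <- lapply(base, function(m) {
    m$pointsPx <- m$pointsPx[20:1, ]; m
  })
  o2 <- orientMidlines(flipped)
  expect_equal(o1[[3L]]$pointsPx, o2[[3L]]$pointsPx)
  # stationary worm: ambiguous head
  stat <- orientMidlines(base[c(1L, 1L, 1L)])
  expect_false(stat[[1L]]$headConfident)
})

test_that("bendAngles matches the constant-curvature closed form", {
  # 28 points on a circular arc turning 90 degrees in total
  theta <- seq(0, pi / 2, length.out = 28L)
  pts <- cbind(100 + 80 * cos(theta), 100 + 80 * sin(theta))
  m <- mkMidline(pts)
  ang <- bendAngles(m)
  expect_identical(length(ang), 26L)
  expect_equal(ang, rep(sum(ang) / 26, 26L), tolerance = 0.01)
  expect_equal(abs(sum(ang)), 90 * 26 / 27, tolerance = 0.01)
  # mirror reflection negates every angle
  mref <- mkMidline(cbind(pts[, 1L], -pts[, 2L]))
  expect_equal(bendAngles(mref), -ang)
})

test_that("headAngle follows the 12-point two-vector definition", {
  straight <- mkMidline(cbind(seq(100, 0, length.out = 12L), rep(5, 12L)))
  expect_equal(headAngle(straight), 0)
  # p0=(0,0), p2=(2,0), p3=(2,1): right angle
  pts <- rbind(c(0, 0), c(1, 0), c(2, 0), c(2, 1),
               cbind(2, seq(2, 9, length.out = 8L)))
  expect_equal(abs(headAngle(mkMidline(pts))), 90)
  expect_error(headAngle(mkMidline(pts[1:10, ])), "12-point")
})

test_that("measured head angles track the simulator ground truth (r >= 0.95)", {
  fx <- fixtureMuscle()
  ok <- fx$pa$usable
  r <- cor(fx$pa$headAngleDeg[ok],
           fx$ses$truth$perFrame$head_angle_deg[ok])
  expect_gte(r, 0.95)
})

test_that("lateralRois yields 27 congruent ROIs per side on a straight worm", {
  mask <- matrix(FALSE, 100L, 700L)
  mask[31:70, 51:650] <- TRUE
  m <- extractMidline(mask, 28L)
  rois <- lateralRois(m, mask)
  expect_identical(length(rois$polys$dorsal), 27L)
  expect_identical(length(rois$polys$ventral), 27L)
  # interior ROI quadrilaterals are congruent within 2% by shoelace area
  shoelace <- function(p) {
    x <- p[, 1L]; y <- p[, 2L]
    abs(sum(x * c(y[-1L], y[1L]) - c(x[-1L], x[1L]) * y)) / 2
  }
  inner <- 2:26
  for (side in c("dorsal", "ventral")) {
    a <- vapply(rois$polys[[side]][inner], shoelace, numeric(1L))
    expect_lt(diff(range(a)) / mean(a), 0.02, label = side)
  }
  # the pixel partition tracks the geometry (coarser: pixel rounding)
  ar <- roiAreas(rois)
  for (s in 1:2)
    expect_lt(diff(range(ar[inner, s])) / mean(ar[inner, s]), 0.08,
              label = colnames(ar)[s])
  # dorsal and ventral partitions are disjoint by construction
  expect_true(all(rois$sideIdx[rois$segIdx > 0L] %in% 1:2))
})

test_that("ROI counts are exactly 27 per side on rig frames", {
  fx <- fixtureMuscle()
  i <- which(fx$pa$usable)[3L]
  mask <- binarizeWorm(getFrame(redChannel(fx$ses$recording), i))
  rois <- lateralRois(fx$pa$midlines[[i]], mask)
  expect_identical(length(rois$polys$dorsal), 27L)
  expect_identical(length(rois$polys$ventral), 27L)
})

test_that("dorsal/ventral ROI intensity follows the muscle drive (r >= 0.9)", {
  fx <- fixtureMuscle()
  ok <- fx$pa$usable
  corsD <- vapply(1:27, function(j)
    cor(fx$pa$dorsal[ok, j], fx$ses$truth$dorsalDrive[ok, j],
        use = "complete.obs"), numeric(1L))
  corsV <- vapply(1:27, function(j)
    cor(fx$pa$ventral[ok, j], fx$ses$truth$ventralDrive[ok, j],
        use = "complete.obs"), numeric(1L))
  expect_gte(min(corsD), 0.9)
  expect_gte(min(corsV), 0.85)
  expect_gte(median(c(corsD, corsV)), 0.95)
  expect_false(fx$pa$flipped)
})

test_that("midline displacement matches the RMS amplitude of the gait", {
  # straight worm: zero everywhere
  straight <- lapply(1:5, function(i)
    mkMidline(cbind(seq(0, 600, length.out = 28L), rep(50, 28L))))
  expect_true(all(midlineDisplacement(straight) < 1e-9))
  # rig session: mid-body displacement ~ A/sqrt(2)
  fx <- fixtureMuscle()
  ml <- fx$pa$midlines[fx$pa$usable]
  prof <- midlineDisplacement(ml, fx$cfg$optics$pixelScaleUm)
  A <- fx$cfg$gait$amplitudeUm
  expect_equal(mean(prof[13:16]), A / sqrt(2), tolerance = 0.15)
})

test_that("head-angle histogram and dispersion behave as closed forms predict", {
  expect_error(headAngleDistribution(rep(5, 50L)), "100")
  const <- headAngleDistribution(rep(5, 200L))
  expect_equal(const$sdDeg, 0)
  # sinusoid amplitude theta: SD = theta / sqrt(2) within 5%
  th <- 40 * sin(seq(0, 20 * pi, length.out = 2000L))
  d <- headAngleDistribution(th)
  expect_equal(d$sdDeg, 40 / sqrt(2), tolerance = 0.05)
  expect_equal(diff(d$breaks), rep(2, length(d$breaks) - 1L))
})

test_that("the posture pipeline is equivariant to a 90-degree frame rotation", {
  fx <- fixtureMuscle()
  i <- which(fx$pa$usable)[2L]
  fr <- getFrame(redChannel(fx$ses$recording), i)
  rot <- t(fr)[, nrow(fr):1, drop = FALSE]   # rotate frame 90 deg
  m1 <- extractMidline(binarizeWorm(fr), 28L)
  m2 <- extractMidline(binarizeWorm(rot), 28L)
  # map m1 into rotated coordinates: (x, y) -> (h - 1 - y, x)
  p1r <- cbind(nrow(fr) - 1 - m1$pointsPx[, 2L], m1$pointsPx[, 1L])
  if (sum((p1r[1L, ] - m2$pointsPx[1L, ])^2) >
      sum((p1r[1L, ] - m2$pointsPx[28L, ])^2))
    m2$pointsPx <- m2$pointsPx[28:1, ]
  expect_lt(mean(sqrt(rowSums((p1r - m2$pointsPx)^2))), 2.5)
  # bend angles unchanged by the rotation (up to orientation choice)
  a1 <- bendAngles(mkMidline(p1r))
  a2 <- bendAngles(m2)
  expect_lt(mean(abs(a1 - a2)), 4)
})

test_that("kymograph assembly is a pure reshaping of per-frame outputs", {
  fx <- fixtureMuscle()
  ok <- which(fx$pa$usable)[1:5]
  sgn <- if (fx$pa$flipped) -1 else 1
  for (i in ok)
    expect_equal(fx$pa$angles[i, ], sgn * bendAngles(fx$pa$midlines[[i]]))
})
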