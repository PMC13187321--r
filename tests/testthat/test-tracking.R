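test_that("segmentTarget honours polarity, size floor and largest-blob rule", {
  fr <- matrix(0L, 60L, 60L)
  fr[21:40, 21:40] <- 60000L
  cfg <- trackerConfig("bright_on_dark", minBlobPx = 10L)
  mask <- segmentTarget(fr, cfg)
  want <- matrix(FALSE, 60L, 60L); want[21:40, 21:40] <- TRUE
  expect_identical(unclass(mask), want)
  # dark-on-light polarity on the same frame finds nothing worm-like
  cfgD <- trackerConfig("dark_on_light", minBlobPx = 500L)
  expect_false(any(segmentTarget(fr, cfgD)))
  # two blobs, 50 px vs 400 px: only the larger survives
  fr2 <- matrix(0L, 60L, 60L)
  fr2[1:5, 1:10] <- 60000L          # 50 px
  fr2[31:50, 31:50] <- 60000L       # 400 px
  m2 <- segmentTarget(fr2, cfg)
  expect_identical(sum(m2), 400L)
  expect_true(all(which(m2, arr.ind = TRUE)[, 1L] >= 31L))
})

test_that("blobCentroid equals the enumeration oracle", {
  m <- matrix(FALSE, 30L, 30L)
  m[11:20, 11:20] <- TRUE
  expect_equal(blobCentroid(m), c(x = 14.5, y = 14.5))
  m1 <- matrix(FALSE, 10L, 10L); m1[8L, 4L] <- TRUE   # (x=3, y=7)
  expect_equal(blobCentroid(m1), c(x = 3, y = 7))
  # L-shaped blob against the brute-force pixel mean
  mL <- matrix(FALSE, 20L, 20L)
  mL[5:15, 5L] <- TRUE; mL[15L, 5:12] <- TRUE
  idx <- which(mL, arr.ind = TRUE)
  expect_equal(blobCentroid(mL),
               c(x = mean(idx[, 2L] - 1), y = mean(idx[, 1L] - 1)))
  expect_null(blobCentroid(matrix(FALSE, 5L, 5L)))
})

test_that("centeringCommand converts pixel error to a clamped stage move", {
  cfg <- trackerConfig(deadbandPx = 0L, gain = 1)
  img <- c(201L, 201L)   # centre at (100, 100)
  expect_equal(centeringCommand(c(100, 100), img, 0.75, cfg), c(0, 0))
  # 100 px right of centre at 0.75 um/px -> +0.075 mm toward the target
  expect_equal(centeringCommand(c(200, 100), img, 0.75, cfg), c(0.075, 0))
  # deadband swallows small errors
  cfg5 <- trackerConfig(deadbandPx = 5L)
  expect_equal(centeringCommand(c(103, 100), img, 0.75, cfg5), c(0, 0))
  # clamp
  cfgC <- trackerConfig(deadbandPx = 0L, maxStepMm = 0.05)
  expect_equal(centeringCommand(c(200, 100), img, 6, cfgC), c(0.05, 0))
})

test_that("applying the centering command reduces the pixel error (sign check)", {
  g <- gaitParams(speedUmS = 0)
  optics <- opticsConfig(noiseSd = 0)
  cfg <- rigConfig(g, optics)
  cfg$stage$xMm <- cfg$stage$xMm + 0.3   # target starts right of centre
  tcfg <- trackerConfig(deadbandPx = 0L)
  st <- wormStateAt(0, g)
  ch <- renderChannels(st, cfg$stage, optics, list())
  cen <- blobCentroid(segmentTarget(ch$brightfield, tcfg))
  err0 <- abs(cen[1L] - (optics$imagePx[1L] - 1) / 2)
  cmd <- centeringCommand(cen, optics$imagePx, optics$pixelScaleUm, tcfg)
  stage2 <- stageStep(cfg$stage, c(cmd, 0), dt = 0.1)
  ch2 <- renderChannels(st, stage2, optics, list())
  cen2 <- blobCentroid(segmentTarget(ch2$brightfield, tcfg))
  err1 <- abs(cen2[1L] - (optics$imagePx[1L] - 1) / 2)
  expect_lt(err1, err0 * 0.2)
})

test_that("a stationary off-centre target is centred within 10 frames", {
  g <- gaitParams(speedUmS = 1e-9)
  cfg <- rigConfig(g)
  cfg$stage$xMm <- cfg$stage$xMm + 0.3
  ts <- trackSession(cfg, trackerConfig(), durationS = 3, seed = 21L)
  err <- abs(ts$report$error_px_x)
  expect_true(all(err[10:30] <= trackerConfig()$deadbandPx + 1))
  # and once inside the deadband the error never grows again (contraction)
  inside <- which(err <= trackerConfig()$deadbandPx)[1L]
  expect_true(all(err[inside:length(err)] <= trackerConfig()$deadbandPx + 1))
})

test_that("brightfield and fluorescence tracking agree on the same scene", {
  fx <- fixtureMuscle()
  bf <- getFrame(redChannel(fx$ses$recording), 10L)
  fl <- getFrame(greenChannel(fx$ses$recording), 10L)
  c1 <- blobCentroid(segmentTarget(bf, trackerConfig("dark_on_light")))
  c2 <- blobCentroid(segmentTarget(fl, trackerConfig("bright_on_dark",
                                                     minBlobPx = 10L)))
  # different targets (whole silhouette vs bright muscle band): within a
  # half worm-width-ish distance at 6 um/px
  halfWorm <- 0.5 * fx$cfg$gait$lengthUm / fx$cfg$optics$pixelScaleUm
  expect_lt(sqrt(sum((c1 - c2)^2)), halfWorm / 2)
})

test_that("a 1 Hz frame rate loses a fast worm and the report flags it", {
  g <- gaitParams(speedUmS = 800)
  cfg <- rigConfig(g, frameRateHz = 1)
  ts <- trackSession(cfg, trackerConfig(), durationS = 10, seed = 23L)
  expect_gt(ts$lostFraction, 0)
})

test_that("wormAbsolutePosition is invariant to pure stage recentring", {
  # synthetic log: worm fixed in the arena while the stage steps around
  imagePx <- c(240L, 150L); sc <- 6
  centre <- (imagePx - 1) / 2
  stageX <- 25 + cumsum(c(0, 0.05, -0.02, 0.03, 0))
  wormArenaX <- 25.45 * 1000
  tpx <- (wormArenaX - stageX * 1000) / sc - 0   # pixel x of the worm
  log <- data.frame(frame = 0:4, time_s = (0:4) / 10, x_mm = stageX,
                    y_mm = 25, z_mm = 5, target_x_px = tpx,
                    target_y_px = centre[2L])
  tr <- wormAbsolutePosition(log, sc, imagePx)
  expect_lt(diff(range(tr$x_um)), 1e-9)
  expect_lt(diff(range(tr$y_um)), 1e-9)
  # rows without targets are skipped with a warning
  log$target_x_px[2L] <- NA
  expect_warning(tr2 <- wormAbsolutePosition(log, sc, imagePx), "skipped")
  expect_identical(nrow(tr2), 4L)
})

test_that("recovered absolute trajectory matches the simulator ground truth", {
  fx <- fixtureMuscle()
  log <- fx$ses$log
  optics <- fx$cfg$optics
  tr <- wormAbsolutePosition(log, optics$pixelScaleUm, optics$imagePx)
  gt <- fx$ses$truth$perFrame[log$frame %in% tr$frame, ]
  centre <- (optics$imagePx - 1) / 2
  # the tracked point is the silhouette centroid; align the constant offset
  dx <- tr$x_um + centre[1L] * optics$pixelScaleUm - gt$centroid_x_um
  dy <- tr$y_um + centre[2L] * optics$pixelScaleUm - gt$centroid_y_um
  rms <- sqrt(mean(dx^2 + dy^2))
  expect_lt(rms, 2 * optics$pixelScaleUm)
  # worm crawls ~150 um/s for 60 s: the trajectory spans that distance
  expect_equal(diff(range(tr$x_um)), diff(range(gt$centroid_x_um)),
               tolerance = 0.05)
})
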