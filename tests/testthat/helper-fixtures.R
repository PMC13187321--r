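# Shared virtual-rig fixtures, generated once per test run and cached.
# Fixed seeds keep every session reproducible; problem sizes are chosen so
# the default suite runs in minutes on one core.

.fixtures <- new.env(parent = emptyenv())

# 60 s muscle-imaging session (10 Hz, 6 um/px) under closed-loop tracking,
# with ground-truth centerlines, plus its posture analysis.
fixtureMuscle <- function() {
  if (is.null(.fixtures$muscle)) {
    cfg <- rigConfig(reporters = list(reporterConfig("muscle")))
    ses <- runSession(cfg,
                      trackingController(trackerConfig(),
                                         cfg$optics$pixelScaleUm),
                      durationS = 60, seed = 101, keepCenterlines = TRUE)
    pa <- postureAnalysis(redChannel(ses$recording),
                          greenChannel(ses$recording),
                          stageLog = ses$log,
                          pixelScaleUm = cfg$optics$pixelScaleUm)
    .fixtures$muscle <- list(cfg = cfg, ses = ses, pa = pa)
  }
  .fixtures$muscle
}

# 20 s RIA-style axon session (10 Hz, 1.5 um/px, 200 frames) and the full
# compartment pipeline: posture (12-point), soma tracking, 80 px crops,
# rotational registration, compartment masks and traces.
fixtureAxon <- function(phaseLagS = 0) {
  key <- paste0("axon", phaseLagS)
  if (is.null(.fixtures[[key]])) {
    optics <- opticsConfig(imagePx = c(960L, 600L))
    rep <- reporterConfig("axon_compartments", gain = 8000,
                          blobSigmaUm = 6, somaPositionS = 0.1,
                          phaseLagS = phaseLagS)
    cfg <- rigConfig(optics = optics, reporters = list(rep))
    ts <- trackSession(cfg, trackerConfig(minBlobPx = 100L),
                       durationS = 20, seed = 103 + round(10 * phaseLagS),
                       keepFrames = TRUE, keepCenterlines = TRUE)
    ses <- ts$session
    pa <- postureAnalysis(redChannel(ses$recording), nPoints = 12L,
                          stageLog = ses$log,
                          pixelScaleUm = optics$pixelScaleUm)
    green <- greenChannel(ses$recording)
    track <- trackSoma(green)
    reg <- rotateRegister(cropSoma(green, track), pa$headOrientationDeg)
    masks <- splitCompartments(reg)
    traces <- compartmentTraces(reg, masks)
    .fixtures[[key]] <- list(cfg = cfg, ses = ses, pa = pa, track = track,
                             reg = reg, masks = masks, traces = traces)
  }
  .fixtures[[key]]
}

# Small deterministic recording for I/O round-trips.
makeTinyRecording <- function(nFrames = 5L, h = 24L, w = 30L, seed = 7L) {
  set.seed(seed)
  mk <- function() {
    frames <- lapply(seq_len(nFrames), function(i) {
      m <- matrix(sample.int(65536L, h * w, replace = TRUE) - 1L, h, w)
      m[1L, 1L] <- 0L; m[h, w] <- 65535L   # dynamic-range edges
      m
    })
    FrameStack(frames, frameRate = 10)
  }
  log <- data.frame(frame = 0:(nFrames - 1L),
                    time_s = (0:(nFrames - 1L)) / 10,
                    x_mm = 25.2 + runif(nFrames) * 1e-3,
                    y_mm = 25.2 + runif(nFrames) * 1e-3,
                    z_mm = 5 + runif(nFrames) * 1e-4,
                    target_x_px = c(NA, runif(nFrames - 1L, 0, 30)),
                    target_y_px = c(NA, runif(nFrames - 1L, 0, 24)))
  SyncedRecording(mk(), mk(), log, pixelScaleUm = 6)
}

# Body mask oracle: pixels within widthProfile(s) of the ground-truth
# centerline, built directly from the simulator's geometry.
truthBodyMask <- function(ses, cfg, frameIdx) {
  cl <- ses$truth$centerlines[[frameIdx]]
  sc <- cfg$optics$pixelScaleUm
  w <- cfg$optics$imagePx[1L]; h <- cfg$optics$imagePx[2L]
  cx <- (cl[, 1L] - ses$log$x_mm[frameIdx] * 1000) / sc
  cy <- (cl[, 2L] - ses$log$y_mm[frameIdx] * 1000) / sc
  hw <- cfg$gait$widthProfile(seq(0, 1, length.out = nrow(cl))) / sc
  mask <- matrix(FALSE, h, w)
  xs <- matrix(0:(w - 1L), h, w, byrow = TRUE)
  ys <- matrix(0:(h - 1L), h, w)
  for (k in seq_len(nrow(cl))) {
    mask <- mask | ((xs - cx[k])^2 + (ys - cy[k])^2 <= hw[k]^2)
  }
  mask
}

# Pixel coordinates of the ground-truth point at arc fraction s.
truthArcPointPx <- function(ses, cfg, frameIdx, s) {
  cl <- ses$truth$centerlines[[frameIdx]]
  sc <- cfg$optics$pixelScaleUm
  n <- nrow(cl)
  idx <- 1 + s * (n - 1)
  lo <- floor(idx); hi <- min(lo + 1, n); fr <- idx - lo
  p <- unname((1 - fr) * cl[lo, ] + fr * cl[hi, ])
  c(x = (p[1L] - ses$log$x_mm[frameIdx] * 1000) / sc,
    y = (p[2L] - ses$log$y_mm[frameIdx] * 1000) / sc)
}
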