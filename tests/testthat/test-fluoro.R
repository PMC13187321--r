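test_that("topNMean equals the sort-and-average oracle", {
  fr <- matrix(500L, 10L, 10L)
  expect_equal(topNMean(fr, n = 25L), 500)
  fr2 <- matrix(0L, 10L, 10L)
  fr2[1:25] <- 1000L
  expect_equal(topNMean(fr2, n = 25L), 1000)
  set.seed(61)
  fr3 <- matrix(sample.int(5000L, 400L, replace = TRUE), 20L, 20L)
  region <- matrix(runif(400L) < 0.5, 20L, 20L)
  n <- 25L
  oracle <- mean(sort(fr3[region], decreasing = TRUE)[seq_len(n)])
  expect_equal(topNMean(fr3, region, n), oracle)
  # monotone: adding a constant adds that constant
  expect_equal(topNMean(fr3 + 37L, region, n), oracle + 37)
  expect_error(topNMean(fr3, matrix(FALSE, 20L, 20L), 25L), "fewer")
})

test_that("deltaFOverF uses the percentile baseline and is scale-invariant", {
  ct <- CalciumTrace(rep(100, 10L))
  expect_true(all(deltaFOverF(ct)@dff == 0))
  # F0 = 100 at the 10th percentile, peak 310 -> max dF/F = 2.1
  tr <- c(rep(100, 10L), seq(100, 310, length.out = 10L))
  d <- deltaFOverF(CalciumTrace(tr))
  expect_equal(d@baselineF0, 100)
  expect_equal(max(d@dff), 2.1)
  # scaling the trace leaves dF/F unchanged
  d2 <- deltaFOverF(CalciumTrace(5 * tr))
  expect_equal(d2@dff, d@dff)
  expect_error(deltaFOverF(CalciumTrace(rep(0, 5L))), "positive")
})

test_that("sbr reproduces the reference worked examples", {
  expect_identical(sbr(15540, 3264), 4.8)
  expect_identical(sbr(37623, 1408), 26.7)
  expect_identical(sbr(100, 100), 1)
  expect_error(sbr(10, 0), "positive")
})

test_that("ratiometric correction cancels common-mode gain exactly", {
  n <- 300L
  t <- seq_len(n)
  commonMode <- 1 + 0.3 * sin(2 * pi * t / 40)          # motion artifact
  transient <- 2 * exp(-(t - 150)^2 / (2 * 15^2))       # green-only event
  green <- 100 * (1 + transient) * commonMode
  red <- 80 * commonMode
  corrected <- ratiometricCorrect(green, red)
  expect_lt(max(abs(corrected - transient)), 0.01 * max(transient))
  # pure common mode: identically zero
  expect_true(all(abs(ratiometricCorrect(red * 1.25, red)) < 1e-12))
  expect_true(all(abs(ratiometricCorrect(rep(5, 10L), rep(2, 10L))) < 1e-12))
  # invariance to any positive shared per-frame gain
  gain <- runif(n, 0.5, 2)
  c2 <- ratiometricCorrect(green * gain, red * gain)
  expect_equal(c2, corrected, tolerance = 1e-12)
  expect_error(ratiometricCorrect(green, c(red[-1L], 0)), "nonpositive")
})

test_that("trackSoma follows blobs and flags their disappearance", {
  # stationary bright blob: the window stays put
  mk <- function(on) {
    fr <- matrix(100L, 120L, 120L)
    if (on) fr[55:65, 70:80] <- 8000L
    fr
  }
  stack <- FrameStack(lapply(rep(TRUE, 6L), mk))
  tr <- trackSoma(stack, sizePx = 40L)
  expect_true(all(!tr$lost))
  expect_lt(diff(range(tr$x_px)), 1e-9)
  expect_equal(tr$x_px[1L], 75, tolerance = 1)
  # blob vanishing mid-stack: lost flags from that frame on
  stack2 <- FrameStack(lapply(c(TRUE, TRUE, TRUE, FALSE, FALSE), mk))
  tr2 <- trackSoma(stack2, sizePx = 40L)
  expect_identical(tr2$lost, c(FALSE, FALSE, FALSE, TRUE, TRUE))
})

test_that("soma tracking on the rig stays within 5 px of the true soma", {
  ax <- fixtureAxon(0)
  n <- nrow(ax$track)
  hits <- vapply(seq_len(n), function(i) {
    gt <- truthArcPointPx(ax$ses, ax$cfg, i, 0.1)
    sqrt((ax$track$x_px[i] - gt["x"])^2 +
         (ax$track$y_px[i] - gt["y"])^2) <= 5
  }, logical(1L))
  expect_gte(mean(hits), 0.95)
  expect_equal(mean(ax$track$lost), 0)
})

test_that("rotateRegister inverts a known rotation about the crop centre", {
  fr <- matrix(0L, 81L, 81L)
  fr[41L, 61L] <- 10000L    # blob at (x=60, y=40), 20 px right of centre
  # identity at angle 0
  expect_identical(getFrame(rotateRegister(FrameStack(list(fr)), 0), 1L), fr)
  # content at orientation +30 deg, registered with 30 -> back on the +x axis
  rot <- matrix(0L, 81L, 81L)
  px <- round(40 + 20 * cos(pi / 6)); py <- round(40 + 20 * sin(pi / 6))
  rot[py + 1L, px + 1L] <- 10000L
  reg <- getFrame(rotateRegister(FrameStack(list(rot)), 30), 1L)
  w <- which(reg == max(reg), arr.ind = TRUE)
  expect_lt(sqrt((w[1L, 2L] - 1 - 60)^2 + (w[1L, 1L] - 1 - 40)^2), 1.5)
})

test_that("registered compartments sit still (centroid SD < 3 px)", {
  ax <- fixtureAxon(0)
  cenSD <- function(mask) {
    cs <- vapply(frames(ax$reg), function(fr) {
      idx <- which(mask, arr.ind = TRUE)
      wts <- fr[mask]
      c(sum((idx[, 2L] - 1) * wts), sum((idx[, 1L] - 1) * wts)) / sum(wts)
    }, numeric(2L))
    apply(cs, 1L, sd)
  }
  expect_lt(max(cenSD(ax$masks$nrv)), 3)
  expect_lt(max(cenSD(ax$masks$nrd)), 3)
})

test_that("splitCompartments finds, labels and covers the two blobs", {
  # synthetic two-blob stack with known ground truth
  mkBlob <- function(cx, cy, amp) {
    xs <- matrix(0:79, 80L, 80L, byrow = TRUE); ys <- matrix(0:79, 80L, 80L)
    amp * exp(-((xs - cx)^2 + (ys - cy)^2) / (2 * 3^2))
  }
  set.seed(62)
  stack <- FrameStack(lapply(1:10, function(i) {
    a <- abs(sin(i / 3)); b <- abs(cos(i / 3))
    m <- 100 + mkBlob(50, 55, 6000 * a) + mkBlob(50, 25, 6000 * b) +
      rnorm(6400L, 0, 20)
    mm <- round(pmax(m, 0)); storage.mode(mm) <- "integer"; mm
  }))
  cm <- splitCompartments(stack)
  expect_false(any(cm$nrv & cm$nrd))
  expect_gte(sum(cm$nrv), 25L)
  # ventral label = larger y: the blob at y = 55
  expect_gt(mean(which(cm$nrv, arr.ind = TRUE)[, 1L]), 40)
  expect_lt(mean(which(cm$nrd, arr.ind = TRUE)[, 1L]), 40)
  # coverage: each mask contains the bright core of its blob
  core <- mkBlob(50, 55, 1) > exp(-0.5)
  expect_gte(sum(cm$nrv & core) / sum(core), 0.8)
  # swapped-side construction swaps labels: the blob that was nrV (larger
  # y) lands on the smaller-y side after flipping and is labelled nrD
  stackSw <- FrameStack(lapply(frames(stack), function(fr)
    fr[80:1, , drop = FALSE]))
  cmSw <- splitCompartments(stackSw)
  expect_gte(sum(cmSw$nrd & core[80:1, ]) / sum(core), 0.8)
  # single blob: error
  one <- FrameStack(lapply(1:4, function(i) {
    m <- round(100 + mkBlob(40, 40, 6000)); storage.mode(m) <- "integer"; m
  }))
  expect_error(splitCompartments(one), "fewer than two")
  # temporal shuffling leaves the masks identical (max projection)
  shuf <- FrameStack(frames(stack)[sample(10L)])
  cm2 <- splitCompartments(shuf)
  expect_identical(cm2$nrv, cm$nrv)
  expect_identical(cm2$nrd, cm$nrd)
})

test_that("compartment traces recover the simulated drives", {
  ax <- fixtureAxon(0)
  gt <- ax$ses$truth$perFrame
  expect_gte(cor(ax$traces$nrv@values, gt$nrv_drive), 0.95)
  expect_gte(cor(ax$traces$nrd@values, gt$nrd_drive), 0.95)
})
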