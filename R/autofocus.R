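## FocusLock: sharpness is the variance of the 3x3 Laplacian response
## (interior pixels only) and a PID controller drives the Z axis.
## Sharpness is unsigned, so a signed error is formed by hill-climbing:
## the move direction is kept while sharpness improves and flipped when it
## worsens, with a small dither step to probe when stationary.

#' Variance-of-Laplacian image sharpness
#'
#' Convolves the frame with the 3x3 Laplacian kernel
#' `[[0,1,0],[1,-4,1],[0,1,0]]` over interior pixels (no border padding)
#' and returns the variance of the response.  The score is invariant to
#' adding a constant to the frame and scales with the square of a
#' multiplicative gain.
#'
#' @param frame single-channel numeric matrix, at least 3 x 3.
#' @return Nonnegative sharpness score.
#' @examples
#' varianceOfLaplacian(matrix(1, 5, 5))  # constant image -> 0
#' @export
varianceOfLaplacian <- function(frame) {
  h <- nrow(frame); w <- ncol(frame)
  if (is.null(h) || h < 3L || w < 3L)
    stop("frame must be at least 3 x 3")
  f <- frame
  storage.mode(f) <- "double"
  ri <- 2:(h - 1L); ci <- 2:(w - 1L)
  lap <- f[ri - 1L, ci] + f[ri + 1L, ci] + f[ri, ci - 1L] +
         f[ri, ci + 1L] - 4 * f[ri, ci]
  n <- length(lap)
  sum((lap - sum(lap) / n)^2) / (n - 1L)
}

#' PID controller state
#'
#' @param kp,ki,kd proportional, integral and derivative gains.
#' @param integralLimit anti-windup clamp on the accumulated error
#'   integral.
#' @param setpoint target value of the controlled quantity (stored for
#'   callers; [pidStep()] itself consumes a precomputed error).
#' @return A list of class `pidState` with zeroed accumulators.
#' @export
pidState <- function(kp = 0.4, ki = 0.05, kd = 0.1, integralLimit = 10,
                     setpoint = NA_real_) {
  stopifnot(integralLimit > 0)
  structure(list(kp = kp, ki = ki, kd = kd, integral = 0,
                 prevError = NA_real_, integralLimit = integralLimit,
                 setpoint = setpoint),
            class = "pidState")
}

#' One PID update
#'
#' `command = kp*error + ki*integral' + kd*(error - prevError)/dt` where
#' `integral' = clamp(integral + error*dt, +/-integralLimit)`; the
#' derivative term is zero on the first step.
#'
#' @param state a [pidState()].
#' @param error current error.
#' @param dt time step (s), > 0.
#' @return list(command, state) with the updated state.
#' @export
pidStep <- function(state, error, dt) {
  stopifnot(dt > 0)
  integ <- state$integral + error * dt
  integ <- max(min(integ, state$integralLimit), -state$integralLimit)
  deriv <- if (is.na(state$prevError)) 0 else (error - state$prevError) / dt
  cmd <- state$kp * error + state$ki * integ + state$kd * deriv
  state$integral <- integ
  state$prevError <- error
  list(command = cmd, state = state)
}

#' Closed-loop focus lock on the virtual rig
#'
#' Runs a session whose controller holds XY and servos Z toward a
#' sharpness setpoint recorded at toggle time (the variance-of-Laplacian
#' sharpness of an in-focus view; supplied, or measured from a reference
#' in-focus render when `setpointSharpness = NULL`).  Sharpness carries no
#' sign, so the error fed to the PID is the normalized deficit
#' `(setpoint - s)/setpoint`, signed by a hill-climb direction that flips
#' whenever a Z move lowers sharpness; inside `holdTol` the stage holds
#' (deadband), outside it a minimum dither step guarantees progress from
#' flat-blur starts.
#'
#' @param config a [rigConfig()]; set `startZMm` there to start defocused.
#' @param gains c(kp, ki, kd) of the PID on the normalized error.
#' @param durationS session length (s).
#' @param seed RNG seed.
#' @param setpointSharpness sharpness recorded when focus was last set;
#'   `NULL` measures it from an in-focus reference frame.
#' @param zScaleMm full-scale Z command (mm) for a unit PID output.
#' @param ditherMm minimum probe step (mm).
#' @param holdTol normalized sharpness deficit treated as "in focus".
#' @param abortAfter abort when the focus error grows for this many
#'   consecutive frames (divergence guard); `Inf` disables.
#' @return data.frame trace (`frame`, `time_s`, `z_mm`, `sharpness`,
#'   `error`); attribute `diverged` flags an aborted run.
#' @export
focusLock <- function(config, gains = c(0.4, 0.05, 0.1), durationS = 15,
                      seed = 1L, setpointSharpness = NULL, zScaleMm = 0.12,
                      ditherMm = 0.004, holdTol = 0.05, abortAfter = 50L) {
  stopifnot(inherits(config, "rigConfig"))
  fps <- config$frameRateHz
  dt <- 1 / fps
  n <- max(1L, round(durationS * fps))
  optics <- config$optics

  .withSeed(seed, {
    stage <- config$stage
    if (is.null(setpointSharpness)) {
      # toggle-time setpoint: sharpness of the in-focus view
      stRef <- wormStateAt(0, config$gait, originUm = config$originUm)
      stgRef <- stage; stgRef$zMm <- optics$focusZMm
      setpointSharpness <- varianceOfLaplacian(
        renderChannels(stRef, stgRef, optics, config$reporters)$brightfield)
    }
    pid <- pidState(gains[1L], gains[2L], gains[3L], integralLimit = 2,
                    setpoint = setpointSharpness)
    dir <- 1   # initial probe direction is arbitrary; one bad move flips it
    sPrev <- NA_real_; lastMove <- 0
    grow <- 0L; diverged <- FALSE
    zPrevErr <- abs(stage$zMm - optics$focusZMm)
    trace <- data.frame(frame = seq_len(n) - 1L,
                        time_s = (seq_len(n) - 1L) * dt,
                        z_mm = NA_real_, sharpness = NA_real_,
                        error = NA_real_)

    for (i in seq_len(n)) {
      t <- (i - 1L) * dt
      st <- wormStateAt(t, config$gait, originUm = config$originUm)
      ch <- renderChannels(st, stage, optics, config$reporters)
      s <- varianceOfLaplacian(ch$brightfield)
      e <- max(0, (setpointSharpness - s) / setpointSharpness)
      if (!is.na(sPrev) && abs(lastMove) > 1e-9 && s < sPrev) dir <- -dir
      sPrev <- s
      trace$z_mm[i] <- stage$zMm
      trace$sharpness[i] <- s
      trace$error[i] <- e

      if (e <= holdTol) {
        dz <- 0
        pid$integral <- 0
      } else {
        res <- pidStep(pid, e, dt)
        pid <- res$state
        dz <- dir * max(min(abs(res$command), 1), 0) * zScaleMm
        if (abs(dz) < ditherMm) dz <- dir * ditherMm
      }
      lastMove <- dz
      stage <- stageStep(stage, c(0, 0, dz), dt)

      zErr <- abs(stage$zMm - optics$focusZMm)
      grow <- if (zErr > zPrevErr + 1e-12) grow + 1L else 0L
      zPrevErr <- zErr
      if (grow >= abortAfter) {
        diverged <- TRUE
        trace <- trace[seq_len(i), , drop = FALSE]
        break
      }
    }
    attr(trace, "diverged") <- diverged
    attr(trace, "focusZMm") <- optics$focusZMm
    trace
  })
}
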