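# wormrig

Closed-loop worm-tracking microscopy without the microscope. `wormrig`
re-creates, in software, a two-channel epifluorescence platform for
freely moving *C. elegans* — a fixed arena, an XYZ stage (50.4 mm travel
per axis) carrying the optics, a 1440 × 900 µm field of view, and two
frame-synced cameras: a brightfield channel that silhouettes the worm
and a fluorescence channel that images GCaMP-like reporters. It is
aimed at people building or analyzing data from such trackers: every
on-line algorithm (tracking, autofocus) and every offline pipeline
(posture, muscle ROIs, soma and axon calcium quantification, phase
analysis) runs against a ground-truthed virtual rig, so the whole
analysis stack is testable without hardware or animal data.

## What's inside

* **Virtual rig** — an undulating worm (`gaitParams()`: midline offset
  `A·sin(2π(u/λ − f·t))`, arc length held at `L`), muscle / soma /
  axon-compartment reporters, camera model with defocus blur and noise,
  and `runSession()` returning a `SyncedRecording` plus full ground
  truth. Identical seed ⇒ bit-identical session.
* **Tracking** — threshold (dark-on-light or bright-on-dark), largest
  blob, centroid, proportional stage command with deadband and clamp
  (`trackSession()`), and stage-log → absolute arena trajectory
  conversion (`wormAbsolutePosition()`).
* **FocusLock** — variance-of-Laplacian sharpness + PID on Z with a
  toggle-time sharpness setpoint (`focusLock()`).
* **Posture** — Zhang–Suen skeletonization to a 28-point midline,
  signed bend angles (ventral positive), 27 dorsal + 27 ventral muscle
  ROIs from perpendiculars, 12-point head angle (chords 3→2 and 2→0),
  midline-displacement and head-angle-distribution gait summaries
  (`postureAnalysis()`).
* **Fluorescence** — brightest-25-pixel soma traces with soma tracking
  and 80 px crops, ΔF/F against a 10th-percentile F₀, signal-to-
  background ratios, ratiometric (G/R) motion-artifact correction,
  rotational registration of neuron crops by head orientation, and
  deterministic nrV/nrD compartment segmentation from the
  temporal-maximum projection.
* **Dynamics** — 0.5 s moving average, min/max and ±1 head-angle
  normalization, phase angle `φ = atan2(scaled dx, x)`, 24 × 15° polar
  profiles, cross-correlation with lag recovery, Hann-periodogram gait
  frequency, event-aligned mean ± s.e.m.

Recordings round-trip losslessly as 16-bit multi-page TIFF pairs plus a
CSV stage log (`saveRecording()` / `loadRecording()`). A thin CLI over
these functions ships in `inst/scripts/wormrig-cli.R`.

## Worked example

Simulate one minute of muscle imaging under closed-loop tracking, then
run the posture pipeline and recover the gait:

```r
library(wormrig)

cfg <- rigConfig(reporters = list(reporterConfig("muscle")))
ses <- runSession(cfg,
                  trackingController(trackerConfig(),
                                     cfg$optics$pixelScaleUm),
                  durationS = 60, seed = 101)

pa <- postureAnalysis(redChannel(ses$recording),
                      greenChannel(ses$recording),
                      stageLog = ses$log,
                      pixelScaleUm = cfg$optics$pixelScaleUm)
gf <- gaitFrequency(pa$headAngleDeg[pa$usable], frameRate = 10)
gf$frequencyHz
#> [1] 0.3
cor(pa$headAngleDeg[pa$usable],
    ses$truth$perFrame$head_angle_deg[pa$usable])
#> [1] 0.9861286
sbr(15540, 3264)   # AWC reference worked example
#> [1] 4.8
```

The recovered gait frequency equals the configured 0.3 Hz; measured head
angles correlate at 0.99 with the simulator's ground truth; `sbr()`
reproduces the reference signal-to-background worked value. `pa$angles`
(frames × 26) and `pa$dorsal` / `pa$ventral` (frames × 27) are the
kymograph-ready matrices.

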