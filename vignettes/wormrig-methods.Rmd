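---
title: "wormrig: methods and design notes"
author: "wormrig maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{wormrig: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# What this package models

`wormrig` is a hardware-free re-creation of a two-channel epifluorescence
microscope for freely moving *C. elegans*: a fixed arena, an XYZ stage
carrying the optics (50.4 mm travel per XY axis, a 1440 x 900 um field of
view), and two frame-synced cameras — a "red" transmission channel that
silhouettes the worm dark on a light background, and a "green" channel
that images GCaMP-like fluorescent reporters. The package contains

* a **virtual rig** (`rigConfig()`, `runSession()`) that simulates an
  undulating worm with configurable reporters and returns both the
  recording and full ground truth;
* the **on-line algorithms** of such a platform: centroid tracking
  (threshold, largest blob, centroid, proportional stage command with
  deadband and clamp) and FocusLock (variance-of-Laplacian sharpness +
  PID on the Z axis);
* the **offline analysis pipelines**: 28-point midline skeletonization
  with bend-angle kymographs and 27 dorsal/ventral muscle ROIs; 12-point
  head angles; brightest-25-pixel soma traces with dF/F and SBR;
  ratiometric motion-artifact correction; rotationally registered 80 px
  neuron crops with deterministic two-compartment (nrV/nrD) segmentation;
  and phase analysis (smoothing, normalization, phase angle, 24 x 15
  degree polar bins, cross-correlation, gait frequency, event-aligned
  averages).

Being hardware-free, every pipeline is validated against the
simulator's ground truth rather than against real recordings; the
worked numeric anchors are reference signal-to-background ratios (median neuron pixel / mean background:
15540/3264 = 4.8 and 37623/1408 = 26.7) and the structural constants of
the method (28 midline points, 27 ROIs per side, 12-point head angle
from the chords 3->2 and 2->0, 0.5 s / 5-frame smoothing at 10 Hz, 24
polar bins of 15 degrees).

# The worm model

The midline is a travelling sinusoid. With body-axis coordinate $u$
(micrometres from the head), the lateral offset at time $t$ is

$$y(u, t) = A \sin\!\big(2\pi(u/\lambda - f t)\big),$$

advected forward at crawl speed $v$. The axial extent is solved
numerically at each instant so the **arc length** equals the worm length
$L$ (conserved within 1% over a session, and tested). Defaults are $A =
100$ um, $\lambda = 500$ um, $f = 0.3$ Hz, $v = 150$ um/s, $L = 1000$
um — typical young-adult crawling values, fixed once as this package's
standing study conditions rather than measurements of any particular
strain.

Conventions: arena and image coordinates are x-right / y-down with
0-based pixel centres; the worm's **ventral side is the plus-normal side
of the head-to-tail traversal** ($n = (T_y, -T_x)$ for tangent $T$), and
all signed angles (bend angles, head angles) are **ventral positive**.
For the default worm crawling toward +x this puts ventral at +y.

The body half-width profile is $35 \sin(\pi s)^{0.4}$ um (blunt head and
tail tapering to zero). The exponent matters more than it looks: a long
thin taper falls below one camera pixel tens of micrometres before the
true nose, so the measured midline is systematically short and every
head-segment quantity degrades; the blunter profile matches the animal's
actual stubby head and keeps the rendered tip within a pixel or two of
the true one.

Reporters map mechanics to fluorescence with an optional first-order
delay (`phaseLagS`):

* **muscle** — drive is the rectified signed curvature, normalized to
  the gait maximum $Ak^2$: dorsal drive $= \max(0, -\kappa)$, ventral $=
  \max(0, +\kappa)$, painted onto the corresponding side of the body.
  Calcium therefore rises in dorsal muscle exactly during dorsal bends.
* **soma** — a Gaussian blob at arc position `somaPositionS` with drive
  $\tfrac12(1 + \text{normalized head angle})$.
* **axon_compartments** — a small tonic soma blob (the stable anchor the
  crop window tracks) plus two blobs 20 um anterior, offset +/-12 um
  perpendicular to the measured head direction; nrV drive $= \max(0,
  +\hat\theta)$ and nrD $= \max(0, -\hat\theta)$ for the normalized head
  angle $\hat\theta$, so compartment activity peaks at the deepest
  ventral/dorsal head bend. The compartment offsets are wide enough that
  the two blobs resolve as separate connected components at the virtual
  camera's sampling; the renderer orients them along the same 12-point
  chord (skeleton points 2 -> 0) that the posture pipeline measures, so
  rotational registration can cancel the axon's rotation exactly.

The camera model renders the silhouette and reporter emission, blurs by
the defocus model $\sigma_{um} = |z - z_{focus}| \cdot$ `blurUmPerMm`
(Gaussian; simple, but monotone in focus error, which is the only
property the focus controller uses), optionally applies Poisson shot
noise, then Gaussian read noise, then clips and quantizes to 16 bits.
All stochastic elements consume one seeded generator: identical seed and
configuration give bit-identical sessions.

What the simulator does **not** emulate: self-occlusion and coiling,
omega turns and reversals, background texture from bacterial lawns,
photobleaching, and non-rigid axon deformation. Passing the recovery
tests therefore shows the pipelines are correct on clean, well-posed
input — not that they are robust to every pathology of real video.

# Tracking and focus control

Tracking mode 1 thresholds a dark worm on a light background (Otsu by
default), keeps the largest connected component (ties broken toward the
previous target), and commands the stage with a proportional law:
error in pixels from image centre, zero inside a 5 px deadband, times
gain 1.0, converted to mm, clamped to 0.5 mm per frame. Mode 2 is the
same with the bright-on-dark polarity on the fluorescence channel.
The control law, gains and deadband are this package's choices, and
deliberately the simplest thing
that satisfies the contraction property (for a stationary target the
pixel error is non-increasing until it enters the deadband). When the
target is lost the stage holds position.

FocusLock scores sharpness as the variance of the 3x3 Laplacian response
(interior pixels only, no padding; invariant to additive offsets,
quadratic in gain). Sharpness is unsigned, so the Z error is formed
against a **setpoint recorded at toggle time** (the sharpness of an
in-focus view): the PID consumes the normalized deficit
$(s_{set} - s)/s_{set}$, signed by a hill-climb direction that flips
whenever a Z move lowers sharpness, with a small dither step so the
controller escapes the flat tails of heavy blur. A pure hill-climber
without a setpoint cannot even detect a defocused start — its deficit
relative to the best sharpness *seen* is zero — which is why the
setpoint reading was chosen. Default gains (kp 0.4, ki 0.05, kd 0.1 on
the normalized error, 0.12 mm full-scale) were set on the virtual rig.

# Posture pipeline

Per frame: Otsu threshold, largest component, hole filling; Zhang-Suen
thinning to a one-pixel skeleton; longest path between skeleton
endpoints (side branches longer than 10% of the main path abort the
frame as a coiled pose); light moving-average smoothing of the path
coordinates; extension of both ends along their local direction to the
mask boundary (the topological skeleton stops about half a body width
short of the tips); arc-length resampling to 28 (muscle) or 12
(head-angle) points. Head/tail assignment flips each frame to minimize
point displacement, then globally orients the head toward the end that
leads the net displacement; with net movement under one body length the
choice is ambiguous and flagged (`headConfident = FALSE`).

Bend angles are the signed angle of each segment against its anterior
neighbour: with the point and ROI counts fixed at 28 and 27, 26
relative angles follow.
Muscle ROIs intersect the perpendicular at each midline point with the
mask boundary on both sides, giving 27 quadrilaterals per side; for
intensity measurement each body pixel is assigned to its nearest segment
midpoint and side, an equivalent disjoint partition that cannot
double-count pixels. Which geometric side is "dorsal" is unknowable from
a silhouette, so the pipeline self-calibrates: dorsal-ROI intensity must
correlate positively with dorsal bending, otherwise ROI labels and angle
signs flip together (`flipDV` overrides).

"Midline displacement" is operationalized as the RMS over frames of the
perpendicular distance of each midline point from that frame's principal
axis — for a sinusoidal gait of amplitude $A$ the mid-body value is
$A/\sqrt2$, which the tests use as the oracle.

# Fluorescence pipelines

The soma measurement is the mean of the 25 brightest pixels in the
region (ties broken in largest-first stable order), with $F_0$ the 10th
percentile of the trace (a low percentile is the common convention and
is robust to transients) and
$\Delta F/F = (F - F_0)/F_0$. SBR is the median target pixel over the
mean background, background being the pixels outside a dilation of the
target mask by twice its equivalent radius.

Ratiometric correction is the transparent ratio form: $R = G/R_{red}$,
baselined as $(R - R_0)/R_0$ with $R_0$ the 10th percentile of $R$. Any
gain applied to both channels at once — motion, defocus — cancels
exactly (tested to 1%). This deliberately prefers a method whose
behaviour is fully analyzable over heavier Bayesian two-channel artifact
models; equivalence to such models is **not** claimed.

For axonal compartments: crops of 80 x 80 px are centred on the tracked
soma, rotated by minus the measured head orientation (bilinear, constant
fill) so the nose direction maps to +x and ventral to +y, and segmented
deterministically — Otsu on the temporal-maximum projection, two largest
components, nrV = the component on the ventral (+y) side. This is a
deterministic, dependency-free stand-in for the interactive
promptable-segmentation step of the original workflow, valid because
registration makes the compartments stationary (their weighted centroids
move < 3 px across a session — tested).

# Phase analysis

Traces are smoothed with a centred equal-weight moving average (default
5 frames = 0.5 s at 10 Hz); calcium is min/max normalized to [0, 1];
head angles are normalized piecewise so the deepest dorsal bend maps to
-1 and the deepest ventral to +1. The phase angle is
$\phi = \operatorname{atan2}(\dot x \cdot c,\ x)$ with $c$ defaulting to
$\max|x| / \max|\dot x|$ per trace so a sinusoid traces a circle (the
two inputs otherwise differ in units). Landmarks: $\phi = 0$ at the
deepest ventral bend, $\pi$ at the deepest dorsal bend, $+\pi/2$ at peak
ventral-ward velocity.

One numerical subtlety: the elementary derivative (`traceDerivative`) is
the adjacent-point difference aligned to the later frame, but pairing
that derivative (centred at $i + \tfrac12$) with the value at $i+1$
biases every phase by $+\omega \Delta t/2$ — about 5-9 degrees at 0.3 Hz
sampled at 10 Hz, enough to push a peak across a 15-degree bin edge.
The pipeline helper `phaseSeries()` therefore uses the centred
difference over $[i-1, i+1]$ paired with the value at $i$, which is
unbiased; the elementary operation keeps its conventional definition.

Polar profiles bin $\phi$ into 24 half-open 15-degree bins with edges at
multiples of 15 degrees and report mean, s.e.m. and count per bin (empty
bins are `NA`, never zero-filled). Cross-correlations are Pearson
correlations of overlapping segments at integer lags; **positive lag
means the second trace lags the first**. Gait frequency is the peak of a
Hann-tapered periodogram in $(0, f_s/2)$, flagged low-confidence unless
the peak reaches three times the median spectral power. Event-aligned
averages keep per-offset counts so truncated windows near trace edges
are averaged over exactly the events that reach them; s.e.m. is `NA`
below two contributing events. Multi-animal polar summaries should be
computed per animal and then averaged, matching how cohort averages are
reported in this field.

# Problem sizes and determinism

The shipped tests and the acceptance script regenerate everything from
seeds at run time: a 60 s muscle session at 10 Hz and 6 um/px under
closed-loop tracking; 20 s axon sessions at 1.5 um/px (200 frames, the
length of a selected forward run in this kind of experiment); a 300 s
tracking-endurance session (frames discarded on the fly, statistics kept);
and 12-30 s focus-lock runs. These sizes keep a full run in minutes on
one core while leaving every recovery margin comfortably wide of its
threshold.

# Known limitations

* The midline pipeline rejects coiled and self-touching poses rather
  than resolving them; omega turns are out of scope.
* Head/tail disambiguation needs net displacement; for stationary worms
  the orientation is flagged, not guessed.
* The dorsal/ventral labels are only as good as the self-calibration;
  with a non-muscle recording and no override the sides are an arbitrary
  but consistent pair.
* The ratio correction removes multiplicative common-mode artifacts
  only; additive background changes or channel-specific motion are not
  modelled.
* The simulator's defocus is an isotropic Gaussian; realistic optics
  defocus asymmetrically, which would slow (not break) the focus lock.
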