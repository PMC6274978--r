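---
title: "Automated calcium-profile extraction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated calcium-profile extraction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(furatrack)
```

## The problem

Intracellular Ca^2+^ concentration regulates proliferation and migration of
vascular endothelial cells, and the ratiometric dye Fura-2 is the standard
probe for long recordings: the cell is excited alternately at 340 and
380 nm, emission is read at 510 nm, and the 340/380 intensity ratio rises
with [Ca^2+^]~i~. A *calcium profile* (CP) is the time series of the mean
ratio inside a region of interest (ROI) drawn around one cell nucleus.

In intact-vessel preparations the endothelial monolayer sits on smooth
muscle that contracts in response to both chemical agonists (ATP) and
mechanical injury, so cells drift during an experiment, transiently dim or
vanish for a few frames, and — at an injury site — die and disappear for
good. Manual ROI repositioning across hundreds of frames is slow and
error-prone, and an ROI left behind by its cell injects false negatives
into the Ca^2+^ signal. `furatrack` automates the whole chain: ratio-image
construction, area-calibrated segmentation, multi-cell tracking with gap
bridging, ONLINE/OFFLINE reliability management, and per-cell CP extraction
with a per-frame performance figure.

## Pipeline

For each run (see `run_pipeline()`):

1. **Load** the two 8-bit TIFF sequences (one per excitation wavelength);
   deeper inputs are rescaled to the 0–255 working range so the calibrated
   thresholds below stay comparable.
2. **Ratio**: the RATIO stack is the frame-by-frame, pixel-by-pixel
   quotient 340/380, computed in real arithmetic. Frames are paired by
   index; zero-denominator pixels map to ratio 0 (flagged), keeping
   downstream means finite. The inputs are never modified: the 340-nm
   sequence is used afterwards for calibration, segmentation and tracking
   (it carries the better contrast), the 380-nm sequence only for the
   ratio.
3. **Calibrate**: from sample cell areas (user ROIs or the areas of
   components found in frame 1), the processing window side is
   \( w = \lceil a\sqrt{\mu_{\mathrm{areas}}} \rfloor \) (round half-up),
   with scale factor \(a = 2\) by default — the value that minimises the
   mask mean-square error against expert segmentations in calibration
   experiments (`calibrate_a()` reproduces that selection procedure for any
   ground truth you supply).
4. **Segment** every 340-nm frame: median filter of side
   \(w_{\mathrm{median}} = \max(1, \lceil w/8 \rfloor)\), linear histogram
   stretch to [0, 255], Niblack local thresholding
   \(T(x,y) = m(x,y) + k_T\, s(x,y)\) with \(k_T = 1\) over the
   \(w \times w\) window, then opening (disc r = 3), hole filling and
   dilation (disc r = 1). Components are labelled 8-connected with
   unweighted centroids.
5. **Track** (below), extracting each found cell's CP as the mean ratio in
   its relocated \(w \times w\) ROI.
6. **Extract & store**: long-format profiles, per-cell summaries (mean CP
   over found frames, final status) and the per-frame density
   \(\rho_i = 100 \times \mathrm{ONLINE}_i / \mathrm{blobs}_i\) are written
   as CSV together with a YAML echo of the configuration.

## Tracking model

Tracking is overlap-first. Each selected cell carries a *kernel*: the
binary mask of the component it was last found in. Advancing to frame
*n*, the kernel is ANDed with the labelled frame; one overlapping
component is accepted outright. With zero or several candidates, the
Kalman-predicted position decides — containment first, then the nearest
candidate centroid within a gate of \(w/2\) px. The kernel persists across
missing frames, so a cell that dims for a frame or two is usually
re-acquired by intersection the moment it reappears; the prediction path
is the fallback, not the primary mechanism.

Each cell has a *reliability counter*: reset on every successful find,
incremented on every miss. When it reaches the reliability limit RL
(default 3, configurable) the track is tagged OFFLINE permanently and is
no longer searched — the fate of cells killed at an injury site. Only
ONLINE cells are tracked. \(\rho\) can exceed 100% when vanished-but-still-
ONLINE cells outnumber the binary objects of a noisy frame; it drops as
tracks retire, and its mean is nondecreasing in RL.

### Kalman filter

The motion model is constant acceleration driven by white jerk. Per axis
the state block is position/velocity/acceleration with transition
\[
F_{\mathrm{axis}} =
\begin{pmatrix} 1 & T & T^2/2\\ 0 & 1 & T\\ 0 & 0 & 1 \end{pmatrix},
\qquad T = 3\ \mathrm{s},
\]
and the observation picks out the two positions. The process noise enters
through \(q = (T^3\sigma_{Jx}/3,\ T^2\sigma_{Jx}/2,\ T\sigma_{Jx},\
T^3\sigma_{Jy}/3,\ T^2\sigma_{Jy}/2,\ T\sigma_{Jy})\) with
\(Q = q^\top q\), and \(R = \mathrm{diag}(\sigma_x^2, \sigma_y^2)\). The
observability matrix \([H; HF; \dots; HF^5]\) has full rank 6, so position
observations determine the whole state. Jerk levels are estimated from
manually tracked cells (`estimate_jerk_stats()`: third forward difference
of position over \(T^3\), sample SD per cell, averaged over cells); the
package defaults are the reference values
\(\sigma_{Jx} = 0.0269,\ \sigma_{Jy} = 0.0993\) (px/s^3^) with
\(\sigma_x = \sigma_y = 0.001\) px, chosen so corrected estimates sit
essentially on the measurements while Q keeps the update non-singular.

Two structural properties of this design are worth knowing. First,
\(Q = q^\top q\) is a rank-one outer product: both axes share a single
noise input, so the pair \((F, q)\) is not controllable and the filter
couples the axes — part of a y-innovation is attributed to x. On a
benchmark trajectory with constant x and sinusoidal y, the x-error is
therefore *larger* than the y-error even though x never moves; this is a
property of the model, not a defect of the implementation, and it is why
the correction cannot pin both coordinates exactly for motion the model
cannot follow (it does pin them, to 10^-6^ px, for constant-acceleration
motion). Second, because \(\sigma_{x,y}\) are tiny, the filter essentially
differences the measured centroids to estimate velocity and acceleration;
measurement jitter is amplified accordingly, which is why coasting through
missing frames (prediction only, one predict per missing frame, no
correction) degrades with gap length and why the overlap kernel — not the
prediction — is the primary re-acquisition mechanism.

Unspecified details fixed here: the state is initialised at the first
observed centroid with zero velocity and acceleration, and
\(P_0 = \mathrm{diag}(\sigma_x^2, 1, 1, \sigma_y^2, 1, 1)\) — a zero-motion
prior appropriate for slow cells with moderately uninformative
velocity/acceleration variances (1 px/s, 1 px/s^2^).

## Numerical choices

* Niblack uses summed-area tables of \(I\) and \(I^2\) (cost independent of
  \(w\)); local SD is the population form
  \(\sqrt{E[I^2] - E[I]^2}\) clamped at 0 against round-off. Windows are
  cropped at image borders (statistics over the valid intersection), the
  comparison is strict (\(I > T\): a uniform frame is all background), and
  a scale-relative epsilon (\(10^{-9}(\max|I|+1)\)) guards the comparison
  against summed-area cancellation, which can return means of \(-10^{-12}\)
  on constant regions. The implementation is verified bit-identical to a
  direct per-window computation on random images.
* Window convention everywhere (median filter, ROI, Niblack): side-\(w\)
  windows extend \(\lfloor (w-1)/2 \rfloor\) pixels before and
  \(\lfloor w/2 \rfloor\) after the centre; coordinates are 0-based,
  x = column, y = row, origin at the top-left pixel centre.
* A constant frame passes the histogram stretch unchanged (no 0/0).
* Hole filling means background regions not 4-connected to the image
  border; foreground components are 8-connected, labelled in raster order.
* Ties in the `calibrate_a()` grid break towards the smaller scale factor.
* ROIs are cropped at image borders rather than rejected, since injury
  drives cells towards the field edge; CP samples are taken only on frames
  where the cell was actually found, so missing frames thin the series
  instead of injecting false zeros.

## The synthetic benchmark

Because no image sequences are deposited with the reference experiments,
validation rests on two generators with exact ground truth.

`gen_sinusoid_test()` renders a single blob of the average calibrated cell
area (100 px^2^) moving along \(x = c\),
\(y = y_0 + A\cos(2\pi f t)\) with a 36 px peak-to-peak excursion and
\(f = 4\) full cycles over 100 frames (\(t\) uniform on [0, 1): at
\(T = 3\) s a literal 4 Hz would alias hopelessly, so cycles-per-sequence
is the only readable interpretation). `sinusoid_kalman_test()` measures
blob centroids and runs the filter in predictor-corrector mode, or with a
contiguous 5-frame mid-sequence observation gap bridged by prediction
alone (the gap length is a configurable stand-in for the unspecified
"several missed points"). Per-axis mean-square errors are compared against
the analytic trajectory; the package's acceptance bound is the ROI
criterion — each axis MSE below \((w/2)^2\), i.e. the estimate stays inside
the average ROI.

`gen_phantom()` renders a dual-wavelength multi-cell phantom. Cell
brightness is \(c\sqrt{\mathrm{CP}}\) at 340 nm and \(c/\sqrt{\mathrm{CP}}\)
at 380 nm so the noise-free pixel ratio inside a cell equals its calcium
waveform (baseline 0.85, rapid peak, exponential decay to a plateau —
the biphasic shape of agonist responses); the background ratio sits at the
baseline. Motion is a coherent tissue drift shared by all cells (AR(1)
per-frame displacement, marginal SD 0.5 px, correlation 0.8) plus 0.1 px
independent jitter: in-situ endothelium rides the smooth-muscle layer, so
cells move together rather than diffusing through one another, and an
overlap tracker is entitled to assume neighbours stay neighbours. Optional
per-cell dropout schedules emulate transient dimming (runs of 1–2 frames,
i.e. 3–6 s) or injury-style permanent disappearance; an optional jump
event emulates the injury jolt. Gaussian intensity noise (SD 5/255 by
default) is added to both channels. The ground-truth CP of a cell is the
ROI mean of the noise-free ratio at the true centroid — what an ideal
extractor would report.

What the phantom does *not* emulate: photorealistic optics (PSF, vignetting,
photobleaching), spatially varying background motion fields, cell shape
change, touching or dividing cells. Passing the phantom benchmarks
therefore demonstrates the correctness of the pipeline's logic and its
robustness to noise, drift and dropout — not performance on arbitrarily
crowded or deforming tissue.

## Problem sizes used in the test-suite benchmarks

The packaged checks run the full pipeline on a 50-frame, 30-cell,
256×256 px phantom with 0.5 px/frame drift and 10% transient dropouts
(frame-association accuracy and CP fidelity), an 8-cell lifecycle phantom
reproducing the one-cell-dies scenario at RL = 3, a 20-cell/60-frame
dropout phantom for the RL sweep {3, 5, 7}, 100 random 64×64 images for
the Niblack equivalence check, and 100 Monte-Carlo replicates of 15 tracks
× 100 frames for jerk-recovery. These sizes give stable statistics while
keeping a complete run in tens of seconds on one core.

## Known limitations

* Association is greedy and per-cell; two tracks may legitimately claim the
  same component (the reference workflow tolerates ROI/blob mismatches),
  and merge/split events (mitosis, collisions) are out of scope.
* The rank-one process noise couples the axes (see above); users wanting
  axis-decoupled estimation should be aware this follows the reference
  model deliberately.
* Ratio values are reported as-is; conversion to absolute [Ca^2+^]
  requires calibration constants outside the scope of the package.
* OFFLINE is absorbing by design: a cell that recovers after RL missed
  frames starts no new track.
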