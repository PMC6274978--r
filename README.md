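# furatrack

Automated intracellular calcium-profile extraction from dual-wavelength
Fura-2 fluorescence image sequences of endothelial monolayers.

## The problem

Fura-2 is excited alternately at 340 and 380 nm; the 340/380 emission
ratio rises with intracellular Ca²⁺, and a cell's **calcium profile (CP)**
is the time series of the mean ratio inside a region of interest (ROI)
around its nucleus. In intact-vessel preparations the monolayer sits on
smooth muscle that contracts under chemical (ATP) or mechanical (injury)
stimulation, so cells drift, transiently dim, or — at a lesion — die and
vanish. Extracting hundreds of CPs by manually repositioning ROIs frame by
frame is slow and injects artifacts; an ROI left behind by its cell
records a false negative in the Ca²⁺ signal.

`furatrack` automates the chain for experimenters analysing such
recordings:

* **Ratio sequence** — pixelwise 340/380 quotient per frame, computed in
  real arithmetic without touching the raw stacks.
* **Calibration** — the processing window side is `w = round(a·√μ_areas)`
  from sample cell areas, `a = 2` by default (the scale that minimises
  segmentation error against expert masks; `calibrate_a()` reruns that
  selection against any ground truth).
* **Segmentation** — per 340-nm frame: median filter (side `w/8`), linear
  histogram stretch, Niblack local threshold `T(x,y) = m(x,y) + k_T·s(x,y)`
  (`k_T = 1`) over `w × w` windows via integral images, then opening
  (disc r = 3), hole filling, dilation (disc r = 1), 8-connected labelling.
* **Tracking** — overlap-first multi-target tracking: each cell's kernel
  (its last-found component mask) is ANDed with the next frame; a 6-state
  constant-acceleration Kalman filter (white-jerk process noise
  `Q = qᵀq`, near-noiseless observation model) resolves ambiguities and
  bridges missing frames by prediction. A per-cell reliability counter
  retires a track as OFFLINE after RL consecutive misses (default 3).
* **Extraction** — per-cell CP from the relocated `w × w` ROI on the ratio
  frames, per-cell summaries, and the per-frame tracked-cell density
  `ρ_i = 100 · ONLINE_i / blobs_i` as figure of merit.
* **Synthetic benchmarks** — a sinusoidal single-cell trajectory for the
  Kalman filter and a dual-wavelength multi-cell phantom (coherent tissue
  drift, transient/permanent dropouts, biphasic CP waveform) with exact
  ground truth for every downstream test.

## Worked example

Generate a phantom whose truth is known, run the pipeline pieces, and look
at the result:

```r
library(furatrack)

spec <- phantom_spec(n_cells = 12, n_frames = 40, dim = c(192, 192),
                     dropout = make_dropout_schedule(12, 40, rate = 0.1,
                                                     run_range = 1:2,
                                                     seed = 2),
                     seed = 2)
ph     <- gen_phantom(spec)
params <- segmentation_params(ph$w)   # w = 20 from the 100 px² mean area
lab    <- segment_sequence(ph$seq340, params)
ratio  <- make_ratio_sequence(ph$seq340, ph$seq380)
res    <- run_tracking(lab, ratio, "all", params, rl = 3)

res
#> <tracking_result> 12 track(s), 12 ONLINE, 40 frame(s), mean rho 112.85%

head(summarize_tracks(res), 4)
#>   cell_id mean_cp frames_found fraction_found status
#> 1    A001  0.8829           36          0.900 ONLINE
#> 2    A002  0.8856           35          0.875 ONLINE
#> 3    A003  0.8825           36          0.900 ONLINE
#> 4    A004  0.8803           36          0.900 ONLINE

association_accuracy(res, ph$truth)
#> [1] 1
```

Every cell stays ONLINE through its 1–2-frame dropouts (kernel overlap
re-acquires it on reappearance), each `mean_cp` sits at the phantom's
baseline-dominated ROI mean (~0.88 on the ratio scale), and the mean
density exceeds 100% exactly as in real recordings — transiently vanished
cells keep more ROIs ONLINE than there are binary objects in a frame.
`fraction_found` = 0.9 reflects the 10% dropout schedule, and
`write_profiles(res, "profiles.csv")` stores the long-format CPs plus a
per-cell summary.

For file-based runs, `run_pipeline(run_config(dir340, dir380, out))`
chains loading, calibration, ratio, segmentation, tracking and CSV output;
the same flow is scriptable from a shell via the thin CLI at
`system.file("cli", "furatrack.R", package = "furatrack")` (subcommands
`run` and `simulate`).

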