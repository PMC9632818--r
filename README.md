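# handkin

Validation tooling for markerless hand kinematics: infer 2D finger
joint angles from single-camera hand keypoint streams and quantify
their agreement with the 2D projection of marker-based optical motion
capture.

## Who it is for

Hand-biomechanics and rehabilitation researchers who want to know
whether pose-estimation keypoints (OpenPose-style JSON: 21 landmarks
per hand with confidences) are accurate enough to replace reflective
markers for measuring finger range of motion, and who need a tested,
configuration-driven pipeline rather than one-off scripts.

## What it computes

Two synchronized streams — per-frame 2D keypoints and 26-marker 3D
trajectories projected onto the frontal image plane — are cleaned and
compared over four guided activities (finger abduction/adduction,
radial walking, MCP flexion, thumb opposition):

* **Cleaning**: low-confidence gating, linear gap interpolation,
  Hampel outlier replacement (9-frame window, threshold 1 robust SD,
  where robust SD = 1.4826·MAD), and zero-phase 2nd-order Butterworth
  smoothing (3 Hz markerless / 5 Hz marker stream, 30 Hz capture), plus
  annotation-driven correction of digit-swap tracking errors.  A
  residual-analysis helper re-derives the cutoff from data.
* **Kinematics**: included joint angles
  θ = arccos(A·B / |A||B|) at the MCP/PIP/DIP (thumb MCP/IP) joints
  and inter-digit angles between base→tip direction vectors, organised
  in per-activity catalogs (8 + 8 + 10 + 10 = 36 angles per participant
  over both hands); Total Active Flexion TAF = max − min per segment,
  with activity-level TAF taken on the repetition-averaged cycle.
* **Agreement**: per-series RMSE and mean absolute difference;
  Bland–Altman bias, SD of differences and 95% limits of agreement
  (bias ± 1.96·SD); ordinary least squares of markerless on
  marker-based TAF with R².
* **Synthetic ground truth**: an articulated planar-hand simulator
  generates commanded joint trajectories, clean 3D markers and
  corrupted keypoint streams (Gaussian jitter, spike outliers, digit
  swaps, occlusion dropouts) in the exact file dialects the pipeline
  reads, so the whole validation runs end to end with no external data.

## Worked example

```r
library(handkin)
fx <- tempfile(); out <- tempfile()
make_fixtures(fx, n_participants = 4, seed = 1, cycle_s = 2)
res <- run_validation(pipeline_config(fx, out))
head(res$rmse[, c("participant","hand","activity","repetition",
                  "angle_name","rmse","mean_abs_diff")])
#>   participant  hand activity repetition    angle_name  rmse mean_abs_diff
#> 1         P01 right  abd_add          1  thumb-middle 0.892         0.711
#> 2         P01 right  abd_add          1  index-middle 0.896         0.692
#> 3         P01 right  abd_add          1   ring-middle 0.754         0.642
#> 4         P01 right  abd_add          1 little-middle 1.392         1.247
#> 5         P01 right  abd_add          2  thumb-middle 0.925         0.788
#> 6         P01 right  abd_add          2  index-middle 1.065         0.772
res$report$bland_altman
#>                activity   bias sd_diff loa_lower loa_upper  n
#>                 abd_add  0.261   0.795    -1.296      1.82 24
#>          radial_walking  2.639   0.850     0.974      4.30 24
#>             mcp_flexion -1.384   1.566    -4.453      1.68 32
#>        thumb_opposition -0.752   1.969    -4.612      3.11 32
res$report$regression
#>                activity slope intercept    r2  n
#>                 abd_add 0.911      2.56 0.771 24
#>          radial_walking 0.894      4.97 0.854 24
#>             mcp_flexion 0.935      3.32 0.815 32
#>        thumb_opposition 0.970      1.66 0.946 32
```

Reading the output: each `rmse` row is the frame-wise disagreement (in
degrees) between the two methods for one angle of one repetition — here
about 1° because the simulated keypoint jitter is 2 px on ~90 px
fingers.  The Bland–Altman table pools repetition-mean TAF of the
2nd–5th digit angles of both hands per activity: bias is the mean
markerless − marker-based difference and the LoA bracket 95% of
differences.  The regression table relates the two methods' TAF values;
slopes near 1 and R² of 0.77–0.95 reflect the between-participant
range-of-motion variability the simulator injects.

The report directory contains `series_index.csv` (one row per
extracted angle series per source), `taf.csv`, `rmse.csv`,
`rmse_by_digit.csv`, `agreement_ba.csv`, `agreement_regression.csv` and
a deterministic `log.txt`.  A thin CLI over the same functions lives at
`inst/cli/handkin.R` (`fixtures` and `run` subcommands).

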