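# skyclass

Synthetic flight trajectories and recurrent classification of birds versus
drones, implemented natively in R and RcppArmadillo with no external deep
learning dependency.

The package provides a self-contained testbed for trajectory-based
discrimination of biological and mechanical flight:

- **Bird simulator** — a stochastic bank-angle kinematic model of flapping
  flight. A behavioural acceleration command (goal attraction, altitude
  preference, crosswind compensation, obstacle repulsion, exploration noise)
  is converted into a desired bank angle; the bank relaxes with a rate limit,
  the realized lateral acceleration is capped at `g·tan(φ_max)`, the heading
  rotates by a Rodrigues rotation, and the airspeed relaxes toward a cruise
  speed with tailwind coupling. Three species presets are included: `pigeon`,
  `gull` and `peregrine`.
- **Drone simulator** — a point-mass quadrotor with PID waypoint control,
  thrust and tilt saturation, flying piecewise-linear survey patterns.
- **Shared environment** — wind with exact-discretization Ornstein–Uhlenbeck
  gusts plus a Gaussian thermal updraft; both flyer types are advected by the
  same field.
- **Interchange format** — one JSON file per trajectory
  (`movement_history` of `[x, y, z]` positions, `dt`, labels), written with
  17 significant digits so round trips are bit-exact.
- **Statistics & plausibility audit** — speed/curvature/velocity-
  autocorrelation summaries, and a biomechanical audit that checks speed
  limits, Savitzky–Golay–estimated lateral acceleration against
  `g·tan(φ_max)` (with a derived allowance for wind and noise contamination
  of the ground-track estimate), continuity, and dataset diversity.
- **Classifier** — a from-scratch bidirectional LSTM (or GRU), 2 layers,
  hidden size 64 per direction, dropout 0.2, with a per-frame logistic head,
  trained with masked binary cross-entropy on zero-padded sequences using
  Adam (lr 1e-3, 35 epochs). Inputs are the raw 3-D positions, globally
  standardized over the pooled training frames and downsampled to 100 frames
  per sequence. Gradients are hand-derived and verified against finite
  differences (≤ 3.3e-7 relative error).
- **Camera** — a pinhole model plus a simple renderer for image-plane tracks
  (PNG frames with apparent-size-correct target discs).

## Worked example

```r
library(skyclass)

## 1. Generate a small balanced dataset (25 birds, species cycled, + 25 drones)
dir <- file.path(tempdir(), "demo")
generate_dataset(25, dir, seed = 7)          # 100 s at dt = 0.03 s each
recs <- load_dataset(dir)

## 2. Inspect and audit one bird trajectory
rec <- recs[[1]]
rec$species                                  # "pigeon"
nrow(rec$positions)                          # 3334 positions
summary(trajectory_summary(rec)$speed)       # ground speed, m/s

rep <- plausibility_report(rec, species_preset(rec$species))
nrow(rep$violations)                         # 0
rep$max_lateral_accel                        # 11.85 m/s^2 (ground estimate)
rep$lateral_accel_bound                      # 8.23 = g*tan(phi_max)
rep$lateral_accel_allowance                  # 7.12 (wind/noise allowance)

## 3. Train a classifier (full defaults: hidden = 64, 35 epochs, batch 16)
cfg   <- classifier_config(seed = 7)
model <- train_classifier(recs, cfg, verbose = TRUE)

## 4. Score held-out sequences (mean per-frame P(drone))
down  <- lapply(recs, downsample, target_len = cfg$max_len)
test  <- split_dataset(down, cfg$split_fraction, cfg$seed)$test
predict_records(model, test)
evaluate_auc(model, test)

## 5. Persist and reload (predictions are bit-identical after reload)
save_model(model, "model.json")
model2 <- load_model("model.json")
```

A dataset of 25 per class trains in seconds but is too small for the model
to converge; it is meant for exploring the API. At the intended scale — 200
trajectories per class, full default configuration — a seeded run produces
(seed 1; ~4 min LSTM + ~2 min GRU on one CPU):

| quantity | value |
|---|---|
| LSTM training loss, mean of epochs 31–35 | 0.156 |
| LSTM validation AUC, final epoch | 1.000 |
| GRU training loss, mean of epochs 31–35 | 0.0008 |
| median held-out drone confidence (mean per-frame P(drone)) | 0.917 |

Note the GRU converges faster and lower than the LSTM on this synthetic
dataset (see the methods vignette for discussion).

## Command-line interface

A thin CLI wraps the package (installed under `inst/cli/`):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "skyclass.R", package = "skyclass"))')" \
    generate --n-per-class 25 --out data/ --seed 7
# likewise: train, predict, evaluate, validate, render
```

## Documentation

The methods vignette (`vignettes/methods.Rmd`) documents the model
equations, integration scheme, species presets with units and rationale,
the classifier architecture and training protocol, the plausibility-audit
allowance derivation, and resolved design questions.
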