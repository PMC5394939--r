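# prfdecode

Population receptive field (pRF) modelling and stimulus position decoding
for fMRI-style voxel populations.

Large receptive fields in higher visual areas (LOC, FFA) are often taken to
imply that position information is lost there; population-coding theory
says otherwise, provided RF centres tile the visual field. `prfdecode`
provides a complete, reproducible pipeline for studying that question with
synthetic voxel populations whose geometry emulates six visual areas
(V1-like through FFA-like): a momentum-random-walk stimulus simulator, a
Gaussian pRF forward model, maximum-likelihood model fitting, two position
decoders, and the population-level analyses built on top.

## The model

A disk of radius 0.8° wanders inside a 6° × 6° field:
s(t+1) = s(t) + c·p(t), with the unit direction p perturbed each frame by
Gaussian noise (σ_stim = 0.1) and renormalised, and reflected at the field
edges (c = 0.008°/frame at 60 Hz). Voxel n responds to the stimulus at
(s_x, s_y) with

    r_n = C0 + C1 ∫ exp(−((x−μx)² + (y−μy)²) / 2σ²) · I(x, y; s_x, s_y) dx dy + ε,
    ε ~ N(0, σ_noise²),

where I is the binary disk indicator. The six constants per voxel are
estimated by grid-initialised profiled maximum likelihood; voxels with
fitted centres inside the 7.6° × 7.6° span field and fit correlation
r > 0.2 are retained. Position is decoded per fMRI volume either by
maximising the population log-likelihood over a 60 × 60 candidate grid or
by kernel support-vector regression (kernel exp(−‖r1−r2‖²/N)), always under
leave-one-run-out cross-validation. Downstream analyses compute per-axis
accuracy (Pearson r between true and decoded coordinates), Fisher-z group
statistics, RF-centre spread, accuracy with matched voxel counts, and the
exponential decay constant τ of accuracy as near-stimulus RFs are excluded.

See the methods vignette (`vignettes/position-decoding.Rmd`) for the full
model account, parameter choices, and known limitations.

## Worked example

```r
library(prfdecode)

# one trajectory and its fMRI volume series (two runs, 960 volumes)
sched <- run_schedule()                       # 1040-s run: 4 x 240-s blocks
traj  <- simulate_trajectory(trajectory_config(seed = 1),
                             2 * frames_per_run(sched))
vols  <- frames_to_volumes(traj, sched, n_runs = 2)

# a V1-like synthetic population and its noisy responses
preset <- area_presets(n_voxels = 100)[1, ]
pop    <- sample_population(preset, seed = 2)
series <- simulate_responses(pop, vols, seed = 3)

# fit pRF models on run 1 and inspect the selected voxels
fits <- fit_prf_population(dplyr::filter(series, run == 1),
                           dplyr::filter(vols, run == 1))
sel  <- select_voxels(fits)
nrow(sel)
#> [1] 76
dplyr::select(head(sel, 3), voxel, mu_x, mu_y, sigma, fit_r)
#> # A tibble: 3 × 5
#>   voxel    mu_x   mu_y  sigma fit_r
#>   <int>   <dbl>  <dbl>  <dbl> <dbl>
#> 1     1 -1.56    2.06  0.890  0.325
#> 2     2 -0.0606 -0.137 0.0778 0.228
#> 3     3  2.81   -0.743 1.08   0.319

# leave-one-run-out grid-ML decoding and its accuracy
decoded <- cross_validate(series, vols, method = "ml")
prediction_accuracy(decoded)
#> # A tibble: 1 × 3
#>   r_horizontal r_vertical n_volumes
#>          <dbl>      <dbl>     <int>
#> 1        0.675      0.627       960
```

76 of 100 voxels survive selection at this noise level; their fitted
centres and sizes sit near the generating values, and held-out decoding
recovers the stimulus coordinates with correlations around 0.65 per axis —
the regime real visual-cortex data occupy. `run_experiment()` chains the
whole design (multiple subjects, all six area presets, group statistics)
from a single seeded configuration, and `autoplot()` / `plot_*()` functions
render trajectories, RF-centre maps, accuracy profiles and decay curves.

A thin command-line wrapper is included at `inst/scripts/prfdecode.R`
(subcommands `run-all`, `simulate`, `decode`, `make-fixture`).

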