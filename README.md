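# skelrefine

Constraint-based cleaning of per-frame 3-D skeleton streams from
single-depth-camera SDKs (Kinect v2 style, 21 joints; Nuitrack style,
20 joints).

SDKs estimate each frame independently, so the output violates what every
physical skeleton satisfies: bone lengths are constant per person, mirrored
limbs have equal lengths, and motion is smooth. `skelrefine` learns stable
per-bone reference lengths from an initialization window, screens joints
for trust (tracking state, bone-length deviation, motion plausibility),
predicts positions by a combined forward/backward second-order
finite-difference scheme (accepting a fixed 3-frame latency — 0.1 s at
30 Hz), and refines each frame by a quasi-Newton minimization of

```
E = λ1 Σ_i ( w_i ||v_i − v̂_i||² + u_i ||p_i − v̂_i||² )
  + λ2 Σ_(i,j)∈E ( l_ij(v̂) − l*_ref )²
```

with `v` the observation, `p` the prediction,
`u = exp(−k²/2σ²)`, `w = 1 − u` driven by the per-joint count `k` of
consecutive inadequate predictions, and `l*_ref` the reference length of
the bone's left/right symmetry class (defaults λ1 = 0.2, λ2 = 8.25,
σ = 3). A seeded synthetic-motion generator (constant bone lengths by
construction, angle-dependent sensor noise, outlier runs, dropouts,
left/right flips) and an evaluation module (per-bone length variance,
prediction-disagreement series, symmetry error, ground-truth recovery)
make the whole pipeline testable without any capture hardware.

## Worked example

```r
library(skelrefine)

cfg <- generator_config(frames = 300, noise_base = 0.005,   # 5 mm noise
                        outlier_rate = 0.05 / 21, seed = 1) # 5% outlier frames
sim <- simulate_sequence(cfg)
res <- refine_sequence(sim$noisy, refine_config(init = init_config(100)))

bone_length_variance(sim$noisy)$total
#> [1] 0.02103362
bone_length_variance(res$sequence)$total
#> [1] 6.517549e-06
head(res$refs[, c("class", "l_ref_final")])
#>                    class l_ref_final
#> 1     SpineBase-SpineMid     0.19990
#> 2 SpineMid-SpineShoulder     0.21911
#> 3     SpineShoulder-Neck     0.08254
#> 4              Neck-Head     0.15015
#> 5 SpineShoulder-Shoulder     0.17991
#> 6         Shoulder-Elbow     0.30090
```

The total per-bone length variance drops by ~3 orders of magnitude
(0.021 m² → 6.5e-6 m²): the length-constancy and symmetry constraints do
their job. Every recovered reference length is within 3 mm of the
generator's ground truth here (true values 0.20, 0.22, 0.08, 0.15, 0.18,
0.30 m for the rows shown). Positional accuracy is a different story — the
default weighting direction anchors reliable joints to
their (noisier) predictions; see the methods vignette
(`vignettes/skeleton-refinement.Rmd`) for the analysis and the
`energy_config(swap_uw = TRUE)` alternative.

Sequences are read and written as JSON Lines
(`{"t": ..., "joints": [{"name", "p", "state"}, ...]}` — one frame per
line) via `read_sequence()` / `write_sequence()`, with a CSV export for
spreadsheets. A command-line layer wraps the three stages:

```sh
Rscript -e 'skelrefine::skelrefine_cli()' simulate --frames 600 --seed 7 \
    --out truth.jsonl --noisy noisy.jsonl --log corruptions.csv
Rscript -e 'skelrefine::skelrefine_cli()' refine --input noisy.jsonl \
    --dialect kinect21 --output refined.jsonl --init-frames 100
Rscript -e 'skelrefine::skelrefine_cli()' evaluate --input noisy.jsonl \
    --refined refined.jsonl --truth truth.jsonl --report report.json
```

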