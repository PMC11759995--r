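# petromap3d

Three-dimensional interpolation of soil petroleum-hydrocarbon concentration
from borehole surveys, for environmental scientists and site-remediation
engineers who need contamination maps from sparse drilling campaigns.

A survey drills boreholes on a horizontal grid and samples each at several
depths; every sample carries coordinates, depth, six soil physico-chemical
covariates (pH, wet bulk density, permeability coefficient, organic carbon,
average water yield, salinity) and the petroleum-hydrocarbon index (TPH).
`petromap3d` arranges the samples as a tensor
`X ∈ R^{D×m×n×T}` (D depth layers, m×n borehole lattice, T = 9 feature
channels) and learns an interpolator `X → ŷ ∈ R^{D×m×n}` with an
encoder–decoder 3D convolutional network:

* encoder: three valid 3D convolutions (16, 32, 64 filters; kernels 2×2×2,
  2×2×2, 1×2×1), each followed by a channel-attention block
  `M_c = σ(MLP(maxpool(F)) + MLP(avgpool(F))) ∈ (0,1)^C` that rescales the
  covariate channels;
* decoder: dropout, then three transposed convolutions (Tanh); the final
  kernel is solved at build time so the output spatial shape equals the
  input's exactly.

Training is full-batch Adam on the masked MSE
`L = (1/|S|) Σ_{i∈S} (y_i − ŷ_i)²` over observed training cells S, with
reduce-on-plateau learning-rate decay, and evaluation reports
RMSE = √(Σ(y−ŷ)²/n), R² = 1 − SS_res/SS_tot and MAE on held-out 7:2:1
splits. From-scratch classical baselines are included: ordinary kriging in
3D (empirical semivariogram, WLS variogram fit, Lagrange-constrained
system), inverse-distance weighting, a feed-forward network on the flat
feature vectors, and an adapter that admits any external `fit`/`predict`
regressor. A seeded synthetic generator of 3D contaminated-soil fields
(correlated latent field, near-surface decay, localized hotspot,
range-calibrated covariates) makes every stage testable without field data.

## Worked example

```r
library(petromap3d)

bench <- run_scenario_benchmark("paperlike", seeds = 1:3,
  methods = c("kriging3d", "idw", "fnn", "cnn2d", "cnn3d", "cnn3d_cam"),
  train_cfg = train_config(epochs = 150))
print(bench$summary, row.names = FALSE)
```

```
    method          r2       rmse        mae n_runs
       fnn  0.72737604 0.08969117 0.07620256      3
     cnn2d  0.06541798 0.18916826 0.15035879      3
       idw  0.05612302 0.17322702 0.13687374      3
 kriging3d -0.01012884 0.18287054 0.13893864      3
     cnn3d -1.02515227 0.26692325 0.21193888      3
 cnn3d_cam -1.13082563 0.25285639 0.19246414      3
```

Each row is the median over three fresh synthetic fields of test-split
metrics on the normalized (0–1) TPH scale: the feed-forward baseline
explains ~73% of held-out variance here, the spatial methods much less —
on a 143-sample field with rough vertical structure, pointwise covariate
regression generalizes while the 20k-parameter spatial network overfits its
100 training cells (negative R² means worse than predicting the mean).
Channel attention still improves the 3D network's error over its plain
counterpart, and the methods vignette discusses why these desk-scale
synthetic conditions bound what can be concluded about larger real surveys.

A single model end to end:

```r
params  <- scenario_params("paperlike", seed = 1)
records <- generate_field(params)                  # 143 borehole samples
ds      <- prepare_dataset(records, seed = 1)      # grid + split + normalization
net     <- build_interpolator(model_config(seed = 1), dim(ds$grid$features))
fit     <- train(net, ds$grid, ds$split, train_config(epochs = 150, seed = 1))
evaluate(fit$network, ds$grid, ds$split, "test")
ck      <- save_checkpoint(fit$network, ds$norm, "model.json")
maps    <- predict_map("model.json", records, m = 12, n = 9, out_dir = "maps")
```

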