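aerial:
  width_px: 288
  height_px: 288
  gsd_m: 0.0775
  sea_state: 1
  n_whales: 1
  whale_length_m:
  - 7.0
  - 9.0
  n_duplicate_frames: 2
  distractors: []
  contrast: 0.15
  n_ms_bands: 0
  seed: 1
satellite:
  width_px: 96
  height_px: 96
  gsd_m: 0.31
  sea_state: 1
  n_whales: 1
  whale_length_m:
  - 12.0
  - 16.0
  n_duplicate_frames: 1
  distractors: []
  contrast: 0.15
  n_ms_bands: 0
  seed: 1001
n_aerial_whale: 24
n_aerial_water: 12
n_satellite_whale: 10
n_satellite_water: 10
grid:
  tile_px: 32
  stride_px: 32
  origin:
  - 0
  - 0
retention_threshold: 0.2
train:
  architecture: smallnet
  pretrained: no
  learning_rate: 0.02
  momentum: 0.9
  step_size_epochs: 7
  decay_factor: 0.1
  batch_size: 16
  n_epochs: 12
  sampler: weighted
  input_px: 32
  seed: 1
baselines:
- model: ridge
  alpha: 1.0
  C: 1.0
  kernel: radial
  seed: 1
- model: c_svc
  alpha: 1.0
  C: 1.0
  kernel: radial
  seed: 1
water_test_n: ~
seed: 1
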