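# Desk-scale run configuration (64 px synthetic tiles, tiny model).
# Full-scale published defaults are the train_config()/model_config()
# defaults: tile_size 224, base_channels 64, state_dim 16, lr 1e-4,
# 100 epochs, warm-up 5, batch 32.
model:
  tile_size: 64
  base_channels: 8
  dropout: 0.1
  gmamba:
    kernel: 3
    state_dim: 8
  ud:
    lambda: 1.0
    eps: 1.0e-8
train:
  lr: 3.0e-3
  min_lr: 1.0e-4
  warmup_epochs: 2
  epochs: 15
  patience: 4
  batch_size: 32
  seed: 1
loss:
  gamma: 0.1
  ual_metric: pearson
  label_smoothing: 0.1
  class_weighting: true
augment:
  crop: true
  crop_scale: [0.8, 1.0]
  flip_h: 0.5
  flip_v: 0.5
  rotate: right-angle
  noise_sd: 0.01
data:
  dir: tiles
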