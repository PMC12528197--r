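# Default run configuration. Every field can be overridden by a user YAML
# (merged over these values) or programmatically via `overrides`.
synth:
  n_channels: 64
  fs: 256
  duration_s: 20
  n_recordings: 4
  class_signatures:
    alpha: {delta: 0.15, theta: 0.10, alpha: 1.00, beta: 0.20, gamma: 0.05}
    theta: {delta: 0.15, theta: 1.00, alpha: 0.10, beta: 0.20, gamma: 0.05}
  artifact_rate: 0
  line_noise_hz: 50
  line_noise_amp: 0
  noise_sigma_pct: 0
  epoch_window_s: 2
  seed: 1
  format: edf            # edf | bundle
filter:
  low_hz: 0.5
  high_hz: 50
  order: 5
  family: butterworth
preprocess:
  run_ica: true
  ica_seed: 1
  window_s: 2
  overlap_s: 0
model:
  n_layers: 6
  n_heads: 8
  d_model: 256
  seq_len: 16
  mask_lambda: 0.1
  mask_sparsity_lambda: 0.01
  dropout: 0.1
  layout: raw_frames
  standardize: true
train:
  lr: 0.001
  batch_size: 32
  max_epochs: 100
  patience: 10
  split: {train: 0.6, val: 0.2, test: 0.2}
  seed: 1
noise:
  levels: [10, 20, 30]
ablation:
  heads: [4, 8, 12]
  depths: [3, 6]
  lrs: [0.001]
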