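# Desk-scale end-to-end run: simulate a small cleavage-stage cohort, train
# the tiny FramePredictor and a small embryo cropper, forecast the held-out
# videos with the rolling next-7 strategy and evaluate with and without
# cropping. Designed to complete in a few minutes on one CPU.
study: cells_stage
category: transfer
rng_seed: 1
out_dir: embryocast_tiny_run
simulate:
  n_videos: 6
  image_size: 250
  fragmentation_rate: 0.05
preprocess:
  F: 7
  H: 64
  W: 64
split:
  n_eval: 2
  ratio: 0.8
predictor:
  scale_preset: tiny
  epochs: 1
  batch_size: 2
  learning_rate: 0.002
  steps_per_epoch: 24
  max_val_pairs: 6
cropper:
  depth: 2
  base_filters: 6
  epochs: 4
  batch_size: 8
  learning_rate: 0.001
  n_images: 24
forecast:
  strategy: next7
evaluate:
  truncations: [10, 14, 28]
  embedder_dim: 32
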