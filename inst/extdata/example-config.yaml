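# Example flimq pipeline configuration (see run_config() for the schema).
seed: 1
out_dir: flimq_run
grid:
  n_bins: 300
  bin_width_ns: 0.04
irf:
  fwhm_ns: 0.23
  peak_bin: 50
dataset:
  n_samples: 50000
  val_fraction: 0.2
  tau_range_ns: [0.1, 5.0]
  nt_range: [100, 10000]
array:
  n_rows: 192
  n_cols: 128
  peak_jitter_span_ns: 4
  hot_pixel_fraction: 0.01
  hot_pixel_rate_multiplier: 100
quant:
  w_bits: 1
  a_bits: 4
train:
  epochs: 100
  batch_size: 128
  learning_rate: 0.0001
cmm:
  window_start_bin: 50
  window_end_bin: 300
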