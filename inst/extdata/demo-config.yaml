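# Demonstration pipeline: 20-patient synthetic cohort, 1-minute records.
seed: 2024
cohort:
  n_no_poaf: 12
  n_poaf: 8
ecg:
  fs: 500
  duration_s: 60
  baseline_amp: 0.05
  powerline_amp: 0.02
  white_sd: 0.01
filter:
  lowpass_hz: 40
  highpass_hz: 0.5
  smooth_ms: 20
delineate:
  search_window_ms: 350
  pre_qrs_gap_ms: 40
qc:
  min_valid_fraction: 0.5
models:
  scheme: A
  k: 5
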