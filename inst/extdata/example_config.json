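{
  "seed": 1,
  "n_per_group": [37, 20, 20],
  "sampling_rate": 128,
  "duration": 16,
  "shared_frac": 0.8,
  "axes": 2,
  "segment_sec": 4,
  "overlap": 0.5,
  "cf_rest_threshold": 6.5,
  "postural_ratio_threshold": 1.5,
  "cf_postural_threshold": 6.5
}
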