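{
  "n_patients": 2000,
  "seed": 7,
  "preset": "ge30",
  "aki_criteria": "all",
  "endpoint": "kf15"
}
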