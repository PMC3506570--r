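{
  "alpha_endo": 60,
  "alpha_epi": -60,
  "orientation_noise_sd": 5
}
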