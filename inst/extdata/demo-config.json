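{
  "sim": {
    "trial_length_s": 30,
    "n_trials": 2,
    "phi": 0.9,
    "tonic_sd": 0.175,
    "noise_sd": 0.05,
    "blink_rate_hz": 0.2
  },
  "groups": [
    { "label": "parent", "n": 12,
      "effect": { "group_label": "parent", "onset_s": 10,
                  "magnitude_mm": -0.3, "ramp_s": 2 } },
    { "label": "child", "n": 12 }
  ],
  "stats": { "alpha_point": 0.1, "alpha_fw": 0.05, "n_sim": 2000 },
  "comparisons": [ { "a": "parent", "b": "child", "tail": "A_less" } ],
  "seed": 42,
  "log_level": "info"
}
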