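{
  "seed": 7,
  "phantom": {
    "tau_w": [0.068, 0.14, 0.17, 0.27, 0.34, 0.67],
    "times": [24, 48, 72, 96, 120, 144],
    "shape": [96, 96, 170],
    "tilt_deg": 0,
    "noise_mean": 30,
    "noise_sigma": 5
  },
  "filter_radius": 2,
  "trim_margin": 3,
  "streamer_threshold": 0.6667
}
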