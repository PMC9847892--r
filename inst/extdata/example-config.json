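{
  "phantom": {
    "dims": [220, 180, 60],
    "voxel_mm": 0.4,
    "pa_depth_mm": 33
  },
  "run": {
    "n_photons": 100000,
    "n_repeats": 4,
    "base_seed": 1,
    "roulette_threshold": 1e-9
  },
  "separation_cm": 2.9,
  "detector_side_mm": 8
}
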