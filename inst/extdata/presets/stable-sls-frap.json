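{
  "preset_version": 1,
  "name": "stable-sls-frap",
  "description": "FRAP of stably incorporated Sls label in mature larval muscle: dominant immobile fraction, 30-min movie at 1-min frames, deep bleach. Expected recovery at 29-30 min stays below 20%.",
  "frap": {
    "immobile_fraction": 0.9,
    "recovery_time_constant_s": 600,
    "bleach_depth": 0.8,
    "frame_interval_s": 60,
    "n_frames": 31,
    "n_prebleach": 3
  },
  "field_um": [40, 30],
  "muscle_um": 20,
  "pixel_size_um": 0.5,
  "muscle_level": 1000,
  "background_level": 50
}
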