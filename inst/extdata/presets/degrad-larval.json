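{
  "preset_version": 1,
  "name": "degrad-larval",
  "description": "Targeted degradation of Sls in larval muscle, quantified on the N-terminal (Nano2) channel: band amplitude reduced by 80% relative to control, identical background.",
  "geometry": {
    "sarcomere_length_um": 8.5,
    "epitope_offsets_um": {
      "Nano2": [
        0
      ]
    },
    "band_kind": {
      "Nano2": "point"
    },
    "amplitudes": {
      "Nano2": 1000
    },
    "psf_sigma_um": 0.25,
    "n_periods": 10
  },
  "pixel_size_um": 0.1,
  "reduction_factor": 0.8,
  "width_px": 12,
  "margin_px": 24,
  "background_level": 50,
  "analysis": {
    "min_prominence": 0.35,
    "min_separation_px": 34,
    "comment": "Band location must still work on the knocked-down image, where residual bands are dim: smoothing plus a prominence threshold above the noise-bump scale and a separation near 0.4 x the band period keep placement on real sarcomere loci."
  }
}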