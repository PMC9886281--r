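{
  "preset_version": 1,
  "name": "degrad-flight-nano39",
  "description": "Segment-wise degradation read out on a neighbouring epitope (Nano39) in flight muscle: ~50% band-amplitude reduction relative to control.",
  "geometry": {
    "sarcomere_length_um": 3.2,
    "epitope_offsets_um": {
      "Nano39": [
        0.3,
        2.9
      ]
    },
    "band_kind": {
      "Nano39": "point"
    },
    "amplitudes": {
      "Nano39": 1000
    },
    "psf_sigma_um": 0.25,
    "n_periods": 10
  },
  "pixel_size_um": 0.1,
  "reduction_factor": 0.5,
  "width_px": 12,
  "margin_px": 24,
  "background_level": 50,
  "analysis": {
    "min_prominence": 0.35,
    "min_separation_px": 13,
    "comment": "Band location must still work on the knocked-down image, where residual bands are dim: smoothing plus a prominence threshold above the noise-bump scale and a separation near 0.4 x the band period keep placement on real sarcomere loci."
  }
}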