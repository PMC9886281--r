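{
  "preset_version": 1,
  "name": "attenuation-nanobody",
  "description": "Depth attenuation of a small-label (nanobody) staining in thick adult muscle: decay length 10 um over a 10-slice, 1-um-step z-stack. Paired with 'attenuation-antibody' (4 um) this encodes the 2.5-fold penetration contrast.",
  "attenuation": {
    "lambda_um": 10,
    "I0": 1000,
    "z_step_um": 1,
    "n_slices": 10
  },
  "geometry": {
    "sarcomere_length_um": 3.2,
    "epitope_offsets_um": { "Nano2": [0] },
    "band_kind": { "Nano2": "point" },
    "amplitudes": { "Nano2": 1000 },
    "psf_sigma_um": 0.3,
    "n_periods": 10
  },
  "pixel_size_um": 0.1,
  "label": "nanobody"
}
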