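{
  "preset_version": 1,
  "name": "flight",
  "description": "Adult indirect flight muscle: ~3.2 um sarcomeres with a minimal I-band, so the Sls N- and C-terminal epitopes (0.15 um from the Z-disc) are unresolvable at the confocal PSF and both channels peak at the Z-disc.",
  "geometry": {
    "sarcomere_length_um": 3.2,
    "epitope_offsets_um": { "Nano2": [0], "Nano42": [0.15, 3.05] },
    "band_kind": { "Nano2": "point", "Nano42": "point" },
    "amplitudes": { "Nano2": 1000, "Nano42": 1000 },
    "psf_sigma_um": 0.3,
    "n_periods": 10
  },
  "pixel_size_um": 0.1
}
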