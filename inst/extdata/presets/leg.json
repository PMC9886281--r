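{
  "preset_version": 1,
  "name": "leg",
  "description": "Adult leg muscle: ~3.0 um sarcomeres with a short but resolvable I-band; the C-terminal Sls label forms a doublet 0.5 um either side of the Z-disc.",
  "geometry": {
    "sarcomere_length_um": 3.0,
    "epitope_offsets_um": { "Nano2": [0], "Nano42": [0.5, 2.5] },
    "band_kind": { "Nano2": "point", "Nano42": "point" },
    "amplitudes": { "Nano2": 1000, "Nano42": 1000 },
    "psf_sigma_um": 0.2,
    "n_periods": 10
  },
  "pixel_size_um": 0.05,
  "analysis": {
    "min_prominence": 0.35,
    "min_separation_um": 0.4,
    "comment": "The default 0.4 x period separation would merge the 1.0-um-spaced C-terminal doublet; 0.4 um resolves it while still suppressing sub-band noise maxima."
  }
}
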