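{
  "preset_version": 1,
  "name": "larval",
  "description": "Relaxed L3 larval body-wall muscle: 8.5 um sarcomeres, Sls N-terminal label (Nano2) at the Z-disc, C-terminal label (Nano42) 2.0 um away on both sides.",
  "geometry": {
    "sarcomere_length_um": 8.5,
    "epitope_offsets_um": { "Nano2": [0], "Nano42": [2.0, 6.5] },
    "band_kind": { "Nano2": "point", "Nano42": "point" },
    "amplitudes": { "Nano2": 1000, "Nano42": 1000 },
    "psf_sigma_um": 0.25,
    "n_periods": 10
  },
  "pixel_size_um": 0.1,
  "analysis": {
    "min_prominence": 0.35,
    "comment": "Z-disc bands have ~10:1 contrast over detection noise; topographic prominence of pure-noise bumps in the long I-band valleys reaches ~0.3 of band amplitude (bump height plus valley depth), so the metrology operating point sits above that and far below the ~1.0 band prominence."
  }
}
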