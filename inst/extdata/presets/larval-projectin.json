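{
  "preset_version": 1,
  "name": "larval-projectin",
  "description": "Larval sarcomere stained for Projectin N-terminal (Nano30) and C-terminal (Nano37) epitopes: staggered blocks on the myosin filament, the C-terminal block centroid 0.2 um closer to the M-band (at 4.25 um) in every half-sarcomere.",
  "geometry": {
    "sarcomere_length_um": 8.5,
    "epitope_offsets_um": {
      "Nano30": [[2.3, 3.9], [4.6, 6.2]],
      "Nano37": [[2.5, 4.1], [4.4, 6.0]]
    },
    "band_kind": { "Nano30": "block", "Nano37": "block" },
    "amplitudes": { "Nano30": 1000, "Nano37": 1000 },
    "psf_sigma_um": 0.15,
    "n_periods": 6
  },
  "pixel_size_um": 0.05,
  "z_disc_channel_offset_um": 0
}
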