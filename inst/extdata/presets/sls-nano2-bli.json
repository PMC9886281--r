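{
  "preset_version": 1,
  "name": "sls-nano2-bli",
  "description": "Biolayer-interferometry series for a very-high-affinity nanobody/antigen pair: kon 1e6 /M/s, koff 1e-5 /s (KD 10 pM), sensor load 0.4 nm, 200 s association / 900 s dissociation, four concentrations log-spaced 1-31.6 nM (the instrument-typical range; the assayed series is not printed in text, so this range is a documented package default).",
  "bli": {
    "kon": 1e6,
    "koff": 1e-5,
    "Rmax_nm": 0.4,
    "t_assoc_s": 200,
    "t_dissoc_s": 900,
    "sample_interval_s": 1,
    "concentrations_M": [1e-9, 3.162e-9, 1e-8, 3.162e-8]
  }
}
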