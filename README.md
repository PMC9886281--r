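# sarcoquant

Quantification pipelines for fluorescence microscopy of striated muscle
labelled with small probes (nanobodies), plus the binding-kinetics analysis
used to characterise such probes. The package targets the measurements that
recur in sarcomere-biology imaging studies of the *Drosophila* titin
homologs Sallimus and Projectin and their neighbours, and ships a
synthetic-data generator with exact ground truth so every pipeline stage is
testable without any external download.

## What it computes

* **Band analysis on line profiles** — linear background estimated from the
  35% lowest-intensity samples and subtracted; peak detection by
  topographic prominence with a minimum separation; per-band Gaussian fits
  `A·exp(−(x−µ)²/2σ²)`; integrated band intensity `A·σ·√(2π)`.
* **Label penetration over depth** — per-slice mean integrated band
  intensity of a myofibril versus imaging depth, fitted with
  `I(z) = I₀·e^(−z/λ)`; the decay length λ (µm) quantifies how fast a
  label's signal is lost in thick tissue, and group ratios (e.g.
  nanobody vs antibody) are compared with a Mann–Whitney test.
* **Sarcomere metrology** — sarcomere length as consecutive Z-disc-channel
  peak spacings; epitope span (in-situ protein extension) as the distance
  from each Z-disc peak to the nearest second-epitope peak on either side;
  block-centroid shifts toward the M-band for staggered A-band patterns.
* **FRAP** — ROI-ratio quantification
  `R(t) = (I_bleached − I_bg)/(I_unbleached − I_bg)` plus a
  double-normalized recovery fraction relative to the pre-bleach ratio.
* **Degradation (deGrad) quantification** — image background from a
  band-free ~10×10 µm ROI, 100 fixed-size rectangles centered on band
  loci, per-animal means, percent reduction and exact Mann–Whitney test.
* **1:1 binding kinetics** — closed-form Langmuir sensorgrams
  (association `R(t) = R_eq(1 − e^(−(k_on·C + k_off)t))`, dissociation
  `R(t_a)·e^(−k_off(t−t_a))`) and a global fit of (k_on, k_off, R_max)
  across a concentration series; K_D is always reported as k_off/k_on.

Synthetic generators cover striated two-channel profiles and images for
flight/leg/larval muscle geometries, depth-attenuated z-stacks, FRAP movies
(two-pool immobile + exponential mobile model), control/knockdown staining
pairs, and sensorgram series — all with named presets under
`inst/extdata/presets/` and bit-reproducible noise per seed.

## Worked example

```r
library(sarcoquant)

p   <- sq_preset("larval")                       # 8.5 um sarcomeres
sim <- make_striated_profile(p$geometry, p$pixel_size_um,
         noise = noise_spec("gaussian", gaussian_sd = 100, seed = 1))
res <- measure_lengths(sim$profiles$Nano2, sim$profiles$Nano42,
         period_hint = 8.5, min_prominence = p$analysis$min_prominence)
res
#> length_measurement: 9 + 20 peaks; mean sarcomere 8.5 um, mean span 2 um
```

The 9 detected Z-disc (Nano2) peaks give 8 spacings averaging 8.5 µm — the
relaxed larval sarcomere length — and each Z-disc peak pairs with the
nearest C-terminal (Nano42) peak on each side at a mean span of 2.0 µm,
the extension of Sallimus across the I-band.

```r
design <- sq_preset("sls-nano2-bli")$bli
fit <- global_fit(reference_subtract(make_bli_sensorgrams(design)))
fit
#> kinetics_fit: kon = 1e+06 /M/s, koff = 1e-05 /s, KD = 1e-11 M (10 pM), Rmax = 0.4 nm
#>   note: koff * t_dissoc = 0.009 << 1: the dissociation data barely decay, ...
```

The global fit recovers the generating rates exactly on noise-free data and
flags that off-rates of order 10⁻⁵ s⁻¹ are barely constrained by a 900 s
dissociation — the fit surfaces this rather than hiding it.

## Command line

Every stage is exposed as a subcommand driven by a JSON config:

```sh
Rscript inst/cli/sarcoquant simulate  --config cfg.json --seed 1 --out outdir
Rscript inst/cli/sarcoquant lengths   --config cfg.json --out lengths.json
Rscript inst/cli/sarcoquant bli-fit   --config cfg.json --out fit.json
```

(Subcommands: `simulate`, `profile`, `depth-decay`, `lengths`, `frap`,
`degrad`, `bli-fit`; see `?sq_cli`.)

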