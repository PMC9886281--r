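---
title: "sarcoquant: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{sarcoquant: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sarcoquant)
```

# Scope

`sarcoquant` implements the quantification chain used in imaging studies of
striated-muscle sarcomeres labelled with small fluorescent probes
(nanobodies), together with the 1:1 binding-kinetics analysis used to
characterise such probes, and a synthetic-data generator that produces
every input with exact ground truth. This vignette explains the models and
their assumptions, the tunable parameters with their defaults and units,
what the generator does and does not emulate, and the numerical choices a
maintainer would want to know.

# The forward model (synthetic data)

A scene is a periodic arrangement of epitope bands within a sarcomere of
length $L$ (µm), repeated `n_periods` times, observed through a Gaussian
PSF of width `psf_sigma` (µm, SD). Two band types exist:

* **point bands** render as pure Gaussians of SD `psf_sigma` — the epitope
  is a plane perpendicular to the myofibril axis, far narrower than the
  PSF;
* **blocks** (e.g. Projectin covering a stretch of the myosin filament)
  render as the analytic convolution of a boxcar with the PSF, i.e. a
  difference of normal CDFs. Using the closed form rather than discrete
  convolution makes the ground truth exact and grid-artifact-free.

Two-dimensional images are deliberately *separable*: the 1-D profile is
replicated across a configurable myofibril width with independent
per-pixel noise, optionally over a band-free background margin. Every
quantification in scope reduces to line profiles or rectangle means, so
nothing is lost by not simulating 2-D structure; conversely, a green test
here says nothing about, e.g., curved or crossing myofibrils.

Positions are pixel centers: sample $i$ (0-based) sits at
$(i + 0.5) \cdot \text{pixel\_size}$ µm. File-level ROIs are 0-based,
half-open pixel rectangles; R code uses the native `[row, col, slice]`
array layout.

Noise is additive Gaussian by default (`gaussian_sd` in a.u.; the presets'
stated worlds use 5–10% of band amplitude), with a Poisson–Gaussian option
for realism checks. The imaging papers this package is modelled on do not
characterise their camera noise, so these defaults are conventions, not
measurements. Identical seed and parameters give bit-identical output; the
per-channel and per-trace streams derive from the spec seed plus the
channel/trace index.

Depth attenuation multiplies slice $k$ (0-based) by
$e^{-k \Delta z / \lambda}$, so band peak intensity follows
$I_0 e^{-z/\lambda}$ exactly before noise. The attenuation presets encode
a 2.5-fold contrast (nanobody $\lambda = 10$ µm vs antibody
$\lambda = 4$ µm over a 10 µm stack); $\lambda = \infty$ is accepted as
"no attenuation".

FRAP movies use a **well-mixed two-pool model**: a fraction $f_{imm}$ of
the label never exchanges, the rest recovers as a single exponential with
time constant $\tau$. Expected bleached-ROI signal relative to pre-bleach:

$$R(t) = (1 - d) + d\,(1 - f_{imm})\,(1 - e^{-t/\tau}),$$

with bleach depth $d$. This reproduces ROI-mean recovery curves but not
spatial diffusion profiles — appropriate because the measurements in scope
are ROI means over 20×10 µm rectangles at minute timescales. The
stable-label preset uses $f_{imm} = 0.9$, $\tau = 600$ s, $d = 0.8$, 1-min
frames for 30 min over a 40×30 µm field (0.5 µm pixels, muscle 1000 a.u.
over 50 a.u. background) — spinning-disc-typical values chosen once; its
analytic recovery at 29 min is 9.4%, comfortably inside the "<20%"
behaviour it emulates.

The degradation pair scales band amplitudes by $1 - r$ (reduction factor
$r$) in the knockdown image while keeping the background identical; the
presets state $r = 0.8$ (larval, N-terminal channel) and $r = 0.5$
(flight, neighbouring-epitope channel).

Sensorgrams follow the 1:1 Langmuir solution of
$dR/dt = k_{on} C (R_{max} - R) - k_{off} R$: association
$R(t) = R_{eq}(1 - e^{-(k_{on}C + k_{off})t})$ with
$R_{eq} = R_{max} C/(C + K_D)$, dissociation continuing from the
association endpoint at rate $k_{off}$. The kinetics preset uses
$k_{on} = 10^6\,\mathrm{M^{-1}s^{-1}}$, $k_{off} = 10^{-5}\,\mathrm{s^{-1}}$
($K_D$ = 10 pM), $R_{max} = 0.4$ nm, 200 s association, 900 s
dissociation. The assayed concentration series is not public, so the
preset documents a package default: four concentrations log-spaced over
1–31.6 nM, an instrument-typical range at these rates.

# Band analysis

**Background.** The baseline is an ordinary least-squares line fitted to
the `fraction = 0.35` lowest-intensity samples (count $\lceil 0.35
n\rceil$, selection by intensity rank, not position) and subtracted
everywhere. Corrected intensities are *not* clipped at zero: band areas
come from the analytic Gaussian integral, so a slightly negative residual
baseline does not bias them. Subtracting twice is a no-op provided band
tails do not reach into the selected samples.

**Peaks.** `find_bands` returns strict local maxima (leftmost sample of an
exact-tie plateau) whose topographic prominence is at least
`min_prominence` (default 0.2) times the corrected maximum, thinned to a
minimum pairwise separation (default 0.4 × the expected period when a
preset supplies one, else 10 pixels) by keeping the higher peak (leftmost
on ties). One property of topographic prominence matters in practice: for
a small noise bump in a deep valley between tall bands, prominence counts
the valley depth below the bump, so pure-noise bumps reach prominences
near 0.3 × band amplitude at the presets' 5–10% noise levels. The
metrology and degradation presets therefore carry an `analysis` block
setting `min_prominence = 0.35` — above the noise-bump population, far
below the ~1.0 relative prominence of true bands. This operating point
follows from the presets' stated signal-to-noise, not from tuning against
test outcomes; the module default remains 0.2 for data where the user has
no such prior.

**Gaussian fits.** Each peak is fitted with $A e^{-(x-\mu)^2/2\sigma^2}$
on a window of half-width $\min(3\hat\sigma_0, \tfrac{1}{2}\,d_{nn})$
($\hat\sigma_0$ = FWHM/2.3548 from the half-max crossings, $d_{nn}$ =
distance to the nearest neighbouring peak). Fitting uses `nls` with the
`port` algorithm and bounds ($A \ge 0$, $\mu$ inside the window, $\sigma$
between one pixel and the window width): the bounded solver also converges
cleanly on noise-free data and on bands centered exactly between two
pixels, where the unbounded Gauss–Newton iteration can oscillate at
machine precision until its iteration cap. Windows with fewer than 5
samples and non-converged fits are flagged and excluded downstream, never
silently dropped. Integrated intensity is $A\sigma\sqrt{2\pi}$.

**Smoothing.** `smooth_profile` convolves with a normalized discrete
Gaussian (radius $\lceil 4\sigma\rceil$, reflect boundary in the
edge-mirroring convention `c(b, a | a, b, c)`); the metrology chain uses
σ = 1 pixel.

# Depth decay

Per slice: extract the myofibril profile (column means over the ROI rows)
→ subtract background → find bands → fit and integrate each band → mean
band area. Slices with no detected band or no converged fit are excluded
and reported, and a decay fit needs at least 3 surviving slices. The decay
model is a **bare exponential with no additive offset**, fitted by
nonlinear least squares in linear intensity space and initialized by
log-linear regression on the positive intensities (on noise-free data the
two coincide). Residual background is the job of the upstream profile
background subtraction, not an offset term. Decay lengths aggregate per
animal before any group comparison.

# Metrology

Sarcomere length is the consecutive difference of sorted Z-disc-channel
peak positions. Epitope spans pair each Z-disc peak with the nearest
second-channel peak on each side, nearest-first (greedy over increasing
distance, leftmost on ties), each second-channel peak consumed at most
once, pairs accepted up to `max_span` (default 0.45 × the median sarcomere
spacing — rejects pairings across a Z-disc while accepting the ~2/8.5
geometry). Left and right spans are pooled; per-pair details are exposed
for callers who prefer per-Z-disc averaging. The M-band is defined as the
midpoint between consecutive Z-disc peaks, never fitted; block-centroid
shifts are intensity-weighted centroids per half-sarcomere, sign-projected
so positive always means "closer to the M-band".

# FRAP quantification

The paper-style ratio
$R(t) = (I_{bleached} - I_{bg}) / (I_{unbleached} - I_{bg})$ is computed
per frame from three disjoint rectangle ROIs; frames where the denominator
is non-positive are flagged invalid. On top, a double-normalized recovery
fraction $(R(t) - R(0^+)) / (R_{pre} - R(0^+))$ is reported, with
$R_{pre}$ the mean pre-bleach ratio and $R(0^+)$ the first post-bleach
ratio (no extrapolation). The raw ratio is gain- and offset-invariant; the
recovery fraction is additionally bleach-depth-invariant, which is what
makes "less than 20% recovery" a well-defined dimensionless statement. No
acquisition-bleaching correction is applied by default. A movie whose
post-bleach ratio is not below its pre-bleach ratio raises an explicit
"no bleach detected" error.

# Degradation quantification

Image background is the mean over a user-chosen band-free rectangle
(~10×10 µm); placing it on a band inflates the estimate and is documented
as misuse rather than detected. 100 rectangles of one fixed size are
centered on detected band loci (cycling over bands, row-jittered
deterministically by seed) and their background-subtracted means recorded.
Where the original procedure placed rectangles manually, automated
band-centered placement preserves the measured quantity while making runs
reproducible. The analysis unit is the animal: ROI means → image mean →
animal mean; the comparison API refuses mixed rectangle sizes, reports
$100(1 - \bar{I}_{treated}/\bar{I}_{control})$, and tests groups with the
Mann–Whitney test below.

# Mann–Whitney test

Mid-ranks for ties throughout; two-sided p. For $\min(n_1, n_2) \le 8$
(and a tractable assignment count) the p-value is exact: all
$\binom{n_1+n_2}{n_1}$ group assignments are enumerated and the tail is
the probability of a U at least as far from $n_1 n_2 / 2$ as observed.
Larger samples use the normal approximation with tie correction and
continuity correction. The exact path is validated in the test suite
against an independent enumeration that computes U by pairwise counting.

# Global 1:1 fit

A single $(k_{on}, k_{off}, R_{max})$ is fitted to all traces and both
phases by least squares. $R_{max}$ is shared across traces (equal sensor
load) and, the model being linear in it, profiled out analytically; the
remaining 2-D problem is solved over $(\log_{10} k_{on}, \log_{10}
k_{off})$ — log-parameterisation keeps rates positive without constraints
— from a 7×7 multi-start grid ($10^3$–$10^9$ × $10^{-6}$–$10^{-1}$) with
Nelder–Mead + BFGS polish. $K_D$ is always $k_{off}/k_{on}$, never fitted
independently. The fit flags two failure modes instead of hiding them:
`ambiguous = TRUE` when a near-equal optimum differs in $K_D$ by more than
2-fold, and a warning when $k_{off} \cdot t_{dissoc} \ll 1$, where the
dissociation data barely decay and the off-rate (hence $K_D$) sits at the
limit of what the experiment constrains. Mass-transport limitation and
per-trace $R_{max}$ are out of scope (the latter available behind the
`reference_subtract`/`global_fit` API by fitting traces separately).

# Numerical choices and degenerate inputs

* Profiles must have ≥ 8 uniformly spaced samples (relative spacing
  tolerance $10^{-6}$); background fits require ≥ 2 selected samples.
* `nls` tolerances: band fits `port` with 200 iterations; decay fits
  relative tolerance $10^{-8}$, `scaleOffset = 1` so zero-residual
  (noise-free) problems converge rather than oscillating.
* Ties: peak plateaus resolve leftmost; separation conflicts keep the
  higher peak, leftmost on exact ties; pairing ties resolve by leftmost
  Z-disc then leftmost partner.
* Empty results (no peaks, no pairs, all-background stacks) return empty
  structures with warnings or explicit reports — only genuinely
  uninterpretable input (no bleach, single concentration, all-negative
  intensities) errors.
* The TIFF codec reads and writes exactly one flavour — little-endian,
  uncompressed, grayscale, 32-bit IEEE float, multi-page — and rejects
  everything else by name; physical metadata travels in a JSON sidecar.
  This codec exists because no TIFF package is available in the supported
  environment; it is not a general TIFF library.

# What a green test establishes — and what it does not

The acceptance suite shows that, on synthetic scenes whose presets encode
the published geometry and physics (8.5 µm relaxed larval sarcomeres with
±2.0 µm epitope offsets; 2.5-fold attenuation contrast; a dominantly
immobile FRAP pool; an 80% band-amplitude reduction; 10 pM-grade kinetics),
the pipelines recover the generating truth at the stated tolerances. It
does not establish performance on real micrographs: the generator omits
3-D PSFs, refractive-index mismatch, sarcomere contraction, motion,
non-uniform background, and any photophysics beyond exponential
attenuation and instantaneous bleaching. Those limitations are inherited
by every downstream claim.
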