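#' Render noise-free band intensities on a position grid
#'
#' Point bands are pure Gaussians of SD `psf_sigma`; block bands are
#' boxcars convolved analytically with the Gaussian PSF (difference of
#' normal CDFs), so the ground truth is exact and carries no discrete
#' convolution artifact.
#'
#' @param geometry A [sarcomere_geometry].
#' @param positions Positions (um) at which to evaluate.
#' @param channel Channel name.
#' @return Numeric vector of clean intensities.
#' @keywords internal
render_channel <- function(geometry, positions, channel) {
  L <- geometry$sarcomere_length
  total <- L * geometry$n_periods
  A <- geometry$amplitudes[[channel]]
  s <- geometry$psf_sigma
  y <- numeric(length(positions))
  if (geometry$band_kind[[channel]] == "point") {
    for (off in geometry$epitope_offsets[[channel]]) {
      centers <- off + L * (0:geometry$n_periods)
      centers <- centers[centers <= total + 1e-9]
      for (c0 in centers) {
        y <- y + A * exp(-(positions - c0)^2 / (2 * s^2))
      }
    }
  } else {
    for (blk in geometry$epitope_offsets[[channel]]) {
      starts <- blk[1] + L * (0:geometry$n_periods)
      keep <- starts <= total + 1e-9
      for (k in which(keep)) {
        s0 <- starts[k]
        e0 <- blk[2] + L * (k - 1L)
        y <- y + A * (stats::pnorm((positions - s0) / s) -
                        stats::pnorm((positions - e0) / s))
      }
    }
  }
  y
}

# ground-truth band table for a geometry
band_truth_table <- function(geometry) {
  L <- geometry$sarcomere_length
  total <- L * geometry$n_periods
  rows <- list()
  for (ch in names(geometry$epitope_offsets)) {
    kind <- geometry$band_kind[[ch]]
    A <- geometry$amplitudes[[ch]]
    if (kind == "point") {
      for (off in geometry$epitope_offsets[[ch]]) {
        centers <- off + L * (0:geometry$n_periods)
        centers <- centers[centers <= total + 1e-9]
        rows[[length(rows) + 1L]] <- data.frame(
          channel = ch, kind = "point", center_um = centers,
          start_um = NA_real_, end_um = NA_real_, amplitude = A)
      }
    } else {
      for (blk in geometry$epitope_offsets[[ch]]) {
        starts <- blk[1] + L * (0:geometry$n_periods)
        starts <- starts[starts <= total + 1e-9]
        ends <- blk[2] + L * (seq_along(starts) - 1L)
        rows[[length(rows) + 1L]] <- data.frame(
          channel = ch, kind = "block", center_um = (starts + ends) / 2,
          start_um = starts, end_um = ends, amplitude = A)
      }
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$channel, out$center_um), , drop = FALSE]
}

#' Simulate a striated multi-channel line profile
#'
#' Generates one [line_profile] per channel of `geometry` on a shared
#' position grid (pixel centers at `(i + 0.5) * pixel_size`), plus the
#' ground-truth band table. An optional linear background
#' `offset + slope * x` is added before noise. Each channel receives an
#' independent noise realization (channel index added to the noise seed).
#'
#' @param geometry A [sarcomere_geometry].
#' @param pixel_size Sampling step in micrometres; must be smaller than
#'   `psf_sigma` so bands remain resolvable.
#' @param noise A [noise_spec]. Default: no noise.
#' @param background `c(offset, slope)` in a.u. and a.u./um. Default zero.
#' @return A list of class `striated_profile_set`: `profiles` (named list
#'   of [line_profile]), `clean` (named list of noise-free intensity
#'   vectors including background), `truth` (band table),
#'   `geometry`, `pixel_size`, `background`.
#' @examples
#' g <- sq_preset("larval")$geometry
#' sim <- make_striated_profile(g, pixel_size = 0.1)
#' sim$truth[sim$truth$channel == "Nano2", "center_um"]
#' @export
make_striated_profile <- function(geometry, pixel_size,
                                  noise = noise_spec("none"),
                                  background = c(0, 0)) {
  stopifnot(inherits(geometry, "sarcomere_geometry"))
  if (!is.numeric(pixel_size) || pixel_size <= 0) {
    stop("make_striated_profile: pixel_size must be > 0")
  }
  if (pixel_size >= geometry$psf_sigma) {
    stop("make_striated_profile: pixel_size (", pixel_size,
         ") must be below psf_sigma (", geometry$psf_sigma,
         ") to sample bands adequately")
  }
  chans <- names(geometry$epitope_offsets)
  if (!length(chans)) stop("make_striated_profile: empty channel map")
  total <- geometry$sarcomere_length * geometry$n_periods
  n <- max(8L, floor(total / pixel_size))
  positions <- (seq_len(n) - 0.5) * pixel_size
  bg <- background[1] + background[2] * positions
  clean <- profiles <- stats::setNames(vector("list", length(chans)), chans)
  for (i in seq_along(chans)) {
    ch <- chans[i]
    sig <- render_channel(geometry, positions, ch) + bg
    clean[[ch]] <- sig
    nz <- noise
    nz$seed <- noise$seed + i - 1L
    profiles[[ch]] <- line_profile(positions, apply_noise(sig, nz),
                                   channel = ch, pixel_size = pixel_size,
                                   source_id = "synthetic")
  }
  structure(
    list(profiles = profiles, clean = clean, truth = band_truth_table(geometry),
         geometry = geometry, pixel_size = pixel_size,
         background = background),
    class = "striated_profile_set"
  )
}

#' Render a striated profile into a separable 2-D image
#'
#' The scene is separable by design: the 1-D clean profile runs along the
#' image columns (x axis) and is replicated across `width_px` rows of
#' myofibril, with per-pixel noise applied independently afterwards.
#' `margin_px` extra rows of pure background are appended below the
#' myofibril so quantification code always has a band-free region for its
#' background ROI.
#'
#' @param clean_profile Numeric vector: noise-free intensities along x
#'   (background included).
#' @param width_px Myofibril width in rows.
#' @param margin_px Background-only rows appended below.
#' @param background_level Scalar background in the margin (and implicitly
#'   part of `clean_profile`).
#' @return Numeric matrix `(width_px + margin_px) x length(clean_profile)`.
#' @keywords internal
profile_to_image <- function(clean_profile, width_px = 12L, margin_px = 0L,
                             background_level = 0) {
  img <- matrix(rep(clean_profile, each = width_px), nrow = width_px)
  if (margin_px > 0L) {
    img <- rbind(img, matrix(background_level, nrow = margin_px,
                             ncol = length(clean_profile)))
  }
  img
}
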