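#' Describe the band geometry of a striated-muscle scene
#'
#' A `sarcomere_geometry` is the forward model behind every simulated
#' profile and image: a periodic arrangement of labelled epitope bands
#' within a sarcomere of fixed length, blurred by a Gaussian PSF. Each
#' channel carries one or more bands per period, given as offsets relative
#' to the Z-disc at position 0. A band is either a point band (rendered as
#' a Gaussian of width `psf_sigma`) or a block (a boxcar between start and
#' end offsets, convolved analytically with the PSF).
#'
#' @param sarcomere_length Period in micrometres (> 0).
#' @param epitope_offsets Named list, one entry per channel. For point-band
#'   channels: numeric vector of band-center offsets in `[0,
#'   sarcomere_length)`. For block channels: a list of `c(start, end)`
#'   pairs (um, start < end, both in `[0, sarcomere_length)`).
#' @param band_kind Named character vector (or single value recycled):
#'   `"point"` or `"block"` per channel.
#' @param amplitudes Named numeric (or single value recycled): peak
#'   amplitude per channel in a.u. For blocks this is the plateau height.
#'   Default 1000.
#' @param psf_sigma PSF standard deviation in micrometres (> 0).
#' @param n_periods Number of sarcomeres in the scene (>= 1).
#' @return An object of class `sarcomere_geometry`.
#' @examples
#' g <- sarcomere_geometry(8.5,
#'   epitope_offsets = list(Nano2 = 0, Nano42 = c(2.0, 6.5)),
#'   psf_sigma = 0.25, n_periods = 10)
#' @export
sarcomere_geometry <- function(sarcomere_length, epitope_offsets,
                               band_kind = "point", amplitudes = 1000,
                               psf_sigma = 0.25, n_periods = 10L) {
  if (!is.numeric(sarcomere_length) || sarcomere_length <= 0) {
    stop("sarcomere_geometry: sarcomere_length must be > 0")
  }
  if (!is.list(epitope_offsets) || is.null(names(epitope_offsets)) ||
      !length(epitope_offsets)) {
    stop("sarcomere_geometry: epitope_offsets must be a non-empty named list")
  }
  if (psf_sigma <= 0) stop("sarcomere_geometry: psf_sigma must be > 0")
  n_periods <- as.integer(n_periods)
  if (n_periods < 1L) stop("sarcomere_geometry: n_periods must be >= 1")
  chans <- names(epitope_offsets)
  band_kind <- expand_per_channel(band_kind, chans, "band_kind")
  amplitudes <- expand_per_channel(amplitudes, chans, "amplitudes")
  for (ch in chans) {
    kind <- band_kind[[ch]]
    if (!kind %in% c("point", "block")) {
      stop("sarcomere_geometry: band_kind must be 'point' or 'block'")
    }
    off <- epitope_offsets[[ch]]
    if (kind == "point") {
      off <- as.numeric(off)
      if (any(off < 0 | off >= sarcomere_length)) {
        stop("sarcomere_geometry: offsets of channel ", ch,
             " must lie in [0, sarcomere_length)")
      }
      epitope_offsets[[ch]] <- off
    } else {
      if (!is.list(off)) off <- list(off)
      for (b in off) {
        if (length(b) != 2 || b[1] >= b[2] ||
            any(b < 0 | b >= sarcomere_length)) {
          stop("sarcomere_geometry: block of channel ", ch,
               " must be c(start, end) with start < end in [0, period)")
        }
      }
      epitope_offsets[[ch]] <- off
    }
  }
  structure(
    list(sarcomere_length = sarcomere_length,
         epitope_offsets = epitope_offsets,
         band_kind = band_kind, amplitudes = amplitudes,
         psf_sigma = psf_sigma, n_periods = n_periods),
    class = "sarcomere_geometry"
  )
}

expand_per_channel <- function(x, chans, what) {
  if (length(x) == 1L && is.null(names(x))) {
    x <- stats::setNames(rep(unname(unlist(x)), length(chans)), chans)
  }
  x <- as.list(x)
  if (!all(chans %in% names(x))) {
    stop("sarcomere_geometry: ", what, " must name every channel")
  }
  x[chans]
}

#' @export
print.sarcomere_geometry <- function(x, ...) {
  cat(sprintf("sarcomere_geometry: period %.3g um x %d, PSF sigma %.3g um\n",
              x$sarcomere_length, x$n_periods, x$psf_sigma))
  for (ch in names(x$epitope_offsets)) {
    off <- x$epitope_offsets[[ch]]
    desc <- if (x$band_kind[[ch]] == "point") {
      paste(sprintf("%.3g", off), collapse = ", ")
    } else {
      paste(vapply(off, function(b) sprintf("[%.3g,%.3g]", b[1], b[2]), ""),
            collapse = ", ")
    }
    cat(sprintf("  %s (%s, A = %.3g): %s um\n", ch, x$band_kind[[ch]],
                x$amplitudes[[ch]], desc))
  }
  invisible(x)
}

#' Specify simulated detection noise
#'
#' @param model `"none"`, `"gaussian"` (additive, SD `gaussian_sd`), or
#'   `"poisson-gaussian"` (signal scaled by `gain`, Poisson-sampled,
#'   rescaled, then Gaussian read noise added).
#' @param gaussian_sd Additive noise SD in a.u. (>= 0).
#' @param gain a.u. per photon for the Poisson component.
#' @param seed Integer seed; the same seed and parameters reproduce the
#'   output bit for bit.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(model = c("none", "gaussian", "poisson-gaussian"),
                       gaussian_sd = 0, gain = 1, seed = 1L) {
  model <- match.arg(model)
  if (gaussian_sd < 0) stop("noise_spec: gaussian_sd must be >= 0")
  if (gain <= 0) stop("noise_spec: gain must be > 0")
  structure(list(model = model, gaussian_sd = gaussian_sd, gain = gain,
                 seed = as.integer(seed)),
            class = "noise_spec")
}

# apply noise to a clean signal vector/array under the spec's own RNG stream
apply_noise <- function(clean, noise) {
  stopifnot(inherits(noise, "noise_spec"))
  if (noise$model == "none") return(clean)
  out <- withr_seed(noise$seed, {
    if (noise$model == "gaussian") {
      clean + stats::rnorm(length(clean), sd = noise$gaussian_sd)
    } else {
      photons <- stats::rpois(length(clean), lambda = pmax(clean, 0) / noise$gain)
      photons * noise$gain +
        stats::rnorm(length(clean), sd = noise$gaussian_sd)
    }
  })
  if (!is.null(dim(clean))) dim(out) <- dim(clean)
  out
}

# evaluate expr under a local RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
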