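#' Specify exponential signal attenuation over imaging depth
#'
#' Detected band intensity in confocal stacks of thick muscle falls off
#' approximately exponentially with depth; the decay length `lambda_um`
#' summarises how quickly a given label's signal is lost. Small labels
#' penetrate better and show a longer decay length than bulky
#' primary/secondary antibody complexes.
#'
#' @param lambda_um Decay length in micrometres (> 0; `Inf` means no
#'   attenuation).
#' @param I0 Band peak intensity at the surface slice, a.u. (> 0).
#' @param z_step Slice spacing in micrometres.
#' @param n_slices Number of slices (>= 3).
#' @return An object of class `attenuation_spec`.
#' @export
attenuation_spec <- function(lambda_um, I0 = 1000, z_step = 1, n_slices = 10L) {
  if (!(lambda_um > 0)) stop("attenuation_spec: lambda_um must be > 0")
  if (!(I0 > 0)) stop("attenuation_spec: I0 must be > 0")
  if (z_step <= 0) stop("attenuation_spec: z_step must be > 0")
  n_slices <- as.integer(n_slices)
  if (n_slices < 3L) stop("attenuation_spec: n_slices must be >= 3")
  structure(list(lambda_um = lambda_um, I0 = I0, z_step = z_step,
                 n_slices = n_slices),
            class = "attenuation_spec")
}

#' Simulate a depth-attenuated z-stack
#'
#' Builds one 2-D image per slice from the combined clean profile of
#' `geometry` (all channels summed — a depth stack images a single label),
#' normalized so the tallest band peaks at `attenuation$I0` in slice 0,
#' then scaled by `exp(-k * z_step / lambda)` for slice index k (0-based).
#' Noise is applied per pixel across the whole stack in a single stream.
#'
#' @param geometry A [sarcomere_geometry].
#' @param attenuation An [attenuation_spec].
#' @param noise A [noise_spec].
#' @param pixel_size Lateral pixel size, um.
#' @param width_px Myofibril width in rows.
#' @param margin_px Band-free background rows appended per slice.
#' @param background_level Constant background level, a.u.
#' @return A list of class `depth_stack`: `stack` (array rows x cols x
#'   slices), `depths_um`, `scale` (per-slice attenuation factor),
#'   `clean_profile` (slice-0 clean profile along x), `truth`
#'   (data.frame slice, depth_um, peak_intensity), plus the generating
#'   specs.
#' @examples
#' g <- sq_preset("larval")$geometry
#' st <- make_depth_stack(g, attenuation_spec(5, z_step = 1, n_slices = 10),
#'                        pixel_size = 0.1)
#' st$truth$peak_intensity[11] / st$truth$peak_intensity[1]  # e^-2 at 10 um
#' @export
make_depth_stack <- function(geometry, attenuation,
                             noise = noise_spec("none"),
                             pixel_size = 0.1, width_px = 12L,
                             margin_px = 0L, background_level = 0) {
  stopifnot(inherits(geometry, "sarcomere_geometry"),
            inherits(attenuation, "attenuation_spec"))
  total <- geometry$sarcomere_length * geometry$n_periods
  n <- max(8L, floor(total / pixel_size))
  positions <- (seq_len(n) - 0.5) * pixel_size
  sig <- Reduce(`+`, lapply(names(geometry$epitope_offsets), function(ch) {
    render_channel(geometry, positions, ch)
  }))
  sig <- sig / max(sig) * attenuation$I0
  depths <- (seq_len(attenuation$n_slices) - 1L) * attenuation$z_step
  scale <- exp(-depths / attenuation$lambda_um)
  slices <- lapply(scale, function(f) {
    profile_to_image(sig * f + background_level, width_px = width_px,
                     margin_px = margin_px,
                     background_level = background_level)
  })
  stack <- array(unlist(slices),
                 dim = c(dim(slices[[1]]), attenuation$n_slices))
  stack <- apply_noise(stack, noise)
  structure(
    list(stack = stack, depths_um = depths, scale = scale,
         clean_profile = sig, positions_um = positions,
         truth = data.frame(slice = seq_along(depths) - 1L,
                            depth_um = depths,
                            peak_intensity = attenuation$I0 * scale),
         geometry = geometry, attenuation = attenuation,
         pixel_size = pixel_size, width_px = as.integer(width_px),
         margin_px = as.integer(margin_px),
         background_level = background_level),
    class = "depth_stack"
  )
}

#' Simulate a control/knockdown staining pair
#'
#' Produces two images of the same scene: a control and a "knockdown" in
#' which every band amplitude is scaled by `1 - reduction_factor` while the
#' background stays identical. This emulates staining of muscles in which
#' the target protein has been partially degraded in vivo, so the
#' downstream intensity-quantification pipeline can be validated against a
#' known ground-truth reduction.
#'
#' @param geometry A [sarcomere_geometry] (the channel to quantify).
#' @param reduction_factor Fraction of band amplitude removed in the
#'   knockdown image, in `[0, 1]`.
#' @param noise A [noise_spec]; control and knockdown get independent
#'   realizations (knockdown seed = seed + 1000).
#' @param pixel_size,width_px,margin_px,background_level Image layout as in
#'   [make_depth_stack]; the margin rows are band-free background for the
#'   background ROI.
#' @return A list of class `degrad_pair`: `control`, `knockdown` (matrices),
#'   `background_level`, `truth` (band table + amplitudes in both images),
#'   `positions_um`, `pixel_size`, `muscle_rows`, `margin_rows`.
#' @export
make_degrad_pair <- function(geometry, reduction_factor,
                             noise = noise_spec("none"),
                             pixel_size = 0.1, width_px = 12L,
                             margin_px = 24L, background_level = 50) {
  stopifnot(inherits(geometry, "sarcomere_geometry"))
  if (!is.numeric(reduction_factor) ||
      reduction_factor < 0 || reduction_factor > 1) {
    stop("make_degrad_pair: reduction_factor must be in [0, 1]")
  }
  total <- geometry$sarcomere_length * geometry$n_periods
  n <- max(8L, floor(total / pixel_size))
  positions <- (seq_len(n) - 0.5) * pixel_size
  sig <- Reduce(`+`, lapply(names(geometry$epitope_offsets), function(ch) {
    render_channel(geometry, positions, ch)
  }))
  ctrl_clean <- profile_to_image(sig + background_level, width_px, margin_px,
                                 background_level)
  kd_clean <- profile_to_image(sig * (1 - reduction_factor) + background_level,
                               width_px, margin_px, background_level)
  kd_noise <- noise
  kd_noise$seed <- noise$seed + 1000L
  truth <- band_truth_table(geometry)
  truth$amplitude_knockdown <- truth$amplitude * (1 - reduction_factor)
  structure(
    list(control = apply_noise(ctrl_clean, noise),
         knockdown = apply_noise(kd_clean, kd_noise),
         control_clean = ctrl_clean, knockdown_clean = kd_clean,
         background_level = background_level, truth = truth,
         positions_um = positions, pixel_size = pixel_size,
         muscle_rows = seq_len(width_px),
         margin_rows = width_px + seq_len(margin_px),
         reduction_factor = reduction_factor),
    class = "degrad_pair"
  )
}
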