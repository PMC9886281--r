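#' Ground truth for a simulated FRAP experiment
#'
#' The generator uses a well-mixed two-pool model: a fraction `f_imm` of
#' the labelled protein never exchanges, the rest recovers with a single
#' exponential time constant `tau`. This reproduces ROI-mean recovery
#' curves; it deliberately ignores spatial diffusion profiles (ROI means
#' are insensitive to them at the movie timescales simulated here).
#'
#' @param f_imm Immobile fraction in `[0, 1]`.
#' @param tau Recovery time constant, seconds (> 0).
#' @param bleach_depth Fraction of pre-bleach signal removed by the bleach
#'   pulse, in `(0, 1]`.
#' @param frame_interval Seconds between frames (> 0).
#' @param n_frames Number of post-bleach frames (>= 2); frame k (0-based)
#'   is at `t = k * frame_interval` with t = 0 the first post-bleach frame.
#' @param n_prebleach Pre-bleach frames recorded before the pulse
#'   (>= 1, default 3).
#' @return An object of class `frap_ground_truth`.
#' @export
frap_ground_truth <- function(f_imm, tau, bleach_depth = 0.8,
                              frame_interval = 60, n_frames = 31L,
                              n_prebleach = 3L) {
  if (!is.numeric(f_imm) || f_imm < 0 || f_imm > 1) {
    stop("frap_ground_truth: f_imm must be in [0, 1]")
  }
  if (tau <= 0) stop("frap_ground_truth: tau must be > 0")
  if (!(bleach_depth > 0 && bleach_depth <= 1)) {
    stop("frap_ground_truth: bleach_depth must be in (0, 1]")
  }
  n_frames <- as.integer(n_frames); n_prebleach <- as.integer(n_prebleach)
  if (n_frames < 2L || n_prebleach < 1L) {
    stop("frap_ground_truth: need >= 2 post-bleach and >= 1 pre-bleach frames")
  }
  structure(list(f_imm = f_imm, tau = tau, bleach_depth = bleach_depth,
                 frame_interval = frame_interval, n_frames = n_frames,
                 n_prebleach = n_prebleach),
            class = "frap_ground_truth")
}

#' Analytic FRAP recovery curve of the two-pool model
#'
#' Expected bleached-ROI signal relative to its pre-bleach level:
#' `R(t) = (1 - bleach_depth) + bleach_depth * (1 - f_imm) *
#' (1 - exp(-t / tau))`, with t = 0 at the first post-bleach frame.
#'
#' @param truth A [frap_ground_truth].
#' @param t Times in seconds (>= 0).
#' @return Numeric vector of expected relative intensities.
#' @export
frap_analytic_curve <- function(truth, t) {
  stopifnot(inherits(truth, "frap_ground_truth"))
  (1 - truth$bleach_depth) +
    truth$bleach_depth * (1 - truth$f_imm) * (1 - exp(-t / truth$tau))
}

#' Simulate a FRAP time-lapse movie
#'
#' The field holds a horizontal band of "muscle" (optionally striated along
#' x via `geometry`, otherwise uniform) above a band-free background
#' margin. After `n_prebleach` frames a rectangular region of the muscle is
#' bleached instantaneously; inside it the expected signal then follows the
#' two-pool recovery curve, outside it stays constant (before noise).
#'
#' @param truth A [frap_ground_truth].
#' @param geometry Optional [sarcomere_geometry] for a striated muscle
#'   texture; `NULL` gives a uniform muscle of intensity `muscle_level`.
#' @param noise A [noise_spec], applied per pixel per frame.
#' @param pixel_size Pixel size, um.
#' @param field_um `c(width, height)` of the field in um; default
#'   `c(40, 30)`.
#' @param muscle_um Height of the muscle band, um (top of the field).
#' @param muscle_level Uniform muscle intensity when `geometry` is `NULL`.
#' @param background_level Background intensity outside the muscle.
#' @return A list of class `frap_movie`: `movie` (array rows x cols x
#'   frames), `times_s` (0 at first post-bleach frame; pre-bleach frames
#'   have negative times), `bleach_frame` (index of the first post-bleach
#'   frame, 1-based), `rois` (bleached / unbleached / background rectangles
#'   as used by [quantify_frap]), `analytic` (data.frame t_s, expected
#'   relative signal), and the generating specs.
#' @export
make_frap_movie <- function(truth, geometry = NULL,
                            noise = noise_spec("none"),
                            pixel_size = 0.5, field_um = c(40, 30),
                            muscle_um = 20, muscle_level = 1000,
                            background_level = 50) {
  stopifnot(inherits(truth, "frap_ground_truth"))
  ncol_px <- round(field_um[1] / pixel_size)
  nrow_px <- round(field_um[2] / pixel_size)
  muscle_px <- round(muscle_um / pixel_size)
  if (muscle_px >= nrow_px) {
    stop("make_frap_movie: muscle must leave a background margin")
  }
  xpos <- (seq_len(ncol_px) - 0.5) * pixel_size
  base_row <- if (is.null(geometry)) {
    rep(muscle_level, ncol_px)
  } else {
    Reduce(`+`, lapply(names(geometry$epitope_offsets), function(ch) {
      render_channel(geometry, xpos, ch)
    })) + background_level
  }
  field <- matrix(background_level, nrow = nrow_px, ncol = ncol_px)
  field[seq_len(muscle_px), ] <- matrix(rep(base_row, each = muscle_px),
                                        nrow = muscle_px)

  # ROI layout (pixels, 0-based, half-open): 20 x 10 um rectangles inside
  # the muscle, background ROI in the margin
  roi_w <- round(20 / pixel_size); roi_h <- round(10 / pixel_size)
  roi_h <- min(roi_h, muscle_px)
  rois <- list(
    bleached = c(x0 = 0L, y0 = 0L, x1 = roi_w, y1 = roi_h),
    unbleached = c(x0 = as.integer(ncol_px - roi_w), y0 = 0L,
                   x1 = as.integer(ncol_px), y1 = roi_h),
    background = c(x0 = 0L, y0 = as.integer(muscle_px),
                   x1 = roi_w, y1 = as.integer(nrow_px))
  )
  if (rois$unbleached["x0"] < rois$bleached["x1"]) {
    stop("make_frap_movie: field too narrow for disjoint 20 um ROIs")
  }
  bl <- rois$bleached
  bleach_mask <- matrix(FALSE, nrow_px, ncol_px)
  bleach_mask[(bl["y0"] + 1L):bl["y1"], (bl["x0"] + 1L):bl["x1"]] <- TRUE
  bleach_mask <- bleach_mask & row(field) <= muscle_px

  n_total <- truth$n_prebleach + truth$n_frames
  times <- (seq_len(n_total) - truth$n_prebleach - 1L) * truth$frame_interval
  post_t <- pmax(times, 0)
  rec <- frap_analytic_curve(truth, post_t)
  movie <- array(0, dim = c(nrow_px, ncol_px, n_total))
  for (k in seq_len(n_total)) {
    fr <- field
    if (times[k] >= 0) {
      # recovery acts on the muscle signal above background
      fr[bleach_mask] <- background_level +
        (fr[bleach_mask] - background_level) * rec[k]
    }
    movie[, , k] <- fr
  }
  movie <- apply_noise(movie, noise)
  structure(
    list(movie = movie, times_s = times,
         bleach_frame = truth$n_prebleach + 1L,
         rois = rois, pixel_size = pixel_size,
         analytic = data.frame(t_s = post_t[times >= 0],
                               relative_signal = rec[times >= 0]),
         truth = truth, background_level = background_level),
    class = "frap_movie"
  )
}
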