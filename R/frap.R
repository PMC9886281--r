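#' Quantify a FRAP movie by ROI ratio normalization
#'
#' Per frame, the mean intensity of three rectangular ROIs is measured:
#' inside the bleached area, in a non-bleached muscle area, and outside
#' the muscle (background). The paper-style ratio is
#' `R(t) = (I_bleached - I_background) / (I_unbleached - I_background)`;
#' on top of that a double-normalized recovery fraction
#' `(R(t) - R(0+)) / (R_pre - R(0+))` is reported, where `R_pre` is the
#' mean ratio over the pre-bleach frames and `R(0+)` the ratio at the
#' first post-bleach frame (no extrapolation). The recovery fraction is 0
#' right after the bleach and 1 at full return to the pre-bleach ratio,
#' independent of bleach depth.
#'
#' @param movie 3-D array (rows x cols x frames) or a [make_frap_movie]
#'   result (in which case ROIs, times, and bleach frame default to the
#'   generator's own layout).
#' @param roi_bleached,roi_unbleached,roi_background Rectangles
#'   `c(x0, y0, x1, y1)` in pixel coordinates, 0-based, half-open
#'   (`x` = column, `y` = row).
#' @param bleach_frame Index (1-based) of the first post-bleach frame.
#' @param times_s Frame times, s; default
#'   `(frame - bleach_frame) * frame_interval` if a `frap_movie` is given.
#' @return A data.frame of class `frap_record` with columns `t_s`, `I_b`,
#'   `I_u`, `I_bg`, `ratio`, `valid`, `recovery_fraction` (NA on
#'   pre-bleach frames); attributes `R_pre`, `R_post0`, `bleach_frame`.
#'   Frames where `I_u - I_bg <= 0` are flagged invalid. If no bleach is
#'   detectable (post-bleach ratio not below the pre-bleach ratio), an
#'   error "no bleach detected" is raised.
#' @export
quantify_frap <- function(movie, roi_bleached = NULL, roi_unbleached = NULL,
                          roi_background = NULL, bleach_frame = NULL,
                          times_s = NULL) {
  if (inherits(movie, "frap_movie")) {
    if (is.null(roi_bleached)) roi_bleached <- movie$rois$bleached
    if (is.null(roi_unbleached)) roi_unbleached <- movie$rois$unbleached
    if (is.null(roi_background)) roi_background <- movie$rois$background
    if (is.null(bleach_frame)) bleach_frame <- movie$bleach_frame
    if (is.null(times_s)) times_s <- movie$times_s
    movie <- movie$movie
  }
  stopifnot(length(dim(movie)) == 3L, !is.null(roi_bleached),
            !is.null(roi_unbleached), !is.null(roi_background),
            !is.null(bleach_frame))
  n_frames <- dim(movie)[3]
  if (bleach_frame < 2L || bleach_frame > n_frames) {
    stop("quantify_frap: need >= 1 pre-bleach frame and bleach_frame ",
         "within the movie")
  }
  if (is.null(times_s)) times_s <- seq_len(n_frames) - bleach_frame
  rois <- list(roi_bleached, roi_unbleached, roi_background)
  for (r in rois) check_rect_roi(r, dim(movie)[1:2])
  if (rects_overlap(roi_bleached, roi_unbleached) ||
      rects_overlap(roi_bleached, roi_background) ||
      rects_overlap(roi_unbleached, roi_background)) {
    stop("quantify_frap: the three ROIs must be disjoint")
  }
  roi_mean <- function(frame, r) {
    mean(frame[(r[2] + 1L):r[4], (r[1] + 1L):r[3]])
  }
  I_b <- I_u <- I_bg <- numeric(n_frames)
  for (k in seq_len(n_frames)) {
    fr <- movie[, , k]
    I_b[k] <- roi_mean(fr, roi_bleached)
    I_u[k] <- roi_mean(fr, roi_unbleached)
    I_bg[k] <- roi_mean(fr, roi_background)
  }
  denom <- I_u - I_bg
  valid <- denom > 0
  ratio <- ifelse(valid, (I_b - I_bg) / denom, NA_real_)
  pre <- seq_len(bleach_frame - 1L)
  R_pre <- mean(ratio[pre], na.rm = TRUE)
  R_post0 <- ratio[bleach_frame]
  if (!is.finite(R_pre) || !is.finite(R_post0) || R_post0 >= R_pre - 1e-9) {
    stop("quantify_frap: no bleach detected (post-bleach ratio ",
         "not below pre-bleach ratio)")
  }
  recovery <- rep(NA_real_, n_frames)
  post <- bleach_frame:n_frames
  recovery[post] <- (ratio[post] - R_post0) / (R_pre - R_post0)
  out <- data.frame(t_s = times_s, I_b = I_b, I_u = I_u, I_bg = I_bg,
                    ratio = ratio, valid = valid,
                    recovery_fraction = recovery)
  attr(out, "R_pre") <- R_pre
  attr(out, "R_post0") <- R_post0
  attr(out, "bleach_frame") <- bleach_frame
  class(out) <- c("frap_record", class(out))
  out
}

check_rect_roi <- function(r, dims) {
  if (length(r) != 4L) stop("ROI rectangle must be c(x0, y0, x1, y1)")
  if (r[1] < 0 || r[2] < 0 || r[3] > dims[2] || r[4] > dims[1] ||
      r[1] >= r[3] || r[2] >= r[4]) {
    stop("ROI rectangle [", paste(r, collapse = ", "),
         "] empty or outside the ", dims[1], " x ", dims[2], " image")
  }
  invisible(r)
}

rects_overlap <- function(a, b) {
  a[1] < b[3] && b[1] < a[3] && a[2] < b[4] && b[2] < a[4]
}

#' Recovery fraction at a given time
#'
#' Linear interpolation of the double-normalized recovery fraction of a
#' [quantify_frap] record at time `t` (seconds after the bleach).
#'
#' @param record A `frap_record`.
#' @param t Time in seconds; must lie within the post-bleach time range.
#' @return Recovery fraction (dimensionless).
#' @export
recovery_at <- function(record, t) {
  stopifnot(inherits(record, "frap_record"))
  post <- !is.na(record$recovery_fraction) & record$valid
  tt <- record$t_s[post]; rr <- record$recovery_fraction[post]
  if (t < min(tt) - 1e-9 || t > max(tt) + 1e-9) {
    stop("recovery_at: t = ", t, " outside post-bleach range [",
         min(tt), ", ", max(tt), "] s")
  }
  stats::approx(tt, rr, xout = t, rule = 2)$y
}
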