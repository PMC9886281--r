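#' Mean background from a myofibril-free image region
#'
#' Average pixel intensity over a rectangular region chosen to contain no
#' myofibrils (conventionally about 10 x 10 um). The value is subtracted
#' from every band ROI mean downstream. Placing the rectangle on a band is
#' not detected here — the function reports the mean of whatever region it
#' is given, so the caller is responsible for a band-free choice.
#'
#' @param image Numeric matrix.
#' @param background_roi Rectangle `c(x0, y0, x1, y1)`, pixels, 0-based,
#'   half-open.
#' @return Mean intensity, a.u.
#' @export
estimate_image_background <- function(image, background_roi) {
  stopifnot(is.matrix(image))
  check_rect_roi(background_roi, dim(image))
  r <- background_roi
  mean(image[(r[2] + 1L):r[4], (r[1] + 1L):r[3]])
}

#' Sample band-centered rectangular ROIs from an image
#'
#' Reproduces the fixed-size-rectangle intensity quantification: `n_rois`
#' rectangles of identical size are centered on labelled sarcomere bands
#' and their background-subtracted mean intensities recorded. Band loci
#' are detected automatically (peaks of the column-mean profile over the
#' myofibril rows) unless supplied; rectangles cycle over the detected
#' bands with a seeded sub-pixel-free jitter of the center within the
#' band's row extent, so placement is deterministic given the seed. ROIs
#' never extend into the background margin.
#'
#' @param image Numeric matrix (myofibril rows on top, optional band-free
#'   margin below).
#' @param background Scalar background estimate (from
#'   [estimate_image_background]) subtracted from every ROI mean.
#' @param band_positions_px Optional 1-based column indices of band
#'   centers; detected when `NULL` via the standard profile chain
#'   (Gaussian blur, background subtraction, [find_bands]) on the
#'   column-mean profile of the myofibril rows.
#' @param smooth_sigma_px,min_prominence,min_separation_px Detection
#'   parameters for automatic band location. Deep knockdowns leave dim
#'   bands, so presets quantified at low signal-to-noise should raise
#'   `min_prominence` and set `min_separation_px` near the band period.
#' @param muscle_rows Row indices of the myofibril region. Default: all
#'   rows.
#' @param n_rois Number of rectangles. Default 100.
#' @param roi_size `c(width, height)` in pixels. Default `c(5, 5)`.
#' @param seed Integer seed controlling placement jitter.
#' @param pixel_size Pixel size, um (metadata only).
#' @return A data.frame of class `roi_intensity_table` with columns `roi`,
#'   `band_px`, `x0`, `y0`, `x1`, `y1`, `mean_intensity`
#'   (background-subtracted); attributes `background`, `roi_size`,
#'   `n_requested`. If fewer than `n_rois` placements are possible the
#'   table is shorter and a warning reports the count.
#' @export
sample_band_rois <- function(image, background, band_positions_px = NULL,
                             muscle_rows = NULL, n_rois = 100L,
                             roi_size = c(5L, 5L), seed = 1L,
                             pixel_size = NULL, smooth_sigma_px = 1,
                             min_prominence = 0.2,
                             min_separation_px = 10) {
  stopifnot(is.matrix(image))
  if (is.null(muscle_rows)) muscle_rows <- seq_len(nrow(image))
  if (is.null(band_positions_px)) {
    prof_int <- colMeans(image[muscle_rows, , drop = FALSE])
    px <- if (is.null(pixel_size)) 1 else pixel_size
    prof <- line_profile((seq_along(prof_int) - 0.5) * px, prof_int,
                         pixel_size = px)
    prof <- smooth_profile(prof, sigma_px = smooth_sigma_px)
    bg <- subtract_background(prof)
    pk <- find_bands(bg$corrected, min_prominence = min_prominence,
                     min_separation = min_separation_px * px)
    band_positions_px <- pk$indices
  }
  w <- as.integer(roi_size[1]); h <- as.integer(roi_size[2])
  if (w < 1L || h < 1L) stop("sample_band_rois: roi_size must be >= 1 px")
  half_w <- w %/% 2L
  band_positions_px <- band_positions_px[
    band_positions_px - half_w >= 1L &
      band_positions_px - half_w + w - 1L <= ncol(image)]
  max_y0 <- length(muscle_rows) - h
  if (!length(band_positions_px) || max_y0 < 0L) {
    warning("sample_band_rois: no valid band placement; 0 ROIs")
    out <- data.frame(roi = integer(0), band_px = integer(0), x0 = integer(0),
                      y0 = integer(0), x1 = integer(0), y1 = integer(0),
                      mean_intensity = numeric(0))
    attr(out, "background") <- background
    attr(out, "roi_size") <- c(w, h)
    attr(out, "n_requested") <- n_rois
    class(out) <- c("roi_intensity_table", class(out))
    return(out)
  }
  rows0 <- muscle_rows[1] - 1L      # 0-based top of muscle region
  placements <- withr_seed(seed, {
    lapply(seq_len(n_rois), function(i) {
      bp <- band_positions_px[(i - 1L) %% length(band_positions_px) + 1L]
      y0 <- rows0 + sample.int(max_y0 + 1L, 1L) - 1L
      x0 <- bp - half_w - 1L        # 0-based
      c(x0 = x0, y0 = y0, band = bp)
    })
  })
  rows <- lapply(seq_along(placements), function(i) {
    p <- placements[[i]]
    x0 <- p[["x0"]]; y0 <- p[["y0"]]
    m <- mean(image[(y0 + 1L):(y0 + h), (x0 + 1L):(x0 + w)])
    data.frame(roi = i, band_px = p[["band"]], x0 = x0, y0 = y0,
               x1 = x0 + w, y1 = y0 + h, mean_intensity = m - background)
  })
  out <- do.call(rbind, rows)
  if (nrow(out) < n_rois) {
    warning("sample_band_rois: only ", nrow(out), " of ", n_rois,
            " ROIs placed")
  }
  attr(out, "background") <- background
  attr(out, "roi_size") <- c(w, h)
  attr(out, "n_requested") <- n_rois
  class(out) <- c("roi_intensity_table", class(out))
  out
}

#' Compare staining intensity between control and treated groups
#'
#' The unit of analysis is the animal: each group is a vector of
#' per-animal mean background-subtracted ROI intensities. Reports the
#' percent change `100 * (1 - mean(treated) / mean(control))` and the
#' two-sided Mann-Whitney test.
#'
#' @param control,treated Numeric vectors of per-animal means (control
#'   mean must be positive).
#' @param roi_size_control,roi_size_treated Optional `c(w, h)` ROI sizes;
#'   when both are given they must match ("same size in all
#'   measurements"), otherwise the comparison refuses.
#' @return A list of class `group_comparison`: `percent_change`, `U`, `p`,
#'   `method`, `n_control`, `n_treated`, `mean_control`, `mean_treated`.
#' @export
compare_groups <- function(control, treated, roi_size_control = NULL,
                           roi_size_treated = NULL) {
  if (!length(control) || !length(treated)) {
    stop("compare_groups: both groups must be non-empty")
  }
  if (!is.null(roi_size_control) && !is.null(roi_size_treated) &&
      !identical(as.integer(roi_size_control),
                 as.integer(roi_size_treated))) {
    stop("compare_groups: ROI sizes differ between groups; all ",
         "measurements must use the same rectangle size")
  }
  mc <- mean(control); mt <- mean(treated)
  if (mc <= 0) stop("compare_groups: control mean must be > 0")
  pct <- 100 * (1 - mt / mc)
  if (length(control) < 2L || length(treated) < 2L) {
    warning("compare_groups: a group has < 2 animals; test skipped")
    test <- list(U = NA_real_, p = NA_real_, method = "skipped")
  } else {
    test <- mann_whitney(control, treated)
  }
  structure(list(percent_change = pct, U = test$U, p = test$p,
                 method = test$method, n_control = length(control),
                 n_treated = length(treated),
                 mean_control = mc, mean_treated = mt),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "group_comparison: %.3g%% change (n = %d vs %d), U = %g, p = %.4g\n",
    x$percent_change, x$n_control, x$n_treated, x$U, x$p))
  invisible(x)
}
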