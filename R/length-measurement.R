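#' Sarcomere lengths from Z-disc peak spacings
#'
#' Sarcomere length is the distance between consecutive peaks of the
#' Z-disc channel (Sls N-terminal label): consecutive differences of the
#' sorted peak positions.
#'
#' @param peaks A `peak_set` (from [find_bands]) or numeric vector of peak
#'   positions, um.
#' @return A list of class `sarcomere_lengths`: `spacings_um` (possibly
#'   empty, with a warning when < 2 peaks) and `mean_um`.
#' @export
measure_sarcomere_lengths <- function(peaks) {
  pos <- if (inherits(peaks, "peak_set")) peaks$positions else as.numeric(peaks)
  pos <- sort(pos)
  if (length(pos) < 2L) {
    warning("measure_sarcomere_lengths: < 2 peaks, no spacings")
    return(structure(list(spacings_um = numeric(0), mean_um = NA_real_),
                     class = "sarcomere_lengths"))
  }
  sp <- diff(pos)
  structure(list(spacings_um = sp, mean_um = mean(sp)),
            class = "sarcomere_lengths")
}

#' @export
print.sarcomere_lengths <- function(x, ...) {
  cat(sprintf("sarcomere_lengths: %d spacings, mean %.4g um\n",
              length(x$spacings_um), x$mean_um))
  invisible(x)
}

#' Epitope spans between two channels' peaks
#'
#' Measures the protein's in-situ extension as the distance between the
#' N-terminal-label peak (channel a, e.g. Sls-Nano2 at the Z-disc) and the
#' nearest C-terminal-label peak (channel b, e.g. Sls-Nano42) on each
#' side. Candidate pairs within `max_span` are assigned nearest-first
#' (greedy over increasing distance, leftmost pair on ties); each channel-b
#' peak is consumed by at most one channel-a peak, and each channel-a peak
#' takes at most one partner per side. Edge peaks missing a flanking
#' partner contribute only their available side.
#'
#' @param nano2_peaks,nano42_peaks Peak positions, um (`peak_set` or
#'   numeric).
#' @param max_span Maximum accepted pairing distance, um. Default: 0.45
#'   times the median spacing of `nano2_peaks` (rejects pairings across a
#'   Z-disc), or `Inf` with fewer than 2 channel-a peaks.
#' @return A list of class `epitope_spans`: `spans_um` (pooled left+right,
#'   the primary value), `pairs` (data.frame a_um, b_um, side, span_um),
#'   `mean_um`.
#' @export
measure_epitope_spans <- function(nano2_peaks, nano42_peaks, max_span = NULL) {
  a <- if (inherits(nano2_peaks, "peak_set")) nano2_peaks$positions else
    as.numeric(nano2_peaks)
  b <- if (inherits(nano42_peaks, "peak_set")) nano42_peaks$positions else
    as.numeric(nano42_peaks)
  if (!length(a) || !length(b)) {
    stop("measure_epitope_spans: both peak sets must be non-empty")
  }
  a <- sort(a); b <- sort(b)
  if (is.null(max_span)) {
    max_span <- if (length(a) >= 2L) 0.45 * stats::median(diff(a)) else Inf
  }
  # all candidate pairs within max_span, labelled by side
  cand <- do.call(rbind, lapply(seq_along(a), function(i) {
    d <- b - a[i]
    ok <- abs(d) <= max_span & abs(d) > 0
    if (!any(ok)) return(NULL)
    data.frame(ai = i, bi = which(ok), span = abs(d[ok]),
               side = ifelse(d[ok] > 0, "right", "left"))
  }))
  if (is.null(cand) || !nrow(cand)) {
    warning("measure_epitope_spans: no pair within max_span = ",
            signif(max_span, 4), " um")
    return(structure(list(spans_um = numeric(0),
                          pairs = data.frame(), mean_um = NA_real_),
                     class = "epitope_spans"))
  }
  cand <- cand[order(cand$span, a[cand$ai], b[cand$bi]), , drop = FALSE]
  used_b <- logical(length(b))
  used_side <- matrix(FALSE, length(a), 2,
                      dimnames = list(NULL, c("left", "right")))
  keep <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    bi <- cand$bi[r]; ai <- cand$ai[r]; sd <- cand$side[r]
    if (!used_b[bi] && !used_side[ai, sd]) {
      keep[r] <- TRUE
      used_b[bi] <- TRUE
      used_side[ai, sd] <- TRUE
    }
  }
  pairs <- cand[keep, , drop = FALSE]
  pairs <- data.frame(a_um = a[pairs$ai], b_um = b[pairs$bi],
                      side = pairs$side, span_um = pairs$span)
  pairs <- pairs[order(pairs$a_um, pairs$b_um), , drop = FALSE]
  structure(list(spans_um = pairs$span_um, pairs = pairs,
                 mean_um = mean(pairs$span_um)),
            class = "epitope_spans")
}

#' @export
print.epitope_spans <- function(x, ...) {
  cat(sprintf("epitope_spans: %d pairs, mean span %.4g um\n",
              length(x$spans_um), x$mean_um))
  invisible(x)
}

#' Block-centroid shift between two channels per half-sarcomere
#'
#' For staggered block-like staining patterns (Projectin on the myosin
#' filament) the informative quantity is how much closer one epitope's
#' intensity centroid sits to the M-band than the other's. Each interval
#' between a Z-disc and the midpoint to the next Z-disc (the M-band
#' position, never fitted directly) is one half-sarcomere; within it the
#' intensity-weighted centroid of each background-corrected channel is
#' computed, and the shift is `centroid_b - centroid_a`, sign-flipped on
#' left-facing halves so that positive always means channel b lies closer
#' to the M-band.
#'
#' @param profile_a,profile_b Background-corrected [line_profile]s on the
#'   same grid.
#' @param z_disc_positions Z-disc positions, um (>= 2, sorted internally).
#' @return A data.frame of class `centroid_shifts`: `half_id`, `start_um`,
#'   `end_um`, `centroid_a_um`, `centroid_b_um`, `shift_um` (positive
#'   toward the M-band). Halves with non-positive total intensity in
#'   either channel are skipped.
#' @export
measure_block_centroid_shift <- function(profile_a, profile_b,
                                         z_disc_positions) {
  stopifnot(inherits(profile_a, "line_profile"),
            inherits(profile_b, "line_profile"))
  if (length(profile_a$positions) != length(profile_b$positions) ||
      max(abs(profile_a$positions - profile_b$positions)) >
      1e-6 * profile_a$pixel_size) {
    stop("measure_block_centroid_shift: channels must share the position grid")
  }
  z <- sort(as.numeric(z_disc_positions))
  if (length(z) < 2L) {
    stop("measure_block_centroid_shift: need >= 2 Z-disc positions")
  }
  x <- profile_a$positions
  rows <- list()
  half_id <- 0L
  for (k in seq_len(length(z) - 1L)) {
    mid <- (z[k] + z[k + 1L]) / 2
    halves <- list(list(lo = z[k], hi = mid, m_side = +1),   # M-band right
                   list(lo = mid, hi = z[k + 1L], m_side = -1)) # M-band left
    for (h in halves) {
      half_id <- half_id + 1L
      sel <- x >= h$lo & x < h$hi
      if (sum(sel) < 2L) next
      wa <- profile_a$intensities[sel]; wb <- profile_b$intensities[sel]
      if (sum(wa) <= 0 || sum(wb) <= 0) next
      ca <- sum(x[sel] * wa) / sum(wa)
      cb <- sum(x[sel] * wb) / sum(wb)
      rows[[length(rows) + 1L]] <- data.frame(
        half_id = half_id, start_um = h$lo, end_um = h$hi,
        centroid_a_um = ca, centroid_b_um = cb,
        shift_um = h$m_side * (cb - ca))
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(half_id = integer(0), start_um = numeric(0),
               end_um = numeric(0), centroid_a_um = numeric(0),
               centroid_b_um = numeric(0), shift_um = numeric(0))
  class(out) <- c("centroid_shifts", class(out))
  out
}

#' Full length-measurement pipeline on a two-channel profile pair
#'
#' The measurement chain used for sarcomere metrology: Gaussian blur
#' (sigma 1 pixel), linear background subtraction, peak detection on each
#' channel, then spacings from the channel-a peaks and epitope spans
#' between the two channels.
#'
#' @param profile_a Z-disc-channel [line_profile] (e.g. Sls-Nano2).
#' @param profile_b Second-epitope [line_profile] (e.g. Sls-Nano42).
#' @param smooth_sigma_px Blur SD in pixels. Default 1.
#' @param fraction Background fraction (see [subtract_background]).
#' @param min_prominence,min_separation Peak-detection parameters; the
#'   default separation is `0.4 *` the expected period when `period_hint`
#'   is given, else 10 pixels, and applies to both channels. For
#'   geometries whose second channel forms a doublet tighter than that
#'   (short I-bands), pass an explicit `min_separation`.
#' @param period_hint Expected sarcomere length, um (from a preset).
#' @param max_span Passed to [measure_epitope_spans].
#' @return A list of class `length_measurement`: `peaks_a`, `peaks_b`,
#'   `lengths` ([measure_sarcomere_lengths] result), `spans`
#'   ([measure_epitope_spans] result).
#' @export
measure_lengths <- function(profile_a, profile_b, smooth_sigma_px = 1,
                            fraction = 0.35, min_prominence = 0.2,
                            min_separation = NULL, period_hint = NULL,
                            max_span = NULL) {
  if (is.null(min_separation) && !is.null(period_hint)) {
    min_separation <- 0.4 * period_hint
  }
  prep <- function(p) {
    sm <- smooth_profile(p, sigma_px = smooth_sigma_px)
    subtract_background(sm, fraction = fraction)$corrected
  }
  ca <- prep(profile_a); cb <- prep(profile_b)
  pa <- find_bands(ca, min_prominence = min_prominence,
                   min_separation = min_separation)
  pb <- find_bands(cb, min_prominence = min_prominence,
                   min_separation = min_separation)
  lengths <- measure_sarcomere_lengths(pa)
  spans <- if (length(pa$positions) && length(pb$positions)) {
    measure_epitope_spans(pa, pb, max_span = max_span)
  } else {
    structure(list(spans_um = numeric(0), pairs = data.frame(),
                   mean_um = NA_real_), class = "epitope_spans")
  }
  structure(list(peaks_a = pa, peaks_b = pb, lengths = lengths,
                 spans = spans),
            class = "length_measurement")
}

#' @export
print.length_measurement <- function(x, ...) {
  cat(sprintf(
    "length_measurement: %d + %d peaks; mean sarcomere %.4g um, mean span %.4g um\n",
    length(x$peaks_a$positions), length(x$peaks_b$positions),
    x$lengths$mean_um, x$spans$mean_um))
  invisible(x)
}
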