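#' Construct a line profile
#'
#' A `line_profile` is the atom all band analysis consumes: a 1-D intensity
#' trace sampled at uniformly spaced physical positions along a scan line
#' (typically drawn along one myofibril), for a single channel.
#'
#' @param positions Numeric vector of sample positions in micrometres.
#'   Must be strictly increasing with uniform spacing (relative tolerance
#'   `1e-6` on the step).
#' @param intensities Numeric vector of intensities (arbitrary units), same
#'   length as `positions`.
#' @param channel Character label of the imaging channel.
#' @param pixel_size Sample spacing in micrometres. Defaults to the observed
#'   spacing of `positions`.
#' @param source_id Free-form identifier of the image/ROI the profile came
#'   from (propagated into result tables).
#'
#' @return An object of class `line_profile`: a list with elements
#'   `positions`, `intensities`, `channel`, `pixel_size`, `source_id`.
#' @examples
#' p <- line_profile(seq(0, 10, by = 0.1), rnorm(101, 10), channel = "Nano2")
#' print(p)
#' @export
line_profile <- function(positions, intensities, channel = "ch0",
                         pixel_size = NULL, source_id = "") {
  positions <- as.numeric(positions)
  intensities <- as.numeric(intensities)
  n <- length(positions)
  if (n < 8L) {
    stop("line_profile: need at least 8 samples, got ", n)
  }
  if (length(intensities) != n) {
    stop("line_profile: positions (", n, ") and intensities (",
         length(intensities), ") differ in length")
  }
  d <- diff(positions)
  if (any(d <= 0)) stop("line_profile: positions must be strictly increasing")
  step <- mean(d)
  if (max(abs(d - step)) > 1e-6 * step) {
    stop("line_profile: positions must be uniformly spaced ",
         "(relative tolerance 1e-6)")
  }
  if (is.null(pixel_size)) pixel_size <- step
  structure(
    list(positions = positions, intensities = intensities,
         channel = as.character(channel), pixel_size = pixel_size,
         source_id = as.character(source_id)),
    class = "line_profile"
  )
}

#' @export
print.line_profile <- function(x, ...) {
  cat("line_profile:", length(x$positions), "samples,",
      sprintf("%.4g-%.4g um,", min(x$positions), max(x$positions)),
      "channel", shQuote(x$channel),
      sprintf("(pixel %.4g um)\n", x$pixel_size))
  invisible(x)
}

#' @export
length.line_profile <- function(x) length(x$positions)

# internal: rebuild a profile with new intensities, keeping metadata
profile_with <- function(profile, intensities) {
  line_profile(profile$positions, intensities, channel = profile$channel,
               pixel_size = profile$pixel_size, source_id = profile$source_id)
}
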