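#' Subtract a linear background estimated from the dimmest samples
#'
#' Fits an ordinary least-squares line of intensity on position using only
#' the `fraction` lowest-intensity samples of the profile (selection by
#' intensity rank, not by position), then subtracts that line everywhere.
#' With bands covering a minority of samples the dimmest samples are
#' baseline, so the fit tracks the additive background without being pulled
#' up by the bands. Corrected intensities are not clipped: negative residual
#' baseline is retained so downstream Gaussian areas stay unbiased.
#'
#' @param profile A [line_profile].
#' @param fraction Fraction of samples, ranked by intensity from the bottom,
#'   used for the baseline fit; the count is `ceiling(fraction * n)`.
#'   Default 0.35.
#' @return A list of class `background_model` with elements
#'   `slope` (a.u./um), `intercept` (a.u.), `fraction`, `points_used`
#'   (indices of the samples in the fit) and `corrected`, the
#'   background-subtracted [line_profile].
#' @examples
#' x <- seq(0, 10, by = 0.05)
#' p <- line_profile(x, 2 + 0.5 * x + 10 * exp(-(x - 5)^2 / 0.18))
#' bg <- subtract_background(p)
#' c(bg$slope, bg$intercept)
#' @export
subtract_background <- function(profile, fraction = 0.35) {
  stopifnot(inherits(profile, "line_profile"))
  if (!(fraction > 0 && fraction < 1)) {
    stop("subtract_background: fraction must be in (0, 1), got ", fraction)
  }
  n <- length(profile$positions)
  m <- ceiling(fraction * n)
  if (m < 2L) {
    stop("subtract_background: fewer than 2 samples selected ",
         "(n = ", n, ", fraction = ", fraction, ")")
  }
  idx <- order(profile$intensities)[seq_len(m)]
  x <- profile$positions[idx]
  y <- profile$intensities[idx]
  if (diff(range(x)) == 0) {
    stop("subtract_background: degenerate positions among selected samples")
  }
  fit <- stats::lm.fit(cbind(1, x), y)
  c0 <- fit$coefficients[[1]]
  m0 <- fit$coefficients[[2]]
  corrected <- profile$intensities - (m0 * profile$positions + c0)
  structure(
    list(slope = m0, intercept = c0, fraction = fraction,
         points_used = sort(idx),
         corrected = profile_with(profile, corrected)),
    class = "background_model"
  )
}

#' @export
print.background_model <- function(x, ...) {
  cat(sprintf("background_model: I = %.6g + %.6g * x (a.u.), %d/%d samples\n",
              x$intercept, x$slope, length(x$points_used),
              length(x$corrected$positions)))
  invisible(x)
}

#' Detect bands as prominent local maxima
#'
#' Finds strict local maxima of a (background-corrected) profile, keeps
#' those whose topographic prominence reaches `min_prominence` times the
#' profile maximum, then enforces a minimum pairwise separation by greedily
#' keeping the higher of two conflicting peaks (leftmost on an exact tie).
#' On a plateau of equal samples the leftmost sample is the candidate.
#'
#' Topographic prominence of a peak is its height above the higher of the
#' two lowest points one must descend to before reaching higher ground (or
#' the profile edge) on either side — the same definition as the peak
#' prominence used in common signal-processing toolkits.
#'
#' @param profile A background-corrected [line_profile].
#' @param min_prominence Minimum prominence as a fraction of the maximum
#'   corrected intensity. Default 0.2.
#' @param min_separation Minimum distance between retained peaks, in
#'   micrometres. Default `10 * pixel_size`.
#' @return A list of class `peak_set` with `positions` (um, ascending),
#'   `heights` (a.u.), `indices` (1-based sample indices), and a `params`
#'   echo. An empty result is not an error.
#' @examples
#' x <- seq(0, 12, by = 0.05)
#' y <- exp(-(x - 2)^2 / 0.18) + exp(-(x - 10.5)^2 / 0.18)
#' find_bands(line_profile(x, y), min_separation = 1)
#' @export
find_bands <- function(profile, min_prominence = 0.2, min_separation = NULL) {
  stopifnot(inherits(profile, "line_profile"))
  if (is.null(min_separation)) min_separation <- 10 * profile$pixel_size
  y <- profile$intensities
  x <- profile$positions
  n <- length(y)

  cand <- local_maxima(y)
  if (length(cand)) {
    prom <- vapply(cand, function(i) peak_prominence(y, i), numeric(1))
    keep <- prom >= min_prominence * max(y)
    cand <- cand[keep]
  }
  # enforce separation: higher peaks win, leftmost on ties
  if (length(cand) > 1L) {
    ord <- order(-y[cand], cand)
    chosen <- integer(0)
    for (i in cand[ord]) {
      if (!length(chosen) || all(abs(x[i] - x[chosen]) >= min_separation)) {
        chosen <- c(chosen, i)
      }
    }
    cand <- sort(chosen)
  }
  structure(
    list(positions = x[cand], heights = y[cand], indices = cand,
         params = list(min_prominence = min_prominence,
                       min_separation = min_separation)),
    class = "peak_set"
  )
}

#' @export
print.peak_set <- function(x, ...) {
  cat("peak_set:", length(x$positions), "peaks")
  if (length(x$positions)) {
    cat(" at", paste(sprintf("%.3g", x$positions), collapse = ", "), "um")
  }
  cat("\n")
  invisible(x)
}

# indices of strict local maxima; for a plateau the leftmost sample counts,
# provided the plateau eventually drops on the right before rising
local_maxima <- function(y) {
  n <- length(y)
  if (n < 3L) return(integer(0))
  out <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (y[i] > y[i - 1L]) {
      # scan over a possible plateau of equal values
      j <- i
      while (j < n && y[j + 1L] == y[j]) j <- j + 1L
      if (j < n && y[j + 1L] < y[j]) out <- c(out, i)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  out
}

# topographic prominence of the peak at index i
peak_prominence <- function(y, i) {
  n <- length(y)
  left_min <- y[i]
  k <- i - 1L
  left_base <- NA_real_
  while (k >= 1L) {
    if (y[k] > y[i]) { left_base <- left_min; break }
    if (y[k] < left_min) left_min <- y[k]
    k <- k - 1L
  }
  if (is.na(left_base)) left_base <- left_min
  right_min <- y[i]
  k <- i + 1L
  right_base <- NA_real_
  while (k <= n) {
    if (y[k] > y[i]) { right_base <- right_min; break }
    if (y[k] < right_min) right_min <- y[k]
    k <- k + 1L
  }
  if (is.na(right_base)) right_base <- right_min
  y[i] - max(left_base, right_base)
}

#' Fit a Gaussian band at a detected peak
#'
#' Nonlinear least-squares fit of `A * exp(-(x - mu)^2 / (2 sigma^2))` to
#' the background-corrected profile on a window centered at the peak. The
#' window half-width is `min(3 * sigma0, half the distance to the nearest
#' neighbouring peak)`, where `sigma0` is the initial width estimate taken
#' from the half-maximum crossings (FWHM / 2.3548). Initial amplitude and
#' center are the peak height and position. A fit that diverges or lands on
#' non-finite parameters is returned with `converged = FALSE` and must be
#' excluded downstream.
#'
#' @param profile Background-corrected [line_profile].
#' @param peak Peak position in micrometres (an element of the
#'   [find_bands] result for this profile).
#' @param neighbours Optional positions of the other peaks of the same
#'   profile, used to bound the window. Default none.
#' @return A list of class `band_fit`: `amplitude`, `center`, `sigma`,
#'   `area` (`A * sigma * sqrt(2*pi)`), `rms_residual`, `converged`,
#'   `n_window`.
#' @examples
#' x <- seq(0, 10, by = 0.05)
#' p <- line_profile(x, 10 * exp(-(x - 5)^2 / (2 * 0.3^2)))
#' fit_band(p, 5)
#' @export
fit_band <- function(profile, peak, neighbours = numeric(0)) {
  stopifnot(inherits(profile, "line_profile"))
  x <- profile$positions
  y <- profile$intensities
  ipk <- which.min(abs(x - peak))
  a0 <- y[ipk]
  s0 <- sigma_from_fwhm(x, y, ipk)
  half <- 3 * s0
  nb <- neighbours[abs(neighbours - peak) > profile$pixel_size / 2]
  if (length(nb)) half <- min(half, min(abs(nb - peak)) / 2)
  win <- which(x >= x[ipk] - half & x <= x[ipk] + half)
  if (length(win) < 5L) {
    stop("fit_band: window around peak at ", signif(peak, 6),
         " um has fewer than 5 samples")
  }
  xw <- x[win]; yw <- y[win]
  fit <- tryCatch(
    stats::nls(yw ~ A * exp(-(xw - mu)^2 / (2 * sigma^2)),
               start = list(A = a0, mu = x[ipk], sigma = s0),
               algorithm = "port",
               lower = c(A = 0, mu = min(xw), sigma = x[2] - x[1]),
               upper = c(A = Inf, mu = max(xw), sigma = diff(range(xw))),
               control = list(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(amplitude = NA_real_, center = NA_real_,
                          sigma = NA_real_, area = NA_real_,
                          rms_residual = NA_real_, converged = FALSE,
                          n_window = length(win)),
                     class = "band_fit"))
  }
  cf <- stats::coef(fit)
  A <- unname(cf["A"]); mu <- unname(cf["mu"]); sigma <- abs(unname(cf["sigma"]))
  ok <- all(is.finite(c(A, mu, sigma))) && sigma > 0 &&
    isTRUE(fit$convInfo$isConv)
  rms <- sqrt(mean(stats::resid(fit)^2))
  structure(
    list(amplitude = A, center = mu, sigma = sigma,
         area = A * sigma * sqrt(2 * pi), rms_residual = rms,
         converged = isTRUE(ok), n_window = length(win)),
    class = "band_fit"
  )
}

#' @export
print.band_fit <- function(x, ...) {
  cat(sprintf(
    "band_fit: A = %.5g, mu = %.5g um, sigma = %.5g um, area = %.5g (%s)\n",
    x$amplitude, x$center, x$sigma, x$area,
    if (isTRUE(x$converged)) "converged" else "NOT converged"))
  invisible(x)
}

# initial sigma from half-max crossings around sample ipk
sigma_from_fwhm <- function(x, y, ipk) {
  half <- y[ipk] / 2
  n <- length(y)
  il <- ipk
  while (il > 1L && y[il] > half) il <- il - 1L
  ir <- ipk
  while (ir < n && y[ir] > half) ir <- ir + 1L
  # linear interpolation of the crossing on each side
  xl <- if (il < ipk && y[il + 1L] != y[il]) {
    x[il] + (half - y[il]) / (y[il + 1L] - y[il]) * (x[il + 1L] - x[il])
  } else x[max(il, 1L)]
  xr <- if (ir > ipk && y[ir - 1L] != y[ir]) {
    x[ir - 1L] + (half - y[ir - 1L]) / (y[ir] - y[ir - 1L]) *
      (x[ir] - x[ir - 1L])
  } else x[min(ir, n)]
  fwhm <- max(xr - xl, x[2] - x[1])
  fwhm / (2 * sqrt(2 * log(2)))
}

#' Area under a fitted Gaussian band
#'
#' The integrated intensity of a converged [fit_band] result, evaluated in
#' closed form as `A * sigma * sqrt(2*pi)`.
#'
#' @param fit A `band_fit`.
#' @return Area in a.u. * um.
#' @export
integrate_band <- function(fit) {
  stopifnot(inherits(fit, "band_fit"))
  if (!isTRUE(fit$converged)) {
    stop("integrate_band: fit did not converge; band must be excluded")
  }
  fit$amplitude * fit$sigma * sqrt(2 * pi)
}

#' Gaussian-smooth a profile
#'
#' Convolution with a normalized discrete Gaussian kernel (radius
#' `ceiling(4 * sigma_px)`), with reflect boundary handling (the edge sample
#' is mirrored: `c(b, a | a, b, c)`). `sigma_px = 0` is the identity.
#'
#' @param profile A [line_profile].
#' @param sigma_px Kernel standard deviation in pixels. Default 1.
#' @return The smoothed [line_profile].
#' @export
smooth_profile <- function(profile, sigma_px = 1.0) {
  stopifnot(inherits(profile, "line_profile"))
  if (sigma_px < 0) stop("smooth_profile: sigma_px must be >= 0")
  if (sigma_px == 0) return(profile)
  r <- ceiling(4 * sigma_px)
  k <- stats::dnorm(-r:r, sd = sigma_px)
  k <- k / sum(k)
  y <- profile$intensities
  n <- length(y)
  if (r >= n) stop("smooth_profile: kernel radius exceeds profile length")
  ypad <- c(rev(y[seq_len(r)]), y, rev(y[(n - r + 1L):n]))
  out <- vapply(seq_len(n), function(i) sum(k * ypad[i:(i + 2L * r)]),
                numeric(1))
  profile_with(profile, out)
}
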