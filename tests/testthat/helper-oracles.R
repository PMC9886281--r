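# Independent brute-force oracles. Each re-derives an expected result from
# the definition, by a different route than the package implementation.

# --- background: sort intensities, lowest ceil(q*n), normal equations ----
oracle_background <- function(positions, intensities, q = 0.35) {
  m <- ceiling(q * length(intensities))
  idx <- order(intensities)[1:m]
  x <- positions[idx]; y <- intensities[idx]
  n <- length(x)
  slope <- (n * sum(x * y) - sum(x) * sum(y)) / (n * sum(x^2) - sum(x)^2)
  intercept <- (sum(y) - slope * sum(x)) / n
  list(slope = slope, intercept = intercept, idx = sort(idx))
}

# --- peaks: definitional scan ------------------------------------------
oracle_local_maxima <- function(y) {
  n <- length(y)
  out <- integer(0)
  for (i in 2:(n - 1)) {
    if (y[i] <= y[i - 1]) next
    # first index of its plateau, find next differing value to the right
    j <- i
    while (j < n && y[j + 1] == y[i]) j <- j + 1
    if (j < n && y[j + 1] < y[i]) out <- c(out, i)
  }
  out
}

oracle_prominence <- function(y, i) {
  n <- length(y)
  higher_l <- which(y[seq_len(i - 1)] > y[i])
  lo_l <- if (length(higher_l)) min(y[(max(higher_l)):i]) else
    min(y[1:i])
  higher_r <- which(y[(i + 1):n] > y[i])
  lo_r <- if (length(higher_r)) min(y[i:(i + min(higher_r))]) else
    min(y[i:n])
  y[i] - max(lo_l, lo_r)
}

oracle_find_bands <- function(x, y, min_prominence = 0.2,
                              min_separation) {
  cand <- oracle_local_maxima(y)
  cand <- cand[vapply(cand, function(i) oracle_prominence(y, i),
                      numeric(1)) >= min_prominence * max(y)]
  kept <- integer(0)
  for (i in cand[order(-y[cand], cand)]) {
    if (all(abs(x[i] - x[kept]) >= min_separation)) kept <- c(kept, i)
  }
  sort(kept)
}

# --- smoothing: naive dense convolution with reflect padding ------------
oracle_smooth <- function(y, sigma_px) {
  r <- ceiling(4 * sigma_px)
  k <- exp(-(-r:r)^2 / (2 * sigma_px^2)); k <- k / sum(k)
  n <- length(y)
  get <- function(j) {        # reflect incl. edge: c(b,a | a,b,c)
    while (j < 1 || j > n) {
      if (j < 1) j <- 1 - j
      if (j > n) j <- 2 * n + 1 - j
    }
    y[j]
  }
  vapply(1:n, function(i) {
    sum(k * vapply(seq(i - r, i + r), get, numeric(1)))
  }, numeric(1))
}

# --- Mann-Whitney: U by pairwise counting, p by full enumeration --------
oracle_mw <- function(x, y) {
  U <- sum(outer(x, y, function(a, b) (a > b) + 0.5 * (a == b)))
  pooled <- c(x, y)
  n1 <- length(x)
  mu <- n1 * length(y) / 2
  combs <- utils::combn(length(pooled), n1)
  Us <- apply(combs, 2, function(idx) {
    sum(outer(pooled[idx], pooled[-idx],
              function(a, b) (a > b) + 0.5 * (a == b)))
  })
  list(U = U, p = mean(abs(Us - mu) >= abs(U - mu) - 1e-9))
}

# --- 1:1 binding: RK4 integration of dR/dt = kon C (Rmax - R) - koff R --
oracle_sensorgram_ode <- function(kon, koff, Rmax, C, t, t_assoc, dt = 0.01) {
  deriv <- function(R, conc) kon * conc * (Rmax - R) - koff * R
  out <- numeric(length(t))
  R <- 0; tcur <- 0
  tg <- sort(t)
  for (k in seq_along(tg)) {
    while (tcur < tg[k] - 1e-12) {
      h <- min(dt, tg[k] - tcur)
      conc <- if (tcur < t_assoc) C else 0
      k1 <- deriv(R, conc)
      k2 <- deriv(R + h / 2 * k1, conc)
      k3 <- deriv(R + h / 2 * k2, conc)
      k4 <- deriv(R + h * k3, conc)
      R <- R + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      tcur <- tcur + h
    }
    out[k] <- R
  }
  out[match(t, tg)]
}

# --- epitope pairing: repeated global-minimum selection -----------------
oracle_pair_spans <- function(a, b, max_span) {
  a <- sort(a); b <- sort(b)
  avail_b <- rep(TRUE, length(b))
  avail_side <- matrix(TRUE, length(a), 2) # left, right
  spans <- data.frame(a_um = numeric(0), b_um = numeric(0),
                      span_um = numeric(0))
  repeat {
    best <- NULL
    for (i in seq_along(a)) for (j in seq_along(b)) {
      d <- b[j] - a[i]
      if (abs(d) > max_span || d == 0 || !avail_b[j]) next
      side <- if (d > 0) 2 else 1
      if (!avail_side[i, side]) next
      cand <- c(abs(d), a[i], b[j], i, j, side)
      if (is.null(best) ||
          cand[1] < best[1] - 1e-12 ||
          (abs(cand[1] - best[1]) <= 1e-12 &&
           (cand[2] < best[2] ||
            (cand[2] == best[2] && cand[3] < best[3])))) best <- cand
    }
    if (is.null(best)) break
    avail_b[best[5]] <- FALSE
    avail_side[best[4], best[6]] <- FALSE
    spans <- rbind(spans, data.frame(a_um = best[2], b_um = best[3],
                                     span_um = best[1]))
  }
  spans[order(spans$a_um, spans$b_um), ]
}

# --- straight-line re-implementation of the band-intensity chain --------
# (background by oracle OLS, peaks by oracle scan, Gaussian fit by optim)
oracle_slice_band_mean <- function(positions, intensities,
                                   min_prominence = 0.2, min_separation) {
  bg <- oracle_background(positions, intensities)
  y <- intensities - (bg$slope * positions + bg$intercept)
  pk <- oracle_find_bands(positions, y, min_prominence, min_separation)
  if (!length(pk)) return(NA_real_)
  areas <- vapply(pk, function(i) {
    others <- setdiff(pk, i)
    # window: same rule as the implementation
    half <- y[i] / 2
    il <- i; while (il > 1 && y[il] > half) il <- il - 1
    ir <- i; while (ir < length(y) && y[ir] > half) ir <- ir + 1
    s0 <- max(positions[ir] - positions[il],
              positions[2] - positions[1]) / 2.3548
    hw <- 3 * s0
    if (length(others)) {
      hw <- min(hw, min(abs(positions[others] - positions[i])) / 2)
    }
    win <- abs(positions - positions[i]) <= hw
    if (sum(win) < 5) return(NA_real_)
    xw <- positions[win]; yw <- y[win]
    obj <- function(p) sum((yw - p[1] * exp(-(xw - p[2])^2 /
                                              (2 * p[3]^2)))^2)
    fit <- stats::optim(c(y[i], positions[i], s0), obj,
                        control = list(maxit = 2000, reltol = 1e-14))
    fit <- stats::optim(fit$par, obj,
                        control = list(maxit = 2000, reltol = 1e-14))
    fit$par[1] * abs(fit$par[3]) * sqrt(2 * pi)
  }, numeric(1))
  if (all(is.na(areas))) NA_real_ else mean(areas, na.rm = TRUE)
}
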