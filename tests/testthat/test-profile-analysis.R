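gaussian <- function(x, A, mu, sigma) A * exp(-(x - mu)^2 / (2 * sigma^2))

test_that("background subtraction recovers exact linear baselines", {
  x <- seq(0, 10, by = 0.1)
  # constant profile
  bg <- subtract_background(line_profile(x, rep(7, length(x))))
  expect_equal(bg$slope, 0, tolerance = 1e-12)
  expect_equal(bg$intercept, 7, tolerance = 1e-12)
  expect_equal(bg$corrected$intensities, rep(0, length(x)),
               tolerance = 1e-12)
  # pure line
  bg <- subtract_background(line_profile(x, 2 + 0.5 * x))
  expect_equal(bg$slope, 0.5, tolerance = 1e-9)
  expect_equal(bg$intercept, 2, tolerance = 1e-9)
  expect_equal(max(abs(bg$corrected$intensities)), 0, tolerance = 1e-9)
})

test_that("background fit equals the sorted-lowest-35% OLS oracle", {
  x <- seq(0, 20, by = 0.05)
  y <- 3 + 0.8 * x + gaussian(x, 50, 4, 0.4) + gaussian(x, 70, 10, 0.3) +
    gaussian(x, 40, 16, 0.5)
  # bands cover < 35% of samples by construction
  bg <- subtract_background(line_profile(x, y))
  orc <- oracle_background(x, y)
  expect_equal(bg$slope, orc$slope, tolerance = 1e-10)
  expect_equal(bg$intercept, orc$intercept, tolerance = 1e-10)
  expect_identical(bg$points_used, orc$idx)
  # count uses the ceiling
  expect_length(bg$points_used, ceiling(0.35 * length(x)))
})

test_that("background subtraction is idempotent and validates inputs", {
  # bands sit where the baseline already exceeds the lowest-35% selection
  # threshold, so the selected samples are exactly collinear
  x <- seq(0, 20, by = 0.05)
  y <- 5 + 0.3 * x + gaussian(x, 80, 12, 0.15) + gaussian(x, 60, 15, 0.15) +
    gaussian(x, 70, 18, 0.15)
  p1 <- subtract_background(line_profile(x, y))$corrected
  p2 <- subtract_background(p1)$corrected
  expect_lt(max(abs(p2$intensities - p1$intensities)),
            1e-6 * diff(range(p1$intensities)))
  expect_error(subtract_background(line_profile(x, y), fraction = 0),
               "fraction")
  expect_error(subtract_background(line_profile(x, y), fraction = 1),
               "fraction")
  expect_error(subtract_background(line_profile(x[1:8], y[1:8]),
                                   fraction = 0.1), "fewer than 2")
})

test_that("find_bands locates noise-free peaks to within half a pixel", {
  x <- seq(0, 12.75, by = 0.05)
  y <- gaussian(x, 10, 2, 0.3) + gaussian(x, 8, 10.5, 0.3)
  pk <- find_bands(line_profile(x, y), min_separation = 1)
  expect_length(pk$positions, 2)
  expect_equal(pk$positions, c(2, 10.5), tolerance = 0.026)
  # periodic profile: floor(R/P) + 1 peaks over the covered range
  P <- 2.5
  x2 <- seq(0, 15, by = 0.05)
  yper <- Reduce(`+`, lapply(0:5, function(k) gaussian(x2, 5, 0.7 + k * P,
                                                       0.2)))
  pk2 <- find_bands(line_profile(x2, yper), min_separation = 1)
  expect_length(pk2$positions, floor((max(x2) - 0.7) / P) + 1)
})

test_that("find_bands agrees with the brute-force definitional oracle", {
  p <- sq_preset("larval")
  for (seed in c(42, 7)) {
    sim <- make_striated_profile(
      p$geometry, p$pixel_size_um,
      noise = noise_spec("gaussian", gaussian_sd = 100, seed = seed))
    for (ch in names(sim$profiles)) {
      prof <- subtract_background(sim$profiles[[ch]])$corrected
      pk <- find_bands(prof, min_prominence = 0.2, min_separation = 3.4)
      orc <- oracle_find_bands(prof$positions, prof$intensities,
                               min_prominence = 0.2, min_separation = 3.4)
      expect_identical(pk$indices, orc)
    }
  }
})

test_that("plateau peaks resolve to the leftmost sample", {
  y <- c(0, 1, 3, 3, 3, 1, 0, 0, 2, 0, 0, 0)
  x <- seq_along(y) * 0.1
  pk <- find_bands(line_profile(x, y), min_prominence = 0.1,
                   min_separation = 0.2)
  expect_identical(pk$indices, c(3L, 9L))
})

test_that("fit_band recovers exact Gaussians and reports closed-form area", {
  x <- seq(0, 10, by = 0.05)
  p <- line_profile(x, gaussian(x, 10, 5, 0.3))
  fit <- fit_band(p, 5)
  expect_true(fit$converged)
  expect_equal(fit$amplitude, 10, tolerance = 1e-6)
  expect_equal(fit$center, 5, tolerance = 1e-6)
  expect_equal(fit$sigma, 0.3, tolerance = 1e-6)
  # area vs trapezoidal quadrature of the fitted curve over +/- 6 sigma
  xx <- seq(fit$center - 6 * fit$sigma, fit$center + 6 * fit$sigma,
            length.out = 4001)
  quad <- sum(diff(xx) * (head(gaussian(xx, fit$amplitude, fit$center,
                                        fit$sigma), -1) +
                            tail(gaussian(xx, fit$amplitude, fit$center,
                                          fit$sigma), -1)) / 2)
  expect_equal(integrate_band(fit), quad, tolerance = 1e-3)
  expect_equal(integrate_band(fit), fit$amplitude * fit$sigma * sqrt(2 * pi),
               tolerance = 1e-12)
})

test_that("two bands 4 sigma apart are both recovered within 1%", {
  x <- seq(0, 10, by = 0.02)
  s <- 0.4
  y <- gaussian(x, 10, 4, s) + gaussian(x, 7, 4 + 4 * s, s)
  p <- line_profile(x, y)
  pk <- find_bands(p, min_separation = 1)
  expect_length(pk$positions, 2)
  fits <- lapply(seq_along(pk$positions), function(i) {
    fit_band(p, pk$positions[i], neighbours = pk$positions[-i])
  })
  centers <- sort(vapply(fits, `[[`, numeric(1), "center"))
  expect_equal(centers[1], 4, tolerance = 0.01 * 4)
  expect_equal(centers[2], 4 + 4 * s, tolerance = 0.01 * (4 + 4 * s))
  # grid-search oracle around the truth confirms the optimum neighbourhood
  grid <- expand.grid(mu1 = seq(3.9, 4.1, 0.01),
                      mu2 = seq(5.5, 5.7, 0.01))
  rss <- mapply(function(m1, m2) {
    sum((y - gaussian(x, 10, m1, s) - gaussian(x, 7, m2, s))^2)
  }, grid$mu1, grid$mu2)
  best <- grid[which.min(rss), ]
  expect_equal(centers, c(best$mu1, best$mu2), tolerance = 0.011)
})

test_that("non-finite fit windows are flagged, integration refuses them", {
  bad <- structure(list(amplitude = 1, sigma = 1, converged = FALSE),
                   class = "band_fit")
  expect_error(integrate_band(bad), "converge")
  # area linearity
  mk <- function(A, s) structure(list(amplitude = A, sigma = s,
                                      converged = TRUE),
                                 class = "band_fit")
  expect_equal(integrate_band(mk(1, 1 / sqrt(2 * pi))), 1, tolerance = 1e-12)
  expect_equal(integrate_band(mk(10, 0.3)), 10 * 0.3 * sqrt(2 * pi),
               tolerance = 1e-12)
  expect_equal(integrate_band(mk(2, 0.3)), 2 * integrate_band(mk(1, 0.3)),
               tolerance = 1e-12)
  expect_equal(integrate_band(mk(1, 0.6)), 2 * integrate_band(mk(1, 0.3)),
               tolerance = 1e-12)
})

test_that("smooth_profile matches the dense-kernel oracle and conserves mass", {
  set.seed(11)
  x <- seq(0, 5, by = 0.05)
  y <- runif(length(x), 0, 10)
  p <- line_profile(x, y)
  expect_identical(smooth_profile(p, 0)$intensities, y)
  for (s in c(0.7, 1, 2.3)) {
    sm <- smooth_profile(p, s)
    expect_equal(sm$intensities, oracle_smooth(y, s), tolerance = 1e-9)
  }
  # delta spike: discrete Gaussian summing to the spike height
  yd <- rep(0, length(x)); yd[50] <- 5
  smd <- smooth_profile(line_profile(x, yd), 1)
  expect_equal(sum(smd$intensities), 5, tolerance = 1e-6)
  expect_equal(which.max(smd$intensities), 50L)
})

test_that("fitted-center error grows with noise (monotone degradation)", {
  p <- sq_preset("larval")
  rmse_at <- function(sd) {
    errs <- unlist(lapply(1:4, function(seed) {
      sim <- make_striated_profile(
        p$geometry, p$pixel_size_um,
        noise = noise_spec("gaussian", gaussian_sd = sd, seed = seed))
      prof <- subtract_background(sim$profiles$Nano2)$corrected
      pk <- find_bands(prof, min_prominence = 0.35, min_separation = 3.4)
      truth <- sim$truth$center_um[sim$truth$channel == "Nano2"]
      vapply(pk$positions, function(pos) {
        fit <- tryCatch(
          suppressWarnings(
            fit_band(prof, pos, neighbours = setdiff(pk$positions, pos))),
          error = function(e) NULL)  # tiny-window bands: excluded
        if (is.null(fit) || !isTRUE(fit$converged)) return(NA_real_)
        min(abs(fit$center - truth))
      }, numeric(1))
    }))
    sqrt(mean(errs^2, na.rm = TRUE))
  }
  r <- vapply(c(10, 60, 150), rmse_at, numeric(1))
  expect_true(all(diff(r) >= 0))
})

test_that("noise-free generator output is fitted to ground truth", {
  p <- sq_preset("larval")
  sim <- make_striated_profile(p$geometry, p$pixel_size_um)
  prof <- subtract_background(sim$profiles$Nano2)$corrected
  pk <- find_bands(prof, min_separation = 3.4)
  truth <- sim$truth[sim$truth$channel == "Nano2", ]
  interior <- pk$positions[pk$positions > 1 & pk$positions < 84]
  for (pos in interior) {
    fit <- fit_band(prof, pos, neighbours = setdiff(pk$positions, pos))
    i <- which.min(abs(truth$center_um - pos))
    expect_equal(fit$center, truth$center_um[i], tolerance = 1e-4)
    expect_equal(fit$amplitude, truth$amplitude[i],
                 tolerance = 1e-4 * truth$amplitude[i])
    expect_equal(fit$sigma, p$geometry$psf_sigma, tolerance = 1e-4)
  }
})
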