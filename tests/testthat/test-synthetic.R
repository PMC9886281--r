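test_that("striated profiles match their closed form and ground truth", {
  p <- sq_preset("larval")
  sim <- make_striated_profile(p$geometry, p$pixel_size_um)
  # larval preset: Nano2 maxima spaced one period, Nano42 2.0 um away
  n2 <- sim$truth$center_um[sim$truth$channel == "Nano2"]
  n42 <- sim$truth$center_um[sim$truth$channel == "Nano42"]
  expect_equal(unique(diff(n2)), 8.5, tolerance = 1e-12)
  expect_equal(min(abs(outer(n2, n42, "-"))), 2.0, tolerance = 1e-12)
  # noise none: each channel is exactly the sum-of-Gaussians closed form
  x <- sim$profiles$Nano2$positions
  expected <- Reduce(`+`, lapply(n2, function(c0) {
    1000 * exp(-(x - c0)^2 / (2 * 0.25^2))
  }))
  expect_equal(sim$profiles$Nano2$intensities, expected, tolerance = 1e-12)
  # detected maxima land on the truth
  pk <- find_bands(sim$profiles$Nano2, min_separation = 3.4)
  interior <- n2[n2 > 0.5 & n2 < 84.5]
  # the bands at 0 and 85 um peak on boundary samples, so only the
  # interior Z-discs are detectable maxima
  expect_equal(length(pk$positions), length(interior))
  for (ctr in interior) {
    expect_lt(min(abs(pk$positions - ctr)), p$pixel_size_um / 2 + 1e-9)
  }
})

test_that("flight preset: sub-PSF epitope separation collapses to one band", {
  p <- sq_preset("flight")
  sim <- make_striated_profile(p$geometry, p$pixel_size_um)
  pk2 <- find_bands(sim$profiles$Nano2, min_separation = 1.3)
  pk42 <- find_bands(sim$profiles$Nano42, min_separation = 1.3)
  expect_equal(length(pk2$positions), length(pk42$positions))
  for (pos in pk2$positions[-c(1, length(pk2$positions))]) {
    expect_lt(min(abs(pk42$positions - pos)), p$pixel_size_um + 1e-9)
  }
})

test_that("profile extremes and background behave by construction", {
  g <- sarcomere_geometry(8.5, list(Nano2 = 4.25), psf_sigma = 0.25,
                         n_periods = 1L, amplitudes = 500)
  sim <- make_striated_profile(g, 0.1)
  expect_equal(max(sim$profiles$Nano2$intensities), 500, tolerance = 1e-6)
  expect_lt(min(sim$profiles$Nano2$intensities), 1e-9)
  simbg <- make_striated_profile(g, 0.1, background = c(10, 2))
  x <- simbg$profiles$Nano2$positions
  expect_equal(simbg$profiles$Nano2$intensities -
                 sim$profiles$Nano2$intensities, 10 + 2 * x,
               tolerance = 1e-9)
  expect_error(make_striated_profile(g, 0.3), "psf_sigma")
  expect_error(make_striated_profile(g, -1), "pixel_size")
  expect_error(sarcomere_geometry(8.5, list(), psf_sigma = 0.25), "empty")
})

test_that("block rendering equals the erf closed form and PSF-free limit", {
  g <- sarcomere_geometry(8.5, list(P = list(c(2.3, 3.9))),
                          band_kind = "block", amplitudes = 100,
                          psf_sigma = 0.15, n_periods = 2L)
  sim <- make_striated_profile(g, 0.05)
  x <- sim$profiles$P$positions
  expected <- 100 * (pnorm((x - 2.3) / 0.15) - pnorm((x - 3.9) / 0.15)) +
    100 * (pnorm((x - 10.8) / 0.15) - pnorm((x - 12.4) / 0.15))
  expect_equal(sim$profiles$P$intensities, expected, tolerance = 1e-12)
  # block plateau reaches the configured amplitude
  expect_equal(max(sim$profiles$P$intensities), 100, tolerance = 1e-6)
})

test_that("generators are bit-reproducible per seed", {
  p <- sq_preset("larval")
  nz <- noise_spec("gaussian", gaussian_sd = 100, seed = 5)
  s1 <- make_striated_profile(p$geometry, p$pixel_size_um, noise = nz)
  s2 <- make_striated_profile(p$geometry, p$pixel_size_um, noise = nz)
  expect_identical(s1$profiles$Nano2$intensities,
                   s2$profiles$Nano2$intensities)
  nz2 <- nz; nz2$seed <- 6L
  s3 <- make_striated_profile(p$geometry, p$pixel_size_um, noise = nz2)
  expect_false(identical(s1$profiles$Nano2$intensities,
                         s3$profiles$Nano2$intensities))
  # poisson-gaussian path is reproducible too
  nzp <- noise_spec("poisson-gaussian", gaussian_sd = 5, gain = 2, seed = 3)
  expect_identical(
    make_striated_profile(p$geometry, p$pixel_size_um,
                          noise = nzp)$profiles$Nano2$intensities,
    make_striated_profile(p$geometry, p$pixel_size_um,
                          noise = nzp)$profiles$Nano2$intensities)
})

test_that("depth stacks attenuate exponentially, exactly", {
  g <- sq_preset("larval")$geometry
  att <- attenuation_spec(5, I0 = 1000, z_step = 1, n_slices = 11L)
  st <- make_depth_stack(g, att, pixel_size = 0.1)
  # slice 10 vs slice 0: e^-2, pointwise and in total intensity
  expect_equal(st$truth$peak_intensity[11] / st$truth$peak_intensity[1],
               exp(-2), tolerance = 1e-12)
  expect_equal(max(st$stack[, , 11]) / max(st$stack[, , 1]), exp(-2),
               tolerance = 1e-12)
  expect_equal(sum(st$stack[, , 11]) / sum(st$stack[, , 1]), exp(-2),
               tolerance = 1e-12)
  # no-attenuation limit: all slices identical
  st_inf <- make_depth_stack(g, attenuation_spec(Inf, z_step = 1,
                                                 n_slices = 3L),
                             pixel_size = 0.1)
  expect_identical(st_inf$stack[, , 1], st_inf$stack[, , 3])
  # lambda ratio r => ground-truth decay-length ratio exactly r
  stA <- make_depth_stack(g, attenuation_spec(10), pixel_size = 0.1)
  stB <- make_depth_stack(g, attenuation_spec(4), pixel_size = 0.1)
  lr <- log(stA$scale[2] / stA$scale[1]) / log(stB$scale[2] / stB$scale[1])
  expect_equal(1 / lr, 10 / 4, tolerance = 1e-12)
  expect_error(attenuation_spec(-3), "lambda")
})

test_that("degrad pairs scale bands, not background", {
  g <- sq_preset("degrad-larval")$geometry
  pair <- make_degrad_pair(g, 0.8, background_level = 50, margin_px = 10)
  # knockdown band amplitude = control x (1 - rf) above the background
  expect_equal(max(pair$knockdown) - 50, (max(pair$control) - 50) * 0.2,
               tolerance = 1e-9)
  # background margin identical between the pair
  expect_identical(pair$control[pair$margin_rows, ],
                   pair$knockdown[pair$margin_rows, ])
  p0 <- make_degrad_pair(g, 0)
  expect_identical(p0$control, p0$knockdown)
  p1 <- make_degrad_pair(g, 1, background_level = 50)
  expect_equal(max(abs(p1$knockdown - 50)), 0, tolerance = 1e-12)
  expect_error(make_degrad_pair(g, 1.2), "reduction_factor")
})

test_that("FRAP movies follow the two-pool recovery model", {
  # f_imm = 1: analytic curve flat at 1 - bleach_depth
  t1 <- frap_ground_truth(1, tau = 300, bleach_depth = 0.8)
  expect_equal(frap_analytic_curve(t1, c(0, 500, 1e5)), rep(0.2, 3),
               tolerance = 1e-12)
  # f_imm = 0, bleach_depth = 1: recovery > 0.9999 at 10 tau
  t2 <- frap_ground_truth(0, tau = 300, bleach_depth = 1)
  expect_gt(frap_analytic_curve(t2, 10 * 300), 0.9999)
  expect_error(frap_ground_truth(1.2, 300), "f_imm")

  tr <- frap_ground_truth(0.6, tau = 120, bleach_depth = 0.7,
                          frame_interval = 30, n_frames = 10L,
                          n_prebleach = 2L)
  mv <- make_frap_movie(tr, pixel_size = 0.5, muscle_level = 800,
                        background_level = 40)
  # outside the bleach ROI the movie is constant over time (noise none)
  ub <- mv$rois$unbleached
  expect_identical(mv$movie[(ub[2] + 1):ub[4], (ub[1] + 1):ub[3], 1],
                   mv$movie[(ub[2] + 1):ub[4], (ub[1] + 1):ub[3], 12])
  # inside, the signal above background follows the analytic curve
  bl <- mv$rois$bleached
  px <- mv$movie[bl[2] + 1, bl[1] + 1, ]
  post <- which(mv$times_s >= 0)
  expect_equal((px[post] - 40) / (800 - 40),
               frap_analytic_curve(tr, mv$times_s[post]), tolerance = 1e-12)
})

test_that("BLI sensorgrams obey the Langmuir closed form", {
  d <- bli_design(c(1e-9, 1e-8), kon = 1e6, koff = 1e-4)
  ser <- make_bli_sensorgrams(d)
  # C = KD: plateau Rmax / 2
  dd <- bli_design(d$KD, kon = 1e6, koff = 1e-4, t_assoc = 2e5,
                   t_dissoc = 10)
  s2 <- make_bli_sensorgrams(dd)
  assoc <- s2[s2$phase == "association" & s2$concentration_M > 0, ]
  expect_equal(max(assoc$signal_nm), 0.4 / 2, tolerance = 1e-4)
  # C = 0 reference identically 0
  expect_true(all(ser$signal_nm[ser$concentration_M == 0] == 0))
  # slow off-rate: < 1% lost over 900 s of dissociation
  d3 <- bli_design(1e-8, kon = 1e6, koff = 1e-5)
  s3 <- make_bli_sensorgrams(d3)
  tr <- s3[s3$concentration_M > 0, ]
  r_end_assoc <- tr$signal_nm[tr$time_s == 200]
  r_final <- tr$signal_nm[nrow(tr)]
  expect_equal(r_final / r_end_assoc, exp(-1e-5 * 900), tolerance = 1e-9)
  expect_gt(r_final / r_end_assoc, 0.99)
  expect_error(bli_design(-1e-9, 1e6, 1e-5), "concentrations")
  expect_error(bli_design(1e-9, -1e6, 1e-5), "rates")
})
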