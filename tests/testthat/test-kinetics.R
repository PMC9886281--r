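test_that("the closed-form sensorgram matches an RK4 ODE oracle", {
  t <- seq(0, 1100, by = 10)
  for (prm in list(c(kon = 1e6, koff = 1e-3, C = 5e-9),
                   c(kon = 1e5, koff = 1e-2, C = 1e-7))) {
    closed <- model_sensorgram(prm[["kon"]], prm[["koff"]], 0.4,
                               prm[["C"]], t, t_assoc = 200)
    ode <- oracle_sensorgram_ode(prm[["kon"]], prm[["koff"]], 0.4,
                                 prm[["C"]], t, t_assoc = 200, dt = 0.005)
    expect_equal(closed, ode, tolerance = 1e-6)
  }
})

test_that("model limits behave: isotherm symmetry and irreversibility", {
  # C = KD -> plateau Rmax/2
  R <- model_sensorgram(1e6, 1e-3, 0.4, C = 1e-9, t = 1e6, t_assoc = 2e6)
  expect_equal(R, 0.2, tolerance = 1e-9)
  # koff -> 0: dissociation flat
  R2 <- model_sensorgram(1e6, 1e-12, 0.4, 1e-8, c(200, 1100), t_assoc = 200)
  expect_equal(R2[2] / R2[1], 1, tolerance = 1e-8)
  expect_error(model_sensorgram(-1, 1e-5, 0.4, 1e-9, 1, 200), "> 0")
})

test_that("reference subtraction cancels exactly", {
  d <- bli_design(c(1e-9, 1e-8), kon = 1e6, koff = 1e-4)
  ser <- make_bli_sensorgrams(d)
  clean <- ser[ser$concentration_M > 0, ]
  # reference == 0: identity
  sub <- reference_subtract(ser)
  expect_equal(sub$signal_nm, clean$signal_nm, tolerance = 1e-12)
  # drifting reference added then subtracted: exact recovery
  drift <- ser
  t <- drift$time_s
  drift$signal_nm <- drift$signal_nm + 0.001 * t
  sub2 <- reference_subtract(drift)
  expect_equal(sub2$signal_nm, clean$signal_nm, tolerance = 1e-9)
  # trace equal to reference -> 0
  self <- data.frame(time_s = t[1:100], signal_nm = sin(t[1:100] / 50),
                     concentration_M = 1e-9, phase = "association")
  ref <- data.frame(time_s = t[1:100], signal_nm = sin(t[1:100] / 50))
  expect_equal(reference_subtract(self, ref)$signal_nm, rep(0, 100),
               tolerance = 1e-12)
})

test_that("global fit recovers exact parameters on noise-free series", {
  d <- bli_design(c(2e-9, 1e-8, 5e-8), kon = 2e6, koff = 5e-4,
                  sample_interval = 2)
  ser <- reference_subtract(make_bli_sensorgrams(d))
  fit <- global_fit(ser)
  expect_true(fit$converged)
  expect_equal(fit$kon, 2e6, tolerance = 1e-6)
  expect_equal(fit$koff, 5e-4, tolerance = 1e-6)
  expect_equal(fit$Rmax, 0.4, tolerance = 1e-6)
  expect_equal(fit$KD, 2.5e-10, tolerance = 1e-6)
  # KD is reported as the quotient, by construction
  expect_identical(fit$KD, fit$koff / fit$kon)
  # residual optimality: +/- 5% perturbation of any parameter worsens RSS
  ss <- function(kon, koff, Rmax) {
    sum(vapply(split(ser, ser$concentration_M), function(tr) {
      sum((tr$signal_nm - model_sensorgram(kon, koff, Rmax,
                                           tr$concentration_M[1],
                                           tr$time_s, 200))^2)
    }, numeric(1)))
  }
  base <- ss(fit$kon, fit$koff, fit$Rmax)
  for (f in c(0.95, 1.05)) {
    expect_gte(ss(fit$kon * f, fit$koff, fit$Rmax), base)
    expect_gte(ss(fit$kon, fit$koff * f, fit$Rmax), base)
    expect_gte(ss(fit$kon, fit$koff, fit$Rmax * f), base)
  }
})

test_that("global fit equals a dense log-grid search on a coarse series", {
  d <- bli_design(c(5e-9, 5e-8), kon = 1e6, koff = 1e-3, t_assoc = 100,
                  t_dissoc = 300, sample_interval = 10)
  ser <- reference_subtract(make_bli_sensorgrams(
    d, noise = noise_spec("gaussian", gaussian_sd = 0.004, seed = 21)))
  fit <- global_fit(ser)
  # oracle: 41 x 41 grid in log10(kon) x log10(koff), Rmax profiled,
  # refined by optim from the best cell
  split_ser <- split(ser, ser$concentration_M)
  rss_of <- function(lk, lo) {
    basis <- lapply(split_ser, function(tr) {
      model_sensorgram(10^lk, 10^lo, 1, tr$concentration_M[1], tr$time_s,
                       100)
    })
    num <- sum(mapply(function(b, tr) sum(b * tr$signal_nm),
                      basis, split_ser))
    den <- sum(vapply(basis, function(b) sum(b^2), numeric(1)))
    Rm <- num / den
    sum(mapply(function(b, tr) sum((tr$signal_nm - Rm * b)^2),
               basis, split_ser))
  }
  grid <- expand.grid(lk = seq(4, 8, length.out = 41),
                      lo = seq(-5, -1, length.out = 41))
  vals <- mapply(rss_of, grid$lk, grid$lo)
  st <- grid[which.min(vals), ]
  ref <- stats::optim(c(st$lk, st$lo), function(p) rss_of(p[1], p[2]),
                      control = list(maxit = 3000, reltol = 1e-14))
  expect_equal(log10(fit$kon), ref$par[1], tolerance = 1e-3)
  expect_equal(log10(fit$koff), ref$par[2], tolerance = 1e-3)
})

test_that("KD stays within half a log unit under 1% noise", {
  d <- bli_design(c(2e-9, 1e-8, 5e-8), kon = 2e6, koff = 5e-4,
                  sample_interval = 5)
  lkd <- vapply(1:10, function(s) {
    ser <- reference_subtract(make_bli_sensorgrams(
      d, noise = noise_spec("gaussian", gaussian_sd = 0.004, seed = s)))
    log10(global_fit(ser)$KD)
  }, numeric(1))
  expect_lt(abs(stats::median(lkd) - log10(2.5e-10)), 0.3)
})

test_that("unit rescaling leaves model curves unchanged", {
  t <- seq(0, 1100, by = 5)
  a <- model_sensorgram(1e6, 1e-4, 0.4, 3e-9, t, 200)
  b <- model_sensorgram(1e6 / 1e3, 1e-4, 0.4, 3e-9 * 1e3, t, 200)
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("identifiability guardrails fire", {
  d <- bli_design(1e-8, kon = 1e6, koff = 1e-4)
  ser <- reference_subtract(make_bli_sensorgrams(d))
  expect_error(global_fit(ser), "2 distinct concentrations")
  # slow off-rate regime is reported, not hidden
  d2 <- bli_design(c(1e-9, 1e-8), kon = 1e6, koff = 1e-5,
                   sample_interval = 5)
  fit <- global_fit(reference_subtract(make_bli_sensorgrams(d2)))
  expect_true(any(grepl("limit", fit$warnings)))
})
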