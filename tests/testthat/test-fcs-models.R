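test_that("the 2D correlation law has its defining limits", {
  # amplitude limit
  expect_equal(model_g(1e-9, G0 = 0.4, tau_D = 0.01), 0.4, tolerance = 1e-6)
  # half decay at the transit time
  expect_equal(model_g(0.01, G0 = 0.4, tau_D = 0.01), 0.2)
  # two equal components collapse to one
  expect_equal(model_g(c(1e-4, 1e-2, 1), G0 = 0.3, tau_D = c(0.01, 0.01),
                       f = c(0.4, 0.6)),
               model_g(c(1e-4, 1e-2, 1), G0 = 0.3, tau_D = 0.01))
  # triplet factor raises G below tau_T and vanishes beyond
  g_t <- model_g(c(1e-6, 1), G0 = 0.3, tau_D = 0.01, Tt = 0.2, tau_T = 1e-5)
  g_0 <- model_g(c(1e-6, 1), G0 = 0.3, tau_D = 0.01)
  expect_gt(g_t[1], g_0[1])
  expect_equal(g_t[2], g_0[2], tolerance = 1e-8)
  expect_error(model_g(-1, G0 = 0.3, tau_D = 0.01), "tau must be")
  expect_error(model_g(1, G0 = 0.3, tau_D = 0.01, alpha = 2.5), "alpha")
})

test_that("noiseless self-fits recover parameters across a grid", {
  tau <- 10^seq(-5.5, 0.5, length.out = 80)
  for (G0 in c(0.1, 0.6)) {
    for (tau_D in c(1e-3, 2e-2)) {
      crv <- fcs_curve(tau, model_g(tau, G0 = G0, tau_D = tau_D))
      fit <- fcs_fit(crv)
      expect_true(fit$converged)
      expect_equal(coef(fit)[["G0"]], G0, tolerance = 1e-6)
      expect_equal(coef(fit)[["tau_D1"]], tau_D, tolerance = 1e-6)
    }
  }
  # anomalous exponent
  crv <- fcs_curve(tau, model_g(tau, G0 = 0.3, tau_D = 5e-3, alpha = 0.8))
  fa <- fcs_fit(crv, anomalous = TRUE)
  expect_equal(coef(fa)[["alpha"]], 0.8, tolerance = 1e-5)
  # two components (slow/fast well separated)
  crv2 <- fcs_curve(tau, model_g(tau, G0 = 0.3, tau_D = c(1e-3, 5e-2),
                                 f = c(0.3, 0.7)))
  f2 <- fcs_fit(crv2, components = 2)
  tds <- sort(coef(f2)[c("tau_D1", "tau_D2")])
  expect_equal(unname(tds), c(1e-3, 5e-2), tolerance = 1e-4)
  # triplet
  crv3 <- fcs_curve(tau, model_g(tau, G0 = 0.3, tau_D = 5e-3, Tt = 0.15,
                                 tau_T = 1e-5))
  f3 <- fcs_fit(crv3, triplet = TRUE)
  expect_equal(coef(f3)[["Tt"]], 0.15, tolerance = 1e-4)
  expect_equal(coef(f3)[["tau_T"]], 1e-5, tolerance = 1e-4)
})

test_that("curves with too few lags are refused", {
  tau <- 10^seq(-4, -1, length.out = 6)
  crv <- fcs_curve(tau, model_g(tau, G0 = 0.3, tau_D = 1e-3))
  expect_error(fcs_fit(crv), "fewer than 8")
})

test_that("spot calibration reproduces the printed observation area", {
  cal <- spot_calibration(fwhm = 250)
  expect_equal(cal$w0, 250 / sqrt(2 * log(2)), tolerance = 1e-12)
  expect_equal(cal$effective_area, 0.0709, tolerance = 0.01)
  expect_gte(cal$effective_area, 0.06)
  expect_lte(cal$effective_area, 0.0715)
  # round trip through the waist convention
  cal2 <- spot_calibration(w0 = cal$w0)
  expect_equal(cal2$fwhm, 250, tolerance = 1e-9)
  expect_error(spot_calibration(), "exactly one")
  expect_error(spot_calibration(fwhm = 250, w0 = 210), "exactly one")
})

test_that("transit-time to D conversion is exact and monotone", {
  cal <- spot_calibration(fwhm = 250)
  w0_um <- cal$w0 / 1000
  expect_equal(transit_to_D(w0_um^2 / 4, cal), 1, tolerance = 1e-12)
  expect_equal(transit_to_D(2 * w0_um^2 / 4, cal),
               transit_to_D(w0_um^2 / 4, cal) / 2)
  tds <- c(0.001, 0.01, 0.1)
  expect_true(all(diff(transit_to_D(tds, cal)) < 0))
  expect_error(transit_to_D(0.01), "calibration")
  expect_error(transit_to_D(-1, cal), "tau_D")
})

test_that("counts per molecule is <I> G0 and errors on bad amplitude", {
  expect_equal(counts_per_molecule(100, 1), 100)
  expect_equal(counts_per_molecule(0, 0.5), 0)
  expect_equal(counts_per_molecule(80, 0.25), 20)
  expect_error(counts_per_molecule(10, 0), "G0")
  expect_error(counts_per_molecule(-1, 0.5), "mean intensity")
})

test_that("brightness is intensive: independent of particle density", {
  # per-particle peak brightness is 1 (a.u.); the Gaussian spot yields
  # cpm = <I>/N = (C pi w0^2 / 2) / (C pi w0^2) = 0.5 at any density
  cpms <- sapply(c(175, 350), function(np) {
    cfg <- sim_config(n_particles = np, duration = 2, dt = 1e-5, seed = 51)
    tr <- simulate_diffusion(cfg)
    crv <- autocorrelate(tr)
    fit <- fcs_fit(crv, offset = TRUE)
    fit$cpm
  })
  expect_lt(abs(cpms[1] - 0.5), 0.15)
  expect_lt(abs(cpms[2] - 0.5), 0.15)
  expect_lt(abs(cpms[1] - cpms[2]), 0.2)
})

test_that("bootstrap uncertainty is reported and sensible", {
  set.seed(52)
  cfg <- sim_config(n_particles = 100, duration = 0.5, dt = 1e-5, seed = 53)
  tr <- simulate_diffusion(cfg)
  crv <- autocorrelate(tr)
  fit <- fcs_fit(crv, trace = tr, bootstrap = 10)
  expect_true(all(c("G0", "tau_D1") %in% names(fit$boot_sd)))
  expect_true(all(is.finite(fit$boot_sd)))
  expect_gt(fit$boot_sd[["tau_D1"]], 0)
})
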