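make_flat_carpet <- function(n_px, n_cycles, level = 50, freq = 2081,
                             seed = 1) {
  set.seed(seed)
  sfcs_carpet(matrix(rpois(n_px * n_cycles, level), n_px), freq)
}

test_that("carpet geometry invariants hold", {
  cp <- make_flat_carpet(52, 1000)
  expect_equal(cp$line_length, 5.2)
  expect_equal(cp$duration, 1000 / 2081)
  expect_error(sfcs_carpet(matrix(-1, 2, 10)), ">= 0")
})

test_that("initial cropping removes exactly the stated cycles", {
  cp <- make_flat_carpet(4, 104050) # 50 s at 2081 Hz
  expect_identical(crop_initial(cp, 0), cp)
  cropped <- crop_initial(cp, 10)
  expect_equal(ncol(cropped$intensities), 83240) # 40 s x 2081
  # locality: output independent of what the cropped cycles contained
  cp2 <- cp
  cp2$intensities[, 1:20810] <- 0
  expect_equal(crop_initial(cp2, 10)$intensities, cropped$intensities)
  expect_error(crop_initial(cp, 60), "smaller than")
})

test_that("bleach correction is identity on stationary traces", {
  cp <- sfcs_carpet(matrix(rep(c(40, 60), 5000), 2), 500)
  out <- bleach_correct(cp, 4)
  expect_equal(out$intensities, cp$intensities, tolerance = 1e-12)
})

test_that("bleach correction flattens an exponential decay", {
  freq <- 500
  tt <- seq_len(20000) / freq # 40 s
  set.seed(71)
  base <- rpois(20000, 80)
  bleached <- base * exp(-tt / 200) # bleaching much slower than the window
  cp <- sfcs_carpet(rbind(bleached, bleached), freq)
  out <- bleach_correct(cp, 18)
  y <- out$intensities[1, ]
  # residual linear trend indistinguishable from noise
  sl <- summary(lm(y ~ tt))$coefficients["tt", ]
  expect_lt(abs(sl["Estimate"]), 3 * sl["Std. Error"] + 0.01)
  # global mean preserved exactly
  expect_equal(mean(out$intensities[1, ]), mean(bleached), tolerance = 1e-9)
  # uncorrected trace, by contrast, has a strong trend
  sl0 <- summary(lm(bleached ~ tt))$coefficients["tt", "Estimate"]
  expect_gt(abs(sl0), 10 * abs(sl["Estimate"]))
})

test_that("pixels whose trend hits zero are flagged and excluded", {
  freq <- 500
  good <- rpois(10000, 50)
  dead <- c(rpois(2000, 50), rep(0, 8000))
  cp <- sfcs_carpet(rbind(good, dead), freq)
  out <- bleach_correct(cp, 4)
  expect_identical(attr(out, "excluded"), c(FALSE, TRUE))
  expect_equal(out$intensities[2, ], dead) # untouched, just flagged
})

test_that("a homogeneous simulated carpet yields one tight population", {
  cp <- small_carpet() # free diffusion, D = 1, 16 pixels
  proc <- bleach_correct(crop_initial(cp, 1), 5)
  res <- analyze_carpet(proc, calibration = study_calibration())
  expect_true(all(res$qc %in% c("ok", "not_converged")))
  expect_gte(length(res$pixels_ok), 12)
  cv <- sd(res$transit_ms) / mean(res$transit_ms)
  expect_lt(cv, 0.25)
  # cpm pooling consistent with a single-spot analysis (pixel 1)
  f1 <- res$fits[[res$pixels_ok[1]]]
  expect_lt(abs(mean(res$cpm, na.rm = TRUE) - f1$cpm) / f1$cpm, 0.35)
})

test_that("a study-condition carpet recovers the input D", {
  cp <- study_carpet() # 3 um domain, 350 particles, D = 1
  proc <- bleach_correct(crop_initial(cp, 1), 5)
  # per-pixel baseline absorbs the closed-domain long-lag anticorrelation
  res <- analyze_carpet(proc, calibration = study_calibration(),
                        offset = TRUE)
  expect_gte(length(res$pixels_ok), 12)
  expect_lt(abs(median(res$D) - 1), 0.3)
})

test_that("identical pixel traces give identical fits (pixel independence)", {
  base <- small_carpet()
  M <- base$intensities
  rep4 <- sfcs_carpet(M[c(1, 1, 1, 1), ], base$scan_frequency,
                      base$pixel_size)
  res <- analyze_carpet(rep4)
  expect_equal(length(unique(round(res$transit_ms, 9))), 1)
  # sub-carpet analysis equals the corresponding subset of the full result
  full <- analyze_carpet(sfcs_carpet(M, base$scan_frequency, base$pixel_size))
  sub <- analyze_carpet(sfcs_carpet(M[1:4, ], base$scan_frequency,
                                    base$pixel_size))
  expect_equal(sub$transit_ms, full$transit_ms[1:4], tolerance = 1e-9)
})

test_that("a two-region carpet produces a bimodal transit-time pool", {
  fast <- small_carpet(seed = 41, D = 1)
  slow <- small_carpet(seed = 42, D = 0.5) # factor 2 in tau_D
  M <- rbind(fast$intensities, slow$intensities)
  cp <- sfcs_carpet(M, fast$scan_frequency, fast$pixel_size)
  res <- analyze_carpet(cp)
  n_fast <- nrow(fast$intensities)
  t_fast <- median(res$transit_ms[res$pixels_ok <= n_fast])
  t_slow <- median(res$transit_ms[res$pixels_ok > n_fast])
  expect_gt(t_slow / t_fast, 1.5)
  expect_lt(t_slow / t_fast, 2.7)
})

test_that("a carpet of uncorrelatable pixels fails loudly", {
  cp <- sfcs_carpet(matrix(0, 4, 2000), 500) # dark pixels: G undefined
  expect_error(analyze_carpet(cp), "50%")
})
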