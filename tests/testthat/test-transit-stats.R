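test_that("single log-normal MLE is the closed form and flags degeneracy", {
  t0 <- c(3, 7, 21, 55, 13)
  fit <- transit_fit(t0, "single")
  expect_equal(fit$mu, mean(log(t0)))
  expect_equal(fit$sigma, sqrt(mean((log(t0) - mean(log(t0)))^2)))
  expect_equal(fit$e_mu, exp(fit$mu))
  expect_equal(fit$bic, 2 * log(5) - 2 * fit$loglik)
  expect_equal(unclass(logLik(fit)), fit$loglik, ignore_attr = TRUE)
  expect_equal(attr(logLik(fit), "df"), 2)
  # all-equal times: degenerate, flagged
  fit0 <- transit_fit(rep(21, 10), "single")
  expect_true(isTRUE(fit0$flags$degenerate_sigma))
  expect_equal(fit0$e_mu, 21)
  expect_error(transit_fit(c(1, -1, 2), "single"), "> 0")
})

test_that("e^mu matches the sample median within its standard error", {
  set.seed(61)
  x <- generate_transit_samples(20000, "single", mu = log(21), sigma = 0.4,
                                seed = 61)
  fit <- transit_fit(x, "single")
  med <- median(x)
  # se of a log-normal sample median: 1/(2 sqrt(n) f(median))
  se_med <- 1 / (2 * sqrt(length(x)) * dlnorm(med, log(21), 0.4))
  expect_lt(abs(fit$e_mu - med), 3 * se_med)
  # recovery at the free-lipid scale: e^mu = 21 ms within 1% at n = 1e5
  y <- generate_transit_samples(1e5, "single", mu = log(21), sigma = 0.35,
                                seed = 62)
  expect_lt(abs(transit_fit(y, "single")$e_mu - 21) / 21, 0.01)
})

test_that("MLE bias shrinks as the sample grows", {
  errs <- sapply(c(100, 1000, 10000), function(n) {
    reps <- sapply(1:20, function(r) {
      x <- generate_transit_samples(n, "single", mu = log(15), sigma = 0.3,
                                    seed = 7000 + 20 * log10(n) + r)
      f <- transit_fit(x, "single")
      c(f$mu - log(15), f$sigma - 0.3)
    })
    sqrt(mean(reps^2))
  })
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 0.01)
})

test_that("the mixture EM recovers both medians at lipid scales", {
  # slow/fast component scales seen for sphingomyelin (42/25 ms) and
  # cholesterol (15/9 ms) probes
  for (mus in list(c(42, 25), c(15, 9))) {
    x <- generate_transit_samples(1e4, "double", mu = log(mus),
                                  sigma = c(0.3, 0.3), B = 0.5,
                                  seed = round(sum(mus)))
    fit <- transit_fit(x, "double")
    expect_equal(fit$model, "double")
    expect_lt(abs(fit$e_mu[1] - mus[1]) / mus[1], 0.10) # C1 slow
    expect_lt(abs(fit$e_mu[2] - mus[2]) / mus[2], 0.10) # C2 fast
    expect_lt(abs(fit$B - 0.5), 0.15)
    expect_equal(fit$bic, 5 * log(1e4) - 2 * fit$loglik)
  }
})

test_that("the mixture likelihood is cross-checked by an independent EM", {
  skip_if_not_installed("mclust")
  suppressPackageStartupMessages(library(mclust))
  x <- generate_transit_samples(5000, "double", mu = log(c(40, 10)),
                                sigma = c(0.3, 0.25), B = 0.4, seed = 63)
  fit <- transit_fit(x, "double")
  mc <- Mclust(log(x), G = 2, modelNames = "V", verbose = FALSE)
  # mclust fits the normal mixture on log t; add the log-transform Jacobian
  # to put its likelihood on the transit-time scale
  expect_equal(fit$loglik, mc$loglik - sum(log(x)), tolerance = 1e-6)
})

test_that("nesting: the mixture never fits worse than the single model", {
  for (s in 64:66) {
    x <- generate_transit_samples(800, "single", mu = log(20), sigma = 0.35,
                                  seed = s)
    single <- transit_fit(x, "single")
    double <- transit_fit(x, "double")
    expect_gte(double$loglik, single$loglik - 1e-6)
  }
})

test_that("component labels are stable: C1 slow, C2 fast, any input order", {
  x <- generate_transit_samples(4000, "double", mu = log(c(50, 10)),
                                sigma = c(0.3, 0.3), B = 0.3, seed = 67)
  f1 <- transit_fit(x, "double")
  f2 <- transit_fit(rev(x), "double")
  f3 <- transit_fit(sample(x), "double")
  expect_gt(f1$e_mu[1], f1$e_mu[2])
  expect_equal(f1$e_mu, f2$e_mu, tolerance = 1e-6)
  expect_equal(f1$e_mu, f3$e_mu, tolerance = 1e-6)
  expect_equal(f1$B, f2$B, tolerance = 1e-6)
})

test_that("BIC selects the generating model on separated data", {
  # single-model data -> single wins; 2x-separated mixture -> double wins;
  # >= 95% of 100 seeded repetitions each (a selector calibration study)
  pick <- function(seed, gen) {
    x <- if (gen == "single")
      generate_transit_samples(1e4, "single", mu = log(21), sigma = 0.3,
                               seed = seed)
    else
      generate_transit_samples(1e4, "double", mu = log(c(42, 21)),
                               sigma = c(0.25, 0.25), B = 0.5, seed = seed)
    transit_fit(x, "auto")$model
  }
  singles <- vapply(1:100, pick, "", gen = "single")
  doubles <- vapply(101:200, pick, "", gen = "double")
  expect_gte(mean(singles == "single"), 0.95)
  expect_gte(mean(doubles == "double"), 0.95)
})

test_that("model selection reports the margin and both candidates", {
  x <- generate_transit_samples(2000, "double", mu = log(c(40, 10)),
                                sigma = c(0.3, 0.3), B = 0.5, seed = 68)
  sel <- select_model_bic(x)
  expect_equal(sel$model, "double")
  expect_gt(sel$delta_bic, 0)
  expect_named(sel$candidates, c("single", "double"))
  expect_equal(sel$bic, min(sel$candidates$single$bic,
                            sel$candidates$double$bic))
})

test_that("histogram modes agree with each other and the CDF definition", {
  x <- generate_transit_samples(1e4, "single", mu = log(18), sigma = 0.35,
                                seed = 69)
  cum <- histogram_modes(x, "cumulative")
  at_med <- cum$height[which.min(abs(cum$x - median(x)))]
  expect_lt(abs(at_med - 0.5), 1 / sqrt(length(x)) + 1e-3)
  logh <- histogram_modes(x, "logarithmic")
  # log-binned log-normal data are symmetric in ln t
  z <- rep(log(logh$mids), pmax(round(logh$height * 1000), 0))
  sk <- mean((z - mean(z))^3) / sd(z)^3
  expect_lt(abs(sk), 0.2)
  lin <- histogram_modes(x, "linear")
  expect_lt(abs(lin$ls_fit[["e_mu"]] - logh$ls_fit[["e_mu"]]) /
              logh$ls_fit[["e_mu"]], 0.05)
  expect_warning(histogram_modes(rep(c(1, 1.0001), 30), "linear", bins = 3),
                 "bins")
})
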