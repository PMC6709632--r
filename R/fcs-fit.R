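#' Fit an FCS model to a correlation curve
#'
#' Weighted nonlinear least-squares fit of the 2D FCS law [model_g()] to a
#' correlation curve, with Levenberg-Marquardt optimisation
#' (`minpack.lm::nls.lm`), box constraints, and a deterministic three-point
#' multi-start (amplitude-based, decay-midpoint-based, perturbed) to avoid
#' local minima. Weights are `1/sem^2` when the curve carries per-lag
#' uncertainties, else uniform. Parameter uncertainties can be estimated by
#' bootstrap: the source trace is re-correlated on random contiguous
#' sub-segments (default 10 rounds) and each bootstrap curve refitted.
#'
#' @param curve an [fcs_curve()] with at least 8 lags.
#' @param components 1 or 2 diffusing components.
#' @param anomalous if `TRUE` the anomalous exponent `alpha` is free in
#'   (0, 2]; otherwise fixed to 1.
#' @param triplet if `TRUE` a triplet-blinking factor is included
#'   (`tau_T` bounded to 1-100 us).
#' @param calibration optional [spot_calibration()]; when given, fitted
#'   transit times are converted to diffusion coefficients.
#' @param trace optional source [intensity_trace()], enabling `bootstrap`.
#' @param bootstrap number of bootstrap rounds (0 = none; needs `trace`).
#' @param points_per_octave correlator setting used for bootstrap curves.
#' @param max_lag optional upper lag cutoff (s) applied before fitting.
#' @param weights `"auto"` (default: `1/sem^2` when the curve carries
#'   per-lag uncertainties, else uniform) or `"none"` (always uniform).
#'   Use `"none"` when the sem comes from only a handful of repeats — such
#'   noisy per-lag weights destabilise the fit more than they help.
#' @param offset if `TRUE`, a free additive baseline `G_inf` is included.
#'   Correlation curves estimated from a finite trace of length `T` sit on a
#'   small negative baseline (the mean of the trace is estimated from the
#'   trace itself, biasing `G` by about `-2 integral(G) / T`); the offset
#'   absorbs it, which matters when `tau_D / T` is not tiny. Off by default
#'   so the plain analytic law is fitted.
#' @return An object of class `"fcs_fit"` with components `par` (named
#'   estimates), `converged`, `D` (um^2/s, per component, when calibrated),
#'   `N` (= 1/G0), `cpm` (counts per molecule, when the curve knows its mean
#'   intensity), `boot_sd`, `fitted`, `residuals`, `ssr`, `curve`, `spec`.
#'   Methods: `print`, `summary`, `coef`, `predict`, `residuals`, `plot`.
#' @examples
#' tau <- 10^seq(-5, 0, length.out = 60)
#' crv <- fcs_curve(tau, model_g(tau, G0 = 0.4, tau_D = 0.01))
#' fit <- fcs_fit(crv)
#' coef(fit)
#' @export
fcs_fit <- function(curve, components = 1L, anomalous = FALSE,
                    triplet = FALSE, calibration = NULL, trace = NULL,
                    bootstrap = 0L, points_per_octave = 16L, max_lag = NULL,
                    offset = FALSE, weights = c("auto", "none")) {
  stopifnot(inherits(curve, "fcs_curve"))
  if (!is.null(max_lag)) {
    keep <- curve$lag <= max_lag
    curve <- fcs_curve(curve$lag[keep], curve$G[keep],
                       sem = if (!is.null(curve$sem)) curve$sem[keep],
                       dt = attr(curve, "dt"),
                       mean_intensity = attr(curve, "mean_intensity"),
                       n_samples = attr(curve, "n_samples"))
  }
  if (nrow(curve) < 8)
    stop("curve has fewer than 8 lags; refusing to fit", call. = FALSE)
  if (any(!is.finite(curve$G))) stop("curve contains non-finite G", call. = FALSE)
  components <- as.integer(components)
  if (!components %in% 1:2) stop("components must be 1 or 2", call. = FALSE)
  spec <- list(components = components, anomalous = isTRUE(anomalous),
               triplet = isTRUE(triplet), offset = isTRUE(offset))

  weights <- match.arg(weights)
  w <- if (weights == "auto" && !is.null(curve$sem) &&
           all(is.finite(curve$sem)) && all(curve$sem > 0))
    1 / curve$sem else rep(1, nrow(curve))

  fit <- fit_fcs_multistart(curve$lag, curve$G, w, spec)
  par <- fit$par

  out <- list(par = par, converged = fit$converged, ssr = fit$ssr,
              fitted = eval_fcs_par(curve$lag, par, spec),
              curve = curve, spec = spec, calibration = calibration)
  out$residuals <- curve$G - out$fitted
  out$N <- 1 / par[["G0"]]
  if (!is.null(calibration))
    out$D <- transit_to_D(par[grep("^tau_D", names(par))], calibration)
  mi <- attr(curve, "mean_intensity")
  if (is.finite(mi) && par[["G0"]] > 0)
    out$cpm <- counts_per_molecule(mi, par[["G0"]])

  if (bootstrap > 0) {
    if (is.null(trace))
      stop("bootstrap requires the source trace", call. = FALSE)
    x <- trace$values
    n <- length(x)
    seg <- max(2 * points_per_octave + 1, n %/% 2)
    boots <- matrix(NA_real_, bootstrap, length(par),
                    dimnames = list(NULL, names(par)))
    for (b in seq_len(bootstrap)) {
      s0 <- sample.int(n - seg + 1, 1)
      sub <- intensity_trace(x[s0:(s0 + seg - 1)], trace$dt)
      bc <- try(autocorrelate(sub, points_per_octave), silent = TRUE)
      if (inherits(bc, "try-error")) next
      if (!is.null(max_lag)) bc <- bc[bc$lag <= max_lag, ]
      bf <- try(fit_fcs_multistart(bc$lag, bc$G, rep(1, nrow(bc)), spec,
                                   start = par), silent = TRUE)
      if (!inherits(bf, "try-error") && bf$converged) boots[b, ] <- bf$par
    }
    out$boot <- boots
    out$boot_sd <- apply(boots, 2, sd, na.rm = TRUE)
  }
  class(out) <- "fcs_fit"
  out
}

# parameter layout per model spec; bounds chosen to cover membrane FCS scales
fcs_par_template <- function(lag, G, spec) {
  lo <- c(G0 = 1e-8)
  hi <- c(G0 = Inf)
  g0 <- max(mean(G[seq_len(min(3, length(G)))]), 1e-6)
  # decay midpoint: first lag where G falls below half the amplitude
  idx <- which(G <= g0 / 2)
  tmid <- if (length(idx)) lag[idx[1]] else lag[round(length(lag) / 2)]
  start <- c(G0 = g0, tau_D1 = tmid)
  lo <- c(lo, tau_D1 = min(lag) / 10)
  hi <- c(hi, tau_D1 = max(lag) * 100)
  if (spec$components == 2) {
    start <- c(start, f1 = 0.5, tau_D2 = tmid * 5)
    lo <- c(lo, f1 = 0, tau_D2 = min(lag) / 10)
    hi <- c(hi, f1 = 1, tau_D2 = max(lag) * 100)
  }
  if (spec$anomalous) {
    start <- c(start, alpha = 1)
    lo <- c(lo, alpha = 0.2)
    hi <- c(hi, alpha = 2)
  }
  if (spec$triplet) {
    start <- c(start, Tt = 0.1, tau_T = 1e-5)
    lo <- c(lo, Tt = 0, tau_T = 1e-6)
    hi <- c(hi, Tt = 0.99, tau_T = 1e-4)
  }
  if (isTRUE(spec$offset)) {
    start <- c(start, G_inf = 0)
    lo <- c(lo, G_inf = -1)
    hi <- c(hi, G_inf = 1)
  }
  list(start = start, lower = lo, upper = hi)
}

eval_fcs_par <- function(lag, par, spec) {
  tau_D <- unname(par[grep("^tau_D", names(par))])
  f <- if (spec$components == 2) c(par[["f1"]], 1 - par[["f1"]]) else 1
  model_g(lag, G0 = par[["G0"]], tau_D = tau_D, f = f,
          alpha = if (spec$anomalous) par[["alpha"]] else 1,
          Tt = if (spec$triplet) par[["Tt"]] else 0,
          tau_T = if (spec$triplet) par[["tau_T"]] else 1e-5) +
    (if (isTRUE(spec$offset)) par[["G_inf"]] else 0)
}

fit_fcs_multistart <- function(lag, G, w, spec, start = NULL) {
  tpl <- fcs_par_template(lag, G, spec)
  starts <- list(tpl$start)
  s2 <- tpl$start; s2["tau_D1"] <- s2[["tau_D1"]] * 4
  s3 <- tpl$start; s3["G0"] <- s3[["G0"]] * 0.5; s3["tau_D1"] <- s3[["tau_D1"]] * 0.3
  starts <- c(starts, list(s2, s3))
  if (!is.null(start)) {
    s <- pmin(pmax(start[names(tpl$start)], tpl$lower), tpl$upper)
    names(s) <- names(tpl$start)
    starts <- c(list(s), starts)
  }
  resid_fn <- function(p) {
    p <- setNames(p, names(tpl$start))
    w * (eval_fcs_par(lag, p, spec) - G)
  }
  best <- NULL
  for (s in starts) {
    fit <- try(minpack.lm::nls.lm(
      par = s, lower = tpl$lower, upper = tpl$upper, fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    ssr <- sum(fit$fvec^2)
    conv <- fit$info %in% 1:3
    if (is.null(best) || (conv && !best$conv) ||
        (conv == best$conv && ssr < best$ssr))
      best <- list(par = setNames(fit$par, names(tpl$start)), ssr = ssr,
                   conv = conv)
  }
  if (is.null(best))
    return(list(par = tpl$start, ssr = Inf, converged = FALSE))
  list(par = best$par, ssr = best$ssr, converged = best$conv)
}

#' @export
coef.fcs_fit <- function(object, ...) object$par

#' @export
residuals.fcs_fit <- function(object, ...) object$residuals

#' @export
predict.fcs_fit <- function(object, tau = NULL, ...) {
  if (is.null(tau)) return(object$fitted)
  eval_fcs_par(tau, object$par, object$spec)
}

#' @export
print.fcs_fit <- function(x, ...) {
  cat(sprintf("2D FCS fit (%d component%s%s%s)%s\n",
              x$spec$components, if (x$spec$components > 1) "s" else "",
              if (x$spec$anomalous) ", anomalous" else "",
              if (x$spec$triplet) ", triplet" else "",
              if (!x$converged) "  [NOT CONVERGED]" else ""))
  print(round(x$par, 6))
  if (!is.null(x$D))
    cat(sprintf("  D = %s um^2/s\n", paste(signif(x$D, 4), collapse = ", ")))
  if (!is.null(x$cpm)) cat(sprintf("  cpm = %.4g\n", x$cpm))
  invisible(x)
}

#' @export
summary.fcs_fit <- function(object, ...) {
  print(object)
  cat(sprintf("  N = 1/G0 = %.3f, SSR = %.3g over %d lags\n",
              object$N, object$ssr, nrow(object$curve)))
  if (!is.null(object$boot_sd)) {
    cat("  bootstrap sd:\n")
    print(signif(object$boot_sd, 3))
  }
  invisible(object)
}

#' @export
plot.fcs_fit <- function(x, ...) {
  plot(x$curve$lag, x$curve$G, log = "x", xlab = "lag (s)",
       ylab = expression(G(tau)), ...)
  tt <- exp(seq(log(min(x$curve$lag)), log(max(x$curve$lag)),
                length.out = 200))
  lines(tt, predict(x, tt), col = "red3", lwd = 2)
  invisible(x)
}
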