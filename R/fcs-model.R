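#' Observation-spot calibration
#'
#' Converts a measured full-width-at-half-maximum of the Gaussian focal spot
#' into the 1/e^2 radius `w0 = fwhm / sqrt(2 log 2)` and the effective
#' two-dimensional observation area `pi * w0^2 / 2`. With the 250 nm FWHM of
#' a confocal spot this gives ~0.071 um^2, inside the 0.06-0.07 um^2 range
#' typical of such calibrations.
#'
#' @param fwhm full width at half maximum of the spot, nm.
#' @param w0 alternatively, the 1/e^2 radius directly, nm (exactly one of
#'   `fwhm`/`w0` must be given).
#' @return An object of class `"spot_calibration"`: `fwhm` (nm), `w0` (nm),
#'   `effective_area` (um^2).
#' @examples
#' spot_calibration(fwhm = 250)
#' @export
spot_calibration <- function(fwhm = NULL, w0 = NULL) {
  if (is.null(fwhm) == is.null(w0))
    stop("give exactly one of fwhm or w0 (nm)", call. = FALSE)
  if (is.null(w0)) w0 <- fwhm / sqrt(2 * log(2))
  else fwhm <- w0 * sqrt(2 * log(2))
  if (w0 <= 0) stop("spot size must be positive", call. = FALSE)
  structure(list(fwhm = fwhm, w0 = w0,
                 effective_area = pi * (w0 / 1000)^2 / 2),
            class = "spot_calibration")
}

#' @export
print.spot_calibration <- function(x, ...) {
  cat(sprintf(
    "Spot calibration: FWHM %.1f nm, w0 %.1f nm, effective area %.4f um^2\n",
    x$fwhm, x$w0, x$effective_area))
  invisible(x)
}

#' Analytic 2D FCS correlation model
#'
#' The community-standard two-dimensional diffusion law with optional
#' anomalous exponent, second component, and triplet blinking:
#' \deqn{G(\tau) = G_0 \left[1 + \frac{T}{1-T} e^{-\tau/\tau_T}\right]
#'   \sum_i f_i \left(1 + (\tau/\tau_{D,i})^\alpha\right)^{-1}}
#' with `sum(f) = 1`. `G0 = 1/N` is the inverse mean spot occupancy and
#' `tau_D` the transit (half-decay) time.
#'
#' @param tau lag times, s (> 0).
#' @param G0 amplitude.
#' @param tau_D transit time(s), s; length 1 or 2.
#' @param f component fractions summing to 1 (default single component).
#' @param alpha anomalous exponent in (0, 2]; 1 = normal diffusion.
#' @param Tt triplet fraction in \[0, 1).
#' @param tau_T triplet correlation time, s.
#' @return `G(tau)`.
#' @examples
#' model_g(c(1e-4, 1e-2), G0 = 0.5, tau_D = 1e-2)
#' @export
model_g <- function(tau, G0, tau_D, f = rep(1 / length(tau_D), length(tau_D)),
                    alpha = 1, Tt = 0, tau_T = 1e-5) {
  if (any(tau <= 0)) stop("tau must be > 0", call. = FALSE)
  if (any(tau_D <= 0)) stop("tau_D must be > 0", call. = FALSE)
  if (alpha <= 0 || alpha > 2) stop("alpha must be in (0, 2]", call. = FALSE)
  if (Tt < 0 || Tt >= 1) stop("triplet fraction must be in [0, 1)", call. = FALSE)
  if (abs(sum(f) - 1) > 1e-8) stop("component fractions must sum to 1",
                                   call. = FALSE)
  diff_part <- rowSums(matrix(vapply(seq_along(tau_D), function(i)
    f[i] / (1 + (tau / tau_D[i])^alpha), numeric(length(tau))),
    nrow = length(tau)))
  trip <- if (Tt > 0) 1 + Tt / (1 - Tt) * exp(-tau / tau_T) else 1
  G0 * trip * diff_part
}

#' Convert a transit time to a diffusion coefficient
#'
#' For 2D diffusion through a Gaussian spot, `D = w0^2 / (4 tau_D)` with
#' `w0` the calibrated 1/e^2 radius.
#'
#' @param tau_D transit time(s), s (> 0).
#' @param calibration a [spot_calibration()]; required, never defaulted.
#' @return Diffusion coefficient(s), um^2/s.
#' @examples
#' cal <- spot_calibration(fwhm = 250)
#' transit_to_D((cal$w0 / 1000)^2 / 4, cal)  # 1 um^2/s
#' @export
transit_to_D <- function(tau_D, calibration) {
  if (missing(calibration) || !inherits(calibration, "spot_calibration"))
    stop("a spot_calibration is required to convert transit times",
         call. = FALSE)
  if (any(tau_D <= 0)) stop("tau_D must be > 0", call. = FALSE)
  (calibration$w0 / 1000)^2 / (4 * tau_D)
}

#' Molecular brightness (counts per molecule)
#'
#' `cpm = <I> * G0 = <I> / N`: the mean detected intensity divided by the
#' mean number of molecules in the spot. Brightness is intensive — it does
#' not change with particle density.
#'
#' @param mean_intensity mean detected intensity (counts/s or a.u., >= 0).
#' @param fit an [fcs_fit()] result, or a plain `G0` amplitude.
#' @return Counts per molecule, same units as `mean_intensity`.
#' @export
counts_per_molecule <- function(mean_intensity, fit) {
  G0 <- if (inherits(fit, "fcs_fit")) coef(fit)[["G0"]] else fit
  if (!is.finite(G0) || G0 <= 0) stop("G0 must be > 0", call. = FALSE)
  if (mean_intensity < 0) stop("mean intensity must be >= 0", call. = FALSE)
  mean_intensity * G0
}
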