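#' Construct a scanning-FCS carpet
#'
#' A carpet is the pixels x scan-cycles intensity matrix produced by
#' repeatedly scanning a line across a membrane: each pixel is sampled once
#' per scan cycle, so every pixel row is an intensity trace at the line
#' frequency. Defaults mirror a typical confocal line-scan protocol: a
#' 5.2 um line of 52 pixels (100 nm pixels) scanned at 2081 Hz for 50 s.
#'
#' @param intensities pixels x cycles matrix of non-negative counts.
#' @param scan_frequency line repetition rate, Hz.
#' @param pixel_size pixel size along the line, nm.
#' @return An object of class `"sfcs_carpet"`: list with `intensities`,
#'   `n_pixels`, `pixel_size` (nm), `line_length` (um), `scan_frequency`
#'   (Hz), `duration` (s).
#' @export
sfcs_carpet <- function(intensities, scan_frequency = 2081, pixel_size = 100) {
  intensities <- as.matrix(intensities)
  if (any(!is.finite(intensities)) || any(intensities < 0))
    stop("carpet intensities must be finite and >= 0", call. = FALSE)
  if (scan_frequency <= 0) stop("scan_frequency must be > 0", call. = FALSE)
  structure(list(
    intensities = intensities, n_pixels = nrow(intensities),
    pixel_size = pixel_size,
    line_length = nrow(intensities) * pixel_size / 1000,
    scan_frequency = scan_frequency,
    duration = ncol(intensities) / scan_frequency
  ), class = "sfcs_carpet")
}

#' @export
print.sfcs_carpet <- function(x, ...) {
  cat(sprintf(
    "sFCS carpet: %d pixels (%.2f um line, %g nm px) x %d cycles @ %g Hz (%.1f s)\n",
    x$n_pixels, x$line_length, x$pixel_size, ncol(x$intensities),
    x$scan_frequency, x$duration))
  invisible(x)
}

#' Crop the initial seconds of a carpet
#'
#' Removes scan cycles within the first `crop_seconds` of the acquisition,
#' the standard guard against strong initial photobleaching (the protocol
#' crops the first 10 s of a 50 s acquisition).
#'
#' @param carpet an [sfcs_carpet()].
#' @param crop_seconds seconds to drop from the start (default 10).
#' @return The cropped carpet.
#' @export
crop_initial <- function(carpet, crop_seconds = 10) {
  stopifnot(inherits(carpet, "sfcs_carpet"))
  if (crop_seconds < 0) stop("crop_seconds must be >= 0", call. = FALSE)
  if (crop_seconds >= carpet$duration)
    stop("crop_seconds must be smaller than the carpet duration",
         call. = FALSE)
  drop_n <- floor(crop_seconds * carpet$scan_frequency)
  if (drop_n == 0) return(carpet)
  sfcs_carpet(carpet$intensities[, -seq_len(drop_n), drop = FALSE],
              carpet$scan_frequency, carpet$pixel_size)
}

# centred running mean; near the edges the window shrinks symmetrically,
# which keeps the trend unbiased (to first order) for monotone decays --
# a one-sided truncation would tilt the corrected trace at both ends
running_mean <- function(x, half) {
  n <- length(x)
  cs <- cumsum(c(0, x))
  w <- pmin(seq_len(n) - 1L, n - seq_len(n), half)
  lo <- seq_len(n) - w
  hi <- seq_len(n) + w
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Photobleaching correction by local averaging
#'
#' Per pixel, a moving-average intensity trend with the given window
#' (default 18 s) is computed and the trace corrected multiplicatively,
#' `I'(t) = I(t) * <I> / trend(t)`, flattening monotone bleaching decays; a
#' final rescale restores the original global mean exactly. Pixels whose
#' trend reaches zero cannot be corrected and are flagged (their rows are
#' returned unchanged; the flag is carried in the `excluded` attribute and
#' honoured by [analyze_carpet()]).
#'
#' @param carpet an [sfcs_carpet()] (crop first: the canonical order is
#'   crop, then bleach-correct, then correlate).
#' @param window_seconds trend window, s (default 18; must not exceed the
#'   carpet duration).
#' @return The corrected carpet, with an `excluded` attribute (logical per
#'   pixel).
#' @export
bleach_correct <- function(carpet, window_seconds = 18) {
  stopifnot(inherits(carpet, "sfcs_carpet"))
  if (window_seconds <= 0) stop("window_seconds must be > 0", call. = FALSE)
  if (window_seconds > carpet$duration)
    stop("bleach window exceeds the carpet duration", call. = FALSE)
  half <- max(1L, floor(window_seconds * carpet$scan_frequency / 2))
  M <- carpet$intensities
  excluded <- logical(nrow(M))
  for (p in seq_len(nrow(M))) {
    x <- M[p, ]
    trend <- running_mean(x, half)
    if (any(trend <= 0)) {
      excluded[p] <- TRUE
      next
    }
    y <- x * mean(x) / trend
    M[p, ] <- y * mean(x) / mean(y)
  }
  out <- sfcs_carpet(M, carpet$scan_frequency, carpet$pixel_size)
  attr(out, "excluded") <- excluded
  out
}

#' Correlate and fit every pixel of a carpet
#'
#' Each retained pixel row is autocorrelated (multi-tau) at the scan
#' frequency and fitted with the 2D one-component FCS model (no triplet, no
#' anomalous subdiffusion — the standard scanning-FCS choice). Transit times
#' and counts per molecule are pooled across pixels; pixels whose fit does
#' not converge are flagged, never silently dropped. More than 50% failing
#' pixels is a carpet-level failure.
#'
#' @param carpet a cropped, bleach-corrected [sfcs_carpet()].
#' @param calibration a [spot_calibration()] for transit-time to D
#'   conversion (optional).
#' @param points_per_octave correlator resolution.
#' @param bootstrap bootstrap rounds per pixel (default 0; the full protocol
#'   uses 10).
#' @param offset passed to [fcs_fit()]: fit a free baseline per pixel
#'   (useful for synthetic carpets from small closed simulation domains,
#'   whose conserved particle number depresses the long-lag correlation).
#' @return An object of class `"carpet_result"`: `fits` (per retained
#'   pixel), `curves`, `transit_ms` (pooled fitted transit times, ms), `cpm`
#'   (pooled counts per molecule), `D` (um^2/s, when calibrated), `qc`
#'   (per-pixel status: "ok", "excluded", "not_converged").
#' @export
analyze_carpet <- function(carpet, calibration = NULL,
                           points_per_octave = 16L, bootstrap = 0L,
                           offset = FALSE) {
  stopifnot(inherits(carpet, "sfcs_carpet"))
  excluded <- attr(carpet, "excluded")
  if (is.null(excluded)) excluded <- logical(carpet$n_pixels)
  dt <- 1 / carpet$scan_frequency
  qc <- character(carpet$n_pixels)
  fits <- curves <- vector("list", carpet$n_pixels)
  for (p in seq_len(carpet$n_pixels)) {
    if (excluded[p]) {
      qc[p] <- "excluded"
      next
    }
    tr <- intensity_trace(carpet$intensities[p, ], dt)
    crv <- try(autocorrelate(tr, points_per_octave), silent = TRUE)
    if (inherits(crv, "try-error")) {
      qc[p] <- "excluded"
      next
    }
    fit <- fcs_fit(crv, components = 1, anomalous = FALSE, triplet = FALSE,
                   calibration = calibration,
                   trace = if (bootstrap > 0) tr else NULL,
                   bootstrap = bootstrap,
                   points_per_octave = points_per_octave, offset = offset)
    curves[[p]] <- crv
    fits[[p]] <- fit
    qc[p] <- if (fit$converged) "ok" else "not_converged"
  }
  if (mean(qc != "ok") > 0.5)
    stop("more than 50% of carpet pixels failed correlation or fitting",
         call. = FALSE)
  ok <- qc == "ok"
  transit_ms <- vapply(fits[ok], function(f) 1000 * coef(f)[["tau_D1"]], 0)
  cpm <- vapply(fits[ok], function(f)
    if (is.null(f$cpm)) NA_real_ else f$cpm, 0)
  out <- list(fits = fits, curves = curves, transit_ms = transit_ms,
              cpm = cpm, qc = qc, calibration = calibration,
              pixels_ok = which(ok))
  if (!is.null(calibration))
    out$D <- transit_to_D(transit_ms / 1000, calibration)
  structure(out, class = "carpet_result")
}

#' @export
print.carpet_result <- function(x, ...) {
  cat(sprintf("sFCS carpet analysis: %d/%d pixels fitted\n",
              length(x$pixels_ok), length(x$qc)))
  cat(sprintf("  transit time (ms): median %.3g (IQR %.3g-%.3g)\n",
              median(x$transit_ms), quantile(x$transit_ms, 0.25),
              quantile(x$transit_ms, 0.75)))
  if (!is.null(x$D))
    cat(sprintf("  D (um^2/s): median %.3g\n", median(x$D)))
  if (any(is.finite(x$cpm)))
    cat(sprintf("  cpm: mean %.3g\n", mean(x$cpm, na.rm = TRUE)))
  invisible(x)
}

#' @export
summary.carpet_result <- function(object, ...) {
  print(object)
  tab <- table(object$qc)
  cat("  pixel QC: ", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(object)
}
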