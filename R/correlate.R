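#' Construct a correlation curve object
#'
#' @param lag strictly increasing lag times (s).
#' @param G normalized autocorrelation amplitudes,
#'   `G(tau) = <dI(t) dI(t+tau)> / <I>^2`.
#' @param sem optional per-lag uncertainty.
#' @param dt sampling interval of the source trace (s).
#' @param mean_intensity mean intensity of the source trace (carried for
#'   counts-per-molecule analysis).
#' @param n_samples source trace length.
#' @return An object of class `"fcs_curve"`: a data frame with columns
#'   `lag`, `G` (and `sem` when given) plus metadata attributes.
#' @export
fcs_curve <- function(lag, G, sem = NULL, dt = NA_real_,
                      mean_intensity = NA_real_, n_samples = NA_integer_) {
  if (length(lag) != length(G)) stop("lag and G differ in length", call. = FALSE)
  if (any(diff(lag) <= 0)) stop("lags must be strictly increasing", call. = FALSE)
  if (any(!is.finite(G))) stop("G must be finite", call. = FALSE)
  df <- data.frame(lag = lag, G = G)
  if (!is.null(sem)) df$sem <- sem
  structure(df, class = c("fcs_curve", "data.frame"), dt = dt,
            mean_intensity = mean_intensity, n_samples = n_samples)
}

check_trace <- function(trace) {
  if (!inherits(trace, "intensity_trace"))
    stop("expected an intensity_trace", call. = FALSE)
  x <- trace$values
  if (is.matrix(x)) stop("correlate one spot at a time", call. = FALSE)
  if (all(x == 0))
    stop("constant-zero trace: normalization <I>^2 is undefined", call. = FALSE)
  x
}

# symmetric normalization over the overlapping segment:
# G(k) = mean(x_t x_{t+k}) / (mean(x_t) mean(x_{t+k})) - 1
norm_corr_at <- function(x, k) {
  n <- length(x)
  a <- x[1:(n - k)]
  b <- x[(k + 1):n]
  mean(a * b) / (mean(a) * mean(b)) - 1
}

#' Multi-tau autocorrelation of an intensity trace
#'
#' Computes the normalized fluorescence autocorrelation
#' `G(tau) = <dI(t) dI(t+tau)> / <I>^2` on a quasi-logarithmic lag grid:
#' lags `1..2m` samples at full resolution, then the trace is binned by two
#' and lags `(m+1)..2m` evaluated at each coarser level until the trace is
#' exhausted (`m = points_per_octave`). Symmetric normalization (separate
#' means over the two overlapping segments) is used to reduce drift bias.
#'
#' @param trace an [intensity_trace()].
#' @param points_per_octave lags per doubling of the lag time (default 16).
#' @return An [fcs_curve()].
#' @examples
#' set.seed(1)
#' tr <- intensity_trace(rpois(4096, 10), dt = 1e-5)
#' head(autocorrelate(tr))
#' @export
autocorrelate <- function(trace, points_per_octave = 16L) {
  x <- check_trace(trace)
  m <- as.integer(points_per_octave)
  if (m < 1) stop("points_per_octave must be >= 1", call. = FALSE)
  if (length(x) < 2 * m)
    stop("trace shorter than 2 * points_per_octave", call. = FALSE)
  lag <- G <- numeric(0)
  cur <- x
  curdt <- trace$dt
  k_set <- seq_len(2 * m)
  repeat {
    k_set <- k_set[k_set < length(cur)]
    if (length(k_set) == 0) break
    G <- c(G, vapply(k_set, function(k) norm_corr_at(cur, k), 0))
    lag <- c(lag, k_set * curdt)
    nn <- 2 * (length(cur) %/% 2)
    if (nn < 2 * (m + 1)) break
    cur <- (cur[seq(1, nn, 2)] + cur[seq(2, nn, 2)]) / 2
    curdt <- curdt * 2
    k_set <- (m + 1):(2 * m)
  }
  fcs_curve(lag, G, dt = trace$dt, mean_intensity = mean(x),
            n_samples = length(x))
}

#' Direct (brute-force) autocorrelation
#'
#' Evaluates the exact normalized autocorrelation by direct summation at
#' every integer lag up to `max_lag`. O(N * max_lag); intended as the
#' testing oracle for [autocorrelate()] and for short traces.
#'
#' @param trace an [intensity_trace()].
#' @param max_lag maximum lag in samples (must be < trace length).
#' @return An [fcs_curve()].
#' @export
autocorrelate_direct <- function(trace, max_lag) {
  x <- check_trace(trace)
  max_lag <- as.integer(max_lag)
  if (max_lag < 1 || max_lag >= length(x))
    stop("max_lag must be in [1, length - 1]", call. = FALSE)
  ks <- seq_len(max_lag)
  G <- vapply(ks, function(k) norm_corr_at(x, k), 0)
  fcs_curve(ks * trace$dt, G, dt = trace$dt, mean_intensity = mean(x),
            n_samples = length(x))
}

#' Average correlation curves across repeats
#'
#' Pointwise mean of curves sharing one lag grid (e.g. independent
#' simulation runs or measurement repeats), with the standard error of the
#' mean attached per lag — the usual way to stabilise an FCS fit before
#' weighted least squares.
#'
#' @param curves list of [fcs_curve()] objects on identical lag grids.
#' @return An [fcs_curve()] with `sem` set (requires >= 2 curves).
#' @export
average_curves <- function(curves) {
  stopifnot(length(curves) >= 2, all(vapply(curves, inherits, TRUE, "fcs_curve")))
  lags <- curves[[1]]$lag
  for (crv in curves[-1])
    if (length(crv$lag) != length(lags) || any(crv$lag != lags))
      stop("curves are not on a common lag grid", call. = FALSE)
  G <- vapply(curves, function(crv) crv$G, numeric(length(lags)))
  fcs_curve(lags, rowMeans(G), sem = apply(G, 1, sd) / sqrt(ncol(G)),
            dt = attr(curves[[1]], "dt"),
            mean_intensity = mean(vapply(curves, attr, 0, "mean_intensity")),
            n_samples = attr(curves[[1]], "n_samples"))
}

#' @export
print.fcs_curve <- function(x, ...) {
  cat(sprintf("FCS correlation curve: %d lags from %.3g to %.3g s\n",
              nrow(x), min(x$lag), max(x$lag)))
  cat(sprintf("  G(first lag) = %.4f, mean intensity = %.4g\n",
              x$G[1], attr(x, "mean_intensity")))
  invisible(x)
}

#' @export
plot.fcs_curve <- function(x, ..., log = "x", xlab = "lag (s)",
                           ylab = expression(G(tau))) {
  plot(x$lag, x$G, log = log, xlab = xlab, ylab = ylab, ...)
  invisible(x)
}
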