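#' Seeded transit-time samples with known ground truth
#'
#' Draws i.i.d. transit times from a single log-normal law or a
#' two-component mixture. The single model is implemented as the `B = 1`
#' limit of the mixture code path, so single and `B = 1` double draws at the
#' same seed are bit-identical.
#'
#' @param n sample size (>= 1).
#' @param model `"single"` or `"double"`.
#' @param mu log-scale location(s) (log ms): length 1 (single) or 2 (double,
#'   component 1 first). `exp(mu)` is the median transit time in ms.
#' @param sigma log-scale width(s), recycled to the number of components.
#' @param B mixture fraction of component 1 (double model).
#' @param seed RNG seed.
#' @return Numeric vector of transit times (ms) with a `"ground_truth"`
#'   attribute (a [ground_truth_record()]).
#' @examples
#' t <- generate_transit_samples(1000, "single", mu = log(21), sigma = 0.3,
#'                               seed = 1)
#' median(t) # ~ 21 ms
#' @export
generate_transit_samples <- function(n, model = c("single", "double"),
                                     mu, sigma, B = 1, seed = 1L) {
  model <- match.arg(model)
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (model == "single") {
    mu <- rep(mu[1], 2)
    sigma <- rep(sigma[1], 2)
    B <- 1
  } else {
    if (length(mu) != 2) stop("double model needs two mu values", call. = FALSE)
    sigma <- rep(sigma, length.out = 2)
    if (B < 0 || B > 1) stop("mixture weight B must be in [0, 1]", call. = FALSE)
  }
  set.seed(seed)
  comp <- 1L + (runif(n) >= B)
  z <- rnorm(n)
  times <- exp(mu[comp] + sigma[comp] * z)
  attr(times, "ground_truth") <- ground_truth_record(
    "generate_transit_samples",
    params = list(n = n, model = model, mu = mu, sigma = sigma, B = B),
    seed = seed,
    expected = list(e_mu = exp(unique(mu)), sigma = sigma, B = B))
  times
}

#' Synthetic two-phase vesicle image
#'
#' Renders a phase-separated vesicle as a ring whose two angular halves have
#' different membrane intensities (upper half Lo, lower half Ld), with a
#' Gaussian radial cross-section standing in for the microscope's point
#' spread, optional additive Gaussian noise, and a second channel marking
#' the Ld half (a disordered-phase reference marker). The true %Lo from the
#' generating intensities is recorded.
#'
#' @param radius_px vesicle radius in pixels (>= 10).
#' @param I_lo,I_ld membrane intensity of the ordered / disordered half.
#' @param noise_sd additive Gaussian noise s.d. (same units as intensities).
#' @param ring_width radial Gaussian width of the membrane signal, px.
#' @param seed RNG seed.
#' @return List of class `"synthetic_vesicle"`: `image` (probe channel),
#'   `reference` (Ld marker channel), `center`, `radius_px`, and a
#'   `ground_truth` record carrying the true %Lo.
#' @export
generate_two_phase_vesicle <- function(radius_px = 40, I_lo = 60, I_ld = 40,
                                       noise_sd = 0, ring_width = 2,
                                       seed = 1L) {
  if (radius_px < 10) stop("radius_px must be >= 10", call. = FALSE)
  set.seed(seed)
  size <- 2 * radius_px + 21
  c0 <- (size + 1) / 2
  xs <- matrix(rep(seq_len(size), each = size), size)   # column index
  ys <- matrix(rep(seq_len(size), times = size), size)  # row index
  r <- sqrt((xs - c0)^2 + (ys - c0)^2)
  radial <- exp(-(r - radius_px)^2 / (2 * ring_width^2))
  upper <- ys < c0 # image rows above the centre: the Lo half
  img <- radial * ifelse(upper, I_lo, I_ld)
  ref <- radial * ifelse(upper, 0, 1)
  if (noise_sd > 0) img <- pmax(img + rnorm(size^2, 0, noise_sd), 0)
  truth <- 100 * I_lo / (I_lo + I_ld)
  structure(list(
    image = img, reference = ref, center = c(c0, c0), radius_px = radius_px,
    ground_truth = ground_truth_record(
      "generate_two_phase_vesicle",
      params = list(radius_px = radius_px, I_lo = I_lo, I_ld = I_ld,
                    noise_sd = noise_sd, ring_width = ring_width),
      seed = seed, expected = list(percent_lo = truth))
  ), class = "synthetic_vesicle")
}

#' Synthetic scanning-FCS carpet from the diffusion simulator
#'
#' Runs one Monte Carlo simulation and evaluates the Gaussian-spot detector
#' at `n_pixels` spot centres spaced `pixel_size` nm along a horizontal line
#' through the domain centre, once per scan cycle (the scan frequency). An
#' optional multiplicative exponential bleaching overlay (injected at the
#' detection stage, leaving the diffusion physics untouched) exercises
#' [bleach_correct()] against a recorded time constant.
#'
#' @param config a [sim_config()]; the line must fit inside the domain.
#' @param n_pixels pixels along the line (default 52).
#' @param pixel_size pixel spacing, nm (default 100).
#' @param scan_frequency line rate, Hz (default 2081).
#' @param bleach_tau optional bleaching time constant, s (`NULL` = none).
#' @return An [sfcs_carpet()] with a `ground_truth` attribute (true D, mode,
#'   bleach constant).
#' @export
generate_carpet <- function(config, n_pixels = 52L, pixel_size = 100,
                            scan_frequency = 2081, bleach_tau = NULL) {
  stopifnot(inherits(config, "sim_config"))
  line_um <- n_pixels * pixel_size / 1000
  if (line_um > config$domain_size)
    stop("the scan line (", line_um, " um) does not fit inside the ",
         config$domain_size, " um domain", call. = FALSE)
  stride <- max(1L, round(1 / (scan_frequency * config$dt)))
  xs <- (seq_len(n_pixels) - (n_pixels + 1) / 2) * pixel_size / 1000
  spots <- cbind(xs, 0)
  tr <- simulate_diffusion(config, spots = spots, sample_stride = stride)
  M <- t(tr$values) # pixels x cycles
  if (!is.null(bleach_tau)) {
    tt <- seq_len(ncol(M)) * stride * config$dt
    M <- sweep(M, 2, exp(-tt / bleach_tau), `*`)
  }
  out <- sfcs_carpet(M, scan_frequency = 1 / (stride * config$dt),
                     pixel_size = pixel_size)
  attr(out, "ground_truth") <- ground_truth_record(
    "generate_carpet",
    params = list(config = unclass(config), n_pixels = n_pixels,
                  pixel_size = pixel_size, scan_frequency = scan_frequency,
                  bleach_tau = bleach_tau),
    seed = config$seed,
    expected = list(D = config$D, mode = config$mode))
  out
}

#' Ground-truth provenance record for a synthetic dataset
#'
#' Captures everything needed to regenerate a synthetic dataset
#' bit-identically (generator, parameters, seed) together with the
#' downstream quantities the generator promises (true D, true mu/sigma/B,
#' true %Lo). Stored as an attribute on every generated object and written
#' as sidecar JSON by [write_ground_truth()].
#'
#' @param generator generator function name.
#' @param params generating parameters.
#' @param seed RNG seed used.
#' @param expected named list of expected downstream quantities.
#' @return An object of class `"ground_truth_record"`.
#' @export
ground_truth_record <- function(generator, params, seed, expected) {
  structure(list(generator = generator, params = params,
                 seed = as.integer(seed), expected = expected,
                 package_version = as.character(utils::packageVersion("lipidfcs"))),
            class = "ground_truth_record")
}

#' @export
print.ground_truth_record <- function(x, ...) {
  cat(sprintf("Ground truth record: %s (seed %d)\n", x$generator, x$seed))
  cat("  expected:", paste(names(x$expected), vapply(x$expected, function(v)
    paste(signif(unlist(v), 4), collapse = "/"), ""), sep = "=",
    collapse = ", "), "\n")
  invisible(x)
}

#' Write / read a ground-truth sidecar JSON
#'
#' @param record a [ground_truth_record()].
#' @param path JSON file path.
#' @return `read_ground_truth` returns the reconstructed record.
#' @export
write_ground_truth <- function(record, path) {
  stopifnot(inherits(record, "ground_truth_record"))
  jsonlite::write_json(unclass(record), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(x, class = "ground_truth_record")
}
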