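#' Configure a membrane diffusion simulation
#'
#' Builds and validates the parameter set for the particle Monte Carlo
#' simulator. The defaults are the conditions of the simulation study the
#' package reproduces: 350 particles moved every 1 microsecond with a
#' microscopic diffusion coefficient of 1 um^2/s for 20 s on a 3 um domain,
#' probed by a 250 nm (FWHM) Gaussian spot. Trapped diffusion uses symmetric
#' per-step trap/untrap probabilities of 5e-5; hop diffusion uses a Voronoi
#' meshwork with a 110 nm characteristic mesh size (square root of the mean
#' compartment area) and a boundary-crossing probability of 0.05.
#'
#' @param n_particles number of particles (>= 1).
#' @param D microscopic diffusion coefficient in um^2/s.
#' @param dt time step in seconds.
#' @param duration total simulated time in seconds.
#' @param domain_size domain extent in um (side of the periodic square, or
#'   diameter of the circular domain).
#' @param domain_shape `"square"` for a periodic square (torus, the default)
#'   or `"circle"` for a circular domain with antipodal re-entry.
#' @param spot_size observation-spot size in nm, interpreted per
#'   `spot_convention`.
#' @param spot_convention `"fwhm"` (default; converted to a 1/e^2 radius
#'   w0 = FWHM / sqrt(2 log 2)) or `"waist"` (spot_size is w0 directly).
#' @param mode diffusion mode: `"free"`, `"trapped"` or `"hop"`.
#' @param p_trap,p_untrap per-step trapping / release probabilities
#'   (trapped mode).
#' @param p_hop probability that a step crossing a compartment boundary is
#'   accepted (hop mode).
#' @param mesh_size characteristic compartment size in nm, defined as the
#'   square root of the mean compartment area (hop mode).
#' @param seed RNG seed used by [simulate_diffusion()].
#' @param photon_noise if `TRUE`, detected intensities are Poisson-sampled.
#' @param count_rate mean detected count rate (counts/s) of one particle at
#'   the spot centre, used only when `photon_noise = TRUE`.
#'
#' @return An object of class `"sim_config"`.
#' @examples
#' cfg <- sim_config(duration = 0.01)
#' cfg
#' @export
sim_config <- function(n_particles = 350L, D = 1, dt = 1e-6, duration = 20,
                       domain_size = 3, domain_shape = c("square", "circle"),
                       spot_size = 250, spot_convention = c("fwhm", "waist"),
                       mode = c("free", "trapped", "hop"),
                       p_trap = 5e-5, p_untrap = 5e-5, p_hop = 0.05,
                       mesh_size = 110, seed = 1L,
                       photon_noise = FALSE, count_rate = 1e5) {
  domain_shape <- match.arg(domain_shape)
  spot_convention <- match.arg(spot_convention)
  mode <- match.arg(mode)
  if (!is.numeric(n_particles) || n_particles < 1)
    stop("n_particles must be >= 1", call. = FALSE)
  if (!is.numeric(D) || D < 0) stop("D must be >= 0", call. = FALSE)
  if (!is.numeric(dt) || dt <= 0) stop("dt must be > 0", call. = FALSE)
  if (!is.numeric(duration) || duration <= 0)
    stop("duration must be > 0", call. = FALSE)
  if (domain_size <= 0) stop("domain_size must be > 0", call. = FALSE)
  if (spot_size <= 0) stop("spot_size must be > 0", call. = FALSE)
  for (p in c(p_trap = p_trap, p_untrap = p_untrap, p_hop = p_hop))
    if (p < 0 || p > 1)
      stop("p_trap, p_untrap and p_hop must lie in [0, 1]", call. = FALSE)
  if (mode == "hop") {
    if (mesh_size <= 0) stop("mesh_size must be > 0 in hop mode", call. = FALSE)
    if (mesh_size / 1000 >= domain_size)
      stop("mesh_size must be smaller than the domain", call. = FALSE)
  }
  structure(list(
    n_particles = as.integer(n_particles), D = D, dt = dt, duration = duration,
    domain_size = domain_size, domain_shape = domain_shape,
    spot_size = spot_size, spot_convention = spot_convention, mode = mode,
    p_trap = p_trap, p_untrap = p_untrap, p_hop = p_hop,
    mesh_size = mesh_size, seed = as.integer(seed),
    photon_noise = isTRUE(photon_noise), count_rate = count_rate
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Membrane diffusion simulation config\n")
  cat(sprintf("  mode: %s | %d particles | D = %g um^2/s\n",
              x$mode, x$n_particles, x$D))
  cat(sprintf("  dt = %g s | duration = %g s (%s steps)\n",
              x$dt, x$duration, format(round(x$duration / x$dt), big.mark = ",")))
  cat(sprintf("  domain: %g um %s | spot %g nm (%s -> w0 = %.1f nm)\n",
              x$domain_size, x$domain_shape, x$spot_size, x$spot_convention,
              1000 * spot_w0(x)))
  if (x$mode == "trapped")
    cat(sprintf("  p_trap = %g, p_untrap = %g\n", x$p_trap, x$p_untrap))
  if (x$mode == "hop")
    cat(sprintf("  mesh = %g nm, p_hop = %g\n", x$mesh_size, x$p_hop))
  invisible(x)
}

# 1/e^2 radius in um implied by the configured spot size and convention
spot_w0 <- function(config) {
  w_nm <- switch(config$spot_convention,
                 fwhm = config$spot_size / sqrt(2 * log(2)),
                 waist = config$spot_size)
  w_nm / 1000
}
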