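#' Initialise a particle ensemble
#'
#' Particles are placed uniformly at random in the domain, untrapped, at
#' time 0. In hop mode a mesh must be supplied (or is built from the config)
#' and compartment ids are assigned by the nearest-seed rule.
#'
#' @param config a [sim_config()].
#' @param mesh a [voronoi_mesh()] (hop mode); built from the config if `NULL`.
#' @return An object of class `"particle_state"`: `positions` (wrapped, um),
#'   `unwrapped` (cumulative true displacement, um), `trapped` (logical),
#'   `cells` (integer or NA), `time` (s), `mesh`.
#' @export
particle_state <- function(config, mesh = NULL) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_particles
  L <- config$domain_size
  if (config$domain_shape == "square") {
    pos <- cbind(runif(n, -L / 2, L / 2), runif(n, -L / 2, L / 2))
  } else {
    pos <- matrix(NA_real_, 0, 2)
    while (nrow(pos) < n) {
      cand <- cbind(runif(n, -L / 2, L / 2), runif(n, -L / 2, L / 2))
      pos <- rbind(pos, cand[rowSums(cand^2) <= (L / 2)^2, , drop = FALSE])
    }
    pos <- pos[seq_len(n), , drop = FALSE]
  }
  cells <- rep(NA_integer_, n)
  if (config$mode == "hop") {
    if (is.null(mesh))
      mesh <- voronoi_mesh(L, config$mesh_size, config$domain_shape)
    cells <- mesh_cell(mesh, pos)
  }
  structure(list(positions = pos, unwrapped = pos, trapped = rep(FALSE, n),
                 cells = cells, time = 0, mesh = mesh),
            class = "particle_state")
}

mode_code <- function(mode) match(mode, c("free", "trapped", "hop")) - 1L

# shared driver behind the step_* helpers and simulate_diffusion
advance_state <- function(state, config, n_steps, mode = config$mode,
                          spots = NULL, sample_stride = 0L, traj_stride = 0L) {
  stopifnot(inherits(state, "particle_state"))
  if (config$D < 0 || config$dt <= 0)
    stop("D must be >= 0 and dt > 0", call. = FALSE)
  seeds <- if (!is.null(state$mesh)) state$mesh$seeds else
    matrix(numeric(0), 0, 2)
  if (mode == "hop" && nrow(seeds) == 0)
    stop("hop mode requires a mesh; use particle_state(config, mesh)",
         call. = FALSE)
  if (is.null(spots)) spots <- matrix(numeric(0), 0, 2)
  if (is.null(dim(spots))) spots <- matrix(spots, ncol = 2)
  cells <- state$cells
  cells[is.na(cells)] <- -1L
  res <- sim_core(state$positions, as.numeric(t(state$unwrapped)),
                  state$trapped, cells,
                  config$D, config$dt, as.integer(n_steps),
                  config$domain_size,
                  if (config$domain_shape == "square") 0L else 1L,
                  mode_code(mode), config$p_trap, config$p_untrap,
                  config$p_hop, seeds, spots, spot_w0(config),
                  as.integer(sample_stride), as.integer(traj_stride),
                  config$photon_noise,
                  config$count_rate * config$dt * sample_stride)
  new_state <- structure(list(
    positions = res$positions, unwrapped = res$unwrapped,
    trapped = res$trapped, cells = res$cells,
    time = state$time + n_steps * config$dt, mesh = state$mesh
  ), class = "particle_state")
  list(state = new_state, raw = res)
}

#' Advance an ensemble by free Brownian steps
#'
#' Each untrapped particle is displaced by independent per-axis Gaussian
#' increments of standard deviation `sqrt(2 * D * dt)`; positions are wrapped
#' back into the domain.
#'
#' @param state a [particle_state()].
#' @param config a [sim_config()].
#' @param n_steps number of time steps to advance.
#' @return The updated `particle_state`.
#' @export
step_free <- function(state, config, n_steps = 1L)
  advance_state(state, config, n_steps, mode = "free")$state

#' Advance an ensemble with transient trapping
#'
#' Before displacement each mobile particle is trapped with probability
#' `p_trap` and each trapped particle released with probability `p_untrap`
#' (independent Bernoulli draws every step); trapped particles do not move
#' but remain fluorescent. A newly released particle moves in the same step.
#'
#' @inheritParams step_free
#' @return The updated `particle_state`.
#' @export
step_trapped <- function(state, config, n_steps = 1L)
  advance_state(state, config, n_steps, mode = "trapped")$state

#' Advance an ensemble with meshwork (hop) hindrance
#'
#' A proposed free step that would change the particle's Voronoi compartment
#' is accepted with probability `p_hop` and otherwise rejected (the particle
#' stays put for that step — the "bounce off" approximation);
#' intra-compartment moves are always accepted.
#'
#' @inheritParams step_free
#' @return The updated `particle_state`.
#' @export
step_hop <- function(state, config, n_steps = 1L)
  advance_state(state, config, n_steps, mode = "hop")$state

#' Gaussian-spot fluorescence detection
#'
#' The detected intensity is `sum_i exp(-2 r_i^2 / w0^2)` over particles,
#' where `r_i` is the (minimum-image, on the periodic domain) distance of
#' particle i to the spot centre and `w0` the 1/e^2 radius implied by the
#' configured spot size. Contributions beyond `3 w0` (< 2e-8 of the peak)
#' are truncated. Trapped particles contribute like mobile ones.
#'
#' @param positions n x 2 matrix of particle positions (um), or a
#'   `particle_state`.
#' @param spot_center length-2 centre of the observation spot (um).
#' @param config a [sim_config()] providing the spot size/convention and
#'   domain; Poisson noise is applied when `config$photon_noise` is `TRUE`
#'   (mean `intensity * count_rate * dt`).
#' @return A single intensity value (a.u., or counts under photon noise).
#' @export
detect_intensity <- function(positions, spot_center = c(0, 0), config) {
  if (inherits(positions, "particle_state")) positions <- positions$positions
  if (nrow(positions) == 0) return(0)
  w0 <- spot_w0(config)
  d <- sweep(positions, 2, spot_center)
  if (config$domain_shape == "square") {
    L <- config$domain_size
    d <- d - L * round(d / L)
  }
  r2 <- rowSums(d^2)
  val <- sum(exp(-2 * r2[r2 < 9 * w0^2] / w0^2))
  if (config$photon_noise) val <- rpois(1, val * config$count_rate * config$dt)
  val
}

#' Run a membrane diffusion simulation
#'
#' Runs the configured Monte Carlo simulation and returns the fluorescence
#' intensity sampled at the spot centre every `sample_stride` time steps.
#' Deterministic for a fixed `config$seed`.
#'
#' @param config a [sim_config()].
#' @param spots spot centres (m x 2 matrix, um); default a single spot at the
#'   domain centre.
#' @param sample_stride record the intensity every this many steps (1 =
#'   every step, the default).
#' @param trajectories if `TRUE`, unwrapped particle trajectories are
#'   recorded every `traj_stride` steps and attached (for mean-squared
#'   displacement analysis).
#' @param traj_stride step stride for trajectory recording.
#' @param max_samples guard against accidental huge traces: configurations
#'   whose trace would exceed this many samples are refused.
#' @return An object of class `"intensity_trace"`: list with `values`
#'   (numeric vector, or samples x spots matrix when `length(spots) > 2`),
#'   `dt` (sampling interval, s), `config`, `n_trapped` (per-sample trapped
#'   count) and optionally `traj` (particles x 2 x times array of unwrapped
#'   positions) and `traj_time`.
#' @examples
#' cfg <- sim_config(n_particles = 50, duration = 5e-4, seed = 7)
#' tr <- simulate_diffusion(cfg)
#' length(tr$values)
#' @export
simulate_diffusion <- function(config, spots = c(0, 0), sample_stride = 1L,
                               trajectories = FALSE, traj_stride = 1000L,
                               max_samples = 5e7) {
  stopifnot(inherits(config, "sim_config"))
  n_steps <- round(config$duration / config$dt)
  sample_stride <- as.integer(sample_stride)
  n_samp <- if (sample_stride > 0) floor(n_steps / sample_stride) else 0L
  if (n_samp > max_samples)
    stop("trace would contain ", n_samp, " samples (> max_samples guard); ",
         "increase sample_stride or raise max_samples", call. = FALSE)
  set.seed(config$seed)
  state <- particle_state(config)
  res <- advance_state(state, config, n_steps, spots = spots,
                       sample_stride = sample_stride,
                       traj_stride = if (trajectories) traj_stride else 0L)
  vals <- res$raw$intensity
  if (ncol(vals) <= 1) vals <- drop(vals)
  out <- list(values = vals, dt = config$dt * sample_stride, config = config,
              n_trapped = res$raw$n_trapped, final_state = res$state)
  if (trajectories) {
    out$traj <- res$raw$traj
    out$traj_time <- res$raw$traj_time
  }
  structure(out, class = "intensity_trace")
}

#' Construct an intensity trace from values
#'
#' @param values non-negative finite intensities (length >= 2).
#' @param dt sampling interval in seconds.
#' @param meta optional origin metadata.
#' @return An `"intensity_trace"`.
#' @export
intensity_trace <- function(values, dt, meta = NULL) {
  values <- as.numeric(values)
  if (length(values) < 2) stop("a trace needs at least 2 samples", call. = FALSE)
  if (any(!is.finite(values)) || any(values < 0))
    stop("intensities must be finite and >= 0", call. = FALSE)
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  structure(list(values = values, dt = dt, meta = meta),
            class = "intensity_trace")
}

#' @export
print.intensity_trace <- function(x, ...) {
  v <- if (is.matrix(x$values)) x$values else matrix(x$values, ncol = 1)
  cat(sprintf(
    "Intensity trace: %d samples x %d spot(s), dt = %g s (%.3g s total)\n",
    nrow(v), ncol(v), x$dt, nrow(v) * x$dt))
  cat(sprintf("  mean intensity %.3f, max %.3f\n", mean(v), max(v)))
  invisible(x)
}

#' Ensemble mean-squared displacement from recorded trajectories
#'
#' @param trace an `"intensity_trace"` from [simulate_diffusion()] with
#'   `trajectories = TRUE`.
#' @return Data frame with `time` (s, relative to the start) and `msd`
#'   (um^2), computed against the initial positions.
#' @export
msd_from_trace <- function(trace) {
  if (is.null(trace$traj))
    stop("simulate_diffusion() was not run with trajectories = TRUE",
         call. = FALSE)
  tr <- trace$traj # particles x 2 x times
  d <- sweep(tr, c(1, 2), tr[, , 1])
  msd <- apply(d^2, 3, function(m) mean(m[, 1] + m[, 2]))
  data.frame(time = trace$traj_time, msd = msd)
}
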