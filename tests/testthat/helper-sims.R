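# Shared simulation products, memoised so expensive runs happen once per
# test session regardless of which test file touches them first.

.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .sim_cache))
    assign(key, force(expr), envir = .sim_cache)
  get(key, envir = .sim_cache)
}

# study-condition curves (350 particles, 1 us steps, 3 um domain, 250 nm
# spot; duration reduced to 2 s for desk scale)
study_curves <- function(mode, seeds, duration = 2) {
  cached(paste0("curves-", mode, "-", duration, "-",
                paste(seeds, collapse = "_")), {
    lapply(seeds, function(s) {
      cfg <- sim_config(duration = duration, mode = mode, seed = s)
      autocorrelate(simulate_diffusion(cfg))
    })
  })
}

study_calibration <- function() spot_calibration(fwhm = 250)

# small homogeneous synthetic carpet (compact domain: box artifacts are
# shared across pixels, so per-pixel estimator spread is isolated)
small_carpet <- function(seed = 41, D = 1, bleach_tau = NULL) {
  cached(paste0("carpet-", seed, "-", D, "-", paste(bleach_tau, collapse = "")), {
    cfg <- sim_config(n_particles = 150, D = D, dt = 1e-5, duration = 10,
                      domain_size = 2, mode = "free", seed = seed)
    generate_carpet(cfg, n_pixels = 16, pixel_size = 100,
                    scan_frequency = 2081, bleach_tau = bleach_tau)
  })
}

# carpet at the study's domain and density, for absolute-D recovery
study_carpet <- function(seed = 41) {
  cached(paste0("study-carpet-", seed), {
    cfg <- sim_config(n_particles = 350, D = 1, dt = 1e-5, duration = 10,
                      domain_size = 3, mode = "free", seed = seed)
    generate_carpet(cfg, n_pixels = 16, pixel_size = 100,
                    scan_frequency = 2081)
  })
}
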