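test_that("config validation rejects unphysical parameters", {
  expect_error(sim_config(D = -1), "D must be")
  expect_error(sim_config(dt = 0), "dt must be")
  expect_error(sim_config(n_particles = 0), "n_particles")
  expect_error(sim_config(mode = "trapped", p_trap = 1.5), "p_trap")
  expect_error(sim_config(mode = "hop", mesh_size = 4000), "mesh_size")
})

test_that("zero diffusion leaves positions unchanged", {
  cfg <- sim_config(n_particles = 100, D = 0, dt = 1e-6, duration = 1e-3,
                    seed = 1)
  set.seed(1)
  st <- particle_state(cfg)
  st2 <- step_free(st, cfg, n_steps = 50)
  expect_identical(st2$positions, st$positions)
  expect_equal(st2$time, 50 * cfg$dt)
})

test_that("free steps have per-axis sd sqrt(2 D dt)", {
  cfg <- sim_config(n_particles = 20000, D = 1, dt = 1e-6, duration = 1,
                    seed = 2)
  set.seed(2)
  st <- particle_state(cfg)
  st2 <- step_free(st, cfg, n_steps = 1)
  d <- st2$unwrapped - st$unwrapped
  target <- sqrt(2 * cfg$D * cfg$dt) # 1.414e-3 um
  expect_equal(target, 1.414214e-3, tolerance = 1e-6)
  for (ax in 1:2) {
    se <- target / sqrt(2 * nrow(d)) # se of an sd estimate
    expect_lt(abs(sd(d[, ax]) - target), 3 * se)
  }
})

test_that("ensemble MSD is linear with slope 4 D in free mode", {
  cfg <- sim_config(n_particles = 4000, D = 1, dt = 1e-5, duration = 0.02,
                    seed = 3)
  tr <- simulate_diffusion(cfg, trajectories = TRUE, traj_stride = 100,
                           sample_stride = 2000)
  m <- msd_from_trace(tr)
  D_hat <- msd_D(m)
  # relative se of a squared-displacement mean is ~ 1/sqrt(n)
  expect_lt(abs(D_hat - 1), 3 / sqrt(cfg$n_particles))
  # linearity: a quadratic term adds nothing beyond noise
  q <- lm(msd ~ time + I(time^2), m)
  expect_gt(summary(q)$coefficients["I(time^2)", "Pr(>|t|)"], 0.001)
})

test_that("trapping follows the two-state Markov stationary distribution", {
  # symmetric rates -> 1/2; asymmetric -> p_trap / (p_trap + p_untrap)
  for (ps in list(c(0.002, 0.002, 0.5), c(0.004, 0.002, 2 / 3))) {
    cfg <- sim_config(n_particles = 3000, D = 1, dt = 1e-6, duration = 1,
                      mode = "trapped", p_trap = ps[1], p_untrap = ps[2],
                      seed = 4)
    set.seed(4)
    st <- particle_state(cfg)
    st <- step_trapped(st, cfg, n_steps = 6000) # >> relaxation time
    frac <- mean(st$trapped)
    expect_lt(abs(frac - ps[3]),
              3 * sqrt(ps[3] * (1 - ps[3]) / cfg$n_particles) + 0.01)
  }
})

test_that("p_trap = 0 reproduces the free trajectory at the same seed", {
  cfg <- sim_config(n_particles = 200, D = 1, dt = 1e-6, duration = 1,
                    mode = "trapped", p_trap = 0, p_untrap = 0, seed = 5)
  set.seed(5); st <- particle_state(cfg)
  set.seed(99); a <- step_trapped(st, cfg, n_steps = 200)
  set.seed(99); b <- step_free(st, cfg, n_steps = 200)
  expect_identical(a$positions, b$positions)
})

test_that("trapped particles hold their positions and stay detectable", {
  cfg <- sim_config(n_particles = 100, D = 1, dt = 1e-6, duration = 1,
                    mode = "trapped", p_trap = 1, p_untrap = 0, seed = 6)
  set.seed(6)
  st <- particle_state(cfg)
  st1 <- step_trapped(st, cfg, n_steps = 1)
  st2 <- step_trapped(st1, cfg, n_steps = 25)
  expect_true(all(st1$trapped))
  expect_identical(st1$positions, st2$positions)
  expect_gt(detect_intensity(st2, c(0, 0), cfg), 0)
})

test_that("trapped mode halves the long-time diffusion at symmetric rates", {
  cfg <- sim_config(n_particles = 600, D = 1, dt = 1e-6, duration = 0.3,
                    mode = "trapped", seed = 7) # p_trap = p_untrap = 5e-5
  tr <- simulate_diffusion(cfg, trajectories = TRUE, traj_stride = 3000,
                           sample_stride = 0)
  m <- msd_from_trace(tr)
  late <- m[m$time > 0.1, ] # beyond the 20 ms trap relaxation
  D_late <- msd_D(late)
  expect_lt(abs(D_late - 0.5), 0.1)
})

test_that("hop mode with p_hop = 1 matches free diffusion statistically", {
  base <- list(n_particles = 2000, D = 1, dt = 1e-6, duration = 0.01)
  cfg_h <- do.call(sim_config, c(base, mode = "hop", p_hop = 1, seed = 8))
  cfg_f <- do.call(sim_config, c(base, mode = "free", seed = 8))
  Dh <- msd_D(msd_from_trace(simulate_diffusion(
    cfg_h, trajectories = TRUE, traj_stride = 100, sample_stride = 0)))
  Df <- msd_D(msd_from_trace(simulate_diffusion(
    cfg_f, trajectories = TRUE, traj_stride = 100, sample_stride = 0)))
  se <- 3 / sqrt(base$n_particles)
  expect_lt(abs(Dh - Df), 2 * se)
  expect_lt(abs(Dh - 1), se)
})

test_that("impermeable mesh confines the MSD to the compartment scale", {
  cfg <- sim_config(n_particles = 1000, D = 1, dt = 1e-6, duration = 0.02,
                    mode = "hop", p_hop = 0, seed = 9)
  tr <- simulate_diffusion(cfg, trajectories = TRUE, traj_stride = 200,
                           sample_stride = 0)
  m <- msd_from_trace(tr)
  mesh_um2 <- (cfg$mesh_size / 1000)^2
  expect_lt(tail(m$msd, 1), mesh_um2)        # plateau below mesh_size^2
  expect_gt(tail(m$msd, 1), 0.1 * mesh_um2)  # but at the compartment scale
  # plateau: last quarter grows much slower than free diffusion would
  late <- m[m$time > 0.015, ]
  expect_lt(msd_D(late), 0.15)
})

test_that("hindered modes suppress the apparent long-time diffusion", {
  base <- list(n_particles = 800, D = 1, dt = 1e-6, duration = 0.05)
  for (mode in c("trapped", "hop")) {
    cfg <- do.call(sim_config, c(base, mode = mode, seed = 10))
    m <- msd_from_trace(simulate_diffusion(
      cfg, trajectories = TRUE, traj_stride = 500, sample_stride = 0))
    late <- m[m$time > 0.025, ]
    expect_lt(msd_D(late), 1)
  }
})

test_that("domain conservation holds at every sampled step", {
  cfg <- sim_config(n_particles = 500, D = 5, dt = 1e-5, duration = 0.01,
                    seed = 11)
  set.seed(11)
  st <- particle_state(cfg)
  for (i in 1:5) {
    st <- step_free(st, cfg, n_steps = 200)
    expect_equal(nrow(st$positions), 500)
    expect_true(all(abs(st$positions) <= cfg$domain_size / 2))
  }
})

test_that("identical config and seed give bit-identical traces", {
  cfg <- sim_config(n_particles = 80, duration = 2e-3, mode = "trapped",
                    p_trap = 0.01, p_untrap = 0.01, seed = 12)
  t1 <- simulate_diffusion(cfg)
  t2 <- simulate_diffusion(cfg)
  expect_identical(t1$values, t2$values)
  cfg$seed <- 13L
  t3 <- simulate_diffusion(cfg)
  expect_false(identical(t1$values, t3$values))
})

test_that("trace length and memory guard behave as documented", {
  cfg <- sim_config(n_particles = 5, duration = 1e-5, dt = 1e-6, seed = 14)
  tr <- simulate_diffusion(cfg)
  expect_length(tr$values, 10)
  cfg2 <- sim_config(n_particles = 5, duration = 10, dt = 1e-6, seed = 14)
  expect_error(simulate_diffusion(cfg2, max_samples = 1e6), "max_samples")
})

test_that("circular domain keeps particles inside the radius", {
  cfg <- sim_config(n_particles = 400, D = 5, dt = 1e-4, duration = 0.1,
                    domain_shape = "circle", seed = 15)
  set.seed(15)
  st <- particle_state(cfg)
  st <- step_free(st, cfg, n_steps = 1000)
  expect_true(all(rowSums(st$positions^2) <= (cfg$domain_size / 2)^2 + 1e-12))
})
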