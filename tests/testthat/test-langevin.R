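# Small but statistically controlled simulations: every tolerance below is
# a multiple of the Monte-Carlo standard error reported by the estimator.

kB <- phys_constants$k_B

quick_cfg <- function(B = 0, seed = 1L, n_steps = 6000L,
                      n_particles = 150L, dt_frac = 0.4, ...) {
  m <- 6e-21; xi_t <- 1.5e-10
  langevin_config(m = m, I_rot = 2e-37, xi_t = xi_t, xi_r = 1e-26,
                  T_b = 300, B = B, dt = dt_frac * m / xi_t,
                  n_steps = n_steps, n_particles = n_particles,
                  seed = seed, ...)
}

test_that("fixed seeds reproduce trajectories bit for bit", {
  t1 <- simulate_langevin(quick_cfg(B = 1e-21, seed = 9L, n_steps = 500L,
                                    n_particles = 8L))
  t2 <- simulate_langevin(quick_cfg(B = 1e-21, seed = 9L, n_steps = 500L,
                                    n_particles = 8L))
  expect_identical(t1$positions, t2$positions)
  expect_identical(t1$velocities, t2$velocities)
  expect_identical(t1$orientations, t2$orientations)
  t3 <- simulate_langevin(quick_cfg(B = 1e-21, seed = 10L, n_steps = 500L,
                                    n_particles = 8L))
  expect_false(identical(t1$positions, t3$positions))
})

test_that("orientations stay unit vectors", {
  tr <- simulate_langevin(quick_cfg(n_steps = 800L, n_particles = 20L))
  nrm <- sqrt(tr$orientations[, , 1]^2 + tr$orientations[, , 2]^2 +
              tr$orientations[, , 3]^2)
  expect_lt(max(abs(nrm - 1)), 1e-9)
})

test_that("equipartition holds thermally and grows linearly with B", {
  kT <- kB * 300
  for (Bfac in c(0, 1)) {
    tr <- simulate_langevin(quick_cfg(B = Bfac * kT, seed = 21L))
    ke <- kinetic_energy(tr)
    target <- (kT + Bfac * kT) / 2
    expect_lt(abs(ke$per_axis - target), 3 * ke$se)
    expect_equal(ke$total, 3 * ke$per_axis)
  }
})

test_that("doubling the mass halves the velocity variance", {
  cfg1 <- quick_cfg(seed = 31L)
  tr1 <- simulate_langevin(cfg1)
  m2 <- 2 * cfg1$m
  cfg2 <- langevin_config(m = m2, I_rot = cfg1$I_rot, xi_t = cfg1$xi_t,
                          xi_r = cfg1$xi_r, T_b = cfg1$T_b, B = 0,
                          dt = cfg1$dt, n_steps = cfg1$n_steps,
                          n_particles = cfg1$n_particles, seed = 31L)
  tr2 <- simulate_langevin(cfg2)
  v1 <- mean(tr1$velocities^2)
  v2 <- mean(tr2$velocities^2)
  expect_equal(v2 / v1, 0.5, tolerance = 0.05)
})

test_that("passive MSD recovers the Einstein relation", {
  cfg <- quick_cfg(seed = 41L, n_steps = 12000L, n_particles = 250L,
                   store_every = 2L)
  tr <- simulate_langevin(cfg)
  t0 <- cfg$m / cfg$xi_t
  est <- msd_diffusivity(tr, t_min = 20 * t0, t_max = 300 * t0)
  D0 <- kB * cfg$T_b / cfg$xi_t
  expect_lt(abs(est$D_est - D0), 0.05 * D0)
})

test_that("the ballistic regime shows quadratic displacement growth", {
  cfg <- quick_cfg(seed = 51L, n_steps = 4000L, n_particles = 200L,
                   dt_frac = 0.05, store_every = 1L)
  tr <- simulate_langevin(cfg)
  t0 <- cfg$m / cfg$xi_t
  # mean-square displacement at lags well inside the inertial time
  lag_idx <- 1:4
  msd <- vapply(lag_idx, function(L) {
    d <- tr$positions[, (L + 1):length(tr$times), , drop = FALSE] -
         tr$positions[, 1:(length(tr$times) - L), , drop = FALSE]
    mean(d^2)
  }, numeric(1))
  slope <- log_slope(lag_idx * cfg$dt, msd)
  expect_equal(unname(slope), 2, tolerance = 0.1)
})

test_that("orientation decorrelation follows rotational diffusion", {
  m <- 6e-21; xi_t <- 1.5e-10
  I_rot <- 2e-37; xi_r <- 1e-26
  tau_rot <- xi_r / (2 * kB * 300)  # 1/(2 D_r)
  dt <- 0.4 * m / xi_t
  cfg <- langevin_config(m = m, I_rot = I_rot, xi_t = xi_t, xi_r = xi_r,
                         T_b = 300, B = 0, dt = dt,
                         n_steps = as.integer(round(8 * tau_rot / dt)),
                         n_particles = 200L, seed = 61L,
                         store_every = max(1L, as.integer(
                           round(tau_rot / dt / 50))))
  tr <- simulate_langevin(cfg)
  oc <- orientation_decorrelation(tr)
  expect_equal(oc$tau_est / oc$tau_theory, 1, tolerance = 0.1)
  # doubling the rotational noise (halving friction) halves the decay time
  cfg2 <- langevin_config(m = m, I_rot = I_rot, xi_t = xi_t,
                          xi_r = xi_r / 2, T_b = 300, B = 0, dt = dt,
                          n_steps = cfg$n_steps, n_particles = 200L,
                          seed = 62L, store_every = cfg$store_every)
  oc2 <- orientation_decorrelation(simulate_langevin(cfg2))
  expect_equal(oc2$tau_est / oc$tau_est, 0.5, tolerance = 0.15)
})

test_that("active particles show no net drift", {
  kT <- kB * 300
  tr <- simulate_langevin(quick_cfg(B = 2 * kT, seed = 71L,
                                    n_steps = 8000L, n_particles = 200L))
  nt <- length(tr$times)
  disp <- tr$positions[, nt, ] - tr$positions[, 1, ]
  se <- apply(disp, 2, stats::sd) / sqrt(nrow(disp))
  for (ax in 1:3)
    expect_lt(abs(mean(disp[, ax])), 3 * se[ax])
})

test_that("configuration invariants are enforced", {
  m <- 6e-21; xi_t <- 1.5e-10
  expect_error(quick_cfg(dt_frac = 1.2), "inertial")
  expect_error(langevin_config(m = m, I_rot = 1e-37, xi_t = xi_t,
                               xi_r = 1e-26, T_b = 300, B = -1,
                               dt = 1e-11, n_steps = 100L, seed = 1L),
               "'B'")
  expect_error(langevin_config(m = m, I_rot = 1e-37, xi_t = xi_t,
                               xi_r = 1e-26, T_b = 300,
                               dt = 1e-11, n_steps = 100L),
               "seed")
})

test_that("the isotropic noise convention triples the energy scale", {
  kT <- kB * 300
  tr <- simulate_langevin(quick_cfg(seed = 81L,
                                    noise_convention = "isotropic_6"))
  ke <- kinetic_energy(tr)
  expect_lt(abs(ke$per_axis - 3 * kT / 2), 3 * ke$se)
})
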