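test_that("no chemical activity means no excess energy on either route", {
  p <- with_groups(base_params(), 0, 0.2)
  g <- compute_dimensionless_groups(p)
  f <- solve_all(p)
  b <- energy_from_fields(p, g, f)
  for (t in c("e_reaction", "e_entropic", "e_electro", "e_diffusio",
              "e_thermo", "total_nd"))
    expect_identical(b[[t]], 0)
  d <- dissipative_energy(p, g, f, tau = 1)
  for (t in c("d_mixing", "d_diffusion", "d_heat", "d_reaction",
              "d_viscous", "total_d"))
    expect_identical(d[[t]], 0)
})

test_that("neutral species carry no electrostatic excess energy", {
  p <- base_params(z_M = 0, z_N = 0)
  p <- with_groups(p, 1, 0.2)
  g <- compute_dimensionless_groups(p)
  b <- energy_from_fields(p, g, solve_all(p))
  expect_identical(b$e_electro, 0)
})

test_that("totals are exact sums and magnitude respects the route", {
  p <- with_groups(base_params(), 1.5, 0.3)
  g <- compute_dimensionless_groups(p)
  f <- solve_all(p)
  b <- energy_from_fields(p, g, f)
  expect_equal(b$total_nd, b$e_reaction + b$e_entropic + b$e_electro +
                 b$e_diffusio + b$e_thermo)
  d <- dissipative_energy(p, g, f)
  expect_equal(d$total_d, d$d_mixing + d$d_diffusion + d$d_heat +
                 d$d_reaction + d$d_viscous)
  expect_equal(total_excess_energy(b, "nd"), abs(b$total_nd))
  expect_equal(total_excess_energy(d, "d"), abs(d$total_d))
  # exact cancellation of a constructed pentad
  bz <- activejanus:::new_energy_breakdown()
  bz$e_reaction <- 1; bz$e_entropic <- -1
  bz$total_nd <- 0
  expect_identical(total_excess_energy(bz, "nd"), 0)
})

test_that("sign flips propagate exactly through the linear terms", {
  p <- with_groups(base_params(), 0.8, 0.2)
  g <- compute_dimensionless_groups(p)
  f <- solve_all(p)
  b <- energy_from_fields(p, g, f)
  # thermophoretic term flips with gamma_T
  pf <- unclass(p); pf$gamma_T <- -p$gamma_T
  bf <- energy_from_fields(activejanus:::validate_physical_params(pf), g, f)
  expect_equal(bf$e_thermo, -b$e_thermo)
  # reaction term flips with the thermochemical combination
  pr <- unclass(p); pr$dH_r <- -p$dH_r; pr$dmu_r0 <- -p$dmu_r0
  br <- energy_from_fields(activejanus:::validate_physical_params(pr), g, f)
  expect_equal(br$e_reaction, -b$e_reaction)
})

test_that("every nondissipative term is proportional to the surface area", {
  p <- with_groups(base_params(), 0.5, 0.1)
  g <- compute_dimensionless_groups(p)
  f <- solve_all(p)
  b1 <- energy_from_fields(p, g, f)
  # double A = 4 pi R^2 at fixed dimensionless groups: rescale R by sqrt(2)
  # and compensate the kinetic/transport fields that would change groups
  pl <- unclass(p)
  s <- sqrt(2)
  pl$R <- s * p$R
  pl$k_r <- p$k_r          # alpha2 = k_r R^2/D_s: compensate via D_s
  pl$D_s <- p$D_s * 2
  pl$U <- p$U
  pl$U_q <- p$U_q / s      # omega2 = U_q R / kappa
  pl$kappa <- p$kappa      # lambda2 = R^2 |dH| k_r C0/(kappa T0)
  pl$dH_r <- p$dH_r / 2
  pl$xi2_prefactor <- p$xi2_prefactor / 2
  pl$C0 <- p$C0            # U scaling: beta2 = U R^2/D_s ok with D_s * 2
  pl$U <- p$U
  p2 <- activejanus:::validate_physical_params(pl)
  g2 <- compute_dimensionless_groups(p2)
  for (nm in c("alpha2", "beta2", "lambda2", "omega2", "xi2"))
    expect_equal(g2[[nm]], g[[nm]], info = nm)
  f2 <- solve_surface_fields(g2, f$grid)
  b2 <- energy_from_fields(p2, g2, f2)
  # (e_reaction is excluded: keeping lambda2 fixed under the rescaling
  # required altering dH_r, which e_reaction depends on directly)
  for (t in c("e_entropic", "e_electro", "e_diffusio", "e_thermo"))
    expect_equal(b2[[t]], 2 * b1[[t]], tolerance = 1e-10, info = t)
})

test_that("parameter/field mismatch is rejected", {
  p <- with_groups(base_params(), 0.5, 0.1)
  g <- compute_dimensionless_groups(p)
  f <- solve_all(p)
  p2 <- with_groups(base_params(), 0.7, 0.1)
  g2 <- compute_dimensionless_groups(p2)
  expect_error(energy_from_fields(p2, g2, f), "mismatch")
})

test_that("nonpositive mole fractions on the cap are rejected", {
  p <- with_groups(base_params(), 0.5, 0.1)
  g <- compute_dimensionless_groups(p)
  f <- solve_all(p)
  f$Chat_N[which(cap_weights(f$grid, g$phi0) > 0)[1]] <- 0
  expect_error(dissipative_energy(p, g, f), "mole fraction")
})

test_that("closed forms track quadrature term-wise in the weak limit", {
  for (preset in c("case1_janus_nano", "case2_vesicle")) {
    p <- with_groups(load_preset(preset), 1e-4, 1e-4)
    g <- compute_dimensionless_groups(p)
    bq <- energy_from_fields(p, g, solve_all(p, n = 512L))
    bc <- energy_closed_form(p, g)
    for (t in c("e_reaction", "e_entropic", "e_electro", "e_diffusio",
                "e_thermo"))
      expect_lt(abs(bc[[t]] / bq[[t]] - 1), 0.05,
                label = paste(preset, t))
  }
})

test_that("closed forms warn outside their validity range", {
  p <- load_preset("case2_vesicle")  # alpha2 ~ 3
  expect_warning(energy_closed_form(p), "validity")
  expect_silent(energy_closed_form(p, override = TRUE))
})

test_that("reaction dissipation grows quadratically with activity", {
  p <- load_preset("case2_vesicle")
  c0s <- exp(seq(log(1e-7), log(1e-5), length.out = 7))
  grid <- azimuthal_grid(128)
  drx <- vapply(c0s, function(c0) {
    pt <- activejanus:::pipeline_point(p, c0, grid, "d")
    abs(pt$breakdown_d$d_reaction)
  }, numeric(1))
  mCs <- p$k_r * c0s  # <C_M> proportional to C0; slope in C0 == slope in <C_M>
  expect_equal(unname(log_slope(c0s, drx)), 2, tolerance = 0.05)
})

test_that("chemical-reaction dissipation dominates at the nanoscale", {
  p <- load_preset("case1_janus_nano")
  c0g <- preset_sweep_grid("case1_janus_nano", n = 5)
  grid <- azimuthal_grid(128)
  for (c0 in c0g) {
    d <- activejanus:::pipeline_point(p, c0, grid, "d")$breakdown_d
    expect_gt(abs(d$d_reaction), 10 * abs(d$d_diffusion))
    expect_gt(abs(d$d_reaction), 10 * abs(d$d_heat))
    expect_gt(abs(d$d_reaction), 10 * abs(d$d_viscous))
  }
})
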