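test_that("no-reaction limit relaxes every field to the bath", {
  p <- with_groups(base_params(), 0, 0.1)
  f <- solve_all(p)
  expect_equal(f$Chat_M, rep(1, f$grid$n))
  expect_equal(f$Chat_N, rep(0, f$grid$n))
  g <- f$groups
  expect_identical(g$lambda2, 0)  # lambda2 carries k_r
  expect_equal(f$That, rep(1, f$grid$n))
})

test_that("degenerate substrate problem is rejected", {
  p <- with_groups(base_params(), 0, 0)
  g <- compute_dimensionless_groups(p)
  expect_error(solve_substrate(g, azimuthal_grid(64)), "degenerate")
})

test_that("discrete production balance holds to solver accuracy", {
  # integrating the product equation over the periodic domain kills the
  # derivative term: beta2 <C_N> = alpha2 * cap-mean(C_M)
  for (ab in list(c(1e-4, 1e-4), c(0.5, 0.1), c(3, 0.12))) {
    p <- with_groups(base_params(), ab[1], ab[2])
    g <- compute_dimensionless_groups(p)
    f <- solve_all(p)
    w <- cap_weights(f$grid, g$phi0)
    capmean_M <- mean(w * f$Chat_M)
    expect_equal(g$beta2 * mean(f$Chat_N), g$alpha2 * capmean_M,
                 tolerance = 1e-7)
    # substrate balance: consumption equals resupply
    expect_equal(g$alpha2 * capmean_M,
                 g$beta2 * (1 - mean(f$Chat_M)), tolerance = 1e-7)
  }
})

test_that("surface mean approaches the weak-coupling closed form", {
  for (ab in c(1e-3, 1e-4)) {
    p <- with_groups(base_params(), ab, ab)
    f <- solve_all(p)
    cf <- mean_substrate_closed_form(compute_dimensionless_groups(p))
    tol <- if (ab == 1e-3) 1e-2 else 1e-3
    expect_lt(abs(f$mean_Chat_M / cf - 1), tol)
  }
})

test_that("profiles are mirror symmetric for a symmetric cap", {
  p <- with_groups(base_params(), 2, 0.3)
  f <- solve_all(p, n = 256L)
  # node j and node n+2-j are at +-phi (node 1 sits at -pi)
  idx <- 2:f$grid$n
  mirror <- function(x) max(abs(x[idx] - rev(x[idx]))) / max(abs(x), 1e-300)
  expect_lt(mirror(f$Chat_M), 1e-8)
  expect_lt(mirror(f$Chat_N), 1e-8)
  expect_lt(mirror(f$That), 1e-8)
  expect_lt(mirror(f$psihat), 1e-8)
})

test_that("fields obey linearity and superposition", {
  p <- with_groups(base_params(), 1.5, 0.2)
  g <- compute_dimensionless_groups(p)
  grid <- azimuthal_grid(128)
  CM <- solve_substrate(g, grid)
  # temperature response is linear in lambda2
  g2 <- g; g2$lambda2 <- 2 * g$lambda2
  T1 <- solve_temperature(g, grid, CM)
  T2 <- solve_temperature(g2, grid, CM)
  expect_equal(attr(T2, "deviation"), 2 * attr(T1, "deviation"),
               tolerance = 1e-12)
  # potential flips exactly with all charges
  CN <- solve_product(g, grid, CM)
  gflip <- g; gflip$z_M <- -g$z_M; gflip$z_N <- -g$z_N
  psi1 <- solve_potential(g, grid, CM, CN)
  psi2 <- solve_potential(gflip, grid, CM, CN)
  expect_equal(as.numeric(psi2), -as.numeric(psi1), tolerance = 1e-12)
  # neutral species produce no potential
  g0 <- g; g0$z_M <- 0; g0$z_N <- 0
  expect_equal(as.numeric(solve_potential(g0, grid, CM, CN)),
               rep(0, grid$n))
})

test_that("potential gauge is zero-mean with recorded projection", {
  p <- with_groups(base_params(), 1, 0.2)
  f <- solve_all(p)
  expect_lt(abs(mean(f$psihat)), 1e-12 * max(abs(f$psihat)))
  expect_true(is.finite(f$psihat_offset))
})

test_that("discretization converges at second order to a refined solve", {
  p <- with_groups(base_params(), 1e-4, 1e-4)
  g <- compute_dimensionless_groups(p)
  f_ref <- solve_surface_fields(g, azimuthal_grid(2048))
  ref_on <- function(x) x[seq(1, 2048, by = 2048 %/% 256)]
  f <- solve_surface_fields(g, azimuthal_grid(256))
  relerr <- function(a, b) max(abs(a - b)) / max(abs(b))
  # 8x refinement oracle: coarse solution within 1e-6 relative; the
  # temperature deviation carries an extra factor 1/omega2 on its mean and
  # converges at the same order but from a larger constant
  expect_lt(relerr(f$Chat_M, ref_on(f_ref$Chat_M)), 1e-6)
  expect_lt(relerr(f$Chat_N, ref_on(f_ref$Chat_N)), 1e-6)
  expect_lt(relerr(f$That, ref_on(f_ref$That)), 1e-5)
  expect_lt(relerr(f$That_dev, ref_on(f_ref$That_dev)), 1e-3)
  # order of convergence measured on a well-conditioned problem (at tiny
  # alpha2, beta2 the refinement pair sits below the linear-solve roundoff
  # floor, so the order is unobservable there)
  pw <- with_groups(base_params(), 2, 0.4)
  gw <- compute_dimensionless_groups(pw)
  fw_ref <- solve_surface_fields(gw, azimuthal_grid(2048))
  fw1 <- solve_surface_fields(gw, azimuthal_grid(256))
  fw2 <- solve_surface_fields(gw, azimuthal_grid(512))
  e1 <- max(abs(fw1$Chat_N - fw_ref$Chat_N[seq(1, 2048, by = 8)]))
  e2 <- max(abs(fw2$Chat_N - fw_ref$Chat_N[seq(1, 2048, by = 4)]))
  order <- log2(e1 / e2)
  expect_gt(order, 1.7)
})

test_that("temperature rises above the bath for an exothermic source", {
  p <- with_groups(base_params(), 1, 0.3)
  f <- solve_all(p)
  expect_true(all(f$That >= 1 - 1e-15))
  expect_gt(max(f$That_dev), 0)
})

test_that("mean reaction rate follows k_r C0 <C_M> and its limits", {
  p0 <- with_groups(base_params(), 0, 0.1)
  expect_equal(mean_reaction_rate(p0, solve_all(p0)), 0)
  p <- with_groups(base_params(), 1e-3, 1e-3)
  f <- solve_all(p)
  g <- compute_dimensionless_groups(p)
  expect_equal(mean_reaction_rate(p, f),
               p$k_r * p$C0 * g$beta2 / (g$alpha2 + g$beta2),
               tolerance = 1e-3)
  # monotone increasing in C0 (linear map)
  p2 <- load_preset("case2_vesicle")
  c0s <- c(1e-7, 1e-6, 1e-5)
  rdots <- vapply(c0s, function(c0) {
    pt <- activejanus:::pipeline_point(p2, c0, azimuthal_grid(128), "nd")
    pt$rdot
  }, numeric(1))
  expect_true(all(diff(rdots) > 0))
})

test_that("grid and cap-weight contracts hold", {
  expect_error(azimuthal_grid(32), ">= 64")
  grid <- azimuthal_grid(256)
  expect_equal(mean(diff(grid$phi)), grid$h)
  w <- cap_weights(grid, pi / 2)
  expect_equal(mean(w), 1)
  # midpoint convention: the two edge nodes carry half weight (before
  # normalization they are half of the interior value)
  edge <- which(abs(abs(grid$phi) - pi / 2) < 1e-12)
  interior <- which(abs(grid$phi) < pi / 2 - 1e-12)
  expect_length(edge, 2L)
  expect_equal(w[edge[1]] * 2, w[interior[1]])
  # grid mismatch rejection
  p <- with_groups(base_params(), 1, 0.2)
  g <- compute_dimensionless_groups(p)
  CM <- solve_substrate(g, grid)
  expect_error(solve_product(g, azimuthal_grid(128), CM), "mismatch")
})
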