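# Shared fixtures: parameter sets are always built in code.

# A generic, well-conditioned parameter set (vesicle-like scales).
base_params <- function(...) {
  overrides <- list(...)
  args <- list(
    C0 = 0.5, T0 = 300, k_r = 50, D_s = 4e-10, eta_s = 1e-3, U = 10,
    dH_r = -50e3, dmu_r0 = -20e3, kappa = 0.6, U_q = 0.01,
    eps_thick = 1e-8, z_M = 1, z_N = -1,
    gamma_CM = 1e-7, gamma_CN = 5e-8, gamma_T = -1e-4,
    D0 = 1e-12, R = 1e-6, w0 = 0.5
  )
  args[names(overrides)] <- overrides
  do.call(physical_params, args)
}

# Override kinetics/exchange so that the reaction-diffusion and exchange
# numbers take prescribed values while every energetic parameter is kept.
with_groups <- function(p, alpha2, beta2) {
  pl <- unclass(p)
  pl$k_r <- alpha2 * p$D_s / p$R^2
  pl$U <- beta2 * p$D_s / p$R^2
  activejanus:::validate_physical_params(pl)
}

solve_all <- function(p, n = 256L) {
  g <- compute_dimensionless_groups(p)
  solve_surface_fields(g, azimuthal_grid(n))
}

log_slope <- function(x, y) {
  stats::coef(stats::lm(log(abs(y)) ~ log(x)))[2]
}
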