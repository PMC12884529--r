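# Surface excess energy: quadrature route over solved interfacial fields.
#
# All surface functionals are reduced to the azimuth. Two operators appear:
#   <f>            -- plain surface mean, mean(f)
#   P[f g']        -- axial projection of a gradient functional,
#                     (1/2pi) Int f(phi) g'(phi) (n.phi_hat) dphi
# with n the particle orientation pointing from the catalytic to the
# noncatalytic side, so that n.phi_hat = +sin(phi) for a cap centred on
# phi = 0. For a closed periodic surface the unprojected mean of a
# gradient vanishes identically; the axial projection is the component of
# the surface integral of the tangential gradient along the symmetry axis,
# which is the quantity that survives for a Janus-symmetric field and the
# one the excess-energy functional is built from.

axial_projection <- function(f, dg, grid) {
  mean(f * dg * sin(grid$phi))
}

# G[f] = P[1 * f'] evaluated in the numerically robust by-parts form; the
# mean of f is removed first (a constant projects to zero analytically,
# and removing it suppresses roundoff when the profile is 1 + tiny).
axial_gradient_mean <- function(f, grid) {
  -mean((f - mean(f)) * cos(grid$phi))
}

new_energy_breakdown <- function() {
  structure(list(
    e_reaction = 0, e_entropic = 0, e_electro = 0, e_diffusio = 0,
    e_thermo = 0, total_nd = 0,
    d_mixing = 0, d_diffusion = 0, d_heat = 0, d_reaction = 0,
    d_viscous = 0, total_d = 0, tau = NA_real_
  ), class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat("<energy_breakdown> (J)\n")
  cat(sprintf("  nd: reaction %.4g | entropic %.4g | electro %.4g | ",
              x$e_reaction, x$e_entropic, x$e_electro))
  cat(sprintf("diffusio %.4g | thermo %.4g | total %.4g\n",
              x$e_diffusio, x$e_thermo, x$total_nd))
  cat(sprintf("  d : mixing %.4g | diffusion %.4g | heat %.4g | ",
              x$d_mixing, x$d_diffusion, x$d_heat))
  cat(sprintf("reaction %.4g | viscous %.4g | total %.4g (tau = %.3g s)\n",
              x$d_reaction, x$d_viscous, x$total_d, x$tau))
  invisible(x)
}

check_fields_params <- function(p, g, f) {
  stopifnot(inherits(f, "surface_fields"))
  gf <- f$groups
  for (nm in c("alpha2", "beta2", "lambda2", "omega2", "xi2")) {
    if (abs(gf[[nm]] - g[[nm]]) >
        1e-9 * max(abs(g[[nm]]), .Machine$double.eps))
      stop("parameter/field mismatch: fields were solved for a different '",
           nm, "'", call. = FALSE)
  }
  invisible(TRUE)
}

# Composition reference scale for mole fractions: x_i = C_i / C_ref with
# C_ref = C0_ref / w0. C0_ref defaults to the parameter set's bulk
# concentration; sweep_activity() keeps it pinned at the nominal (preset)
# concentration while C0 is varied, so that mole fractions remain tied to
# the physical composition of the experiment rather than to the sweep
# variable.
c_ref <- function(p) {
  c0ref <- if (!is.null(p$C0_ref)) p$C0_ref else p$C0
  c0ref / p$w0
}

#' Nondissipative surface excess energy from solved fields
#'
#' Evaluates the five contributions to the surface excess energy by
#' quadrature of the interfacial-energy balance over the solved azimuthal
#' profiles: reaction (enthalpy + standard free energy advected by the
#' extent-of-reaction gradient), entropic (ideal mixing term), electrostatic
#' (charge-weighted potential-gradient coupling), diffusiophoretic
#' (surface-tension sensitivity to concentration) and thermophoretic
#' (surface-tension sensitivity to temperature):
#' \deqn{E_s^{(e)} = -A(\Delta H_r + \Delta\mu_r^0)\langle\nabla_S \xi\rangle
#'  + A R_g \sum_i \langle T \ln x_i \nabla_S \Gamma_i\rangle
#'  + A F \sum_i z_i \langle \psi \nabla_S \Gamma_i \rangle
#'  - A \sum_i \gamma_{C_i}\langle\nabla_S C_i\rangle
#'  - A \gamma_T \langle\nabla_S T\rangle,}
#' with surface concentrations \eqn{\Gamma_i = \epsilon C_i} (interface
#' thickness times volumetric concentration) and the extent-of-reaction
#' gradient identified with the product surface-concentration gradient.
#' The standard chemical potentials reduce exactly to the reaction free
#' energy because substrate + product relax to a uniform profile.
#'
#' @param p A [physical_params()] object.
#' @param g The `dimensionless_groups` the fields were solved with.
#' @param f A [solve_surface_fields()] result.
#' @return An `energy_breakdown` with the nondissipative terms and
#'   `total_nd` populated (dissipative slots zero).
#' @export
energy_from_fields <- function(p, g, f) {
  p <- validate_physical_params(p)
  check_fields_params(p, g, f)
  b <- new_energy_breakdown()
  if (g$alpha2 == 0) return(b)

  grid <- f$grid
  A <- 4 * pi * p$R^2
  eps <- p$eps_thick
  RgT0 <- phys_constants$R_g * p$T0

  GM <- axial_gradient_mean(f$Chat_M, grid)
  GN <- axial_gradient_mean(f$Chat_N, grid)
  GT <- axial_gradient_mean(f$That_dev, grid)

  # reaction: -(dH_r + dmu_r0) * <grad xi>, grad xi = eps C0 grad Chat_N
  b$e_reaction <- -A * eps * p$C0 * (p$dH_r + p$dmu_r0) * GN

  # entropic: Rg sum_i <T ln(x_i) grad Gamma_i>, x_i = C_i / C_ref
  xM <- p$C0 * f$Chat_M / c_ref(p)
  xN <- p$C0 * f$Chat_N / c_ref(p)
  lnxM <- ifelse(xM > 0, log(pmax(xM, .Machine$double.xmin)), 0)
  lnxN <- ifelse(xN > 0, log(pmax(xN, .Machine$double.xmin)), 0)
  b$e_entropic <- A * eps * p$C0 * phys_constants$R_g * p$T0 *
    (axial_projection(f$That * lnxM, f$grad_Chat_M, grid) +
     axial_projection(f$That * lnxN, f$grad_Chat_N, grid))

  # electrostatic: F sum_i z_i <psi grad Gamma_i>; F * (k_B T0/q0) = R_g T0
  b$e_electro <- A * eps * p$C0 * RgT0 *
    (p$z_M * axial_projection(f$psihat, f$grad_Chat_M, grid) +
     p$z_N * axial_projection(f$psihat, f$grad_Chat_N, grid))

  # diffusiophoretic: -sum_i gamma_Ci <grad C_i> (volumetric sensitivity)
  b$e_diffusio <- -A * p$C0 * (p$gamma_CM * GM + p$gamma_CN * GN)

  # thermophoretic: -gamma_T <grad T>
  b$e_thermo <- -A * p$gamma_T * p$T0 * GT

  b$total_nd <- b$e_reaction + b$e_entropic + b$e_electro +
    b$e_diffusio + b$e_thermo
  b
}

#' Dissipative surface excess energy from solved fields
#'
#' Entropy-route evaluation: the dissipative surface energy over one
#' characteristic time `tau` is the mixing-entropy flux plus the integrated
#' entropy production,
#' \deqn{E_s^{(d)}/\tau = -R_g \sum_i \langle T \dot R_i \ln x_i\rangle
#'   + \langle T\sigma\rangle,}
#' with local reaction rates \eqn{\dot R_N = -\dot R_M = k_r C_M
#' \tilde\Theta} and the entropy-production density assembled from the
#' standard bilinear flux-force forms: Fickian interface diffusion
#' \eqn{\sum_i R_g D_s (\nabla_S C_i)^2 / C_i}, Fourier heat conduction
#' \eqn{\kappa(\nabla_S T)^2/T^2}, linear-response reaction dissipation
#' \eqn{R_g \dot R^2/(k_r C_{ref})}, and a Marangoni viscous term
#' \eqn{(\nabla_S\gamma)^2/\eta_s} (closed form in the solved gradients; no
#' surface velocity field is modeled). Activity coefficients are ideal.
#'
#' @param p A [physical_params()] object.
#' @param g The `dimensionless_groups` the fields were solved with.
#' @param f A [solve_surface_fields()] result.
#' @param tau Characteristic time in s; defaults to [characteristic_time()].
#' @return An `energy_breakdown` with the dissipative terms and `total_d`
#'   populated.
#' @export
dissipative_energy <- function(p, g, f, tau = characteristic_time(p)) {
  p <- validate_physical_params(p)
  check_fields_params(p, g, f)
  b <- new_energy_breakdown()
  if (g$alpha2 == 0) return(b)   # no activity: all terms zero, tau unused
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau <= 0)
    stop("tau must be a single positive number", call. = FALSE)
  b$tau <- tau

  grid <- f$grid
  A <- 4 * pi * p$R^2
  eps <- p$eps_thick
  Rg <- phys_constants$R_g
  w <- cap_weights(grid, g$phi0)

  # mole fractions on the reactive cap must be positive for ln x_i
  onc <- w > 0
  if (any(f$Chat_M[onc] <= 0) || any(f$Chat_N[onc] <= 0)) {
    bad <- which(onc & (f$Chat_M <= 0 | f$Chat_N <= 0))[1]
    stop("nonpositive mole fraction under the composition mapping at node ",
         bad, " (phi = ", signif(grid$phi[bad], 4), ")", call. = FALSE)
  }

  Tdim <- p$T0 * f$That
  Rdot_loc <- p$k_r * p$C0 * w * f$Chat_M   # product formation, mol/(m^3 s)

  # mixing: -Rg sum_i <T Rdot_i ln x_i> = -Rg <T Rdot (ln x_N - ln x_M)>,
  # measured as the excess over the surface-mean composition (ln x_i
  # relative to ln xbar_i): the uniform-background mixing flux is not part
  # of the asymmetry-driven surface excess, and with this reference the
  # term inherits the gradient suppression of weakly nonuniform interfaces
  lnratio <- ifelse(onc, log(pmax(f$Chat_N, .Machine$double.xmin) /
                             pmax(f$Chat_M, .Machine$double.xmin)), 0)
  lnratio_ref <- log(max(mean(f$Chat_N), .Machine$double.xmin) /
                     max(mean(f$Chat_M), .Machine$double.xmin))
  b$d_mixing <- -tau * A * eps * Rg *
    mean(Tdim * Rdot_loc * (lnratio - lnratio_ref))

  # diffusion: sum_i Rg D_s (grad_S C_i)^2 / C_i, grad_S = (1/R) d/dphi
  sq_over <- function(grad, val) ifelse(val > 1e-300, grad^2 / val, 0)
  sigma_diff <- Rg * p$D_s * (p$C0 / p$R^2) *
    (sq_over(f$grad_Chat_M, f$Chat_M) + sq_over(f$grad_Chat_N, f$Chat_N))
  b$d_diffusion <- tau * A * eps * mean(Tdim * sigma_diff)

  # heat conduction: kappa (grad_S T)^2 / T^2; times T -> kappa grad^2 / T
  b$d_heat <- tau * A * eps * p$kappa * (p$T0 / p$R^2) *
    mean(f$grad_That^2 / f$That)

  # reaction (linear-response bilinear form): T sigma_r = Rg T Rdot^2 /
  # (k_r C_ref), with the Onsager coefficient fixed by first-order kinetics
  b$d_reaction <- tau * A * eps * Rg *
    mean(Tdim * Rdot_loc^2) / (p$k_r * c_ref(p))

  # Marangoni viscous closed form: (grad_S gamma)^2 / eta_s, including the
  # electrocapillary stress -q_s grad_S psi with q_s = F eps C0 sum z Chat
  kT0_q0 <- phys_constants$k_B * p$T0 / phys_constants$q0
  grad_gamma <- (p$C0 * (p$gamma_CM * f$grad_Chat_M +
                         p$gamma_CN * f$grad_Chat_N) +
                 p$gamma_T * p$T0 * f$grad_That) / p$R
  q_s <- phys_constants$F * eps * p$C0 * (p$z_M * f$Chat_M +
                                          p$z_N * f$Chat_N)
  grad_psi <- kT0_q0 * f$grad_psihat / p$R
  b$d_viscous <- tau * A * eps *
    mean((grad_gamma - q_s * grad_psi)^2) / p$eta_s

  b$total_d <- b$d_mixing + b$d_diffusion + b$d_heat +
    b$d_reaction + b$d_viscous
  b
}

#' Magnitude of the total surface excess energy
#'
#' The diffusivity enhancement is driven by the absolute value of the
#' signed sum of the per-mechanism contributions; cancellations between
#' mechanisms (sign changes of the total across an activity sweep) happen
#' before the absolute value is taken.
#'
#' @param b An `energy_breakdown`.
#' @param route `"nd"` (nondissipative) or `"d"` (dissipative).
#' @return `|E_s|` in J.
#' @export
total_excess_energy <- function(b, route = c("nd", "d")) {
  route <- match.arg(route)
  stopifnot(inherits(b, "energy_breakdown"))
  abs(if (route == "nd") b$total_nd else b$total_d)
}

#' Export one or more energy breakdowns as CSV
#'
#' @param breakdowns A single `energy_breakdown` or a list of them.
#' @param path Output CSV path.
#' @return The exported data frame, invisibly.
#' @export
export_energy_csv <- function(breakdowns, path) {
  if (inherits(breakdowns, "energy_breakdown")) breakdowns <- list(breakdowns)
  out <- do.call(rbind, lapply(breakdowns, function(b)
    as.data.frame(unclass(b))))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
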